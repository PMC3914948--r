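# Synthetic coordinate and topology fixtures.
#
# Coordinate fixtures are idealized A-form geometry built from the
# standard-frame base templates: each Watson-Crick step applies a 32.7
# degree twist and 2.81 Angstrom rise, and the complementary base is the
# template rotated 180 degrees about the pair dyad (x axis).  These are
# standard A-form constants; the fixtures are synthetic stand-ins for
# crystal structures so every stage of the pipeline is testable offline.

.aform_twist <- 32.7     # degrees per step
.aform_rise <- 2.81      # Angstrom per step

.rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
.flip_x <- diag(c(1, -1, -1))

.complement <- c(A = "U", U = "A", G = "C", C = "G")

# atoms of `base` placed at helical step k (1-based); strand2 flips
# about the dyad first.  Extra offset displaces the whole residue.
.place_base <- function(base, step, strand2 = FALSE, offset = c(0, 0, 0)) {
  m <- .template_coords[[base]]
  if (strand2) m <- m %*% t(.flip_x)
  m <- m %*% t(.rotz((step - 1) * .aform_twist))
  m <- sweep(m, 2, c(0, 0, (step - 1) * .aform_rise) + offset, "+")
  dimnames(m) <- dimnames(.template_coords[[base]])
  m
}

.fixture_structure <- function(chains) {
  # chains: named list of lists(base=, atoms=, auth=)
  res <- NULL; atoms <- list()
  for (cn in names(chains)) {
    rs <- chains[[cn]]
    for (k in seq_along(rs)) {
      res <- rbind(res, data.frame(
        chain_id = cn, seq_index = k, auth_number = rs[[k]]$auth,
        base_code = rs[[k]]$base, base = rs[[k]]$base,
        complete_base = TRUE, stringsAsFactors = FALSE))
      atoms[[length(atoms) + 1L]] <- rs[[k]]$atoms
    }
  }
  new_rna_structure(res, atoms)
}

#' Generate an idealized A-form RNA duplex fixture
#'
#' Builds a two-chain duplex: chain A carries `sequence` 5'->3', chain B
#' its reverse complement, with every position Watson-Crick paired.  The
#' mmCIF file plus the ground-truth pair list (k, 2n+1-k) are returned;
#' generation is deterministic, so repeated calls produce byte-identical
#' files.
#'
#' @param sequence string over A/C/G/U, length >= 2.
#' @param dir output directory (created if needed).
#' @param name file stem (default "duplex_<sequence>").
#' @return list with `path` (mmCIF), `structure` (the `rna_structure`
#'   before writing), `pairs` (ground-truth data frame i, j),
#'   `n_residues`.
#' @export
#' @examples
#' make_ideal_duplex("GCGC", dir = tempdir())$pairs
make_ideal_duplex <- function(sequence, dir = tempdir(), name = NULL) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2 || !all(bases %in% names(.complement)))
    stop("sequence must be A/C/G/U of length >= 2")
  n <- length(bases)
  chainA <- lapply(seq_len(n), function(k)
    list(base = bases[k], auth = k,
         atoms = .place_base(bases[k], k)))
  # chain B residue m (5'->3') sits at step n+1-m and pairs A:(n+1-m)
  chainB <- lapply(seq_len(n), function(m) {
    step <- n + 1 - m
    list(base = .complement[[bases[step]]], auth = m,
         atoms = .place_base(.complement[[bases[step]]], step, strand2 = TRUE))
  })
  s <- .fixture_structure(list(A = chainA, B = chainB))
  if (is.null(name)) name <- paste0("duplex_", paste(bases, collapse = ""))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".cif"))
  write_structure_cif(s, path, title = name)
  pairs <- data.frame(i = seq_len(n), j = 2L * n + 1L - seq_len(n))
  list(path = path, structure = s, pairs = pairs, n_residues = 2L * n)
}

#' Generate a single-chain hairpin fixture with an optional bulge
#'
#' The stem is ideal A-form with `stem_len` Watson-Crick pairs;
#' `bulge_len` unpaired nucleotides are inserted in the 5' strand
#' between stem pairs `stem_len/2` and `stem_len/2 + 1`, displaced away
#' from the helix so they neither pair nor stack, while the flanking
#' stem steps remain in stacking contact (the stack is unbroken).
#' `loop_len` unpaired nucleotides join the two strands.
#'
#' @param stem_len number of stem pairs (>= 2).
#' @param bulge_len bulged nucleotides (0 for a plain hairpin).
#' @param loop_len loop nucleotides (>= 3).
#' @param dir output directory.
#' @return list with `path`, `structure`, `pairs` (ground truth),
#'   `n_residues`, `bulge_residues`, `loop_residues`.
#' @export
make_bulged_hairpin <- function(stem_len, bulge_len = 0, loop_len = 4,
                                dir = tempdir()) {
  if (stem_len < 2) stop("stem_len must be >= 2")
  if (loop_len < 3) stop("loop_len must be >= 3")
  if (bulge_len < 0) stop("bulge_len must be >= 0")
  half <- floor(stem_len / 2)
  stem_seq <- rep(c("G", "C"), length.out = stem_len)
  n <- 2L * stem_len + bulge_len + loop_len
  res <- vector("list", n)
  idx <- 0L
  add <- function(base, atoms) {
    idx <<- idx + 1L
    res[[idx]] <<- list(base = base, auth = idx, atoms = atoms)
  }
  # 5' strand of the stem, bulge after pair `half`
  for (k in seq_len(half)) add(stem_seq[k], .place_base(stem_seq[k], k))
  for (b in seq_len(bulge_len)) {
    # bulged residues pushed 18 A off-axis at intermediate height,
    # 8 A apart so they neither pair nor stack with anything
    off <- c(18, 8 * b, (half - 0.5) * .aform_rise)
    add("A", .place_base("A", half, offset = off))
  }
  for (k in (half + 1):stem_len) add(stem_seq[k], .place_base(stem_seq[k], k))
  # loop: arc 20 A beyond the last stem step
  for (l in seq_len(loop_len)) {
    off <- c(-20 - 4 * l, 6 * l, (stem_len + 1) * .aform_rise)
    add("U", .place_base("U", stem_len, offset = off))
  }
  # 3' strand, antiparallel: pairs stem position stem_len down to 1
  for (k in stem_len:1)
    add(.complement[[stem_seq[k]]],
        .place_base(.complement[[stem_seq[k]]], k, strand2 = TRUE))
  s <- .fixture_structure(list(A = res))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- sprintf("hairpin_s%d_b%d_l%d", stem_len, bulge_len, loop_len)
  path <- file.path(dir, paste0(name, ".cif"))
  write_structure_cif(s, path, title = name)
  i5 <- c(seq_len(half), half + bulge_len + seq_len(stem_len - half))
  j3 <- n - seq_len(stem_len) + 1L  # residue pairing stem position k
  pairs <- data.frame(i = i5, j = j3[seq_len(stem_len)])
  bulge_res <- if (bulge_len > 0) half + seq_len(bulge_len) else integer(0)
  loop_res <- stem_len + bulge_len + seq_len(loop_len)
  list(path = path, structure = s, pairs = pairs, n_residues = n,
       bulge_residues = bulge_res, loop_residues = loop_res)
}

#' Generate pairing-list topology fixtures
#'
#' Pure pairing-list fixtures (no coordinates) with their expected
#' topology recorded, for exercising helix assembly, nesting and triple
#' decomposition:
#' \describe{
#'   \item{figure2}{four helices — an enclosing helix, two helices
#'     nested inside it, and one helix crossing the enclosing helix
#'     (the non-nested, pseudoknotted element).}
#'   \item{central_pseudoknot}{two crossing helices in a 920-residue
#'     index space; the one labeled "Helix 2" (pairs 17-19 with
#'     916-918) is the SSU central-pseudoknot helix conventionally kept
#'     secondary; the other (10-13 with 22-25) is heavier, so unforced
#'     selection prefers it.}
#'   \item{triple_a915}{the A915-U15-U20 base triple: the helix pairs
#'     (14,916), (15,915), (16,914) plus the triple pair (15,20); hub
#'     residue 15 ends with partners 915 then 20.}
#'   \item{random}{`n_helices` non-overlapping helices of random length
#'     and placement (seeded), for nesting-oracle tests.}
#' }
#'
#' @param name fixture name.
#' @param n_helices,seed for `name = "random"`.
#' @return list with `name`, `n_residues`, `pairs` (i, j, canonical),
#'   `labels` (named ranges for [label_helices()], may be empty) and
#'   `expected` (fixture-specific expectations).
#' @export
make_topology <- function(name = c("figure2", "central_pseudoknot",
                                   "triple_a915", "random"),
                          n_helices = 6, seed = 1) {
  name <- match.arg(name)
  hx <- function(i0, j1, len)  # pairs (i0+t, j1-t)
    data.frame(i = i0 + seq_len(len) - 1L, j = j1 - seq_len(len) + 1L)
  if (name == "figure2") {
    red    <- hx(1L, 60L, 5L)     # encloses yellow and green
    yellow <- hx(10L, 25L, 4L)
    green  <- hx(30L, 45L, 4L)
    blue   <- hx(48L, 72L, 3L)    # crosses red: i' < j' < q' < p'
    pairs <- rbind(red, yellow, green, blue)
    pairs$canonical <- TRUE
    list(name = name, n_residues = 80L, pairs = pairs, labels = list(),
         expected = list(n_helices = 4L, n_nonnested = 1L,
                         nonnested_start = 48L))
  } else if (name == "central_pseudoknot") {
    h1 <- hx(10L, 25L, 4L)        # 10-13 with 22-25, weight 4
    h2 <- hx(17L, 918L, 3L)       # 17-19 with 916-918, weight 3
    pairs <- rbind(h1, h2)
    pairs$canonical <- TRUE
    list(name = name, n_residues = 920L, pairs = pairs,
         labels = list("Helix 2" = c(17L, 19L)),
         expected = list(n_helices = 2L, unforced_layer0_weight = 4L))
  } else if (name == "triple_a915") {
    helix <- data.frame(i = c(14L, 15L, 16L), j = c(916L, 915L, 914L))
    triple <- data.frame(i = 15L, j = 20L)
    pairs <- rbind(helix, triple)
    pairs$canonical <- c(TRUE, TRUE, TRUE, FALSE)
    list(name = name, n_residues = 920L, pairs = pairs,
         labels = list("Helix 2" = c(14L, 16L)),
         expected = list(partners_15 = c(915L, 20L), n_pairs = 4L))
  } else {
    stopifnot(n_helices >= 1)
    rng <- .seeded_rng(seed)
    n_res <- 40L * n_helices
    taken <- rep(FALSE, n_res)
    helices <- list()
    tries <- 0
    while (length(helices) < n_helices && tries < 1000) {
      tries <- tries + 1
      len <- 1L + rng(5)
      i0 <- rng(n_res - 4L * len - 2L)
      gap <- len + rng(n_res %/% 2)
      j1 <- i0 + 2L * len + gap
      if (j1 > n_res) next
      span <- c(i0:(i0 + len - 1L), (j1 - len + 1L):j1)
      if (any(taken[span])) next
      taken[span] <- TRUE
      helices[[length(helices) + 1L]] <- hx(i0, j1, len)
    }
    pairs <- do.call(rbind, helices)
    pairs$canonical <- TRUE
    pairs <- pairs[order(pairs$i), ]
    rownames(pairs) <- NULL
    list(name = name, n_residues = n_res, pairs = pairs, labels = list(),
         expected = list(n_helices = length(helices)))
  }
}

# small deterministic linear-congruential sampler: rng(k) in 1..k.
# Keeps fixture generation independent of the session RNG state.
.seeded_rng <- function(seed) {
  state <- as.integer(seed) %% 2147483647L
  if (state <= 0) state <- state + 2147483646L
  function(k) {
    state <<- as.integer((as.double(state) * 48271) %% 2147483647)
    1L + state %% as.integer(k)
  }
}
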