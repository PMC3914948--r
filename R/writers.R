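# Serialization of the annotated secondary structure.
#
# CT and BPSEQ are flat one-partner-per-residue formats, so only the
# slot-0 partner goes in the body; extra triple partners are never
# silently lost — BPSEQ carries them as "# TRIPLE i j" trailer lines and
# every writer reports its omitted-pair count.  JSON is the lossless
# format of record.

#' Build a secondary-structure record
#'
#' Aggregates sequence, layered partner lists, helices, topology
#' annotation and domains into the serializable record all writers
#' consume.
#'
#' @param sequence character vector of parent bases (global order).
#' @param partners list of ordered partner vectors from
#'   [decompose_triples()].
#' @param helices helix list (post unique-membership).
#' @param annotation result of [classify_nesting()].
#' @param pairs classified pair table from [classify_pair_roles()].
#' @param domains per-residue domain labels (default all unassigned).
#' @param title record title used in file headers.
#' @param params detection parameters to embed in the JSON dump.
#' @return object of class `ss_record`.
#' @export
build_record <- function(sequence, partners, helices, annotation, pairs,
                         domains = NULL, title = "rss3d",
                         params = default_params()) {
  n <- length(sequence)
  stopifnot(length(partners) == n)
  for (r in seq_len(n)) for (p in partners[[r]])
    if (!r %in% partners[[p]])
      stop("asymmetric partner table: ", r, " -> ", p)
  helix_of <- rep(NA_integer_, n)
  for (h in helices)
    helix_of[c(h$pairs$i, h$pairs$j)] <- h$helix_id
  labels <- stats::setNames(
    vapply(helices, function(h)
      if (is.null(h$label) || is.na(h$label)) NA_character_ else h$label,
      character(1)),
    vapply(helices, `[[`, 0L, "helix_id"))
  structure(list(
    sequence = sequence, partners = partners, helix_of = helix_of,
    helices = helices, pairs = pairs,
    layer = annotation$layer, helix_class = annotation$helix_class,
    domain_of = if (is.null(domains)) rep("unassigned", n) else domains,
    labels = labels, title = title, params = params,
    schema_version = "1.0"), class = "ss_record")
}

#' @export
print.ss_record <- function(x, ...) {
  cat(sprintf("ss_record '%s': %d nt, %d pairs (%d secondary, %d tertiary), %d helices, %d layer(s)\n",
              x$title, length(x$sequence), nrow(x$pairs),
              sum(x$pairs$role == "secondary"),
              sum(x$pairs$role == "tertiary"),
              length(x$helices),
              length(unique(x$layer))))
  invisible(x)
}

.slot0 <- function(record) {
  n <- length(record$sequence)
  vapply(seq_len(n), function(r) {
    v <- record$partners[[r]]
    if (length(v) == 0) 0L else as.integer(v[1])
  }, integer(1))
}

# slot-0 partners that are mutual; anything else renders as unpaired in
# the flat formats (and is counted among the omitted pairs)
.slot0_mutual <- function(record) {
  s0 <- .slot0(record)
  ifelse(s0 > 0 & s0[pmax(s0, 1L)] == seq_along(s0), s0, 0L)
}

# pairs not representable in one-partner formats: every pair of the
# record that is not a mutual slot-0 pair, as an i < j matrix
.extra_pairs <- function(record) {
  s0 <- .slot0(record)
  p <- record$pairs
  if (is.null(p) || nrow(p) == 0) return(matrix(integer(0), ncol = 2))
  drop <- s0[p$i] == p$j & s0[p$j] == p$i
  cbind(p$i[!drop], p$j[!drop])
}

#' Write a CT file
#'
#' Standard 6-column CT (index, base, index-1, index+1, slot-0 partner
#' or 0, index) with a single `count title` header line.  Triple
#' partners beyond slot 0 cannot be expressed in CT and are omitted;
#' their count is reported in the return value and via a message.
#'
#' @param record an `ss_record`.
#' @param path output file.
#' @return invisibly, `list(path, n_omitted)`.
#' @export
write_ct <- function(record, path) {
  n <- length(record$sequence)
  s0 <- .slot0_mutual(record)
  omitted <- nrow(.extra_pairs(record))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, record$title), con, sep = "\n")
  writeLines(sprintf("%d %s %d %d %d %d",
                     seq_len(n), record$sequence, seq_len(n) - 1L,
                     ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L),
                     s0, seq_len(n)),
             con, sep = "\n")
  if (omitted > 0)
    message("write_ct: ", omitted, " triple pair(s) beyond slot 0 omitted")
  invisible(list(path = path, n_omitted = omitted))
}

#' Read a CT file back into a minimal record
#'
#' @param path CT file written by [write_ct()] (or any 6-column CT).
#' @return list with `sequence`, `partners` (slot-0 only, as a list of
#'   length-0/1 integer vectors) and `title`.  Asymmetric partner
#'   columns and header/body count mismatches are format errors naming
#'   the offending line.
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n)) stop("CT format error at line 1: bad residue count")
  title <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else ""
  if (length(lines) - 1 != n)
    stop("CT format error: header says ", n, " residues but file has ",
         length(lines) - 1, " data lines")
  f <- do.call(rbind, strsplit(trimws(lines[-1]), "[ \t]+"))
  idx <- as.integer(f[, 1]); base <- f[, 2]; part <- as.integer(f[, 5])
  if (any(idx != seq_len(n)))
    stop("CT format error at line ", which(idx != seq_len(n))[1] + 1,
         ": indices not sequential")
  for (r in seq_len(n)) {
    p <- part[r]
    if (p != 0 && (p < 1 || p > n || part[p] != r))
      stop("CT format error at line ", r + 1, ": partner ", p,
           " does not point back to ", r)
  }
  partners <- lapply(part, function(p) if (p == 0) integer(0) else p)
  list(sequence = base, partners = partners, title = title)
}

#' Write an extended BPSEQ file
#'
#' 3-column BPSEQ body (`index base partner`) for slot-0 pairs, with
#' every additional (triple) pair appended as a `# TRIPLE i j` trailer
#' line so no pairing is lost.
#'
#' @inheritParams write_ct
#' @return invisibly, `list(path, n_triples)`.
#' @export
write_bpseq_extended <- function(record, path) {
  n <- length(record$sequence)
  s0 <- .slot0_mutual(record)
  extra <- .extra_pairs(record)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %s %d", seq_len(n), record$sequence, s0),
             con, sep = "\n")
  if (nrow(extra) > 0)
    writeLines(sprintf("# TRIPLE %d %d", extra[, 1], extra[, 2]),
               con, sep = "\n")
  invisible(list(path = path, n_triples = nrow(extra)))
}

#' Write a layered dot-bracket file
#'
#' One sequence line and one structure line.  Layer-0 helices use `()`;
#' pseudoknot layers 1, 2, ... use `[]`, `{}`, `<>`, `Aa`, ... in order.
#' Slot-0 pairs outside any helix are placed in the lowest layer where
#' they cross nothing.  Pairs beyond the available alphabets and triple
#' extra slots are omitted with their counts reported.
#'
#' @inheritParams write_ct
#' @return invisibly, `list(path, n_omitted)`.
#' @export
write_dotbracket <- function(record, path) {
  n <- length(record$sequence)
  s0 <- .slot0_mutual(record)
  # rendered pairs: mutual slot-0
  rp <- NULL
  for (r in seq_len(n)) {
    p <- s0[r]
    if (p > r && s0[p] == r) rp <- rbind(rp, c(r, p))
  }
  omitted <- nrow(.extra_pairs(record))
  struct <- rep(".", n)
  if (!is.null(rp)) {
    lay <- integer(nrow(rp))
    for (k in seq_len(nrow(rp))) {
      h <- record$helix_of[rp[k, 1]]
      lay[k] <- if (!is.na(h)) record$layer[[as.character(h)]] else NA_integer_
    }
    # unhelixed pairs: lowest non-crossing layer
    crosses <- function(a, b) (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) ||
      (b[1] < a[1] && a[1] < b[2] && b[2] < a[2])
    for (k in which(is.na(lay))) {
      l <- 0L
      repeat {
        members <- which(lay == l)
        if (!any(vapply(members, function(m)
          crosses(rp[k, ], rp[m, ]), logical(1)))) break
        l <- l + 1L
      }
      lay[k] <- l
    }
    nalpha <- nrow(.bracket_alphabets)
    over <- lay >= nalpha
    if (any(over)) {
      message("write_dotbracket: ", sum(over),
              " pair(s) beyond available bracket alphabets omitted")
      omitted <- omitted + sum(over)
    }
    for (k in which(!over)) {
      struct[rp[k, 1]] <- .bracket_alphabets[lay[k] + 1, 1]
      struct[rp[k, 2]] <- .bracket_alphabets[lay[k] + 1, 2]
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(record$sequence, collapse = ""),
               paste(struct, collapse = "")), con, sep = "\n")
  if (is.null(omitted)) omitted <- 0L
  invisible(list(path = path, n_omitted = omitted))
}

#' Write the lossless JSON dump
#'
#' Serializes everything: residues, all pairs with edges, orientation
#' and role, helices with defects and labels, layers and classes,
#' domains and the detection parameters, under a schema version field.
#' `read_json_record()` restores the record exactly.
#'
#' @inheritParams write_ct
#' @return invisibly, the path.
#' @export
write_json_record <- function(record, path) {
  helices <- lapply(record$helices, function(h) list(
    helix_id = h$helix_id,
    pairs = h$pairs[, c("i", "j")],
    strand5_range = h$strand5_range, strand3_range = h$strand3_range,
    has_defect = h$has_defect,
    label = if (is.null(h$label) || is.na(h$label)) NULL else h$label,
    layer = record$layer[[as.character(h$helix_id)]],
    class = record$helix_class[[as.character(h$helix_id)]]))
  payload <- list(
    schema_version = record$schema_version,
    title = record$title,
    n_residues = length(record$sequence),
    sequence = paste(record$sequence, collapse = ""),
    partners = record$partners,
    helix_of = record$helix_of,
    pairs = record$pairs,
    helices = helices,
    domain_of = record$domain_of,
    labels = as.list(record$labels[!is.na(record$labels)]),
    params = record$params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON dump back into an `ss_record`
#' @param path file written by [write_json_record()].
#' @return an `ss_record`.
#' @export
read_json_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  helices <- lapply(x$helices, function(h) {
    pm <- do.call(rbind, lapply(h$pairs, function(p)
      data.frame(i = as.integer(p$i), j = as.integer(p$j))))
    list(helix_id = as.integer(h$helix_id), pairs = pm,
         strand5_range = num(h$strand5_range),
         strand3_range = num(h$strand3_range),
         has_defect = isTRUE(h$has_defect),
         label = if (is.null(h$label)) NA_character_ else h$label)
  })
  hid <- vapply(helices, `[[`, 0L, "helix_id")
  layer <- stats::setNames(
    vapply(x$helices, function(h) as.integer(h$layer), integer(1)), hid)
  hclass <- stats::setNames(
    vapply(x$helices, function(h) h$class, character(1)), hid)
  pairs <- do.call(rbind, lapply(x$pairs, function(p)
    as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v))))
  structure(list(
    sequence = strsplit(x$sequence, "")[[1]],
    partners = lapply(x$partners, function(v) as.integer(unlist(v))),
    helix_of = vapply(x$helix_of, function(v)
      if (is.null(v)) NA_integer_ else as.integer(v), integer(1)),
    helices = helices,
    pairs = if (is.null(pairs))
      data.frame(i = integer(0), j = integer(0)) else pairs,
    layer = layer, helix_class = hclass,
    domain_of = unlist(x$domain_of),
    labels = stats::setNames(
      vapply(helices, function(h) h$label, character(1)), hid),
    title = x$title, params = x$params,
    schema_version = x$schema_version), class = "ss_record")
}
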