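# Shared test helpers: fixture-to-record plumbing, rigid motions, and an
# independent brute-force oracle for the nested-set selection.

# run the topology stages on a pairing-list fixture and build a record
topology_record <- function(tp, forced_secondary = character(0)) {
  h <- assemble_helices(tp$pairs, NULL, tp$n_residues)
  uq <- enforce_unique_membership(h)
  h <- uq$helices
  if (length(tp$labels) > 0) h <- label_helices(h, tp$labels)
  cl <- classify_pair_roles(h, tp$pairs)
  ann <- classify_nesting(h, forced_secondary)
  pt <- suppressWarnings(decompose_triples(cl, tp$n_residues))
  rec <- build_record(rep("A", tp$n_residues), pt, h, ann, cl,
                      title = tp$name)
  list(record = rec, helices = h, annotation = ann, classified = cl,
       partners = pt, demoted = uq$demoted)
}

# apply one global rotation + translation to every atom of a structure
rigid_motion <- function(s, axis = c(1, 2, 3), angle = 35, shift = c(10, -4, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angle * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  s$atoms <- lapply(s$atoms, function(m) {
    out <- sweep(m %*% t(R), 2, shift, "+")
    rownames(out) <- rownames(m)
    out
  })
  s
}

# independent oracle: maximum crossing-free pair count over all 2^n
# helix subsets, using its own interleaving test on helix pair lists
brute_force_layer0_weight <- function(helices) {
  n <- length(helices)
  if (n == 0) return(0L)
  cross <- function(a, b) {
    pa <- a$pairs; pb <- b$pairs
    for (x in seq_len(nrow(pa))) for (y in seq_len(nrow(pb))) {
      i <- pa$i[x]; q <- pa$j[x]; j <- pb$i[y]; p <- pb$j[y]
      if ((i < j && j < q && q < p) || (j < i && i < p && p < q)) return(TRUE)
    }
    FALSE
  }
  cmat <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
    cmat[a, b] <- cross(helices[[a]], helices[[b]])
    cmat[b, a] <- cmat[a, b]
  }
  w <- vapply(helices, function(h) nrow(h$pairs), integer(1))
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1 && any(cmat[sel, sel])) next
    best <- max(best, sum(w[sel]))
  }
  best
}
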