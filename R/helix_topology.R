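# Helix assembly and topology classification.
#
# A helix is a continuous base-paired stack faithful to strand
# connectivity: consecutive pairs (i,j), (i',j') satisfy
# i < i' <= i+1+g and j' < j <= j'+1+g (g = bulge tolerance) and the
# stack must be unbroken across the junction.  Helices are then split
# into a nested (layer 0) set and pseudoknot layers, with pairs inside
# helices classed secondary and all remaining pairs tertiary.

.new_helix <- function(id, pairs, label = NA_character_) {
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  gaps_i <- diff(pairs$i); gaps_j <- -diff(pairs$j)
  list(helix_id = as.integer(id), pairs = pairs,
       strand5_range = range(pairs$i), strand3_range = range(pairs$j),
       has_defect = length(gaps_i) > 0 && any(gaps_i > 1 | gaps_j > 1),
       label = label)
}

.validate_helix <- function(h) {
  p <- h$pairs
  stopifnot(nrow(p) >= 1, all(p$i < p$j))
  if (nrow(p) > 1)
    stopifnot(all(diff(p$i) > 0), all(diff(p$j) < 0))
  stopifnot(!anyDuplicated(c(p$i, p$j)))
  invisible(h)
}

#' Assemble helices from base pairs and stacking contacts
#'
#' Chains pairs into maximal continuous stacks.  Pair (i,j) is followed
#' by (i',j') when `i < i' <= i + 1 + g` and `j' < j <= j' + 1 + g`
#' (`g` = `params$bulge_tolerance`) and a stacking contact bridges the
#' junction on at least one strand (between i and i', or between j' and
#' j).  When `stacks` is empty the caller is in pairing-list-only mode
#' and plain sequence adjacency (g = 0) substitutes for the stack
#' requirement.  Non-canonical pairs participate exactly like canonical
#' ones.  Every pair ends up in exactly one helix; unpaired-stack
#' singletons become 1-pair helices.
#'
#' @param pairs data frame as returned by [detect_base_pairs()] (only
#'   `i`, `j` are required; `canonical` is carried if present).
#' @param stacks data frame as returned by [detect_stacking()], or an
#'   empty/`NULL` data frame for pairing-list-only mode.
#' @param n_residues total number of residues (index bound check).
#' @param params threshold list; only `bulge_tolerance` is used.
#' @return list of helices ordered by 5' start; each helix is a list
#'   with `helix_id`, `pairs`, `strand5_range`, `strand3_range`,
#'   `has_defect`, `label`.
#' @export
assemble_helices <- function(pairs, stacks = NULL, n_residues,
                             params = default_params()) {
  if (is.null(pairs) || nrow(pairs) == 0) return(list())
  stopifnot(all(pairs$i >= 1), all(pairs$j >= 1))
  if (any(pairs$i > n_residues | pairs$j > n_residues))
    stop("pair index exceeds n_residues = ", n_residues)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  np <- nrow(pairs)
  pairing_only <- is.null(stacks) || nrow(stacks) == 0
  g <- if (pairing_only) 0L else params$bulge_tolerance
  stack_key <- if (pairing_only) character(0) else
    paste(stacks$i, stacks$j)
  stacked <- function(a, b) {
    paste(min(a, b), max(a, b)) %in% stack_key
  }
  can_chain <- function(a, b) {
    # pair a followed by pair b
    di <- pairs$i[b] - pairs$i[a]
    dj <- pairs$j[a] - pairs$j[b]
    if (di < 1 || di > 1 + g || dj < 1 || dj > 1 + g) return(FALSE)
    if (pairing_only) return(di == 1 && dj == 1)
    stacked(pairs$i[a], pairs$i[b]) || stacked(pairs$j[b], pairs$j[a])
  }
  nxt <- rep(NA_integer_, np)
  has_prev <- rep(FALSE, np)
  for (a in seq_len(np)) {
    cands <- which(!has_prev & seq_len(np) != a)
    cands <- cands[vapply(cands, function(b) can_chain(a, b), logical(1))]
    if (length(cands) == 0) next
    cost <- (pairs$i[cands] - pairs$i[a]) + (pairs$j[a] - pairs$j[cands])
    b <- cands[order(cost, pairs$i[cands])][1]
    nxt[a] <- b
    has_prev[b] <- TRUE
  }
  helices <- list()
  for (a in which(!has_prev)) {
    chain <- a
    while (!is.na(nxt[chain[length(chain)]]))
      chain <- c(chain, nxt[chain[length(chain)]])
    helices[[length(helices) + 1L]] <- pairs[chain, , drop = FALSE]
  }
  ord <- order(vapply(helices, function(p) min(p$i), numeric(1)),
               vapply(helices, function(p) min(p$j), numeric(1)))
  helices <- helices[ord]
  out <- lapply(seq_along(helices), function(k) .new_helix(k, helices[[k]]))
  lapply(out, .validate_helix)
  out
}

.helix_residues <- function(h) c(h$pairs$i, h$pairs$j)

#' Enforce unique helix membership per nucleotide
#'
#' When a residue takes part in pairs of two different helices (a base
#' triple spanning helices), the pair in the larger helix keeps its
#' membership; ties go to the helix whose 5' strand starts earlier, then
#' to the earlier 3' strand.  The losing pair is removed from its helix
#' and returned as a demoted pair (it remains a pair and is later
#' classified tertiary).  Helices are re-validated and re-chained after
#' removal; empty helices disappear.  The operation is idempotent.
#'
#' @param helices list from [assemble_helices()].
#' @param params passed to the internal re-chaining of split helices.
#' @return list with `helices` (cleaned, re-numbered by 5' start) and
#'   `demoted` (data frame of pairs removed from helices).
#' @export
enforce_unique_membership <- function(helices, params = default_params()) {
  demoted <- NULL
  repeat {
    occ <- do.call(rbind, lapply(helices, function(h)
      data.frame(res = .helix_residues(h), hid = h$helix_id)))
    if (is.null(occ) || nrow(occ) == 0) break
    dup <- unique(occ$res[duplicated(occ$res)])
    dup <- dup[vapply(dup, function(r)
      length(unique(occ$hid[occ$res == r])) > 1, logical(1))]
    if (length(dup) == 0) break
    r <- dup[1]
    hids <- unique(occ$hid[occ$res == r])
    hs <- helices[match(hids, vapply(helices, `[[`, 0L, "helix_id"))]
    sz <- vapply(hs, function(h) nrow(h$pairs), integer(1))
    s5 <- vapply(hs, function(h) h$strand5_range[1], numeric(1))
    s3 <- vapply(hs, function(h) h$strand3_range[1], numeric(1))
    keep <- order(-sz, s5, s3)[1]
    for (k in seq_along(hs)) {
      if (k == keep) next
      h <- hs[[k]]
      lose <- h$pairs$i == r | h$pairs$j == r
      demoted <- rbind(demoted, h$pairs[lose, , drop = FALSE])
      idx <- which(vapply(helices, `[[`, 0L, "helix_id") == h$helix_id)
      helices[[idx]] <- NULL
      # removal splits the chain exactly at the removed pair(s): keep
      # each surviving run of originally-consecutive pairs as a helix
      pos <- which(!lose)
      if (length(pos) > 0) {
        run <- cumsum(c(1, diff(pos) != 1))
        maxid <- max(0L, vapply(helices, `[[`, 0L, "helix_id"))
        for (rn in split(pos, run)) {
          maxid <- maxid + 1L
          helices[[length(helices) + 1L]] <-
            .new_helix(maxid, h$pairs[rn, , drop = FALSE], h$label)
        }
      }
    }
  }
  ord <- order(vapply(helices, function(h) h$strand5_range[1], numeric(1)),
               vapply(helices, function(h) h$strand3_range[1], numeric(1)))
  helices <- helices[ord]
  helices <- lapply(seq_along(helices), function(k) {
    h <- helices[[k]]; h$helix_id <- k; h
  })
  lapply(helices, .validate_helix)
  if (!is.null(demoted)) rownames(demoted) <- NULL
  list(helices = helices,
       demoted = if (is.null(demoted))
         data.frame(i = integer(0), j = integer(0)) else demoted)
}

#' Classify every detected pair as secondary or tertiary
#'
#' Pairs inside helices are secondary interactions; all remaining pairs
#' (isolated pairs that chained to nothing, and triple partners demoted
#' by [enforce_unique_membership()]) are tertiary.  Non-canonical pairs
#' that are internal to or extend a helix are secondary like any other
#' helix member.
#'
#' @param helices list of helices after unique membership is enforced.
#' @param all_pairs data frame of every detected pair.
#' @return `all_pairs` with columns `role` ("secondary"/"tertiary") and
#'   `helix_id` (NA for non-helix pairs) added.
#' @export
classify_pair_roles <- function(helices, all_pairs) {
  key <- function(p) paste(p$i, p$j)
  hkey <- unlist(lapply(helices, function(h) key(h$pairs)))
  hid <- unlist(lapply(helices, function(h) rep(h$helix_id, nrow(h$pairs))))
  m <- match(key(all_pairs), hkey)
  all_pairs$role <- ifelse(is.na(m), "tertiary", "secondary")
  all_pairs$helix_id <- hid[m]
  all_pairs
}

# TRUE when helices a and b cross: some pair (i,q) of one and (j,p) of
# the other interleave as i < j < q < p.
helices_cross <- function(a, b) {
  pa <- a$pairs; pb <- b$pairs
  for (k in seq_len(nrow(pa))) {
    i <- pa$i[k]; q <- pa$j[k]
    if (any(pb$i > i & pb$i < q & pb$j > q)) return(TRUE)
    if (any(pb$i < i & pb$j > i & pb$j < q)) return(TRUE)
  }
  FALSE
}

# exact maximum-weight independent set on the crossing graph, by
# connected component, branch and bound.  Ties prefer the selection
# whose sorted 5' starts are lexicographically smallest.
.mwis_exact <- function(weights, adj, starts) {
  n <- length(weights)
  if (n == 0) return(integer(0))
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    queue <- v
    while (length(queue) > 0) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & is.na(comp)))
    }
  }
  sel <- integer(0)
  for (cc in seq_len(cid)) {
    verts <- which(comp == cc)
    if (length(verts) == 1) { sel <- c(sel, verts); next }
    vw <- weights[verts]
    ord <- order(-vw, starts[verts])
    verts <- verts[ord]
    vw <- weights[verts]
    best <- list(w = -Inf, set = integer(0))
    better <- function(w, set) {
      if (w > best$w) return(TRUE)
      if (w < best$w) return(FALSE)
      a <- sort(starts[set]); b <- sort(starts[best$set])
      la <- length(a); lb <- length(b)
      for (t in seq_len(min(la, lb))) {
        if (a[t] < b[t]) return(TRUE)
        if (a[t] > b[t]) return(FALSE)
      }
      la > lb
    }
    rec <- function(idx, cur, curw) {
      if (idx > length(verts)) {
        if (better(curw, cur)) best <<- list(w = curw, set = cur)
        return(invisible())
      }
      if (curw + sum(vw[idx:length(verts)]) < best$w) return(invisible())
      v <- verts[idx]
      if (!any(adj[v, cur])) rec(idx + 1, c(cur, v), curw + weights[v])
      rec(idx + 1, cur, curw)
    }
    rec(1, integer(0), 0)
    sel <- c(sel, best$set)
  }
  sort(sel)
}

#' Classify helices as nested (layer 0) or pseudoknotted layers
#'
#' Builds the helix crossing graph, selects the maximum-weight
#' crossing-free subset (weight = pair count) by exact search as the
#' nested layer 0, and assigns the remaining helices greedily (by
#' descending weight) to layers 1, 2, ... such that no two helices in a
#' layer cross.  Helices named in `forced_secondary` are constrained
#' into layer 0 regardless of weight (class `forced_secondary`), and any
#' helix crossing a forced helix is excluded from layer 0 — this is how
#' the SSU central pseudoknot's helix 2 is kept a secondary element.
#'
#' @param helices list of helices (labels set via [label_helices()] or
#'   the `label` field).
#' @param forced_secondary character vector of helix labels to force
#'   into the secondary set.
#' @return list with `layer` (named integer by helix_id), `helix_class`
#'   (named character: nested_secondary / forced_secondary /
#'   non_nested_tertiary) and `crossing_pairs` (data frame h1, h2).
#' @export
classify_nesting <- function(helices, forced_secondary = character(0)) {
  nh <- length(helices)
  ids <- vapply(helices, `[[`, 0L, "helix_id")
  if (nh == 0)
    return(list(layer = stats::setNames(integer(0), character(0)),
                helix_class = stats::setNames(character(0), character(0)),
                crossing_pairs = data.frame(h1 = integer(0), h2 = integer(0))))
  adj <- matrix(FALSE, nh, nh)
  for (a in seq_len(nh)) for (b in seq_len(nh)) if (a < b) {
    x <- helices_cross(helices[[a]], helices[[b]])
    adj[a, b] <- x; adj[b, a] <- x
  }
  labs <- vapply(helices, function(h)
    if (is.null(h$label) || is.na(h$label)) "" else h$label, character(1))
  forced <- which(labs %in% forced_secondary)
  missing_lab <- setdiff(forced_secondary, labs)
  if (length(missing_lab) > 0)
    warning("forced_secondary label(s) not found: ",
            paste(missing_lab, collapse = ", "))
  if (length(forced) > 1 && any(adj[forced, forced]))
    stop("infeasible constraint: forced_secondary helices cross each other")
  weights <- vapply(helices, function(h) nrow(h$pairs), integer(1))
  starts <- vapply(helices, function(h) h$strand5_range[1], numeric(1))
  excluded <- if (length(forced) > 0)
    unique(c(forced, which(apply(adj[, forced, drop = FALSE], 1, any)))) else
      integer(0)
  free <- setdiff(seq_len(nh), excluded)
  sel_free <- if (length(free) > 0) {
    sub <- .mwis_exact(weights[free], adj[free, free, drop = FALSE],
                       starts[free])
    free[sub]
  } else integer(0)
  layer0 <- sort(c(forced, sel_free))

  layer <- stats::setNames(rep(NA_integer_, nh), ids)
  hclass <- stats::setNames(rep(NA_character_, nh), ids)
  layer[layer0] <- 0L
  hclass[layer0] <- ifelse(seq_len(nh)[layer0] %in% forced,
                           "forced_secondary", "nested_secondary")
  rest <- setdiff(seq_len(nh), layer0)
  rest <- rest[order(-weights[rest], starts[rest])]
  occupied <- list()
  for (v in rest) {
    l <- 1L
    repeat {
      members <- if (l <= length(occupied)) occupied[[l]] else integer(0)
      if (!any(adj[v, members])) break
      l <- l + 1L
    }
    if (l > length(occupied)) occupied[[l]] <- integer(0)
    occupied[[l]] <- c(occupied[[l]], v)
    layer[v] <- l
    hclass[v] <- "non_nested_tertiary"
  }
  cross <- which(adj & upper.tri(adj), arr.ind = TRUE)
  list(layer = layer, helix_class = hclass,
       crossing_pairs = data.frame(h1 = ids[cross[, 1]], h2 = ids[cross[, 2]]))
}

#' Decompose base triples into layered per-residue partner lists
#'
#' Every residue gets an ordered partner list: its helix (secondary)
#' pair fills slot 0, any further pairs — triple partners — fill slots
#' 1, 2, ... in ascending partner order.  For a residue with no helix
#' pair, slot 0 is its lowest-index partner.  No pair is dropped: a base
#' triple joined by two pairs appears as exactly those two pairs.
#'
#' @param all_pairs classified pairs from [classify_pair_roles()].
#' @param n_residues total residue count.
#' @return list of integer vectors, one per residue (empty = unpaired).
#' @export
decompose_triples <- function(all_pairs, n_residues) {
  partners <- vector("list", n_residues)
  for (r in seq_len(n_residues)) partners[[r]] <- integer(0)
  if (nrow(all_pairs) == 0) return(partners)
  add <- function(r, p, primary) {
    cur <- partners[[r]]
    if (primary) partners[[r]] <<- c(p, cur) else partners[[r]] <<- c(cur, p)
  }
  in_helix <- !is.na(all_pairs$helix_id)
  for (k in seq_len(nrow(all_pairs))) {
    add(all_pairs$i[k], all_pairs$j[k], in_helix[k])
    add(all_pairs$j[k], all_pairs$i[k], in_helix[k])
  }
  partners <- lapply(seq_len(n_residues), function(r) {
    v <- partners[[r]]
    if (length(v) <= 1) return(v)
    khel <- which(in_helix & (all_pairs$i == r | all_pairs$j == r))
    prim <- if (length(khel) > 0) {
      k <- khel[1]
      if (all_pairs$i[k] == r) all_pairs$j[k] else all_pairs$i[k]
    } else min(v)
    c(prim, sort(setdiff(v, prim)))
  })
  many <- which(vapply(partners, length, integer(1)) > 3)
  if (length(many) > 0)
    warning("structural anomaly: residue(s) with > 3 partners kept: ",
            paste(many, collapse = ", "))
  partners
}

#' Attach text labels to helices by index range
#'
#' @param helices helix list.
#' @param label_map named list: label -> `c(start5, end5)` (a helix gets
#'   the label when its 5' range overlaps the given range), or a YAML
#'   file path with the same content.
#' @return helix list with `label` fields filled.
#' @export
label_helices <- function(helices, label_map) {
  if (is.character(label_map) && length(label_map) == 1)
    label_map <- yaml::read_yaml(label_map)
  for (nm in names(label_map)) {
    rg <- as.numeric(label_map[[nm]])
    for (k in seq_along(helices)) {
      h <- helices[[k]]
      if (h$strand5_range[1] <= rg[2] && h$strand5_range[2] >= rg[1])
        helices[[k]]$label <- nm
    }
  }
  helices
}

#' Read a domain scheme from a config file
#'
#' The scheme is a YAML list of domains, each with `name`, `color` and
#' `ranges` (list of inclusive 1-based `[start, end]` pairs).
#'
#' @param path YAML file.
#' @return object of class `domain_scheme`.
#' @export
read_domain_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  doms <- lapply(cfg$domains, function(d) {
    stopifnot(!is.null(d$name), !is.null(d$ranges))
    rg <- do.call(rbind, lapply(d$ranges, function(r) as.integer(r[1:2])))
    list(name = d$name, color = if (is.null(d$color)) NA else d$color,
         ranges = rg)
  })
  structure(list(domains = doms), class = "domain_scheme")
}

#' Assign a domain label to every residue
#'
#' @param n_residues residue count.
#' @param scheme a `domain_scheme` (or `NULL` for all-unassigned).
#' @return character vector of domain names, `"unassigned"` outside all
#'   ranges.  Overlapping ranges raise a config error.
#' @export
assign_domains <- function(n_residues, scheme = NULL) {
  out <- rep("unassigned", n_residues)
  if (is.null(scheme) || length(scheme$domains) == 0) return(out)
  seen <- rep(FALSE, n_residues)
  for (d in scheme$domains) {
    for (k in seq_len(nrow(d$ranges))) {
      lo <- d$ranges[k, 1]; hi <- d$ranges[k, 2]
      if (lo < 1 || hi > n_residues || lo > hi)
        stop("domain range out of bounds: ", d$name, " [", lo, ", ", hi, "]")
      if (any(seen[lo:hi]))
        stop("overlapping domain ranges at domain '", d$name, "'")
      seen[lo:hi] <- TRUE
      out[lo:hi] <- d$name
    }
  }
  out
}
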