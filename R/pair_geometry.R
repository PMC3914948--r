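# Geometric annotation of base pairing and base stacking.
#
# Each complete base gets a reference frame by least-squares superposition
# of its standard-frame ring template onto the observed ring atoms.
# Pairing and stacking are then decided from frame-derived metrics plus
# donor/acceptor heavy-atom contacts, with all thresholds exposed in
# default_params().

.kabsch <- function(P, Q) {
  # rotation R and translation mapping template P onto observed Q
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, origin = cq, rmsd = rmsd)
}

#' Fit the standard base reference frame to one residue
#'
#' Superposes the standard-frame ring template of the residue's parent
#' base onto its observed ring atoms (least squares, proper rotation).
#'
#' @param residue one-row slice of `structure$residues` together with its
#'   atom matrix; most conveniently obtained via
#'   `base_frames(structure)`.  Can be given as `list(base =, atoms =)`.
#' @return list with `origin` (observed ring centroid, Angstrom),
#'   `rotation` (3x3, template frame to observed), `normal` (unit base
#'   normal), `rmsd_fit`.
#' @export
compute_base_frame <- function(residue) {
  base <- residue$base
  atoms <- residue$atoms
  ring <- .ring_atoms[[base]]
  if (is.null(ring)) stop("unknown parent base: ", base)
  if (!all(ring %in% rownames(atoms)))
    stop("frame unavailable: incomplete base (missing ",
         paste(setdiff(ring, rownames(atoms)), collapse = ", "), ")")
  fit <- .kabsch(.template_coords[[base]][ring, , drop = FALSE],
                 atoms[ring, , drop = FALSE])
  normal <- as.numeric(fit$rotation %*% c(0, 0, 1))
  normal <- normal / sqrt(sum(normal^2))
  list(origin = fit$origin, rotation = fit$rotation, normal = normal,
       rmsd_fit = fit$rmsd)
}

#' Compute base reference frames for every residue of a structure
#'
#' @param structure an `rna_structure`.
#' @return list of frames (as [compute_base_frame()]) indexed by
#'   `global_index`; `NULL` for residues with incomplete bases.
#' @export
base_frames <- function(structure) {
  res <- structure$residues
  lapply(seq_len(nrow(res)), function(i) {
    if (!res$complete_base[i]) return(NULL)
    compute_base_frame(list(base = res$base[i], atoms = structure$atoms[[i]]))
  })
}

.angle_between <- function(u, v) {
  ca <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# fold normal-normal angle into [0, 90]
.plane_angle <- function(n1, n2) {
  a <- .angle_between(n1, n2)
  min(a, 180 - a)
}

# Representative atom for the coarse distance prefilter.
.anchor_xyz <- function(structure) {
  res <- structure$residues
  t(vapply(seq_len(nrow(res)), function(i) {
    m <- structure$atoms[[i]]
    for (nm in c("C1'", .glyc_atom[[res$base[i]]], rownames(m)[1]))
      if (nm %in% rownames(m)) return(m[nm, ])
    m[1, ]
  }, numeric(3)))
}

# glycosidic bond vector N -> C1' (NULL when C1' absent)
.glyc_vector <- function(base, atoms) {
  n <- .glyc_atom[[base]]
  if (!all(c(n, "C1'") %in% rownames(atoms))) return(NULL)
  atoms["C1'", ] - atoms[n, ]
}

# cis/trans: the two glycosidic bonds point to the same side of the
# pair axis (in the mean base plane) for cis, opposite sides for trans.
.orientation <- function(axis, nmean, g1, g2) {
  if (is.null(g1) || is.null(g2)) return(NA_character_)
  s1 <- sum(pracma::cross(axis, g1) * nmean)
  s2 <- sum(pracma::cross(axis, g2) * nmean)
  if (s1 == 0 || s2 == 0) return(NA_character_)
  if (sign(s1) == sign(s2)) "cis" else "trans"
}

.edge_assign <- function(base, contact_atoms) {
  edges <- .edge_atoms[[base]]
  votes <- vapply(edges, function(a) sum(contact_atoms %in% a), integer(1))
  if (all(votes == 0)) return(NA_character_)
  # priority on ties: WC > Hoogsteen > Sugar (list order)
  names(votes)[which.max(votes)]
}

.is_canonical <- function(b1, b2, e1, e2, orient) {
  if (is.na(e1) || is.na(e2) || is.na(orient)) return(FALSE)
  e1 == "WC" && e2 == "WC" && orient == "cis" &&
    paste0(b1, b2) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Detect base pairs geometrically
#'
#' Candidate residue pairs within the coarse C1'-C1' prefilter are
#' accepted as base pairs when (a) their frame origins are within
#' `d_origin`, (b) the inter-plane angle is at most `a_plane`, (c) the
#' mean vertical offset along the base normals is at most `v_offset`,
#' and (d) at least `h_min` donor-acceptor heavy-atom contacts exist at
#' `d_hb` or less.  Edges are assigned per base from which edge's
#' donor/acceptor set carries the contacts; orientation (cis/trans) from
#' the glycosidic bond vectors.  Residues without a fittable base frame
#' are left unpaired.  A residue may take part in several pairs (base
#' triples); a given (i, j) pair is reported once.
#'
#' @param structure an `rna_structure`.
#' @param params threshold list, see [default_params()].
#' @return data frame with one row per pair, columns `i`, `j` (global
#'   indices, `i < j`), `base_i`, `base_j`, `edge_i`, `edge_j`,
#'   `orientation`, `canonical`, `dist_origin`, `plane_angle`,
#'   `vertical_offset`, `n_hbonds`, `borderline` (within 10% of any
#'   threshold), sorted by (i, j).
#' @export
#' @examples
#' fx <- make_ideal_duplex("GCGCGCGC", dir = tempdir())
#' s <- read_structure(fx$path)
#' detect_base_pairs(s)
detect_base_pairs <- function(structure, params = default_params()) {
  n <- n_residues(structure)
  frames <- base_frames(structure)
  res <- structure$residues
  anchors <- .anchor_xyz(structure)
  empty <- data.frame(i = integer(0), j = integer(0),
                      base_i = character(0), base_j = character(0),
                      edge_i = character(0), edge_j = character(0),
                      orientation = character(0), canonical = logical(0),
                      dist_origin = numeric(0), plane_angle = numeric(0),
                      vertical_offset = numeric(0), n_hbonds = integer(0),
                      borderline = logical(0))
  if (n < 2) return(empty)
  d2 <- as.matrix(stats::dist(anchors))
  cand <- which(upper.tri(d2) & d2 <= params$prefilter_c1p, arr.ind = TRUE)
  out <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    fi <- frames[[i]]; fj <- frames[[j]]
    if (is.null(fi) || is.null(fj)) next
    d <- fj$origin - fi$origin
    dist_origin <- sqrt(sum(d^2))
    if (dist_origin > params$d_origin) next
    pa <- .plane_angle(fi$normal, fj$normal)
    if (pa > params$a_plane) next
    voff <- mean(c(abs(sum(fi$normal * d)), abs(sum(fj$normal * d))))
    if (voff > params$v_offset) next

    ai <- structure$atoms[[i]]; aj <- structure$atoms[[j]]
    bi <- res$base[i]; bj <- res$base[j]
    pol_i <- intersect(unique(unlist(.edge_atoms[[bi]])), rownames(ai))
    pol_j <- intersect(unique(unlist(.edge_atoms[[bj]])), rownames(aj))
    if (length(pol_i) == 0 || length(pol_j) == 0) next
    dm <- as.matrix(stats::dist(rbind(ai[pol_i, , drop = FALSE],
                                      aj[pol_j, , drop = FALSE])))
    dm <- dm[seq_along(pol_i), length(pol_i) + seq_along(pol_j), drop = FALSE]
    hb <- which(dm <= params$d_hb, arr.ind = TRUE)
    if (nrow(hb) < params$h_min) next

    e_i <- .edge_assign(bi, pol_i[hb[, 1]])
    e_j <- .edge_assign(bj, pol_j[hb[, 2]])
    nm <- fi$normal + fj$normal * sign(sum(fi$normal * fj$normal))
    nm <- nm / sqrt(sum(nm^2))
    orient <- .orientation(d / dist_origin, nm,
                           .glyc_vector(bi, ai), .glyc_vector(bj, aj))
    borderline <- dist_origin > 0.9 * params$d_origin ||
      pa > 0.9 * params$a_plane || voff > 0.9 * params$v_offset ||
      min(dm) > 0.9 * params$d_hb
    out[[k]] <- data.frame(
      i = i, j = j, base_i = bi, base_j = bj,
      edge_i = e_i, edge_j = e_j,
      orientation = orient,
      canonical = .is_canonical(bi, bj, e_i, e_j, orient),
      dist_origin = dist_origin, plane_angle = pa,
      vertical_offset = voff, n_hbonds = nrow(hb),
      borderline = borderline)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# --- stacking ---------------------------------------------------------------

# area of the convex polygon intersection (Sutherland-Hodgman on 2D hulls)
.clip_area <- function(P, Q) {
  hull <- function(M) M[grDevices::chull(M), , drop = FALSE]
  P <- hull(P); Q <- hull(Q)
  # ensure counter-clockwise
  ccw <- function(M) {
    a <- sum(M[, 1] * M[c(2:nrow(M), 1), 2] - M[c(2:nrow(M), 1), 1] * M[, 2])
    if (a < 0) M[nrow(M):1, , drop = FALSE] else M
  }
  P <- ccw(P); Q <- ccw(Q)
  subj <- P
  nq <- nrow(Q)
  for (e in seq_len(nq)) {
    if (nrow(subj) == 0) return(0)
    a <- Q[e, ]; b <- Q[if (e == nq) 1 else e + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= 0
    isect <- function(p, q) {
      dc <- a - b; dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    out <- matrix(numeric(0), ncol = 2)
    ns <- nrow(subj)
    for (v in seq_len(ns)) {
      p <- subj[v, ]; q <- subj[if (v == ns) 1 else v + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) out <- rbind(out, p)
      if (pin != qin) out <- rbind(out, isect(p, q))
    }
    subj <- out
  }
  if (nrow(subj) < 3) return(0)
  abs(sum(subj[, 1] * subj[c(2:nrow(subj), 1), 2] -
            subj[c(2:nrow(subj), 1), 1] * subj[, 2])) / 2
}

#' Detect base-stacking contacts geometrically
#'
#' Two bases stack when their ring centroids are within `d_stack`, their
#' normals within `a_stack` of parallel, and their ring polygons overlap
#' when projected onto the mean base plane.
#'
#' @inheritParams detect_base_pairs
#' @return data frame with columns `i`, `j` (`i < j`), `center_distance`
#'   (Angstrom), `normal_angle` (degrees, folded to 0-90), `overlap`
#'   (projected intersection area, Angstrom^2), sorted by (i, j).
#' @export
detect_stacking <- function(structure, params = default_params()) {
  n <- n_residues(structure)
  frames <- base_frames(structure)
  res <- structure$residues
  empty <- data.frame(i = integer(0), j = integer(0),
                      center_distance = numeric(0),
                      normal_angle = numeric(0), overlap = numeric(0))
  if (n < 2) return(empty)
  ok <- which(!vapply(frames, is.null, logical(1)))
  if (length(ok) < 2) return(empty)
  cent <- t(vapply(ok, function(i) frames[[i]]$origin, numeric(3)))
  d2 <- as.matrix(stats::dist(cent))
  cand <- which(upper.tri(d2) & d2 <= params$d_stack, arr.ind = TRUE)
  out <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- ok[cand[k, 1]]; j <- ok[cand[k, 2]]
    fi <- frames[[i]]; fj <- frames[[j]]
    na <- .plane_angle(fi$normal, fj$normal)
    if (na > params$a_stack) next
    # project both rings onto the mean plane through the midpoint
    nm <- fi$normal + fj$normal * sign(sum(fi$normal * fj$normal))
    nm <- nm / sqrt(sum(nm^2))
    e1 <- c(nm[2], -nm[1], 0)
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- pracma::cross(nm, e1)
    proj <- function(idx) {
      ring <- structure$atoms[[idx]][.ring_atoms[[res$base[idx]]], , drop = FALSE]
      cbind(ring %*% e1, ring %*% e2)
    }
    ov <- .clip_area(proj(i), proj(j))
    if (ov <= 0) next
    out[[k]] <- data.frame(i = i, j = j,
                           center_distance = d2[cand[k, 1], cand[k, 2]],
                           normal_angle = na, overlap = ov)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  st <- do.call(rbind, out)
  st <- st[order(st$i, st$j), , drop = FALSE]
  rownames(st) <- NULL
  st
}
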