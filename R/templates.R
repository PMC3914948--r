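# Standard-frame base geometry and chemical lookup tables.
#
# Base-atom coordinates are the standard reference-frame templates of
# Olson et al. (2001) as distributed with 3DNA: each base lies in the
# z = 0 plane, the WC edge faces -y, and an ideal Watson-Crick partner
# is generated by a 180 degree rotation about the x axis.

.template_coords <- local({
  A <- rbind(
    "C1'" = c(-2.479, 5.346, 0.000),
    N9  = c(-1.291, 4.498, 0.000),
    C8  = c( 0.024, 4.897, 0.000),
    N7  = c( 0.877, 3.902, 0.000),
    C5  = c( 0.071, 2.771, 0.000),
    C6  = c( 0.369, 1.398, 0.000),
    N6  = c( 1.611, 0.909, 0.000),
    N1  = c(-0.668, 0.532, 0.000),
    C2  = c(-1.912, 1.023, 0.000),
    N3  = c(-2.320, 2.290, 0.000),
    C4  = c(-1.267, 3.124, 0.000))
  G <- rbind(
    "C1'" = c(-2.477, 5.399, 0.000),
    N9  = c(-1.289, 4.551, 0.000),
    C8  = c( 0.023, 4.962, 0.000),
    N7  = c( 0.870, 3.969, 0.000),
    C5  = c( 0.071, 2.833, 0.000),
    C6  = c( 0.424, 1.460, 0.000),
    O6  = c( 1.554, 0.955, 0.000),
    N1  = c(-0.700, 0.641, 0.000),
    C2  = c(-1.999, 1.087, 0.000),
    N2  = c(-2.949, 0.139, -0.001),
    N3  = c(-2.342, 2.364, 0.001),
    C4  = c(-1.265, 3.177, 0.000))
  C <- rbind(
    "C1'" = c(-2.477, 5.402, 0.000),
    N1  = c(-1.285, 4.542, 0.000),
    C2  = c(-1.472, 3.158, 0.000),
    O2  = c(-2.628, 2.709, 0.001),
    N3  = c(-0.391, 2.344, 0.000),
    C4  = c( 0.837, 2.868, 0.000),
    N4  = c( 1.875, 2.027, 0.001),
    C5  = c( 1.056, 4.275, 0.000),
    C6  = c(-0.023, 5.068, 0.000))
  U <- rbind(
    "C1'" = c(-2.481, 5.354, 0.000),
    N1  = c(-1.284, 4.500, 0.000),
    C2  = c(-1.462, 3.131, 0.000),
    O2  = c(-2.563, 2.608, 0.000),
    N3  = c(-0.302, 2.397, 0.000),
    C4  = c( 0.989, 2.884, 0.000),
    O4  = c( 1.935, 2.094, -0.001),
    C5  = c( 1.089, 4.311, 0.000),
    C6  = c(-0.024, 5.053, 0.000))
  list(A = A, G = G, C = C, U = U)
})

# Ring atoms used for the least-squares frame fit (and for stacking
# overlap polygons).  Purines use the fused 9-atom ring, pyrimidines the
# 6-atom ring; C1' is excluded from the fit.
.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"))

# Glycosidic nitrogen per parent base (bond to C1').
.glyc_atom <- c(A = "N9", G = "N9", C = "N1", U = "N1")

# Polar (N/O) atoms of each Leontis-Westhof edge, used both as hydrogen
# bond donors/acceptors and to vote on edge assignment.  O2' (when
# present) contributes to the sugar edge.
.edge_atoms <- list(
  A = list(WC = c("N1", "N6"),        Hoogsteen = c("N7", "N6"),
           Sugar = c("N3", "O2'")),
  G = list(WC = c("N1", "N2", "O6"),  Hoogsteen = c("N7", "O6"),
           Sugar = c("N3", "N2", "O2'")),
  C = list(WC = c("N3", "N4", "O2"),  Hoogsteen = c("N4"),
           Sugar = c("O2", "O2'")),
  U = list(WC = c("N3", "O2", "O4"),  Hoogsteen = c("O4"),
           Sugar = c("O2", "O2'")))

# Common modified ribonucleotides mapped to the parent base whose pairing
# geometry they follow.  Residues not listed here (and not A/C/G/U) are
# excluded from the selection with a warning.
.modified_parent <- c(
  PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  "3MU" = "U", U8U = "U", "2MU" = "U", DHU = "U", T = "U",
  "1MA" = "A", A2M = "A", MA6 = "A", "6MZ" = "A", "2MA" = "A", RIA = "A",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", G7M = "G", OMG = "G",
  YG = "G", QUO = "G",
  "5MC" = "C", OMC = "C", "4OC" = "C", M4C = "C", C5M = "C")

# Dot-bracket alphabets by pseudoknot layer (layer 0 first).
.bracket_alphabets <- rbind(
  c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"),
  c("A", "a"), c("B", "b"), c("C", "c"), c("D", "d"))

#' Default geometric detection parameters
#'
#' Thresholds for base-pair and base-stack detection and for helix
#' assembly.  All distances are in Angstrom, angles in degrees.
#'
#' @return Named list:
#' \describe{
#'   \item{prefilter_c1p}{coarse C1'-C1' distance prefilter for pairing
#'     candidates (15).}
#'   \item{d_origin}{maximum distance between base-frame origins of a
#'     pair (9).}
#'   \item{a_plane}{maximum inter-plane angle of a pair (65).}
#'   \item{v_offset}{maximum vertical offset of a pair, i.e. mean
#'     displacement along the base normals (2.5).}
#'   \item{h_min}{minimum number of donor-acceptor heavy-atom contacts
#'     (1).}
#'   \item{d_hb}{maximum donor-acceptor heavy-atom distance (3.5).}
#'   \item{d_stack}{maximum ring-centroid distance of a stack (5.5).}
#'   \item{a_stack}{maximum angle between base normals of a stack (30).}
#'   \item{bulge_tolerance}{maximum unpaired nucleotides bridged per
#'     strand when chaining pairs into a helix (3).}
#' }
#' @export
#' @examples
#' default_params()$d_origin
default_params <- function() {
  list(prefilter_c1p = 15, d_origin = 9, a_plane = 65, v_offset = 2.5,
       h_min = 1L, d_hb = 3.5, d_stack = 5.5, a_stack = 30,
       bulge_tolerance = 3L)
}

#' Read detection parameters from a flat key/value config file
#'
#' Accepts YAML (or the equivalent `key: value` flat text).  Unknown keys
#' are rejected; missing keys keep their defaults.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return parameter list as [default_params()].
#' @export
read_params <- function(path = NULL) {
  p <- default_params()
  if (is.null(path)) return(p)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(p))
  if (length(bad) > 0)
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  for (k in names(cfg)) p[[k]] <- cfg[[k]]
  thr <- setdiff(names(p), "bulge_tolerance")
  stopifnot(all(vapply(p[thr], function(v) is.numeric(v) && v > 0, logical(1))),
            is.numeric(p$bulge_tolerance), p$bulge_tolerance >= 0)
  p[c("h_min", "bulge_tolerance")] <-
    lapply(p[c("h_min", "bulge_tolerance")], as.integer)
  p
}
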