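#' The 25 heavy atoms of the Fe-porphyrin skeleton
#'
#' Atom names of the iron, the four pyrrole nitrogens, the sixteen pyrrole
#' carbons and the four methine bridge carbons shared by all heme variants
#' (HEM, HEA, HEB, HEC, HEO).  A heme instance missing any of these is
#' considered incomplete and is excluded from analysis.
#'
#' @return character vector of length 25.
#' @export
heme_skeleton_names <- function() {
  c("FE",
    "NA", "NB", "NC", "ND",
    paste0("C", rep(1:4, 4), rep(c("A", "B", "C", "D"), each = 4)),
    paste0("CH", c("A", "B", "C", "D")))
}

#' Heme compound identifiers recognised as heme
#' @return character vector of chemical component ids.
#' @export
heme_compound_ids <- function() c("HEM", "HEA", "HEB", "HEC", "HEO")

#' Methine bridge carbon names
#' @keywords internal
methine_names <- function() c("CHA", "CHB", "CHC", "CHD")

# Idealised planar Fe-porphyrin geometry (D4h-symmetric, angstrom units).
# Methines sit on the axes so that CHA -> CHC points along +x and the
# CHA -> CHB -> CHC -> CHD winding is counterclockwise seen from +z; with
# that pose the heme coordinate frame of compute_heme_frame() is exactly
# the identity, which anchors the frame round-trip tests.
ideal_porphyrin_coords <- function() {
  deg <- function(a) a * pi / 180
  pol <- function(r, a) c(r * cos(deg(a)), r * sin(deg(a)), 0)
  methine_ang <- c(CHA = 180, CHB = 270, CHC = 0, CHD = 90)
  ring_ang <- c(A = 225, B = 315, C = 45, D = 135)
  out <- list(FE = c(0, 0, 0))
  for (ring in names(ring_ang)) {
    th <- ring_ang[[ring]]
    out[[paste0("N", ring)]]  <- pol(2.01, th)
    out[[paste0("C1", ring)]] <- pol(3.08, th - 25)
    out[[paste0("C2", ring)]] <- pol(4.25, th - 11)
    out[[paste0("C3", ring)]] <- pol(4.25, th + 11)
    out[[paste0("C4", ring)]] <- pol(3.08, th + 25)
  }
  for (m in names(methine_ang))
    out[[m]] <- pol(3.42, methine_ang[[m]])
  xyz <- do.call(rbind, out[heme_skeleton_names()])
  rownames(xyz) <- heme_skeleton_names()
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Van der Waals radii used for cavity occlusion
#'
#' Element-wise heavy-atom radii (angstrom) applied when deciding whether a
#' lattice point is occluded by a protein atom.
#'
#' @return named numeric vector.
#' @export
vdw_radii <- function() c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
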