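# Voxelization of the protein environment into 4-channel binary occupancy
# grids, and the outside/inside information-discarding masks.

voxel_channels <- function() c("C", "N", "O", "S")

#' Voxelize a heme site
#'
#' Transforms the site's host-protein heavy atoms into the heme frame and
#' marks occupancy on a cubic grid centred on the frame origin.  One
#' binary channel per element (C, N, O, S); heme atoms and non-protein
#' molecules contribute nothing, as do elements outside the four
#' channels.  Under the default "center" rule a voxel is occupied iff an
#' atom center falls inside its half-open cube `[low, high)`, so every
#' atom lands in exactly one voxel.  The "vdw" rule instead marks every
#' voxel whose center lies within the element's van der Waals radius of
#' an atom center.
#'
#' @param site a `heme_site` (or list with a `protein` atom data frame).
#' @param frame a `heme_frame`; computed from `site$heme` when `NULL`.
#' @param edge edge length of the cubic inclusion region (angstrom).
#' @param voxel voxel edge length (angstrom); `edge/voxel` must be a
#'   whole number.
#' @param rule occupancy rule, "center" (default) or "vdw".
#' @return integer array of dimension `c(n, n, n, 4)` (x, y, z, channel)
#'   with values 0/1, `n = edge/voxel`; attributes `edge` and `voxel`
#'   record the geometry.  Voxel `[1, 1, 1, ]` sits at the (-, -, -)
#'   corner.
#' @export
voxelize_site <- function(site, frame = NULL, edge = 24, voxel = 1,
                          rule = c("center", "vdw")) {
  rule <- match.arg(rule)
  stopifnot_scalar_number(edge, "edge")
  stopifnot_scalar_number(voxel, "voxel")
  n <- edge / voxel
  if (abs(n - round(n)) > 1e-9)
    stop("'edge' must be a whole multiple of 'voxel'", call. = FALSE)
  n <- as.integer(round(n))
  if (is.null(frame)) frame <- compute_heme_frame(site$heme)
  atoms <- site$protein
  grid <- array(0L, dim = c(n, n, n, 4L),
                dimnames = list(NULL, NULL, NULL, voxel_channels()))
  keep <- atoms$element %in% voxel_channels()
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms)) {
    fc <- to_frame(frame, atoms)
    ch <- match(atoms$element, voxel_channels())
    if (rule == "center") {
      idx <- floor((fc + edge / 2) / voxel)     # 0-based
      ok <- idx[, 1] >= 0 & idx[, 1] < n &
        idx[, 2] >= 0 & idx[, 2] < n &
        idx[, 3] >= 0 & idx[, 3] < n
      if (any(ok)) {
        lin <- 1L + idx[ok, 1] + n * (idx[ok, 2] + n * (idx[ok, 3] +
                 n * (ch[ok] - 1L)))
        grid[as.integer(lin)] <- 1L
      }
    } else {
      centers <- -edge / 2 + (seq_len(n) - 0.5) * voxel
      radii <- vdw_radii()
      for (a in seq_len(nrow(atoms))) {
        r <- radii[[atoms$element[a]]]
        near <- lapply(1:3, function(d)
          which(abs(centers - fc[a, d]) <= r))
        if (any(!lengths(near))) next
        sub <- expand.grid(ix = near[[1]], iy = near[[2]], iz = near[[3]])
        d2 <- (centers[sub$ix] - fc[a, 1])^2 +
          (centers[sub$iy] - fc[a, 2])^2 +
          (centers[sub$iz] - fc[a, 3])^2
        sub <- sub[d2 <= r^2, , drop = FALSE]
        if (nrow(sub))
          grid[cbind(sub$ix, sub$iy, sub$iz, ch[a])] <- 1L
      }
    }
  }
  structure(grid, edge = edge, voxel = voxel)
}

#' Voxel-center coordinates along one axis
#' @keywords internal
voxel_centers <- function(edge, voxel) {
  n <- as.integer(round(edge / voxel))
  -edge / 2 + (seq_len(n) - 0.5) * voxel
}

#' Discard voxel information outside or inside an inner cube
#'
#' Occlusion masking for the information-discarding analysis.  Both modes
#' share an outer cube of vertex (+/-h, +/-h, +/-h) with `h = edge/2`.
#' "outside" zeroes every voxel whose center lies outside the inner cube
#' of vertex +/-(h - r); "inside" zeroes voxels whose centers lie inside
#' the cube of vertex +/-r.  Depth 0 leaves the grid unchanged in both
#' modes.  Membership is decided by voxel-center coordinates, consistent
#' with the voxelization convention.
#'
#' @param grid a grid from [voxelize_site()] (attributes `edge`/`voxel`).
#' @param mode "outside" or "inside".
#' @param r discarding depth in angstrom, `0 <= r < edge/2`.
#' @return masked grid with the same attributes.
#' @export
discard_region <- function(grid, mode = c("outside", "inside"), r) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(r, "r")
  edge <- attr(grid, "edge")
  voxel <- attr(grid, "voxel")
  if (is.null(edge) || is.null(voxel))
    stop("grid lacks edge/voxel attributes", call. = FALSE)
  if (r < 0 || r >= edge / 2)
    stop(sprintf("'r' must be in [0, %g)", edge / 2), call. = FALSE)
  centers <- abs(voxel_centers(edge, voxel))
  n <- length(centers)
  m <- pmax(centers[rep(seq_len(n), times = n * n)],
            centers[rep(rep(seq_len(n), each = n), times = n)],
            centers[rep(seq_len(n), each = n * n)])
  drop <- if (mode == "outside") m > edge / 2 - r else m < r
  if (any(drop)) {
    dim(drop) <- c(n, n, n)
    for (ch in seq_len(dim(grid)[4]))
      grid[, , , ch][drop] <- 0L
  }
  grid
}

#' Retained-information volume of a discarding mask
#'
#' Volume (cubic angstrom) of the region whose voxels keep their original
#' information: `(edge - 2r)^3` for outside discarding and
#' `edge^3 - (2r)^3` for inside discarding.
#'
#' @param mode "outside" or "inside".
#' @param r discarding depth in angstrom.
#' @param edge outer-cube edge length.
#' @return numeric volume.
#' @export
retained_volume <- function(mode = c("outside", "inside"), r, edge = 24) {
  mode <- match.arg(mode)
  if (mode == "outside") (edge - 2 * r)^3 else edge^3 - (2 * r)^3
}
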