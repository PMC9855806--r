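# Heme-centric coordinate frame built from the four methine carbons.

#' Compute the heme coordinate frame
#'
#' Fits a least-squares plane through the four methine bridge carbons
#' (CHA, CHB, CHC, CHD).  The x axis is the unit projection of the
#' CHA to CHC vector onto that plane; the z axis is the plane normal with
#' its sign fixed so that CHA, CHB, CHC, CHD wind counterclockwise when
#' viewed from +z; y = z x x.  The origin is the barycenter of the four
#' methines.  Frame coordinates of a point p are `axes %*% (p - origin)`.
#'
#' @param heme atom data frame containing the four methine atoms (e.g.
#'   the `heme` element of a `heme_site`, or [make_porphyrin()] output).
#' @return object of class `heme_frame`: list with `origin` (length-3)
#'   and `axes` (3x3 rotation, rows = x, y, z unit vectors, det +1).
#' @export
compute_heme_frame <- function(heme) {
  pts <- vapply(methine_names(), function(nm) {
    row <- heme[heme$atom_name == nm, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("methine atom ", nm, " not present exactly once", call. = FALSE)
    c(row$x, row$y, row$z)
  }, numeric(3))
  pts <- t(pts)                              # 4 x 3, rows CHA..CHD
  origin <- colMeans(pts)
  q <- sweep(pts, 2L, origin)
  sv <- svd(q)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1))
    stop("methine carbons are (near-)collinear; frame undefined",
         call. = FALSE)
  z <- sv$v[, 3]
  # fix the normal so the methine sequence winds counterclockwise from +z
  wind <- sum(vapply(1:4, function(i) {
    j <- if (i == 4L) 1L else i + 1L
    sum(crossprod3(q[i, ], q[j, ]) * z)
  }, numeric(1)))
  if (wind < 0) z <- -z
  v <- pts[3, ] - pts[1, ]                   # CHA -> CHC
  x <- v - sum(v * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8)
    stop("CHA->CHC vector is normal to the plane; frame undefined",
         call. = FALSE)
  x <- x / nx
  y <- crossprod3(z, x)
  structure(list(origin = origin, axes = rbind(x = x, y = y, z = z)),
            class = "heme_frame")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Transform coordinates into a heme frame
#'
#' @param frame a `heme_frame`.
#' @param xyz numeric matrix (n x 3) or data frame with x/y/z columns.
#' @return n x 3 matrix of frame coordinates.
#' @export
to_frame <- function(frame, xyz) {
  if (is.data.frame(xyz)) xyz <- as.matrix(xyz[, c("x", "y", "z")])
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  sweep(xyz, 2L, frame$origin) %*% t(frame$axes)
}

#' @export
print.heme_frame <- function(x, ...) {
  cat("heme frame\n  origin:", sprintf("%.3f", x$origin), "\n")
  cat("  axes (rows x,y,z):\n")
  print(round(x$axes, 4))
  invisible(x)
}
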