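# Cavity bit-vectors on a fixed spherical lattice around the heme iron,
# and the group dispersion statistic (mean distance from the barycenter).

#' Lattice offsets of the cavity sphere
#'
#' Integer-multiples-of-`spacing` offsets whose norm is at most `radius`
#' (boundary inclusive), enumerated in lexicographic (x, y, z) order over
#' the bounding cube.  The same enumeration is used for every sample, so
#' cavity vectors are element-wise comparable across proteins.
#'
#' @param radius sphere radius (angstrom).
#' @param spacing lattice spacing (angstrom).
#' @return m x 3 matrix of offsets.
#' @export
cavity_lattice <- function(radius = 8.5, spacing = 1.0) {
  k <- floor(radius / spacing)
  s <- seq(-k, k) * spacing
  n <- length(s)
  off <- cbind(x = rep(s, each = n * n),
               y = rep(rep(s, each = n), times = n),
               z = rep(s, times = n * n))
  off[rowSums(off^2) <= radius^2 + 1e-9, , drop = FALSE]
}

#' Compute the cavity bit-vector of a heme site
#'
#' A 1 angstrom lattice (by default) is anchored on the heme iron in heme-
#' frame coordinates and clipped to a sphere of radius 8.5 angstrom around
#' the iron.  Each lattice point is 1 (cavity) unless it lies within the
#' element's van der Waals radius (plus `padding`) of a host-protein heavy
#' atom, in which case it is 0 (protein).  Isolated cavity points are
#' deliberately not removed.
#'
#' @param site a `heme_site`.
#' @param frame a `heme_frame`; computed from the site when `NULL`.
#' @param radius inclusion-sphere radius (angstrom).
#' @param spacing lattice spacing (angstrom).
#' @param radii named per-element occlusion radii (angstrom); elements
#'   not listed use `default_radius`.
#' @param padding extra occlusion distance added to every radius.
#' @param default_radius radius for elements missing from `radii`.
#' @return object of class `cavity_vector`: integer 0/1 vector with
#'   attributes `radius`, `spacing` and `n_points`.
#' @export
cavity_vector <- function(site, frame = NULL, radius = 8.5, spacing = 1.0,
                          radii = vdw_radii(), padding = 0,
                          default_radius = 1.80) {
  if (is.null(frame)) frame <- compute_heme_frame(site$heme)
  off <- cavity_lattice(radius, spacing)
  fe <- drop(to_frame(frame, matrix(site$iron, ncol = 3L)))
  pts <- sweep(off, 2L, fe, `+`)
  v <- rep(1L, nrow(pts))
  atoms <- site$protein
  if (nrow(atoms)) {
    fc <- to_frame(frame, atoms)
    rr <- unname(radii[atoms$element])
    rr[is.na(rr)] <- default_radius
    rr <- (rr + padding)^2
    # only atoms that can reach the sphere matter
    reach <- rowSums(sweep(fc, 2L, fe)^2) <=
      (radius + sqrt(max(rr)))^2
    fc <- fc[reach, , drop = FALSE]
    rr <- rr[reach]
    for (a in seq_len(nrow(fc))) {
      d2 <- (pts[, 1] - fc[a, 1])^2 + (pts[, 2] - fc[a, 2])^2 +
        (pts[, 3] - fc[a, 3])^2
      v[d2 <= rr[a]] <- 0L
    }
  }
  structure(v, radius = radius, spacing = spacing, n_points = length(v),
            class = "cavity_vector")
}

#' Dispersion of a group of cavity vectors
#'
#' For a group I of cavity vectors the statistic is the mean Euclidean
#' distance of the member vectors from their barycenter:
#' `d_bar = mean_i || v_i - mu ||`, with `mu` the element-wise mean
#' vector and `N = |I|`.  A singleton group has `d_bar = 0` by
#' construction; larger values indicate more variable cavity shapes
#' within the group.
#'
#' @param vectors list of `cavity_vector`s (or numeric vectors of equal
#'   length), or a numeric matrix with one row per sample.
#' @return object of class `cavity_dispersion`: list with `n`, `mu`
#'   (barycenter), `d_bar`, `distances` (per-sample `||v_i - mu||`) and
#'   `sd` (population standard deviation of the distances).
#' @export
group_dispersion <- function(vectors) {
  if (is.list(vectors)) {
    len <- unique(lengths(vectors))
    if (length(len) != 1L)
      stop("cavity vectors differ in length", call. = FALSE)
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  }
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) stop("empty group", call. = FALSE)
  mu <- colMeans(vectors)
  d <- sqrt(rowSums(sweep(vectors, 2L, mu)^2))
  structure(list(n = nrow(vectors), mu = mu, d_bar = mean(d),
                 distances = d,
                 sd = sqrt(mean((d - mean(d))^2))),
            class = "cavity_dispersion")
}

#' @export
print.cavity_dispersion <- function(x, ...) {
  cat(sprintf("cavity group: n = %d, d_bar = %.2f (sd %.2f)\n",
              x$n, x$d_bar, x$sd))
  invisible(x)
}

#' Per-group cavity dispersion table
#'
#' Convenience wrapper computing [group_dispersion()] for each group of a
#' grouping vector, plus a combined row over all samples.
#'
#' @param vectors list/matrix as in [group_dispersion()].
#' @param groups character vector of group names, one per sample.
#' @return data frame with columns `group`, `n`, `d_bar`, `sd`.
#' @export
cavity_group_table <- function(vectors, groups) {
  if (is.list(vectors)) vectors <- do.call(rbind, lapply(vectors, as.numeric))
  stopifnot(nrow(vectors) == length(groups))
  lev <- unique(groups)
  rows <- lapply(c(lev, "Combined"), function(g) {
    idx <- if (g == "Combined") seq_along(groups) else which(groups == g)
    gd <- group_dispersion(vectors[idx, , drop = FALSE])
    data.frame(group = g, n = gd$n, d_bar = gd$d_bar, sd = gd$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
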