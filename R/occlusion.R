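# Occlusion (information-discarding) analysis over a completed
# cross-validation run.

#' Occlusion sweep over a cross-validation run
#'
#' For each discarding depth r, every test-fold sample's voxel grid is
#' masked with [discard_region()] and re-scored with that fold's already
#' trained model (no retraining; batch-norm statistics stay frozen).  The
#' dataset accuracy is recorded per fold together with the volume of the
#' region that kept its original information: `(edge - 2r)^3` for outside
#' discarding and `edge^3 - (2r)^3` for inside discarding.  At r = 0 the
#' curve reproduces the run's unoccluded score exactly.
#'
#' @param cv a `heme_cnn_cv` from [cv_heme_cnn()].
#' @param x the voxel grids the run was trained on (same order).
#' @param mode "outside" or "inside".
#' @param r_values discarding depths in angstrom, each in
#'   \[0, edge/2).
#' @return data frame of class `occlusion_curve` with columns `mode`,
#'   `r`, `retained_volume`, `sacc_mean`, `sacc_sd`.
#' @export
occlusion_sweep <- function(cv, x, mode = c("outside", "inside"),
                            r_values = 0:11) {
  mode <- match.arg(mode)
  stopifnot(inherits(cv, "heme_cnn_cv"))
  if (is.array(x) && length(dim(x)) == 5L)
    x <- lapply(seq_len(dim(x)[5]), function(i) x[, , , , i])
  if (length(x) != length(cv$fold))
    stop("'x' does not match the cross-validation run", call. = FALSE)
  if (any(vapply(cv$models, is.null, logical(1))))
    stop("cross-validation run lacks fold models", call. = FALSE)
  edge <- attr(x[[1]], "edge")
  rows <- lapply(r_values, function(r) {
    masked <- lapply(x, discard_region, mode = mode, r = r)
    per_fold <- vapply(seq_len(cv$config$k), function(f) {
      te <- which(cv$fold == f)
      pred <- predict(cv$models[[f]], masked[te], type = "class")
      sacc(cv$observed[te], pred, cv$classes)
    }, numeric(1))
    data.frame(mode = mode, r = r,
               retained_volume = retained_volume(mode, r, edge),
               sacc_mean = mean(per_fold),
               sacc_sd = stats::sd(per_fold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("occlusion_curve", class(out))
  attr(out, "edge") <- edge
  out
}

#' @export
plot.occlusion_curve <- function(x, against = c("r", "volume"), ...) {
  against <- match.arg(against)
  xv <- if (against == "r") x$r else x$retained_volume
  xl <- if (against == "r") "r (A)" else
    "retained-information volume (A^3)"
  graphics::plot(xv, x$sacc_mean, type = "b", ylim = c(0, 1),
                 xlab = xl, ylab = "Sacc", ...)
  graphics::arrows(xv, x$sacc_mean - x$sacc_sd, xv,
                   x$sacc_mean + x$sacc_sd, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}
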