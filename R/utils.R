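#' @keywords internal
#' Evaluate `expr` under a temporary RNG state seeded with `seed`.
#' The caller's `.Random.seed` is restored afterwards, so no function in
#' this package leaks RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Random proper rotation matrix
#'
#' Draws a rotation uniformly (Haar) via QR decomposition of a Gaussian
#' matrix, with the sign fixed so the determinant is +1.
#'
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    d <- diag(qr.R(qr_))
    q <- q %*% diag(sign(d))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' @keywords internal
stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
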