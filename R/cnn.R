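# The 3D CNN classifier: fitting interface and S3 methods.

#' Layer-by-layer spatial sizes of the network
#'
#' Pure size arithmetic for the fixed layer stack: three 2x2x2
#' convolutions (paddings 0, 1, 0), a stride-2 max pool, and a flatten.
#' With 22 grid points per edge the intermediate spatial sizes are 21,
#' 22, 21, 10 and the flattened width is 128,000; with the 24-point grid
#' they are 23, 24, 23, 11 and 170,368.
#'
#' @param input_points_per_edge grid points per edge (>= 8).
#' @return list with `conv1`, `conv2`, `conv3`, `pool` (spatial edge
#'   sizes) and `flatten` (flattened width).
#' @export
heme_cnn_shapes <- function(input_points_per_edge) {
  n <- as.integer(input_points_per_edge)
  if (n < 8L)
    stop("input grid must have at least 8 points per edge", call. = FALSE)
  pool <- (n - 1L) %/% 2L
  list(conv1 = n - 1L, conv2 = n, conv3 = n - 1L, pool = pool,
       flatten = 128L * pool^3)
}

grids_to_matrix <- function(grids) {
  if (is.array(grids) && length(dim(grids)) == 5L)
    grids <- lapply(seq_len(dim(grids)[5]), function(i) grids[, , , , i])
  n <- dim(grids[[1]])[1]
  stopifnot(all(vapply(grids, function(g)
    identical(dim(g), c(n, n, n, 4L)), logical(1))))
  x <- vapply(grids, as.numeric, numeric(4 * n^3))
  list(x = x, n = n)
}

#' Fit the heme-pocket CNN classifier
#'
#' Trains the fixed-architecture 3D convolutional network (three 2x2x2
#' convolutions with 64/128/128 channels, batch normalization, a stride-2
#' max pool and three dense layers ending in per-label sigmoids) on
#' voxelized heme pockets.  The loss is binary cross-entropy summed over
#' the output labels; the optimizer is plain stochastic gradient descent.
#' Training is deterministic given `seed` (weight initialization, batch
#' shuffling and dropout all flow from it).
#'
#' @param x list of voxel grids from [voxelize_site()] (all the same
#'   shape), or a 5-D array with samples in the last dimension.
#' @param y observed labels: a character vector of class names, or a
#'   matrix of 0/1 label vectors (samples in rows).
#' @param scheme label encoding scheme when `y` is a class vector.
#' @param epochs number of training epochs.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param params optional initial parameter list (e.g. from a previous
#'   fit); default is fan-in uniform initialization from `seed`.
#' @return object of class `heme_cnn` with elements `params`, `loss`
#'   (per-epoch mean training loss), `n` (grid points per edge),
#'   `scheme`, `config` and `call`.
#' @examples
#' ds <- generate_dataset(n_per_class = 6, seed = 1, n_atoms = 120)
#' g <- lapply(ds$sites, voxelize_site, edge = 24, voxel = 3)
#' fit <- heme_cnn(g, ds$classes, scheme = "three-label", epochs = 2)
#' predict(fit, g[1:2], type = "class")
#' @export
heme_cnn <- function(x, y, scheme = c("two-label", "three-label"),
                     epochs = 100L, lr = 0.01, batch_size = 32L,
                     seed = 0L, params = NULL) {
  scheme <- match.arg(scheme)
  gm <- grids_to_matrix(x)
  if (is.character(y) || is.factor(y)) {
    y <- t(vapply(as.character(y), encode_labels, integer(
      ncol(encoding_table(scheme))), scheme = scheme))
  }
  y <- as.matrix(y)
  if (nrow(y) != ncol(gm$x))
    stop("'x' and 'y' disagree on the number of samples", call. = FALSE)
  K <- ncol(y)
  if (K != ncol(encoding_table(scheme)))
    stop("label width does not match the scheme", call. = FALSE)
  if (is.null(params))
    params <- cnn_init_cpp(gm$n, K, as.integer(seed))
  res <- cnn_train_cpp(params, gm$x, t(y), gm$n, as.integer(epochs),
                       lr, as.integer(batch_size), as.integer(seed))
  structure(list(params = res$params, loss = res$loss, n = gm$n,
                 K = K, scheme = scheme,
                 config = list(epochs = as.integer(epochs), lr = lr,
                               batch_size = as.integer(batch_size),
                               seed = as.integer(seed)),
                 call = match.call()),
            class = "heme_cnn")
}

#' Untrained network with the same interface
#'
#' Initializes parameters without any training; useful as a chance-level
#' baseline for validating evaluation code.
#'
#' @inheritParams heme_cnn
#' @param n grid points per edge.
#' @return a `heme_cnn` with empty loss history.
#' @export
heme_cnn_untrained <- function(n, scheme = c("two-label", "three-label"),
                               seed = 0L) {
  scheme <- match.arg(scheme)
  K <- ncol(encoding_table(scheme))
  structure(list(params = cnn_init_cpp(as.integer(n), K,
                                       as.integer(seed)),
                 loss = numeric(), n = as.integer(n), K = K,
                 scheme = scheme,
                 config = list(epochs = 0L, seed = as.integer(seed)),
                 call = match.call()),
            class = "heme_cnn")
}

#' Predict from a fitted heme-pocket CNN
#'
#' Sigmoid outputs are thresholded at 0.5 to a 0/1 label vector, which is
#' decoded to a class name; any vector matching no class (notably
#' all-zeros) decodes to "Others".
#'
#' @param object a `heme_cnn`.
#' @param newdata list of voxel grids (or 5-D array).
#' @param type "class" (default), "encoding" (0/1 matrix) or "prob"
#'   (sigmoid outputs).
#' @param ... unused.
#' @return character vector, or a samples-by-labels matrix.
#' @export
predict.heme_cnn <- function(object, newdata,
                             type = c("class", "encoding", "prob"), ...) {
  type <- match.arg(type)
  gm <- grids_to_matrix(newdata)
  if (gm$n != object$n)
    stop("grid size differs from the fitted model", call. = FALSE)
  probs <- t(cnn_forward_cpp(object$params, gm$x, object$n, object$K))
  if (type == "prob") return(probs)
  enc <- (probs >= 0.5) + 0L
  if (type == "encoding") return(enc)
  apply(enc, 1L, decode_labels, scheme = object$scheme)
}

#' @export
print.heme_cnn <- function(x, ...) {
  sh <- heme_cnn_shapes(x$n)
  cat(sprintf("heme-pocket CNN (%s, %d-point grid, flatten %d)\n",
              x$scheme, x$n, sh$flatten))
  if (length(x$loss))
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
                length(x$loss), x$loss[1], x$loss[length(x$loss)]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.heme_cnn <- function(object, ...) {
  sh <- heme_cnn_shapes(object$n)
  npar <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("heme-pocket CNN, %s scheme\n", object$scheme))
  cat(sprintf("  input: 4 x %d^3 voxels; conv sizes %d/%d/%d; pool %d;",
              object$n, sh$conv1, sh$conv2, sh$conv3, sh$pool),
      sprintf("flatten %d\n", sh$flatten))
  cat(sprintf("  parameters: %d\n", npar))
  if (length(object$loss))
    cat(sprintf("  config: %d epochs, lr %g, batch %d, seed %d\n",
                object$config$epochs, object$config$lr,
                object$config$batch_size, object$config$seed))
  invisible(object)
}

#' @export
coef.heme_cnn <- function(object, ...) object$params

#' @export
plot.heme_cnn <- function(x, ...) {
  if (!length(x$loss)) {
    message("untrained model; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "mean training loss", ...)
  invisible(x)
}
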