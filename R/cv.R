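# Cross-validation, the dataset-level accuracy score, confusion
# summaries and per-class metrics.

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that within every class the
#' fold sizes differ by at most one.
#'
#' @param classes character vector of per-sample class names.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(classes, k = 5L, seed = 0L) {
  fold <- integer(length(classes))
  with_seed(seed, {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

#' Dataset-level accuracy score
#'
#' The score is the total number of exact label-vector matches (true
#' positives) over the total number of samples across the class list:
#' `sum_c N_c^TP / sum_c N_c`.  A prediction is a true positive only when
#' every 0/1 label matches, i.e. when the predicted class equals the
#' observed one; predictions decoding to "Others" are never true
#' positives.
#'
#' @param observed character vector of observed classes, or a combined
#'   confusion-count matrix whose row names are the observed classes and
#'   whose columns include those classes (extra columns such as "Others"
#'   count toward the totals only).
#' @param predicted character vector of predicted classes (vector form).
#' @param L class list; defaults to the observed classes / row names.
#' @return score in \[0, 1\].
#' @export
sacc <- function(observed, predicted = NULL, L = NULL) {
  if (inherits(observed, "heme_cnn_cv"))
    return(sacc(observed$combined, L = L))
  if (is.matrix(observed) || is.table(observed)) {
    m <- as.matrix(observed)
    if (is.null(L)) L <- rownames(m)
    if (!length(L)) stop("empty class list", call. = FALSE)
    tp <- sum(vapply(L, function(cl) m[cl, cl], numeric(1)))
    return(tp / sum(m[L, , drop = FALSE]))
  }
  if (is.null(L)) L <- unique(observed)
  if (!length(L)) stop("empty class list", call. = FALSE)
  keep <- observed %in% L
  sum(observed[keep] == predicted[keep]) / sum(keep)
}

confusion_counts <- function(observed, predicted, L) {
  cols <- c(L, "Others")
  m <- matrix(0L, length(L), length(cols), dimnames = list(L, cols))
  pred <- ifelse(predicted %in% L, predicted, "Others")
  for (i in seq_along(observed))
    m[observed[i], pred[i]] <- m[observed[i], pred[i]] + 1L
  m
}

#' Per-class accuracy, recall, precision and specificity
#'
#' For class i of a confusion matrix M (rows observed, columns predicted,
#' plus an "Others" outcome column), TP = M\[i,i\], FP = sum of column i
#' off the diagonal, FN = sum of row i off the diagonal, and TN is
#' everything else.  For a cross-validation object the metrics are
#' computed per fold and averaged; undefined ratios (0/0) are excluded
#' from the average and the number of contributing folds is reported.
#'
#' @param x a `heme_cnn_cv` object or a single count matrix
#'   (classes x classes(+Others)).
#' @return data frame with one row per (class, metric): `mean`, `sd` and
#'   `n_folds` (folds where the metric was defined; `NA` sd for single
#'   matrices).
#' @export
per_class_metrics <- function(x) {
  one <- function(m) {
    L <- rownames(m)
    total <- sum(m)
    do.call(rbind, lapply(seq_along(L), function(i) {
      tp <- m[i, i]
      fp <- sum(m[-i, L[i]])
      fn <- sum(m[i, ]) - tp
      tn <- total - tp - fp - fn
      ratio <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
      data.frame(class = L[i],
                 accuracy = (tp + tn) / total,
                 recall = ratio(tp, fn),
                 precision = ratio(tp, fp),
                 specificity = ratio(tn, fp),
                 stringsAsFactors = FALSE)
    }))
  }
  mats <- if (inherits(x, "heme_cnn_cv")) x$counts else list(as.matrix(x))
  per_fold <- lapply(mats, one)
  metrics <- c("accuracy", "recall", "precision", "specificity")
  out <- do.call(rbind, lapply(seq_len(nrow(per_fold[[1]])), function(i) {
    do.call(rbind, lapply(metrics, function(met) {
      vals <- vapply(per_fold, function(df) df[i, met], numeric(1))
      ok <- !is.na(vals)
      data.frame(class = per_fold[[1]]$class[i], metric = met,
                 mean = mean(vals[ok]),
                 sd = if (sum(ok) > 1) stats::sd(vals[ok]) else NA_real_,
                 n_folds = sum(ok), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-validate the heme-pocket CNN
#'
#' Runs stratified k-fold cross-validation: each fold's model is trained
#' on the remaining folds and predicts its own test fold, so every sample
#' is predicted exactly once.  Per-fold confusion matrices (with an
#' "Others" outcome column for predictions matching no class), their
#' normalized mean and standard deviation, the combined counts and the
#' per-fold dataset accuracy are all recorded.
#'
#' @param x list of voxel grids (or 5-D array), one per sample.
#' @param classes character vector of observed class names.
#' @param scheme label scheme ("two-label" for OB/OR/OB-OR,
#'   "three-label" adds ET).
#' @param k number of folds; every class must have at least `k` samples.
#' @param epochs,lr,batch_size,seed training configuration (see
#'   [heme_cnn()]); the fold split and each fold's training derive their
#'   seeds from `seed`.
#' @return object of class `heme_cnn_cv`: `fold`, `observed`,
#'   `predicted`, `counts` (per-fold), `combined`, `norm_mean`,
#'   `norm_sd`, `sacc_folds`, `models`, `classes`, `scheme`, `config`.
#' @export
cv_heme_cnn <- function(x, classes, scheme = c("two-label", "three-label"),
                        k = 5L, epochs = 100L, lr = 0.01,
                        batch_size = 32L, seed = 0L) {
  scheme <- match.arg(scheme)
  classes <- as.character(classes)
  tab <- table(classes)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("class(es) with fewer than k samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  L <- intersect(rownames(encoding_table(scheme)), unique(classes))
  if (is.array(x) && length(dim(x)) == 5L)
    x <- lapply(seq_len(dim(x)[5]), function(i) x[, , , , i])
  fold <- stratified_folds(classes, k, seed)
  predicted <- character(length(classes))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    models[[f]] <- heme_cnn(x[tr], classes[tr], scheme = scheme,
                            epochs = epochs, lr = lr,
                            batch_size = batch_size,
                            seed = as.integer(seed) + f)
    predicted[te] <- predict(models[[f]], x[te], type = "class")
  }
  counts <- lapply(seq_len(k), function(f)
    confusion_counts(classes[fold == f], predicted[fold == f], L))
  combined <- Reduce(`+`, counts)
  norm <- lapply(counts, function(m) m / rowSums(m))
  norm_mean <- Reduce(`+`, norm) / k
  norm_sd <- sqrt(Reduce(`+`, lapply(norm, function(m)
    (m - norm_mean)^2)) / (k - 1))
  sacc_folds <- vapply(seq_len(k), function(f)
    sacc(classes[fold == f], predicted[fold == f], L), numeric(1))
  structure(list(fold = fold, observed = classes, predicted = predicted,
                 counts = counts, combined = combined,
                 norm_mean = norm_mean, norm_sd = norm_sd,
                 sacc_folds = sacc_folds, models = models, classes = L,
                 scheme = scheme,
                 config = list(k = k, epochs = as.integer(epochs),
                               lr = lr, batch_size = as.integer(batch_size),
                               seed = as.integer(seed))),
            class = "heme_cnn_cv")
}

#' @export
print.heme_cnn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s), %d samples\n",
              x$config$k, x$scheme, length(x$observed)))
  cat(sprintf("  Sacc = %.3f +/- %.3f\n", mean(x$sacc_folds),
              stats::sd(x$sacc_folds)))
  invisible(x)
}

#' @export
summary.heme_cnn_cv <- function(object, ...) {
  print(object)
  cat("\ncombined confusion counts:\n")
  print(object$combined)
  cat("\nnormalized mean over folds:\n")
  print(round(object$norm_mean, 3))
  invisible(object)
}
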