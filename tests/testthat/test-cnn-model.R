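# Network shape arithmetic, training contracts, prediction decoding,
# cross-validation bookkeeping and the evaluation metrics.

test_that("layer shape arithmetic reproduces the reference widths", {
  sh22 <- heme_cnn_shapes(22)
  expect_equal(c(sh22$conv1, sh22$conv2, sh22$conv3, sh22$pool),
               c(21L, 22L, 21L, 10L))
  expect_equal(sh22$flatten, 128000L)
  sh24 <- heme_cnn_shapes(24)
  expect_equal(sh24$flatten, 128L * 11L^3)
  expect_error(heme_cnn_shapes(7), "at least 8")

  # a real forward pass through the 22-point network agrees with the
  # arithmetic: parameter matrix widths and a finite sigmoid output
  m <- heme_cnn_untrained(22, "two-label", seed = 0)
  expect_equal(ncol(m$params$fc1_W), 128000L)
  g <- structure(array(0L, c(22, 22, 22, 4)), edge = 22, voxel = 1)
  g[11, 11, 11, 1] <- 1L
  p <- predict(m, list(g), type = "prob")
  expect_equal(dim(p), c(1L, 2L))
  expect_true(all(is.finite(p)) && all(p > 0 & p < 1))
  # output width follows the scheme
  m3 <- heme_cnn_untrained(8, "three-label", seed = 0)
  x8 <- structure(array(0L, c(8, 8, 8, 4)), edge = 24, voxel = 3)
  expect_equal(ncol(predict(m3, list(x8), type = "prob")), 3L)
})

test_that("training is deterministic and learns separable classes", {
  # two linearly separable synthetic classes, 40 samples
  grids <- lapply(1:40, function(i) {
    g <- array(0L, c(8, 8, 8, 4))
    if (i <= 20) g[2:4, 2:4, 2:4, 1] <- 1L else g[5:7, 5:7, 5:7, 2] <- 1L
    structure(g, edge = 24, voxel = 3)
  })
  classes <- rep(c("OB", "OR"), each = 20)
  fit <- heme_cnn(grids, classes, scheme = "two-label", epochs = 40,
                  seed = 2)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1])
  expect_gt(mean(predict(fit, grids, type = "class") == classes), 0.9)

  # identical seeds give identical loss histories and parameters
  fit2 <- heme_cnn(grids, classes, scheme = "two-label", epochs = 40,
                   seed = 2)
  expect_identical(fit$loss, fit2$loss)
  expect_equal(fit$params$conv1_W, fit2$params$conv1_W)

  # empty training set is refused
  expect_error(heme_cnn(list(), character(), scheme = "two-label"),
               "subscript|sample|empty")
})

test_that("sigmoid outputs are thresholded at 0.5 and decoded", {
  # decoding contract exercised through the documented rules
  expect_equal(decode_labels((c(0.9, 0.2) >= 0.5) + 0L, "two-label"),
               "OR")
  expect_equal(decode_labels((c(0.4, 0.4, 0.4) >= 0.5) + 0L,
                             "three-label"), "Others")
  expect_equal(decode_labels((c(0.6, 0.6) >= 0.5) + 0L, "two-label"),
               "OB-OR")

  # predict(type = "encoding") is the thresholded version of "prob"
  m <- heme_cnn_untrained(8, "three-label", seed = 3)
  g <- replicate(3, structure(array(rbinom(2048, 1, 0.1), c(8, 8, 8, 4)),
                              edge = 24, voxel = 3), simplify = FALSE)
  pr <- predict(m, g, type = "prob")
  expect_identical(predict(m, g, type = "encoding"),
                   (pr >= 0.5) + 0L)
  cl <- predict(m, g, type = "class")
  expect_true(all(cl %in% c("OB", "OR", "OB-OR", "ET", "Others")))
})

test_that("cross-validation partitions, stratifies and bookkeeps", {
  with_seed_test(10, {
    grids <- replicate(50, structure(
      array(rbinom(2048, 1, 0.05), c(8, 8, 8, 4)), edge = 24,
      voxel = 3), simplify = FALSE)
  })
  classes <- rep(c("OB", "OR"), times = c(22, 28))
  cv <- cv_heme_cnn(grids, classes, scheme = "two-label", k = 5,
                    epochs = 1, seed = 4)
  # each sample is tested exactly once
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(length(cv$predicted), 50L)
  expect_true(all(nzchar(cv$predicted)))
  # stratified: per-class fold sizes differ by at most one
  for (cl in c("OB", "OR")) {
    sizes <- table(cv$fold[classes == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # combined counts row-sum to the class totals
  expect_equal(unname(rowSums(cv$combined)), c(22, 28))
  expect_equal(sum(cv$combined), 50)
  # per-fold counts add to the combined matrix
  expect_equal(Reduce(`+`, cv$counts), cv$combined)
  # a class with fewer than k samples is refused by name
  expect_error(cv_heme_cnn(grids, rep(c("OB", "OR"), c(3, 47)),
                           scheme = "two-label", k = 5, epochs = 1),
               "OB")
})

test_that("the dataset accuracy score implements the TP-ratio formula", {
  expect_equal(sacc(c("OB", "OR"), c("OB", "OR")), 1)
  expect_equal(sacc(c("OB", "OR"), c("OR", "Others")), 0)
  # predictions decoding to Others are never true positives
  expect_equal(sacc(rep("OB", 4), c("OB", "Others", "OB", "OR")), 0.5)
  # matrix form: diagonal over the class list / total
  m <- matrix(c(8, 1, 0, 2, 7, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("OB", "OR"), c("OB", "OR", "Others")))
  expect_equal(sacc(m), 15 / 19)
  # equals the N_c-weighted mean of per-class recalls when no
  # prediction falls outside the class list
  m2 <- matrix(c(5, 3, 0, 2, 6, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("OB", "OR"), c("OB", "OR", "Others")))
  recalls <- c(5 / 8, 6 / 8)
  expect_equal(sacc(m2), sum(recalls * c(8, 8)) / 16)
  expect_error(sacc(m[0, , drop = FALSE]), "empty class list")
})

test_that("per-class metrics match a brute-force enumeration", {
  # perfect matrix: every metric 1 for every class
  perfect <- diag(c(10, 12, 8))
  dimnames(perfect) <- list(c("OB", "OR", "ET"),
                            c("OB", "OR", "ET"))
  pm <- per_class_metrics(cbind(perfect, Others = 0))
  expect_true(all(pm$mean == 1))

  # random integer matrices against the oracle
  for (s in 1:5) {
    m <- with_seed_test(s, matrix(rpois(12, 6), nrow = 3,
      dimnames = list(c("OB", "OR", "ET"),
                      c("OB", "OR", "ET", "Others"))))
    pm <- per_class_metrics(m)
    oracle <- metrics_oracle(m)
    for (cl in rownames(m))
      for (met in c("accuracy", "recall", "precision", "specificity")) {
        got <- pm$mean[pm$class == cl & pm$metric == met]
        want <- oracle[[cl]][[met]]
        if (is.na(want)) expect_true(is.nan(got) || is.na(got))
        else expect_equal(got, want, tolerance = 1e-12)
      }
  }

  # undefined ratios (0/0) are excluded from fold averages and reported
  m_zero <- matrix(c(0, 5, 0, 0, 7, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("OB", "OR"),
                                   c("OB", "OR", "Others")))
  pm <- per_class_metrics(m_zero)
  prec_ob <- pm[pm$class == "OB" & pm$metric == "precision", ]
  expect_equal(prec_ob$n_folds, 0L)
})

test_that("an untrained model on balanced data scores at chance level", {
  with_seed_test(20, {
    grids <- replicate(60, structure(
      array(rbinom(2048, 1, 0.08), c(8, 8, 8, 4)), edge = 24,
      voxel = 3), simplify = FALSE)
  })
  classes <- rep(c("OB", "OR", "ET"), each = 20)
  scores <- vapply(1:5, function(s) {
    m <- heme_cnn_untrained(8, "three-label", seed = s)
    sacc(classes, predict(m, grids, type = "class"),
         c("OB", "OR", "ET"))
  }, numeric(1))
  # chance for balanced 3-class data is 1/3; allow broad sampling noise
  expect_lt(mean(scores), 0.55)
})
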