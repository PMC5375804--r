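test_that("detection labels collapse to cotton vs foreign matter", {
  full <- rep(names(study_classes()), each = 20)
  lab <- detection_labels(full)
  expect_equal(sum(lab == "cotton"), 20)
  expect_equal(sum(lab == "foreign_matter"), 220)
  expect_equal(detection_labels(character(0)), character(0))
  expect_equal(unique(detection_labels(rep("cotton", 5))), "cotton")
  expect_error(detection_labels(c("cotton", "plastic")), "unknown class")
})

test_that("LOOCV is perfect on far-separated clusters and keeps its books straight", {
  tbl <- gaussian_feature_table(list(lo = -10, hi = 10), n_per = 20, p = 2,
                                seed = 3)
  for (clf in c("lda", "svm")) {
    rep <- loocv(tbl, c("f1", "f2"), task = "identification",
                 classifier = clf, class_col = "class")
    expect_equal(rep$accuracy, 1.0)
    expect_equal(sum(rep$confusion), 40)
    expect_equal(unname(rowSums(rep$confusion)), c(20, 20))
    expect_equal(sum(diag(rep$confusion)) / sum(rep$confusion), rep$accuracy)
  }
})

test_that("LOOCV predictions are invariant to sample order", {
  tbl <- gaussian_feature_table(list(a = 0, b = 2.5, c = 5), n_per = 12,
                                p = 3, seed = 8)
  tbl$sample_id <- sprintf("s%02d", seq_len(nrow(tbl)))
  set.seed(1)
  shuffled <- tbl[sample(nrow(tbl)), ]
  for (clf in c("lda", "svm")) {
    r1 <- loocv(tbl, paste0("f", 1:3), classifier = clf, id_col = "sample_id")
    r2 <- loocv(shuffled, paste0("f", 1:3), classifier = clf,
                id_col = "sample_id")
    p1 <- dplyr::arrange(r1$predictions, sample_id)
    p2 <- dplyr::arrange(r2$predictions, sample_id)
    expect_equal(p1, p2)
    expect_equal(r1$accuracy, r2$accuracy)
  }
})

test_that("permuted labels give chance-level LOOCV accuracy", {
  set.seed(12)
  tbl <- gaussian_feature_table(list(a = 0, b = 0), n_per = 30, p = 4,
                                seed = 40)
  tbl$class <- sample(tbl$class)
  rep <- loocv(tbl, paste0("f", 1:4), classifier = "lda")
  # central 99% binomial band around 0.5 at n = 60
  band <- qbinom(c(0.005, 0.995), 60, 0.5) / 60
  expect_gte(rep$accuracy, band[1] - 1e-9)
  expect_lte(rep$accuracy, band[2] + 1e-9)
})

test_that("LDA on 1-D two-class data equals the pooled-variance discriminant rule", {
  set.seed(33)
  for (i in 1:5) {
    tbl <- gaussian_feature_table(list(a = 0, b = runif(1, 1, 3)),
                                  n_per = 15, p = 1, seed = 100 + i)
    rep <- loocv(tbl, "f1", classifier = "lda")
    # brute-force oracle: 1-D Gaussian discriminant with pooled variance and
    # training-fold priors (the midpoint rule when the fold is balanced)
    x <- tbl$f1; y <- tbl$class
    oracle <- vapply(seq_along(x), function(j) {
      xa <- x[-j][y[-j] == "a"]; xb <- x[-j][y[-j] == "b"]
      s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) /
        (length(xa) + length(xb) - 2)
      pa <- length(xa) / (length(xa) + length(xb))
      da <- x[j] * mean(xa) / s2 - mean(xa)^2 / (2 * s2) + log(pa)
      db <- x[j] * mean(xb) / s2 - mean(xb)^2 / (2 * s2) + log(1 - pa)
      if (da >= db) "a" else "b"
    }, character(1))
    expect_equal(rep$predictions$predicted, oracle)
  }
  # with a balanced training set the rule is exactly the means' midpoint
  train <- gaussian_feature_table(list(a = 0, b = 2), n_per = 20, p = 1,
                                  seed = 200)
  fit <- MASS::lda(matrix(train$f1), grouping = factor(train$class))
  mid <- mean(c(mean(train$f1[train$class == "a"]),
                mean(train$f1[train$class == "b"])))
  probe <- matrix(mid + c(-0.3, -0.01, 0.01, 0.3))
  expect_equal(as.character(predict(fit, probe)$class), c("a", "a", "b", "b"))
})

test_that("single-class or undersized tasks are rejected", {
  tbl <- gaussian_feature_table(list(cotton = 0), n_per = 10, p = 2, seed = 2)
  expect_error(loocv(tbl, c("f1", "f2"), task = "detection"), "2 classes")
  tiny <- gaussian_feature_table(list(a = 0, b = 1), n_per = 1, p = 2,
                                 seed = 2)
  expect_error(loocv(tiny, c("f1", "f2")), "at least 2 samples")
})

test_that("feature-count sweep returns one accuracy per k and flags overruns", {
  set.seed(50)
  n <- 40
  base <- gaussian_feature_table(list(a = 0, b = 4), n_per = n / 2, p = 1,
                                 seed = 9)
  tbl <- tibble::tibble(class = base$class)
  # class signal lives only in the 0-Hz amplitude; higher components are noise
  tbl$amp_whole_1 <- base$f1
  for (k in 2:16) tbl[[sprintf("amp_whole_%d", k)]] <- rnorm(n)
  sweep <- feature_count_sweep(tbl, mode = "whole", task = "identification",
                               classifier = "lda", k_max = 15)
  expect_equal(sweep$k, 1:15)
  expect_equal(nrow(sweep), 15)
  # k = 1 already achieves within-epsilon of the best accuracy
  expect_gte(sweep$accuracy[1], max(sweep$accuracy) - 0.1)

  expect_error(feature_count_sweep(tbl, k_max = 20), "k_max exceeds")
})

test_that("degenerate all-identical features fall to chance accuracy", {
  tbl <- tibble::tibble(class = rep(c("a", "b", "c", "d"), each = 8))
  for (k in 1:3) tbl[[sprintf("amp_whole_%d", k)]] <- 1
  suppressWarnings({
    sweep <- feature_count_sweep(tbl, task = "identification",
                                 classifier = "lda", k_max = 3)
  })
  expect_true(all(sweep$accuracy <= 0.45))
})

test_that("the classification grid covers 4 sets x 2 tasks x 2 classifiers deterministically", {
  set.seed(71)
  # well-separated classes: every task/classifier cell is near-perfect, so
  # collapsing to detection can only merge classes, never split them
  tbl <- gaussian_feature_table(
    stats::setNames(as.list(seq(0, 55, by = 5)), names(study_classes())),
    n_per = 4, p = 2, sd = 0.3, seed = 15)
  names(tbl)[1:2] <- c("wf_peak_minus_rest", "wf_final_minus_rest")
  for (mode in c("whole", "rising", "falling")) {
    for (k in 1:10) {
      tbl[[sprintf("amp_%s_%d", mode, k)]] <-
        tbl$wf_peak_minus_rest + rnorm(nrow(tbl), 0, 0.2)
    }
  }
  grid <- run_classification_grid(tbl, feature_count = 10)
  expect_equal(nrow(grid), 16)
  expect_equal(sort(unique(grid$n_features)), c(2L, 10L))
  expect_equal(
    unname(vapply(split(grid$n_features, grid$feature_set), unique, 0L)),
    c(10L, 10L, 2L, 10L))
  grid2 <- run_classification_grid(tbl, feature_count = 10)
  expect_equal(grid$accuracy, grid2$accuracy)

  wide <- classification_table(grid)
  expect_equal(nrow(wide), 4)
  expect_true(all(c("detection_lda", "identification_svm") %in% names(wide)))

  expect_error(
    run_classification_grid(tbl[, setdiff(names(tbl), "wf_final_minus_rest")],
                            feature_count = 10),
    "lacks columns")
})
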