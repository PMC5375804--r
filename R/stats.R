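#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalization of the two-sample t test on mean vectors:
#' `T2 = (n1 n2 / (n1 + n2)) d' S^-1 d` with `d` the mean difference and `S`
#' the pooled sample covariance. Inference uses the exact F transform
#' `F = T2 (n1 + n2 - p - 1) / ((n1 + n2 - 2) p)` with
#' `(p, n1 + n2 - p - 1)` degrees of freedom. For two groups this is
#' identical to a one-way MANOVA.
#'
#' @param group1,group2 Numeric matrices (or data frames) with the same
#'   number of columns; rows are samples.
#' @return An object of class `hotelling_t2` with `statistic` (T2),
#'   `f_statistic`, `df1`, `df2`, `p_value` and sample sizes.
#' @examples
#' x <- matrix(rnorm(40), 20); y <- matrix(rnorm(40, 1), 20)
#' hotelling_t2(x, y)
#' @export
hotelling_t2 <- function(group1, group2) {
  x <- as.matrix(group1); y <- as.matrix(group2)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x); n2 <- nrow(y); p <- ncol(x)
  if (n1 + n2 <= p + 1) {
    stop("too few samples: need n1 + n2 > p + 1", call. = FALSE)
  }
  d <- colMeans(x) - colMeans(y)
  s_pooled <- ((n1 - 1) * stats::cov(x) + (n2 - 1) * stats::cov(y)) / (n1 + n2 - 2)
  sol <- tryCatch(solve(s_pooled, d), error = function(e) NULL)
  if (is.null(sol)) {
    stop("singular pooled covariance: reduce the feature set or apply shrinkage",
         call. = FALSE)
  }
  t2 <- as.numeric((n1 * n2 / (n1 + n2)) * crossprod(d, sol))
  df1 <- p
  df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  structure(list(statistic = t2, f_statistic = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 n1 = n1, n2 = n2),
            class = "hotelling_t2")
}

#' @export
print.hotelling_t2 <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$statistic, x$df1, x$df2, x$f_statistic, x$p_value))
  invisible(x)
}

#' @rdname hotelling_t2
#' @param x A `hotelling_t2` object.
#' @param ... Unused.
#' @method tidy hotelling_t2
#' @export
tidy.hotelling_t2 <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, f_statistic = x$f_statistic,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' @rdname hotelling_t2
#' @method glance hotelling_t2
#' @export
glance.hotelling_t2 <- function(x, ...) tidy.hotelling_t2(x)

#' Pairwise Hotelling T-squared tests over all class pairs
#'
#' Runs [hotelling_t2()] for every unordered pair of classes in a feature
#' table (66 pairs for 12 classes). No multiple-testing correction is
#' applied; separation is conventionally judged against a raw threshold of
#' 0.001. Per-pair failures (e.g. singular covariance) are recorded, not
#' fatal.
#'
#' @param data Data frame with a class column and feature columns.
#' @param features Character vector of feature column names.
#' @param class_col Name of the class column (default `"class"`).
#' @return An object of class `pairwise_hotelling`: a `pairs` tibble and a
#'   symmetric p-value matrix (diagonal `NA`).
#' @export
pairwise_hotelling <- function(data, features, class_col = "class") {
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            class_col %in% names(data))
  cls <- as.character(data[[class_col]])
  levels <- unique(cls)
  counts <- table(cls)
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  x <- as.matrix(data[, features, drop = FALSE])
  combos <- utils::combn(levels, 2)
  rows <- purrr::map(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    res <- tryCatch(hotelling_t2(x[cls == a, , drop = FALSE],
                                 x[cls == b, , drop = FALSE]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(class1 = a, class2 = b, statistic = NA_real_,
                     f_statistic = NA_real_, df1 = NA_integer_,
                     df2 = NA_integer_, p_value = NA_real_,
                     error = conditionMessage(res))
    } else {
      dplyr::mutate(tidy.hotelling_t2(res), class1 = a, class2 = b,
                    error = NA_character_, .before = 1)
    }
  })
  pairs <- dplyr::bind_rows(rows)
  pmat <- matrix(NA_real_, length(levels), length(levels),
                 dimnames = list(levels, levels))
  for (i in seq_len(nrow(pairs))) {
    pmat[pairs$class1[i], pairs$class2[i]] <- pairs$p_value[i]
    pmat[pairs$class2[i], pairs$class1[i]] <- pairs$p_value[i]
  }
  structure(list(pairs = pairs, p_matrix = pmat, features = features),
            class = "pairwise_hotelling")
}

#' @export
print.pairwise_hotelling <- function(x, ...) {
  cat(sprintf("<pairwise_hotelling> %d pairs on %d features; %d with p < 0.001\n",
              nrow(x$pairs), length(x$features),
              sum(x$pairs$p_value < 0.001, na.rm = TRUE)))
  invisible(x)
}

#' @rdname pairwise_hotelling
#' @param x A `pairwise_hotelling` object.
#' @param ... Unused.
#' @method tidy pairwise_hotelling
#' @export
tidy.pairwise_hotelling <- function(x, ...) x$pairs

#' Canonical discriminant analysis
#'
#' Projects the feature space onto the canonical variates that maximize
#' between-class relative to within-class scatter, by the generalized
#' eigenproblem `B v = lambda W v` (solved symmetrically through a Cholesky
#' factor of the pooled within-class covariance). Scores are scaled so the
#' pooled within-class covariance of the scores is the identity; eigenvalues
#' (of `W^-1 B` on scatter matrices) come back non-increasing, and each
#' eigenvector's first nonzero loading is made positive so signs are
#' deterministic. There are `min(p, k - 1)` variates for `p` features and
#' `k` classes.
#'
#' @param data Data frame with class and feature columns.
#' @param features Feature column names.
#' @param class_col Name of the class column.
#' @param shrinkage Ridge weight in `[0, 1)` blended into the within-class
#'   covariance only if it is singular (a logged fallback, never default).
#' @return An object of class `canonical_discriminant`: `scores` (n x m),
#'   `eigenvalues`, `loadings`, `class` labels.
#' @export
canonical_discriminant <- function(data, features, class_col = "class",
                                   shrinkage = 1e-8) {
  stopifnot(is.data.frame(data), all(features %in% names(data)))
  x <- as.matrix(data[, features, drop = FALSE])
  cls <- as.character(data[[class_col]])
  levels <- unique(cls)
  n <- nrow(x); p <- ncol(x); k <- length(levels)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  grand <- colMeans(x)
  w_scatter <- matrix(0, p, p)
  b_scatter <- matrix(0, p, p)
  for (lv in levels) {
    xi <- x[cls == lv, , drop = FALSE]
    ci <- sweep(xi, 2, colMeans(xi))
    w_scatter <- w_scatter + crossprod(ci)
    dm <- colMeans(xi) - grand
    b_scatter <- b_scatter + nrow(xi) * tcrossprod(dm)
  }
  sw <- w_scatter / (n - k)   # pooled within-class covariance
  ch <- tryCatch(chol(sw), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular within-class scatter: applying ridge shrinkage fallback")
    sw <- (1 - shrinkage) * sw +
      shrinkage * mean(diag(sw) + 1e-12) * diag(p)
    ch <- chol(sw)
  }
  # symmetric form: L^-1 B L^-T with Sw = L L'
  li <- backsolve(ch, diag(p), transpose = TRUE)  # L^-1 where L = t(ch)
  sym <- li %*% (b_scatter / (n - k)) %*% t(li)
  eig <- eigen((sym + t(sym)) / 2, symmetric = TRUE)
  m <- min(p, k - 1)
  vecs <- t(li) %*% eig$vectors[, seq_len(m), drop = FALSE]  # A' Sw A = I
  # deterministic sign: first nonzero loading positive
  for (j in seq_len(m)) {
    nz <- which(abs(vecs[, j]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(x, 2, grand) %*% vecs
  colnames(scores) <- paste0("can", seq_len(m))
  rownames(vecs) <- features
  structure(list(scores = scores,
                 eigenvalues = pmax(eig$values[seq_len(m)], 0),
                 loadings = vecs, class = cls, features = features),
            class = "canonical_discriminant")
}

#' @export
print.canonical_discriminant <- function(x, ...) {
  cat(sprintf("<canonical_discriminant> %d variates over %d classes; eigenvalues: %s\n",
              ncol(x$scores), length(unique(x$class)),
              paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", ")))
  invisible(x)
}

#' @rdname canonical_discriminant
#' @param x A `canonical_discriminant` object.
#' @param ... Unused.
#' @method tidy canonical_discriminant
#' @export
tidy.canonical_discriminant <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(class = x$class),
                   tibble::as_tibble(x$scores))
}

#' @rdname canonical_discriminant
#' @method glance canonical_discriminant
#' @export
glance.canonical_discriminant <- function(x, ...) {
  tibble::tibble(variate = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 proportion = x$eigenvalues / sum(x$eigenvalues))
}
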