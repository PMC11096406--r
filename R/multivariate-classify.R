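# Standardize columns by training-fold mean/sd; constant columns get sd 1
# so they become exactly zero after centering.
fold_standardize <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  sd[sd == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sd, "/"),
       test = sweep(sweep(test, 2, mu, check.margin = FALSE), 2, sd, "/"))
}

# Deterministic multinomial logistic fit: zero starting weights and a small
# L2 ridge (nnet's weight decay) that guarantees a finite optimum under
# separation or collinearity without materially changing dense-data fits.
fit_multinom <- function(X, y, ridge = 1e-6) {
  df <- data.frame(y = y, X)
  n_wts <- (ncol(X) + 2L) * nlevels(y)
  nnet::multinom(y ~ ., data = df, trace = FALSE, decay = ridge,
                 Wts = rep(0, n_wts), maxit = 500)
}

#' Leave-one-out cross-validated multiclass classification
#'
#' For each sample, a multinomial (softmax) logistic model is fit on all
#' other samples — features standardized using the training fold's mean and
#' standard deviation, so no information leaks from the held-out sample —
#' and the held-out sample's rate class is predicted. Predictions are
#' accumulated into a confusion matrix (rows = true class, columns =
#' predicted class). A small L2 ridge (default 1e-6 on standardized
#' features) keeps the fit well defined under separation or duplicated
#' features; the procedure is deterministic given the cohort.
#'
#' @param features Feature table with `rate_class` and the five parameter
#'   columns; at least 2 samples per class.
#' @param ridge L2 penalty on standardized coefficients (default 1e-6).
#' @param feature_cols Columns used as predictors (default the five
#'   mechanical parameters).
#' @return A list of class `loocv_result`: `confusion` (3 x 3 integer
#'   matrix with rate labels), `truth` and `predicted` factors.
#' @export
loocv_classify <- function(features, ridge = 1e-6,
                           feature_cols = feature_columns) {
  if (identical(feature_cols, feature_columns)) check_feature_table(features)
  stopifnot(all(feature_cols %in% names(features)),
            "rate_class" %in% names(features))
  X <- as.matrix(features[, feature_cols])
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite")
  y <- factor(features$rate_class)
  if (nlevels(y) < 2L || any(table(y) < 2L)) {
    stop("need at least 2 samples in each class")
  }
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    std <- fold_standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    fit <- fit_multinom(std$train, droplevels(y[-i]), ridge = ridge)
    newdata <- as.data.frame(std$test)
    pred[i] <- as.character(stats::predict(fit, newdata = newdata))
  }
  pred <- factor(pred, levels = levels(y))
  confusion <- table(truth = y, predicted = pred)
  structure(
    list(confusion = unclass(confusion), truth = y, predicted = pred),
    class = "loocv_result"
  )
}

pair_counts <- function(confusion) {
  m <- as.matrix(confusion)
  n <- sum(m)
  list(
    tp = sum(choose(m, 2)),                # together in both labelings
    row_pairs = sum(choose(rowSums(m), 2)),
    col_pairs = sum(choose(colSums(m), 2)),
    total_pairs = choose(n, 2)
  )
}

#' Classification quality metrics from a confusion matrix
#'
#' Computes accuracy (trace over total), the multiclass (R_k) Matthews
#' correlation coefficient, the Fowlkes-Mallows index and the adjusted Rand
#' index. FMI and ARI use the pair-counting (partition comparison)
#' definitions, consistent with their clustering origin; both are therefore
#' functions of the confusion matrix alone. Degenerate-denominator
#' conventions: MCC and FMI are defined as 0 when a denominator factor
#' vanishes; ARI's chance-corrected denominator can only vanish for trivial
#' partitions, where 0 is returned as well.
#'
#' @param confusion A k x k matrix of counts (rows = truth, columns =
#'   predicted), or a `loocv_result`.
#' @return A list with `accuracy`, `mcc`, `fmi`, `ari`.
#' @examples
#' classification_metrics(diag(10, 3))
#' @export
classification_metrics <- function(confusion) {
  if (inherits(confusion, "loocv_result")) confusion <- confusion$confusion
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m) || any(m < 0)) {
    stop("confusion must be a square nonnegative count matrix")
  }
  n <- sum(m)
  if (n < 2) stop("confusion matrix must hold at least 2 samples")
  acc <- sum(diag(m)) / n

  tk <- rowSums(m)  # true class totals
  pk <- colSums(m)  # predicted class totals
  mcc_num <- sum(diag(m)) * n - sum(pk * tk)
  mcc_den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  mcc <- if (mcc_den > 0) mcc_num / mcc_den else 0

  pc <- pair_counts(m)
  fmi <- if (pc$row_pairs > 0 && pc$col_pairs > 0) {
    pc$tp / sqrt(pc$row_pairs * pc$col_pairs)
  } else {
    0
  }
  expected <- pc$row_pairs * pc$col_pairs / pc$total_pairs
  ari_den <- (pc$row_pairs + pc$col_pairs) / 2 - expected
  ari <- if (ari_den != 0) (pc$tp - expected) / ari_den else 0

  list(accuracy = acc, mcc = mcc, fmi = fmi, ari = ari)
}

#' Per-feature contribution fractions of the multiclass classifier
#'
#' Fits the multinomial logistic model on the full (standardized) cohort
#' and summarizes how much each feature drives the class decision. The
#' default `"coef"` method converts the fitted coefficients to the
#' symmetric (sum-to-zero over classes) softmax parameterization and
#' reports, per feature, the mean absolute standardized coefficient across
#' the three classes, normalized so the fractions sum to 1. The
#' `"permutation"` alternative instead measures the drop in in-sample
#' mean log-likelihood when each feature column is permuted (averaged over
#' `n_perm` seeded permutations), normalized the same way.
#'
#' @param features Feature table with the five parameter columns.
#' @param method `"coef"` (default) or `"permutation"`.
#' @param ridge L2 penalty, as in [loocv_classify()].
#' @param n_perm Permutations per feature for the permutation method.
#' @param seed Seed for the permutation method.
#' @return Named numeric vector of nonnegative fractions summing to 1, in
#'   feature-table order.
#' @export
feature_contributions <- function(features,
                                  method = c("coef", "permutation"),
                                  ridge = 1e-6, n_perm = 20, seed = 1) {
  check_feature_table(features)
  method <- match.arg(method)
  X <- as.matrix(features[, feature_columns])
  y <- factor(features$rate_class)
  std <- fold_standardize(X, X)
  fit <- fit_multinom(std$train, y, ridge = ridge)
  if (!fit$convergence == 0) {
    warning("multinomial fit did not fully converge; contributions use ",
            "the best iterate")
  }
  if (method == "coef") {
    # coef() is (K-1) x (p+1) relative to the reference class; rebuild the
    # full K x p slope block and center per feature (sum-to-zero softmax).
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    B <- rbind(0, cf[, -1, drop = FALSE])
    B <- sweep(B, 2, colMeans(B))
    raw <- colMeans(abs(B))
  } else {
    ll <- function(Xs) {
      pr <- stats::predict(fit, newdata = as.data.frame(Xs),
                           type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
      mean(log(pmax(pr[cbind(seq_along(y), as.integer(y))], 1e-12)))
    }
    base_ll <- ll(std$train)
    raw <- withr::with_seed(seed, {
      vapply(seq_len(ncol(X)), function(j) {
        drops <- vapply(seq_len(n_perm), function(r) {
          Xp <- std$train
          Xp[, j] <- sample(Xp[, j])
          base_ll - ll(Xp)
        }, numeric(1))
        max(mean(drops), 0)
      }, numeric(1))
    })
  }
  names(raw) <- feature_columns
  if (sum(raw) == 0) {
    rep(1 / length(raw), length(raw))
  } else {
    raw / sum(raw)
  }
}

#' Full multivariate classification report
#'
#' Runs [loocv_classify()], [classification_metrics()] and
#' [feature_contributions()] on a screened feature table.
#'
#' @inheritParams loocv_classify
#' @param contribution_method Passed to [feature_contributions()].
#' @return An object of class `classification_report` with `confusion`,
#'   `metrics` and `contributions`.
#' @export
classify_report <- function(features, ridge = 1e-6,
                            contribution_method = "coef") {
  cv <- loocv_classify(features, ridge = ridge)
  structure(
    list(confusion = cv$confusion,
         metrics = classification_metrics(cv$confusion),
         contributions = feature_contributions(
           features, method = contribution_method, ridge = ridge)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("LOOCV confusion matrix (rows = true rate, cols = predicted):\n")
  print(x$confusion)
  with(x$metrics, cat(sprintf(
    "accuracy = %.4f, MCC = %.4f, FMI = %.4f, ARI = %.4f\n",
    accuracy, mcc, fmi, ari)))
  cat("feature contributions:\n")
  print(round(x$contributions, 4))
  invisible(x)
}
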