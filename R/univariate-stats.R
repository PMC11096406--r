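feature_columns <- c("ut_stress", "ut_strain", "toughness", "mu", "gamma")

check_feature_table <- function(features) {
  missing <- setdiff(c("rate_class", feature_columns), names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  invisible(NULL)
}

#' Screen outliers by interquartile-range fences
#'
#' For each of the five parameters, quartiles Q1 and Q3 are computed with
#' linear interpolation between order statistics (R quantile type 7) and
#' fences placed at `Q1 - k*IQR` and `Q3 + k*IQR` (default `k = 3`). A
#' sample is removed iff at least one of its five parameters falls strictly
#' outside its fences; values exactly on a fence are kept. The pass is
#' single-shot — fences are not recomputed after removal. Fences default to
#' the pooled cohort ("the distribution of the parameter"); `scope =
#' "by_rate"` computes them within each rate class instead.
#'
#' @param features Feature table from [build_feature_table()].
#' @param k Fence multiplier on the IQR (default 3).
#' @param scope `"pooled"` (default) or `"by_rate"`.
#' @return A list of class `outlier_screen`: `kept` and `removed` subsets
#'   of `features`, plus the `fences` matrix.
#' @export
outlier_screen <- function(features, k = 3, scope = c("pooled", "by_rate")) {
  check_feature_table(features)
  scope <- match.arg(scope)
  fence_of <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  }
  out <- rep(FALSE, nrow(features))
  fences <- list()
  groups <- if (scope == "pooled") {
    list(pooled = seq_len(nrow(features)))
  } else {
    split(seq_len(nrow(features)), features$rate_class)
  }
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (p in feature_columns) {
      f <- fence_of(features[[p]][idx])
      fences[[paste(g, p, sep = ".")]] <-
        data.frame(group = g, parameter = p, lower = f["lower"],
                   upper = f["upper"], row.names = NULL)
      x <- features[[p]][idx]
      out[idx] <- out[idx] | x < f["lower"] | x > f["upper"]
    }
  }
  structure(
    list(kept = features[!out, , drop = FALSE],
         removed = features[out, , drop = FALSE],
         fences = do.call(rbind, fences), k = k, scope = scope),
    class = "outlier_screen"
  )
}

# Default test battery; each element returns list(statistic, p.value).
# decide_pair() accepts overrides so the branch logic can be exercised with
# stubbed p-values.
default_tests <- function() {
  list(
    shapiro = function(x) {
      h <- stats::shapiro.test(x)
      list(statistic = unname(h$statistic), p.value = h$p.value)
    },
    f = function(x, y) {
      h <- stats::var.test(x, y)
      list(statistic = unname(h$statistic), p.value = h$p.value)
    },
    t_pooled = function(x, y) {
      h <- stats::t.test(x, y, var.equal = TRUE)
      list(statistic = unname(h$statistic), p.value = h$p.value)
    },
    t_welch = function(x, y) {
      h <- stats::t.test(x, y, var.equal = FALSE)
      list(statistic = unname(h$statistic), p.value = h$p.value)
    },
    ks = function(x, y) {
      h <- suppressWarnings(stats::ks.test(x, y))
      list(statistic = unname(h$statistic), p.value = h$p.value)
    },
    wilcoxon = function(x, y) {
      exact <- length(x) <= 25 && length(y) <= 25 &&
        !anyDuplicated(c(x, y))
      h <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)
      )
      list(statistic = unname(h$statistic), p.value = h$p.value)
    }
  )
}

#' Normality-gated two-sample decision tree
#'
#' Compares one parameter between two loading rates with the following
#' branch logic at significance `alpha`:
#' \enumerate{
#'   \item Shapiro-Wilk normality on each sample.
#'   \item If both retain normality (p > alpha): an F-test for equal
#'     variances selects the pooled-variance t-test (p > alpha) or the
#'     unequal-variance (Welch) t-test, whose p-value decides.
#'   \item Otherwise: the two-sample Kolmogorov-Smirnov test. If it
#'     retains (same continuous shape), the Wilcoxon rank-sum test
#'     decides; if it rejects (different shapes), the Welch t-test
#'     decides.
#' }
#' The conclusion is "not equal" iff the terminal p-value is `<= alpha`.
#' No multiple-testing correction is applied: decisions are raw per-pair
#' calls at `alpha`.
#'
#' Wilcoxon uses the exact null distribution when both samples have at most
#' 25 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (each n >= 3) of the same parameter at two
#'   rates.
#' @param alpha Significance level for every test in the tree
#'   (default 0.01).
#' @param tests Optional named list overriding any of `shapiro`, `f`,
#'   `t_pooled`, `t_welch`, `ks`, `wilcoxon`; each must return
#'   `list(statistic, p.value)`. Intended for injecting stubs.
#' @return An object of class `decision_trace`: `steps` data frame (test,
#'   statistic, p_value, branch), `terminal_test`, `p_value`, `conclusion`
#'   (`"equal"` / `"not equal"`) and `alpha`.
#' @export
decide_pair <- function(x, y, alpha = 0.01, tests = NULL) {
  if (length(x) < 3L || length(y) < 3L) {
    stop("each sample must have at least 3 observations")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  tb <- utils::modifyList(default_tests(), tests %||% list())
  # every test in the tree is invariant under a common positive rescale;
  # dividing by the pooled maximum keeps variance computations finite for
  # extremely heavy-tailed inputs
  scale <- max(abs(c(x, y)))
  if (is.finite(scale) && scale > 0) {
    x <- x / scale
    y <- y / scale
  }
  steps <- list()
  add <- function(test, res, branch) {
    steps[[length(steps) + 1L]] <<- data.frame(
      test = test, statistic = res$statistic, p_value = res$p.value,
      branch = branch, stringsAsFactors = FALSE
    )
    res$p.value
  }
  p_swx <- add("shapiro_x", tb$shapiro(x), "")
  p_swy <- add("shapiro_y", tb$shapiro(y), "")
  if (p_swx > alpha && p_swy > alpha) {
    p_f <- add("f_variance", tb$f(x, y),
               "both normal -> compare variances")
    if (p_f > alpha) {
      terminal <- "t_pooled"
      p_term <- add(terminal, tb$t_pooled(x, y),
                    "equal variances -> pooled t")
    } else {
      terminal <- "t_welch"
      p_term <- add(terminal, tb$t_welch(x, y),
                    "unequal variances -> Welch t")
    }
  } else {
    p_ks <- add("ks", tb$ks(x, y), "non-normal -> compare shapes")
    if (p_ks > alpha) {
      terminal <- "wilcoxon"
      p_term <- add(terminal, tb$wilcoxon(x, y),
                    "same shape -> rank-sum")
    } else {
      terminal <- "t_welch"
      p_term <- add(terminal, tb$t_welch(x, y),
                    "different shapes -> Welch t")
    }
  }
  structure(
    list(steps = do.call(rbind, steps), terminal_test = terminal,
         p_value = p_term,
         conclusion = if (p_term <= alpha) "not equal" else "equal",
         alpha = alpha),
    class = "decision_trace"
  )
}

#' @export
print.decision_trace <- function(x, ...) {
  cat(sprintf("decision tree at alpha = %g\n", x$alpha))
  print(x$steps, row.names = FALSE)
  cat(sprintf("conclusion: %s (terminal %s, p = %.4g)\n",
              x$conclusion, x$terminal_test, x$p_value))
  invisible(x)
}

#' Cohen's d standardized mean difference
#'
#' `d = |mean(x) - mean(y)| / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @return The (nonnegative) effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least 2 observations")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 <= 0) stop("pooled variance is zero; Cohen's d is undefined")
  abs(mean(x) - mean(y)) / sqrt(sp2)
}

#' Power of the two-sample t-test by the noncentral t distribution
#'
#' Exact power for group sizes `n1` and `n2 = ratio * n1` at effect size
#' `d`: noncentrality `ncp = d * sqrt(n1 * n2 / (n1 + n2))` on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param n1 First group size (>= 2).
#' @param d Cohen's d effect size (> 0).
#' @param alpha Significance level.
#' @param ratio Allocation ratio `n2 / n1` (default 1); `n2` is rounded up
#'   to an integer.
#' @param tails `"one"` or `"two"`.
#' @return Achieved power in (0, 1).
#' @export
power_t_test2 <- function(n1, d, alpha = 0.05, ratio = 1,
                          tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(n1 >= 2, d > 0, alpha > 0, alpha < 1, ratio > 0)
  n2 <- ceiling(ratio * n1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp)
  }
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Smallest integer `n1` (with `n2 = ceiling(ratio * n1)`) whose exact
#' noncentral-t power reaches the requested power, found by doubling the
#' bracket and bisecting. By construction `power(n) >= power_target` and
#' `power(n - 1) < power_target`.
#'
#' @param d Cohen's d effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power, in (alpha, 1) (default 0.85).
#' @param ratio Allocation ratio `n2 / n1` (default 1).
#' @param tails `"one"` or `"two"`.
#' @return Integer per-group sample size `n1`.
#' @examples
#' min_sample_size(d = 0.4, alpha = 0.05, power = 0.85, tails = "one")
#' @export
min_sample_size <- function(d, alpha = 0.05, power = 0.85, ratio = 1,
                            tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(d > 0, power > alpha, power < 1)
  pw <- function(n) power_t_test2(n, d, alpha, ratio, tails)
  hi <- 2L
  while (pw(hi) < power) {
    hi <- hi * 2L
    if (hi > 1e7) stop("requested power not reachable at a feasible n")
  }
  lo <- 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Run the full univariate comparison over a cohort
#'
#' Applies [decide_pair()] to every parameter (ultimate tensile stress and
#' strain, toughness, mu, gamma) for every pair of loading rates: 15
#' decisions on a three-rate cohort.
#'
#' @param features Screened feature table; all three rate classes must be
#'   present.
#' @param alpha Significance level (default 0.01).
#' @return A data frame with one row per (parameter, pair): terminal test,
#'   statistic, p-value, conclusion, and Cohen's d for the pair. The full
#'   `decision_trace` objects are attached as attribute `"traces"`.
#' @export
run_univariate <- function(features, alpha = 0.01) {
  check_feature_table(features)
  rates <- sort(unique(features$rate_class))
  if (length(rates) != 3L) {
    stop("feature table must contain exactly the three rate classes")
  }
  pairs <- utils::combn(rates, 2)
  traces <- list()
  rows <- list()
  for (p in feature_columns) {
    for (j in seq_len(ncol(pairs))) {
      ra <- pairs[1, j]; rb <- pairs[2, j]
      x <- features[[p]][features$rate_class == ra]
      y <- features[[p]][features$rate_class == rb]
      tr <- decide_pair(x, y, alpha = alpha)
      key <- sprintf("%s:%g-%g", p, ra, rb)
      traces[[key]] <- tr
      rows[[key]] <- data.frame(
        parameter = p, rate_a = ra, rate_b = rb,
        terminal_test = tr$terminal_test,
        statistic = tr$steps$statistic[nrow(tr$steps)],
        p_value = tr$p_value, conclusion = tr$conclusion,
        cohens_d = cohens_d(x, y), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "traces") <- traces
  attr(res, "alpha") <- alpha
  res
}

#' Effect-size matrix and aggregate for a cohort
#'
#' Cohen's d for every (parameter, rate pair); the paper-style single
#' summary number can be taken as the mean or the max of the matrix —
#' both aggregators are returned without asserting either as canonical.
#'
#' @param features Feature table with the three rate classes.
#' @return A list with the 5 x 3 `d` matrix and scalar `mean` and `max`.
#' @export
cohens_d_matrix <- function(features) {
  check_feature_table(features)
  rates <- sort(unique(features$rate_class))
  pairs <- utils::combn(rates, 2)
  d <- matrix(NA_real_, nrow = length(feature_columns),
              ncol = ncol(pairs),
              dimnames = list(feature_columns,
                              apply(pairs, 2, paste, collapse = "-")))
  for (p in feature_columns) {
    for (j in seq_len(ncol(pairs))) {
      x <- features[[p]][features$rate_class == pairs[1, j]]
      y <- features[[p]][features$rate_class == pairs[2, j]]
      d[p, j] <- cohens_d(x, y)
    }
  }
  list(d = d, mean = mean(d), max = max(d))
}
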