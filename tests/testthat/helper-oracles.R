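# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exact two-sided Wilcoxon rank-sum p-value by enumerating all
# choose(nx+ny, nx) assignments of the pooled ranks to group x
# (two-tailed doubling convention, capped at 1).
wilcoxon_enum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Pair-counting agreement indices computed by brute force over all sample
# pairs of two label vectors.
pair_metrics_enum <- function(truth, pred) {
  n <- length(truth)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- truth[i] == truth[j]
      b <- pred[i] == pred[j]
      if (a && b) ss <- ss + 1
      else if (a && !b) sd <- sd + 1
      else if (!a && b) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  tot <- ss + sd + ds + dd
  fmi <- if ((ss + sd) > 0 && (ss + ds) > 0) {
    ss / sqrt((ss + sd) * (ss + ds))
  } else 0
  expected <- (ss + sd) * (ss + ds) / tot
  den <- ((ss + sd) + (ss + ds)) / 2 - expected
  ari <- if (den != 0) (ss - expected) / den else 0
  list(fmi = fmi, ari = ari)
}

# Central-difference derivative, used to check stress = dPsi/dlambda.
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Small synthetic feature table with a controllable class separation, for
# classifier tests that do not need the full tensile machinery.
make_feature_table <- function(n_per_class = c(20, 20, 20), delta = 0,
                               seed = 1) {
  withr::with_seed(seed, {
    rates <- c(0.3, 2, 8)
    rows <- lapply(1:3, function(k) {
      n <- n_per_class[k]
      base <- matrix(rnorm(n * 5), n, 5)
      base <- base + (k - 1) * delta
      df <- as.data.frame(abs(base) + 0.1)
      names(df) <- c("ut_stress", "ut_strain", "toughness", "mu", "gamma")
      cbind(data.frame(sample_id = sprintf("r%d_%02d", k, seq_len(n)),
                       rate_class = rates[k]), df)
    })
    do.call(rbind, rows)
  })
}
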