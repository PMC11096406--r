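#' Quartile triplet describing a positive, right-skewed parameter
#'
#' @param median,q25,q75 Strictly positive numbers with
#'   `q25 < median < q75`.
#' @return A list of class `param_dist`.
#' @export
param_dist <- function(median, q25, q75) {
  vals <- c(median = median, q25 = q25, q75 = q75)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("median, q25 and q75 must all be strictly positive")
  }
  if (!(q25 < median && median < q75)) {
    stop("quartiles must satisfy q25 < median < q75")
  }
  structure(list(median = median, q25 = q25, q75 = q75),
            class = "param_dist")
}

#' Calibrate a lognormal law to a median/quartile triplet
#'
#' Returns the lognormal whose median equals the requested median and whose
#' log-scale spread reproduces the requested quartile ratio:
#' `meanlog = log(median)` and
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))` (the 0.75 normal quantile is
#' approximately 0.67449). The calibrated law is log-symmetric, so its
#' 25th/75th percentiles bracket the target quartiles symmetrically in log
#' space; when the requested triplet is itself log-symmetric they are
#' matched exactly.
#'
#' @param dist A [param_dist()].
#' @return Named numeric vector `c(meanlog, sdlog)` usable with
#'   [stats::rlnorm()].
#' @examples
#' calibrate_lognormal(param_dist(0.32, 0.17, 0.66))
#' @export
calibrate_lognormal <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  c(meanlog = log(dist$median),
    sdlog = log(dist$q75 / dist$q25) / (2 * stats::qnorm(0.75)))
}

#' Calibrate a quartile-exact split lognormal law
#'
#' A two-piece ("split") lognormal: `log(X) = log(median) + s * Z` with
#' `Z` standard normal and `s = sdlog_lower` when `Z < 0`,
#' `s = sdlog_upper` when `Z >= 0`, where
#' `sdlog_lower = log(median/q25) / qnorm(0.75)` and
#' `sdlog_upper = log(q75/median) / qnorm(0.75)`. This reproduces the
#' requested median, 25th and 75th percentiles exactly for any positive
#' ordered triplet, and collapses to the plain lognormal of
#' [calibrate_lognormal()] when the triplet is log-symmetric. It is the law
#' the cohort generator samples from, so that strongly asymmetric triplets
#' (such as a strain-stiffening exponent with quartiles 0.01/0.07/0.12)
#' keep their configured quartiles.
#'
#' @param dist A [param_dist()].
#' @return Named numeric vector `c(log_median, sdlog_lower, sdlog_upper)`.
#' @seealso [calibrate_lognormal()] for the single-scale log-symmetric
#'   calibration.
#' @export
calibrate_split_lognormal <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  z75 <- stats::qnorm(0.75)
  c(log_median = log(dist$median),
    sdlog_lower = log(dist$median / dist$q25) / z75,
    sdlog_upper = log(dist$q75 / dist$median) / z75)
}

# Draw n values from the split lognormal calibrated to `dist`, with an
# optional standardized location shift in units of the mean log-scale
# spread (the rate_effect mechanism).
r_param_dist <- function(n, dist, shift = 0) {
  cal <- calibrate_split_lognormal(dist)
  z <- stats::rnorm(n)
  s <- ifelse(z < 0, cal["sdlog_lower"], cal["sdlog_upper"])
  spread <- (cal["sdlog_lower"] + cal["sdlog_upper"]) / 2
  exp(cal["log_median"] + shift * spread + s * z)
}

#' Configuration of a synthetic three-rate tensile cohort
#'
#' Defaults reproduce the study conditions of the analysis this package
#' implements: three loading-rate classes at 0.3, 2 and 8 mm/s with
#' post-screening cohort sizes 95, 92 and 102; per-sample material
#' parameters (`mu`, `gamma`) and rupture strain drawn from quartile-exact
#' split lognormal laws ([calibrate_split_lognormal()]) matching the pooled
#' cohort summary (mu: median 0.32 MPa,
#' quartiles 0.17/0.66; gamma: 0.07, 0.01/0.12; rupture strain: 1.69,
#' 1.27/2.47); ASTM D638 Type V gauge geometry (gauge length 7.62 mm,
#' width 3.18 mm at mean thickness 2.1 mm). Ultimate tensile stress and
#' toughness are not sampled: they emerge from the Veronda-Westmann
#' constitutive response at the drawn parameters, mirroring their physical
#' coupling.
#'
#' @param n_per_class Integer vector of three class sizes.
#' @param rate_classes The three loading rates (mm/s).
#' @param mu_dist,gamma_dist,rupture_strain_dist [param_dist()] triplets
#'   calibrating the per-sample parameter laws.
#' @param rate_effect Standardized between-rate location shift, in units of
#'   each parameter's log-scale spread. A scalar `r` applies shifts
#'   `c(0, r, 2r)` to the three classes (a linear rate gradient); a
#'   length-3 vector gives per-class shifts directly. The default 0 makes
#'   the rate label a pure label with no effect on the generating law —
#'   the rate-independent null.
#' @param noise_cv Coefficient of variation of multiplicative stress noise.
#'   The noise standard deviation at a point is
#'   `noise_cv * max(stress, 1e-4)` MPa; the small additive floor avoids a
#'   degenerate zero-noise point at zero stress. Default 0.03.
#' @param n_points Number of evenly spaced strain samples per curve
#'   (>= 20; default 100).
#' @param gauge_length_mm,area_mm2 Specimen gauge geometry.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(95L, 92L, 102L),
                          rate_classes = c(0.3, 2, 8),
                          mu_dist = param_dist(0.32, 0.17, 0.66),
                          gamma_dist = param_dist(0.07, 0.01, 0.12),
                          rupture_strain_dist = param_dist(1.69, 1.27, 2.47),
                          rate_effect = 0,
                          noise_cv = 0.03,
                          n_points = 100L,
                          gauge_length_mm = 7.62,
                          area_mm2 = 6.678,
                          seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || any(n_per_class < 1L)) {
    stop("n_per_class must be three positive integers")
  }
  if (length(rate_classes) != 3L || any(rate_classes <= 0)) {
    stop("rate_classes must be three positive loading rates (mm/s)")
  }
  for (d in list(mu_dist, gamma_dist, rupture_strain_dist)) {
    stopifnot(inherits(d, "param_dist"))
  }
  if (!length(rate_effect) %in% c(1L, 3L) || anyNA(rate_effect)) {
    stop("rate_effect must be a scalar or a length-3 numeric vector")
  }
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  n_points <- as.integer(n_points)
  if (n_points < 20L) stop("n_points must be at least 20")
  if (gauge_length_mm <= 0 || area_mm2 <= 0) {
    stop("gauge geometry must be positive")
  }
  structure(
    list(n_per_class = n_per_class, rate_classes = as.numeric(rate_classes),
         mu_dist = mu_dist, gamma_dist = gamma_dist,
         rupture_strain_dist = rupture_strain_dist,
         rate_effect = as.numeric(rate_effect), noise_cv = noise_cv,
         n_points = n_points, gauge_length_mm = gauge_length_mm,
         area_mm2 = area_mm2, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Per-class shifts in units of log-sigma: scalar r -> linear gradient
# (0, r, 2r); a length-3 vector is used as given.
class_shifts <- function(rate_effect) {
  if (length(rate_effect) == 3L) rate_effect else rate_effect * c(0, 1, 2)
}

#' Generate a seeded synthetic tensile cohort
#'
#' For each class, per-sample true parameters (`mu`, `gamma`, rupture
#' strain) are drawn independently from the quartile-calibrated split
#' lognormal laws ([calibrate_split_lognormal()]) with the class's
#' `rate_effect` shift added to each log-location. Each
#' specimen's Veronda-Westmann nominal stress is evaluated on an even
#' strain grid from 0 to its rupture strain, multiplicative Gaussian noise
#' with coefficient of variation `noise_cv` is applied (truncated at zero;
#' the zero-strain point stays exactly zero), and the curve is converted
#' back to raw units as `force = stress * area` and
#' `displacement = strain * gauge_length`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with `records` (list of
#'   [tensile_record()]) and `truth` (data frame of the per-sample true
#'   `mu`, `gamma` and `rupture_strain`, for recovery studies), plus the
#'   generating `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_class = c(3, 3, 3)))
#' length(cohort$records)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  shifts <- class_shifts(config$rate_effect)

  withr::with_seed(config$seed, {
    records <- list()
    truth <- list()
    sample_no <- 0L
    for (k in 1:3) {
      n <- config$n_per_class[k]
      mu <- r_param_dist(n, config$mu_dist, shifts[k])
      ga <- r_param_dist(n, config$gamma_dist, shifts[k])
      ru <- r_param_dist(n, config$rupture_strain_dist, shifts[k])
      for (i in seq_len(n)) {
        sample_no <- sample_no + 1L
        id <- sprintf("S%04d", sample_no)
        eps <- seq(0, ru[i], length.out = config$n_points)
        sigma <- vw_nominal_stress(eps, mu[i], ga[i])
        if (!all(is.finite(sigma))) {
          stop("non-finite stress for sample ", id,
               ": the drawn (gamma, rupture strain) overflow the ",
               "exponential law; reduce rate_effect or the configured ",
               "spreads")
        }
        if (config$noise_cv > 0) {
          sd_i <- config$noise_cv * pmax(sigma, 1e-4)
          sigma <- pmax(sigma + stats::rnorm(length(sigma), 0, sd_i), 0)
          sigma[1] <- 0
        }
        records[[sample_no]] <- tensile_record(
          sample_id = id, rate_class = config$rate_classes[k],
          displacement = eps * config$gauge_length_mm,
          force = sigma * config$area_mm2,
          gauge_length = config$gauge_length_mm, area = config$area_mm2,
          thickness = NA_real_
        )
        truth[[sample_no]] <- data.frame(
          sample_id = id, rate_class = config$rate_classes[k],
          mu = mu[i], gamma = ga[i], rupture_strain = ru[i],
          stringsAsFactors = FALSE
        )
      }
    }
    structure(
      list(records = records, truth = do.call(rbind, truth),
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' Write a cohort as delimited text files
#'
#' One file per specimen (`<sample_id>.txt`: comment header carrying
#' sample id, rate, gauge length and area, then a `displacement_mm,force_N`
#' CSV body), plus `manifest.csv` (file, sample id, rate, geometry, seed)
#' and `truth.csv` with the generating parameters.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort$records, function(rec) {
    file <- paste0(rec$sample_id, ".txt")
    path <- file.path(dir, file)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# sample_id: %s", rec$sample_id),
      sprintf("# rate_mm_per_s: %.10g", rec$rate_class),
      sprintf("# gauge_length_mm: %.10g", rec$gauge_length),
      sprintf("# area_mm2: %.10g", rec$area),
      "displacement_mm,force_N"
    ), con)
    utils::write.table(
      data.frame(rec$displacement, rec$force), con, sep = ",",
      row.names = FALSE, col.names = FALSE
    )
    data.frame(file = file, sample_id = rec$sample_id,
               rate_mm_per_s = rec$rate_class,
               gauge_length_mm = rec$gauge_length, area_mm2 = rec$area,
               seed = cohort$config$seed, stringsAsFactors = FALSE)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read one specimen file written by [write_cohort()]
#'
#' Also accepts a headerless two-column (displacement, force) CSV if the
#' geometry is supplied explicitly.
#'
#' @param path Path to the specimen file.
#' @param gauge_length,area,rate_class,sample_id Overrides / fallbacks for
#'   files without a comment header.
#' @return A [tensile_record()].
#' @export
read_tensile_record <- function(path, gauge_length = NULL, area = NULL,
                                rate_class = NA_real_, sample_id = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("[A-Za-z]", body[1])) body <- body[-1]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         header = FALSE)
  if (ncol(dat) < 2L) stop("specimen file must have two columns")
  tensile_record(
    sample_id = sample_id %||% meta$sample_id %||%
      sub("\\.[^.]*$", "", basename(path)),
    rate_class = if (!is.na(rate_class)) rate_class else
      as.numeric(meta$rate_mm_per_s %||% NA),
    displacement = dat[[1]], force = dat[[2]],
    gauge_length = gauge_length %||% as.numeric(meta$gauge_length_mm),
    area = area %||% as.numeric(meta$area_mm2)
  )
}

#' Read a whole cohort directory via its manifest
#'
#' @param dir Directory containing `manifest.csv` and specimen files.
#' @return A list of [tensile_record()] objects.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    read_tensile_record(file.path(dir, manifest$file[i]))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
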