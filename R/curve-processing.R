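#' Construct a uniaxial tensile record
#'
#' One specimen's raw test output: grip displacement (mm) and force (N)
#' series together with the gauge geometry needed to normalize them.
#'
#' @param sample_id Specimen identifier (string).
#' @param rate_class Loading rate of the test (mm/s).
#' @param displacement Nondecreasing displacement series starting at 0 (mm).
#' @param force Force series (N), same length as `displacement`.
#' @param gauge_length Initial gauge length L0 (mm, > 0).
#' @param area Initial cross-sectional area A0 (mm^2, > 0).
#' @param thickness Optional specimen thickness (mm).
#' @return An object of class `tensile_record`.
#' @export
tensile_record <- function(sample_id, rate_class, displacement, force,
                           gauge_length, area, thickness = NA_real_) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force) || length(force) < 2L) {
    stop("displacement and force must have equal length >= 2")
  }
  if (anyNA(displacement) || anyNA(force)) {
    stop("displacement and force must not contain missing values")
  }
  if (displacement[1] != 0) stop("displacement must start at 0")
  if (is.unsorted(displacement)) {
    stop("displacement must be nondecreasing; see clean_record()")
  }
  if (!is.finite(gauge_length) || gauge_length <= 0) {
    stop("gauge_length must be positive")
  }
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  structure(
    list(sample_id = as.character(sample_id),
         rate_class = as.numeric(rate_class),
         displacement = displacement, force = force,
         gauge_length = as.numeric(gauge_length), area = as.numeric(area),
         thickness = as.numeric(thickness)),
    class = "tensile_record"
  )
}

#' Drop points with non-increasing displacement
#'
#' Raw signals sometimes carry grip chatter where displacement steps back.
#' This keeps the subsequence on which displacement strictly advances
#' (always retaining the first point) and warns when points are dropped.
#' No other smoothing or filtering is applied.
#'
#' @param displacement,force Equal-length numeric series.
#' @return A list with the cleaned `displacement` and `force`.
#' @export
clean_record <- function(displacement, force) {
  stopifnot(length(displacement) == length(force))
  keep <- c(TRUE, diff(cummax(displacement)) > 0)
  if (!all(keep)) {
    warning(sprintf("dropped %d point(s) with non-increasing displacement",
                    sum(!keep)))
  }
  list(displacement = displacement[keep], force = force[keep])
}

#' Construct a nominal stress-strain curve
#'
#' @param strain Nondecreasing nominal strain series starting at 0.
#' @param stress Nonnegative nominal stress series (MPa).
#' @param sample_id,rate_class Optional provenance carried as attributes.
#' @return A data frame of class `stress_strain` with columns `strain` and
#'   `stress`.
#' @export
stress_strain <- function(strain, stress, sample_id = NA_character_,
                          rate_class = NA_real_) {
  strain <- as.numeric(strain)
  stress <- as.numeric(stress)
  if (length(strain) != length(stress) || length(strain) < 2L) {
    stop("strain and stress must have equal length >= 2")
  }
  if (strain[1] != 0) stop("strain must start at 0")
  if (is.unsorted(strain)) stop("strain must be nondecreasing")
  if (any(stress < 0)) stop("stress must be nonnegative")
  structure(
    data.frame(strain = strain, stress = stress),
    sample_id = as.character(sample_id),
    rate_class = as.numeric(rate_class),
    class = c("stress_strain", "data.frame")
  )
}

#' Convert a tensile record to nominal stress and strain
#'
#' Nominal stress is force over initial area, `sigma_N = F / A0`
#' (N/mm^2 = MPa), and nominal strain is displacement over initial gauge
#' length, `eps_N = dL / L0`. Point order is preserved; no deformed-area
#' update is made.
#'
#' @param record A [tensile_record()].
#' @return A [stress_strain()] curve.
#' @export
to_stress_strain <- function(record) {
  stopifnot(inherits(record, "tensile_record"))
  stress_strain(
    strain = record$displacement / record$gauge_length,
    stress = record$force / record$area,
    sample_id = record$sample_id,
    rate_class = record$rate_class
  )
}

#' Extract ultimate stress, ultimate strain and toughness from a curve
#'
#' Failure onset is taken at the global stress maximum; when the maximum is
#' attained at several points the last index of the maximal plateau is used,
#' so a degenerate constant curve keeps its full area. Ultimate tensile
#' stress and strain are read at that index. Toughness is the trapezoidal
#' integral of stress over strain from the origin up to the failure index;
#' any post-peak tail is excluded, which makes the property well defined on
#' curves whose recording continues past rupture.
#'
#' @param curve A [stress_strain()] curve (>= 2 points).
#' @return A list of class `mechanical_properties` with `ut_stress` (MPa),
#'   `ut_strain`, `toughness` (MPa) and `failure_index`.
#' @examples
#' extract_properties(stress_strain(c(0, 0.5, 1), c(0, 1, 2)))
#' @export
extract_properties <- function(curve) {
  strain <- as.numeric(curve$strain)
  stress <- as.numeric(curve$stress)
  if (length(strain) < 2L) stop("curve must have at least 2 points")
  smax <- max(stress)
  idx <- max(which(stress == smax))
  toughness <- if (idx >= 2L) {
    pracma::trapz(strain[seq_len(idx)], stress[seq_len(idx)])
  } else {
    0
  }
  structure(
    list(ut_stress = stress[idx], ut_strain = strain[idx],
         toughness = toughness, failure_index = idx),
    class = "mechanical_properties"
  )
}

#' Truncate a curve at its failure peak
#'
#' Returns the portion of the curve from the origin up to (and including)
#' the failure index defined by [extract_properties()]; this is the segment
#' the hyperelastic fit uses.
#'
#' @param curve A [stress_strain()] curve.
#' @return A `stress_strain` curve ending at the stress peak.
#' @export
truncate_at_peak <- function(curve) {
  idx <- extract_properties(curve)$failure_index
  stress_strain(curve$strain[seq_len(idx)], curve$stress[seq_len(idx)],
                sample_id = attr(curve, "sample_id"),
                rate_class = attr(curve, "rate_class"))
}

#' Build the per-specimen feature table
#'
#' Runs every record through stress-strain conversion, property extraction
#' and (optionally) the Veronda-Westmann fit, producing the five-parameter
#' feature table that the statistical stages consume.
#'
#' @param records A list of [tensile_record()] objects (e.g. from
#'   [generate_cohort()] or [read_cohort()]).
#' @param fit If `TRUE` (default) fit the Veronda-Westmann law on the
#'   peak-truncated curve and append `mu`, `gamma`, `r_squared`,
#'   `converged` columns.
#' @param law Hyperelastic law passed to [fit_hyperelastic()].
#' @return A data frame with one row per specimen: `sample_id`,
#'   `rate_class` (mm/s), `ut_stress` (MPa), `ut_strain`, `toughness`
#'   (MPa), and fit columns when `fit = TRUE`.
#' @export
build_feature_table <- function(records, fit = TRUE, law = vw_law()) {
  stopifnot(is.list(records), length(records) >= 1L)
  rows <- lapply(records, function(rec) {
    curve <- to_stress_strain(rec)
    props <- extract_properties(curve)
    row <- data.frame(
      sample_id = rec$sample_id,
      rate_class = rec$rate_class,
      ut_stress = props$ut_stress,
      ut_strain = props$ut_strain,
      toughness = props$toughness,
      stringsAsFactors = FALSE
    )
    if (fit) {
      f <- fit_hyperelastic(truncate_at_peak(curve), law = law)
      row$mu <- unname(f$par[1])
      row$gamma <- unname(f$par[2])
      row$r_squared <- f$r_squared
      row$converged <- f$converged
    }
    row
  })
  do.call(rbind, rows)
}
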