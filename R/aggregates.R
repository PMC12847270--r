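#' Default representative diameters of the six sieve classes
#'
#' Class midpoints in mm for the bounded classes (1–2, 0.5–1, 0.25–0.5,
#' 0.053–0.25, <0.053 mm); the open-top >2 mm class uses its lower bound
#' 2.0 mm rather than an invented cap. All six are overridable wherever a
#' `diameters` argument is accepted.
#'
#' @return named numeric vector of length 6, mm, descending.
#' @export
default_diameters <- function() {
  stats::setNames(c(2.0, 1.5, 0.75, 0.375, 0.1515, 0.0265),
                  SIEVE_CLASSES$column)
}

#' Mass proportions of the sieve fractions
#'
#' W_i = mass_i / total mass, the weight share of each of the six
#' water-stable aggregate size classes.
#'
#' @param mass_g non-negative numeric vector of class masses (g), in the
#'   descending class order of [schema_columns()] for `"sieve"`.
#' @return numeric vector of proportions summing to 1.
#' @export
fraction_proportions <- function(mass_g) {
  if (any(mass_g < 0)) {
    stop_psq("negative sieve fraction mass", class = "psq_validation_error")
  }
  total <- sum(mass_g)
  if (total <= 0) {
    stop_psq("degenerate sample: total sieve mass is zero",
             class = "psq_degenerate_error")
  }
  mass_g / total
}

#' Water-stable macroaggregate fraction (R0.25)
#'
#' Share of total mass held in aggregates larger than 0.25 mm: the sum of
#' the four classes with lower bound >= 0.25 mm divided by total mass.
#'
#' @inheritParams fraction_proportions
#' @param class_lower lower bounds (mm) of the size classes; defaults to the
#'   standard six-class scheme.
#' @return fraction in \[0, 1\].
#' @export
r025 <- function(mass_g, class_lower = SIEVE_CLASSES$lower) {
  if (length(mass_g) != length(class_lower)) {
    stop_psq("mass and class-bound vectors differ in length",
             class = "psq_shape_error")
  }
  if (any(mass_g < 0)) {
    stop_psq("negative sieve fraction mass", class = "psq_validation_error")
  }
  total <- sum(mass_g)
  if (total <= 0) {
    stop_psq("degenerate sample: total sieve mass is zero",
             class = "psq_degenerate_error")
  }
  sum(mass_g[class_lower >= 0.25]) / total
}

#' Mean weight diameter (MWD)
#'
#' MWD = sum_i X_i W_i, the proportion-weighted mean of the representative
#' class diameters (mm). Higher values indicate coarser, more stable
#' aggregation.
#'
#' @param proportions class proportions W_i (need not be normalized; they
#'   are weights).
#' @param diameters representative class diameters X_i (mm).
#' @return mm.
#' @export
mwd <- function(proportions, diameters = default_diameters()) {
  if (length(proportions) != length(diameters)) {
    stop_psq("proportions and diameters differ in length",
             class = "psq_shape_error")
  }
  sum(proportions * diameters)
}

#' Geometric mean diameter (GMD)
#'
#' GMD = exp( sum_i W_i ln X_i / sum_i W_i ). The denominator is computed
#' explicitly, so unnormalized weights are accepted; classes with W_i = 0
#' contribute nothing and may have any diameter. GMD <= MWD always
#' (weighted AM-GM), with equality only when all mass sits in one class.
#'
#' @inheritParams mwd
#' @return mm.
#' @export
gmd <- function(proportions, diameters = default_diameters()) {
  if (length(proportions) != length(diameters)) {
    stop_psq("proportions and diameters differ in length",
             class = "psq_shape_error")
  }
  active <- proportions > 0
  if (any(diameters[active] <= 0)) {
    stop_psq("non-positive diameter with positive weight",
             class = "psq_domain_error")
  }
  exp(sum(proportions[active] * log(diameters[active])) / sum(proportions))
}

#' Aggregate stability indices per sample
#'
#' Computes R0.25, MWD and GMD plus the six fraction proportions for every
#' row of a validated sieve table.
#'
#' @param sieve a sieve table from [read_tidy_table()] / [validate_table()]
#'   (schema `"sieve"`).
#' @param diameters representative class diameters, see
#'   [default_diameters()].
#' @param as_percent report proportions (`W_*` columns) as percentages
#'   instead of fractions. Indices are always computed on fractions.
#' @return data.frame with the design columns, `r025`, `mwd`, `gmd`, and
#'   the six proportions `W_<class>`.
#' @export
aggregate_indices <- function(sieve, diameters = default_diameters(),
                              as_percent = FALSE) {
  m <- as.matrix(as.data.frame(sieve)[SIEVE_CLASSES$column])
  w <- t(apply(m, 1, fraction_proportions))
  out <- data.frame(
    sieve[c("sample_id", "treatment", "depth", "replicate")],
    r025 = apply(m, 1, r025),
    mwd = apply(w, 1, mwd, diameters = diameters),
    gmd = apply(w, 1, gmd, diameters = diameters),
    stringsAsFactors = FALSE
  )
  wout <- if (as_percent) 100 * w else w
  colnames(wout) <- sub("^class_", "W_", SIEVE_CLASSES$column)
  cbind(out, wout)
}
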