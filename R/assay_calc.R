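# Quantitative assay formulas for molecular tension probes: fluorophore-
# quencher quenching efficiency, fold-dequenching, F-factor brightness
# correction, supported-lipid-bilayer density calibration, probe density and
# inter-probe spacing, and nuclease-degradation half-life fitting.

#' Quenching efficiency of a fluorophore-quencher pair
#'
#' `QE = (1 - I_quenched / I_unquenched) * 100`, in percent, clipped to
#' `[0, 100]` with a warning if the raw value falls outside.
#'
#' @param i_quenched quenched intensity (>= 0).
#' @param i_unquenched unquenched intensity (> 0).
#' @return Percent quenching efficiency.
#' @examples
#' quenching_efficiency(13, 100)  # 87
#' @export
quenching_efficiency <- function(i_quenched, i_unquenched) {
  if (any(i_unquenched <= 0)) stop("unquenched intensity must be positive", call. = FALSE)
  if (any(i_quenched < 0)) stop("quenched intensity must be non-negative", call. = FALSE)
  qe <- (1 - i_quenched / i_unquenched) * 100
  if (any(qe < 0 | qe > 100)) {
    warning("quenching efficiency outside [0, 100]%; clipping")
    qe <- pmin(pmax(qe, 0), 100)
  }
  qe
}

#' Fold fluorescence enhancement implied by a quenching efficiency
#'
#' `fold = 1 / (1 - QE/100)`: the signal gain on rupture of a quenched
#' probe. 87% quenching implies about an 8-fold enhancement.
#'
#' @param qe quenching efficiency, percent, in `[0, 100)`.
#' @return Fold enhancement (>= 1).
#' @export
fold_enhancement <- function(qe) {
  if (any(qe < 0 | qe >= 100))
    stop("quenching efficiency must lie in [0, 100)", call. = FALSE)
  1 / (1 - qe / 100)
}

#' F-factor: molecular-brightness ratio of two fluorophores
#'
#' Ratio of the intensity-versus-concentration calibration slopes of the
#' labelled oligonucleotide and the reference lipid dye.
#'
#' @param i_dna slope of the DNA-dye titration (> 0).
#' @param i_lipid slope of the lipid-dye titration (> 0).
#' @return The F-factor `i_dna / i_lipid`.
#' @export
f_factor <- function(i_dna, i_lipid) {
  if (any(i_dna <= 0) || any(i_lipid <= 0))
    stop("calibration slopes must be positive", call. = FALSE)
  i_dna / i_lipid
}

#' Fluorophore surface density of a supported lipid bilayer
#'
#' `density = mole_fraction * leaflet_factor * 1e6 / footprint` fluorophores
#' per um^2, from the known lipid footprint (nm^2) and the number of
#' leaflets carrying fluorescent lipid.
#'
#' @param mole_fraction fluorescent lipid mole fraction in `[0, 1]`.
#' @param footprint lipid footprint, nm^2 (default 0.72).
#' @param leaflet_factor leaflets counted (default 2).
#' @return Fluorophores per um^2.
#' @examples
#' fraction_to_density(0.001)  # 2777.8 per um^2
#' @export
fraction_to_density <- function(mole_fraction, footprint = 0.72,
                                leaflet_factor = 2) {
  stopifnot(footprint > 0, leaflet_factor > 0)
  mole_fraction * leaflet_factor * 1e6 / footprint
}

#' Fit the supported-lipid-bilayer density calibration curve
#'
#' Each fluorophore mole fraction is converted to a surface density of
#' fluorophores, `fraction * leaflet_factor * 1e6 / footprint` per um^2
#' (footprint in nm^2; leaflet factor 2 counts fluorescent lipid in both
#' leaflets), and intensity is regressed on density by ordinary least
#' squares.
#'
#' @param points data frame or 2-column matrix of (mole_fraction, intensity),
#'   at least 3 points with non-zero density variance.
#' @param footprint lipid footprint, nm^2 (default 0.72).
#' @param leaflet_factor leaflets counted (default 2).
#' @return Object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `footprint`, `leaflet_factor`, `usable`.
#' @export
fit_density_calibration <- function(points, footprint = 0.72,
                                    leaflet_factor = 2) {
  stopifnot(footprint > 0, leaflet_factor > 0)
  points <- as.data.frame(points)
  names(points)[1:2] <- c("mole_fraction", "intensity")
  if (nrow(points) < 3L) stop("at least 3 calibration points required", call. = FALSE)
  density <- fraction_to_density(points$mole_fraction, footprint, leaflet_factor)
  if (stats::var(density) < 1e-12) stop("zero variance in density", call. = FALSE)
  fit <- stats::lm(points$intensity ~ density)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((points$intensity - mean(points$intensity))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, footprint = footprint,
                 leaflet_factor = leaflet_factor,
                 usable = is.finite(slope) && slope > 0),
            class = "calibration_curve")
}

#' Convert a fluorescence intensity to a probe surface density
#'
#' `density = ((intensity - intercept) / slope) / F`, per um^2, using the
#' SLB calibration curve and the F-factor brightness correction. Intensities
#' below the intercept map to 0 with a warning.
#'
#' @param i_probe measured intensity.
#' @param curve a [fit_density_calibration()] result (must be usable).
#' @param f F-factor (> 0).
#' @return Probes per um^2.
#' @export
intensity_to_density <- function(i_probe, curve, f) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$usable) stop("calibration curve is not usable", call. = FALSE)
  if (any(f <= 0)) stop("F-factor must be positive", call. = FALSE)
  d <- ((i_probe - curve$intercept) / curve$slope) / f
  if (any(d < 0)) {
    warning("intensity below calibration intercept; reporting 0")
    d <- pmax(d, 0)
  }
  d
}

#' Mean inter-probe spacing from a surface density
#'
#' Square-lattice convention: `spacing = sqrt(1e6 / density)` nm for a
#' density in probes per um^2. The measured density of 2890 per um^2
#' corresponds to a spacing of about 18.6 nm.
#'
#' @param density probes per um^2 (> 0).
#' @return Spacing in nm.
#' @export
mean_spacing <- function(density) {
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  sqrt(1e6 / density)
}

#' Fit an exponential decay and report the half-life
#'
#' Least-squares fit of `I(t) = A * exp(-lambda * t) + c` (offset `c` fixed
#' to 0 unless `fit_offset`); the half-life is `ln(2) / lambda` in the time
#' unit of `times`. Non-decaying data give an invalid fit rather than an
#' error.
#'
#' @param times strictly increasing time points (>= 4).
#' @param intensities intensities at those times.
#' @param fit_offset logical; also fit a plateau term (default FALSE).
#' @return Object of class `decay_fit`: list with `amplitude`, `rate`
#'   (per time unit), `offset`, `half_life`, `valid`.
#' @export
decay_halflife <- function(times, intensities, fit_offset = FALSE) {
  if (length(times) < 4L) stop("at least 4 points required", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  stopifnot(length(times) == length(intensities))
  invalid <- structure(list(amplitude = NA_real_, rate = NA_real_,
                            offset = NA_real_, half_life = NA_real_,
                            valid = FALSE), class = "decay_fit")
  # log-linear start values on the positive part
  off0 <- if (fit_offset) min(intensities) * 0.5 else 0
  pos <- intensities - off0 > 0
  if (sum(pos) < 3L) return(invalid)
  lin <- stats::lm(log(intensities[pos] - off0) ~ times[pos])
  lam0 <- -unname(stats::coef(lin)[2]); a0 <- exp(unname(stats::coef(lin)[1]))
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- 1 / max(times)
  df <- data.frame(t = times, y = intensities)
  fit <- tryCatch({
    if (fit_offset)
      minpack.lm::nlsLM(y ~ A * exp(-lambda * t) + c0, data = df,
                        start = list(A = a0, lambda = lam0, c0 = off0))
    else
      minpack.lm::nlsLM(y ~ A * exp(-lambda * t), data = df,
                        start = list(A = a0, lambda = lam0))
  }, error = function(e) NULL)
  if (is.null(fit)) return(invalid)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["lambda"]]) || cf[["lambda"]] <= 0) return(invalid)
  structure(list(amplitude = cf[["A"]], rate = cf[["lambda"]],
                 offset = if (fit_offset) cf[["c0"]] else 0,
                 half_life = log(2) / cf[["lambda"]], valid = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("exponential decay: A = %.3g, lambda = %.3g, t1/2 = %.3g\n",
                x$amplitude, x$rate, x$half_life))
  else cat("invalid decay fit (non-decaying data)\n")
  invisible(x)
}
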