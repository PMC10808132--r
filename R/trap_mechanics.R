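# Force reconstruction for the dual harmonic-trap pulling protocol: one trap
# fixed at the surface-anchor nucleotide, one translated at constant speed at
# the ligand nucleotide. The measured force is the tension of the two traps
# in series, projected on the pulling axis.

#' Effective stiffness of springs in series
#'
#' `1/k_eff = sum(1/k_i)`. For the standard protocol of two 11.42 pN/nm
#' traps the effective stiffness is 5.71 pN/nm.
#'
#' @param stiffnesses numeric vector of positive stiffnesses (pN/nm).
#' @return Effective stiffness, pN/nm.
#' @examples
#' effective_stiffness(c(11.42, 11.42))  # 5.71
#' @export
effective_stiffness <- function(stiffnesses) {
  if (length(stiffnesses) < 1L || any(!is.finite(stiffnesses)) || any(stiffnesses <= 0))
    stop("all stiffnesses must be positive", call. = FALSE)
  1 / sum(1 / stiffnesses)
}

#' Convert a trap loading rate from simulation units to nm/s
#'
#' @param rate_sim rate in simulation length per simulation time (>= 0).
#' @param units an [oxdna_units()] object.
#' @return Rate in nm/s. The canonical protocol rate 5e-8 converts to
#'   about 1.4e4 nm/s.
#' @export
loading_rate_si <- function(rate_sim, units = oxdna_units()) {
  if (any(rate_sim < 0)) stop("loading rate must be non-negative", call. = FALSE)
  convert_units(rate_sim, "rate", from = "sim", to = "si", units = units)
}

#' Exponential moving average
#'
#' `y[1] = x[1]; y[i] = alpha * x[i] + (1 - alpha) * y[i-1]`. With
#' `alpha = 1` the input is returned unchanged. Output is bounded by the
#' running extrema of the input.
#'
#' @param x numeric series (non-empty).
#' @param alpha smoothing factor in (0, 1].
#' @return Smoothed series of the same length.
#' @export
ema <- function(x, alpha) {
  if (length(x) == 0L) stop("series must be non-empty", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  if (alpha == 1) return(x)
  # y_i = alpha * sum_j (1-alpha)^(i-j) x_j + (1-alpha)^(i-1) x_1, via filter()
  y <- stats::filter(alpha * x, 1 - alpha, method = "recursive", init = x[1])
  as.numeric(y)
}

#' Dual harmonic-trap pulling protocol
#'
#' @param index_a,index_b 0-based nucleotide indices of the fixed (anchor)
#'   and moving (ligand) trap attachments; must be distinct.
#' @param k_a,k_b trap stiffnesses, pN/nm (default 11.42 each).
#' @param anchor_a fixed trap position, 3-vector nm.
#' @param start_b moving trap start position, 3-vector nm.
#' @param rate translation speed of trap b, nm/s (>= 0).
#' @param axis unit 3-vector, direction of trap-b motion.
#' @return An object of class `trap_protocol`.
#' @export
trap_protocol <- function(index_a, index_b, k_a = 11.42, k_b = 11.42,
                          anchor_a, start_b, rate, axis) {
  stopifnot(k_a > 0, k_b > 0, rate >= 0,
            length(anchor_a) == 3, length(start_b) == 3, length(axis) == 3)
  if (index_a == index_b) stop("trap indices must be distinct", call. = FALSE)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be non-zero", call. = FALSE)
  structure(
    list(index_a = as.integer(index_a), index_b = as.integer(index_b),
         k_a = k_a, k_b = k_b,
         anchor_a = as.numeric(anchor_a), start_b = as.numeric(start_b),
         rate = rate, axis = as.numeric(axis) / nrm),
    class = "trap_protocol"
  )
}

#' Reconstruct a force-extension curve from a pulling trajectory
#'
#' Per frame, the moving trap sits at `start_b + rate * axis * t`. The raw
#' force is the series-spring tension
#' `k_eff * ((trap_b - r_b) - (trap_a - r_a)) . axis`, i.e. the sum of the
#' two spring stretches projected on the pulling axis times the effective
#' stiffness; positive values are tensile. The extension is, by default, the
#' projected separation of the two attachment nucleotides minus its value in
#' the first frame (`convention = "nucleotide"`); `convention = "trap"` uses
#' the trap separation instead.
#'
#' @param trajectory an `oxdna_trajectory` (non-empty).
#' @param protocol a [trap_protocol()] (positions/rates in nm, nm/s).
#' @param units an [oxdna_units()] object used to convert frame times and
#'   positions to SI.
#' @param alpha EMA smoothing factor; default `2 / (W + 1)` with
#'   `W = max(1, 1%% of frames)`.
#' @param convention extension convention, `"nucleotide"` or `"trap"`.
#' @return A `force_extension_curve`: data frame with columns `time` (s),
#'   `extension` (nm), `force_raw` (pN), `force_ema` (pN); attributes
#'   `k_eff` (pN/nm), `loading_rate` (nm/s), `convention`, `alpha`.
#' @export
force_extension_curve <- function(trajectory, protocol, units = oxdna_units(),
                                  alpha = NULL,
                                  convention = c("nucleotide", "trap")) {
  stopifnot(inherits(trajectory, "oxdna_trajectory"),
            inherits(protocol, "trap_protocol"))
  convention <- match.arg(convention)
  nf <- n_frames(trajectory)
  if (nf == 0L) stop("trajectory has no frames", call. = FALSE)
  n_nt <- dim(trajectory$positions)[1]
  ia <- protocol$index_a; ib <- protocol$index_b
  if (ia < 0L || ia >= n_nt || ib < 0L || ib >= n_nt)
    stop("trap nucleotide index out of range", call. = FALSE)
  if (is.null(alpha)) alpha <- 2 / (max(1, ceiling(0.01 * nf)) + 1)

  t_si <- convert_units(trajectory$times - trajectory$times[1], "time",
                        from = "sim", to = "si", units = units)
  ra <- t(trajectory$positions[ia + 1L, , , drop = TRUE]) # frames x 3 (or 3 if nf==1)
  rb <- t(trajectory$positions[ib + 1L, , , drop = TRUE])
  if (nf == 1L) { ra <- matrix(ra, 1, 3); rb <- matrix(rb, 1, 3) }
  ra <- ra * units$nm_per_length_unit
  rb <- rb * units$nm_per_length_unit
  axis <- protocol$axis
  trap_b <- matrix(protocol$start_b, nf, 3, byrow = TRUE) +
    outer(t_si * protocol$rate, axis)
  trap_a <- matrix(protocol$anchor_a, nf, 3, byrow = TRUE)
  k_eff <- effective_stiffness(c(protocol$k_a, protocol$k_b))
  stretch <- ((trap_b - rb) - (trap_a - ra)) %*% axis
  force_raw <- as.numeric(k_eff * stretch)
  extension <- switch(convention,
    nucleotide = as.numeric((rb - ra) %*% axis),
    trap       = as.numeric((trap_b - trap_a) %*% axis))
  extension <- extension - extension[1]
  curve <- data.frame(time = t_si, extension = extension,
                      force_raw = force_raw,
                      force_ema = ema(force_raw, alpha))
  structure(curve, k_eff = k_eff, loading_rate = protocol$rate,
            convention = convention, alpha = alpha,
            class = c("force_extension_curve", "data.frame"))
}

#' Detect the rupture force on a force-extension curve
#'
#' The candidate rupture force is the global maximum of the smoothed force.
#' The detection is valid only if the smoothed force falls below
#' `(1 - drop_fraction) * peak` within the subsequent `window_fraction` of
#' frames — i.e. the peak is followed by the force drop characteristic of
#' strand release. Otherwise `valid = FALSE` and no force is reported.
#'
#' @param curve a [force_extension_curve()].
#' @param drop_fraction required fractional force drop after the peak
#'   (default 0.5).
#' @param window_fraction fraction of total frames after the peak inspected
#'   for the drop (default 0.1).
#' @return An object of class `rupture_result`: list with `rupture_force`
#'   (pN, `NA` if invalid), `rupture_frame` (1-based), `valid`,
#'   `drop_observed`.
#' @export
detect_rupture <- function(curve, drop_fraction = 0.5, window_fraction = 0.1) {
  f <- curve$force_ema
  n <- length(f)
  if (n == 0L) stop("curve is empty", call. = FALSE)
  peak <- which.max(f)
  window <- min(n, peak + max(1L, ceiling(window_fraction * n)))
  after_min <- min(f[peak:window])
  drop_observed <- if (f[peak] > 0) 1 - after_min / f[peak] else 0
  valid <- peak < n && drop_observed >= drop_fraction
  structure(
    list(rupture_force = if (valid) f[peak] else NA_real_,
         rupture_frame = peak, valid = valid,
         drop_observed = drop_observed),
    class = "rupture_result"
  )
}

#' @export
print.rupture_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("rupture: %.2f pN at frame %d (drop %.0f%%)\n",
                x$rupture_force, x$rupture_frame, 100 * x$drop_observed))
  else
    cat(sprintf("no valid rupture (peak frame %d, drop %.0f%%)\n",
                x$rupture_frame, 100 * x$drop_observed))
  invisible(x)
}

#' Write a force-extension curve as CSV
#'
#' Columns: time (s), extension (nm), force_raw (pN), force_ema (pN).
#'
#' @param curve a `force_extension_curve`.
#' @param path output path.
#' @export
write_force_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
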