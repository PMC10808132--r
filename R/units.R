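#' oxDNA simulation unit system
#'
#' Conversion constants between oxDNA "classic" simulation units and SI-style
#' units (nm, s, pN). One simulation length unit is 0.8518 nm and one
#' simulation time unit is 3.03e-12 s; the force unit follows the standard
#' oxDNA energy/length convention (48.63 pN per simulation force unit, so
#' that a trap stiffness of 0.2 simulation units corresponds to 11.42 pN/nm).
#'
#' @param nm_per_length_unit nm per simulation length unit.
#' @param s_per_time_unit seconds per simulation time unit.
#' @param pN_per_force_unit pN per simulation force unit.
#'
#' @return An object of class `oxdna_units`.
#' @examples
#' u <- oxdna_units()
#' convert_units(1, "length", from = "sim", to = "si", units = u)   # 0.8518 nm
#' convert_units(5e-8, "rate", from = "sim", to = "si", units = u)  # ~1.4e4 nm/s
#' @export
oxdna_units <- function(nm_per_length_unit = 0.8518,
                        s_per_time_unit = 3.03e-12,
                        pN_per_force_unit = 48.63) {
  stopifnot(nm_per_length_unit > 0, s_per_time_unit > 0, pN_per_force_unit > 0)
  structure(
    list(nm_per_length_unit = nm_per_length_unit,
         s_per_time_unit = s_per_time_unit,
         pN_per_force_unit = pN_per_force_unit),
    class = "oxdna_units"
  )
}

#' Convert values between simulation units and SI units
#'
#' Supported kinds: `length` (nm), `time` (s), `force` (pN), `stiffness`
#' (pN/nm) and `rate` (nm/s). The rate factor is the length factor divided by
#' the time factor; stiffness is force over length. Conversions are exactly
#' invertible.
#'
#' @param x numeric vector of values.
#' @param kind one of `"length"`, `"time"`, `"force"`, `"stiffness"`, `"rate"`.
#' @param from,to `"sim"` or `"si"` (must differ unless identical request).
#' @param units an [oxdna_units()] object.
#' @return Numeric vector of converted values.
#' @export
convert_units <- function(x, kind, from = c("sim", "si"), to = NULL,
                          units = oxdna_units()) {
  from <- match.arg(from)
  if (is.null(to)) to <- if (from == "sim") "si" else "sim"
  to <- match.arg(to, c("sim", "si"))
  factor <- switch(kind,
    length    = units$nm_per_length_unit,
    time      = units$s_per_time_unit,
    force     = units$pN_per_force_unit,
    stiffness = units$pN_per_force_unit / units$nm_per_length_unit,
    rate      = units$nm_per_length_unit / units$s_per_time_unit,
    stop("unknown unit kind: ", kind)
  )
  if (from == to) return(x)
  if (from == "sim") x * factor else x / factor
}
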