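#' Mass-loss fractions from a thermogravimetric curve
#'
#' Reads the step-horizontal mass losses of the two-phase 25 to 550 degree C
#' experiment: dehydration between `t_low` and `t_mid`, organic combustion
#' between `t_mid` and the end of the run, mineral (ash) as the remainder.
#' Masses at the boundary temperatures are obtained by local linear
#' interpolation; the final boundary is read from the last sample, which
#' folds any isothermal hold into the ash value.
#'
#' @param tg Data frame with columns `temperature_C` (monotone increasing)
#'   and `mass_mg` (positive).
#' @param t_low,t_mid,t_high Window boundaries in degrees C (defaults
#'   25/200/550).
#'
#' @return A one-row tibble `W_pct`, `Or_pct`, `Ash_pct`; the three always
#'   sum to 100 exactly.
#' @export
#' @examples
#' tg <- data.frame(temperature_C = c(25, 150, 250, 550),
#'                  mass_mg = c(10, 9.5, 8, 7))
#' tga_steps(tg)
tga_steps <- function(tg, t_low = 25, t_mid = 200, t_high = 550) {
  stopifnot(all(c("temperature_C", "mass_mg") %in% names(tg)))
  if (any(tg$mass_mg <= 0)) {
    abort("Masses must be positive.", class = "rib_extract_error")
  }
  rng <- range(tg$temperature_C)
  if (t_low < rng[1] - 1e-8 || t_high > rng[2] + 1e-8) {
    abort("Window boundaries lie outside the measured temperature span.",
          class = "rib_extract_error")
  }
  m_at <- function(t) approx(tg$temperature_C, tg$mass_mg, xout = t,
                             rule = 2)$y
  m0 <- m_at(t_low)
  m_mid <- m_at(t_mid)
  m_end <- tg$mass_mg[nrow(tg)]
  w <- 100 * (m0 - m_mid) / m0
  or <- 100 * (m_mid - m_end) / m0
  tibble::tibble(W_pct = w, Or_pct = or, Ash_pct = 100 - w - or)
}

#' Transition enthalpies from a DSC heat-flow curve
#'
#' Integrates the heat flow above a linear baseline over the dehydration
#' (`[t_low, t_mid]`) and combustion (`[t_mid, t_high]`) windows. The
#' baseline of each window is the chord between the curve values at its
#' endpoints; temperature is converted to time through the heating rate so
#' the integral of W/g over seconds yields J/g. The dehydration enthalpy is
#' reported with the endothermic sign convention (positive for an endotherm)
#' and the combustion enthalpy with the exothermic one.
#'
#' @param hf Data frame with columns `temperature_C` and `heatflow_Wg`.
#' @param t_low,t_mid,t_high Window boundaries in degrees C.
#' @param heating_rate Heating rate in degrees C per minute (> 0).
#' @param exo_positive Logical; `TRUE` when the curve records exothermic
#'   heat flow as positive (the default convention).
#'
#' @return A one-row tibble `LdH`, `CdH` in J/g.
#' @export
dsc_enthalpies <- function(hf, t_low = 25, t_mid = 200, t_high = 550,
                           heating_rate = 10, exo_positive = TRUE) {
  stopifnot(all(c("temperature_C", "heatflow_Wg") %in% names(hf)))
  if (heating_rate <= 0) {
    abort("`heating_rate` must be positive.", class = "rib_extract_error")
  }
  if (any(!is.finite(hf$heatflow_Wg))) {
    abort("Non-finite heat-flow values.", class = "rib_extract_error")
  }
  sec_per_degC <- 60 / heating_rate

  window_integral <- function(lo, hi) {
    sel <- hf$temperature_C >= lo & hf$temperature_C <= hi
    if (sum(sel) < 3) {
      abort("Integration window narrower than 3 samples.",
            class = "rib_extract_error")
    }
    t <- hf$temperature_C[sel]
    y <- hf$heatflow_Wg[sel]
    base <- y[1] + (y[length(y)] - y[1]) * (t - t[1]) / (t[length(t)] - t[1])
    d <- y - base
    sum(diff(t) * (head(d, -1) + tail(d, -1)) / 2) * sec_per_degC
  }

  i1 <- window_integral(t_low, t_mid)
  i2 <- window_integral(t_mid, t_high)
  sgn <- if (exo_positive) 1 else -1
  tibble::tibble(LdH = -sgn * i1, CdH = sgn * i2)
}
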