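#' Oliver-Pharr analysis of one instrumented-indentation curve
#'
#' Computes indentation hardness, elastic modulus, creep and the elastic work
#' ratio from a load--depth--time record with loading, hold and unloading
#' phases.
#'
#' \describe{
#'   \item{Hardness}{\eqn{H_{IT} = P_{max}/A(h_c)} with the projected contact
#'     area from the calibrated area function \eqn{A = C_0 h_c^2} at contact
#'     depth \eqn{h_c = h_{max} - \epsilon P_{max}/S}. Reported in MPa with a
#'     Vickers-equivalent number alongside (\eqn{HV \approx H/(9.807 \times
#'     1.0757)} for load over developed area of the 136-degree geometry).}
#'   \item{Modulus}{The unloading branch is fitted with a power law
#'     \eqn{P = \alpha (h - h_f)^m} over the configured load fraction of the
#'     unloading segment; the contact stiffness \eqn{S = dP/dh} at
#'     \eqn{h_{max}} gives the reduced modulus
#'     \eqn{E_r = \sqrt{\pi} S / (2\sqrt{A})}, and the sample modulus follows
#'     from \eqn{1/E_r = (1-\nu_s^2)/E_s + (1-\nu_i^2)/E_i} with
#'     \eqn{\nu_s = 0.3} and diamond indenter constants.}
#'   \item{Creep}{\eqn{C_{IT} = (h_2 - h_1)/h_1 \times 100} over the
#'     constant-load hold, positive when depth grows (ISO 14577 convention;
#'     the sign-inverted printed form \eqn{(h_1 - h_2)/h_1} is equivalent up
#'     to sign).}
#'   \item{Elastic work ratio}{\eqn{\eta_{IT} = w_{elast}/(w_{elast} +
#'     w_{plast}) \times 100}, with the elastic work the trapezoidal integral
#'     of load over depth on unloading and the plastic work the loading+hold
#'     work minus the elastic work.}
#' }
#'
#' @param curve Data frame with columns `time_s`, `load_mN`, `depth_nm` and
#'   optionally `phase` (`"loading"`, `"hold"`, `"unloading"`). Without
#'   labels, points with load within 1 % of the maximum are taken as the
#'   hold.
#' @param config A [rib_config()]; the `indenter` block holds all constants.
#'
#' @return A one-row tibble: `H_IT_MPa`, `H_IT_vickers`, `E_IT_GPa`,
#'   `C_IT_pct`, `eta_IT_pct`, `S_mN_nm`, `h_max_nm`, `h_c_nm`.
#' @export
analyze_indentation <- function(curve, config = rib_config()) {
  ic <- config$indenter
  stopifnot(all(c("load_mN", "depth_nm") %in% names(curve)))
  if (any(curve$load_mN < -1e-9)) {
    abort("Negative loads in the indentation curve.", class = "rib_extract_error")
  }

  if (!"phase" %in% names(curve)) {
    p_max <- max(curve$load_mN)
    hold_idx <- which(curve$load_mN >= 0.99 * p_max)
    phase <- rep("unloading", nrow(curve))
    phase[seq_len(min(hold_idx) - 1)] <- "loading"
    phase[seq(min(hold_idx), max(hold_idx))] <- "hold"
    curve$phase <- phase
  }
  load_seg <- curve[curve$phase == "loading", ]
  hold_seg <- curve[curve$phase == "hold", ]
  unl_seg <- curve[curve$phase == "unloading", ]
  if (nrow(hold_seg) < 2) {
    abort("Missing hold phase; creep is undefined.", class = "rib_extract_error")
  }
  if (nrow(load_seg) < 10 || nrow(unl_seg) < 10) {
    abort("Need at least 10 points in the loading and unloading phases.",
          class = "rib_extract_error")
  }

  p_max <- max(curve$load_mN)
  h1 <- hold_seg$depth_nm[1]
  h2 <- hold_seg$depth_nm[nrow(hold_seg)]
  h_max <- max(c(hold_seg$depth_nm, unl_seg$depth_nm[1]))

  # Unloading power-law fit P = alpha (h - hf)^m over the configured band of
  # the unloading load range; hf profiled out by 1-D optimisation.
  band <- ic$unload_fit_range
  keep <- unl_seg$load_mN >= band[1] * p_max & unl_seg$load_mN <= band[2] * p_max
  uh <- unl_seg$depth_nm[keep]
  up <- unl_seg$load_mN[keep]
  if (length(uh) < 5) {
    abort("Too few unloading points in the fit band.", class = "rib_extract_error")
  }
  sse_for_hf <- function(hf) {
    d <- uh - hf
    if (any(d <= 0)) return(Inf)
    f <- lm(log(up) ~ log(d))
    sum(residuals(f)^2)
  }
  hf_hi <- min(uh) - 1e-6 * max(uh)
  opt <- optimize(sse_for_hf, interval = c(0, hf_hi))
  hf <- opt$minimum
  pl <- lm(log(up) ~ log(uh - hf))
  m <- unname(coef(pl)[2])
  alpha <- exp(unname(coef(pl)[1]))
  S <- alpha * m * (h_max - hf)^(m - 1)   # mN/nm
  if (!is.finite(S) || S <= 0) {
    abort("Non-positive unloading stiffness.", class = "rib_extract_error")
  }

  h_c <- h_max - ic$epsilon * p_max / S
  A_nm2 <- ic$area_c0 * h_c^2
  H_MPa <- p_max / A_nm2 * 1e9          # mN/nm^2 -> MPa

  # Reduced modulus: S in N/m, A in m^2.
  S_si <- S * 1e6
  A_si <- A_nm2 * 1e-18
  Er_GPa <- sqrt(pi) / 2 * S_si / sqrt(A_si) / 1e9
  inv_Es <- 1 / Er_GPa - (1 - ic$nu_i^2) / ic$E_i
  E_GPa <- (1 - ic$nu_s^2) / inv_Es

  C_pct <- (h2 - h1) / h1 * 100

  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  w_load <- trapz(load_seg$depth_nm, load_seg$load_mN) +
    trapz(c(load_seg$depth_nm[nrow(load_seg)], hold_seg$depth_nm[1]),
          c(load_seg$load_mN[nrow(load_seg)], hold_seg$load_mN[1]))
  w_hold <- trapz(hold_seg$depth_nm, hold_seg$load_mN)
  ord <- order(unl_seg$depth_nm)
  w_elast <- trapz(unl_seg$depth_nm[ord], unl_seg$load_mN[ord])
  w_total <- w_load + w_hold
  eta <- w_elast / w_total * 100

  # Vickers-equivalent of the load-over-area hardness: MPa is N/mm^2, one
  # kgf/mm^2 is 9.807 N/mm^2, and the developed area of the 136-degree
  # pyramid is 1.0757x the projected one.
  H_vickers <- H_MPa / (9.807 * 1.0757)

  tibble::tibble(
    H_IT_MPa = H_MPa, H_IT_vickers = H_vickers,
    E_IT_GPa = E_GPa, C_IT_pct = C_pct, eta_IT_pct = eta,
    S_mN_nm = S, h_max_nm = h_max, h_c_nm = h_c,
    w_elast = w_elast, w_total = w_total
  )
}

#' Aggregate per-site indentation results to specimen level
#'
#' Averages results over all indentations of each tissue compartment
#' (osteonal `On`, interstitial `It`) and reports mean-tissue values as the
#' average of the two compartment means.
#'
#' @param results A tibble of per-indentation results carrying a `compartment`
#'   column (`"On"`/`"It"`) plus numeric result columns.
#' @param cols Names of the numeric columns to aggregate.
#'
#' @return A tibble with one row per compartment plus a `"mean"` row.
#' @export
aggregate_sites <- function(results,
                            cols = c("H_IT_MPa", "E_IT_GPa", "C_IT_pct",
                                     "eta_IT_pct")) {
  stopifnot("compartment" %in% names(results))
  present <- unique(results$compartment)
  missing <- setdiff(c("On", "It"), present)
  if (length(missing) > 0) {
    abort(paste0("No indentations for compartment(s): ",
                 paste(missing, collapse = ", ")),
          class = "rib_aggregate_error")
  }
  comp <- results %>%
    group_by(.data$compartment) %>%
    summarise(across(all_of(cols), mean), .groups = "drop")
  mean_row <- comp %>%
    summarise(across(all_of(cols), mean)) %>%
    mutate(compartment = "mean", .before = 1)
  bind_rows(comp, mean_row)
}

#' Vickers microhardness from an indent diagonal
#'
#' \eqn{HV = 1.8544\, P / d^2} with the load in kgf and the mean indent
#' diagonal in mm (standard geometry of the 136-degree square pyramid).
#'
#' @param load_gf Indentation load in grams-force.
#' @param diagonal_um Mean indent diagonal in micrometres.
#' @param geometry Geometry constant (default 1.8544).
#'
#' @return Hardness in kg/mm^2.
#' @export
#' @examples
#' vickers_hv(10, 19.3)
vickers_hv <- function(load_gf, diagonal_um, geometry = 1.8544) {
  if (any(load_gf <= 0)) abort("Load must be positive.", class = "rib_extract_error")
  if (any(diagonal_um <= 0)) {
    abort("Diagonal must be positive.", class = "rib_extract_error")
  }
  geometry * (load_gf / 1000) / (diagonal_um / 1000)^2
}
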