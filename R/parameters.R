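#' Generate a per-specimen parameter table
#'
#' Draws the 24 directly generated parameters conditionally on age, then adds
#' the 9 structurally derived columns, giving the full 33-parameter feature
#' vector per specimen.
#'
#' Each drawn parameter follows
#' \eqn{X = \mu + R\sigma z + \sigma\sqrt{1-R^2}\varepsilon} with \eqn{z} the
#' sample-standardised age and \eqn{\varepsilon} independent standard normal,
#' so `cor(X, age)` converges to the configured `R` as n grows.
#' Derived columns:
#' \itemize{
#'   \item mean-tissue mechanics `EIT`, `HIT`, `CIT`, `etaIT`, `HV` are the
#'     average of the osteonal (`On_`) and interstitial (`It_`) values;
#'   \item `Ash_pct = 100 - W_pct - Or_pct` (mass conservation);
#'   \item `CC = 1/MM` (the two indices share the same band areas);
#'   \item `CL002` and `CL004` follow from `Size` (L) and `Strain`
#'     (\eqn{\varepsilon}) through the Williamson-Hall line
#'     \eqn{\beta\cos\theta = 4\varepsilon\sin\theta + K\lambda/L} evaluated
#'     at the specimen's own 002/004 Bragg angles (from its `c_axis`).
#' }
#'
#' @param population A tibble with columns `id`, `age` (and optionally `sex`),
#'   e.g. from [draw_population()]. Ages must be non-degenerate.
#' @param specs Parameter specification tibble with columns `name`, `mean`,
#'   `sd`, `age_correlation`; defaults to [rib_parameter_specs()].
#' @param seed Integer seed.
#' @param config A [rib_config()] (used for the diffraction geometry of the
#'   derived coherence lengths).
#'
#' @return The population tibble with 33 added parameter columns.
#' @export
#' @examples
#' pop <- draw_population(20, seed = 2)
#' draw_parameters(pop, seed = 2)
draw_parameters <- function(population,
                            specs = rib_parameter_specs(),
                            seed = 1L,
                            config = rib_config()) {
  stopifnot(all(c("id", "age") %in% names(population)))
  if (sd(population$age) == 0) {
    abort("Ages are degenerate; the correlation structure is undefined.",
          class = "rib_config_error")
  }
  if (any(!is.finite(specs$mean)) || any(!is.finite(specs$sd)) || any(specs$sd <= 0)) {
    abort("Every parameter spec needs finite `mean` and positive `sd`.",
          class = "rib_config_error")
  }
  if (any(abs(specs$age_correlation) > 1)) {
    abort("`age_correlation` must lie in [-1, 1].", class = "rib_config_error")
  }

  n <- nrow(population)
  z <- as.numeric(scale(population$age))

  # Scramble the seed so the parameter noise stream never replays the
  # population's age stream when both are driven by one master seed.
  par_seed <- (as.integer(seed) + 1013904223L) %% .Machine$integer.max
  drawn <- withr::with_seed(par_seed, {
    cols <- purrr::pmap(specs, function(name, mean, sd, age_correlation, ...) {
      mean + age_correlation * sd * z +
        sd * sqrt(1 - age_correlation^2) * rnorm(n)
    })
    tibble::as_tibble(setNames(cols, specs$name))
  })

  out <- bind_cols(population, drawn)

  # Derived columns (structural identities; see roxygen above). Each is
  # added only when its inputs are part of the supplied spec, so reduced
  # custom specs stay usable.
  has <- function(...) all(c(...) %in% names(out))
  if (has("On_EIT", "It_EIT")) out$EIT <- (out$On_EIT + out$It_EIT) / 2
  if (has("On_HIT", "It_HIT")) out$HIT <- (out$On_HIT + out$It_HIT) / 2
  if (has("On_CIT", "It_CIT")) out$CIT <- (out$On_CIT + out$It_CIT) / 2
  if (has("On_etaIT", "It_etaIT")) {
    out$etaIT <- (out$On_etaIT + out$It_etaIT) / 2
  }
  if (has("On_HV", "It_HV")) out$HV <- (out$On_HV + out$It_HV) / 2
  if (has("W_pct", "Or_pct")) out$Ash_pct <- 100 - out$W_pct - out$Or_pct
  if (has("MM")) out$CC <- 1 / out$MM

  if (has("Size", "Strain", "c_axis")) {
    lam_nm <- config$xrd$wavelength_nm
    k <- config$xrd$scherrer_k
    th002 <- bragg_theta(hex_d_spacing(0, 0, 2, a = config$xrd$a_ref,
                                       c = out$c_axis), lam_nm * 10)
    th004 <- bragg_theta(hex_d_spacing(0, 0, 4, a = config$xrd$a_ref,
                                       c = out$c_axis), lam_nm * 10)
    out$CL002 <- k * lam_nm / (4 * out$Strain * sin(th002) + k * lam_nm / out$Size)
    out$CL004 <- k * lam_nm / (4 * out$Strain * sin(th004) + k * lam_nm / out$Size)
  }

  out
}

#' Implied age correlations of the full parameter set
#'
#' Derived columns are deterministic functions of drawn ones, so their age
#' correlations are implied rather than configured. This helper returns the
#' configured correlation for every drawn parameter together with the
#' analytically implied correlation for the linear (or near-linear) derived
#' columns, for use in fidelity checks and documentation. The two derived
#' coherence lengths are omitted: they are mildly nonlinear in `Size`,
#' `Strain` and `c_axis` and carry no printed reference correlation.
#'
#' @param specs Parameter specification tibble.
#' @return A tibble with columns `name`, `age_correlation`, `source`
#'   (`"configured"` or `"implied"`).
#' @export
implied_age_correlations <- function(specs = rib_parameter_specs()) {
  s <- function(nm) specs[specs$name == nm, ]
  # corr of A + B with age when A, B are independent given age:
  # cov(A, B) = rA rB sdA sdB through the shared age term.
  sum_corr <- function(a, b, sign = 1) {
    ra <- s(a)$age_correlation; rb <- s(b)$age_correlation
    sa <- s(a)$sd; sb <- s(b)$sd
    sign * (ra * sa + rb * sb) /
      sqrt(sa^2 + sb^2 + 2 * ra * rb * sa * sb)
  }
  implied <- tibble::tribble(
    ~name,     ~age_correlation,
    "EIT",     sum_corr("On_EIT", "It_EIT"),
    "HIT",     sum_corr("On_HIT", "It_HIT"),
    "CIT",     sum_corr("On_CIT", "It_CIT"),
    "etaIT",   sum_corr("On_etaIT", "It_etaIT"),
    "HV",      sum_corr("On_HV", "It_HV"),
    "Ash_pct", sum_corr("W_pct", "Or_pct", sign = -1),
    # 1/MM is monotone decreasing and near-linear over the generated range,
    # so the correlation flips sign and keeps magnitude to first order.
    "CC",      -s("MM")$age_correlation
  )
  dplyr::bind_rows(
    tibble::tibble(name = specs$name,
                   age_correlation = specs$age_correlation,
                   source = "configured"),
    dplyr::mutate(implied, source = "implied")
  )
}
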