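#' Default per-parameter generating specifications
#'
#' One row per rib cortical-bone parameter that the forward simulator draws
#' directly. Each drawn parameter \eqn{X} is generated conditionally on age as
#' \deqn{X = \mu + R \sigma z_{age} + \sigma \sqrt{1 - R^2}\, \varepsilon,}
#' where \eqn{z_{age}} is the sample-standardised age and \eqn{\varepsilon}
#' independent standard normal, so the sample correlation with age converges
#' to the configured `age_correlation`.
#'
#' Correlations come from the study's screening of 113 specimens (e.g.
#' porosity R = 0.83, interstitial Vickers hardness R = 0.55, organic weight
#' loss R = -0.39). Parameters whose age correlation was not reported carry a
#' small plausible value. Means and SDs are literature-scale defaults for
#' adult human rib cortical bone.
#'
#' Nine further columns of the full 33-parameter table are *derived*, not
#' drawn, because they are structurally tied to drawn columns (see
#' [draw_parameters()]): mean-tissue mechanics are compartment averages,
#' `Ash_pct = 100 - W_pct - Or_pct`, `CC = 1/MM`, and `CL002`/`CL004` follow
#' from `Size` and `Strain` through the Williamson-Hall line.
#'
#' @return A tibble with columns `name`, `mean`, `sd`, `age_correlation`,
#'   `unit`, `modality`.
#' @export
#' @examples
#' rib_parameter_specs()
rib_parameter_specs <- function() {
  tibble::tribble(
    ~name,       ~mean,   ~sd,     ~age_correlation, ~unit,     ~modality,
    "On_EIT",    19,      2.5,     -0.20,            "GPa",     "nanoindentation",
    "It_EIT",    21,      2.5,      0.00,            "GPa",     "nanoindentation",
    "On_HIT",    580,     90,       0.15,            "MPa",     "nanoindentation",
    "It_HIT",    640,     90,       0.15,            "MPa",     "nanoindentation",
    "On_CIT",    8.0,     1.0,     -0.29,            "%",       "nanoindentation",
    "It_CIT",    7.5,     1.0,     -0.27,            "%",       "nanoindentation",
    "On_etaIT",  34,      4.5,      0.40,            "%",       "nanoindentation",
    "It_etaIT",  36,      4.5,      0.38,            "%",       "nanoindentation",
    "On_HV",     42,      7,        0.44,            "kg/mm2",  "microindentation",
    "It_HV",     48,      7,        0.55,            "kg/mm2",  "microindentation",
    "PoAr_pct",  10,      1.8,      0.83,            "%",       "histomorphometry",
    "W_pct",     7.0,     0.9,     -0.25,            "%",       "thermal",
    "Or_pct",    24,      2.2,     -0.39,            "%",       "thermal",
    "LdH",       65,      10,      -0.27,            "J/g",     "thermal",
    "CdH",       2100,    260,     -0.24,            "J/g",     "thermal",
    "MM",        3.6,     0.30,     0.30,            "ratio",   "ftir",
    "CP",        0.0072,  0.0007,   0.36,            "ratio",   "ftir",
    "CI",        3.85,    0.22,     0.20,            "ratio",   "ftir",
    "CL030",     9.5,     1.1,      0.23,            "nm",      "xrd",
    "CL210",     8.5,     1.0,      0.10,            "nm",      "xrd",
    "a_axis",    9.418,   0.004,   -0.20,            "Angstrom", "xrd",
    "c_axis",    6.884,   0.003,    0.10,            "Angstrom", "xrd",
    "Size",      22,      2.0,      0.22,            "nm",      "xrd",
    "Strain",    0.0030,  0.00035, -0.20,            "1",       "xrd"
  )
}

#' Names of the 33 model parameters
#'
#' The full feature vector of a specimen record: 24 drawn parameters (see
#' [rib_parameter_specs()]) plus 9 derived columns.
#'
#' @return Character vector of length 33.
#' @export
rib_parameter_names <- function() {
  c(
    rib_parameter_specs()$name,
    "EIT", "HIT", "CIT", "etaIT", "HV",   # mean tissue = (On + It)/2
    "Ash_pct",                            # 100 - W_pct - Or_pct
    "CC",                                 # 1/MM
    "CL002", "CL004"                      # from Size + Strain (W-H line)
  )
}

#' Instrument and protocol constants
#'
#' Bundles every tunable constant used by the renderers and extractors into
#' one list so a run's configuration can be hashed and recorded.
#'
#' @param ... Named overrides of any default listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{indenter}{Oliver-Pharr constants: diamond indenter modulus
#'     `E_i = 1141` GPa and Poisson ratio `nu_i = 0.07`, sample Poisson ratio
#'     `nu_s = 0.3`, geometric factor `epsilon = 0.75`, ideal
#'     Berkovich-equivalent area function `A = 24.5 h_c^2`, unloading power-law
#'     fit over the top 40--98 % of the unloading load range, maximum load
#'     10 mN, loading/unloading rate 20 mN/min, 30 s hold.}
#'   \item{vickers}{Load 10 gf, geometry constant 1.8544 for the 136-degree
#'     square pyramid.}
#'   \item{thermal}{Window boundaries 25 / 200 / 550 degrees C, heating rate
#'     10 degrees C per minute, exothermic-positive heat-flow convention.}
#'   \item{ftir}{Integration bands: phosphate nu1nu3 900--1200, amide I
#'     1600--1750, carbonate nu2 850--890 cm^-1; crystallinity intensities at
#'     605, 565, 595 cm^-1 with a local baseline over 500--650 cm^-1.}
#'   \item{xrd}{Cu K-alpha wavelength 0.15406 nm, Scherrer constant 0.9,
#'     hydroxyapatite reference lattice a = 9.418, c = 6.884 Angstrom,
#'     Caglioti instrument broadening (U, V, W) in degrees^2 from a silicon
#'     standard, and per-reflection fit windows.}
#'   \item{porosity}{Mask edge length in pixels used by the renderer.}
#' }
#'
#' @return A named list of class `rib_config`.
#' @export
rib_config <- function(...) {
  cfg <- list(
    indenter = list(
      E_i = 1141, nu_i = 0.07, nu_s = 0.3,
      epsilon = 0.75, area_c0 = 24.5,
      unload_fit_range = c(0.40, 0.98),
      p_max_mN = 10, rate_mN_min = 20, hold_s = 30
    ),
    vickers = list(load_gf = 10, geometry = 1.8544),
    thermal = list(t_low = 25, t_mid = 200, t_high = 550,
                   heating_rate = 10, exo_positive = TRUE),
    ftir = list(
      band_phosphate = c(900, 1200),
      band_amide = c(1600, 1750),
      band_carbonate = c(850, 890),
      ci_positions = c(605, 565, 595),
      ci_baseline = c(500, 650)
    ),
    xrd = list(
      wavelength_nm = 0.15406, scherrer_k = 0.9,
      a_ref = 9.418, c_ref = 6.884,
      caglioti = c(U = 0.004, V = -0.002, W = 0.003),
      # windows must span several FWHM: biogenic apatite peaks reach
      # ~1.3 degrees FWHM, so 210/030 get wider windows than the minimal
      # single-degree brackets around their maxima
      windows = list(`002` = c(23, 27), `210` = c(27.2, 30.6),
                     `030` = c(31.3, 34.8), `004` = c(50, 55))
    ),
    porosity = list(mask_px = 192)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "rib_config")
}

#' Hash of a configuration
#'
#' Deterministic hash recorded in run reports so any change in constants is
#' visible downstream.
#'
#' @param config A [rib_config()] list.
#' @return A character scalar.
#' @export
rib_config_hash <- function(config) rlang::hash(config)

#' Published age-estimation equations
#'
#' Coefficient sets of the three fixed equations fitted on the reference
#' cohort of 113 ribs: E1 uses the full parameter pool (10 predictors), E2
#' indentation mechanics plus porosity (6 predictors), E3 physicochemical
#' parameters only (5 predictors). Ages are predicted in years as
#' `constant + sum(coefficient * value)`.
#'
#' The printed source table interleaves the three columns; the encoded
#' assignment follows the stated model compositions and degrees of freedom.
#' One cell is ambiguous between the osteonal and interstitial Vickers rows:
#' the narrative composition of E2 names the interstitial value, which is
#' what is encoded here (override by editing the returned tibble).
#'
#' @return A tibble with columns `equation`, `term`, `estimate`; the
#'   intercept rows have `term == "(Intercept)"`.
#' @export
#' @examples
#' published_equations()
published_equations <- function() {
  tibble::tribble(
    ~equation, ~term,         ~estimate,
    "E1",      "PoAr_pct",      6.001,
    "E1",      "HIT",          -0.446,
    "E1",      "On_EIT",        1.222,
    "E1",      "On_etaIT",      2.523,
    "E1",      "On_HV",         0.624,
    "E1",      "CdH",          -0.005,
    "E1",      "CL030",         5.450,
    "E1",      "a_axis",     -369.968,
    "E1",      "c_axis",      597.609,
    "E1",      "CL004",        -3.455,
    "E1",      "(Intercept)", -759.525,
    "E2",      "PoAr_pct",      6.120,
    "E2",      "HIT",          -0.858,
    "E2",      "On_EIT",        1.683,
    "E2",      "HV",            0.531,
    "E2",      "On_etaIT",      1.946,
    "E2",      "It_HV",         0.466,
    "E2",      "(Intercept)",  -62.450,
    "E3",      "CIT",           3.825,
    "E3",      "Ash_pct",       4.697,
    "E3",      "CdH",          -0.012,
    "E3",      "CC",          204.382,
    "E3",      "CL030",         8.938,
    "E3",      "(Intercept)", -249.937
  )
}

#' Candidate predictor pools for the stepwise fits
#'
#' `"all"` is the full 33-parameter pool; `"nano"` restricts to indentation
#' mechanics (nano and micro) plus porosity, the quick single-instrument
#' workflow; `"physchem"` to the thermal, FTIR and XRD parameters measured
#' on bone powder.
#'
#' @param which One of `"all"`, `"nano"`, `"physchem"`.
#' @return Character vector of parameter names.
#' @export
rib_candidate_set <- function(which = c("all", "nano", "physchem")) {
  which <- match.arg(which)
  mech <- c("On_EIT", "It_EIT", "EIT", "On_HIT", "It_HIT", "HIT",
            "On_CIT", "It_CIT", "CIT", "On_etaIT", "It_etaIT", "etaIT",
            "On_HV", "It_HV", "HV", "PoAr_pct")
  phys <- c("W_pct", "Or_pct", "Ash_pct", "LdH", "CdH",
            "MM", "CP", "CI", "CC",
            "CL002", "CL004", "CL030", "CL210",
            "a_axis", "c_axis", "Size", "Strain")
  switch(which, all = c(mech, phys), nano = mech, physchem = phys)
}
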