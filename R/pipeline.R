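#' Extract all 33 parameters from one raw bundle
#'
#' Runs every extraction stage on an in-memory [render_raw()] bundle:
#' Oliver-Pharr analysis and per-compartment aggregation of the indentation
#' curves, Vickers hardness from the indent diagonals, TGA step fractions,
#' DSC enthalpies, FTIR indices, split pseudo-Voigt XRD analysis and mask
#' porosity.
#'
#' @param bundle A `rib_bundle` from [render_raw()] (or an equivalent list
#'   assembled from files).
#' @param config A [rib_config()].
#'
#' @return A one-row tibble with `id` and the 33 parameter columns.
#' @export
extract_bundle <- function(bundle, config = rib_config()) {
  ind <- bundle$indentation %>%
    group_by(.data$quadrant, .data$compartment, .data$replicate) %>%
    dplyr::group_modify(~ analyze_indentation(.x, config)) %>%
    ungroup()
  agg <- aggregate_sites(ind)
  g <- function(comp, col) agg[[col]][agg$compartment == comp]

  hv <- bundle$vickers %>%
    mutate(HV = vickers_hv(.data$load_gf, .data$diagonal_um,
                           config$vickers$geometry)) %>%
    group_by(.data$compartment) %>%
    summarise(HV = mean(.data$HV), .groups = "drop")
  on_hv <- hv$HV[hv$compartment == "On"]
  it_hv <- hv$HV[hv$compartment == "It"]

  th <- config$thermal
  tga <- tga_steps(bundle$thermogram, th$t_low, th$t_mid, th$t_high)
  dsc <- dsc_enthalpies(bundle$heatflow, th$t_low, th$t_mid, th$t_high,
                        th$heating_rate, th$exo_positive)
  ftir <- ftir_indices(bundle$ftir, config)
  xrd <- analyze_xrd(bundle$xrd$wide, bundle$xrd$stepped_002,
                     bundle$xrd$stepped_004, config)
  po <- specimen_porosity(purrr::map_dbl(bundle$masks, porosity))

  tibble::tibble(
    id = bundle$specimen_id,
    On_EIT = g("On", "E_IT_GPa"), It_EIT = g("It", "E_IT_GPa"),
    EIT = g("mean", "E_IT_GPa"),
    On_HIT = g("On", "H_IT_MPa"), It_HIT = g("It", "H_IT_MPa"),
    HIT = g("mean", "H_IT_MPa"),
    On_CIT = g("On", "C_IT_pct"), It_CIT = g("It", "C_IT_pct"),
    CIT = g("mean", "C_IT_pct"),
    On_etaIT = g("On", "eta_IT_pct"), It_etaIT = g("It", "eta_IT_pct"),
    etaIT = g("mean", "eta_IT_pct"),
    On_HV = on_hv, It_HV = it_hv, HV = (on_hv + it_hv) / 2,
    PoAr_pct = po
  ) %>%
    bind_cols(tga, dsc, ftir, xrd)
}

#' Simulate a cohort and write its raw bundles to disk
#'
#' Draws a population and parameter table, renders every specimen's raw
#' modality data, and writes `parameters.csv` plus per-specimen curve files
#' (`*_tga.csv`, `*_dsc.csv`, `*_ftir.csv`, `*_xrd_wide.csv`, `*_xrd_002.csv`,
#' `*_xrd_004.csv`, `*_indent_q<1-4>_<on|it>_<k>.csv`, `*_vickers.csv`) and
#' PNG masks (`*_quadrant<1-4>.png`) to `dir`. Re-running with the same seed
#' and configuration reproduces the files byte for byte.
#'
#' @param n Number of specimens.
#' @param seed Integer master seed; per-specimen sub-seeds are derived from
#'   it deterministically.
#' @param dir Output directory (created if absent).
#' @param specs Parameter specification tibble.
#' @param config A [rib_config()].
#' @param curves_per_site Indentation curves per quadrant and compartment.
#' @param population Optional pre-drawn population tibble (overrides `n`).
#'
#' @return Invisibly, the parameter table that was written.
#' @export
simulate_bundles <- function(n = 113, seed = 17L, dir,
                             specs = rib_parameter_specs(),
                             config = rib_config(),
                             curves_per_site = 2,
                             population = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(population)) population <- draw_population(n, seed = seed)
  table <- draw_parameters(population, specs, seed = seed, config = config)
  readr::write_csv(table, file.path(dir, "parameters.csv"))

  for (i in seq_len(nrow(table))) {
    rec <- table[i, ]
    sub_seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    b <- render_raw(rec, seed = sub_seed, config = config,
                    curves_per_site = curves_per_site)
    p <- function(suffix) file.path(dir, paste0(rec$id, "_", suffix))
    readr::write_csv(b$thermogram, p("tga.csv"))
    readr::write_csv(b$heatflow, p("dsc.csv"))
    readr::write_csv(b$ftir, p("ftir.csv"))
    readr::write_csv(b$xrd$wide, p("xrd_wide.csv"))
    readr::write_csv(b$xrd$stepped_002, p("xrd_002.csv"))
    readr::write_csv(b$xrd$stepped_004, p("xrd_004.csv"))
    readr::write_csv(b$vickers, p("vickers.csv"))
    curves <- b$indentation
    for (key in split(seq_len(nrow(curves)),
                      paste0("q", curves$quadrant, "_",
                             tolower(curves$compartment), "_",
                             curves$replicate))) {
      cv <- curves[key, ]
      nm <- paste0("indent_q", cv$quadrant[1], "_",
                   tolower(cv$compartment[1]), "_", cv$replicate[1], ".csv")
      readr::write_csv(select(cv, "time_s", "load_mN", "depth_nm", "phase"),
                       p(nm))
    }
    for (q in 1:4) {
      png::writePNG(matrix(as.numeric(b$masks[[q]]),
                           nrow(b$masks[[q]]), ncol(b$masks[[q]])),
                    p(paste0("quadrant", q, ".png")))
    }
  }
  invisible(table)
}

# Read one specimen's bundle back from a simulate_bundles() directory.
read_bundle <- function(dir, id) {
  p <- function(suffix) file.path(dir, paste0(id, "_", suffix))
  rd <- function(f) readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  ind_files <- list.files(dir, pattern = paste0("^", id, "_indent_.*\\.csv$"),
                          full.names = TRUE)
  curves <- purrr::map(ind_files, function(f) {
    meta <- regmatches(basename(f),
                       regexec("indent_q(\\d)_(on|it)_(\\d+)\\.csv$", basename(f)))[[1]]
    mutate(rd(f),
           quadrant = as.integer(meta[2]),
           compartment = ifelse(meta[3] == "on", "On", "It"),
           replicate = as.integer(meta[4]))
  })
  masks <- purrr::map(1:4, function(q) {
    png::readPNG(p(paste0("quadrant", q, ".png"))) >= 0.5
  })
  structure(list(
    specimen_id = id,
    indentation = bind_rows(curves),
    vickers = rd(p("vickers.csv")),
    thermogram = rd(p("tga.csv")),
    heatflow = rd(p("dsc.csv")),
    ftir = rd(p("ftir.csv")),
    xrd = list(wide = rd(p("xrd_wide.csv")),
               stepped_002 = rd(p("xrd_002.csv")),
               stepped_004 = rd(p("xrd_004.csv"))),
    masks = masks
  ), class = "rib_bundle")
}

#' Extract the parameter table from a directory of raw bundles
#'
#' Discovers specimens from the `*_tga.csv` files in `dir`, reads each raw
#' bundle and runs the full extraction. Failing specimens yield an all-`NA`
#' parameter row plus a warning, or an error under `strict = TRUE`.
#'
#' @param dir Directory written by [simulate_bundles()] (or laid out the
#'   same way).
#' @param config A [rib_config()].
#' @param strict Abort on the first failing specimen instead of collecting.
#'
#' @return A tibble with one row per specimen: `id` plus the 33 parameters.
#' @export
extract_all <- function(dir, config = rib_config(), strict = FALSE) {
  tga <- list.files(dir, pattern = "_tga\\.csv$")
  ids <- sub("_tga\\.csv$", "", tga)
  if (length(ids) == 0) {
    if (strict) abort("No raw bundles found.", class = "rib_extract_error")
    warn("No raw bundles found; returning an empty table.")
    return(tibble::tibble(id = character()))
  }
  rows <- purrr::map(ids, function(id) {
    tryCatch(
      extract_bundle(read_bundle(dir, id), config),
      error = function(e) {
        if (strict) abort(paste0("Extraction failed for ", id, ": ",
                                 conditionMessage(e)),
                          class = "rib_extract_error")
        warn(paste0("Extraction failed for ", id, ": ", conditionMessage(e)))
        tibble::tibble(id = id)
      }
    )
  })
  bind_rows(rows)
}

#' Fit, diagnose and cross-validate the age models on a parameter table
#'
#' The validation analogue of the study's model tables: fits the stepwise
#' model for each requested candidate pool, populates the full diagnostic
#' block and the leave-one-out metrics, and returns everything as one
#' report.
#'
#' @param table Parameter table with an `age` column.
#' @param candidate_sets Character vector drawn from `"all"`, `"nano"`,
#'   `"physchem"`.
#' @param config A [rib_config()] (hashed into the report).
#' @param seed Seed for the permutation p-value of the Durbin-Watson test.
#'
#' @return A list of class `rib_report`: `fits` (named list of
#'   [fit_stepwise()] objects), `summary` (tibble of fit and CV metrics side
#'   by side), `config_hash`, `software_version`.
#' @export
validate_models <- function(table, candidate_sets = c("all", "nano", "physchem"),
                            config = rib_config(), seed = 1L) {
  if (!"age" %in% names(table)) {
    abort("Table has no `age` column.", class = "rib_config_error")
  }
  candidate_sets <- match.arg(candidate_sets, several.ok = TRUE)
  fits <- purrr::map(setNames(candidate_sets, candidate_sets), function(cs) {
    fit_stepwise(table, candidates = rib_candidate_set(cs), seed = seed)
  })
  summary <- purrr::imap_dfr(fits, function(f, nm) {
    g <- glance(f)
    cv <- loo_cv(table, f$predictors)
    tibble::tibble(
      candidate_set = nm,
      n_predictors = length(f$predictors),
      r_squared = g$r.squared, adj_r_squared = g$adj.r.squared,
      rse = g$sigma, aic = g$AIC, bic = g$BIC,
      mae = mean(abs(residuals(f$model))),
      cv_r2 = cv$cv_r2, cv_rmse = cv$cv_rmse, cv_mae = cv$cv_mae
    )
  })
  structure(list(fits = fits, summary = summary,
                 config_hash = rib_config_hash(config),
                 software_version = as.character(utils::packageVersion("ribchron"))),
            class = "rib_report")
}

#' @export
print.rib_report <- function(x, ...) {
  cat("Age-model validation report (config ", substr(x$config_hash, 1, 8),
      ", ribchron ", x$software_version, ")\n\n", sep = "")
  print(x$summary)
  invisible(x)
}
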