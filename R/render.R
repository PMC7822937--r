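# Forward models: render raw modality data from a specimen's parameter
# record so that the extraction stages can be validated by round-trip
# recovery. Each renderer is the designed inverse of its extractor.

gauss_band <- function(x, center, sigma) exp(-(x - center)^2 / (2 * sigma^2))

check_range <- function(value, name, lo, hi) {
  if (!is.finite(value) || value <= lo || value >= hi) {
    abort(sprintf("Parameter `%s` = %s outside physical range (%s, %s).",
                  name, format(value), lo, hi),
          class = "rib_render_error")
  }
  invisible(value)
}

#' Render an instrumented-indentation curve from target mechanics
#'
#' Builds a load--depth--time record whose Oliver-Pharr analysis recovers the
#' supplied hardness, modulus, creep and elastic work ratio. The loading
#' branch is a power law whose exponent is solved so the work partition
#' matches `eta_IT`; the hold adds `C_IT` percent of depth at constant load;
#' the unloading branch is the Oliver-Pharr power law with exponent `m` and
#' stiffness consistent with `E_IT`.
#'
#' @param H_IT_MPa,E_IT_GPa,C_IT_pct,eta_IT_pct Target parameters.
#' @param config A [rib_config()].
#' @param n_per_phase Points per phase.
#' @param m Unloading power-law exponent.
#' @param noise_nm Gaussian depth noise SD in nm (0 for a noiseless curve).
#' @param seed Integer seed for the noise.
#'
#' @return A tibble `time_s`, `load_mN`, `depth_nm`, `phase`.
#' @export
render_indentation_curve <- function(H_IT_MPa, E_IT_GPa, C_IT_pct, eta_IT_pct,
                                     config = rib_config(),
                                     n_per_phase = 80, m = 1.5,
                                     noise_nm = 0.2, seed = 1L) {
  ic <- config$indenter
  check_range(H_IT_MPa, "H_IT", 0, 1e5)
  check_range(E_IT_GPa, "E_IT", 0, 500)
  check_range(C_IT_pct, "C_IT", -50, 50)
  check_range(eta_IT_pct, "eta_IT", 0, 100)

  p_max <- ic$p_max_mN
  A_nm2 <- p_max * 1e9 / H_IT_MPa
  h_c <- sqrt(A_nm2 / ic$area_c0)
  Er <- 1 / ((1 - ic$nu_s^2) / E_IT_GPa + (1 - ic$nu_i^2) / ic$E_i)
  S <- 2 * Er * 1e9 * sqrt(A_nm2 * 1e-18) / sqrt(pi) / 1e6  # mN/nm
  h_max <- h_c + ic$epsilon * p_max / S
  h_f <- h_max - m * p_max / S
  if (h_f <= 0) {
    abort("Infeasible mechanics: unloading foot depth would be negative.",
          class = "rib_render_error")
  }
  h_1 <- h_max / (1 + C_IT_pct / 100)

  w_elast <- p_max * (h_max - h_f) / (m + 1)
  w_total <- 100 * w_elast / eta_IT_pct
  w_hold <- p_max * (h_max - h_1)
  w_load <- w_total - w_hold
  if (w_load <= 0 || w_load >= p_max * h_1) {
    abort("Parameter `eta_IT` infeasible for this curve geometry.",
          class = "rib_render_error")
  }
  p_exp <- p_max * h_1 / w_load - 1

  rate_s <- ic$rate_mN_min / 60  # mN/s
  t_load <- p_max / rate_s

  h_l <- seq(0, h_1, length.out = n_per_phase + 1)
  P_l <- p_max * (h_l / h_1)^p_exp
  t_l <- P_l / rate_s

  u <- seq(0, 1, length.out = n_per_phase)
  h_h <- h_1 + (h_max - h_1) * (1 - exp(-4 * u)) / (1 - exp(-4))
  t_h <- t_load + u * ic$hold_s
  P_h <- rep(p_max, length(u))

  # uniform in depth so trapezoidal work integrals converge fast
  h_u <- seq(h_max, h_f, length.out = n_per_phase + 1)
  P_u <- p_max * ((h_u - h_f) / (h_max - h_f))^m
  t_u <- t_load + ic$hold_s + (1 - P_u / p_max) * t_load

  out <- tibble::tibble(
    time_s = c(t_l, t_h, t_u),
    load_mN = c(P_l, P_h, P_u),
    depth_nm = c(h_l, h_h, h_u),
    phase = c(rep("loading", length(h_l)), rep("hold", length(h_h)),
              rep("unloading", length(h_u)))
  )
  if (noise_nm > 0) {
    out$depth_nm <- out$depth_nm +
      withr::with_seed(as.integer(seed), rnorm(nrow(out), 0, noise_nm))
    # keep the hold endpoints exact so creep stays interpretable
    out$depth_nm[out$phase == "hold"][1] <- h_1
    out$depth_nm[max(which(out$phase == "hold"))] <- h_max
  }
  out
}

#' Render a thermogravimetric curve
#'
#' Two smooth sigmoidal mass-loss steps (dehydration centred near 110 C,
#' organic combustion near 330 C) with magnitudes `W_pct` and `Or_pct` of
#' the initial mass.
#'
#' @param W_pct,Or_pct Step magnitudes in percent of initial mass.
#' @param initial_mass_mg Initial sample mass.
#' @param t_step Temperature grid step in degrees C.
#' @param noise_mg Mass noise SD.
#' @param seed Integer seed.
#' @return A tibble `temperature_C`, `mass_mg`.
#' @export
render_thermogram <- function(W_pct, Or_pct, initial_mass_mg = 10,
                              t_step = 0.5, noise_mg = 0, seed = 1L) {
  check_range(W_pct, "W_pct", 0, 100)
  check_range(Or_pct, "Or_pct", 0, 100)
  if (W_pct + Or_pct >= 100) {
    abort("W_pct + Or_pct must be below 100.", class = "rib_render_error")
  }
  tt <- seq(25, 550, by = t_step)
  s1 <- stats::plogis((tt - 110) / 12)
  s2 <- stats::plogis((tt - 330) / 20)
  mass <- initial_mass_mg * (1 - W_pct / 100 * s1 - Or_pct / 100 * s2)
  if (noise_mg > 0) {
    mass <- mass + withr::with_seed(as.integer(seed), rnorm(length(tt), 0, noise_mg))
  }
  tibble::tibble(temperature_C = tt, mass_mg = mass)
}

#' Render a DSC heat-flow curve
#'
#' One endothermic (dehydration) and one exothermic (organic combustion)
#' Gaussian excursion on a linear baseline, whose linear-baseline time
#' integrals equal `LdH` and `CdH` at the configured heating rate.
#' Exothermic-positive convention.
#'
#' @param LdH,CdH Target enthalpies in J/g (both positive magnitudes).
#' @param heating_rate Degrees C per minute.
#' @param t_step Temperature grid step.
#' @param noise_Wg Heat-flow noise SD.
#' @param seed Integer seed.
#' @return A tibble `temperature_C`, `heatflow_Wg`.
#' @export
render_heatflow <- function(LdH, CdH, heating_rate = 10,
                            t_step = 0.5, noise_Wg = 0, seed = 1L) {
  check_range(LdH, "LdH", 0, 1e4)
  check_range(CdH, "CdH", 0, 1e5)
  tt <- seq(25, 550, by = t_step)
  sec_per_degC <- 60 / heating_rate
  amp_endo <- LdH / (18 * sqrt(2 * pi) * sec_per_degC)
  amp_exo <- CdH / (30 * sqrt(2 * pi) * sec_per_degC)
  hf <- 0.05 + 1e-4 * tt -
    amp_endo * gauss_band(tt, 110, 18) +
    amp_exo * gauss_band(tt, 350, 30)
  if (noise_Wg > 0) {
    hf <- hf + withr::with_seed(as.integer(seed), rnorm(length(tt), 0, noise_Wg))
  }
  tibble::tibble(temperature_C = tt, heatflow_Wg = hf)
}

#' Render an ATR-FTIR absorbance spectrum
#'
#' Gaussian bands on the standard bone-matrix intervals whose areas and
#' intensities reproduce the target indices: the phosphate/amide area ratio
#' gives `MM` (and `CC = 1/MM`), the carbonate/phosphate ratio `CP`, and the
#' shared width of the nu4 doublet is solved numerically so the extracted
#' crystallinity index equals `CI`.
#'
#' @param MM,CP,CI Target indices.
#' @param config A [rib_config()].
#' @param noise_au Absorbance noise SD.
#' @param seed Integer seed.
#' @return A tibble `wavenumber_cm1` (descending 4000 to 400), `absorbance`.
#' @export
render_ftir_spectrum <- function(MM, CP, CI, config = rib_config(),
                                 noise_au = 0, seed = 1L) {
  check_range(MM, "MM", 0, 100)
  check_range(CP, "CP", 0, 1)
  check_range(CI, "CI", 2.2, 8.5)
  wn <- seq(4000, 400, by = -2)
  a_amide <- 4.0
  a_phos <- MM * a_amide
  a_carb <- CP * a_phos
  base <- 0.02 + 1e-6 * (wn - 400)
  # band widths sit >= 4 sigma inside their integration limits so the
  # chord-baseline extraction sees effectively complete bands
  fixed <- base +
    a_amide / (15 * sqrt(2 * pi)) * gauss_band(wn, 1660, 15) +
    a_phos / (34 * sqrt(2 * pi)) * gauss_band(wn, 1035, 34) +
    a_carb / (4.5 * sqrt(2 * pi)) * gauss_band(wn, 872, 4.5)

  h603 <- 0.08
  v4 <- function(sigma) {
    h603 * gauss_band(wn, 603, sigma) + h603 * gauss_band(wn, 566, sigma)
  }
  ci_of <- function(sigma) {
    sp <- tibble::tibble(wavenumber_cm1 = wn, absorbance = fixed + v4(sigma))
    ii <- corrected_intensity(sp, config$ftir$ci_positions, config$ftir$ci_baseline)
    (ii[1] + ii[2]) / ii[3]
  }
  sigma <- uniroot(function(s) ci_of(s) - CI, c(4.5, 14), tol = 1e-6)$root

  ab <- fixed + v4(sigma)
  if (noise_au > 0) {
    ab <- ab + withr::with_seed(as.integer(seed), rnorm(length(wn), 0, noise_au))
  }
  tibble::tibble(wavenumber_cm1 = wn, absorbance = ab)
}

# FWHM (degrees 2-theta) observed for a reflection with coherence length
# cl_nm at Bragg angle theta_rad, including instrument broadening.
observed_fwhm <- function(cl_nm, theta_rad, config) {
  xc <- config$xrd
  beta_s <- xc$scherrer_k * xc$wavelength_nm / (cl_nm * cos(theta_rad))
  t <- tan(theta_rad)
  inst2 <- xc$caglioti[["U"]] * t^2 + xc$caglioti[["V"]] * t + xc$caglioti[["W"]]
  sqrt(rad2deg(beta_s)^2 + inst2)
}

#' Render powder-diffraction scans for one specimen
#'
#' Split pseudo-Voigt peaks at the 002, 210, 030 and 004 positions implied
#' by the specimen's lattice parameters, with observed widths implied by its
#' coherence lengths plus the configured Caglioti instrument broadening, on
#' a linear background with counting noise. Produces the wide 10--80 degree
#' scan and the two stepped scans around 002 and 004.
#'
#' @param CL002,CL004,CL030,CL210 Coherence lengths in nm.
#' @param a_axis,c_axis Lattice parameters in Angstrom.
#' @param config A [rib_config()].
#' @param noise Relative counting-noise scale (SD as a fraction of the
#'   largest peak height; the stepped scans use a third of it, mirroring
#'   their longer count time).
#' @param seed Integer seed.
#' @return A list `wide`, `stepped_002`, `stepped_004` of tibbles with
#'   `two_theta`, `intensity`.
#' @export
render_diffraction <- function(CL002, CL004, CL030, CL210, a_axis, c_axis,
                               config = rib_config(), noise = 0.005,
                               seed = 1L) {
  for (nm in c("CL002", "CL004", "CL030", "CL210")) {
    check_range(get(nm), nm, 0.5, 500)
  }
  check_range(a_axis, "a_axis", 8, 11)
  check_range(c_axis, "c_axis", 6, 8)
  lam_A <- config$xrd$wavelength_nm * 10

  refl <- tibble::tibble(
    hkl = c("002", "210", "030", "004"),
    h = c(0, 2, 0, 0), k = c(0, 1, 3, 0), l = c(2, 0, 0, 4),
    cl = c(CL002, CL210, CL030, CL004),
    height = c(100, 60, 60, 40)
  )
  refl$d <- hex_d_spacing(refl$h, refl$k, refl$l, a_axis, c_axis)
  refl$theta <- bragg_theta(refl$d, lam_A)
  refl$pos <- 2 * rad2deg(refl$theta)
  refl$fwhm <- observed_fwhm(refl$cl, refl$theta, config)

  render_scan <- function(grid, which, noise_sd, sub_seed) {
    y <- 20 + 0.05 * grid
    for (i in which) {
      y <- y + refl$height[i] *
        spv_profile(grid, refl$pos[i], refl$fwhm[i] / 2, refl$fwhm[i] / 2, 0.5)
    }
    if (noise_sd > 0) {
      y <- y + withr::with_seed(as.integer(sub_seed),
                                rnorm(length(grid), 0, noise_sd))
    }
    tibble::tibble(two_theta = grid, intensity = pmax(y, 0))
  }

  top <- max(refl$height)
  list(
    wide = render_scan(seq(10, 80, by = 0.02), 1:4, noise * top, seed),
    stepped_002 = render_scan(seq(23, 27, by = 0.01), 1, noise * top / 3,
                              seed + 1L),
    stepped_004 = render_scan(seq(50, 55, by = 0.01), 4, noise * top / 3,
                              seed + 2L)
  )
}

#' Render a binary porosity mask
#'
#' Non-overlapping void disks (vascular-canal scale) topped up with single
#' void pixels (osteocyte-lacuna scale) until the void fraction equals the
#' target to within one pixel.
#'
#' @param target_pct Target void fraction in percent.
#' @param px Mask edge length in pixels.
#' @param seed Integer seed.
#' @return A logical matrix (`TRUE` = void).
#' @export
render_porosity_mask <- function(target_pct, px = 192, seed = 1L) {
  check_range(target_pct, "PoAr_pct", 0, 60)
  target <- round(target_pct / 100 * px^2)
  withr::with_seed(as.integer(seed), {
    mask <- matrix(FALSE, px, px)
    attempts <- 0
    while (sum(mask) < 0.9 * target && attempts < 500) {
      attempts <- attempts + 1
      r <- sample(3:9, 1)
      cx <- runif(1, r + 1, px - r)
      cy <- runif(1, r + 1, px - r)
      ix <- seq(floor(cx - r), ceiling(cx + r))
      iy <- seq(floor(cy - r), ceiling(cy + r))
      disk <- outer(ix, iy, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
      patch <- mask[ix, iy]
      if (any(patch & disk)) next                    # overlap: reject
      if (sum(mask) + sum(disk) > target) next       # would overshoot
      patch[disk] <- TRUE
      mask[ix, iy] <- patch
    }
    deficit <- target - sum(mask)
    if (deficit > 0) {
      bone <- which(!mask)
      mask[sample(bone, deficit)] <- TRUE
    }
    mask
  })
}

# Vickers indents: one On and one It indent per quadrant, diagonals solved
# from the target hardness values.
render_vickers <- function(On_HV, It_HV, config = rib_config(),
                           noise_rel = 0.001, seed = 1L) {
  check_range(On_HV, "On_HV", 0, 2000)
  check_range(It_HV, "It_HV", 0, 2000)
  vc <- config$vickers
  grid <- tidyr::expand_grid(quadrant = 1:4, compartment = c("On", "It"))
  hv <- ifelse(grid$compartment == "On", On_HV, It_HV)
  d_um <- sqrt(vc$geometry * vc$load_gf / 1000 / hv) * 1000
  if (noise_rel > 0) {
    d_um <- d_um * (1 + withr::with_seed(as.integer(seed),
                                         rnorm(length(d_um), 0, noise_rel)))
  }
  tibble::tibble(grid, load_gf = vc$load_gf, diagonal_um = d_um)
}

#' Render the full raw-data bundle for one specimen
#'
#' Applies every forward model to one row of a parameter table, producing
#' the raw modality data whose extraction recovers the generating
#' parameters.
#'
#' @param record One-row data frame holding `id` and the 33 parameters (see
#'   [rib_parameter_names()]).
#' @param seed Integer seed; per-modality sub-seeds are derived from it.
#' @param config A [rib_config()].
#' @param curves_per_site Indentation curves rendered per quadrant and
#'   compartment.
#'
#' @return A list of class `rib_bundle`: `specimen_id`, `indentation`
#'   (tibble of curves with `quadrant`, `compartment`, `replicate`),
#'   `vickers`, `thermogram`, `heatflow`, `ftir`, `xrd` (list of three
#'   scans), `masks` (list of 4 logical matrices).
#' @export
render_raw <- function(record, seed = 1L, config = rib_config(),
                       curves_per_site = 2) {
  stopifnot(nrow(record) == 1)
  seed <- as.integer(seed)

  sites <- tidyr::expand_grid(quadrant = 1:4, compartment = c("On", "It"),
                              replicate = seq_len(curves_per_site))
  curves <- purrr::pmap(sites, function(quadrant, compartment, replicate) {
    pre <- if (compartment == "On") "On_" else "It_"
    cv <- render_indentation_curve(
      H_IT_MPa = record[[paste0(pre, "HIT")]],
      E_IT_GPa = record[[paste0(pre, "EIT")]],
      C_IT_pct = record[[paste0(pre, "CIT")]],
      eta_IT_pct = record[[paste0(pre, "etaIT")]],
      config = config,
      seed = seed + 13L * quadrant + 101L * replicate +
        ifelse(compartment == "On", 0L, 7L)
    )
    mutate(cv, quadrant = quadrant, compartment = compartment,
           replicate = replicate)
  })

  masks <- purrr::map(1:4, function(q) {
    render_porosity_mask(record$PoAr_pct, px = config$porosity$mask_px,
                         seed = seed + 211L * q)
  })

  structure(list(
    specimen_id = record$id,
    indentation = bind_rows(curves),
    vickers = render_vickers(record$On_HV, record$It_HV, config,
                             seed = seed + 3L),
    thermogram = render_thermogram(record$W_pct, record$Or_pct,
                                   noise_mg = 1e-4, seed = seed + 5L),
    heatflow = render_heatflow(record$LdH, record$CdH,
                               heating_rate = config$thermal$heating_rate,
                               noise_Wg = 1e-4, seed = seed + 7L),
    ftir = render_ftir_spectrum(record$MM, record$CP, record$CI, config,
                                noise_au = 1e-5, seed = seed + 11L),
    xrd = render_diffraction(record$CL002, record$CL004, record$CL030,
                             record$CL210, record$a_axis, record$c_axis,
                             config, seed = seed + 17L),
    masks = masks
  ), class = "rib_bundle")
}
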