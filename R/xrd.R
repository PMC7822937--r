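#' @rdname lattice_parameters
#' @param h,k,l Miller indices.
#' @param a,c Hexagonal lattice parameters (Angstrom).
#' @export
hex_d_spacing <- function(h, k, l, a, c) {
  1 / sqrt((4 / 3) * (h^2 + h * k + k^2) / a^2 + l^2 / c^2)
}

# Bragg angle theta (radians) from d-spacing and wavelength, both in Angstrom.
bragg_theta <- function(d, lam) asin(lam / (2 * d))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Split pseudo-Voigt profile: common mixing eta, independent left/right
# half-widths at half maximum (wl, wr), unit height at x0.
spv_profile <- function(x, x0, wl, wr, eta) {
  w <- ifelse(x < x0, wl, wr)
  u <- (x - x0) / w
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

#' Fit a split pseudo-Voigt peak to a diffraction window
#'
#' Nonlinear least-squares fit of an asymmetric split pseudo-Voigt (shared
#' Gaussian--Lorentzian mixing, independent left/right half-widths) plus a
#' linear background over a 2-theta window containing one dominant maximum.
#'
#' @param pattern A data frame with columns `two_theta` (degrees, strictly
#'   increasing) and `intensity` (counts, >= 0).
#' @param window Length-2 numeric, the 2-theta fit window in degrees.
#' @param hkl Optional reflection label stored in the result.
#'
#' @return A one-row tibble: `hkl`, `position` (degrees), `fwhm_obs`
#'   (degrees), `height`, `eta` (Lorentzian fraction), `asymmetry`
#'   (right/left half-width ratio), `rss` (residual sum of squares) and
#'   `converged`.
#' @export
#' @examples
#' tt <- seq(24, 28, by = 0.01)
#' y <- 100 * exp(-log(2) * ((tt - 25.9) / 0.2)^2) + 5
#' fit_peak(data.frame(two_theta = tt, intensity = y), c(24.5, 27.5), "002")
fit_peak <- function(pattern, window, hkl = NA_character_) {
  stopifnot(all(c("two_theta", "intensity") %in% names(pattern)))
  sel <- pattern$two_theta >= window[1] & pattern$two_theta <= window[2]
  if (sum(sel) < 10) {
    abort("Fit window contains fewer than 10 points.", class = "rib_fit_error")
  }
  x <- pattern$two_theta[sel]
  y <- pattern$intensity[sel]

  # Starting values from the data.
  edge <- c(head(y, 5), tail(y, 5))
  b0 <- mean(edge)
  imax <- which.max(y)
  x0 <- x[imax]
  h0 <- max(y) - b0
  half <- y - b0 >= h0 / 2
  w0 <- max(diff(range(x[half])), 4 * mean(diff(x))) / 2

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * spv_profile(x, x0, wl, wr, eta) + c0 + c1 * (x - mean(x)),
      data = dat,
      start = list(A = h0, x0 = x0, wl = w0, wr = w0, eta = 0.5,
                   c0 = b0, c1 = 0),
      lower = c(A = 0, x0 = window[1], wl = 1e-4, wr = 1e-4, eta = 0,
                c0 = -Inf, c1 = -Inf),
      upper = c(A = Inf, x0 = window[2], wl = diff(window), wr = diff(window),
                eta = 1, c0 = Inf, c1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("Peak fit failed in window [", window[1], ", ", window[2],
                   "]: ", conditionMessage(e)),
            class = "rib_fit_error")
    }
  )
  cf <- coef(fit)
  fwhm <- unname(cf["wl"] + cf["wr"])
  if (fwhm >= 0.9 * diff(window)) {
    abort("Fitted FWHM hit the window bounds; widen the window or check the data.",
          class = "rib_fit_error")
  }
  tibble::tibble(
    hkl = hkl,
    position = unname(cf["x0"]),
    fwhm_obs = fwhm,
    height = unname(cf["A"]),
    eta = unname(cf["eta"]),
    asymmetry = unname(cf["wr"] / cf["wl"]),
    rss = sum(residuals(fit)^2),
    converged = fit$convInfo$isConv
  )
}

#' Remove instrument broadening from an observed peak width
#'
#' The instrument contribution at the peak's Bragg angle is evaluated from
#' the Caglioti polynomial \eqn{FWHM^2 = U\tan^2\theta + V\tan\theta + W}
#' (calibrated on a silicon standard) and removed. The default removal is
#' Gaussian quadrature subtraction
#' \eqn{\beta_s = \sqrt{\beta_{obs}^2 - \beta_{inst}^2}}; a Lorentzian linear
#' subtraction is available via `method`.
#'
#' @param fwhm_obs Observed FWHM in degrees 2-theta.
#' @param theta Bragg angle theta in degrees (half the peak position).
#' @param caglioti Named numeric `(U, V, W)` in degrees^2.
#' @param method `"quadrature"` (default) or `"linear"`.
#'
#' @return Sample broadening in **radians**, ready for [scherrer_cl()].
#' @export
correct_instrument <- function(fwhm_obs, theta,
                               caglioti = rib_config()$xrd$caglioti,
                               method = c("quadrature", "linear")) {
  method <- match.arg(method)
  t <- tan(deg2rad(theta))
  inst2 <- caglioti[["U"]] * t^2 + caglioti[["V"]] * t + caglioti[["W"]]
  if (any(inst2 < 0)) {
    abort("Caglioti polynomial is negative at this angle; check (U, V, W).",
          class = "rib_fit_error")
  }
  beta_inst <- sqrt(inst2)
  if (any(fwhm_obs <= beta_inst)) {
    abort("Observed width does not exceed the instrument width (non-physical).",
          class = "rib_fit_error")
  }
  beta_deg <- switch(method,
    quadrature = sqrt(fwhm_obs^2 - inst2),
    linear = fwhm_obs - beta_inst
  )
  deg2rad(beta_deg)
}

#' Scherrer coherence length
#'
#' \eqn{CL = K\lambda / (\beta \cos\theta)} with the sample broadening
#' \eqn{\beta} in radians.
#'
#' @param beta_sample Sample broadening (radians).
#' @param theta Bragg angle theta in **radians**.
#' @param k Scherrer constant (default 0.9).
#' @param lam Wavelength in nm (default Cu K-alpha, 0.15406 nm).
#'
#' @return Coherence length in nm.
#' @export
#' @examples
#' scherrer_cl(0.009, deg2rad(12.9))
scherrer_cl <- function(beta_sample, theta, k = 0.9, lam = 0.15406) {
  stopifnot(all(beta_sample > 0), all(theta > 0), all(theta < pi / 2))
  k * lam / (beta_sample * cos(theta))
}

#' Williamson-Hall size/strain separation
#'
#' Fits \eqn{\beta\cos\theta = 4\varepsilon\sin\theta + K\lambda/L} to the
#' order-pair of a common crystallographic direction (here 002 and 004 for
#' the c-axis). Two points give the exact line; more are fitted by least
#' squares.
#'
#' @param beta_sample Sample broadenings (radians), one per reflection.
#' @param theta Bragg angles (radians).
#' @param k,lam Scherrer constant and wavelength (nm).
#'
#' @return A list with `size_nm` (L), `strain` (epsilon), `slope`,
#'   `intercept`.
#' @export
williamson_hall <- function(beta_sample, theta, k = 0.9, lam = 0.15406) {
  stopifnot(length(beta_sample) == length(theta), length(theta) >= 2)
  if (diff(range(sin(theta))) < 1e-8) {
    abort("Degenerate Bragg angles; the Williamson-Hall system is singular.",
          class = "rib_fit_error")
  }
  y <- beta_sample * cos(theta)
  x <- 4 * sin(theta)
  fit <- lm(y ~ x)
  intercept <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  if (intercept <= 0) {
    abort("Non-positive Williamson-Hall intercept; crystallite size undefined.",
          class = "rib_fit_error")
  }
  list(size_nm = k * lam / intercept, strain = slope,
       slope = slope, intercept = intercept)
}

#' Lattice parameters from fitted peak positions
#'
#' Converts fitted 2-theta maxima to d-spacings via Bragg's law
#' (\eqn{\lambda = 2d\sin\theta}) and inverts the hexagonal relation
#' \deqn{1/d^2 = (4/3)(h^2 + hk + k^2)/a^2 + l^2/c^2.}
#' The c-axis comes from 002 (`c = 2 d_002`) cross-checked against 004
#' (`c = 4 d_004`) and reported as their mean; the a-axis from 030
#' (`a = d_030 \sqrt{12}`).
#'
#' @param pos_002,pos_004,pos_030 Fitted peak positions in degrees 2-theta.
#' @param lam Wavelength in Angstrom (default Cu K-alpha 1.5406).
#' @param tol Relative disagreement between the two c estimates above which a
#'   consistency warning is raised (default 0.5 %).
#'
#' @return A list with `a_axis`, `c_axis` (Angstrom) and the individual
#'   estimates `c_from_002`, `c_from_004`.
#' @export
lattice_parameters <- function(pos_002, pos_004, pos_030,
                               lam = 1.5406, tol = 0.005) {
  d <- function(two_theta) lam / (2 * sin(deg2rad(two_theta / 2)))
  c1 <- 2 * d(pos_002)
  c2 <- 4 * d(pos_004)
  if (abs(c1 - c2) / c1 > tol) {
    warn(sprintf(
      "c-axis estimates from 002 (%.4f) and 004 (%.4f) disagree by more than %.1f%%",
      c1, c2, 100 * tol
    ))
  }
  a <- d(pos_030) * sqrt(12)
  list(a_axis = a, c_axis = (c1 + c2) / 2, c_from_002 = c1, c_from_004 = c2)
}

# Joint fit of several neighbouring pseudo-Voigt peaks (each symmetric)
# plus a linear background. Broad biogenic 002/210/030 maxima overlap
# through their Lorentzian tails in the wide scan, so fitting them together
# removes the bias a single-peak window fit would inherit from its
# neighbours.
fit_peaks_multi <- function(pattern, window, guesses, hkl) {
  sel <- pattern$two_theta >= window[1] & pattern$two_theta <= window[2]
  x <- pattern$two_theta[sel]
  y <- pattern$intensity[sel]
  b0 <- mean(c(head(y, 5), tail(y, 5)))
  k <- length(guesses)
  h0 <- vapply(guesses, function(g) max(y[abs(x - g) < 1]) - b0, numeric(1))

  model <- function(par) {
    yy <- par[[4 * k + 1]] + par[[4 * k + 2]] * (x - mean(x))
    for (j in seq_len(k)) {
      A <- par[[4 * j - 3]]; x0 <- par[[4 * j - 2]]
      w <- par[[4 * j - 1]]; e <- par[[4 * j]]
      yy <- yy + A * spv_profile(x, x0, w, w, e)
    }
    yy
  }
  # data-driven half-width starts: half-height crossing around each maximum
  w0 <- vapply(seq_len(k), function(j) {
    near <- abs(x - guesses[j]) < 1.5
    yj <- y[near] - b0
    xh <- x[near][yj >= max(yj) / 2]
    max(min(diff(range(xh)) / 2, 1.5), 0.05)
  }, numeric(1))

  lower <- numeric(4 * k + 2)
  upper <- numeric(4 * k + 2)
  for (j in seq_len(k)) {
    lower[4 * j - 3:0] <- c(0, guesses[j] - 1, 1e-3, 0)
    upper[4 * j - 3:0] <- c(Inf, guesses[j] + 1, 3, 1)
  }
  lower[4 * k + 1:2] <- c(-Inf, -Inf)
  upper[4 * k + 1:2] <- c(Inf, Inf)

  # restart over mixing values; keep the lowest-residual solution
  fit <- NULL
  for (eta0 in c(0.5, 0.2, 0.8)) {
    start <- numeric(4 * k + 2)
    for (j in seq_len(k)) start[4 * j - 3:0] <- c(h0[j], guesses[j], w0[j], eta0)
    start[4 * k + 1:2] <- c(b0, 0)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = function(par) y - model(par),
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL
    )
    if (!is.null(cand) && cand$info >= 1 && cand$info <= 4 &&
        (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    abort("Multi-peak fit did not converge.", class = "rib_fit_error")
  }
  cf <- fit$par
  idx <- seq_len(k)
  tibble::tibble(
    hkl = hkl,
    position = cf[4 * idx - 2],
    fwhm_obs = 2 * cf[4 * idx - 1],
    height = cf[4 * idx - 3],
    eta = cf[4 * idx],
    asymmetry = rep(1, k),
    rss = sum(fit$fvec^2),
    converged = TRUE
  )
}

#' Full XRD analysis of one specimen's diffraction scans
#'
#' Fits the 002 and 004 maxima on their dedicated stepped scans, fits the
#' overlapping 210 and 030 maxima jointly on the wide scan (two pseudo-Voigt
#' peaks over a combined window, since their Lorentzian tails interpenetrate
#' at biogenic peak widths), corrects each width for instrument broadening,
#' and derives Scherrer coherence lengths, Williamson-Hall size/strain along
#' c, and lattice parameters.
#'
#' @param wide,stepped_002,stepped_004 Data frames with `two_theta`,
#'   `intensity` for the 10--80, 23--27 and 50--55 degree scans.
#' @param config A [rib_config()].
#'
#' @return A one-row tibble with `CL002`, `CL004`, `CL030`, `CL210` (nm),
#'   `a_axis`, `c_axis` (Angstrom), `Size` (nm) and `Strain`.
#' @export
analyze_xrd <- function(wide, stepped_002, stepped_004, config = rib_config()) {
  xc <- config$xrd
  # joint wide-scan fit of the interpenetrating 002/210/030 region; the
  # 210 and 030 widths come from here, 002 and 004 from the stepped scans
  guess_002 <- 2 * rad2deg(bragg_theta(xc$c_ref / 2, xc$wavelength_nm * 10))
  wide_fit <- fit_peaks_multi(
    wide, c(xc$windows[["002"]][1], xc$windows[["030"]][2]),
    c(guess_002, mean(xc$windows[["210"]]), mean(xc$windows[["030"]])),
    c("002w", "210", "030")
  )
  fits <- dplyr::bind_rows(
    fit_peak(stepped_002, xc$windows[["002"]], "002"),
    wide_fit[wide_fit$hkl != "002w", ],
    fit_peak(stepped_004, xc$windows[["004"]], "004")
  )
  theta_deg <- fits$position / 2
  beta <- correct_instrument(fits$fwhm_obs, theta_deg, xc$caglioti)
  cl <- scherrer_cl(beta, deg2rad(theta_deg), xc$scherrer_k, xc$wavelength_nm)
  names(cl) <- fits$hkl

  wh <- williamson_hall(beta[fits$hkl %in% c("002", "004")],
                        deg2rad(theta_deg[fits$hkl %in% c("002", "004")]),
                        xc$scherrer_k, xc$wavelength_nm)
  lat <- lattice_parameters(
    pos_002 = fits$position[fits$hkl == "002"],
    pos_004 = fits$position[fits$hkl == "004"],
    pos_030 = fits$position[fits$hkl == "030"],
    lam = xc$wavelength_nm * 10
  )
  tibble::tibble(
    CL002 = cl[["002"]], CL004 = cl[["004"]],
    CL030 = cl[["030"]], CL210 = cl[["210"]],
    a_axis = lat$a_axis, c_axis = lat$c_axis,
    Size = wh$size_nm, Strain = wh$strain
  )
}
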