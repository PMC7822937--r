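#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a stepwise age-model fit
#'
#' One row per model term with the coefficient, standard error, t statistic,
#' p-value and variance inflation factor.
#'
#' @param x A `rib_fit` from [fit_stepwise()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rib_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
  vif <- c("(Intercept)" = NA_real_, x$diagnostics$vif)
  out$vif <- unname(vif[out$term])
  out
}

#' Glance at a stepwise age-model fit
#'
#' One-row model summary: R-squared, adjusted R-squared, residual standard
#' error, F statistic, AIC/BIC, and the headline diagnostics
#' (Breusch-Pagan, residual Shapiro-Wilk, Durbin-Watson).
#'
#' @param x A `rib_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.rib_fit <- function(x, ...) {
  s <- summary(x$model)
  d <- x$diagnostics
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(s$fstatistic[1]),
    df = unname(s$fstatistic[2]),
    df.residual = x$model$df.residual,
    AIC = AIC(x$model), BIC = BIC(x$model),
    bp.p = d$breusch_pagan$p,
    shapiro.p = d$shapiro$p,
    dw.statistic = d$durbin_watson$statistic,
    dw.p = d$durbin_watson$p,
    max.vif = if (length(d$vif)) max(d$vif) else NA_real_,
    condition.index = d$condition_index
  )
}

#' Augment a parameter table with fitted ages and influence measures
#'
#' @param x A `rib_fit`.
#' @param data The table the model was fitted on (defaults to the model
#'   frame).
#' @param ... Unused.
#' @return `data` with `.fitted`, `.resid`, `.cooksd` columns.
#' @export
augment.rib_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) data <- tibble::as_tibble(x$model$model)
  mutate(data,
         .fitted = fitted(x$model),
         .resid = residuals(x$model),
         .cooksd = cooks.distance(x$model))
}

#' Diagnostic plot of a stepwise age model
#'
#' Predicted against chronological age with the identity line, the analogue
#' of the usual regression accuracy panel.
#'
#' @param object A `rib_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rib_fit <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = d,
      ggplot2::aes(x = .data$age, y = .data$.fitted), alpha = 0.7
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Chronological age (yr)", y = "Predicted age (yr)",
                  title = sprintf("age ~ %s",
                                  paste(object$predictors, collapse = " + ")))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the age-correlation screen
#'
#' Bar chart of the Pearson correlation of each parameter with age, flagged
#' at the screening significance level.
#'
#' @param screen A tibble from [screen_parameters()].
#' @return A ggplot object.
#' @export
plot_screen <- function(screen) {
  d <- arrange(screen, .data$pearson_r)
  d$parameter <- factor(d$parameter, levels = d$parameter)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$pearson_r,
                                  fill = .data$age_correlated)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r with age", fill = "p <= 0.05")
}

#' Plot cross-validated against fitted accuracy
#'
#' @param report A `rib_report` from [validate_models()].
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  d <- tidyr::pivot_longer(report$summary,
                           c("r_squared", "cv_r2"),
                           names_to = "kind", values_to = "r2")
  d$kind <- ifelse(d$kind == "r_squared", "fit", "LOO CV")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$candidate_set, y = .data$r2,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Candidate pool", y = expression(R^2), fill = NULL)
}
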