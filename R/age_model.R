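#' Screen parameters against age and sex
#'
#' For every parameter column: Shapiro-Wilk normality test, one-way ANOVA of
#' mean differences by sex, and Pearson correlation with age, each flagged
#' at `alpha`.
#'
#' @param table Parameter table with `age`, `sex` and numeric parameter
#'   columns.
#' @param parameters Columns to screen (default: all 33 present).
#' @param alpha Significance level for the flags.
#'
#' @return A tibble with one row per parameter: `parameter`, `shapiro_w`,
#'   `shapiro_p`, `anova_f`, `anova_p`, `pearson_r`, `pearson_p`,
#'   `normal`, `sex_difference`, `age_correlated`.
#' @export
screen_parameters <- function(table,
                              parameters = intersect(rib_parameter_names(),
                                                     names(table)),
                              alpha = 0.05) {
  stopifnot("age" %in% names(table))
  purrr::map_dfr(parameters, function(p) {
    x <- table[[p]]
    if (sd(x) == 0) {
      return(tibble::tibble(parameter = p, shapiro_w = NA_real_,
                            shapiro_p = NA_real_, anova_f = NA_real_,
                            anova_p = NA_real_, pearson_r = NA_real_,
                            pearson_p = NA_real_, normal = NA,
                            sex_difference = NA, age_correlated = NA))
    }
    # Shapiro-Wilk is defined for 3..5000 observations; larger tables are
    # screened on an evenly spaced subsample.
    xs <- if (length(x) > 5000) x[round(seq(1, length(x), length.out = 5000))]
          else x
    sw <- shapiro.test(xs)
    if ("sex" %in% names(table) && length(unique(table$sex)) > 1 &&
        min(table(table$sex)) >= 3) {
      an <- summary(aov(x ~ factor(table$sex)))[[1]]
      f <- an$`F value`[1]; fp <- an$`Pr(>F)`[1]
    } else {
      f <- NA_real_; fp <- NA_real_
    }
    ct <- cor.test(x, table$age)
    tibble::tibble(
      parameter = p,
      shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
      anova_f = f, anova_p = fp,
      pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
      normal = sw$p.value > alpha,
      sex_difference = !is.na(fp) & fp <= alpha,
      age_correlated = ct$p.value <= alpha
    )
  })
}

#' Stepwise-AIC age regression
#'
#' Builds an ordinary-least-squares age model by bidirectional stepwise
#' search over the candidate pool, entering and removing predictors to
#' minimise AIC (best improvement first, ties broken by candidate order),
#' then populates the full diagnostic block.
#'
#' @param table Parameter table with an `age` column.
#' @param candidates Candidate predictor names (default: the full pool
#'   present in the table).
#' @param direction Stepwise direction (default `"both"` from the empty
#'   model).
#' @param seed Seed for the Durbin-Watson permutation p-value.
#'
#' @return An object of class `rib_fit`: `model` (the `lm`), `predictors`,
#'   `diagnostics` (see [model_diagnostics()]), `candidates`, `direction`.
#' @export
fit_stepwise <- function(table,
                         candidates = intersect(rib_candidate_set("all"),
                                                names(table)),
                         direction = c("both", "forward", "backward"),
                         seed = 1L) {
  direction <- match.arg(direction)
  stopifnot("age" %in% names(table))
  missing_cols <- setdiff(candidates, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("Candidates absent from the table: ",
                 paste(missing_cols, collapse = ", ")),
          class = "rib_config_error")
  }
  dat <- table[, c("age", candidates)]
  if (any(!complete.cases(dat))) {
    abort("Missing values in the candidate columns; no imputation is done.",
          class = "rib_config_error")
  }

  full_formula <- as.formula(paste("age ~", paste(candidates, collapse = " + ")))
  start <- if (direction == "backward") {
    lm(full_formula, data = dat)
  } else {
    lm(age ~ 1, data = dat)
  }
  stepped <- step(start, scope = list(lower = age ~ 1, upper = full_formula),
                  direction = direction, trace = 0)
  predictors <- setdiff(names(coef(stepped)), "(Intercept)")
  # refit on a clean environment for predictable downstream use
  model <- if (length(predictors) == 0) {
    lm(age ~ 1, data = dat)
  } else {
    lm(as.formula(paste("age ~", paste(predictors, collapse = " + "))),
       data = dat)
  }
  structure(list(model = model, predictors = predictors,
                 diagnostics = model_diagnostics(model, seed = seed),
                 candidates = candidates, direction = direction),
            class = "rib_fit")
}

#' @export
print.rib_fit <- function(x, ...) {
  cat("Stepwise age model:", length(x$predictors), "predictors of",
      length(x$candidates), "candidates\n")
  cat("  age ~", paste(x$predictors, collapse = " + "), "\n")
  g <- glance(x)
  cat(sprintf("  R2 = %.3f, adj. R2 = %.3f, RSE = %.3f yr (df = %d), AIC = %.1f\n",
              g$r.squared, g$adj.r.squared, g$sigma, g$df.residual, g$AIC))
  invisible(x)
}

# Variance inflation factors from auxiliary regressions: VIF_j = 1/(1-R2_j)
# where R2_j regresses predictor j on the other predictors.
vif_auxiliary <- function(model, cap = 1e6) {
  X <- stats::model.matrix(model)[, -1, drop = FALSE]
  if (ncol(X) < 2) {
    return(setNames(rep(1, ncol(X)), colnames(X)))
  }
  vif <- purrr::map_dbl(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1 / cap) cap else 1 / (1 - r2)
  })
  setNames(vif, colnames(X))
}

#' Regression diagnostics block
#'
#' Populates every diagnostic the modelling workflow reports: per-predictor
#' variance inflation factors (from auxiliary regressions, capped at a
#' sentinel of 1e6 with a collinearity flag), the condition index of the
#' unit-length-scaled design matrix, the Breusch-Pagan heteroscedasticity
#' test (with optional Bonferroni adjustment across models), Shapiro-Wilk on
#' the residuals, the Durbin-Watson statistic with a seeded permutation
#' p-value, and Cook's distances with a 4/n flag threshold.
#'
#' @param model A fitted `lm`.
#' @param n_comparisons Bonferroni divisor for the Breusch-Pagan p-value.
#' @param n_permutations Permutations for the Durbin-Watson p-value.
#' @param seed Seed for the permutations.
#'
#' @return A list with elements `vif`, `collinearity_flag`,
#'   `condition_index`, `breusch_pagan` (statistic, p, p_adjusted),
#'   `shapiro` (W, p), `durbin_watson` (statistic, p), `cooks` (distances,
#'   threshold, flagged).
#' @export
model_diagnostics <- function(model, n_comparisons = 1,
                              n_permutations = 2000, seed = 1L) {
  e <- residuals(model)
  n <- length(e)

  vif <- vif_auxiliary(model)
  X <- stats::model.matrix(model)
  Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  sv <- svd(Xs, nu = 0, nv = 0)$d
  ci <- max(sv) / min(sv)

  bp <- if (length(coef(model)) > 1) {
    b <- lmtest::bptest(model)
    list(statistic = unname(b$statistic), p = b$p.value,
         p_adjusted = min(1, b$p.value * n_comparisons))
  } else {
    list(statistic = NA_real_, p = NA_real_, p_adjusted = NA_real_)
  }

  swt <- if (n >= 3 && n <= 5000) shapiro.test(e) else NULL

  dw_stat <- function(r) sum(diff(r)^2) / sum(r^2)
  dw <- dw_stat(e)
  dw_p <- withr::with_seed(as.integer(seed), {
    perm <- replicate(n_permutations, dw_stat(e[sample.int(n)]))
    lo <- mean(perm <= dw)
    hi <- mean(perm >= dw)
    min(1, 2 * min(lo, hi))
  })

  cd <- cooks.distance(model)
  thr <- 4 / n

  list(
    vif = vif,
    collinearity_flag = any(vif >= 1e6),
    condition_index = ci,
    breusch_pagan = bp,
    shapiro = if (is.null(swt)) list(W = NA_real_, p = NA_real_)
              else list(W = unname(swt$statistic), p = swt$p.value),
    durbin_watson = list(statistic = dw, p = dw_p),
    cooks = list(distances = cd, threshold = thr,
                 flagged = which(cd > thr))
  )
}

#' Leave-one-out cross-validation of a fixed predictor set
#'
#' Refits the OLS age model n times, each time holding one specimen out and
#' predicting its age, then summarises the held-out predictions:
#' `cv_r2 = 1 - SS_pred/SS_tot`, `cv_rmse` and `cv_mae` in years.
#'
#' @param table Parameter table with `age`.
#' @param predictors Predictor column names (fixed; no reselection inside
#'   the folds).
#'
#' @return A one-row tibble `cv_r2`, `cv_rmse`, `cv_mae`, `n`.
#' @export
loo_cv <- function(table, predictors) {
  stopifnot("age" %in% names(table))
  n <- nrow(table)
  if (n < length(predictors) + 3) {
    abort("Too few rows for leave-one-out with this predictor count.",
          class = "rib_config_error")
  }
  dat <- as.data.frame(table[, c("age", predictors)])
  f <- if (length(predictors) == 0) age ~ 1 else
    as.formula(paste("age ~", paste(predictors, collapse = " + ")))
  pred <- purrr::map_dbl(seq_len(n), function(i) {
    fit <- lm(f, data = dat[-i, , drop = FALSE])
    unname(predict(fit, newdata = dat[i, , drop = FALSE]))
  })
  err <- dat$age - pred
  tibble::tibble(
    cv_r2 = 1 - sum(err^2) / sum((dat$age - mean(dat$age))^2),
    cv_rmse = sqrt(mean(err^2)),
    cv_mae = mean(abs(err)),
    n = n
  )
}

#' Predict age with a published fixed equation
#'
#' Evaluates `constant + sum(coefficient * value)` for each specimen row
#' using one of the published coefficient sets (see
#' [published_equations()]) or any tibble in the same `equation`/`term`/
#' `estimate` layout.
#'
#' @param table Parameter table (rows = specimens).
#' @param equation `"E1"`, `"E2"` or `"E3"`, or a coefficient tibble.
#' @param warn_range Warn when a prediction falls outside `[0, 120]` years.
#'
#' @return The input with an added `age_predicted` column.
#' @export
#' @examples
#' tab <- draw_parameters(draw_population(20, seed = 3), seed = 3)
#' predict_age(tab, "E3")
predict_age <- function(table, equation = "E1", warn_range = TRUE) {
  eq <- if (is.character(equation)) {
    filter(published_equations(), .data$equation == !!equation)
  } else {
    equation
  }
  if (nrow(eq) == 0) {
    abort("Unknown equation.", class = "rib_config_error")
  }
  terms <- setdiff(eq$term, "(Intercept)")
  missing_terms <- terms[!terms %in% names(table)]
  if (length(missing_terms) > 0) {
    abort(paste0("Missing predictors: ", paste(missing_terms, collapse = ", ")),
          class = "rib_config_error")
  }
  bad <- terms[purrr::map_lgl(terms, ~ any(!is.finite(table[[.x]])))]
  if (length(bad) > 0) {
    abort(paste0("Non-finite predictor values in: ", paste(bad, collapse = ", ")),
          class = "rib_config_error")
  }
  const <- eq$estimate[eq$term == "(Intercept)"]
  if (length(const) == 0) const <- 0
  coefs <- setNames(eq$estimate[eq$term != "(Intercept)"],
                    eq$term[eq$term != "(Intercept)"])
  pred <- const + as.matrix(table[, names(coefs)]) %*% coefs
  pred <- as.numeric(pred)
  if (warn_range && any(pred < 0 | pred > 120)) {
    warn(sprintf("%d prediction(s) outside [0, 120] years.",
                 sum(pred < 0 | pred > 120)))
  }
  mutate(table, age_predicted = pred)
}
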