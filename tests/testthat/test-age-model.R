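test_that("screening matches hand-computed statistics on a toy table", {
  tab <- tibble::tibble(
    id = letters[1:5],
    sex = c("M", "M", "F", "F", "M"),
    age = c(20, 35, 40, 55, 70),
    x = c(3.1, 4.0, 4.4, 5.9, 7.2)
  )
  sc <- screen_parameters(tab, parameters = "x")
  r_hand <- sum((tab$x - mean(tab$x)) * (tab$age - mean(tab$age))) /
    sqrt(sum((tab$x - mean(tab$x))^2) * sum((tab$age - mean(tab$age))^2))
  expect_equal(sc$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(sc$shapiro_w, unname(shapiro.test(tab$x)$statistic))
})

test_that("screening recovers a strong generated age correlation", {
  pop <- draw_population(1e4, seed = 2)
  tab <- draw_parameters(pop, tibble::tibble(
    name = "po", mean = 10, sd = 2, age_correlation = 0.83
  ), seed = 2)
  sc <- screen_parameters(tab, parameters = "po")
  expect_lt(abs(sc$pearson_r - 0.83), 0.02)
  expect_true(sc$age_correlated)
})

test_that("a sex-invariant column shows a null ANOVA", {
  tab <- toy_table(60, seed = 17)
  withr::with_seed(1, tab$flat <- rnorm(60))
  tab$flat <- ave(tab$flat, tab$sex, FUN = function(v) v - mean(v) + 1.1)
  sc <- screen_parameters(tab, parameters = "flat")
  expect_gt(sc$anova_p, 0.9)
})

test_that("constant columns are reported as undefined, not dropped", {
  tab <- toy_table(20)
  tab$const <- 5
  sc <- screen_parameters(tab, parameters = "const")
  expect_true(is.na(sc$pearson_r))
})

test_that("stepwise selection matches the exhaustive minimum-AIC subset", {
  withr::with_seed(42, {
    n <- 60
    age <- runif(n, 15, 80)
    tab <- tibble::tibble(
      age = age,
      a = age + rnorm(n, 0, 6),
      b = 0.5 * age + rnorm(n, 0, 8),
      c = rnorm(n),
      d = rnorm(n),
      e = rnorm(n),
      f = age^0 * rnorm(n)
    )
  })
  cands <- c("a", "b", "c", "d", "e", "f")
  fit <- fit_stepwise(tab, candidates = cands)

  # independent oracle: all 2^6 subsets, same AIC definition
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  aics <- apply(subsets, 1, function(keep) {
    f <- if (any(keep)) paste("age ~", paste(cands[keep], collapse = "+"))
         else "age ~ 1"
    AIC(lm(as.formula(f), data = tab))
  })
  best <- cands[unlist(subsets[which.min(aics), ])]
  expect_setequal(fit$predictors, best)
})

test_that("a dominant predictor is selected and noise excluded", {
  tab <- signal_noise_table()
  fit <- fit_stepwise(tab, candidates = c("strong", paste0("x", 1:5)))
  expect_true("strong" %in% fit$predictors)
  expect_lt(length(fit$predictors), 4)
  # final AIC no worse than empty and full models
  empty <- AIC(lm(age ~ 1, data = tab))
  full <- AIC(lm(age ~ ., data = dplyr::select(tab, age, strong,
                                               dplyr::starts_with("x"))))
  expect_lte(AIC(fit$model), empty)
  expect_lte(AIC(fit$model), full)
})

test_that("missing values fail fast", {
  tab <- toy_table(30)
  tab$PoAr_pct[3] <- NA
  expect_error(fit_stepwise(tab, candidates = c("PoAr_pct", "It_HV")),
               class = "rib_config_error")
})

test_that("auxiliary-regression VIFs agree with the reference implementation", {
  skip_if_not_installed("car")
  tab <- toy_table(80, seed = 23)
  m <- lm(age ~ PoAr_pct + It_HV + On_etaIT + Ash_pct, data = tab)
  ours <- ribchron:::vif_auxiliary(m)
  theirs <- car::vif(m)
  expect_equal(ours, theirs[names(ours)], tolerance = 1e-8)
})

test_that("perfect collinearity is reported as a capped sentinel", {
  tab <- toy_table(40)
  # an exactly duplicated predictor is aliased by lm itself, so probe the
  # numerically collinear case the sentinel is designed for
  tab$near <- tab$PoAr_pct + rnorm(40, 0, 1e-9)
  m2 <- lm(age ~ PoAr_pct + near + It_HV, data = tab)
  d <- model_diagnostics(m2)
  expect_true(d$collinearity_flag)
  expect_gte(max(d$vif), 1e6)
})

test_that("Durbin-Watson sits near 2 for independent residuals", {
  withr::with_seed(11, e <- rnorm(1e4))
  dw <- sum(diff(e)^2) / sum(e^2)
  expect_lt(abs(dw - 2), 0.06)
  # the package statistic agrees with the reference implementation
  tab <- toy_table(80, seed = 5)
  m <- lm(age ~ PoAr_pct + It_HV, data = tab)
  d <- model_diagnostics(m, seed = 3)
  expect_equal(d$durbin_watson$statistic,
               unname(lmtest::dwtest(m)$statistic), tolerance = 1e-9)
  expect_gt(d$durbin_watson$p, 0)
})

test_that("diagnostics block is fully populated", {
  fit <- fit_stepwise(toy_table(60, seed = 9),
                      candidates = c("PoAr_pct", "It_HV", "On_etaIT"))
  d <- fit$diagnostics
  expect_true(all(d$vif >= 1))
  expect_gt(d$condition_index, 1)
  expect_true(is.numeric(d$breusch_pagan$p))
  expect_true(is.numeric(d$shapiro$p))
  expect_length(d$cooks$distances, 60)
  expect_equal(d$cooks$threshold, 4 / 60)
})

test_that("LOO metrics equal an explicit refit loop on a toy table", {
  tab <- toy_table(12, seed = 3)
  preds <- c("PoAr_pct", "It_HV")
  cv <- loo_cv(tab, preds)
  # hand-rolled loop
  p <- vapply(1:12, function(i) {
    m <- lm(age ~ PoAr_pct + It_HV, data = tab[-i, ])
    predict(m, newdata = tab[i, ])
  }, numeric(1))
  err <- tab$age - p
  expect_equal(cv$cv_rmse, sqrt(mean(err^2)), tolerance = 1e-12)
  expect_equal(cv$cv_mae, mean(abs(err)), tolerance = 1e-12)
  expect_equal(cv$cv_r2, 1 - sum(err^2) / sum((tab$age - mean(tab$age))^2),
               tolerance = 1e-12)
  expect_gte(cv$cv_rmse, cv$cv_mae)
})

test_that("LOO is exact for noise-free linear data and row-order invariant", {
  tab <- tibble::tibble(age = seq(20, 70, length.out = 15))
  tab$x <- 2 * tab$age + 5
  cv <- loo_cv(tab, "x")
  expect_equal(cv$cv_r2, 1, tolerance = 1e-9)
  expect_equal(cv$cv_mae, 0, tolerance = 1e-9)

  tab2 <- toy_table(25, seed = 8)
  cv1 <- loo_cv(tab2, c("PoAr_pct", "It_HV"))
  cv2 <- loo_cv(tab2[sample(25), ], c("PoAr_pct", "It_HV"))
  expect_equal(cv1[, c("cv_r2", "cv_rmse", "cv_mae")],
               cv2[, c("cv_r2", "cv_rmse", "cv_mae")], tolerance = 1e-12)
})

test_that("published equations evaluate as a dot product", {
  eq <- published_equations()
  expect_equal(sum(eq$equation == "E1" & eq$term != "(Intercept)"), 10)
  expect_equal(sum(eq$equation == "E2" & eq$term != "(Intercept)"), 6)
  expect_equal(sum(eq$equation == "E3" & eq$term != "(Intercept)"), 5)

  tab <- toy_table(10, seed = 44)
  # all predictors zero: prediction equals the published constant
  zero <- tab
  for (p in setdiff(eq$term, "(Intercept)")) zero[[p]] <- 0
  pred0 <- suppressWarnings(predict_age(zero, "E1"))
  expect_equal(unique(pred0$age_predicted), -759.525)

  # independent dot-product oracle on the real table
  e1 <- dplyr::filter(eq, equation == "E1")
  co <- setNames(e1$estimate, e1$term)
  manual <- co[["(Intercept)"]] +
    rowSums(sapply(setdiff(names(co), "(Intercept)"),
                   function(p) co[[p]] * tab[[p]]))
  pred <- suppressWarnings(predict_age(tab, "E1"))
  expect_equal(pred$age_predicted, unname(manual), tolerance = 1e-12)

  # unit increase in porosity moves the E1 prediction by its coefficient
  bump <- dplyr::mutate(tab, PoAr_pct = PoAr_pct + 1)
  pred_b <- suppressWarnings(predict_age(bump, "E1"))
  expect_equal(pred_b$age_predicted - pred$age_predicted, rep(6.001, 10),
               tolerance = 1e-9)

  expect_error(predict_age(dplyr::select(tab, -PoAr_pct), "E1"),
               class = "rib_config_error")
})

test_that("refitting a known linear model recovers its coefficients", {
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      x <- rnorm(80)
      age <- 40 + 5 * x + rnorm(80, 0, 4)
    })
    m <- lm(age ~ x, data = data.frame(age = age, x = x))
    se <- summary(m)$coefficients["x", "Std. Error"]
    if (abs(coef(m)[["x"]] - 5) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 90)  # ~95% nominal coverage
})

test_that("tidiers summarise the fit in broom style", {
  fit <- fit_stepwise(toy_table(50, seed = 12),
                      candidates = c("PoAr_pct", "It_HV", "CdH"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value", "vif") %in% names(td)))
  g <- glance(fit)
  expect_gte(g$r.squared, 0)
  expect_lte(g$r.squared, 1)
  expect_equal(g$df.residual + length(fit$predictors) + 1, 50)
  au <- augment(fit)
  expect_true(all(c(".fitted", ".resid", ".cooksd") %in% names(au)))
  expect_s3_class(autoplot(fit), "ggplot")
})
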