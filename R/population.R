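#' Draw a study population
#'
#' Samples specimen ages from a normal distribution truncated to
#' `[age_min, age_max]` (by rejection) and assigns sex labels. Defaults match
#' the reference cohort: 113 ribs, ages 12--84 years with mean 46.64 and SD
#' 16.33, and 77/113 males.
#'
#' @param n_specimens Number of specimens (>= 2).
#' @param age_mean,age_sd Mean and SD (years) of the untruncated normal.
#' @param age_min,age_max Truncation bounds (years), `age_min < age_max`.
#' @param sex_fraction_male Proportion of males in `[0, 1]`.
#' @param seed Integer seed; the global RNG state is left untouched.
#'
#' @return A tibble with columns `id`, `sex` (`"M"`/`"F"`), `age`.
#' @export
#' @examples
#' draw_population(n_specimens = 10, seed = 1)
draw_population <- function(n_specimens = 113,
                            age_mean = 46.64, age_sd = 16.33,
                            age_min = 12, age_max = 84,
                            sex_fraction_male = 77 / 113,
                            seed = 1L) {
  if (!is.numeric(n_specimens) || n_specimens < 2) {
    abort("`n_specimens` must be at least 2.", class = "rib_config_error")
  }
  if (age_min >= age_max) {
    abort("`age_min` must be smaller than `age_max`.", class = "rib_config_error")
  }
  if (sex_fraction_male < 0 || sex_fraction_male > 1) {
    abort("`sex_fraction_male` must lie in [0, 1].", class = "rib_config_error")
  }
  if (age_sd < 0) abort("`age_sd` must be non-negative.", class = "rib_config_error")
  n_specimens <- as.integer(n_specimens)

  withr::with_seed(as.integer(seed), {
    ages <- numeric(0)
    if (age_sd == 0) {
      if (age_mean < age_min || age_mean > age_max) {
        abort("Degenerate age distribution falls outside the bounds.",
              class = "rib_config_error")
      }
      ages <- rep(age_mean, n_specimens)
    } else {
      while (length(ages) < n_specimens) {
        draw <- rnorm(2L * n_specimens, age_mean, age_sd)
        ages <- c(ages, draw[draw >= age_min & draw <= age_max])
      }
      ages <- ages[seq_len(n_specimens)]
    }
    n_male <- round(sex_fraction_male * n_specimens)
    sex <- sample(c(rep("M", n_male), rep("F", n_specimens - n_male)))
    tibble::tibble(
      id = sprintf("S%03d", seq_len(n_specimens)),
      sex = sex,
      age = ages
    )
  })
}
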