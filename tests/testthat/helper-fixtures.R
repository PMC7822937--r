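# Shared fixtures built in code.

# A small deterministic parameter table.
toy_table <- function(n = 30, seed = 7) {
  draw_parameters(draw_population(n, seed = seed), seed = seed)
}

# A design with one strong predictor and pure-noise candidates.
signal_noise_table <- function(n = 60, seed = 99, p_noise = 5) {
  withr::with_seed(seed, {
    age <- runif(n, 15, 80)
    noise <- matrix(rnorm(n * p_noise), n)
    colnames(noise) <- paste0("x", seq_len(p_noise))
    tibble::tibble(age = age, strong = age + rnorm(n, 0, 0.5)) |>
      dplyr::bind_cols(tibble::as_tibble(noise))
  })
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(max(abs((actual - expected) / expected)), tol)
}
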