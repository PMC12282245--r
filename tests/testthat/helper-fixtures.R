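# Shared fixtures: one panel, noise-free simulation parameters, and small
# constructors used across the test files.

test_panel <- default_panel()

zero_noise <- sim_params(noise_cv = 0, size_jitter_sd = 0, scale_sd = 0)

gt <- function(a1, a2, b1 = "bN", b2 = "bN")
  list(alpha = c(a1, a2), beta = c(b1, b2))

sim_call <- function(genotype, panel = test_panel, params = zero_noise,
                     seed = 1L) {
  call_sample(simulate_peak_table(genotype, panel, params, seed = seed),
              panel)
}

# measurement object for direct classify_cnv tests
ratio_m <- function(a, y, heights = c(alpha1 = 1000, alpha2 = 1000,
                                      Y1 = 1000, Y2 = 1000)) {
  structure(list(heights = heights, a_ratio = a, y_ratio = y,
                 absent = names(heights)[heights == 0]),
            class = "thal_ratio_measurement")
}

all_unordered_pairs <- function(x) {
  out <- list()
  for (i in seq_along(x)) for (j in i:length(x))
    out[[length(out) + 1L]] <- c(x[i], x[j])
  out
}
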