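# Shared fixtures, built in code at test time.

# A small dry-season surface-water dataset with its normalization and split.
small_campaign <- function(n = 80L, seed = 7L, noise_rel_sd = 0.05) {
  ds <- make_dataset("dry", "surface", n = n, seed = seed,
                     noise_rel_sd = noise_rel_sd)
  split <- split_dataset(n, seed = 3L)
  norm <- fit_normalizer(cbind(ds$features, ds$targets))
  list(ds = ds, split = split, norm = norm,
       Xn = normalize(ds$features, norm))
}

random_params <- function(hn, seed = 1L) {
  withr::with_seed(seed, nn_params(
    matrix(stats::rnorm(hn * 4), hn, 4),
    stats::rnorm(hn), stats::rnorm(hn), stats::rnorm(1)
  ))
}
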