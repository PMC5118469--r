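# Shared fixtures: the two-dataset latent-variable benchmark, split in halves.
benchmark_halves <- function(seed, n = 1000) {
  sim <- simulate_latent_data(synthetic_spec(n_samples = n, seed = seed))
  sp <- lapply(sim$datasets, split_halves)
  list(train = lapply(sp, `[[`, "train"),
       test = lapply(sp, `[[`, "test"),
       latents = sim$latents)
}

# residuals of y regressed on x (exactly orthogonal to x in-sample)
resid_on <- function(y, x) stats::residuals(stats::lm(y ~ x))

random_blocks <- function(seed, n, ps) {
  set.seed(seed)
  lapply(ps, function(p) matrix(rnorm(n * p), n, p))
}
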