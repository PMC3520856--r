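# shared test helpers

rel_err <- function(x, ref) {
  i <- ref != 0
  out <- abs(x - ref)
  out[i] <- out[i] / abs(ref[i])
  out
}

# random weight set spanning `orders` orders of magnitude
random_weights <- function(m, seed, orders = 12) {
  withr::with_seed(seed, 10^runif(m, -orders / 2, orders / 2))
}

random_spins <- function(n, seed) {
  withr::with_seed(seed, sample(c(-1, 1), n, replace = TRUE))
}

cond_at <- function(t_star) thermo_conditions(t_star)
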