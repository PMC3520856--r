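# the direct interaction algorithm: weight construction, averaging,
# exactness guarantees, and consistency properties

test_that("boltzmann_weights folds direct interactions per the selected particle", {
  g <- matrix(0, 3, 3)
  g[1, 2] <- g[2, 1] <- 0.8
  sys <- two_state_system(c(0, 0, 0), g)
  cond <- cond_at(1)
  expect_equal(boltzmann_weights(sys, 1, cond, include_direct = FALSE),
               c(1, 1))
  expect_equal(boltzmann_weights(sys, 1, cond),
               c(exp(-0.8), 1))
  # include_direct differs exactly by the direct Boltzmann factor
  sys2 <- random_system(7, seed = 4, heterogeneity = 1)
  w0 <- boltzmann_weights(sys2, 3, cond_at(1.7), include_direct = FALSE)
  w1 <- boltzmann_weights(sys2, 3, cond_at(1.7), include_direct = TRUE)
  gm <- pair_matrix(sys2)
  expect_equal(w1 / w0,
               exp(-gm[3, -3] / 1.7), tolerance = 1e-14)
  # overflow routes to an error, never Inf
  big <- two_state_system(c(-1e6, 0), matrix(0, 2, 2))
  expect_error(boltzmann_weights(big, 2, cond_at(0.5)), "log = TRUE")
  expect_equal(boltzmann_weights(big, 2, cond_at(0.5), log = TRUE), 2e6)
})

test_that("mean_indirect averages over all non-selected pairs", {
  g <- matrix(0, 3, 3)
  g[2, 3] <- g[3, 2] <- 5
  sys <- two_state_system(rep(0, 3), g)
  expect_equal(mean_indirect(sys, 1), 5)
  g4 <- matrix(0, 4, 4)
  g4[2, 3] <- g4[3, 2] <- 1
  g4[2, 4] <- g4[4, 2] <- 2
  g4[3, 4] <- g4[4, 3] <- 3
  expect_equal(mean_indirect(two_state_system(rep(0, 4), g4), 1), 2)
  # constant pair energies: the mean is that constant for any selection
  sysc <- random_system(8, seed = 1, heterogeneity = 0, base_pair = -0.3)
  for (s in c(1, 4, 8)) expect_equal(mean_indirect(sysc, s), -0.3)
  expect_warning(v <- mean_indirect(two_state_system(c(0, 0)), 1),
                 "n < 3")
  expect_equal(v, 0)
})

test_that("mean_cross_interaction averages ordered cross pairs", {
  g <- matrix(0, 4, 4)
  g[2, 4] <- g[4, 2] <- 1
  g[3, 4] <- g[4, 3] <- 3
  sys <- two_state_system(rep(0, 4), g)
  expect_equal(mean_cross_interaction(sys, c(2, 3), 4), 2)
  expect_equal(mean_cross_interaction(sys, 2, 4), 1)
  sysc <- random_system(6, seed = 2, heterogeneity = 0, base_pair = 1.25)
  expect_equal(mean_cross_interaction(sysc, c(2, 3), c(4, 5, 6)), 1.25)
  expect_error(mean_cross_interaction(sys, c(2, 3), c(3, 4)), "disjoint")
  expect_error(mean_cross_interaction(sys, integer(0), 2), "non-empty")
})

test_that("both DIA variants are exact when the guarantee applies", {
  cond <- cond_at(1.1)
  # (a) n <= 3
  for (s in 1:5) {
    sys <- random_system(3, seed = s, heterogeneity = 3)
    bf <- partition_bruteforce(sys, 1, cond)$log_z_total
    expect_equal(dia_global(sys, 1, cond)$log_z_total, bf, tolerance = 1e-10)
    expect_equal(dia_local(sys, 1, cond)$log_z_total, bf, tolerance = 1e-10)
  }
  # n = 2: the four-microstate sum, all interactions direct
  sys2 <- two_state_system(c(0.3, -0.4),
                           pairs = data.frame(i = 1, j = 2, value = 0.9),
                           offset = 0.2)
  z4 <- sum(exp(-c(0.2, 0.5, -0.2, 0.2 + 0.3 - 0.4 + 0.9) / 1.1))
  expect_equal(z_total(dia_global(sys2, 1, cond)), z4, tolerance = 1e-12)
  expect_equal(z_total(dia_local(sys2, 1, cond)), z4, tolerance = 1e-12)
  # (b) all indirect pair energies equal
  for (s in 1:5) {
    sys <- random_system(10, seed = 50 + s, heterogeneity = 0)
    bf <- partition_bruteforce(sys, 1, cond)$log_z_total
    expect_equal(dia_global(sys, 1, cond)$log_z_total, bf, tolerance = 1e-10)
    expect_equal(dia_local(sys, 1, cond)$log_z_total, bf, tolerance = 1e-10)
  }
  # (c) all pair energies zero: independent particles factorize
  sys0 <- two_state_system(withr::with_seed(8, runif(9, -1, 1)), offset = 0.4)
  bf <- -0.4 / 1.1 + sum(log1p(exp(-sys0$self_energy / 1.1)))
  expect_equal(dia_global(sys0, 1, cond)$log_z_total, bf, tolerance = 1e-10)
  expect_equal(dia_local(sys0, 1, cond)$log_z_total, bf, tolerance = 1e-10)
})

test_that("per-merge homogeneous cross interactions make dia_local exact", {
  # 8-particle system built so every merge of the 7-leaf tree sees
  # homogeneous cross energies, though they differ between merges.
  # leaves (particles 2..8): tree splits 7 -> (3, 4) -> ((1,2),(1,2)x2)
  n <- 8
  g <- matrix(0, n, n)
  other <- 2:8
  grp <- list(2:4, 5:8)                 # top merge
  for (i in grp[[1]]) for (j in grp[[2]]) g[i, j] <- g[j, i] <- 0.7
  g[2, 3] <- g[3, 2] <- -0.5            # within left: merge of (2) vs (3,4)
  g[2, 4] <- g[4, 2] <- -0.5
  g[3, 4] <- g[4, 3] <- 1.2             # bottom-left merge
  g[5, 7] <- g[7, 5] <- 0.3             # right: (5,6) vs (7,8)
  g[5, 8] <- g[8, 5] <- 0.3
  g[6, 7] <- g[7, 6] <- 0.3
  g[6, 8] <- g[8, 6] <- 0.3
  g[5, 6] <- g[6, 5] <- -1.1
  g[7, 8] <- g[8, 7] <- 2.0
  g[1, other] <- 0.25                   # direct interactions, any values
  g[other, 1] <- 0.25
  sys <- two_state_system(withr::with_seed(4, runif(n, -1, 1)), g)
  cond <- cond_at(0.9)
  bf <- partition_bruteforce(sys, 1, cond)$log_z_total
  expect_equal(dia_local(sys, 1, cond)$log_z_total, bf, tolerance = 1e-10)
  # global averaging is NOT exact here
  expect_gt(abs(dia_global(sys, 1, cond)$log_z_total - bf), 1e-4)
})

test_that("dia_local collapses to dia_global for equal indirect energies", {
  sys <- random_system(11, seed = 21, heterogeneity = 0, base_pair = 0.8)
  cond <- cond_at(1.6)
  a <- dia_local(sys, 1, cond)
  b <- dia_global(sys, 1, cond)
  expect_equal(a$log_z0, b$log_z0, tolerance = 1e-12)
  expect_equal(a$log_z1, b$log_z1, tolerance = 1e-12)
})

test_that("decompositions are internally consistent and positive", {
  cond <- cond_at(1.3)
  for (s in 1:5) {
    sys <- random_system(9, seed = 70 + s, heterogeneity = 1)
    for (pd in list(dia_global(sys, 1, cond), dia_local(sys, 1, cond),
                    partition_bruteforce(sys, 1, cond))) {
      expect_true(all(is.finite(pd$log_z0)))  # z > 0 throughout
      expect_true(all(is.finite(pd$log_z1)))
      expect_equal(pd$log_z_total,
                   diapart:::logsumexp(c(pd$log_z0, pd$log_z1)),
                   tolerance = 1e-12)
    }
  }
})

test_that("dia_global is invariant under permutation of non-selected particles", {
  sys <- random_system(8, seed = 31, heterogeneity = 1)
  cond <- cond_at(0.8)
  ref <- dia_global(sys, 1, cond)$log_z_total
  perm <- c(1, withr::with_seed(5, sample(2:8)))
  gm <- pair_matrix(sys)[perm, perm]
  sysp <- two_state_system(sys$self_energy[perm], gm)
  expect_equal(dia_global(sysp, 1, cond)$log_z_total, ref,
               tolerance = 1e-12)
})

test_that("dia_local is invariant under swapping merge branches", {
  sys <- random_system(5, seed = 41, heterogeneity = 1)
  cond <- cond_at(1.2)
  ref <- dia_local(sys, 1, cond)$log_z_total
  # leaves (2,3,4,5): tree ((2,3),(4,5)); swapping the top branches or
  # either bottom merge is a reordering of the input
  for (perm in list(c(1, 4, 5, 2, 3), c(1, 3, 2, 4, 5), c(1, 2, 3, 5, 4))) {
    gm <- pair_matrix(sys)[perm, perm]
    sysp <- two_state_system(sys$self_energy[perm], gm)
    expect_equal(dia_local(sysp, 1, cond)$log_z_total, ref,
                 tolerance = 1e-12)
  }
})

test_that("DIA runs are deterministic and heterogeneous errors reproducible", {
  sys <- random_system(10, seed = 5, heterogeneity = 1)
  cond <- cond_at(1.0)
  a <- dia_local(sys, 1, cond)
  b <- dia_local(sys, 1, cond)
  expect_identical(a$log_z0, b$log_z0)
  expect_identical(a$log_z_total, b$log_z_total)
  err1 <- dia_local(sys, 1, cond)$log_z_total -
    partition_bruteforce(sys, 1, cond)$log_z_total
  err2 <- dia_local(sys, 1, cond)$log_z_total -
    partition_bruteforce(sys, 1, cond)$log_z_total
  expect_identical(err1, err2)
  expect_gt(abs(err1), 0)  # the approximation is genuinely approximate here
})

test_that("infinite-temperature limit counts microstates", {
  sys <- random_system(9, seed = 61, heterogeneity = 2)
  cond <- thermo_conditions(1e9)
  for (pd in list(dia_global(sys, 1, cond), dia_local(sys, 1, cond),
                  partition_bruteforce(sys, 1, cond))) {
    expect_equal(pd$log_z_total, 9 * log(2), tolerance = 1e-6)
  }
})

test_that("brute-force oracle reproduces closed-form cases", {
  cond <- cond_at(1)
  # all energies zero: z = 2^n with binomial k-pattern
  sys <- two_state_system(rep(0, 5))
  pd <- partition_bruteforce(sys, 1, cond)
  expect_equal(exp(pd$log_z0), choose(4, 0:4))
  expect_equal(exp(pd$log_z1), choose(4, 0:4))
  expect_equal(z_total(pd), 2^5)
  # hand-summed 16-term total for a 4-particle toy
  g <- matrix(0, 4, 4)
  g[1, 2] <- g[2, 1] <- 1
  g[3, 4] <- g[4, 3] <- -1
  sys4 <- two_state_system(c(0.5, -0.5, 0.25, 0), g, offset = 0.1)
  states <- as.matrix(expand.grid(rep(list(0:1), 4)))
  z16 <- sum(exp(-apply(states, 1, function(x) microstate_energy(sys4, x))))
  expect_equal(z_total(partition_bruteforce(sys4, 1, cond)), z16,
               tolerance = 1e-12)
  expect_error(partition_bruteforce(two_state_system(rep(0, 21)), 1, cond),
               "n <= 20")
})
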