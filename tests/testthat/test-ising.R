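# 2D Ising lattice, spin-occupancy mapping, and DIA observables

test_that("lattice construction yields 2L^2 unique degree-4 bonds", {
  for (L in c(3, 4, 8)) {
    lat <- build_lattice(L)
    expect_equal(nrow(lat$pairs), 2 * L^2)
    expect_true(all(lat$pairs[, 1] < lat$pairs[, 2]))
    expect_equal(anyDuplicated(lat$pairs), 0L)
    deg <- tabulate(c(lat$pairs), nbins = L^2)
    expect_true(all(deg == 4L))
  }
  expect_error(build_lattice(2), "doubled")
})

test_that("configuration energies match closed forms", {
  lat <- build_lattice(4)
  all_up <- rep(1, 16)
  expect_equal(ising_energy(lat, all_up), -32)  # -2NJ
  one_flip <- all_up
  one_flip[6] <- -1
  expect_equal(ising_energy(lat, one_flip), -32 + 8)
  checker <- ifelse((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2 == 0,
                    1, -1)
  expect_equal(ising_energy(lat, as.vector(checker)), 32)  # +2NJ
  expect_error(ising_energy(lat, rep(1, 15)), "length")
  expect_error(ising_energy(lat, c(rep(1, 15), 2)), "-1 or \\+1")
})

test_that("the occupancy mapping reproduces every configuration energy exactly", {
  for (L in c(3, 4, 5)) {
    lat <- build_lattice(L)
    sys <- to_two_state(lat)
    expect_equal(sys$self_energy, rep(8, L^2))
    expect_equal(sys$offset, -2 * L^2)
    expect_true(all(sys$pairs$value == -4))
    for (s in 1:20) {
      sp <- random_spins(L^2, seed = 1000 * L + s)
      expect_identical(microstate_energy(sys, (sp + 1) / 2),
                       ising_energy(lat, sp))
    }
  }
})

test_that("spin enumeration agrees with the mapped-system enumeration", {
  lat <- build_lattice(3)
  en <- enumerate_thermo(lat, 2.0)
  bf <- partition_bruteforce(to_two_state(lat), 1, cond_at(2.0))
  expect_equal(attr(en, "log_z"), bf$log_z_total, tolerance = 1e-10)
  # global spin flip: the k-resolved decomposition mirrors k <-> N-1-k
  # across the two selected states
  expect_equal(bf$log_z1, rev(bf$log_z0), tolerance = 1e-12)
})

test_that("enumeration limits behave thermodynamically", {
  expect_lt(abs(enumerate_thermo(build_lattice(3), 1000)$u_per_site), 1e-2)
  expect_gt(enumerate_thermo(build_lattice(4), 0.5)$m_per_site, 0.999)
  expect_error(enumerate_thermo(build_lattice(5), 1), "L <= 4")
})

test_that("DIA observables hit the temperature limits", {
  lat <- build_lattice(8)
  low <- dia_thermo(lat, 0.5)
  expect_gte(low$m_per_site, 0.99)
  expect_equal(low$u_per_site, -2, tolerance = 1e-3)
  hot <- dia_thermo(lat, 100)
  expect_lt(abs(hot$u_per_site), 0.05)
  expect_lt(abs(hot$cv_per_site), 0.05)
  expect_true(hot$m_per_site >= 0 && hot$m_per_site <= 1)
})

test_that("DIA observables at L = 4 sit at the recorded offsets from enumeration", {
  # frozen small-lattice error fixture at the critical temperature:
  # deviations of the merge-averaged DIA from exact enumeration
  tp <- dia_thermo(build_lattice(4), 2.269)
  en <- enumerate_thermo(build_lattice(4), 2.269)
  expect_equal(tp$m_per_site - en$m_per_site, 0.0351999903, tolerance = 1e-6)
  expect_equal(tp$u_per_site - en$u_per_site, -0.0599623943, tolerance = 1e-6)
  expect_equal(tp$cv_per_site - en$cv_per_site, -0.1005159837, tolerance = 1e-6)
})

test_that("dia_thermo is deterministic and insensitive to halving dt", {
  lat <- build_lattice(8)
  a <- dia_thermo(lat, 2.3)
  expect_identical(a, dia_thermo(lat, 2.3))
  b <- dia_thermo(lat, 2.3, dt = 5e-4)
  expect_lt(abs(a$u_per_site / b$u_per_site - 1), 1e-3)
  expect_lt(abs(a$cv_per_site / b$cv_per_site - 1), 1e-3)
  expect_error(dia_thermo(lat, 1e-3, dt = 1e-3), "t_star - 2")
})
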