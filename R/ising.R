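#' Isotropic 2D Ising lattice
#'
#' An `L x L` square lattice with periodic boundary conditions, no
#' external field, and uniform nearest-neighbor ferromagnetic coupling
#' `J > 0`.  Sites are numbered row-major (1-based); the bond list
#' holds each of the `2 L^2` unordered nearest-neighbor pairs exactly
#' once (right and down neighbors with wraparound).
#'
#' `L = 2` is rejected: under periodic boundaries the right and left
#' neighbor of a site coincide there, which would double every bond
#' and change the model.
#'
#' @param L lattice side (>= 3).
#' @param J coupling constant (> 0).
#' @return An object of class `"ising_lattice"` with fields `side`,
#'   `coupling`, `n_sites`, and `pairs` (two-column matrix, `i < j`).
#' @examples
#' lat <- build_lattice(4)
#' nrow(lat$pairs)  # 32 bonds
#' @export
build_lattice <- function(L, J = 1) {
  if (L < 3L)
    stopf(paste0("L must be >= 3: for L = 2 the periodic right and left ",
                 "neighbors coincide, so every bond would be doubled"))
  if (J <= 0) stopf("J must be > 0")
  L <- as.integer(L)
  n <- L * L
  s <- seq_len(n) - 1L
  r <- s %/% L
  cc <- s %% L
  right <- r * L + (cc + 1L) %% L
  down <- ((r + 1L) %% L) * L + cc
  i <- c(s, s) + 1L
  j <- c(right, down) + 1L
  pairs <- cbind(i = pmin(i, j), j = pmax(i, j))
  structure(list(side = L, coupling = J, n_sites = n, pairs = pairs),
            class = "ising_lattice")
}

#' @export
print.ising_lattice <- function(x, ...) {
  cat(sprintf("<ising_lattice> %d x %d periodic, J = %g, %d bonds\n",
              x$side, x$side, x$coupling, nrow(x$pairs)))
  invisible(x)
}

#' Ising configuration energy
#'
#' `E = -J * sum over nearest-neighbor bonds of s_i s_j` for a spin
#' configuration `s in {-1, +1}^N`.
#'
#' @param lat an [build_lattice()] lattice.
#' @param spins vector of `N` spins, each -1 or +1.
#' @export
ising_energy <- function(lat, spins) {
  stopifnot(inherits(lat, "ising_lattice"))
  if (length(spins) != lat$n_sites)
    stopf("spins must have length %d", lat$n_sites)
  if (!all(spins %in% c(-1, 1)))
    stopf("spins must be -1 or +1")
  -lat$coupling * sum(spins[lat$pairs[, 1]] * spins[lat$pairs[, 2]])
}

#' Map an Ising lattice to an occupancy (0/1) two-state system
#'
#' Substituting `sigma = 2 x - 1` into the Ising energy yields an
#' equivalent [two_state_system()] with, for every site,
#' `self_energy = 2 J * degree = 8 J`, pair energy `-4 J` on each
#' nearest-neighbor bond (0 elsewhere), and the state-independent
#' offset `-2 N J` (the all-down ground-state energy).  The mapping is
#' exact: for every configuration the mapped microstate energy equals
#' [ising_energy()].
#'
#' @inheritParams ising_energy
#' @return A `two_state_system` with `N = L^2` particles.
#' @export
to_two_state <- function(lat) {
  stopifnot(inherits(lat, "ising_lattice"))
  J <- lat$coupling
  n <- lat$n_sites
  two_state_system(rep(8 * J, n),
                   pairs = data.frame(i = lat$pairs[, 1],
                                      j = lat$pairs[, 2],
                                      value = -4 * J),
                   offset = -2 * n * J)
}

#' Critical temperature of the infinite 2D Ising model
#'
#' `2 / log(1 + sqrt(2))`, about 2.269, in units of `J / k_B`.
#' @export
ising_critical_temperature <- function() 2 / log(1 + sqrt(2))

new_thermo_point <- function(t_star, m, u, cv) {
  structure(list(t_star = t_star, m_per_site = m, u_per_site = u,
                 cv_per_site = cv),
            class = "thermo_point")
}

#' @export
print.thermo_point <- function(x, ...) {
  cat(sprintf("<thermo_point> t* = %g: <|M|>/N = %.6f, U/NJ = %.6f, Cv/NkB = %.6f\n",
              x$t_star, x$m_per_site, x$u_per_site, x$cv_per_site))
  invisible(x)
}

#' @export
as.data.frame.thermo_point <- function(x, ...) {
  data.frame(t_star = x$t_star, m_per_site = x$m_per_site,
             u_per_site = x$u_per_site, cv_per_site = x$cv_per_site)
}

# dimensionless observables from a log-partition-function evaluator.
# lnZ is evaluated at t - dt, t, t + dt (all in units of J / k_B);
# U = kB T^2 dlnZ/dT by the central difference, and Cv = dU/dT from
# the two staggered half-step U estimates, so three evaluations serve
# both derivatives.  Returned values are per site, per J (u) and per
# k_B (cv).
thermo_from_logz <- function(logz_fn, t_star, dt, n_sites) {
  if (t_star - dt <= 0)
    stopf("derivative step dt = %g collides with T <= 0 at t* = %g", dt, t_star)
  fm <- logz_fn(t_star - dt)
  f0 <- logz_fn(t_star)
  fp <- logz_fn(t_star + dt)
  u_site <- t_star^2 * (fp - fm) / (2 * dt) / n_sites
  u_half_p <- (t_star + dt / 2)^2 * (fp - f0) / dt
  u_half_m <- (t_star - dt / 2)^2 * (f0 - fm) / dt
  cv_site <- (u_half_p - u_half_m) / dt / n_sites
  list(u = u_site, cv = cv_site, f0 = f0)
}

#' DIA thermodynamic observables for the 2D Ising model
#'
#' Runs the direct interaction algorithm on the occupancy mapping of
#' `lat` ([to_two_state()]) and reports dimensionless per-site
#' observables at dimensionless temperature `t_star = k_B T / J`:
#' thermal average absolute magnetization `<|M|>/N` read off the
#' k-resolved decomposition (`|M| = |2 (k + s) - N|` when `k` others
#' and the selected site contribute `k + s` up-spins), internal energy
#' `U/(N J)` from the central-difference derivative of `ln Z`, and heat
#' capacity `Cv/(N k_B)` from the temperature derivative of `U`
#' (staggered half-step stencil; three `ln Z` evaluations in total).
#'
#' @param lat an [build_lattice()] lattice.
#' @param t_star dimensionless temperature `k_B T / J` (> 0).
#' @param dt dimensionless central-difference step (default `1e-3`);
#'   must satisfy `t_star - 2 dt > 0`.
#' @param variant `"local"` (merge-level averaging, the default) or
#'   `"global"`.
#' @param selected selected site (default 1; immaterial under
#'   translation symmetry).
#' @return A `"thermo_point"` with fields `t_star`, `m_per_site`,
#'   `u_per_site`, `cv_per_site`.
#' @export
dia_thermo <- function(lat, t_star, dt = 1e-3,
                       variant = c("local", "global"), selected = 1L) {
  stopifnot(inherits(lat, "ising_lattice"))
  variant <- match.arg(variant)
  if (t_star <= 0) stopf("t_star must be > 0")
  if (t_star - 2 * dt <= 0)
    stopf("need t_star - 2 * dt > 0 for the derivative stencil")
  sys <- to_two_state(lat)
  J <- lat$coupling
  fn <- function(ts) {
    cond <- thermo_conditions(ts * J)  # k_B = 1: T = t* J
    pd <- if (variant == "local") dia_local(sys, selected, cond)
          else dia_global(sys, selected, cond)
    pd
  }
  pd0 <- fn(t_star)
  d <- thermo_from_logz(function(ts) {
    if (ts == t_star) pd0$log_z_total else fn(ts)$log_z_total
  }, t_star, dt, lat$n_sites)
  n <- lat$n_sites
  k <- 0:(n - 1)
  lzt <- pd0$log_z_total
  m <- sum(abs(2 * k - n) / n * exp(pd0$log_z0 - lzt)) +
    sum(abs(2 * (k + 1) - n) / n * exp(pd0$log_z1 - lzt))
  new_thermo_point(t_star, m, d$u, d$cv)
}

#' Exact small-lattice thermodynamics by spin enumeration
#'
#' Sums all `2^N` spin configurations (guarded at `L <= 4`) and
#' returns the same dimensionless observables as [dia_thermo()], with
#' `U` and `Cv` from the exact thermal moments
#' `U = <E>` and `Cv = (<E^2> - <E>^2) / (k_B T^2)`.
#'
#' @inheritParams dia_thermo
#' @return A `"thermo_point"`; additionally carries `attr(, "log_z")`.
#' @export
enumerate_thermo <- function(lat, t_star) {
  stopifnot(inherits(lat, "ising_lattice"))
  if (lat$side > 4L)
    stopf("enumerate_thermo sums 2^(L^2) states and is guarded at L <= 4")
  if (t_star <= 0) stopf("t_star must be > 0")
  J <- lat$coupling
  n <- lat$n_sites
  r <- cpp_enumerate_ising(lat$side, J, 1 / (J * t_star))
  tp <- new_thermo_point(
    t_star,
    r$mean_absM / n,
    r$mean_E / (n * J),
    (r$mean_E2 - r$mean_E^2) / (n * (J * t_star)^2))
  attr(tp, "log_z") <- r$log_Z
  tp
}
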