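#' Thermodynamic conditions
#'
#' Temperature and Boltzmann constant for partition-function
#' evaluations.  The default `boltzmann_constant = 1` is the
#' dimensionless convention in which temperatures are quoted in units
#' of energy (for the Ising test bed, `J / k_B`).
#'
#' @param temperature positive temperature.
#' @param boltzmann_constant positive Boltzmann constant.
#' @export
thermo_conditions <- function(temperature, boltzmann_constant = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stopf("temperature must be a single positive number")
  if (boltzmann_constant <= 0) stopf("boltzmann_constant must be > 0")
  structure(list(temperature = temperature,
                 boltzmann_constant = boltzmann_constant),
            class = "thermo_conditions")
}

inv_kt <- function(cond) 1 / (cond$boltzmann_constant * cond$temperature)

#' Single-particle Boltzmann factors seen from a selected particle
#'
#' For each non-selected particle `j` (in input order), the Boltzmann
#' factor of its state-1 configuration: `exp(-self_j / kT)` without
#' direct interactions, or `exp(-(self_j + g_{sj}) / kT)` when the
#' direct interaction with the selected particle `s` is folded in (the
#' weight set used when the selected particle is itself in state 1).
#'
#' @param sys a [two_state_system()].
#' @param selected 1-based index of the selected particle.
#' @param cond a [thermo_conditions()] object.
#' @param include_direct fold the direct interaction with `selected`
#'   into each factor?
#' @param log return log-weights?  Plain weights that would overflow
#'   the double range raise an error directing callers to the log
#'   representation; they are never returned as `Inf`.
#' @return Numeric vector of length `n - 1`.
#' @export
boltzmann_weights <- function(sys, selected, cond, include_direct = TRUE,
                              log = FALSE) {
  stopifnot(inherits(sys, "two_state_system"))
  if (selected < 1L || selected > sys$n)
    stopf("selected must be in 1..%d", sys$n)
  others <- setdiff(seq_len(sys$n), selected)
  e <- sys$self_energy[others]
  if (include_direct && nrow(sys$pairs)) {
    touch <- sys$pairs$i == selected | sys$pairs$j == selected
    if (any(touch)) {
      p <- sys$pairs[touch, ]
      other_end <- ifelse(p$i == selected, p$j, p$i)
      e[match(other_end, others)] <- e[match(other_end, others)] + p$value
    }
  }
  lw <- -e * inv_kt(cond)
  if (log) return(lw)
  if (any(lw > log(.Machine$double.xmax)))
    stopf("Boltzmann factors overflow the double range; call with log = TRUE")
  exp(lw)
}

#' Average indirect interaction energy
#'
#' Arithmetic mean of the pair energies over all unordered pairs of
#' non-selected particles -- including pairs whose interaction is zero,
#' so the divisor is always `(n-1)(n-2)/2`.  This is the single value
#' by which [dia_global()] replaces every indirect interaction.
#'
#' @inheritParams boltzmann_weights
#' @return Mean indirect energy; `0` with a warning when `n < 3` (no
#'   indirect pairs exist).
#' @export
mean_indirect <- function(sys, selected) {
  stopifnot(inherits(sys, "two_state_system"))
  if (selected < 1L || selected > sys$n)
    stopf("selected must be in 1..%d", sys$n)
  if (sys$n < 3L) {
    warning("no indirect pairs for n < 3; returning 0")
    return(0)
  }
  keep <- sys$pairs$i != selected & sys$pairs$j != selected
  total <- sum(sys$pairs$value[keep])
  total / ((sys$n - 1) * (sys$n - 2) / 2)
}

#' Average interaction between two particle groups
#'
#' Arithmetic mean of `pair(i, j)` over `i` in `group_a`, `j` in
#' `group_b` (all `|A| |B|` ordered cross pairs, zeros included).  This
#' is the per-merge average used by [dia_local()].
#'
#' @inheritParams boltzmann_weights
#' @param group_a,group_b disjoint non-empty vectors of particle
#'   indices.
#' @export
mean_cross_interaction <- function(sys, group_a, group_b) {
  stopifnot(inherits(sys, "two_state_system"))
  if (!length(group_a) || !length(group_b))
    stopf("groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stopf("groups must be disjoint")
  ina <- sys$pairs$i %in% group_a & sys$pairs$j %in% group_b
  inb <- sys$pairs$i %in% group_b & sys$pairs$j %in% group_a
  sum(sys$pairs$value[ina | inb]) / (length(group_a) * length(group_b))
}

new_partition_decomposition <- function(log_z0, log_z1, n, selected, cond,
                                        variant, ops = NA_real_) {
  structure(list(log_z0 = log_z0, log_z1 = log_z1,
                 log_z_total = logsumexp(c(log_z0, log_z1)),
                 n = n, selected = selected,
                 temperature = cond$temperature,
                 boltzmann_constant = cond$boltzmann_constant,
                 variant = variant),
            ops = ops, class = "partition_decomposition")
}

#' @export
print.partition_decomposition <- function(x, ...) {
  cat(sprintf("<partition_decomposition> n = %d, selected = %d, T = %g (%s)\n",
              x$n, x$selected, x$temperature, x$variant))
  cat(sprintf("  log Z = %.10g\n", x$log_z_total))
  invisible(x)
}

#' @describeIn dia_global log of the total partition function.
#' @param pd a `partition_decomposition`.
#' @export
log_z_total <- function(pd) {
  stopifnot(inherits(pd, "partition_decomposition"))
  pd$log_z_total
}

#' @describeIn dia_global plain-value partition function; errors on
#'   overflow rather than returning `Inf`.
#' @export
z_total <- function(pd) {
  stopifnot(inherits(pd, "partition_decomposition"))
  if (pd$log_z_total > log(.Machine$double.xmax))
    stopf("Z overflows the double range; use log_z_total()")
  exp(pd$log_z_total)
}

# shared machinery: k-resolved decomposition from ESF vectors plus the
# quadratic average-interaction exponent (global averaging)
dia_decompose_global <- function(sys, selected, cond) {
  b <- inv_kt(cond)
  lw0 <- boltzmann_weights(sys, selected, cond, include_direct = FALSE,
                           log = TRUE)
  lw1 <- boltzmann_weights(sys, selected, cond, include_direct = TRUE,
                           log = TRUE)
  gbar <- if (sys$n >= 3) mean_indirect(sys, selected) else 0
  e0 <- esf_split_merge(log_w = lw0)
  e1 <- esf_split_merge(log_w = lw1)
  k <- 0:(sys$n - 1)
  lind <- -gbar * k * (k - 1) / 2 * b
  loff <- -sys$offset * b
  list(log_z0 = log_coeffs(e0) + lind + loff,
       log_z1 = log_coeffs(e1) + lind + loff -
         sys$self_energy[selected] * b,
       ops = attr(e0, "ops") + attr(e1, "ops"))
}

#' Direct interaction algorithm (global averaging)
#'
#' Approximates the canonical partition function of a
#' [two_state_system()] in `O(n^2)` operations.  Microstates are
#' partitioned by the selected particle's state `s` and by the number
#' `k` of other particles in state 1.  Interactions involving the
#' selected particle ("direct") enter exactly through elementary
#' symmetric functions of the per-particle Boltzmann factors
#' ([esf_split_merge()]); every interaction among the remaining
#' particles ("indirect") is replaced by the single global average
#' `gbar` ([mean_indirect()]), contributing
#' `exp(-k (k-1)/2 * gbar / kT)` to the subset with `k` particles in
#' state 1.  The approximation is exact whenever all indirect pair
#' energies are equal (in particular for `n <= 3` or all-zero pair
#' energies).
#'
#' @inheritParams boltzmann_weights
#' @param selected 1-based index of the selected particle.  All
#'   results are invariant under permutation of the others; for
#'   heterogeneous systems different choices give (slightly) different
#'   approximations.
#' @return A `partition_decomposition`: log-domain k-resolved
#'   contributions `log_z0`, `log_z1` (each length `n`, index `k + 1`)
#'   and `log_z_total`, all including the energy-offset factor.
#' @seealso [dia_local()] for per-merge averaging, and
#'   [partition_bruteforce()] for the exact oracle.
#' @export
dia_global <- function(sys, selected = 1L, cond) {
  stopifnot(inherits(sys, "two_state_system"),
            inherits(cond, "thermo_conditions"))
  if (sys$n < 2L) stopf("need n >= 2")
  d <- dia_decompose_global(sys, selected, cond)
  new_partition_decomposition(d$log_z0, d$log_z1, sys$n, selected, cond,
                              "dia-global", ops = d$ops)
}

#' Direct interaction algorithm (merge-level averaging)
#'
#' Refines [dia_global()]: instead of one global average, each merge of
#' the binary split-merge tree applies the average interaction between
#' the two particle subsets being combined.  Merging subsets A and B
#' with `j` and `k - j` particles in state 1 contributes the factor
#' `x^(j (k-j))`, `x = exp(-gbar_AB / kT)`, where `gbar_AB` is the
#' arithmetic mean of the cross pair energies
#' ([mean_cross_interaction()]).  Every indirect pair is averaged
#' exactly once, at the merge where its endpoints first land on
#' opposite branches, so when all indirect pair energies are equal the
#' result coincides with [dia_global()]; when cross interactions are
#' homogeneous merely within each merge, the result is exact.
#'
#' @inheritParams dia_global
#' @return A `partition_decomposition`, as for [dia_global()].
#' @export
dia_local <- function(sys, selected = 1L, cond) {
  stopifnot(inherits(sys, "two_state_system"),
            inherits(cond, "thermo_conditions"))
  if (sys$n < 2L) stopf("need n >= 2")
  b <- inv_kt(cond)
  others <- setdiff(seq_len(sys$n), selected)
  pos <- integer(sys$n)          # particle index -> 0-based leaf position
  pos[others] <- seq_along(others) - 1L
  keep <- sys$pairs$i != selected & sys$pairs$j != selected
  pr <- sys$pairs[keep, ]
  pa <- pmin(pos[pr$i], pos[pr$j])
  pb <- pmax(pos[pr$i], pos[pr$j])
  lw0 <- boltzmann_weights(sys, selected, cond, include_direct = FALSE,
                           log = TRUE)
  lw1 <- boltzmann_weights(sys, selected, cond, include_direct = TRUE,
                           log = TRUE)
  t0 <- cpp_dia_tree_log(lw0, pa, pb, pr$value, b)
  t1 <- cpp_dia_tree_log(lw1, pa, pb, pr$value, b)
  loff <- -sys$offset * b
  new_partition_decomposition(
    t0$log_z + loff,
    t1$log_z + loff - sys$self_energy[selected] * b,
    sys$n, selected, cond, "dia-local", ops = t0$ops + t1$ops)
}

#' Exact k-resolved partition function by enumeration
#'
#' Sums the Boltzmann factors of all `2^n` microstates, resolved by the
#' selected particle's state and the count of other particles in state
#' 1 -- the exact oracle both DIA variants are measured against.
#' Guarded at `n <= 20`.
#'
#' @inheritParams dia_global
#' @return A `partition_decomposition` (variant `"bruteforce"`).
#' @export
partition_bruteforce <- function(sys, selected = 1L, cond) {
  stopifnot(inherits(sys, "two_state_system"),
            inherits(cond, "thermo_conditions"))
  if (sys$n > 20L)
    stopf("partition_bruteforce enumerates 2^n microstates and is guarded at n <= 20 (got n = %d)",
          sys$n)
  if (selected < 1L || selected > sys$n)
    stopf("selected must be in 1..%d", sys$n)
  r <- cpp_partition_bruteforce(sys$self_energy,
                                sys$pairs$i - 1L, sys$pairs$j - 1L,
                                sys$pairs$value,
                                selected - 1L, sys$offset, inv_kt(cond))
  new_partition_decomposition(r$log_z0, r$log_z1, sys$n, selected, cond,
                              "bruteforce")
}
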