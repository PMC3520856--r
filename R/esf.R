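#' Elementary symmetric functions over nonnegative weights
#'
#' The elementary symmetric function (ESF) of order `k` over weights
#' `w_1, ..., w_M` is the sum over all k-subsets of the product of the
#' selected weights; equivalently, `e_k` is the coefficient of `x^k` in
#' `prod_i (1 + w_i x)`.  When the weights are single-particle Boltzmann
#' factors, `e_k` is the contribution to a partition function from all
#' microstates with exactly `k` particles in state 1, which is what
#' makes ESFs the computational backbone of the direct interaction
#' algorithm ([dia_global()], [dia_local()]).
#'
#' Three routes are provided:
#' \describe{
#'   \item{[esf_bruteforce()]}{direct enumeration of all `2^M` subsets;
#'     the oracle, usable up to `M = 25`.}
#'   \item{[esf_newton()]}{the Newton's-identity recursion relating
#'     ESFs to power sums.  Its alternating signs make it numerically
#'     unstable for weight sets of widely varying magnitude: in machine
#'     doubles the recursion can lose essentially all significant
#'     digits (catastrophic cancellation), which this function exposes
#'     rather than hides.  An extended-precision mode (compensated
#'     double-double arithmetic, roughly 31 significant digits) is the
#'     reference against which the cancellation is measured.}
#'   \item{[esf_split_merge()]}{the numerically stable binary
#'     split-merge algorithm: the weight set is halved recursively into
#'     a binary tree, leaf ESFs are `(1, w_i)`, and sibling ESFs are
#'     combined by discrete convolution.  Every summand is nonnegative,
#'     so no cancellation can occur; total work is `Theta(M^2)`
#'     multiply-adds.}
#' }
#'
#' @section Representation:
#' ESF vectors are stored canonically in the log domain (class `"esf"`)
#' together with a sign vector, so coefficients spanning thousands of
#' orders of magnitude -- e.g. from a 128 x 128 lattice at low
#' temperature -- are held without overflow or underflow.
#' `as.numeric()` converts back to plain values and fails rather than
#' silently returning `Inf` when a coefficient exceeds the double
#' range.  Signs other than `+1` only arise from the machine-precision
#' Newton route, where they are part of the error being demonstrated.
#'
#' @name esf
NULL

new_esf <- function(log_abs, sign = NULL, ops = NA_real_) {
  if (is.null(sign)) sign <- rep(1L, length(log_abs))
  sign[!is.finite(log_abs) & log_abs < 0] <- 1L  # zero coefficients
  structure(list(log_abs = as.numeric(log_abs), sign = as.integer(sign)),
            ops = ops, class = "esf")
}

esf_from_values <- function(v, ops = NA_real_) {
  new_esf(log(abs(v)), sign = ifelse(v < 0, -1L, 1L), ops = ops)
}

validate_weights <- function(w) {
  if (!is.numeric(w) || length(w) < 1L)
    stopf("weights must be a non-empty numeric vector")
  if (any(!is.finite(w)) || any(w < 0))
    stopf("weights must be finite and >= 0")
  invisible(w)
}

#' @describeIn esf number of coefficients, `M + 1`.
#' @param x,... an `"esf"` object (further arguments ignored).
#' @export
length.esf <- function(x) length(x$log_abs)

#' @describeIn esf convert to a plain numeric coefficient vector
#'   (`as.numeric()` dispatches here too).  Errors if any coefficient
#'   overflows the double range; coefficients below the smallest normal
#'   double convert to zero.
#' @export
as.double.esf <- function(x, ...) {
  if (any(x$log_abs > log(.Machine$double.xmax)))
    stopf(paste0("ESF coefficients exceed the double range; ",
                 "work with log_coeffs() instead"))
  x$sign * exp(x$log_abs)
}

#' @describeIn esf log-domain coefficients (natural log; `-Inf` for
#'   exact zeros).
#' @export
log_coeffs <- function(x) {
  stopifnot(inherits(x, "esf"))
  if (any(x$sign < 0))
    stopf("negative coefficients have no log-domain value")
  x$log_abs
}

#' @export
print.esf <- function(x, ...) {
  m <- length(x$log_abs) - 1L
  cat(sprintf("<esf> order 0..%d\n", m))
  if (all(x$log_abs < log(.Machine$double.xmax))) {
    print(x$sign * exp(x$log_abs))
  } else {
    cat("log-domain coefficients:\n")
    print(x$log_abs)
  }
  invisible(x)
}

#' Brute-force ESF by subset enumeration
#'
#' Enumerates all `2^M` subsets and accumulates each subset product
#' into the coefficient of its cardinality.  Exponential cost; guarded
#' at `M <= 25`.  This is the oracle against which the fast routes are
#' validated.
#'
#' @param w numeric vector of `M` nonnegative finite weights.
#' @return An `"esf"` object with `M + 1` coefficients.
#' @examples
#' as.numeric(esf_bruteforce(c(1, 2, 3)))  # 1 6 11 6
#' @export
esf_bruteforce <- function(w) {
  validate_weights(w)
  if (length(w) > 25L)
    stopf("esf_bruteforce enumerates 2^M subsets and is guarded at M <= 25 (got M = %d)",
          length(w))
  esf_from_values(cpp_esf_bruteforce(w))
}

#' ESF via Newton's identities
#'
#' Computes ESFs by the power-sum recursion
#' `k e_k = sum_{j=1..k} (-1)^(j-1) e_{k-j} p_j`, `p_j = sum_i w_i^j`.
#' The alternating signs subtract near-equal large quantities whenever
#' the weights span many orders of magnitude, so the machine-double
#' mode can be wrong by orders of magnitude -- the failure mode that
#' motivates the split-merge algorithm.  The extended mode runs the
#' same recursion in double-double arithmetic (about 31 significant
#' digits) and serves as the reference.
#'
#' The cancellation the recursion must perform grows roughly like
#' `(max(w) / geometric mean(w))^k` with the coefficient order `k`, so
#' even the extended mode is only trustworthy while that factor stays
#' within its ~31-digit headroom; for wider weight sets no fixed
#' working precision suffices and [esf_split_merge()] (or
#' [esf_bruteforce()] at small `M`) is the reference.
#'
#' @param w numeric vector of nonnegative finite weights.
#' @param precision `"double"` for machine doubles, `"extended"` for
#'   compensated double-double arithmetic.
#' @return An `"esf"` object.  In `"double"` mode the result may
#'   violate ESF invariants (including negative coefficients); that
#'   deviation is the quantity of interest.  Overflow in `"double"`
#'   mode raises an error rather than returning infinities.
#' @examples
#' as.numeric(esf_newton(c(1, 2, 3), "extended"))  # 1 6 11 6
#' @export
esf_newton <- function(w, precision = c("double", "extended")) {
  validate_weights(w)
  precision <- match.arg(precision)
  m <- length(w)
  if (precision == "extended") return(esf_from_values(cpp_esf_newton_dd(w)))
  p <- vapply(seq_len(m), function(j) sum(w^j), numeric(1))
  e <- numeric(m + 1)
  e[1] <- 1
  for (k in seq_len(m)) {
    j <- seq_len(k)
    e[k + 1] <- sum((-1)^(j - 1) * e[k - j + 1] * p[j]) / k
  }
  if (any(!is.finite(e)) || any(!is.finite(p)))
    stopf("numeric overflow in machine-double Newton recursion; use precision = \"extended\" or esf_split_merge()")
  esf_from_values(e)
}

#' Merge two ESF vectors by discrete convolution
#'
#' Implements the subsystem-combination identity: if a weight set is
#' split into two disjoint subsets with ESF vectors `a` and `b`, the
#' ESF of the union is `c[k] = sum_j a[j] b[k-j]`.  All summands are
#' nonnegative, so the merge is cancellation-free.
#'
#' @param a,b `"esf"` objects (all-nonnegative coefficients).
#' @return An `"esf"` object of length `length(a) + length(b) - 1`.
#' @examples
#' as.numeric(esf_merge(esf_from_weights(2), esf_from_weights(3)))  # 1 5 6
#' @export
esf_merge <- function(a, b) {
  stopifnot(inherits(a, "esf"), inherits(b, "esf"))
  if (any(a$sign < 0) || any(b$sign < 0))
    stopf("esf_merge requires nonnegative coefficients")
  la <- a$log_abs
  lb <- b$log_abs
  fin <- c(la[is.finite(la)], lb[is.finite(lb)])
  plain_ok <- length(fin) > 0 &&
    max(la) + max(lb) + log(length(la) + length(lb)) < 700 &&
    min(fin) * 2 > -700
  if (plain_ok) {
    esf_from_values(cpp_conv_plain(exp(la), exp(lb)))
  } else {
    new_esf(cpp_conv_log(la, lb, 0))
  }
}

#' ESF of the empty weight set
#'
#' The multiplicative identity for [esf_merge()]: the single
#' coefficient `e_0 = 1` (the empty product).
#' @export
esf_empty <- function() new_esf(0)

#' Single-weight ESF leaf
#'
#' The ESF vector of a one-particle system, `(1, w)`; the leaf of the
#' split-merge tree.
#' @param w a single nonnegative weight.
#' @export
esf_from_weights <- function(w) {
  validate_weights(w)
  if (length(w) == 1L) return(new_esf(c(0, log(w))))
  esf_split_merge(w)
}

#' Numerically stable ESF via the binary split-merge algorithm
#'
#' Recursively halves the weight sequence (left branch gets
#' `floor(n/2)` weights, input order preserved), computes leaf ESFs
#' `(1, w_i)`, and merges sibling ESFs bottom-up by convolution.  Work
#' is `Theta(M^2)` multiply-adds and every summand is nonnegative, so
#' the route is free of the catastrophic cancellation that afflicts
#' Newton's identities.
#'
#' Small, moderate-magnitude inputs are convolved in plain doubles; the
#' computation switches to log-domain coefficients (combined by
#' log-sum-exp) whenever plain arithmetic could overflow or underflow,
#' which keeps weight sets as large as a 128 x 128 lattice at low
#' temperature in range.
#'
#' @param w numeric vector of nonnegative finite weights (ignored when
#'   `log_w` is given).
#' @param log_w optional vector of log-weights, for weights not
#'   representable as doubles.
#' @return An `"esf"` object; `attr(, "ops")` counts convolution
#'   multiply-adds.
#' @examples
#' as.numeric(esf_split_merge(c(1, 2, 3)))  # 1 6 11 6
#' @export
esf_split_merge <- function(w, log_w = NULL) {
  if (is.null(log_w)) {
    validate_weights(w)
    log_w <- log(w)
  } else {
    if (any(is.nan(log_w)) || any(log_w == Inf))
      stopf("log_w must be < Inf and not NaN")
  }
  fin <- log_w[is.finite(log_w)]
  if (length(fin) == 0 || sum(abs(fin)) < 600) {
    r <- cpp_esf_split_merge_plain(exp(log_w))
    esf_from_values(r$coeffs, ops = r$ops)
  } else {
    r <- cpp_esf_split_merge_log(log_w)
    new_esf(r$log_coeffs, ops = r$ops)
  }
}

#' Weight set demonstrating catastrophic cancellation in Newton's identities
#'
#' A packaged fixture: the direct-interaction Boltzmann factors seen
#' from one site of a 3 x 3 periodic square Ising lattice (coupling
#' J = 1, occupancy mapping of [to_two_state()]) at low dimensionless
#' temperature 0.4, normalized to geometric mean 1 (an exact
#' rescaling, `e_k(c w) = c^k e_k(w)`, which keeps the Newton power
#' sums within double range without changing any relative error).  The
#' four neighbor weights sit `e^10` above the other four, so the
#' high-order ESF coefficients require the alternating-sign Newton
#' recursion to cancel terms up to `e^40 ~ 2e17` times larger than the
#' result -- total loss of machine-double precision -- while the
#' all-positive split-merge route is unaffected.
#'
#' The same vector ships as
#' `system.file("extdata", "cancellation_weights.tsv", package = "diapart")`.
#'
#' @return Numeric vector of 8 weights.
#' @export
cancellation_weights <- function() {
  t_star <- 0.4
  lat <- build_lattice(3)
  lw <- boltzmann_weights(to_two_state(lat), 1L,
                          thermo_conditions(t_star * lat$coupling),
                          include_direct = TRUE, log = TRUE)
  w <- exp(lw - mean(lw))
  sort(w, decreasing = TRUE)
}
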