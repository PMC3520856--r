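#' Two-state interacting particle systems
#'
#' A `two_state_system` describes `n` particles that each occupy state
#' 0 or state 1: `self_energy[i]` is the energy cost of particle `i`
#' being in state 1, `pair(i, j)` is the additional energy when
#' particles `i` and `j` are both in state 1, and `energy_offset` is a
#' state-independent constant (such systems arise, e.g., as
#' protonation-state models of ionizable residues, or from mapping spin
#' lattices onto occupancy variables).  The energy of a microstate
#' `x in {0,1}^n` is
#' `offset + sum_i self_i x_i + sum_{i<j} g_ij x_i x_j`.
#'
#' Pair energies are held sparsely as an `(i, j, value)` triplet table
#' with `i < j`; absent pairs are zero.  This keeps lattice systems
#' (where almost all pairs are zero) at size `n = 16384` cheap.
#'
#' @param self_energy numeric vector of length `n`.
#' @param pair_energy optional symmetric `n x n` matrix with zero
#'   diagonal (dense input; converted to triplets).
#' @param pairs optional data frame with columns `i`, `j`, `value`
#'   (1-based, `i < j`, no duplicates); alternative to `pair_energy`.
#' @param offset state-independent additive energy constant.
#' @return An object of class `"two_state_system"`.
#' @examples
#' g <- matrix(0, 3, 3); g[1, 2] <- g[2, 1] <- -1
#' sys <- two_state_system(c(0.5, -0.2, 0.1), g)
#' microstate_energy(sys, c(1, 1, 0))
#' @export
two_state_system <- function(self_energy, pair_energy = NULL, pairs = NULL,
                             offset = 0) {
  n <- length(self_energy)
  if (n < 1L || !is.numeric(self_energy) || any(!is.finite(self_energy)))
    stopf("self_energy must be a finite numeric vector")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    stopf("offset must be a single finite number")
  if (!is.null(pair_energy) && !is.null(pairs))
    stopf("give pair_energy or pairs, not both")
  if (!is.null(pair_energy)) {
    if (!is.matrix(pair_energy) || !all(dim(pair_energy) == n))
      stopf("pair_energy must be an %d x %d matrix", n, n)
    if (any(!is.finite(pair_energy)))
      stopf("pair energies must be finite")
    if (!isTRUE(all.equal(pair_energy, t(pair_energy), tolerance = 0)))
      stopf("pair_energy must be exactly symmetric")
    if (any(diag(pair_energy) != 0))
      stopf("pair_energy must have a zero diagonal")
    idx <- which(upper.tri(pair_energy) & pair_energy != 0, arr.ind = TRUE)
    pairs <- data.frame(i = idx[, 1], j = idx[, 2],
                        value = pair_energy[idx])
  } else if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer(), value = numeric())
  } else {
    pairs <- as.data.frame(pairs)
    if (!all(c("i", "j", "value") %in% names(pairs)))
      stopf("pairs needs columns i, j, value")
    pairs <- pairs[, c("i", "j", "value")]
    if (nrow(pairs)) {
      swap <- pairs$i > pairs$j
      tmp <- pairs$i[swap]
      pairs$i[swap] <- pairs$j[swap]
      pairs$j[swap] <- tmp
      if (any(pairs$i == pairs$j))
        stopf("pair energies on the diagonal (i == j) are not allowed")
      if (any(pairs$i < 1L | pairs$j > n))
        stopf("pair indices out of range 1..%d", n)
      if (anyDuplicated(pairs[c("i", "j")]))
        stopf("duplicate pair entries")
      if (any(!is.finite(pairs$value)))
        stopf("pair energies must be finite")
    }
  }
  structure(list(n = n, self_energy = as.numeric(self_energy),
                 pairs = pairs, offset = offset),
            class = "two_state_system")
}

#' @export
print.two_state_system <- function(x, ...) {
  cat(sprintf("<two_state_system> n = %d particles, %d nonzero pair energies, offset = %g\n",
              x$n, nrow(x$pairs), x$offset))
  invisible(x)
}

#' @describeIn two_state_system dense symmetric pair-energy matrix
#'   (guarded to `n <= 4000`).
#' @param sys a `two_state_system`.
#' @export
pair_matrix <- function(sys) {
  stopifnot(inherits(sys, "two_state_system"))
  if (sys$n > 4000)
    stopf("dense pair matrix for n = %d would be too large; use sys$pairs", sys$n)
  g <- matrix(0, sys$n, sys$n)
  if (nrow(sys$pairs)) {
    g[cbind(sys$pairs$i, sys$pairs$j)] <- sys$pairs$value
    g[cbind(sys$pairs$j, sys$pairs$i)] <- sys$pairs$value
  }
  g
}

#' @describeIn two_state_system energy of one microstate `x` (0/1
#'   vector of length `n`), including the offset.
#' @param x 0/1 state vector.
#' @export
microstate_energy <- function(sys, x) {
  stopifnot(inherits(sys, "two_state_system"))
  if (length(x) != sys$n || !all(x %in% c(0, 1)))
    stopf("x must be a 0/1 vector of length %d", sys$n)
  e <- sys$offset + sum(sys$self_energy * x)
  if (nrow(sys$pairs))
    e <- e + sum(sys$pairs$value * x[sys$pairs$i] * x[sys$pairs$j])
  e
}

#' Read / write the generic two-state system format
#'
#' Plain UTF-8 TSV with `#` comments and 0-based particle indices:
#' \preformatted{
#' SELF  i  value
#' PAIR  i  j  value
#' OFFSET  value
#' }
#' Unmentioned pair (and self) energies default to 0; a pair mentioned
#' twice -- in either orientation -- is a hard error.  `n` is inferred
#' from the largest index unless given.
#'
#' @param path file path.
#' @param n optional particle count (otherwise inferred).
#' @return `read_two_state_system()` returns a `two_state_system`;
#'   `write_two_state_system()` returns `path` invisibly.
#' @export
read_two_state_system <- function(path, n = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) stopf("no records in %s", path)
  tok <- strsplit(raw, "\t", fixed = TRUE)
  kind <- vapply(tok, `[[`, "", 1L)
  bad <- !kind %in% c("SELF", "PAIR", "OFFSET")
  if (any(bad)) stopf("unknown record type '%s'", kind[bad][1])
  self_i <- integer()
  self_v <- numeric()
  pi <- integer(); pj <- integer(); pv <- numeric()
  offset <- 0
  seen_offset <- FALSE
  for (t in tok) {
    if (t[[1]] == "SELF") {
      if (length(t) != 3L) stopf("malformed SELF record")
      self_i <- c(self_i, as.integer(t[[2]]) + 1L)
      self_v <- c(self_v, as.numeric(t[[3]]))
    } else if (t[[1]] == "PAIR") {
      if (length(t) != 4L) stopf("malformed PAIR record")
      a <- as.integer(t[[2]]) + 1L
      b <- as.integer(t[[3]]) + 1L
      if (a == b) stopf("PAIR record with i == j")
      pi <- c(pi, min(a, b)); pj <- c(pj, max(a, b))
      pv <- c(pv, as.numeric(t[[4]]))
    } else {
      if (length(t) != 2L) stopf("malformed OFFSET record")
      if (seen_offset) stopf("duplicate OFFSET record")
      offset <- as.numeric(t[[2]])
      seen_offset <- TRUE
    }
  }
  if (anyDuplicated(self_i)) stopf("duplicate SELF record")
  if (anyDuplicated(data.frame(pi, pj))) stopf("duplicate PAIR record")
  if (is.null(n)) n <- max(c(self_i, pj, 1L))
  self <- numeric(n)
  self[self_i] <- self_v
  two_state_system(self,
                   pairs = data.frame(i = pi, j = pj, value = pv),
                   offset = offset)
}

#' @rdname read_two_state_system
#' @param sys a `two_state_system`.
#' @export
write_two_state_system <- function(sys, path) {
  stopifnot(inherits(sys, "two_state_system"))
  ln <- c(sprintf("# two-state system: n = %d", sys$n),
          sprintf("OFFSET\t%.17g", sys$offset),
          sprintf("SELF\t%d\t%.17g", seq_len(sys$n) - 1L, sys$self_energy))
  if (nrow(sys$pairs))
    ln <- c(ln, sprintf("PAIR\t%d\t%d\t%.17g", sys$pairs$i - 1L,
                        sys$pairs$j - 1L, sys$pairs$value))
  writeLines(ln, path)
  invisible(path)
}

#' Random heterogeneous test systems
#'
#' Draws a reproducible random `two_state_system`: self energies
#' uniform on \[-1, 1\]; every pair energy equal to `base_pair` plus a
#' zero-mean uniform perturbation of half-width `heterogeneity`.  With
#' `heterogeneity = 0` all pair energies are equal, which is exactly
#' the regime where the direct interaction algorithm is exact -- the
#' generator therefore spans the range from "DIA exact by construction"
#' to strongly heterogeneous interactions as `heterogeneity` grows.
#'
#' @param n particle count (>= 2).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param heterogeneity nonnegative perturbation half-width (energy
#'   units).
#' @param base_pair common base pair energy.
#' @return A `two_state_system` with all `choose(n, 2)` pair energies
#'   set.
#' @export
random_system <- function(n, seed, heterogeneity = 0, base_pair = 0.5) {
  if (n < 2L) stopf("need n >= 2")
  if (heterogeneity < 0) stopf("heterogeneity must be >= 0")
  with_seed(seed, {
    self <- stats::runif(n, -1, 1)
    np <- n * (n - 1L) / 2L
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    val <- base_pair + stats::runif(np, -heterogeneity, heterogeneity)
    two_state_system(self,
                     pairs = data.frame(i = idx[, 1], j = idx[, 2],
                                        value = val))
  })
}
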