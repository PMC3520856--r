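#' Temperature-sweep specification
#'
#' Describes a benchmark run: which lattice sizes, which dimensionless
#' temperature grid, which methods, and the numerical settings.  The
#' default grid (0.5 to 5.0 in steps of 0.1) spans deep sub-critical to
#' strongly super-critical temperatures around the transition at
#' `t* ~ 2.269`.
#'
#' @param sizes integer vector of lattice sides.
#' @param t_min,t_max,t_step dimensionless temperature grid.
#' @param methods subset of `"dia-local"`, `"dia-global"`, `"mc"`,
#'   `"enum"`; the exact baseline is always evaluated.
#' @param dt derivative step for the DIA observables.
#' @param mc_steps named vector mapping size to sweeps (default
#'   [mc_table_presets()]).
#' @param seed integer seed for the MC runs (each (size, temperature)
#'   run gets a distinct sub-seed derived from it).
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(sizes, t_min = 0.5, t_max = 5.0, t_step = 0.1,
                       methods = "dia-local", dt = 1e-3,
                       mc_steps = mc_table_presets(), seed = 1L) {
  if (t_min <= 0 || t_step <= 0 || t_max < t_min)
    stopf("need t_min > 0, t_step > 0, t_max >= t_min")
  bad <- setdiff(methods, c("dia-local", "dia-global", "mc", "enum"))
  if (length(bad)) stopf("unknown method '%s'", bad[1])
  if ("enum" %in% methods && any(sizes > 4))
    stopf("enum is limited to L <= 4")
  structure(list(sizes = as.integer(sizes), t_min = t_min, t_max = t_max,
                 t_step = t_step, methods = methods, dt = dt,
                 mc_steps = mc_steps, seed = as.integer(seed)),
            class = "sweep_spec")
}

sweep_grid <- function(spec) {
  seq(spec$t_min, spec$t_max, by = spec$t_step)
}

#' Root-mean-square error between two series
#'
#' `sqrt(mean((approx - reference)^2))`; the accuracy measure of the
#' benchmark.
#'
#' @param approx,reference equal-length numeric vectors.
#' @export
rms_error <- function(approx, reference) {
  if (length(approx) != length(reference) || length(approx) < 1L)
    stopf("series must have equal length >= 1")
  sqrt(mean((approx - reference)^2))
}

#' Run a temperature sweep and collect RMS errors
#'
#' Evaluates every requested method at each (size, temperature) grid
#' point plus the exact baseline ([exact_thermo()] /
#' [onsager_magnetization()]), and tabulates per-size and pooled RMS
#' errors of each method against the baseline for all three
#' observables.  Deterministic methods are bit-reproducible; MC runs
#' are seeded from `spec$seed`.
#'
#' @param spec a [sweep_spec()].
#' @return A `"bench_report"`: `series` (data frame `method, L,
#'   t_star, m_per_site, u_per_site, cv_per_site`), `rms` (data frame
#'   `method, L, observable, rms`, with `L = NA` for the pooled rows),
#'   and `spec`.
#' @export
temperature_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- sweep_grid(spec)
  obs <- c("m_per_site", "u_per_site", "cv_per_site")
  rows <- list()
  run_counter <- 0L
  for (L in spec$sizes) {
    lat <- build_lattice(L)
    ex <- exact_series(L, grid)
    rows[[length(rows) + 1L]] <- data.frame(method = "exact", L = L, ex)
    for (meth in spec$methods) {
      pts <- lapply(grid, function(ts) {
        if (meth == "dia-local") {
          as.data.frame(dia_thermo(lat, ts, dt = spec$dt, variant = "local"))
        } else if (meth == "dia-global") {
          as.data.frame(dia_thermo(lat, ts, dt = spec$dt, variant = "global"))
        } else if (meth == "enum") {
          as.data.frame(enumerate_thermo(lat, ts))
        } else {
          run_counter <<- run_counter + 1L
          sub_seed <- (spec$seed * 7919L + run_counter * 104729L) %% 2147483647L
          steps <- spec$mc_steps[[as.character(L)]]
          if (is.null(steps)) stopf("no MC sweep preset for L = %d", L)
          mc_run(lat, ts, mc_config(steps, seed = sub_seed))$point |>
            as.data.frame()
        }
      })
      rows[[length(rows) + 1L]] <-
        data.frame(method = meth, L = L, do.call(rbind, pts))
    }
  }
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  rms <- list()
  for (meth in setdiff(unique(series$method), "exact")) {
    for (L in spec$sizes) {
      a <- series[series$method == meth & series$L == L, ]
      b <- series[series$method == "exact" & series$L == L, ]
      for (o in obs)
        rms[[length(rms) + 1L]] <- data.frame(
          method = meth, L = L, observable = o,
          rms = rms_error(a[[o]], b[[o]]))
    }
    a <- series[series$method == meth, ]
    b <- series[series$method == "exact", ]
    a <- a[order(a$L, a$t_star), ]
    b <- b[order(b$L, b$t_star), ]
    for (o in obs)
      rms[[length(rms) + 1L]] <- data.frame(
        method = meth, L = NA_integer_, observable = o,
        rms = rms_error(a[[o]], b[[o]]))
  }
  rms <- if (length(rms)) do.call(rbind, rms) else
    data.frame(method = character(), L = integer(),
               observable = character(), rms = numeric())
  rownames(rms) <- NULL
  structure(list(series = series, rms = rms, spec = spec),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf("<bench_report> sizes {%s}, t* %g..%g step %g\n",
              paste(x$spec$sizes, collapse = ","), x$spec$t_min,
              x$spec$t_max, x$spec$t_step))
  pooled <- x$rms[is.na(x$rms$L), ]
  if (nrow(pooled)) {
    cat("pooled RMS vs exact baseline:\n")
    print(stats::reshape(pooled[, c("method", "observable", "rms")],
                         direction = "wide", idvar = "observable",
                         timevar = "method"), row.names = FALSE)
  }
  invisible(x)
}

#' Pooled accuracy comparison across lattice sizes
#'
#' Runs the full benchmark protocol -- by default lattice sizes 4
#' through 128, the default temperature grid, DIA with merge-level
#' averaging, and the Monte Carlo comparator at the per-size sweep
#' presets -- and reports the pooled RMS error of each method against
#' the exact baseline for magnetization, internal energy, and heat
#' capacity.  Pooling is joint over all (size, temperature) points.
#'
#' @param sizes lattice sides (default `c(4, 8, 16, 32, 64, 128)`).
#' @param methods methods to benchmark (default DIA-local and MC).
#' @param dt DIA derivative step.
#' @param seed MC seed.
#' @param mc_steps per-size sweep budgets.
#' @return A list: `table` (data frame `observable` x method of pooled
#'   RMS errors) and `report` (the underlying `"bench_report"`).
#' @export
reproduce_accuracy_table <- function(sizes = c(4, 8, 16, 32, 64, 128),
                                     methods = c("dia-local", "mc"),
                                     dt = 1e-3, seed = 1L,
                                     mc_steps = mc_table_presets()) {
  spec <- sweep_spec(sizes = sizes, methods = methods, dt = dt,
                     seed = seed, mc_steps = mc_steps)
  rep <- temperature_sweep(spec)
  pooled <- rep$rms[is.na(rep$rms$L), ]
  tab <- stats::reshape(pooled[, c("method", "observable", "rms")],
                        direction = "wide", idvar = "observable",
                        timevar = "method")
  names(tab) <- sub("^rms\\.", "", names(tab))
  rownames(tab) <- NULL
  list(table = tab, report = rep)
}

#' Write a benchmark report to disk
#'
#' One CSV per (method, size) with 17-significant-digit values (so a
#' round trip preserves the series to the last bit that matters for
#' recomputing RMS errors), plus a JSON summary carrying the full
#' configuration and every RMS value.
#'
#' @param report a `"bench_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bench_report <- function(report, dir) {
  stopifnot(inherits(report, "bench_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- report$series
  for (meth in unique(s$method)) {
    for (L in unique(s$L[s$method == meth])) {
      d <- s[s$method == meth & s$L == L,
             c("t_star", "m_per_site", "u_per_site", "cv_per_site")]
      f <- file.path(dir, sprintf("series_%s_L%03d.csv", meth, L))
      lines <- c("t_star,m_per_site,u_per_site,cv_per_site",
                 sprintf("%.17g,%.17g,%.17g,%.17g", d$t_star,
                         d$m_per_site, d$u_per_site, d$cv_per_site))
      writeLines(lines, f)
    }
  }
  sp <- report$spec
  summary <- list(
    config = list(sizes = sp$sizes, t_min = sp$t_min, t_max = sp$t_max,
                  t_step = sp$t_step, methods = sp$methods, dt = sp$dt,
                  mc_steps = as.list(sp$mc_steps), seed = sp$seed),
    rms = report$rms)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read back a series CSV written by [write_bench_report()]
#'
#' @param path CSV path.
#' @return Data frame with the four series columns.
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
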