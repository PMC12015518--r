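# Acquisition feasibility arithmetic: cycle time vs. injection time vs.
# assay density, points per chromatographic peak, and DIA/GPF isolation
# window construction.

#' Worst-case PRM cycle time
#'
#' Injection-time-dominated model: each of the `n_concurrent` scheduled
#' targets costs its maximum ion injection time plus a fixed per-scan
#' overhead, so the worst-case cycle time is
#' `n_concurrent * (max_iit_ms + per_scan_overhead_ms) / 1000` seconds.
#' This is an upper bound: at high load scans rarely fill for the full
#' injection time, and real cycles run faster.
#'
#' @param n_concurrent Number of concurrently scheduled targets (>= 0).
#' @param max_iit_ms Maximum ion injection time per scan, ms.
#' @param per_scan_overhead_ms Fixed per-scan overhead, ms (default 0; about
#'   5 ms is a reasonable allowance for ion routing).
#' @return Worst-case cycle time in seconds.
#' @export
#' @examples
#' cycle_time(10, 200)   # 2 s: the 1 ng, 10-peptides-per-cycle configuration
#' cycle_time(20, 95)    # 1.9 s
cycle_time <- function(n_concurrent, max_iit_ms, per_scan_overhead_ms = 0) {
  stopifnot(n_concurrent >= 0, max_iit_ms >= 0, per_scan_overhead_ms >= 0)
  n_concurrent * (max_iit_ms + per_scan_overhead_ms) / 1000
}

#' Largest maximum ion injection time fitting a cycle-time budget
#'
#' Inverse of [cycle_time()]: the largest whole-millisecond maxIIT such that
#' `n_concurrent` scans (each costing maxIIT plus overhead) complete within
#' `cycle_budget_s`.
#'
#' @param n_concurrent Number of concurrently scheduled targets (>= 1).
#' @param cycle_budget_s Cycle-time budget, seconds.
#' @param per_scan_overhead_ms Fixed per-scan overhead, ms.
#' @return Maximum ion injection time in whole ms.
#' @export
#' @examples
#' max_iit_for_budget(10, 2)      # 200 ms
#' max_iit_for_budget(20, 2, 5)   # 95 ms
max_iit_for_budget <- function(n_concurrent, cycle_budget_s,
                               per_scan_overhead_ms = 0) {
  stopifnot(n_concurrent >= 1, cycle_budget_s > 0, per_scan_overhead_ms >= 0)
  iit <- cycle_budget_s * 1000 / n_concurrent - per_scan_overhead_ms
  if (iit <= 0) {
    stop("cycle budget of ", cycle_budget_s, " s cannot cover the ",
         per_scan_overhead_ms, " ms per-scan overhead for ", n_concurrent,
         " targets")
  }
  floor(iit)
}

#' Points per chromatographic peak
#'
#' @param peak_width_s Chromatographic peak width at base, seconds.
#' @param cycle_time_s Acquisition cycle time, seconds.
#' @return `peak_width_s / cycle_time_s`.
#' @export
#' @examples
#' points_per_peak(15, 2)  # 7.5 for 15 s peaks at a 2 s cycle
points_per_peak <- function(peak_width_s, cycle_time_s) {
  stopifnot(peak_width_s > 0, cycle_time_s > 0)
  peak_width_s / cycle_time_s
}

#' Gas-phase-fractionation DIA isolation windows
#'
#' Tiles `[low_mz, high_mz]` contiguously with windows of `width_mz` Th
#' (default 2, the narrow-window GPF configuration). If the width does not
#' divide the range the final window is truncated and flagged.
#'
#' @param low_mz,high_mz Precursor m/z range bounds, Th, `high_mz > low_mz`.
#' @param width_mz Isolation window width, Th.
#' @return An object of class `isolation_scheme`: data frame `windows` with
#'   columns `center_mz`, `width_mz`, `low_mz`, `high_mz`; `range`; and
#'   logical `truncated`.
#' @export
#' @examples
#' gpf_windows(400, 500)  # 50 windows, centers 401, 403, ..., 499
gpf_windows <- function(low_mz, high_mz, width_mz = 2) {
  if (width_mz <= 0) stop("width_mz must be positive")
  if (high_mz <= low_mz) stop("high_mz must exceed low_mz")
  n <- ceiling((high_mz - low_mz) / width_mz)
  lows <- low_mz + (seq_len(n) - 1) * width_mz
  highs <- pmin(lows + width_mz, high_mz)
  truncated <- highs[n] - lows[n] < width_mz
  windows <- data.frame(
    center_mz = (lows + highs) / 2,
    width_mz = highs - lows,
    low_mz = lows, high_mz = highs
  )
  structure(list(windows = windows, range = c(low_mz, high_mz),
                 truncated = truncated),
            class = "isolation_scheme")
}

#' Combine isolation schemes from several gas-phase fractions
#'
#' @param schemes A list of `isolation_scheme` objects covering adjacent
#'   ranges (e.g. six 100 m/z fractions from 400 to 1000).
#' @return One `isolation_scheme` spanning the union of ranges.
#' @export
combine_schemes <- function(schemes) {
  windows <- do.call(rbind, lapply(schemes, function(s) s$windows))
  windows <- windows[order(windows$low_mz), , drop = FALSE]
  rownames(windows) <- NULL
  structure(list(
    windows = windows,
    range = range(unlist(lapply(schemes, function(s) s$range))),
    truncated = any(vapply(schemes, function(s) s$truncated, logical(1)))
  ), class = "isolation_scheme")
}

#' @export
print.isolation_scheme <- function(x, ...) {
  cat("Isolation scheme:", nrow(x$windows), "windows over",
      sprintf("%.1f-%.1f m/z", x$range[1], x$range[2]), "\n")
  if (x$truncated) cat("  (final window truncated)\n")
  invisible(x)
}

#' Export an isolation scheme as CSV
#'
#' Two columns: `center_mz`, `width_mz`.
#'
#' @param scheme An `isolation_scheme`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isolation_scheme <- function(scheme, path) {
  write.csv(scheme$windows[, c("center_mz", "width_mz")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a dilution series to a reference load
#'
#' Divides every intensity by the intensity at the reference load so the
#' reference maps to 1; used to display linearity of response across input
#' levels on a common scale.
#'
#' @param series Named numeric vector: names are loads, values intensities.
#' @param reference_load The load (name) to scale to 1; must be present with
#'   positive intensity.
#' @return Named numeric vector of scaled intensities.
#' @export
#' @examples
#' normalize_to_reference(c(`500` = 1e6, `50` = 1e5), 500)
normalize_to_reference <- function(series, reference_load) {
  key <- as.character(reference_load)
  if (!key %in% names(series)) {
    stop("reference load ", key, " not present in series")
  }
  ref <- series[[key]]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference intensity must be positive")
  }
  series / ref
}
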