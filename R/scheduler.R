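# Greedy, density-constrained PRM assay builder.
#
# Candidates are visited once in rank order (most intense third fragment
# first). A candidate is accepted iff (a) no time point of its scheduling
# window would exceed the maximum assay density and (b) none of its proteins
# has reached the per-protein peptide cap. "Time point" is continuous: the
# density check is an exact closed-interval overlap maximum, not a grid.

#' Acquisition configuration for PRM scheduling
#'
#' @param max_assay_density Maximum number of concurrently scheduled targets
#'   at any chromatographic time point (the instrument's peptides-per-cycle
#'   budget).
#' @param rt_window_min Scheduling window width, minutes.
#' @param gradient_length_min Gradient length, minutes.
#' @param isolation_width_mz Precursor isolation width, Th (default 2, wide
#'   enough to capture the monoisotopic and +1 isotope).
#' @param max_iit_ms Maximum ion injection time, ms (informational; see
#'   [cycle_time()]).
#' @param cycle_time_budget_s Cycle-time budget, seconds (informational).
#' @param peptides_per_protein_cap After this many peptides of one protein
#'   are scheduled, its remaining candidates are skipped (default 5).
#' @param isolation_offset_mz Offset added to the precursor m/z per unit
#'   charge when centering the isolation window, Th; the default `0.25`
#'   shifts the 2 Th window so it spans the monoisotopic and +1 isotopes.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(max_assay_density,
                               rt_window_min,
                               gradient_length_min = 60,
                               isolation_width_mz = 2,
                               max_iit_ms = NULL,
                               cycle_time_budget_s = NULL,
                               peptides_per_protein_cap = 5L,
                               isolation_offset_mz = 0.25) {
  stopifnot(
    max_assay_density >= 1, rt_window_min > 0, gradient_length_min > 0,
    isolation_width_mz > 0, peptides_per_protein_cap >= 1
  )
  if (rt_window_min > gradient_length_min) {
    stop("rt_window_min must not exceed gradient_length_min")
  }
  structure(list(
    max_assay_density = as.integer(max_assay_density),
    rt_window_min = rt_window_min,
    gradient_length_min = gradient_length_min,
    isolation_width_mz = isolation_width_mz,
    max_iit_ms = max_iit_ms,
    cycle_time_budget_s = cycle_time_budget_s,
    peptides_per_protein_cap = as.integer(peptides_per_protein_cap),
    isolation_offset_mz = isolation_offset_mz
  ), class = "acquisition_config")
}

#' Build a scheduled PRM assay
#'
#' Greedy single-pass scheduler: candidates are visited in rank order and
#' placed in a window of width `rt_window_min` centered on their mapped
#' retention time, clipped to the gradient. A candidate is skipped with
#' reason `density_full` if any time point of its window would exceed
#' `max_assay_density`, with `protein_cap` once one of its proteins has
#' `peptides_per_protein_cap` accepted peptides, and with `out_of_gradient`
#' if its mapped retention time falls outside `[0, gradient_length_min]`.
#' Windows whose retention time lies outside the mapping's anchor range
#' (extrapolated) are widened by the mapping's residual SD on each side.
#'
#' @param cands A `prm_candidates` frame (already ranked and filtered).
#' @param mapping An `rt_mapping`; use [identity_rt_mapping()] to schedule on
#'   library retention times directly.
#' @param config An [acquisition_config()].
#' @return An object of class `assay_schedule` with elements `targets`
#'   (data frame: sequence, charge, precursor m/z, isolation window, window
#'   start/end, rank at selection), `skipped` (sequence, charge, rank,
#'   reason), `config`, and `max_density_reached`.
#' @export
build_schedule <- function(cands, mapping, config) {
  if (!inherits(mapping, "rt_mapping")) {
    stop("mapping must be a fitted rt_mapping (see fit_rt_mapping)")
  }
  if (!inherits(config, "acquisition_config")) {
    stop("config must be an acquisition_config")
  }
  n <- nrow(cands)
  half0 <- config$rt_window_min / 2
  grad <- config$gradient_length_min

  acc_count <- new.env(parent = emptyenv())
  S <- numeric(0); E <- numeric(0)   # accepted window bounds
  tgt_idx <- integer(0)
  tgt_start <- numeric(0); tgt_end <- numeric(0)
  skip_idx <- integer(0); skip_reason <- character(0)

  for (i in seq_len(n)) {
    rt <- cands$retention_time_min[i]
    mrt <- apply_mapping(mapping, rt)
    if (mrt < 0 || mrt > grad) {
      skip_idx <- c(skip_idx, i); skip_reason <- c(skip_reason, "out_of_gradient")
      next
    }
    half <- half0 + if (is_extrapolated(mapping, rt)) mapping$residual_sd else 0
    ws <- max(0, mrt - half)
    we <- min(grad, mrt + half)

    prots <- cands$accessions[[i]]
    counts <- vapply(prots, function(p) {
      if (exists(p, acc_count)) get(p, acc_count) else 0L
    }, integer(1))
    if (any(counts >= config$peptides_per_protein_cap)) {
      skip_idx <- c(skip_idx, i); skip_reason <- c(skip_reason, "protein_cap")
      next
    }

    occ <- max_overlap_in(S, E, ws, we)
    if (occ + 1L > config$max_assay_density) {
      skip_idx <- c(skip_idx, i); skip_reason <- c(skip_reason, "density_full")
      next
    }

    S <- c(S, ws); E <- c(E, we)
    tgt_idx <- c(tgt_idx, i); tgt_start <- c(tgt_start, ws)
    tgt_end <- c(tgt_end, we)
    for (p in prots) {
      assign(p, (if (exists(p, acc_count)) get(p, acc_count) else 0L) + 1L,
             envir = acc_count)
    }
  }

  targets <- data.frame(
    sequence = cands$sequence[tgt_idx],
    charge = cands$charge[tgt_idx],
    precursor_mz = cands$precursor_mz[tgt_idx],
    isolation_center_mz = cands$precursor_mz[tgt_idx] +
      config$isolation_offset_mz / cands$charge[tgt_idx],
    isolation_width_mz = rep(config$isolation_width_mz, length(tgt_idx)),
    window_start = tgt_start,
    window_end = tgt_end,
    rank_at_selection = cands$rank[tgt_idx],
    extrapolated = is_extrapolated(mapping,
                                   cands$retention_time_min[tgt_idx]),
    stringsAsFactors = FALSE
  )
  targets$accessions <- cands$accessions[tgt_idx]
  skipped <- data.frame(
    sequence = cands$sequence[skip_idx],
    charge = cands$charge[skip_idx],
    rank = cands$rank[skip_idx],
    reason = skip_reason,
    stringsAsFactors = FALSE
  )
  prof <- density_profile(targets)
  structure(list(
    targets = targets, skipped = skipped, config = config,
    mapping_method = mapping$method,
    max_density_reached = prof$max
  ), class = "assay_schedule")
}

# Maximum number of accepted closed intervals [S, E] simultaneously
# overlapping any time point of the query window [ws, we]. Evaluated at the
# query start plus every accepted interval start inside the query window;
# the overlap count of closed intervals can only attain its maximum at such
# points.
max_overlap_in <- function(S, E, ws, we) {
  if (!length(S)) return(0L)
  pts <- c(ws, S[S >= ws & S <= we])
  max(vapply(pts, function(p) sum(S <= p & E >= p), numeric(1)))
}

#' Assay-density profile by exact boundary sweep
#'
#' Computes the number of concurrently scheduled targets at every window
#' boundary point. Because scheduling windows are closed intervals, the
#' overlap-count step function attains its maximum at a boundary, so the
#' returned `max` is the true maximum assay density.
#'
#' @param targets The `targets` data frame of an `assay_schedule` (or the
#'   schedule itself).
#' @param resolution Profile algorithm; only `"exact_sweep"` is defined.
#' @return An object of class `density_profile`: data frame `profile` with
#'   columns `time` and `count` (concurrency evaluated at each boundary),
#'   and scalar `max`.
#' @export
density_profile <- function(targets, resolution = c("exact_sweep")) {
  resolution <- match.arg(resolution)
  if (inherits(targets, "assay_schedule")) targets <- targets$targets
  S <- targets$window_start
  E <- targets$window_end
  if (!length(S)) {
    return(structure(list(profile = data.frame(time = numeric(0),
                                               count = integer(0)),
                          max = 0L), class = "density_profile"))
  }
  pts <- sort(unique(c(S, E)))
  cnt <- vapply(pts, function(p) sum(S <= p & E >= p), integer(1))
  structure(list(profile = data.frame(time = pts, count = cnt),
                 max = max(cnt)), class = "density_profile")
}

#' Build one schedule per acquisition tier
#'
#' The one-workday workflow builds several assays from the same candidate
#' bank, each sized to an input level (e.g. 10, 20 and 50 peptides per cycle
#' for 1, 10 and 100 ng on-column). Tiers are independent: every tier starts
#' from the full bank.
#'
#' @param cands A `prm_candidates` frame.
#' @param mapping An `rt_mapping`.
#' @param tiers A list of [acquisition_config()] objects.
#' @return A list of `assay_schedule` objects, one per tier.
#' @export
build_tiered_assays <- function(cands, mapping, tiers) {
  if (!length(tiers)) stop("tiers must be a non-empty list of configs")
  lapply(tiers, function(cfg) build_schedule(cands, mapping, cfg))
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat("PRM assay schedule\n")
  cat("  targets scheduled:", nrow(x$targets), "\n")
  cat("  skipped:", nrow(x$skipped))
  if (nrow(x$skipped)) {
    tab <- table(x$skipped$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n  max assay density reached:", x$max_density_reached,
      "of", x$config$max_assay_density, "\n")
  if (any(x$targets$extrapolated)) {
    cat("  windows widened by RT extrapolation:",
        sum(x$targets$extrapolated), "\n")
  }
  invisible(x)
}

#' @export
plot.assay_schedule <- function(x, ...) {
  prof <- density_profile(x)
  plot(prof$profile$time, prof$profile$count, type = "s",
       xlab = "retention time (min)", ylab = "assay density",
       main = "Scheduled assay density", ...)
  abline(h = x$config$max_assay_density, lty = 2, col = "red")
}

#' Write a scheduled inclusion list
#'
#' Two dialects: `"generic"` (columns `compound`, `mz`, `z`, `t_start_min`,
#' `t_stop_min`, `isolation_width`) and `"thermo"` with the method-editor
#' column names (`Compound`, `m/z`, `z`, `t start (min)`, `t stop (min)`).
#'
#' @param schedule An `assay_schedule`.
#' @param path Output CSV path.
#' @param dialect `"generic"` or `"thermo"`.
#' @return `path`, invisibly.
#' @export
write_inclusion_list <- function(schedule, path,
                                 dialect = c("generic", "thermo")) {
  dialect <- match.arg(dialect)
  t <- schedule$targets
  compound <- paste0(t$sequence, "/", t$charge)
  out <- data.frame(
    compound = compound,
    mz = round(t$isolation_center_mz, 4),
    z = t$charge,
    t_start_min = round(t$window_start, 3),
    t_stop_min = round(t$window_end, 3),
    isolation_width = t$isolation_width_mz,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (dialect == "thermo") {
    names(out) <- c("Compound", "m/z", "z", "t start (min)", "t stop (min)",
                    "Isolation Window (m/z)")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the scheduling report
#'
#' A TSV listing every candidate with its decision (scheduled/skipped),
#' reason, rank, and window, preceded by `#`-prefixed summary lines
#' (targets scheduled, maximum density reached, extrapolated windows,
#' mapping method).
#'
#' @param schedule An `assay_schedule`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_report <- function(schedule, path) {
  t <- schedule$targets
  sched <- data.frame(
    sequence = t$sequence, charge = t$charge, rank = t$rank_at_selection,
    decision = rep_len("scheduled", nrow(t)), reason = rep_len("", nrow(t)),
    window_start = round(t$window_start, 3),
    window_end = round(t$window_end, 3),
    stringsAsFactors = FALSE
  )
  s <- schedule$skipped
  skip <- data.frame(
    sequence = s$sequence, charge = s$charge, rank = s$rank,
    decision = rep_len("skipped", nrow(s)), reason = s$reason,
    window_start = rep_len(NA_real_, nrow(s)),
    window_end = rep_len(NA_real_, nrow(s)),
    stringsAsFactors = FALSE
  )
  all <- rbind(sched, skip)
  all <- all[order(all$rank), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#prmsched_schedule_report_v1",
    paste0("# targets_scheduled=", nrow(t)),
    paste0("# skipped=", nrow(s)),
    paste0("# max_density_reached=", schedule$max_density_reached),
    paste0("# density_cap=", schedule$config$max_assay_density),
    paste0("# extrapolated_windows=", sum(t$extrapolated)),
    paste0("# rt_mapping_method=", schedule$mapping_method)
  ), con)
  write.table(all, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
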