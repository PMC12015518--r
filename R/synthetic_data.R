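# Seeded synthetic-data generators for every input the pipeline consumes.
#
# Each generator draws from its own pseudo-random stream derived from
# (seed, generator name), so adding a generator never perturbs fixtures made
# by another, and the caller's RNG state is left untouched.

stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}

with_stream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(code)
}

#' Synthetic-data configuration
#'
#' Bundles the knobs shared by the generators. Defaults emulate the study
#' conditions the pipeline is designed for: a 60-minute gradient, peptides
#' carrying 3-12 fragment ions, log-normal fragment intensities spanning
#' several orders of magnitude, and anchor noise of about 0.1 min.
#'
#' @param seed Integer seed; fixes all generator outputs bit-for-bit.
#' @param n_proteins,peptides_per_protein Library size.
#' @param gradient_length_min Gradient length, minutes.
#' @param fragment_count_range Inclusive range of fragments per entry; the
#'   lower bound must be >= 3 so every entry is rankable.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment-intensity
#'   parameters (natural-log scale).
#' @param drift_model RT drift for anchor generation: `"none"`, `"affine"`
#'   or `"logistic"`.
#' @param drift_params Named list of drift parameters: `a`, `b` for affine
#'   (`a * t + b`); `amplitude`, `midpoint`, `scale` for logistic warp.
#' @param noise_sd_min Gaussian anchor noise SD, minutes.
#' @param outlier_fraction Fraction of anchors displaced as gross outliers.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_proteins = 50L,
                         peptides_per_protein = 5L,
                         gradient_length_min = 60,
                         fragment_count_range = c(3L, 12L),
                         intensity_meanlog = log(1e4),
                         intensity_sdlog = 1.5,
                         drift_model = c("none", "affine", "logistic"),
                         drift_params = list(a = 1.02, b = 0.3,
                                             amplitude = 2, midpoint = 30,
                                             scale = 8),
                         noise_sd_min = 0.1,
                         outlier_fraction = 0.05) {
  drift_model <- match.arg(drift_model)
  stopifnot(n_proteins >= 1, peptides_per_protein >= 1,
            gradient_length_min > 0, fragment_count_range[1] >= 3,
            fragment_count_range[2] >= fragment_count_range[1],
            noise_sd_min >= 0, outlier_fraction >= 0, outlier_fraction < 1)
  structure(list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    gradient_length_min = gradient_length_min,
    fragment_count_range = as.integer(fragment_count_range),
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    drift_model = drift_model, drift_params = drift_params,
    noise_sd_min = noise_sd_min, outlier_fraction = outlier_fraction
  ), class = "synth_config")
}

random_tryptic_sequence <- function(min_len = 7L, max_len = 20L) {
  # internal residues exclude K/R (no missed cleavages), C-terminus is K or R
  internal <- setdiff(names(RESIDUE_MASS), c("K", "R"))
  len <- sample(min_len:max_len, 1L)
  paste0(paste(sample(internal, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a synthetic translation library
#'
#' Draws `n_proteins * peptides_per_protein` unique tryptic peptide
#' precursors with uniform retention times over the gradient, realistic
#' precursor m/z from residue masses (charge 2 or 3), and per-entry
#' fragment-ion sets with log-normal intensities. The ground-truth table
#' records each entry's true retention time and rank key (third-largest
#' fragment intensity) for downstream recovery tests.
#'
#' @param config A [synth_config()].
#' @return A list: `library` (a `prm_library`) and `truth` (data frame
#'   `sequence`, `charge`, `accession`, `true_rt`, `rank_key`).
#' @export
synth_library <- function(config = synth_config()) {
  with_stream(config$seed, "library", {
    n <- config$n_proteins * config$peptides_per_protein
    seqs <- character(0)
    while (length(seqs) < n) {
      seqs <- unique(c(seqs, replicate(n, random_tryptic_sequence())))
    }
    seqs <- seqs[seq_len(n)]
    acc <- sprintf("SYNP%04d", rep(seq_len(config$n_proteins),
                                   each = config$peptides_per_protein))
    charge <- sample(2:3, n, replace = TRUE)
    mz <- peptide_mz(seqs, charge)
    rt <- runif(n, 0.02, 0.98) * config$gradient_length_min
    fragments <- lapply(seq_len(n), function(i) {
      nf <- sample(config$fragment_count_range[1]:config$fragment_count_range[2],
                   1L)
      data.frame(
        label = paste0("y", seq_len(nf)),
        mz = sort(runif(nf, 200, 1400)),
        intensity = stats::rlnorm(nf, config$intensity_meanlog,
                                  config$intensity_sdlog)
      )
    })
    lib <- prm_library(seqs, charge, mz, rt,
                       accessions = as.list(acc), fragments = fragments)
    rank_key <- vapply(lib$fragments, function(fr) fr$intensity[3], numeric(1))
    list(library = lib,
         truth = data.frame(sequence = seqs, charge = charge,
                            accession = acc, true_rt = rt,
                            rank_key = rank_key,
                            stringsAsFactors = FALSE))
  })
}

drift_function <- function(config) {
  p <- config$drift_params
  switch(config$drift_model,
         none = function(t) t,
         affine = function(t) p$a * t + p$b,
         logistic = function(t) t + p$amplitude /
           (1 + exp(-(t - p$midpoint) / p$scale)))
}

#' Generate synthetic retention-time anchors
#'
#' Anchors are `(library_rt, drift(library_rt) + noise)` pairs with an
#' optional fraction of gross outliers displaced by 5-15 minutes, emulating
#' mis-assigned anchor peptides from a fresh DIA injection.
#'
#' @param config A [synth_config()]; `drift_model`, `noise_sd_min` and
#'   `outlier_fraction` control the generator.
#' @param n_anchors Number of anchors.
#' @return A list: `anchors` (data frame `library_rt`, `observed_rt`),
#'   `drift` (the generating function), and `outlier_idx`.
#' @export
synth_rt_anchors <- function(config = synth_config(), n_anchors = 100L) {
  drift <- drift_function(config)
  with_stream(config$seed, "rt_anchors", {
    x <- sort(runif(n_anchors, 0, config$gradient_length_min))
    y <- drift(x) + rnorm(n_anchors, 0, config$noise_sd_min)
    n_out <- floor(config$outlier_fraction * n_anchors)
    idx <- if (n_out > 0) sample(n_anchors, n_out) else integer(0)
    if (n_out > 0) {
      disp <- sample(c(-1, 1), n_out, replace = TRUE) * runif(n_out, 5, 15)
      moved <- y[idx] + disp
      neg <- moved < 0  # early eluters are displaced upward, never below 0
      moved[neg] <- y[idx][neg] + abs(disp[neg])
      y[idx] <- moved
    }
    y <- pmax(y, 0)
    list(anchors = data.frame(library_rt = x, observed_rt = y),
         drift = drift, outlier_idx = sort(idx))
  })
}

#' Generate a synthetic bilinear calibration curve
#'
#' Intensities follow `max(plateau, slope * ratio)` plus Gaussian noise of
#' SD `plateau_sd` on every replicate: a flat background plateau below the
#' detection limit and a proportional (through-origin) response above it.
#' The analytic intersection of the two segments, `plateau / slope`, is the
#' constructed LoD and is returned in the truth record. The default ratio
#' ladder spans four orders of magnitude in half-decade steps, matching the
#' usual matrix-matched dilution design.
#'
#' @param true_lod Constructed intersection on the ratio axis.
#' @param plateau Plateau (background) intensity.
#' @param plateau_sd Gaussian noise SD applied to every replicate intensity.
#' @param ratios Dilution ratios.
#' @param n_replicates Replicates per ratio.
#' @param slope Linear-segment slope; defaults to `plateau / true_lod` so
#'   the intersection is exactly `true_lod`.
#' @param seed Integer seed.
#' @return A list: `curve` (a [calibration_curve()]) and `truth`
#'   (`true_lod`, `plateau`, `slope`, `plateau_sd`).
#' @export
synth_calibration_curve <- function(true_lod, plateau = 100, plateau_sd = 0,
                                    ratios = 10^seq(-4, 0, by = 0.5),
                                    n_replicates = 3L,
                                    slope = plateau / true_lod,
                                    seed = 1L) {
  stopifnot(true_lod > 0, plateau > 0, plateau_sd >= 0, n_replicates >= 1)
  with_stream(seed, "calibration_curve", {
    rr <- rep(sort(ratios), each = n_replicates)
    mu <- pmax(plateau, slope * rr)
    y <- mu + rnorm(length(rr), 0, plateau_sd)
    y <- pmax(y, plateau * 1e-6)  # intensities stay positive
    list(curve = calibration_curve(rr, y, peptide = "SYNTHETIC/2"),
         truth = list(true_lod = true_lod, plateau = plateau, slope = slope,
                      plateau_sd = plateau_sd))
  })
}

#' Write synthetic anchors in the anchor-table dialect
#'
#' @param anchors Data frame with `library_rt`, `observed_rt`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  out <- data.frame(library_rt_min = anchors$library_rt,
                    observed_rt_min = anchors$observed_rt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calibration curves in the curve-table dialect
#'
#' @param curves A list of `calibration_curve` objects (or one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    key <- if (is.na(cv$peptide)) "PEPTIDE/2" else cv$peptide
    parts <- strsplit(key, "/", fixed = TRUE)[[1]]
    pts <- cv$points
    rep_id <- stats::ave(pts$ratio, pts$ratio, FUN = seq_along)
    data.frame(peptide = parts[1],
               charge = if (length(parts) > 1) as.integer(parts[2]) else 2L,
               ratio = pts$ratio,
               replicate = as.integer(rep_id),
               intensity = pts$intensity, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
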