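# Independent oracles used by the property suites. These deliberately
# re-derive decisions with naive code rather than calling into the package's
# own internals.

# Count of closed intervals [S,E] covering point p.
naive_cover_count <- function(S, E, p) {
  k <- 0L
  for (j in seq_along(S)) {
    if (S[j] <= p && E[j] >= p) k <- k + 1L
  }
  k
}

# Greedy-replay oracle: walks candidates in rank order and re-evaluates the
# density and protein-cap rules from scratch, checking occupancy at every
# interval boundary that falls inside the candidate window.
replay_schedule_oracle <- function(cands, mapping, config) {
  S <- numeric(0); E <- numeric(0)
  counts <- list()
  decision <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    mrt <- apply_mapping(mapping, cands$retention_time_min[i])
    if (mrt < 0 || mrt > config$gradient_length_min) {
      decision[i] <- "out_of_gradient"
      next
    }
    half <- config$rt_window_min / 2
    if (is_extrapolated(mapping, cands$retention_time_min[i])) {
      half <- half + mapping$residual_sd
    }
    ws <- max(0, mrt - half)
    we <- min(config$gradient_length_min, mrt + half)

    over_cap <- FALSE
    for (p in cands$accessions[[i]]) {
      n_now <- if (is.null(counts[[p]])) 0L else counts[[p]]
      if (n_now >= config$peptides_per_protein_cap) over_cap <- TRUE
    }
    if (over_cap) {
      decision[i] <- "protein_cap"
      next
    }

    probe <- c(ws, we, S, E)
    probe <- probe[probe >= ws & probe <= we]
    occ <- 0L
    for (p in probe) occ <- max(occ, sum(S <= p & E >= p))
    if (occ + 1L > config$max_assay_density) {
      decision[i] <- "density_full"
      next
    }

    decision[i] <- "scheduled"
    S <- c(S, ws); E <- c(E, we)
    for (p in cands$accessions[[i]]) {
      counts[[p]] <- (if (is.null(counts[[p]])) 0L else counts[[p]]) + 1L
    }
  }
  decision
}

# Flatten a schedule into the same per-candidate decision vector.
schedule_decisions <- function(cands, schedule) {
  key <- paste(cands$sequence, cands$charge)
  dec <- setNames(rep(NA_character_, nrow(cands)), key)
  dec[paste(schedule$targets$sequence, schedule$targets$charge)] <- "scheduled"
  dec[paste(schedule$skipped$sequence, schedule$skipped$charge)] <-
    schedule$skipped$reason
  unname(dec)
}

# Brute-force maximum overlap of scheduled windows, checking every boundary.
brute_max_density <- function(targets) {
  S <- targets$window_start; E <- targets$window_end
  if (!length(S)) return(0L)
  best <- 0L
  for (p in c(S, E)) best <- max(best, naive_cover_count(S, E, p))
  best
}

# Exhaustive changepoint search for the bilinear LoD fit on log10 axes,
# written as a direct transcription of the model definition.
brute_force_lod <- function(curve) {
  pts <- curve$points
  r <- sort(unique(pts$ratio))
  n <- length(r)
  ybar <- sapply(r, function(ri) mean(pts$intensity[pts$ratio == ri]))
  best_rss <- Inf; best <- NULL
  for (k in 1:(n - 2)) {
    noise <- median(ybar[1:k])
    lx <- log10(r[(k + 1):n]); ly <- log10(ybar[(k + 1):n])
    fit <- lm(ly ~ lx)
    rss <- sum((log10(ybar[1:k]) - log10(noise))^2) + sum(resid(fit)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- list(k = k, noise = noise, coefs = coef(fit))
    }
  }
  lod <- 10^((log10(best$noise) - best$coefs[1]) / best$coefs[2])
  list(k = best$k, lod = unname(lod))
}

# A random scheduling instance built from the synthetic library generator.
random_instance <- function(seed, max_candidates = 500) {
  n_prot <- sample(5:100, 1)
  per <- sample(1:5, 1)
  while (n_prot * per > max_candidates) n_prot <- ceiling(n_prot / 2)
  cfg <- synth_config(seed = seed, n_proteins = n_prot,
                      peptides_per_protein = per)
  lib <- synth_library(cfg)$library
  cands <- rank_candidates(lib)
  acq <- acquisition_config(
    max_assay_density = sample(2:25, 1),
    rt_window_min = runif(1, 1, 8),
    gradient_length_min = 60,
    peptides_per_protein_cap = sample(1:5, 1)
  )
  list(cands = cands, config = acq)
}
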