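# Calibration-curve figures of merit: bilinear LoD/LoQ fits, percent CV and
# all-pairs log2 fold changes.

#' Construct a calibration curve
#'
#' A per-peptide dilution series on the matrix-matched ratio scale: each
#' point is a foreground:background ratio with one or more replicate summed
#' transition intensities.
#'
#' @param ratio Numeric vector of foreground fractions, strictly positive
#'   (repeated across replicates).
#' @param intensity Non-negative replicate intensities, same length.
#' @param peptide Optional peptide/charge label.
#' @return An object of class `calibration_curve`: data frame `points`
#'   sorted by ratio, plus `peptide`.
#' @export
calibration_curve <- function(ratio, intensity, peptide = NA_character_) {
  stopifnot(length(ratio) == length(intensity))
  if (any(ratio <= 0)) stop("ratios must be strictly positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (length(unique(ratio)) < 2) stop("need at least 2 distinct ratios")
  pts <- data.frame(ratio = ratio, intensity = intensity)
  pts <- pts[order(pts$ratio), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(peptide = peptide, points = pts),
            class = "calibration_curve")
}

#' Read calibration curves from TSV
#'
#' Columns: `peptide`, `charge`, `ratio`, `replicate`, `intensity`.
#'
#' @param path Path to the curve TSV.
#' @return Named list of `calibration_curve` objects, one per
#'   peptide/charge.
#' @export
read_curves <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("peptide", "charge", "ratio", "replicate", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("curve file is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("ratio", "intensity")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at row ", bad[1])
    }
    tab[[col]] <- val
  }
  key <- paste0(tab$peptide, "/", tab$charge)
  lapply(split(tab, key), function(d) {
    calibration_curve(d$ratio, d$intensity,
                      peptide = paste0(d$peptide[1], "/", d$charge[1]))
  })
}

#' Fit LoD and LoQ from a bilinear calibration curve
#'
#' Fits the two-segment model underlying matrix-matched figures of merit: a
#' horizontal "maximum line through the noise" at the median intensity of
#' the low-ratio plateau, and a straight line through the linear dynamic
#' range (by default on log10(ratio) vs log10(intensity) axes). Every
#' changepoint along the ordered ratios is evaluated and the split
#' minimizing the total squared residual (on the fitting axes) is chosen.
#' The LoD is the abscissa where the two lines intersect; the LoQ is where
#' the linear fit crosses the noise level plus three standard deviations of
#' the noise. When no usable linear segment exists - fewer than
#' `min_linear_points` points above the changepoint, a non-positive or
#' statistically indistinguishable-from-zero slope, or a segment that never
#' climbs three noise SDs above the plateau - the LoQ (and LoD) are reported
#' as not assignable, mirroring curves that never leave the background.
#'
#' Replicates are averaged within each ratio for segment fitting; all
#' replicates in the noise segment contribute to `noise_sd`.
#'
#' @param curve A [calibration_curve()].
#' @param axes `"log10"` (default) or `"linear"` fitting axes.
#' @param min_linear_points Minimum points in the linear segment (default 3).
#' @return An object of class `fom_fit`: `noise_level`, `noise_sd`,
#'   `linear_slope`, `linear_intercept` (on the fitting axes), `lod`, `loq`
#'   (ratio units; `NA` when not assignable), `loq_assignable`,
#'   `changepoint` (index of the last noise point), `r_squared`, `n_points`,
#'   `axes`, and 3-SD `bands` for both lines.
#' @export
fit_lod_loq <- function(curve, axes = c("log10", "linear"),
                        min_linear_points = 3L) {
  axes <- match.arg(axes)
  stopifnot(inherits(curve, "calibration_curve"))
  pts <- curve$points
  r <- sort(unique(pts$ratio))
  n <- length(r)
  if (n < 4) stop("need at least 4 distinct ratios to fit two segments")
  ybar <- vapply(r, function(ri) mean(pts$intensity[pts$ratio == ri]),
                 numeric(1))
  tx <- if (axes == "log10") log10(r) else r
  ty <- if (axes == "log10") log10(pmax(ybar, .Machine$double.xmin)) else ybar

  best <- NULL
  for (k in seq_len(n - 2L)) {
    noise_level <- median(ybar[seq_len(k)])
    t_noise <- if (axes == "log10") {
      log10(max(noise_level, .Machine$double.xmin))
    } else noise_level
    lin_idx <- (k + 1L):n
    fit <- lm(ty[lin_idx] ~ tx[lin_idx])
    rss <- sum((ty[seq_len(k)] - t_noise)^2) + sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(k = k, rss = rss, fit = fit, noise_level = noise_level,
                   t_noise = t_noise, lin_idx = lin_idx)
    }
  }

  k <- best$k
  noise_level <- best$noise_level
  noise_reps <- pts$intensity[pts$ratio %in% r[seq_len(k)]]
  noise_sd <- if (length(noise_reps) > 1) sd(noise_reps) else 0
  slope <- unname(coef(best$fit)[2])
  intercept <- unname(coef(best$fit)[1])
  n_lin <- length(best$lin_idx)
  lin_resid_sd <- if (n_lin > 2) sd(best$fit$residuals) else 0
  smry <- suppressWarnings(summary(best$fit))  # perfect fits are expected
  r2 <- if (n_lin > 2) smry$r.squared else NA_real_

  # slope distinguishable from zero: positive, significant, and the linear
  # segment must actually climb three noise SDs above the plateau
  slope_p <- if (n_lin > 2 && !is.na(smry$coefficients[2, 4])) {
    smry$coefficients[2, 4]
  } else 1
  rises <- max(ybar[best$lin_idx]) > noise_level + 3 * noise_sd
  assignable <- n_lin >= min_linear_points && slope > 0 &&
    (slope_p < 0.05 || lin_resid_sd == 0) && rises

  if (assignable) {
    t_loq_level <- if (axes == "log10") {
      log10(noise_level + 3 * noise_sd)
    } else noise_level + 3 * noise_sd
    t_lod <- (best$t_noise - intercept) / slope
    t_loq <- (t_loq_level - intercept) / slope
    lod <- if (axes == "log10") 10^t_lod else t_lod
    loq <- if (axes == "log10") 10^t_loq else t_loq
  } else {
    lod <- NA_real_
    loq <- NA_real_
  }

  structure(list(
    peptide = curve$peptide,
    noise_level = noise_level, noise_sd = noise_sd,
    linear_slope = slope, linear_intercept = intercept,
    lod = lod, loq = loq, loq_assignable = assignable,
    changepoint = k, r_squared = r2, n_points = n, axes = axes,
    bands = list(noise = c(lower = noise_level - 3 * noise_sd,
                           upper = noise_level + 3 * noise_sd),
                 linear_sd = lin_resid_sd),
    curve = curve
  ), class = "fom_fit")
}

#' @export
print.fom_fit <- function(x, ...) {
  cat("Calibration-curve figures of merit")
  if (!is.na(x$peptide)) cat(" for", x$peptide)
  cat("\n")
  cat(sprintf("  noise level: %.4g (SD %.4g), %d plateau point(s)\n",
              x$noise_level, x$noise_sd, x$changepoint))
  if (x$loq_assignable) {
    cat(sprintf("  LoD: %.4g  LoQ: %.4g (ratio units)\n", x$lod, x$loq))
    cat(sprintf("  linear segment: slope %.3f, R^2 %.3f (%s axes)\n",
                x$linear_slope, x$r_squared, x$axes))
  } else {
    cat("  LoQ: not assignable (no usable linear segment)\n")
  }
  invisible(x)
}

#' @export
plot.fom_fit <- function(x, ...) {
  pts <- x$curve$points
  plot(pts$ratio, pmax(pts$intensity, .Machine$double.xmin), log = "xy",
       xlab = "foreground:background ratio", ylab = "summed intensity",
       main = if (!is.na(x$peptide)) x$peptide else "calibration curve", ...)
  rr <- range(pts$ratio)
  nb <- x$bands$noise
  polygon(c(rr, rev(rr)),
          pmax(c(nb["lower"], nb["lower"], nb["upper"], nb["upper"]),
               .Machine$double.xmin),
          col = adjustcolor("gold", 0.3), border = NA)
  abline(h = x$noise_level, col = "gold3")
  if (x$loq_assignable && x$axes == "log10") {
    grid_x <- 10^seq(log10(rr[1]), log10(rr[2]), length.out = 50)
    lines(grid_x, 10^(x$linear_intercept + x$linear_slope * log10(grid_x)),
          col = "steelblue")
    points(x$lod, x$noise_level, pch = 21, cex = 1.5, bg = "grey")
    abline(v = x$loq, lty = 3, col = "red")
    abline(h = x$noise_level + 3 * x$noise_sd, lty = 3, col = "red")
  }
}

#' Percent coefficient of variation
#'
#' `100 * sd(values) / mean(values)` (sample SD). Technical-replicate
#' precision below 20 percent CV is the conventional quantitative-rigor
#' threshold.
#'
#' @param values Numeric vector of at least 2 replicate quantities.
#' @return Percent CV; `NA` (with a warning) when the mean is zero.
#' @export
#' @examples
#' percent_cv(c(90, 100, 110))  # 10
percent_cv <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicate values")
  m <- mean(values)
  if (m == 0) {
    warning("mean of replicates is zero; CV undefined")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' All-pairs log2 fold changes between two replicate sets
#'
#' Every replicate of `a` is compared against every replicate of `b`, so two
#' triplicates give the nine pairwise log2 ratios used to display
#' between-condition fold-change spread.
#'
#' @param a,b Positive numeric vectors of replicate quantities.
#' @return Numeric vector of `length(a) * length(b)` log2 ratios.
#' @export
#' @examples
#' all_pairs_log2fc(c(2, 2, 2), c(1, 1, 1))  # nine 1s
all_pairs_log2fc <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("replicate values must be positive")
  as.vector(outer(a, b, function(x, y) log2(x / y)))
}

#' Classify a measured ratio against fitted figures of merit
#'
#' @param measured_ratio Measured foreground:background ratio.
#' @param fom An `fom_fit` from [fit_lod_loq()].
#' @return One of `"above_loq"`, `"between_lod_loq"`, `"below_lod"`,
#'   `"no_loq"`.
#' @export
classify_vs_fom <- function(measured_ratio, fom) {
  stopifnot(inherits(fom, "fom_fit"))
  if (!fom$loq_assignable) return("no_loq")
  if (measured_ratio > fom$loq) return("above_loq")
  if (measured_ratio >= fom$lod) return("between_lod_loq")
  "below_lod"
}

#' Write a figures-of-merit report
#'
#' TSV columns: `peptide`, `lod`, `loq`, `noise_level`, `noise_sd`, `slope`,
#' `r_squared`, `n_points`; `loq` is the string `"not assignable"` where no
#' linear segment was established.
#'
#' @param fits List of `fom_fit` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fom_report <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(
      peptide = if (is.na(f$peptide)) "" else f$peptide,
      lod = if (f$loq_assignable) signif(f$lod, 6) else NA,
      loq = if (f$loq_assignable) as.character(signif(f$loq, 6)) else
        "not assignable",
      noise_level = signif(f$noise_level, 6),
      noise_sd = signif(f$noise_sd, 6),
      slope = signif(f$linear_slope, 6),
      r_squared = signif(f$r_squared, 6),
      n_points = f$n_points,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#prmsched_fom_report_v1", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
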