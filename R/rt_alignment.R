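# Retention-time re-calibration: map library RTs onto the current LC column
# conditions using anchor pairs from a recently acquired DIA injection.

#' Read an anchor table
#'
#' Two-column TSV with header `library_rt_min`, `observed_rt_min`.
#'
#' @param path Path to the anchor TSV.
#' @return Data frame with columns `library_rt` and `observed_rt` (minutes).
#' @export
read_anchors <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("library_rt_min", "observed_rt_min")
  if (!all(need %in% names(tab))) {
    stop("anchor file must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(library_rt = as.numeric(tab$library_rt_min),
             observed_rt = as.numeric(tab$observed_rt_min))
}

#' Fit a retention-time mapping from anchors
#'
#' Maps library retention times onto observed times from a recent DIA
#' injection so the schedule reflects current column conditions. Gross
#' outlier anchors are rejected by iterative trimming at `mad_mult` times the
#' MAD of the residuals (at most `max_rounds` rounds). Two mapping families
#' are available:
#'
#' * `"monotone_smooth"` (default): a monotone piecewise-cubic interpolant
#'   through bin medians (bin width `bin_width` minutes on the library-RT
#'   axis); medians are isotonised first so the mapping is non-decreasing by
#'   construction. Requires at least 10 anchors.
#' * `"linear"`: ordinary least squares; requires at least 2 anchors.
#'
#' Outside the fitted knot range the mapping extrapolates linearly from the
#' terminal two knots, and [build_schedule()] widens windows that touch the
#' extrapolated region.
#'
#' @param anchors Data frame with columns `library_rt`, `observed_rt`
#'   (minutes), both finite and non-negative.
#' @param method `"monotone_smooth"` or `"linear"`.
#' @param bin_width Bin width in minutes for the monotone smoother.
#' @param mad_mult,max_rounds Outlier-trimming controls.
#' @return An object of class `rt_mapping` with elements `knots` (data frame
#'   `library_rt`, `mapped_rt`), `residual_sd` (minutes, on retained
#'   anchors), `anchors_used`, `anchors_rejected`, `method` and `range`.
#' @export
#' @examples
#' a <- data.frame(library_rt = 1:20, observed_rt = 1:20 + 0.5)
#' m <- fit_rt_mapping(a, method = "linear")
#' apply_mapping(m, 10)  # 10.5
fit_rt_mapping <- function(anchors,
                           method = c("monotone_smooth", "linear"),
                           bin_width = 2, mad_mult = 3, max_rounds = 5) {
  method <- match.arg(method)
  x <- as.numeric(anchors$library_rt)
  y <- as.numeric(anchors$observed_rt)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0) || any(y < 0)) {
    stop("anchors must be finite and >= 0")
  }
  n_min <- if (method == "linear") 2L else 10L
  if (length(x) < n_min) {
    stop("need at least ", n_min, " anchors for method '", method, "'")
  }
  if (diff(range(x)) == 0) stop("degenerate anchors: all library_rt identical")

  # Outliers are trimmed against a straight-line prefit: gross anchor
  # mis-assignments sit minutes off the trend while genuine drift curvature
  # is sub-minute, so the line separates them cleanly, whereas a fine
  # interpolant would chase the very anchors it should reject.
  keep <- rep(TRUE, length(x))
  for (round in seq_len(max_rounds)) {
    fit <- fit_rt_core(x[keep], y[keep], "linear", bin_width)
    resid <- y[keep] - fit$fun(x[keep])
    scale <- mad(resid)
    if (scale == 0) break
    out <- abs(resid) > mad_mult * scale
    if (!any(out)) break
    if (sum(keep) - sum(out) < n_min) break
    keep[keep][out] <- FALSE
  }
  fit <- fit_rt_core(x[keep], y[keep], method, bin_width)
  resid <- y[keep] - fit$fun(x[keep])
  structure(list(
    method = method,
    knots = fit$knots,
    fun = fit$fun,
    residual_sd = if (length(resid) > 1) sd(resid) else 0,
    anchors_used = sum(keep),
    anchors_rejected = sum(!keep),
    range = range(fit$knots$library_rt)
  ), class = "rt_mapping")
}

fit_rt_core <- function(x, y, method, bin_width) {
  if (method == "linear") {
    fit <- lm(y ~ x)
    kx <- range(x)
    ky <- unname(coef(fit)[1] + coef(fit)[2] * kx)
    if (ky[2] < ky[1]) {  # pathological decreasing fit: flatten
      ky <- rep(mean(y), 2)
    }
    knots <- data.frame(library_rt = kx, mapped_rt = ky)
  } else {
    breaks <- seq(min(x), max(x) + bin_width, by = bin_width)
    bin <- cut(x, breaks, include.lowest = TRUE, right = FALSE)
    kx <- as.numeric(tapply(x, bin, median))
    ky <- as.numeric(tapply(y, bin, median))
    ok <- !is.na(kx)
    kx <- kx[ok]; ky <- ky[ok]
    if (length(kx) < 2) {
      stop("too few occupied retention-time bins for monotone_smooth; ",
           "reduce bin_width or use method = 'linear'")
    }
    ky <- isoreg(kx, ky)$yf  # enforce non-decreasing knot ordinates
    knots <- data.frame(library_rt = kx, mapped_rt = ky)
  }
  list(knots = knots, fun = make_mapping_fun(knots))
}

make_mapping_fun <- function(knots) {
  kx <- knots$library_rt
  ky <- knots$mapped_rt
  # Hyman-filtered cubic needs strictly increasing ordinates; with ties
  # (flat isotonic stretches) piecewise-linear interpolation is used, which
  # is equally monotone.
  inner <- if (length(kx) > 2 && all(diff(ky) > 0)) {
    splinefun(kx, ky, method = "hyman")
  } else {
    stats::approxfun(kx, ky, rule = 2)
  }
  slope_lo <- (ky[2] - ky[1]) / (kx[2] - kx[1])
  m <- length(kx)
  slope_hi <- (ky[m] - ky[m - 1]) / (kx[m] - kx[m - 1])
  function(t) {
    out <- numeric(length(t))
    lo <- t < kx[1]
    hi <- t > kx[m]
    mid <- !lo & !hi
    if (any(mid)) out[mid] <- inner(t[mid])
    if (any(lo)) out[lo] <- ky[1] + slope_lo * (t[lo] - kx[1])
    if (any(hi)) out[hi] <- ky[m] + slope_hi * (t[hi] - kx[m])
    out
  }
}

#' Apply a fitted retention-time mapping
#'
#' Inside the knot range the mapping interpolates; outside it extrapolates
#' linearly from the terminal two knots (see [is_extrapolated()]).
#'
#' @param mapping An `rt_mapping` from [fit_rt_mapping()] or
#'   [identity_rt_mapping()].
#' @param rt Numeric vector of library retention times (minutes).
#' @return Mapped retention times (minutes).
#' @export
apply_mapping <- function(mapping, rt) {
  stopifnot(inherits(mapping, "rt_mapping"))
  mapping$fun(rt)
}

#' @export
predict.rt_mapping <- function(object, newdata, ...) {
  apply_mapping(object, newdata)
}

#' Does a retention time fall outside the fitted anchor range?
#'
#' @inheritParams apply_mapping
#' @return Logical vector; `TRUE` where the mapping extrapolates.
#' @export
is_extrapolated <- function(mapping, rt) {
  rt < mapping$range[1] | rt > mapping$range[2]
}

#' Identity retention-time mapping
#'
#' Used when no fresh DIA injection is available: library retention times are
#' taken as-is.
#'
#' @param gradient_length_min Gradient length (minutes), defining the knot
#'   range.
#' @return An `rt_mapping` with `mapped_rt == library_rt` and
#'   `residual_sd = 0`.
#' @export
identity_rt_mapping <- function(gradient_length_min = 60) {
  knots <- data.frame(library_rt = c(0, gradient_length_min),
                      mapped_rt = c(0, gradient_length_min))
  structure(list(
    method = "identity", knots = knots, fun = make_mapping_fun(knots),
    residual_sd = 0, anchors_used = 0L, anchors_rejected = 0L,
    range = c(0, gradient_length_min)
  ), class = "rt_mapping")
}

#' @export
print.rt_mapping <- function(x, ...) {
  cat("Retention-time mapping (", x$method, ")\n", sep = "")
  cat("  anchors used:", x$anchors_used,
      " rejected:", x$anchors_rejected, "\n")
  cat("  residual SD:", sprintf("%.3f min", x$residual_sd), "\n")
  cat("  knot range:", sprintf("%.2f-%.2f min", x$range[1], x$range[2]), "\n")
  invisible(x)
}
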