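# Dimethyl-labeled matrix-matched background design.
#
# A matrix-matched calibration curve dilutes the unlabeled (foreground)
# proteome into a chemically identical background whose free amines
# (N-terminus and lysines) carry dimethyl labels. Each complete label adds
# two methyl groups (+28 Da nominal); even a single residual methyl shifts
# the precursor far enough in m/z to leave the narrow PRM isolation window,
# so background never bleeds into foreground signal.

#' Dimethyl labeling scheme
#'
#' @param type `"exact"` uses monoisotopic masses (14.01565 Da per methyl,
#'   28.0313 Da per complete label); `"nominal"` uses the rounded +28 Da /
#'   +14 Da figures for display.
#' @return An object of class `labeling_scheme` with `label_mass_da`,
#'   `partial_mass_da` and the site rule (one label per free amine:
#'   N-terminus plus each lysine).
#' @export
labeling_scheme <- function(type = c("exact", "nominal")) {
  type <- match.arg(type)
  if (type == "exact") {
    structure(list(type = type, label_mass_da = 2 * MASS_METHYL,
                   partial_mass_da = MASS_METHYL),
              class = "labeling_scheme")
  } else {
    structure(list(type = type, label_mass_da = 28, partial_mass_da = 14),
              class = "labeling_scheme")
  }
}

#' Count dimethyl labeling sites on a peptide
#'
#' Free amines: the peptide N-terminus plus every lysine residue.
#'
#' @param sequence Peptide string (bracketed modifications ignored).
#' @return Integer count of labeling sites.
#' @export
#' @examples
#' count_label_sites("PEPTIDER")  # 1 (N-terminus only)
#' count_label_sites("PEPTIDEK")  # 2
count_label_sites <- function(sequence) {
  plain <- strip_modifications(sequence)
  1L + vapply(strsplit(plain, ""), function(ch) sum(ch == "K"), integer(1))
}

#' Precursor m/z shift of a (possibly partially) labeled form
#'
#' A background peptide with `n_methyl_groups` attached methyls (from 1, a
#' single incomplete reaction, up to twice the number of labeling sites)
#' shifts in m/z by `n_methyl_groups * partial_mass_da / charge`.
#'
#' @param entry A library entry row or any list with `sequence` and `charge`.
#' @param n_methyl_groups Number of attached methyl groups.
#' @param scheme A [labeling_scheme()].
#' @return m/z shift in Th.
#' @export
labeled_mz_shift <- function(entry, n_methyl_groups,
                             scheme = labeling_scheme()) {
  sites <- count_label_sites(entry$sequence)
  if (n_methyl_groups < 1 || n_methyl_groups > 2L * sites) {
    stop("n_methyl_groups must be in [1, ", 2L * sites,
         "] for this peptide (unlabeled forms are foreground)")
  }
  n_methyl_groups * scheme$partial_mass_da / entry$charge
}

#' Check that all labeled forms fall outside the PRM isolation window
#'
#' For every labeled form of a background peptide (1 methyl group up to full
#' labeling) the check computes the distance of the labeled precursor m/z
#' from the scheduled isolation-window center (which sits
#' `isolation_offset_mz / charge` above the unlabeled precursor m/z, see
#' [acquisition_config()]). The background is cleanly excluded when the
#' smallest such distance exceeds the window half-width.
#'
#' @param entry A library entry row or list with `sequence`, `charge` and
#'   `precursor_mz`.
#' @param scheme A [labeling_scheme()].
#' @param isolation_width_mz Isolation window width, Th (default 2).
#' @param isolation_offset_mz Window-centering offset per unit charge, Th.
#' @return An object of class `collision_check`: `min_shift_mz` (minimum
#'   distance of any labeled form from the window center, Th),
#'   `window_halfwidth_mz`, and logical `excluded`
#'   (`min_shift_mz > window_halfwidth_mz`).
#' @export
check_background_exclusion <- function(entry, scheme = labeling_scheme(),
                                       isolation_width_mz = 2,
                                       isolation_offset_mz = 0.25) {
  stopifnot(entry$charge >= 1, entry$charge <= 8)
  sites <- count_label_sites(entry$sequence)
  n_forms <- seq_len(2L * sites)
  shifts <- n_forms * scheme$partial_mass_da / entry$charge
  center_offset <- isolation_offset_mz / entry$charge
  dist <- abs(shifts - center_offset)
  halfwidth <- isolation_width_mz / 2
  structure(list(
    sequence = entry$sequence, charge = entry$charge,
    n_sites = sites,
    min_shift_mz = min(dist),
    window_halfwidth_mz = halfwidth,
    excluded = min(dist) > halfwidth
  ), class = "collision_check")
}

#' @export
print.collision_check <- function(x, ...) {
  cat(sprintf("%s/%d: %d labeling site(s), min labeled-form distance %.3f Th",
              x$sequence, x$charge, x$n_sites, x$min_shift_mz),
      "from window center;",
      if (x$excluded) "background excluded" else "POSSIBLE COLLISION", "\n")
  invisible(x)
}

#' Plan a matrix-matched dilution series
#'
#' For each foreground:background ratio, the foreground (unlabeled) and
#' background (dimethyl-labeled) amounts are chosen so every point loads the
#' same total amount on-column - the constant-matrix property that keeps
#' background interference fixed across the curve.
#'
#' @param ratios Foreground fractions in `(0, 1]` (e.g. `c(1, 0.1, 0.01)`).
#' @param total_load Total on-column load per point (same units throughout,
#'   typically ng).
#' @return Data frame with columns `ratio`, `foreground`, `background`; rows
#'   sum to `total_load`.
#' @export
#' @examples
#' plan_matrix_curve(c(1, 0.1, 0.01), total_load = 1)
plan_matrix_curve <- function(ratios, total_load) {
  if (any(ratios <= 0) || any(ratios > 1)) {
    stop("ratios must lie in (0, 1]")
  }
  if (total_load <= 0) stop("total_load must be positive")
  data.frame(
    ratio = ratios,
    foreground = ratios * total_load,
    background = (1 - ratios) * total_load
  )
}

#' Write a matrix-curve mixing table
#'
#' CSV columns: `ratio`, `foreground_ng`, `background_ng`.
#'
#' @param plan Output of [plan_matrix_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixing_table <- function(plan, path) {
  out <- data.frame(ratio = plan$ratio, foreground_ng = plan$foreground,
                    background_ng = plan$background)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
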