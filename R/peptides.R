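# Peptide mass arithmetic shared by the synthetic generator and the
# dimethyl-background collision checks.

# Monoisotopic residue masses (Da). Cysteine is the bare residue; fixed
# carbamidomethylation is carried explicitly as a bracketed modification.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_METHYL <- 14.01565          # per single methyl group (CH2)
MASS_CARBAMIDOMETHYL <- 57.02146

#' Strip bracketed modification masses from a peptide string
#'
#' Modified sequences use bracketed delta masses after the residue, e.g.
#' `"C[+57.0215]PEPTIDEK"`. This returns the plain residue string.
#'
#' @param sequence Character vector of (possibly modified) peptide strings.
#' @return Character vector of unmodified residue strings.
#' @export
#' @examples
#' strip_modifications("C[+57.0215]PEPTIDEK")
strip_modifications <- function(sequence) {
  gsub("\\[[^]]*\\]", "", sequence)
}

#' Monoisotopic peptide mass and precursor m/z
#'
#' Computes the neutral monoisotopic mass of a peptide (residues plus water
#' plus any bracketed modification masses) and, for `peptide_mz`, the m/z of
#' the protonated precursor at a given charge.
#'
#' @param sequence Peptide string; upper-case residues with optional bracketed
#'   modification masses (e.g. `"C[+57.0215]"`).
#' @param charge Positive integer precursor charge.
#' @return Neutral mass in Da (`peptide_mass`) or precursor m/z in Th
#'   (`peptide_mz`).
#' @export
#' @examples
#' peptide_mass("PEPTIDEK")
#' peptide_mz("PEPTIDEK", charge = 2)
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    mods <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    delta <- if (length(mods)) {
      sum(as.numeric(gsub("[][+]", "", mods)))
    } else 0
    plain <- strip_modifications(s)
    resid <- strsplit(plain, "")[[1]]
    unknown <- setdiff(resid, names(RESIDUE_MASS))
    if (length(unknown)) {
      stop("unknown residue(s) in '", s, "': ",
           paste(unknown, collapse = ", "))
    }
    sum(RESIDUE_MASS[resid]) + MASS_WATER + delta
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname peptide_mass
#' @export
peptide_mz <- function(sequence, charge) {
  stopifnot(all(charge >= 1), all(charge == round(charge)))
  (peptide_mass(sequence) + charge * MASS_PROTON) / charge
}
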