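# Translation-library domain model: loading, validation, ranking and
# filtering of candidate peptide precursors.

#' Construct a translation library
#'
#' A translation library is a data frame with one row per peptide precursor
#' and list-columns for fragment ions and protein accessions. Fragment lists
#' are re-sorted by descending intensity on construction so that the ranking
#' convention (third-largest fragment) is well defined.
#'
#' @param sequence Character vector of peptide strings (bracketed modification
#'   masses allowed, e.g. `"C[+57.0215]"`).
#' @param charge Integer precursor charges in `[1, 8]`.
#' @param precursor_mz Precursor m/z in Th, positive.
#' @param retention_time_min Retention time on the library gradient, minutes,
#'   non-negative.
#' @param accessions List of non-empty character vectors of protein
#'   accessions (one vector per entry).
#' @param fragments List of data frames with columns `label`, `mz`,
#'   `intensity` (one per entry); `mz > 0`, `intensity >= 0`.
#' @param source Library provenance, one of `"dia"`, `"dda"`, `"predicted"`.
#' @return A data frame of class `prm_library`.
#' @export
prm_library <- function(sequence, charge, precursor_mz, retention_time_min,
                        accessions, fragments,
                        source = "dia") {
  n <- length(sequence)
  charge <- as.integer(charge)
  stopifnot(
    length(charge) == n, length(precursor_mz) == n,
    length(retention_time_min) == n,
    length(accessions) == n, length(fragments) == n
  )
  source <- rep_len(source, n)
  if (n > 0) {
    if (any(charge < 1L | charge > 8L)) {
      stop("charge must be in [1, 8]")
    }
    if (any(precursor_mz <= 0)) stop("precursor_mz must be positive")
    if (any(retention_time_min < 0)) stop("retention_time_min must be >= 0")
    if (any(!vapply(accessions, length, 1L))) {
      stop("every entry needs at least one protein accession")
    }
    if (any(!source %in% c("dia", "dda", "predicted"))) {
      stop("source must be one of 'dia', 'dda', 'predicted'")
    }
    fragments <- lapply(fragments, function(fr) {
      fr <- as.data.frame(fr)
      stopifnot(all(c("label", "mz", "intensity") %in% names(fr)))
      if (any(fr$mz <= 0) || any(fr$intensity < 0)) {
        stop("fragment mz must be > 0 and intensity >= 0")
      }
      fr[order(-fr$intensity), c("label", "mz", "intensity"), drop = FALSE]
    })
  }
  out <- data.frame(
    sequence = as.character(sequence),
    charge = charge,
    precursor_mz = as.numeric(precursor_mz),
    retention_time_min = as.numeric(retention_time_min),
    source = source,
    stringsAsFactors = FALSE
  )
  out$accessions <- accessions
  out$fragments <- fragments
  class(out) <- c("prm_library", "data.frame")
  out
}

LIBRARY_COLUMNS <- c("sequence", "charge", "precursor_mz",
                     "retention_time_min", "accessions", "fragments")

#' Load a translation library from TSV
#'
#' Reads the package's versioned translation-library dialect: a tab-separated
#' table with header columns `sequence`, `charge`, `precursor_mz`,
#' `retention_time_min`, `accessions` (semicolon-separated) and `fragments`
#' (semicolon-separated `label:mz:intensity` triples). Lines starting with
#' `#` (including the `#prmsched_library_v1` version stamp written by
#' [write_library()]) are ignored. Duplicate (sequence, charge) pairs are
#' collapsed, keeping the row with the larger total fragment intensity.
#'
#' @param path Path to the TSV file.
#' @param dialect Input dialect; only `"prmsched"` is currently defined.
#' @return A `prm_library` (see [prm_library()]).
#' @export
load_library <- function(path, dialect = c("prmsched")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("library file not found: ", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  missing_cols <- setdiff(setdiff(LIBRARY_COLUMNS, "source"), names(tab))
  if (length(missing_cols)) {
    stop("library file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("charge", "precursor_mz", "retention_time_min")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " at row ", bad[1], ": '",
           tab[[col]][bad[1]], "'")
    }
    tab[[col]] <- val
  }
  fragments <- lapply(seq_len(nrow(tab)), function(i) {
    parse_fragment_field(tab$fragments[i], row = i)
  })
  accessions <- strsplit(as.character(tab$accessions), ";", fixed = TRUE)
  src <- if ("source" %in% names(tab)) tab$source else "dia"
  lib <- prm_library(tab$sequence, tab$charge, tab$precursor_mz,
                     tab$retention_time_min, accessions, fragments, src)
  dedupe_library(lib)
}

parse_fragment_field <- function(field, row) {
  triples <- strsplit(as.character(field), ";", fixed = TRUE)[[1]]
  triples <- triples[nzchar(triples)]
  parts <- strsplit(triples, ":", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("malformed fragment triple at row ", row, ": expected label:mz:intensity")
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  if (anyNA(mz) || anyNA(int)) {
    stop("non-numeric fragment m/z or intensity at row ", row)
  }
  data.frame(label = vapply(parts, `[`, "", 1), mz = mz, intensity = int,
             stringsAsFactors = FALSE)
}

# Collapse duplicate (sequence, charge) pairs, keeping the row whose
# fragments carry the larger summed intensity.
dedupe_library <- function(lib) {
  key <- paste(lib$sequence, lib$charge, sep = "/")
  if (!anyDuplicated(key)) return(lib)
  total <- vapply(lib$fragments, function(fr) sum(fr$intensity), numeric(1))
  keep <- unlist(lapply(split(seq_len(nrow(lib)), key), function(idx) {
    idx[which.max(total[idx])]
  }), use.names = FALSE)
  out <- lib[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(lib)
  out
}

#' Write a translation library to TSV
#'
#' Serialises a `prm_library` in the same dialect [load_library()] reads,
#' with a `#prmsched_library_v1` version stamp as the first line.
#'
#' @param lib A `prm_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  frag_str <- vapply(lib$fragments, function(fr) {
    paste(sprintf("%s:%.5f:%.6g", fr$label, fr$mz, fr$intensity),
          collapse = ";")
  }, character(1))
  acc_str <- vapply(lib$accessions, paste, character(1), collapse = ";")
  flat <- data.frame(
    sequence = lib$sequence, charge = lib$charge,
    precursor_mz = lib$precursor_mz,
    retention_time_min = lib$retention_time_min,
    accessions = acc_str, fragments = frag_str, source = lib$source,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#prmsched_library_v1", con)
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.prm_library <- function(x, ...) {
  cat("Translation library:", nrow(x), "precursors,",
      length(unique(unlist(x$accessions))), "proteins\n")
  if (nrow(x)) {
    cat("  RT range:", sprintf("%.2f-%.2f min", min(x$retention_time_min),
                               max(x$retention_time_min)), "\n")
    cat("  charges:", paste(sort(unique(x$charge)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank library entries by their third-largest fragment ion
#'
#' Implements the PRM candidate-ordering convention: entries are scored by
#' the intensity of their third-largest fragment (so that at least three
#' quantifiable transitions back the score) and sorted in descending order.
#' Entries with fewer than `min_fragments` fragment ions are dropped. Ties
#' are broken by descending total fragment intensity, then ascending
#' precursor m/z, then sequence, so ranking is fully deterministic.
#'
#' @param entries A `prm_library`.
#' @param min_fragments Minimum fragment count per entry; must be >= 3.
#' @return A `prm_candidates` data frame: the surviving library rows plus
#'   `rank_key` (third-largest fragment intensity), `proteotypic` (maps to
#'   exactly one accession) and `rank` (1 = scheduled first).
#' @export
rank_candidates <- function(entries, min_fragments = 3L) {
  if (min_fragments < 3) stop("min_fragments must be >= 3")
  n_frag <- vapply(entries$fragments, nrow, integer(1))
  keep <- entries[n_frag >= min_fragments, , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- keep
    out$rank_key <- numeric(0)
    out$proteotypic <- logical(0)
    out$rank <- integer(0)
    class(out) <- c("prm_candidates", "data.frame")
    return(out)
  }
  # fragments are stored sorted descending, so element 3 is the rank key
  rank_key <- vapply(keep$fragments, function(fr) fr$intensity[3], numeric(1))
  total <- vapply(keep$fragments, function(fr) sum(fr$intensity), numeric(1))
  ord <- order(-rank_key, -total, keep$precursor_mz, keep$sequence)
  out <- keep[ord, , drop = FALSE]
  out$rank_key <- rank_key[ord]
  out$proteotypic <- lengths(out$accessions) == 1L
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prm_candidates", "data.frame")
  out
}

#' Filter and re-stratify ranked candidates
#'
#' Applies the assay-modification rules: peptides on the exclusion list are
#' removed outright; candidates are restricted to a set of target protein
#' accessions; shared (non-proteotypic) peptides are optionally removed; and
#' peptides on the inclusion list are promoted ahead of all others while rank
#' order is preserved within each stratum. Sequences on the lists may be
#' given with or without bracketed modification masses.
#'
#' @param cands A `prm_candidates` frame from [rank_candidates()].
#' @param target_accessions Character vector of protein accessions to keep,
#'   or `NULL` to keep all proteins.
#' @param include_peptides,exclude_peptides Character vectors of peptide
#'   sequences; a sequence present in both is an error.
#' @param proteotypic_only Drop peptides mapping to more than one accession
#'   (default `TRUE`, the conservative SRM/PRM convention).
#' @return A `prm_candidates` frame with `rank` renumbered 1..n.
#' @export
filter_candidates <- function(cands, target_accessions = NULL,
                              include_peptides = character(),
                              exclude_peptides = character(),
                              proteotypic_only = TRUE) {
  both <- intersect(normalize_pep(include_peptides),
                    normalize_pep(exclude_peptides))
  if (length(both)) {
    stop("peptide(s) present in both include and exclude lists: ",
         paste(both, collapse = ", "))
  }
  plain <- normalize_pep(cands$sequence)
  keep <- !(plain %in% normalize_pep(exclude_peptides))
  if (!is.null(target_accessions) && length(target_accessions)) {
    keep <- keep & vapply(cands$accessions, function(a) {
      any(a %in% target_accessions)
    }, logical(1))
  }
  if (proteotypic_only) keep <- keep & cands$proteotypic
  out <- cands[keep, , drop = FALSE]
  promoted <- normalize_pep(out$sequence) %in% normalize_pep(include_peptides)
  out <- out[order(!promoted), , drop = FALSE]  # stable: promoted first
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prm_candidates", "data.frame")
  out
}

normalize_pep <- function(x) strip_modifications(trimws(x))

#' Read a peptide inclusion/exclusion list
#'
#' One peptide sequence per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of sequences.
#' @export
read_peptide_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' In-silico tryptic digest of a FASTA database
#'
#' Cleaves every protein after K or R not followed by P (trypsin `[KR|P]`),
#' allowing up to `missed_cleavages` missed sites, and retains peptides whose
#' length lies in `[min_len, max_len]`. UniProt-style headers
#' (`db|ACCESSION|NAME`) contribute the accession token; otherwise the first
#' whitespace-delimited word of the header is used.
#'
#' @param fasta Path to a protein FASTA file.
#' @param missed_cleavages Maximum missed cleavage sites, in `[0, 3]`.
#' @param min_len,max_len Peptide length bounds (defaults 7 and 40).
#' @return A named list mapping each peptide sequence to the character vector
#'   of accessions containing it.
#' @export
digest_fasta <- function(fasta, missed_cleavages = 2L, min_len = 7L,
                         max_len = 40L) {
  if (missed_cleavages < 0 || missed_cleavages > 3) {
    stop("missed_cleavages must be in [0, 3]")
  }
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta),
                   error = function(e) stop("unreadable FASTA: ",
                                            conditionMessage(e)))
  accs <- vapply(names(seqs), parse_fasta_accession, character(1),
                 USE.NAMES = FALSE)
  pep2acc <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    peps <- tryptic_peptides(as.character(seqs[[i]]), missed_cleavages,
                             min_len, max_len)
    for (p in peps) {
      assign(p, unique(c(if (exists(p, pep2acc)) get(p, pep2acc), accs[i])),
             envir = pep2acc)
    }
  }
  as.list(pep2acc)
}

parse_fasta_accession <- function(header) {
  first <- strsplit(header, "\\s+")[[1]][1]
  parts <- strsplit(first, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2) parts[2] else first
}

tryptic_peptides <- function(sequence, missed_cleavages, min_len, max_len) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage after position i when residue i is K/R and i+1 is not P
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n & chars[pmin(sites + 1L, n)] != "P" | sites == n]
  bounds <- c(0L, sites, if (!n %in% sites) n)
  bounds <- unique(bounds)
  out <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    for (mc in 0:missed_cleavages) {
      j <- i + 1L + mc
      if (j > length(bounds)) break
      len <- bounds[j] - bounds[i]
      if (len >= min_len && len <= max_len) {
        out <- c(out, substr(sequence, bounds[i] + 1L, bounds[j]))
      }
    }
  }
  unique(out)
}
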