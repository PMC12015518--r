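test_that("library TSV loads with fragments sorted descending", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tiny_library_tsv(path)
  lib <- load_library(path)
  expect_s3_class(lib, "prm_library")
  expect_equal(nrow(lib), 3)
  for (fr in lib$fragments) {
    expect_true(all(diff(fr$intensity) <= 0))
  }
  expect_equal(lib$accessions[[3]], c("P2", "P3"))
})

test_that("duplicate (sequence, charge) rows collapse to the more intense one", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sequence", "charge", "precursor_mz", "retention_time_min",
          "accessions", "fragments", sep = "\t"),
    paste("PEPTIDEK", 2, 450.73, 10.5, "P1",
          "y1:300.2:10;y2:401.3:9;y3:502.4:8", sep = "\t"),
    paste("PEPTIDEK", 2, 450.73, 10.6, "P1",
          "y1:300.2:100;y2:401.3:90;y3:502.4:80", sep = "\t")
  ), path)
  lib <- load_library(path)
  expect_equal(nrow(lib), 1)
  expect_equal(lib$fragments[[1]]$intensity[1], 100)
})

test_that("missing and malformed columns raise informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sequence", "charge", "precursor_mz", "accessions", "fragments",
          sep = "\t"),
    paste("PEPTIDEK", 2, 450.73, "P1", "y1:300:1;y2:400:1;y3:500:1",
          sep = "\t")
  ), path)
  expect_error(load_library(path), "retention_time_min")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("sequence", "charge", "precursor_mz", "retention_time_min",
          "accessions", "fragments", sep = "\t"),
    paste("PEPTIDEK", 2, "oops", 10.5, "P1", "y1:300:1;y2:400:1;y3:500:1",
          sep = "\t")
  ), path2)
  expect_error(load_library(path2), "row 1")
})

test_that("library round-trips through write_library/load_library", {
  lib <- synth_library(synth_config(seed = 11, n_proteins = 5))$library
  path <- withr::local_tempfile(fileext = ".tsv")
  write_library(lib, path)
  back <- load_library(path)
  expect_equal(back$sequence, lib$sequence)
  expect_equal(back$charge, lib$charge)
  expect_equal(back$retention_time_min, lib$retention_time_min,
               tolerance = 1e-6)
  for (i in seq_len(nrow(lib))) {
    expect_equal(back$fragments[[i]]$intensity, lib$fragments[[i]]$intensity,
                 tolerance = 1e-5)
  }
})

test_that("rank key is the third-largest fragment intensity", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
    rt = c(10, 20, 30),
    intensities = list(c(100, 90, 80, 10), c(60, 55, 50), c(70, 40))
  )
  ranked <- rank_candidates(lib)
  # the 2-fragment entry is never promoted to a candidate
  expect_equal(nrow(ranked), 2)
  expect_equal(ranked$rank_key, c(80, 50))
  expect_equal(ranked$sequence, c("AAAAAAAK", "CCCCCCCK"))
  expect_error(rank_candidates(lib, min_fragments = 2), "min_fragments")
})

test_that("ranking is a permutation-plus-filter with descending rank keys", {
  lib <- synth_library(synth_config(seed = 3, n_proteins = 30))$library
  ranked <- rank_candidates(lib)
  expect_true(all(diff(ranked$rank_key) <= 0))
  expect_setequal(ranked$sequence, lib$sequence)  # all have >= 3 fragments
  truth <- synth_library(synth_config(seed = 3, n_proteins = 30))$truth
  expect_equal(
    ranked$rank_key[match(truth$sequence, ranked$sequence)],
    truth$rank_key
  )
})

test_that("rank ties break deterministically", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK"),
    rt = c(10, 20),
    intensities = list(c(100, 90, 80), c(200, 90, 80)),
    mz = c(500, 400)
  )
  ranked <- rank_candidates(lib)
  # equal rank_key 80: higher total intensity first
  expect_equal(ranked$sequence, c("CCCCCCCK", "AAAAAAAK"))
})

test_that("tryptic digest respects the KR-not-before-P rule and lengths", {
  path <- withr::local_tempfile(fileext = ".fasta")
  tiny_fasta(path)
  peps <- digest_fasta(path, missed_cleavages = 0)
  # P1 = MKAAAAAAREEETTTKPGGGWWWK: cleavage after K2 and R9; K16 is followed
  # by P so EEETTTKPGGGWWWK stays intact
  expect_true("EEETTTKPGGGWWWK" %in% names(peps))
  expect_false("EEETTTK" %in% names(peps))
  # MK dropped by the 7-residue minimum
  expect_false("MK" %in% names(peps))
  expect_true("AAAAAAR" %in% names(peps))
})

test_that("shared peptides map to every source accession", {
  path <- withr::local_tempfile(fileext = ".fasta")
  tiny_fasta(path)
  peps <- digest_fasta(path, missed_cleavages = 0)
  expect_setequal(peps[["AAAAAAR"]], c("P1", "P2"))
})

test_that("raising missed cleavages only adds peptides", {
  path <- withr::local_tempfile(fileext = ".fasta")
  tiny_fasta(path)
  for (mc in 1:3) {
    lo <- names(digest_fasta(path, missed_cleavages = mc - 1, min_len = 1,
                             max_len = 100))
    hi <- names(digest_fasta(path, missed_cleavages = mc, min_len = 1,
                             max_len = 100))
    expect_true(all(lo %in% hi))
  }
})

test_that("every digested peptide is a substring of a mapped protein", {
  path <- withr::local_tempfile(fileext = ".fasta")
  tiny_fasta(path)
  seqs <- c(P1 = "MKAAAAAAREEETTTKPGGGWWWK", P2 = "SSSSSSSKAAAAAAR")
  peps <- digest_fasta(path, missed_cleavages = 2, min_len = 1, max_len = 100)
  for (p in names(peps)) {
    for (acc in peps[[p]]) {
      expect_true(grepl(p, seqs[[acc]], fixed = TRUE))
    }
  }
})

test_that("filtering applies exclusion, targets, proteotypicity, promotion", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK", "EEEEEEEK"),
    rt = c(10, 20, 30, 40),
    intensities = list(c(100, 90, 80), c(70, 60, 50), c(40, 30, 20),
                       c(15, 10, 5)),
    accession = list("P1", "P1", c("P1", "P2"), "P3")
  )
  ranked <- rank_candidates(lib)

  out <- filter_candidates(ranked, exclude_peptides = "AAAAAAAK")
  expect_false("AAAAAAAK" %in% out$sequence)

  out <- filter_candidates(ranked, target_accessions = "P1",
                           proteotypic_only = TRUE)
  expect_equal(out$sequence, c("AAAAAAAK", "CCCCCCCK"))  # shared DDD dropped

  # no target restriction: proteotypic filter alone removes shared peptides
  out <- filter_candidates(ranked)
  expect_false("DDDDDDDK" %in% out$sequence)
  expect_equal(nrow(out), 3)

  out <- filter_candidates(ranked, proteotypic_only = FALSE,
                           include_peptides = "EEEEEEEK")
  expect_equal(out$sequence[1], "EEEEEEEK")  # promoted ahead of all strata
  expect_equal(out$sequence[-1], c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"))
  expect_equal(out$rank, seq_len(nrow(out)))

  expect_error(
    filter_candidates(ranked, include_peptides = "AAAAAAAK",
                      exclude_peptides = "AAAAAAAK"),
    "both include and exclude"
  )
})

test_that("peptide lists parse with comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header comment", "PEPTIDEK", "", "ELVISK  # trailing"),
             path)
  expect_equal(read_peptide_list(path), c("PEPTIDEK", "ELVISK"))
})
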