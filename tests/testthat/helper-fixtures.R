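# Small in-code fixtures shared across tests.

tiny_library_tsv <- function(path) {
  writeLines(c(
    "#prmsched_library_v1",
    paste("sequence", "charge", "precursor_mz", "retention_time_min",
          "accessions", "fragments", sep = "\t"),
    paste("PEPTIDEK", 2, 450.73, 10.5, "P1",
          "y1:300.2:100;y2:401.3:90;y3:502.4:80;y4:603.5:10", sep = "\t"),
    paste("ELVISLIVESK", 2, 608.36, 25.0, "P2",
          "y3:350.1:500;y5:561.3:400;y7:775.4:300", sep = "\t"),
    paste("AVERYTINYR", 2, 590.31, 40.2, "P2;P3",
          "y2:276.2:50;y4:505.3:45;y6:733.4:40", sep = "\t")
  ), path)
  path
}

tiny_fasta <- function(path) {
  writeLines(c(
    ">sp|P1|PROT1_MOUSE Test protein one",
    "MKAAAAAAREEETTTKPGGGWWWK",
    ">sp|P2|PROT2_MOUSE Test protein two",
    "SSSSSSSKAAAAAAR"
  ), path)
  path
}

make_entry <- function(sequence = "PEPTIDEK", charge = 2L,
                       precursor_mz = peptide_mz(sequence, charge)) {
  list(sequence = sequence, charge = charge, precursor_mz = precursor_mz)
}

# Library built directly in code with controlled fragments/RTs.
make_library <- function(sequence, rt, intensities,
                         accession = as.list(sprintf("P%d", seq_along(sequence))),
                         charge = rep(2L, length(sequence)),
                         mz = 400 + seq_along(sequence)) {
  fragments <- lapply(intensities, function(ints) {
    data.frame(label = paste0("y", seq_along(ints)),
               mz = 300 + 100 * seq_along(ints), intensity = ints)
  })
  prm_library(sequence, charge, mz, rt, accession, fragments)
}
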