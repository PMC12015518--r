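id_map <- identity_rt_mapping(60)

test_that("the per-protein cap skips surplus peptides of a protein", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
    rt = c(10, 25, 40),
    intensities = list(c(100, 90, 80), c(70, 60, 50), c(40, 30, 20)),
    accession = list("P1", "P1", "P1")
  )
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 10, rt_window_min = 4,
                            peptides_per_protein_cap = 2)
  sched <- build_schedule(cands, id_map, cfg)
  expect_equal(nrow(sched$targets), 2)
  expect_equal(sched$skipped$sequence, "DDDDDDDK")
  expect_equal(sched$skipped$reason, "protein_cap")
})

test_that("the density cap keeps the higher-ranked of two co-eluting targets", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK"),
    rt = c(30, 30),
    intensities = list(c(100, 90, 80), c(70, 60, 50)),
    accession = list("P1", "P2")
  )
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 1, rt_window_min = 4)
  sched <- build_schedule(cands, id_map, cfg)
  expect_equal(sched$targets$sequence, "AAAAAAAK")
  expect_equal(sched$skipped$sequence, "CCCCCCCK")
  expect_equal(sched$skipped$reason, "density_full")
})

test_that("empty candidate lists produce empty schedules", {
  lib <- make_library(character(0), rt = numeric(0), intensities = list())
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 5, rt_window_min = 4)
  sched <- build_schedule(cands, id_map, cfg)
  expect_equal(nrow(sched$targets), 0)
  expect_equal(nrow(sched$skipped), 0)
  expect_equal(sched$max_density_reached, 0L)
})

test_that("mapped retention times outside the gradient are skipped", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK"),
    rt = c(30, 59.9),
    intensities = list(c(100, 90, 80), c(70, 60, 50)),
    accession = list("P1", "P2")
  )
  cands <- rank_candidates(lib)
  offset <- data.frame(library_rt = seq(0, 60, by = 5),
                       observed_rt = seq(0, 60, by = 5) + 2)
  m <- fit_rt_mapping(offset, method = "linear")
  cfg <- acquisition_config(max_assay_density = 5, rt_window_min = 4)
  sched <- build_schedule(cands, m, cfg)
  expect_equal(sched$targets$sequence, "AAAAAAAK")
  expect_equal(sched$skipped$reason, "out_of_gradient")
})

test_that("configuration and mapping preconditions are enforced", {
  expect_error(acquisition_config(max_assay_density = 10, rt_window_min = 70,
                                  gradient_length_min = 60),
               "rt_window_min")
  lib <- make_library("AAAAAAAK", rt = 10, intensities = list(c(3, 2, 1)))
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 5, rt_window_min = 4)
  expect_error(build_schedule(cands, list(), cfg), "rt_mapping")
  expect_error(build_schedule(cands, id_map, list()), "acquisition_config")
})

test_that("greedy replay oracle reproduces every accept/skip decision", {
  for (seed in 1:25) {
    set.seed(seed)
    inst <- random_instance(seed)
    sched <- build_schedule(inst$cands, id_map, inst$config)
    expect_equal(schedule_decisions(inst$cands, sched),
                 replay_schedule_oracle(inst$cands, id_map, inst$config))
    # conservation: every candidate lands in targets or skipped exactly once
    expect_equal(nrow(sched$targets) + nrow(sched$skipped), nrow(inst$cands))
    # density invariant, via exact sweep and brute force
    expect_lte(density_profile(sched)$max, inst$config$max_assay_density)
    expect_equal(density_profile(sched)$max, brute_max_density(sched$targets))
    # protein cap invariant
    acc <- unlist(sched$targets$accessions)
    if (length(acc)) {
      expect_lte(max(table(acc)), inst$config$peptides_per_protein_cap)
    }
  }
})

test_that("replay oracle agreement holds under a fitted nonlinear mapping", {
  cfg <- synth_config(seed = 31, drift_model = "logistic")
  m <- fit_rt_mapping(synth_rt_anchors(cfg, 100)$anchors)
  set.seed(31)
  inst <- random_instance(31)
  sched <- build_schedule(inst$cands, m, inst$config)
  expect_equal(schedule_decisions(inst$cands, sched),
               replay_schedule_oracle(inst$cands, m, inst$config))
})

test_that("density profile matches brute force on random window sets", {
  set.seed(99)
  S <- runif(1000, 0, 55)
  targets <- data.frame(window_start = S, window_end = S + runif(1000, 1, 5))
  prof <- density_profile(targets)
  expect_equal(prof$max, brute_max_density(targets))
  # spot-check profile counts at each boundary
  idx <- sample(nrow(prof$profile), 50)
  for (i in idx) {
    p <- prof$profile$time[i]
    expect_equal(prof$profile$count[i],
                 naive_cover_count(targets$window_start,
                                   targets$window_end, p))
  }
})

test_that("density profile handles disjoint and coincident windows", {
  two <- data.frame(window_start = c(0, 10), window_end = c(5, 15))
  expect_equal(density_profile(two)$max, 1L)
  three <- data.frame(window_start = c(0, 2, 4), window_end = c(4, 6, 8))
  expect_equal(density_profile(three)$max, 3L)  # all share t = 4
})

test_that("tiered assays schedule non-decreasing target counts", {
  set.seed(7)
  lib <- synth_library(synth_config(seed = 7, n_proteins = 60))$library
  cands <- rank_candidates(lib)
  tiers <- lapply(c(10, 20, 50), function(d) {
    acquisition_config(max_assay_density = d, rt_window_min = 4)
  })
  scheds <- build_tiered_assays(cands, id_map, tiers)
  counts <- vapply(scheds, function(s) nrow(s$targets), integer(1))
  expect_true(all(diff(counts) >= 0))
  # single tier is identical to a direct build
  single <- build_tiered_assays(cands, id_map, tiers[1])[[1]]
  expect_equal(single$targets, scheds[[1]]$targets)
  # a bank below every density limit schedules everything
  small <- rank_candidates(synth_library(
    synth_config(seed = 8, n_proteins = 3, peptides_per_protein = 2))$library)
  all_in <- build_tiered_assays(small, id_map, tiers)
  expect_true(all(vapply(all_in, function(s) nrow(s$targets), integer(1)) ==
                    nrow(small)))
  expect_error(build_tiered_assays(cands, id_map, list()), "non-empty")
})

test_that("inclusion lists and scheduling reports serialize correctly", {
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK"),
    rt = c(10, 50),
    intensities = list(c(100, 90, 80), c(70, 60, 50)),
    accession = list("P1", "P2"), charge = c(2L, 3L)
  )
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 5, rt_window_min = 4)
  sched <- build_schedule(cands, id_map, cfg)

  inc <- withr::local_tempfile(fileext = ".csv")
  write_inclusion_list(sched, inc)
  got <- read.csv(inc, check.names = FALSE)
  expect_equal(names(got), c("compound", "mz", "z", "t_start_min",
                             "t_stop_min", "isolation_width"))
  expect_equal(nrow(got), 2)
  # isolation center carries the +0.25/z isotope-envelope offset
  expect_equal(got$mz, round(lib$precursor_mz + 0.25 / lib$charge, 4))

  thermo <- withr::local_tempfile(fileext = ".csv")
  write_inclusion_list(sched, thermo, dialect = "thermo")
  head <- readLines(thermo, n = 1)
  expect_match(head, "Compound,m/z,z,t start \\(min\\),t stop \\(min\\)")

  rep <- withr::local_tempfile(fileext = ".tsv")
  write_schedule_report(sched, rep)
  lines <- readLines(rep)
  expect_true(any(grepl("targets_scheduled=2", lines)))
  tab <- read.delim(rep, comment.char = "#")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$decision == "scheduled"))
})

test_that("windows touching the extrapolated region are widened", {
  a <- data.frame(library_rt = seq(20, 40, by = 2),
                  observed_rt = seq(20, 40, by = 2))
  m <- fit_rt_mapping(a, method = "linear")
  # force a nonzero residual SD
  m$residual_sd <- 0.5
  lib <- make_library(
    c("AAAAAAAK", "CCCCCCCK"),
    rt = c(30, 10),  # 10 is outside the 20-40 anchor range
    intensities = list(c(100, 90, 80), c(70, 60, 50)),
    accession = list("P1", "P2")
  )
  cands <- rank_candidates(lib)
  cfg <- acquisition_config(max_assay_density = 5, rt_window_min = 4)
  sched <- build_schedule(cands, m, cfg)
  widths <- sched$targets$window_end - sched$targets$window_start
  inside <- sched$targets$sequence == "AAAAAAAK"
  expect_equal(widths[inside], 4)
  expect_equal(widths[!inside], 4 + 2 * 0.5)
  expect_true(sched$targets$extrapolated[!inside])
})
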