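test_that("simulation_config validates its parameters", {
  cfg <- simulation_config(seed = 1L)
  expect_s3_class(cfg, "simulation_config")
  expect_error(simulation_config(drift = 1.2), "probabilities")
  expect_error(simulation_config(genome_length = 0L))
})

test_that("simulate_reference is seeded, uniform and guarded", {
  r1 <- simulate_reference(10000L, seed = 7L)
  r2 <- simulate_reference(10000L, seed = 7L)
  expect_identical(r1$sequence, r2$sequence)
  expect_error(simulate_reference(0L), ">= 1")
  # GC fraction near 1/2 for a long genome (binomial bound)
  r <- simulate_reference(100000L, seed = 8L)
  gc <- sum(strsplit(r$sequence, "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.5), 0.05)
})

test_that("simulate_strain draws a binomial number of SNVs", {
  ref <- simulate_reference(100000L, seed = 9L)
  expect_length(simulate_strain(ref, 0, seed = 1L)$pos, 0L)
  h1 <- simulate_strain(ref, 0.01, seed = 2L)
  h2 <- simulate_strain(ref, 0.01, seed = 2L)
  expect_identical(h1, h2)
  # n = 1e5, p = 0.01: 3 sigma around 1000 is about +/- 94
  expect_lt(abs(length(h1$pos) - 1000), 3 * sqrt(100000 * 0.01 * 0.99))
  # alt bases never equal the reference base
  ref_b <- substring(ref$sequence, h1$pos, h1$pos)
  expect_true(all(h1$alt != ref_b))
})

test_that("evolve_or_replace separates persistence from replacement", {
  ref <- simulate_reference(20000L, seed = 10L)
  h <- simulate_strain(ref, 0.01, seed = 11L)

  same <- evolve_or_replace(h, 0, 0, ref, 0.01, seed = 12L)
  expect_equal(same$truth_label, "related")
  expect_identical(same$haplotype, h)

  repl <- evolve_or_replace(h, 0, 1, ref, 0.01, seed = 13L)
  expect_equal(repl$truth_label, "unrelated")
  expect_false(identical(repl$haplotype$pos, h$pos))

  # drift 0.05: changed fraction of polymorphic sites within 3 sigma over reps
  changed <- vapply(1:20, function(s) {
    ev <- evolve_or_replace(h, 0.05, 0, ref, 0.01, seed = 100L + s)
    key_old <- paste(h$pos, h$alt)
    key_new <- paste(ev$haplotype$pos, ev$haplotype$alt)
    sum(!(key_old %in% key_new)) / length(h$pos)
  }, numeric(1))
  n_tot <- 20 * length(h$pos)
  expect_lt(abs(mean(changed) - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("observe applies the depth, dropout and error model", {
  ref <- simulate_reference(20000L, seed = 20L)
  h <- simulate_strain(ref, 0.01, seed = 21L)

  # error-free observations of the same strain score WSS 1.0
  o1 <- observe(h, ref, mean_depth = 20, dropout = 0, call_error = 0,
                sample_id = "A", seed = 22L)
  o2 <- observe(h, ref, mean_depth = 20, dropout = 0, call_error = 0,
                sample_id = "B", seed = 23L)
  p <- harmonize_states(list(o1, o2))
  expect_identical(compute_wss(p[[1]], p[[2]], make_windows(20000L))$score, 1.0)
  # calls are the haplotype restricted to covered sites
  expect_equal(o1$calls$pos, h$pos[o1$depth[h$pos] >= 1L])

  # heavy dropout: breadth near 0.2, fails the breadth filter
  o3 <- observe(h, ref, mean_depth = 20, dropout = 0.8, call_error = 0,
                seed = 24L)
  expect_lt(abs(o3$breadth - 0.2), 0.02)
  expect_false(qc_filter(o3)$passed)
  expect_true("breadth" %in% qc_filter(o3)$reasons$metric)

  # shallow sequencing: fails the mean-depth filter
  o4 <- observe(h, ref, mean_depth = 2, dropout = 0, call_error = 0,
                seed = 25L)
  expect_false(qc_filter(o4)$passed)
  expect_true("mean_depth" %in% qc_filter(o4)$reasons$metric)
})

test_that("cohort truth labels follow the replacement regime", {
  cfg_rel <- simulation_config(genome_length = 5000L, n_individuals = 8L,
                               replacement_prob = 0, seed = 31L)
  co_rel <- simulate_cohort(cfg_rel)
  expect_equal(nrow(co_rel$truth), 8L)
  expect_true(all(co_rel$truth$truth_label == "related"))

  cfg_unrel <- simulation_config(genome_length = 5000L, n_individuals = 22L,
                                 replacement_prob = 1, seed = 32L)
  co_unrel <- simulate_cohort(cfg_unrel)
  expect_true(all(co_unrel$truth$truth_label == "unrelated"))
  expect_length(co_unrel$profiles, 44L)
})

test_that("multi-timepoint truth composes drift across replacement events", {
  cfg <- simulation_config(genome_length = 4000L, n_individuals = 6L,
                           n_timepoints = 3L, replacement_prob = 0.5,
                           seed = 33L)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth), 6L * 3L)  # 3 pairs per individual
  # a pair spanning an unrelated transition must itself be unrelated
  for (ind in unique(co$truth$individual_id)) {
    tt <- co$truth[co$truth$individual_id == ind, ]
    l12 <- tt$truth_label[tt$timepoint_a == "T1" & tt$timepoint_b == "T2"]
    l23 <- tt$truth_label[tt$timepoint_a == "T2" & tt$timepoint_b == "T3"]
    l13 <- tt$truth_label[tt$timepoint_a == "T1" & tt$timepoint_b == "T3"]
    want <- if (l12 == "unrelated" || l23 == "unrelated") "unrelated" else "related"
    expect_equal(l13, want)
  }
})

test_that("cohorts are bit-identical under a fixed seed, on disk too", {
  cfg <- simulation_config(genome_length = 3000L, n_individuals = 3L,
                           seed = 55L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  co1 <- simulate_cohort(cfg, dir = d1)
  co2 <- simulate_cohort(cfg, dir = d2)
  expect_identical(co1$profiles, co2$profiles)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("a written cohort round-trips losslessly through the I/O path", {
  cfg <- simulation_config(genome_length = 5000L, n_individuals = 3L,
                           seed = 66L)
  dir <- file.path(tempdir(), "roundtrip")
  co <- simulate_cohort(cfg, dir = dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$profiles), names(co$profiles))
  for (s in names(co$profiles)) {
    orig <- co$profiles[[s]]; got <- back$profiles[[s]]
    expect_equal(got$calls$pos, orig$calls$pos)
    expect_equal(got$calls$state, orig$calls$state)
    expect_equal(got$calls$alt, orig$calls$alt)
    expect_equal(as.integer(got$depth), as.integer(orig$depth))
    expect_equal(got$breadth, orig$breadth)
    expect_equal(got$mean_depth, orig$mean_depth)
    expect_equal(got$individual_id, orig$individual_id)
  }
  expect_equal(back$truth$truth_label, co$truth$truth_label)
})

test_that("related pairs outscore unrelated pairs on average", {
  w <- make_windows(10000L)
  rel <- vapply(1:8, function(s)
    compute_wss(make_pair(s, TRUE, 10000L)$a,
                make_pair(s, TRUE, 10000L)$b, w)$score, numeric(1))
  unrel <- vapply(1:8, function(s)
    compute_wss(make_pair(50 + s, FALSE, 10000L)$a,
                make_pair(50 + s, FALSE, 10000L)$b, w)$score, numeric(1))
  expect_gt(mean(rel), mean(unrel))
})
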