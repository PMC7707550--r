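test_that("reference catalog reads FASTA + species table with cutoff sentinels", {
  fa <- write_test_fasta(tempfile(fileext = ".fasta"),
                         list(sp1_ref = strrep("ACGT", 2500),
                              sp2_ref = strrep("GGCC", 25)))
  tab <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\tsequence_id\tcutoff",
               "sp1\tsp1_ref\t0.80",
               "sp2\tsp2_ref\tNA"), tab)
  cat <- read_reference_catalog(fa, tab)
  expect_length(cat, 2L)
  expect_equal(cat$sp1$length, 10000L)
  expect_equal(cat$sp1$cutoff, 0.80)
  expect_true(is.na(cat$sp2$cutoff))       # "CO:NA" state
  expect_equal(cat$sp2$length, 100L)
})

test_that("reference catalog rejects malformed inputs", {
  fa <- write_test_fasta(tempfile(fileext = ".fasta"), list(sp1_ref = "ACGT"))
  tab <- write_species_table(tempfile(fileext = ".tsv"), "sp1", "other_ref", "NA")
  expect_error(read_reference_catalog(fa, tab), "mismatch")

  tab2 <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\tsequence_id\tcutoff",
               "sp1\tsp1_ref\t0.8", "sp1\tsp1_ref\t0.9"), tab2)
  expect_error(read_reference_catalog(fa, tab2), "duplicate")

  empty_fa <- tempfile(fileext = ".fasta"); file.create(empty_fa)
  tab3 <- write_species_table(tempfile(fileext = ".tsv"), "sp1", "sp1_ref", "NA")
  expect_error(read_reference_catalog(empty_fa, tab3))

  tab4 <- write_species_table(tempfile(fileext = ".tsv"), "sp1", "sp1_ref", "1.2")
  expect_error(read_reference_catalog(fa, tab4), "strictly in")
})

test_that("read_depth builds a dense track; absent positions are zero", {
  ref <- make_ref(3L)
  f <- tempfile()
  writeLines(c("sp1_ref\t1\t5", "sp1_ref\t3\t7", "other\t2\t99"), f)
  d <- read_depth(f, ref)
  expect_equal(as.integer(d), c(5L, 0L, 7L))

  empty <- tempfile(); file.create(empty)
  expect_equal(as.integer(read_depth(empty, ref)), c(0L, 0L, 0L))

  oob <- tempfile(); writeLines("sp1_ref\t4\t2", oob)
  expect_error(read_depth(oob, ref), "outside reference")
  neg <- tempfile(); writeLines("sp1_ref\t2\t-1", neg)
  expect_error(read_depth(neg, ref), "negative")
})

test_that("read_depth sum equals the depth column restricted to the chrom", {
  ref <- make_ref(50L)
  set.seed(11)
  for (rep in 1:5) {
    pos <- sample(50L, 20L)
    dep <- sample(0:30, 20L, replace = TRUE)
    f <- tempfile()
    writeLines(c(paste("sp1_ref", pos, dep, sep = "\t"),
                 "decoy\t1\t1000"), f)
    expect_equal(sum(read_depth(f, ref)), sum(dep))
  }
})

test_that("read_variant_profiles honors genotype semantics and skips indels", {
  ref <- make_ref(200L)
  vcf <- write_test_vcf(
    tempfile(fileext = ".vcf"), "sp1_ref",
    records = c(
      "sp1_ref\t100\t.\tT\tC\t.\tPASS\t.\tGT\t1\t0",
      "sp1_ref\t120\t.\tT\tC,G\t.\tPASS\t.\tGT\t1\t2",
      "sp1_ref\t150\t.\tTA\tT\t.\tPASS\t.\tGT\t1\t1",   # indel: skipped
      "sp1_ref\t180\t.\tT\tA\t.\tPASS\t.\tGT\t.\t1"),
    samples = c("A", "B"))
  depths <- list(A = rep(10L, 200L), B = rep(10L, 200L))
  expect_warning(p <- read_variant_profiles(vcf, ref, depths), "non-SNV")
  expect_named(p, c("A", "B"))
  expect_equal(p$A$calls$pos, c(100L, 120L))
  expect_equal(p$A$calls$state, c(1L, 1L))
  expect_equal(p$A$calls$alt, c("C", "C"))
  # B: ref at 100, second alternate at 120, alt at 180
  expect_equal(p$B$calls$pos, c(120L, 180L))
  expect_equal(p$B$calls$state, c(2L, 1L))
  expect_equal(p$B$calls$alt, c("G", "A"))
  expect_equal(p$A$breadth, 1)
  expect_equal(p$A$mean_depth, 10)
})

test_that("read_variant_profiles rejects a chrom mismatch and needs depths", {
  ref <- make_ref(200L)
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), "wrong_ref",
                        "wrong_ref\t10\t.\tG\tA\t.\tPASS\t.\tGT\t1",
                        samples = "A")
  expect_error(read_variant_profiles(vcf, ref, list(A = rep(5L, 200L))),
               "do not match")
  vcf2 <- write_test_vcf(tempfile(fileext = ".vcf"), "sp1_ref",
                         "sp1_ref\t10\t.\tG\tA\t.\tPASS\t.\tGT\t1",
                         samples = "A")
  expect_error(read_variant_profiles(vcf2, ref, list(B = rep(5L, 200L))),
               "no depth track")
})

test_that("qc_filter applies the strict breadth/depth thresholds", {
  ref <- make_ref(100L)
  cases <- list(
    list(breadth = 0.29, md = 10, passed = FALSE, metric = "breadth"),
    list(breadth = 0.30, md = 3.5, passed = TRUE, metric = NULL),
    list(breadth = 0.90, md = 3.4, passed = FALSE, metric = "mean_depth"))
  for (cs in cases) {
    p <- make_profile(ref, depth = make_depth(100L, cs$breadth, cs$md))
    expect_equal(p$breadth, cs$breadth)
    expect_equal(p$mean_depth, cs$md)
    q <- qc_filter(p)
    expect_equal(q$passed, cs$passed)
    if (!is.null(cs$metric)) expect_true(cs$metric %in% q$reasons$metric)
    expect_equal(q$passed, nrow(q$reasons) == 0L)
  }
  # both metrics failing are both reported
  p <- make_profile(ref, depth = make_depth(100L, 0.1, 1))
  expect_setequal(qc_filter(p)$reasons$metric, c("breadth", "mean_depth"))
})

test_that("qc_filter is monotone in breadth and mean depth", {
  ref <- make_ref(100L)
  set.seed(5)
  for (i in 1:30) {
    b1 <- runif(1); m1 <- runif(1, 0, 8)
    b2 <- min(1, b1 + runif(1, 0, 0.3)); m2 <- m1 + runif(1, 0, 3)
    p1 <- make_profile(ref, depth = make_depth(100L, b1, m1))
    p2 <- make_profile(ref, depth = make_depth(100L, b2, m2))
    if (qc_filter(p1)$passed) expect_true(qc_filter(p2)$passed)
  }
})

test_that("qc_filter depth-over-covered flag averages over covered bases", {
  ref <- make_ref(100L)
  depth <- integer(100L); depth[1:40] <- 8L   # breadth 0.4, gw mean 3.2
  p <- make_profile(ref, depth = depth)
  expect_false(qc_filter(p)$passed)
  expect_true(qc_filter(p, depth_over_covered = TRUE)$passed)
})

test_that("merge_profiles sums depth and takes depth-weighted majority states", {
  ref <- make_ref(200L)
  a <- make_profile(ref, pos = c(50L, 100L), state = 1L,
                    depth = rep(10L, 200L), sample_id = "A",
                    individual_id = "I1")
  # identical profiles: same calls, doubled depth
  m <- merge_profiles(list(a, a), sample_id = "AA")
  expect_equal(m$calls$pos, a$calls$pos)
  expect_equal(m$calls$state, a$calls$state)
  expect_equal(as.integer(m$depth), as.integer(a$depth) * 2L)
  expect_equal(m$mean_depth, 2 * a$mean_depth)

  # alt (site depth 10) vs covered reference (site depth 2): alt wins
  b <- make_profile(ref, depth = rep(2L, 200L), sample_id = "B",
                    individual_id = "I1")
  m2 <- merge_profiles(list(a, b))
  expect_equal(m2$calls$pos, c(50L, 100L))
  expect_equal(m2$calls$state, c(1L, 1L))
  # reversed depths: reference wins, call dropped
  a_shallow <- make_profile(ref, pos = 100L, state = 1L,
                            depth = rep(2L, 200L), sample_id = "A",
                            individual_id = "I1")
  deep_ref <- make_profile(ref, depth = rep(10L, 200L), sample_id = "B",
                           individual_id = "I1")
  expect_equal(nrow(merge_profiles(list(a_shallow, deep_ref))$calls), 0L)

  # single profile: identity up to recomputed metrics
  m3 <- merge_profiles(list(a))
  expect_equal(m3$calls, a$calls)
  expect_equal(m3$breadth, a$breadth)

  # mixed references rejected
  other <- make_profile(make_ref(200L, "sp2", "sp2_ref"), individual_id = "I1")
  expect_error(merge_profiles(list(a, other)), "different references")
})

test_that("merge_profiles is commutative and recomputes profile invariants", {
  ref <- make_ref(300L)
  set.seed(21)
  mk <- function(id) {
    depth <- sample(0:20, 300L, replace = TRUE)
    pos <- sort(sample(300L, 12L))
    make_profile(ref, pos = pos, state = sample(1:2, 12L, replace = TRUE),
                 depth = depth, sample_id = id, individual_id = "I1")
  }
  for (i in 1:5) {
    ps <- list(mk("A"), mk("B"), mk("C"))
    m1 <- merge_profiles(ps, sample_id = "M")
    m2 <- merge_profiles(rev(ps), sample_id = "M")
    expect_equal(m1$calls[c("pos", "state")], m2$calls[c("pos", "state")])
    expect_equal(m1$depth, m2$depth)
    # SampleProfile invariants hold after merging
    expect_equal(m1$breadth, mean(m1$depth >= 1))
    expect_equal(m1$mean_depth, sum(m1$depth) / ref$length)
    expect_false(anyDuplicated(m1$calls$pos) > 0)
  }
})
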