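test_that("threshold closed forms match hand evaluation", {
  expect_equal(genotype_frequency_threshold(threshold_params(50)), 0.99)
  expect_equal(genotype_frequency_threshold(threshold_params(50, 1)), 0.97)
  expect_equal(genotype_frequency_threshold(threshold_params(1)), 0.5)
  expect_equal(read_frequency_threshold(100, 0.003), 0.987)
  expect_equal(read_frequency_threshold(25, 0.003), 0.957)
  expect_equal(read_frequency_threshold(1, 0.003), -0.003)
  expect_true(is.na(read_frequency_threshold(0)))
  expect_error(threshold_params(0), "n must be")
  expect_error(threshold_params(10, 10), "m_mis")
})

test_that("thresholds are monotone and below one", {
  for (n in c(1, 5, 50, 500)) {
    gfs <- sapply(0:(n - 1), function(m) {
      genotype_frequency_threshold(threshold_params(n, m))
    })
    expect_true(all(diff(gfs) < 0))
    expect_true(all(gfs < 1))
  }
  rfs <- read_frequency_threshold(c(2, 5, 25, 100, 1000))
  expect_true(all(diff(rfs) > 0))
  expect_true(all(rfs < 1))
})

test_that("homozygous calling applies both thresholds and the coverage
          guard", {
  mk_counts <- function(cov, mut) {
    structure(
      data.frame(chrom = "c1", pos = seq_along(cov) * 1000,
                 locus_type = "mutation", cov = cov, count_mut = mut,
                 count_wt = cov - mut, stringsAsFactors = FALSE),
      class = c("pool_counts", "data.frame")
    )
  }
  # causal-like locus at frequency 1 is always called above min coverage
  out <- call_homozygous(mk_counts(50L, 50L), threshold_params(50))
  expect_equal(nrow(out), 1)

  # 49/50 reads: below g_f = 0.99 with m_mis = 0, called with m_mis = 1
  x <- mk_counts(50L, 49L)
  expect_equal(nrow(call_homozygous(x, threshold_params(50, 0))), 0)
  expect_equal(nrow(call_homozygous(x, threshold_params(50, 1))), 1)

  # an unlinked locus at frequency ~ 0.5 is never called
  expect_equal(nrow(call_homozygous(mk_counts(50L, 25L),
                                    threshold_params(50))), 0)

  # coverage below min_coverage is not callable even at frequency 1
  expect_equal(nrow(call_homozygous(mk_counts(1L, 1L),
                                    threshold_params(50))), 0)
})

test_that("mapping interval localizes an extreme signal and flags null
          data", {
  set.seed(19)
  pos <- seq(1e4, 2e6, by = 1e4)
  k <- length(pos)
  cov <- rep(200L, k)
  # linked decay around marker 100 on c1; chromosome c2 unlinked
  d <- abs(seq_len(k) - 100) / 60
  f_true <- 0.5 + 0.5 * exp(-d)
  cnt <- rbinom(k, cov, f_true)
  counts <- structure(
    data.frame(chrom = "c1", pos = pos, locus_type = "marker", cov = cov,
               count_mut = cnt, count_wt = cov - cnt,
               stringsAsFactors = FALSE),
    class = c("pool_counts", "data.frame")
  )
  iv <- map_interval(counts, window = 11, n_pool = 100)
  expect_false(iv$warning)
  expect_equal(iv$chrom, "c1")
  expect_true(iv$start <= pos[100] && iv$end >= pos[100])
  expect_lt(iv$length, 2e6)

  # shuffled, unlinked frequencies: uninformative flag, whole genome
  cnt0 <- rbinom(k, cov, 0.5)
  counts0 <- counts
  counts0$count_mut <- cnt0
  counts0$count_wt <- cov - cnt0
  g <- genome_spec("c1", 2e6)
  iv0 <- map_interval(counts0, window = 11, n_pool = 100, genome = g)
  expect_true(iv0$warning)
  expect_equal(iv0$length, 2e6)
  expect_equal(count_cams(iv0, mutagenize(g, 30, seed = 1)), 30)

  expect_error(map_interval(counts[1, ]), "at least 2")
})

test_that("CAM counting is a pure interval query", {
  g <- tiny_genome()
  mut <- mutagenize(g, 200, seed = 31)
  iv <- structure(list(chrom = "c1", start = 5e5, end = 1.5e6,
                       warning = FALSE), class = "mapping_result")
  expect_equal(count_cams(iv, mut),
               sum(mut$chrom == "c1" & mut$pos >= 5e5 & mut$pos <= 1.5e6))
  iv0 <- structure(list(chrom = "c1", start = 2, end = 1,
                        warning = FALSE), class = "mapping_result")
  expect_equal(count_cams(iv0, mut), 0)
  ivall <- structure(list(chrom = "c1", start = 1, end = 2e6,
                          warning = FALSE), class = "mapping_result")
  expect_equal(count_cams(ivall, mut), sum(mut$chrom == "c1"))
  expect_true(interval_contains(iv, "c1", 1e6))
  expect_false(interval_contains(iv, "c2", 1e6))
})

test_that("direct sequencing recovers founder mutations and degrades with
          backcrossing", {
  ap <- arabidopsis_plan(markers_per_chrom = 40)
  mut <- mutagenize(ap$genome, 700, seed = 41)
  set.seed(42)
  founder <- founder_genome(ap$genome, "A")
  res <- direct_sequencing_cams(founder, mut, seq_params(coverage = 50))
  expect_gt(res$cam_count, 0.97 * 700)

  # a BC2 mutant retains far fewer homozygous mutations
  set.seed(43)
  pop <- breed_population("backcross", 40, ap$plan, mutations = mut,
                          backcross_rounds = 2)
  pool <- select_pool(pop, mut, 1, 0)
  res2 <- direct_sequencing_cams(pool$individuals[[1]], mut,
                                 seq_params(coverage = 50))
  expect_lt(res2$cam_count, 700 / 2)
  # the causal mutation itself is homozygous and called
  cl <- popseqsim:::causal_locus(mut)
  expect_true(any(res2$cams$chrom == cl$chrom & res2$cams$pos == cl$pos))

  # zero coverage: no calls, warning
  expect_warning(
    res0 <- direct_sequencing_cams(founder, mut, seq_params(total_reads = 0)),
    "zero coverage"
  )
  expect_equal(res0$cam_count, 0)
})
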