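test_that("multinomial coverage allocation conserves the read total", {
  expect_equal(assign_coverage(1, 500), 500L)
  expect_identical(assign_coverage(rep(1, 10), 0), integer(10))
  expect_error(assign_coverage(rep(0, 3), 10), "positive")

  set.seed(3)
  cov <- assign_coverage(rep(1, 100), 10000)
  expect_identical(sum(cov), 10000L)
  # each locus is Binomial(10000, 0.01): all within 3 sigma plus a small
  # allowance for the 100 simultaneous comparisons
  se <- sqrt(10000 * 0.01 * 0.99)
  expect_true(all(abs(cov - 100) < 4 * se))
})

test_that("true allele frequencies count pool chromosomes", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 5, seed = 2)
  cl <- popseqsim:::causal_locus(mut)
  set.seed(5)
  pop <- breed_population("outcross", 700, tp$plan, mutations = mut)

  pool <- select_pool(pop, mut, 50, 0)
  a1 <- true_allele_frequencies(pool, data.frame(chrom = cl$chrom,
                                                 pos = cl$pos))
  expect_equal(a1, 1)

  # one mis-scored heterozygote at the causal locus gives 99/100
  gt <- popseqsim:::causal_genotypes(pop$individuals, mut)
  pool2 <- pool
  pool2$individuals[[1]] <- pop$individuals[[which(gt == 1L)[1]]]
  a1b <- true_allele_frequencies(pool2, data.frame(chrom = cl$chrom,
                                                   pos = cl$pos))
  expect_equal(a1b, 99 / 100)

  # an unlinked locus converges to 1/2 in a large mutant pool
  other <- setdiff(g$chrom, cl$chrom)[1]
  big <- select_pool(pop, mut, 150, 0)
  a1c <- true_allele_frequencies(big, data.frame(chrom = other, pos = 5e5))
  expect_lt(abs(a1c - 0.5), 0.15)
})

test_that("allele-count sampling conserves reads and models errors", {
  expect_equal(sample_allele_counts(100, 1, 0)[1, ],
               c(count_mut = 100, count_wt = 0))
  expect_equal(unname(sample_allele_counts(0, 0.5)[1, ]), c(0, 0))

  set.seed(8)
  x <- sample_allele_counts(rep(50L, 1000), 0.3)
  expect_true(all(rowSums(x) == 50))

  # error floor under the split rule: E[wt fraction] = s/2 at a1 = 1
  set.seed(9)
  cc <- 100000L
  y <- sample_allele_counts(cc, 1, 0.003)
  exp_wt <- cc * 0.003 / 2
  expect_lt(abs(y[1, "count_wt"] - exp_wt), 3 * sqrt(cc * 0.0015))

  # flip rule sends all error reads at a fixed locus to the other allele
  set.seed(10)
  z <- sample_allele_counts(cc, 1, 0.003, error_mode = "flip")
  exp_wt2 <- cc * 0.003
  expect_lt(abs(z[1, "count_wt"] - exp_wt2), 3 * sqrt(cc * 0.003))

  # unbiasedness at a1 = 0.5 across many loci
  set.seed(11)
  w <- sample_allele_counts(rep(50L, 10000), 0.5)
  fbar <- mean(w[, 1] / 50)
  expect_lt(abs(fbar - 0.5), 3 * sqrt(0.25 / 50 / 10000))
})

test_that("pool sequencing composes coverage and allele draws", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g, markers_per_chrom = 30)
  mut <- mutagenize(g, 20, seed = 3)
  set.seed(12)
  pop <- breed_population("outcross", 150, tp$plan, mutations = mut)
  pool <- select_pool(pop, mut, 30, 0)

  counts <- sequence_pool(pool, tp$markers, mut,
                          seq_params(coverage = 25))
  n_loci <- nrow(tp$markers) + nrow(mut)
  expect_equal(nrow(counts), n_loci)
  expect_identical(sum(counts$cov), as.integer(round(25 * n_loci)))
  expect_true(all(counts$count_mut + counts$count_wt == counts$cov))

  # two seeds: different counts, same totals
  set.seed(13)
  c2 <- sequence_pool(pool, tp$markers, mut, seq_params(coverage = 25))
  expect_identical(sum(c2$cov), sum(counts$cov))
  expect_false(identical(c2$count_mut, counts$count_mut))

  # enrichment mode: non-enriched loci get zero reads
  mk <- tp$markers
  mk$enriched <- seq_len(nrow(mk)) %% 3 == 0
  ce <- sequence_pool(pool, mk, mut,
                      seq_params(coverage = 40, mode = "enrichment"))
  expect_true(all(ce$cov[ce$locus_type == "mutation"] == 0))
  expect_true(all(ce$cov[!c(mk$enriched, rep(TRUE, nrow(mut)))] == 0))
  expect_identical(sum(ce$cov), as.integer(round(40 * sum(mk$enriched))))
  mk$enriched <- FALSE
  expect_error(
    sequence_pool(pool, mk, NULL, seq_params(coverage = 10,
                                             mode = "enrichment")),
    "enrich"
  )
})

test_that("pool counts round-trip through TSV and export to VCF", {
  counts <- structure(
    data.frame(chrom = c("c1", "c2"), pos = c(100, 200),
               locus_type = c("marker", "mutation"), cov = c(10L, 20L),
               count_mut = c(9L, 20L), count_wt = c(1L, 0L),
               stringsAsFactors = FALSE),
    class = c("pool_counts", "data.frame")
  )
  p <- withr::local_tempfile()
  write_pool_counts(counts, p)
  back <- read_pool_counts(p)
  expect_equal(back$count_mut, counts$count_mut)
  expect_equal(back$pos, counts$pos)

  v <- withr::local_tempfile()
  export_vcf(counts, v)
  lines <- readLines(v)
  expect_match(lines[1], "fileformat=VCF")
  expect_match(lines[length(lines)], "0,20$")  # AD field is other,mutant
})
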