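test_that("mutagenesis places a uniform set with one causal mutation", {
  g <- tiny_genome()
  m1 <- mutagenize(g, 1, seed = 4)
  expect_equal(nrow(m1), 1)
  expect_true(m1$causal)

  m <- mutagenize(g, 1400, seed = 5)
  expect_equal(sum(m$causal), 1)
  expect_false(anyDuplicated(paste(m$chrom, m$pos)) > 0)
  # uniformity over the concatenated genome coordinate
  offset <- c(c1 = 0, c2 = 2e6)
  u <- (offset[m$chrom] + m$pos) / 3e6
  expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)

  expect_identical(mutagenize(g, 50, seed = 9), mutagenize(g, 50, seed = 9))
  expect_error(mutagenize(g, 0), ">= 1")
})

test_that("phenotype is homozygous-causal and F2 segregates 1:2:1", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 10, seed = 21)

  expect_equal(phenotype(founder_genome(g, "A"), mut), "mutant")
  expect_equal(phenotype(founder_genome(g, "B"), mut), "wildtype")
  f1 <- popseqsim:::f1_hybrid(g)  # heterozygous everywhere
  expect_equal(phenotype(f1, mut), "wildtype")

  set.seed(31)
  pop <- breed_population("outcross", 600, tp$plan, mutations = mut)
  gt <- popseqsim:::causal_genotypes(pop$individuals, mut)
  pv <- stats::chisq.test(tabulate(gt + 1, 3),
                          p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(pv, 0.001)
  expect_error(breed_population("outcross", 0, tp$plan), "pop_size")
  expect_error(
    breed_population("backcross", 10, tp$plan, mutations = mut,
                     backcross_rounds = 0),
    "backcross_rounds"
  )
})

test_that("BC1F2 causal allele frequency is 1/2 before selection", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 5, seed = 8)
  set.seed(12)
  pop <- breed_population("backcross", 500, tp$plan, mutations = mut,
                          backcross_rounds = 1)
  gt <- popseqsim:::causal_genotypes(pop$individuals, mut)
  af <- mean(gt) / 2
  expect_lt(abs(af - 0.5), 3 * sd(gt / 2) / sqrt(length(gt)))
})

test_that("pool selection controls mis-scored plants exactly", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 5, seed = 14)
  set.seed(15)
  pop <- breed_population("outcross", 500, tp$plan, mutations = mut)

  p0 <- select_pool(pop, mut, 50, misscore_rate = 0)
  expect_equal(p0$misscored_count, 0)
  gt <- popseqsim:::causal_genotypes(p0$individuals, mut)
  expect_true(all(gt == 2L))

  p1 <- select_pool(pop, mut, 50, misscore_rate = 0.02)
  expect_equal(p1$misscored_count, 1)
  gt1 <- popseqsim:::causal_genotypes(p1$individuals, mut)
  expect_equal(sum(gt1 < 2L), 1)

  p2 <- select_pool(pop, mut, 4, misscore_rate = 0.5)
  expect_equal(p2$misscored_count, 2)

  expect_error(select_pool(pop, mut, 1e5, 0), "pop_size")
  expect_error(select_pool(pop, mut, 10, 1), "misscore_rate")
})

test_that("foreground fraction matches the backcross expectation", {
  ap <- arabidopsis_plan(markers_per_chrom = 40)
  expect_equal(foreground_fraction(founder_genome(ap$genome, "A"),
                                   ap$genome), 1)
  expect_equal(foreground_fraction(founder_genome(ap$genome, "B"),
                                   ap$genome), 0)

  set.seed(61)
  for (n in 1:3) {
    inds <- unselected_backcross(ap$plan, n, 250)
    fg <- vapply(inds, foreground_fraction, numeric(1), genome = ap$genome)
    theory <- 2^-(n + 1)
    expect_lt(abs(mean(fg) - theory), 3 * sd(fg) / sqrt(length(fg)))
    expect_true(all(fg >= 0 & fg <= 1))
  }
})

test_that("phenotype selection inflates foreground above the unselected
          expectation (linkage drag)", {
  ap <- arabidopsis_plan(markers_per_chrom = 40)
  fs <- foreground_backcross_study(ap$plan, rounds = 2, n_individuals = 120,
                                   n_mutations = 40, seed = 62)
  expect_gte(nrow(fs), 120)
  # selection at the causal locus retains a linked founder segment, so the
  # mean clearly exceeds the unselected 12.5%
  expect_gt(mean(fs$foreground), 0.14)
  expect_lt(mean(fs$foreground), 0.35)
})

test_that("individual genome dumps tile the genome consistently", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 12, seed = 81)
  set.seed(82)
  pop <- breed_population("backcross", 2, tp$plan, mutations = mut)
  p <- withr::local_tempfile()
  write_individual(pop$individuals[[1]], g, p, mutations = mut)
  lines <- readLines(p)
  blank <- which(lines == "")
  seg <- utils::read.table(text = lines[seq_len(blank - 1)], header = TRUE,
                           sep = "\t")
  gt <- utils::read.table(text = lines[-seq_len(blank)], header = TRUE,
                          sep = "\t")
  # segments of each haplotype tile the chromosome without gaps
  for (ch in g$chrom) {
    for (h in c("h1", "h2")) {
      s <- seg[seg$chrom == ch & seg$haplotype == h, ]
      expect_equal(s$start[1], 1)
      expect_equal(s$end[nrow(s)], g$length[g$chrom == ch])
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
  }
  expect_equal(gt$genotype, genotype_at(pop$individuals[[1]], mut))
  expect_equal(sum(gt$causal), 1)
})

test_that("genotypes are reconstructible from segment origins", {
  g <- tiny_genome()
  tp <- tiny_plan(genome = g)
  mut <- mutagenize(g, 30, seed = 71)
  set.seed(72)
  pop <- breed_population("backcross", 60, tp$plan, mutations = mut,
                          backcross_rounds = 2, n_parent_siblings = 3)
  expect_setequal(unique(pop$lineage), 1:3)
  expect_equal(pop$generation, "BC2F2")
  for (ind in pop$individuals[1:25]) {
    gt <- genotype_at(ind, mut)
    expect_true(all(gt %in% 0:2))
    # recompute from raw haplotype origins, locus by locus
    for (j in sample.int(nrow(mut), 5)) {
      h <- ind$haps[[mut$chrom[j]]]
      manual <- popseqsim:::hap_origin_A(h$h1, mut$pos[j]) +
        popseqsim:::hap_origin_A(h$h2, mut$pos[j])
      expect_identical(gt[j], as.integer(manual))
    }
  }
})
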