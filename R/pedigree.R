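# Pedigree: mutant founders, outcross and backcross schemes, phenotype
# selection, mis-scoring, pooling, and foreground-genome quantification.

#' Create a founder (or partner) genome
#'
#' A `recombinant_genome` holds two haplotypes per chromosome, each a list
#' of breakpoints with alternating parental-origin labels. The mutagenized
#' founder is homozygous origin "A" everywhere (and therefore homozygous
#' for every induced mutation); the crossing partner is homozygous "B".
#'
#' @param genome a [genome_spec].
#' @param origin `"A"` (mutagenized founder) or `"B"` (crossing partner).
#' @return a `recombinant_genome`.
#' @export
founder_genome <- function(genome, origin = c("A", "B")) {
  origin <- match.arg(origin)
  a <- identical(origin, "A")
  haps <- lapply(genome$chrom, function(ch) {
    list(h1 = new_haplotype(startA = a), h2 = new_haplotype(startA = a))
  })
  names(haps) <- genome$chrom
  structure(list(haps = haps), class = "recombinant_genome")
}

new_individual <- function(g1, g2) {
  haps <- lapply(names(g1), function(ch) list(h1 = g1[[ch]], h2 = g2[[ch]]))
  names(haps) <- names(g1)
  structure(list(haps = haps), class = "recombinant_genome")
}

#' Place random homozygous mutations on a genome
#'
#' Mutation positions are uniform over the genome (chromosome chosen with
#' probability proportional to its length). Exactly one mutation is marked
#' as causal. All mutations are homozygous in the founder.
#'
#' @param genome a [genome_spec].
#' @param n_mutations number of induced mutations (>= 1); typical chemical
#'   mutagenesis loads are 700 or 1400 for a ~119 Mb genome.
#' @param seed optional integer seed for a reproducible set.
#' @return a `mutation_set`: data.frame with columns `chrom`, `pos`,
#'   `causal` (exactly one `TRUE`).
#' @export
mutagenize <- function(genome, n_mutations, seed = NULL) {
  if (n_mutations < 1) stop("n_mutations must be >= 1")
  if (n_mutations > sum(genome$length)) {
    stop("n_mutations exceeds genome length")
  }
  if (!is.null(seed)) set.seed(seed)
  repeat {
    ch_idx <- sample.int(nrow(genome), n_mutations, replace = TRUE,
                         prob = genome$length)
    pos <- ceiling(stats::runif(n_mutations) * genome$length[ch_idx])
    key <- paste(ch_idx, pos)
    if (!anyDuplicated(key)) break
  }
  o <- order(ch_idx, pos)
  mut <- data.frame(
    chrom = genome$chrom[ch_idx][o], pos = pos[o],
    causal = FALSE, stringsAsFactors = FALSE
  )
  mut$causal[sample.int(n_mutations, 1)] <- TRUE
  structure(mut, class = c("mutation_set", "data.frame"))
}

causal_locus <- function(mutations) {
  i <- which(mutations$causal)
  if (length(i) != 1) stop("mutation set must have exactly one causal mutation")
  list(chrom = mutations$chrom[i], pos = mutations$pos[i])
}

#' Genotype an individual at a set of loci
#'
#' The genotype is the number of founder-derived ("A") alleles, i.e. the
#' number of mutant-allele copies at an induced-mutation locus; it is
#' derived entirely from segment origins.
#'
#' @param ind a `recombinant_genome`.
#' @param loci data.frame with columns `chrom`, `pos`.
#' @return integer vector (0, 1 or 2) aligned with `loci` rows.
#' @export
genotype_at <- function(ind, loci) {
  out <- integer(nrow(loci))
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    x <- loci$pos[sel]
    h <- ind$haps[[ch]]
    if (is.null(h)) stop("individual has no chromosome ", ch)
    out[sel] <- hap_origin_A(h$h1, x) + hap_origin_A(h$h2, x)
  }
  out
}

#' Phenotype an individual
#'
#' An individual shows the mutant phenotype if and only if it is homozygous
#' for the causal mutation (recessive model).
#'
#' @param ind a `recombinant_genome`.
#' @param mutations a `mutation_set` (see [mutagenize()]).
#' @return `"mutant"` or `"wildtype"`.
#' @export
phenotype <- function(ind, mutations) {
  cl <- causal_locus(mutations)
  g <- genotype_at(ind, data.frame(chrom = cl$chrom, pos = cl$pos))
  if (g == 2L) "mutant" else "wildtype"
}

# Causal genotypes of a list of individuals (vectorized over individuals).
causal_genotypes <- function(pop, mutations) {
  cl <- causal_locus(mutations)
  loci <- data.frame(chrom = cl$chrom, pos = cl$pos)
  vapply(pop, genotype_at, integer(1), loci = loci)
}

#' Breed a mapping population
#'
#' Implements the two crossing schemes used in mapping-by-sequencing:
#'
#' * **outcross**: mutagenized founder x diverged accession, then selfing of
#'   the F1, giving an F2 population in which natural polymorphisms (the
#'   marker map) and the induced mutations segregate.
#' * **backcross**: `backcross_rounds` successive crosses of a
#'   causal-allele carrier to the isogenic recurrent parent, then selfing of
#'   the final BC plant, giving a BC_nF2 population in which only induced
#'   mutations segregate.
#'
#' With `n_parent_siblings > 1`, that many independent carrier lineages are
#' bred and contribute equal numbers of F2 individuals (remainder assigned
#' round-robin).
#'
#' @param scheme `"outcross"` or `"backcross"`.
#' @param pop_size number of F2 individuals to generate.
#' @param landscape a `recomb_landscape` or a [simulation_plan()].
#' @param markers marker map (required when `landscape` is not a plan).
#' @param mutations a `mutation_set`; required for the backcross scheme
#'   (carrier selection tracks the causal locus).
#' @param backcross_rounds number of backcross generations (1-3 typical);
#'   ignored for the outcross scheme.
#' @param n_parent_siblings independent carrier lineages contributing to the
#'   F2 (backcross scheme).
#' @param carrier `"het"` (default): the plant carried into each backcross
#'   round is selected to carry one causal allele; `"none"`: no selection,
#'   used to study the unconditional backcross expectation.
#' @return a list with elements `individuals` (list of
#'   `recombinant_genome`), `scheme`, `generation` (e.g. `"F2"`,
#'   `"BC2F2"`), and `lineage` (integer lineage id per individual).
#' @export
breed_population <- function(scheme = c("outcross", "backcross"), pop_size,
                             landscape, markers = NULL, mutations = NULL,
                             backcross_rounds = 1, n_parent_siblings = 1,
                             carrier = c("het", "none")) {
  scheme <- match.arg(scheme)
  carrier <- match.arg(carrier)
  if (pop_size < 1) stop("pop_size must be >= 1")
  plan <- as_sim_plan(landscape, markers)

  if (scheme == "outcross") {
    f1 <- f1_hybrid(plan$genome)
    inds <- lapply(seq_len(pop_size), function(i) {
      new_individual(sample_gamete(f1, plan), sample_gamete(f1, plan))
    })
    return(list(individuals = inds, scheme = scheme, generation = "F2",
                lineage = rep(1L, pop_size)))
  }

  if (backcross_rounds < 1) stop("backcross_rounds must be >= 1")
  if (is.null(mutations)) stop("backcross breeding requires `mutations`")
  cl <- causal_locus(mutations)
  sizes <- lineage_sizes(pop_size, n_parent_siblings)
  inds <- vector("list", pop_size)
  lineage <- integer(pop_size)
  at <- 0L
  for (s in seq_len(n_parent_siblings)) {
    parent <- bc_lineage_parent(plan, cl, backcross_rounds, carrier)
    for (j in seq_len(sizes[s])) {
      at <- at + 1L
      inds[[at]] <- new_individual(sample_gamete(parent, plan),
                                   sample_gamete(parent, plan))
      lineage[at] <- s
    }
  }
  list(individuals = inds, scheme = scheme,
       generation = sprintf("BC%dF2", backcross_rounds), lineage = lineage)
}

f1_hybrid <- function(genome) {
  # founder gametes are unrecombined single-origin haplotypes, so the F1 is
  # A/B on every chromosome regardless of crossovers
  a <- founder_genome(genome, "A")
  b <- founder_genome(genome, "B")
  g1 <- lapply(a$haps, function(h) h$h1)
  g2 <- lapply(b$haps, function(h) h$h1)
  new_individual(g1, g2)
}

lineage_sizes <- function(pop_size, n_lineages) {
  base <- pop_size %/% n_lineages
  sizes <- rep(base, n_lineages)
  extra <- pop_size - base * n_lineages
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Breed the BC_n plant that is selfed to make the mapping population.
bc_lineage_parent <- function(plan, cl, rounds, carrier, max_tries = 10000L) {
  b_hap <- new_haplotype(startA = FALSE)
  cur <- f1_hybrid(plan$genome)
  for (r in seq_len(rounds)) {
    tries <- 0L
    repeat {
      g <- sample_gamete(cur, plan)
      if (carrier == "none" || hap_origin_A(g[[cl$chrom]], cl$pos)) break
      tries <- tries + 1L
      if (tries >= max_tries) stop("failed to recover a causal carrier")
    }
    bg <- lapply(g, function(x) b_hap)
    cur <- new_individual(g, bg)
  }
  cur
}

#' Simulate unselected backcross individuals
#'
#' Breeds independent BC_n individuals with no carrier selection at any
#' round, realizing the textbook expectation that each backcross halves the
#' foreground genome: the expected recurrent-parent fraction after `n`
#' rounds is `(2^(n+1) - 1) / 2^(n+1)`.
#'
#' @param plan a [simulation_plan()] (or landscape plus `markers`).
#' @param rounds number of backcross rounds.
#' @param n number of independent individuals.
#' @param markers marker map if `plan` is a landscape.
#' @return list of `recombinant_genome`.
#' @export
unselected_backcross <- function(plan, rounds, n, markers = NULL) {
  plan <- as_sim_plan(plan, markers)
  b_hap <- new_haplotype(startA = FALSE)
  lapply(seq_len(n), function(i) {
    cur <- f1_hybrid(plan$genome)
    for (r in seq_len(rounds)) {
      g <- sample_gamete(cur, plan)
      cur <- new_individual(g, lapply(g, function(x) b_hap))
    }
    cur
  })
}

#' Select a phenotyped mutant pool from a population
#'
#' Samples `n_mutants` phenotypically mutant individuals (causal genotype
#' 2). A fraction `misscore_rate` of the pool (rounded to the nearest
#' individual) is then replaced by phenotypically wild-type individuals
#' drawn from the same population, in their natural mixture of causal
#' genotypes 0 and 1, emulating mis-scored plants.
#'
#' @param population result of [breed_population()].
#' @param mutations the founder `mutation_set`.
#' @param n_mutants pool size.
#' @param misscore_rate fraction of mis-scored (wild-type) plants in
#'   `[0, 1)`; e.g. 0.02 in a pool of 50 puts exactly one wild-type plant
#'   into the pool.
#' @return a `pool`: list with `individuals`, `scheme`, `generation`,
#'   `misscored_count`, and `is_misscored` (logical per pool member).
#' @export
select_pool <- function(population, mutations, n_mutants,
                        misscore_rate = 0) {
  if (misscore_rate < 0 || misscore_rate >= 1) {
    stop("misscore_rate must be in [0, 1)")
  }
  gt <- causal_genotypes(population$individuals, mutations)
  mut_idx <- which(gt == 2L)
  wt_idx <- which(gt < 2L)
  if (length(mut_idx) < n_mutants) {
    stop("population contains only ", length(mut_idx),
         " phenotypic mutants; increase pop_size")
  }
  n_mis <- round(misscore_rate * n_mutants)
  if (n_mis > length(wt_idx)) {
    stop("not enough wild-type individuals to mis-score; increase pop_size")
  }
  take_mut <- mut_idx[sample.int(length(mut_idx), n_mutants)]
  is_mis <- logical(n_mutants)
  if (n_mis > 0) {
    slots <- sample.int(n_mutants, n_mis)
    take_mut[slots] <- wt_idx[sample.int(length(wt_idx), n_mis)]
    is_mis[slots] <- TRUE
  }
  structure(
    list(individuals = population$individuals[take_mut],
         scheme = population$scheme, generation = population$generation,
         misscored_count = n_mis, is_misscored = is_mis),
    class = "pool"
  )
}

#' Dump an individual genome as segment and genotype tables
#'
#' Writes the parental-origin segments of both haplotypes (tab-separated:
#' `chrom`, `start`, `end`, `haplotype`, `origin`) followed by a genotype
#' table at the mutation loci (`chrom`, `pos`, `genotype`, `causal`),
#' separated by a blank line. Intended for debugging and for inspecting
#' directly sequenced genomes.
#'
#' @param ind a `recombinant_genome`.
#' @param genome the [genome_spec] it was bred on.
#' @param path output file path.
#' @param mutations optional `mutation_set` for the genotype table.
#' @return `path`, invisibly.
#' @export
write_individual <- function(ind, genome, path, mutations = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tstart\tend\thaplotype\torigin", con)
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    L <- genome$length[i]
    for (hi in 1:2) {
      h <- ind$haps[[ch]][[hi]]
      bounds <- c(0, h$bp, L)
      lab <- rep(c("A", "B"), length.out = length(bounds) - 1)
      if (!h$startA) lab <- rep(c("B", "A"), length.out = length(lab))
      writeLines(sprintf("%s\t%.0f\t%.0f\th%d\t%s", ch,
                         bounds[-length(bounds)] + 1, bounds[-1], hi, lab),
                 con)
    }
  }
  if (!is.null(mutations)) {
    writeLines("", con)
    writeLines("chrom\tpos\tgenotype\tcausal", con)
    gt <- genotype_at(ind, mutations)
    writeLines(sprintf("%s\t%.0f\t%d\t%d", mutations$chrom, mutations$pos,
                       gt, as.integer(mutations$causal)), con)
  }
  invisible(path)
}

#' Fraction of an individual's genome derived from the mutagenized founder
#'
#' Base-pair-weighted fraction of the diploid genome with parental origin
#' "A" (the mutagenized foreground parent). The complement is the
#' recurrent-parent fraction; the two sum to 1.
#'
#' @param ind a `recombinant_genome`.
#' @param genome the [genome_spec] the individual was bred on.
#' @return numeric in `[0, 1]`.
#' @examples
#' g <- genome_spec("chr1", 1e6)
#' foreground_fraction(founder_genome(g, "A"), g)  # 1
#' @export
foreground_fraction <- function(ind, genome) {
  tot <- 0
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    L <- genome$length[i]
    for (h in ind$haps[[ch]]) {
      lens <- diff(c(0, h$bp, L))
      first <- if (h$startA) 1L else 2L
      if (first <= length(lens)) {
        tot <- tot + sum(lens[seq.int(first, length(lens), by = 2L)])
      }
    }
  }
  tot / (2 * sum(genome$length))
}
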