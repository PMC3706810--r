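# Shared fixtures: all tiny and built in code.

tiny_genome <- function() genome_spec(c("c1", "c2"), c(2e6, 1e6))

# one chromosome, uniform placement, mean one crossover
tiny_plan <- function(markers_per_chrom = 20, mean_crossovers = 1,
                      seed = 101, genome = tiny_genome(), ...) {
  syn <- synthesize_landscape(genome, markers_per_chrom, mean_crossovers,
                              seed = seed, ...)
  list(landscape = syn$landscape, markers = syn$markers,
       plan = simulation_plan(syn$landscape, syn$markers))
}

arabidopsis_plan <- function(markers_per_chrom = 100, seed = 42) {
  sp <- species_preset("arabidopsis")
  syn <- synthesize_landscape(sp$genome, markers_per_chrom,
                              sp$mean_crossovers, seed = seed)
  list(genome = sp$genome, landscape = syn$landscape,
       markers = syn$markers,
       plan = simulation_plan(syn$landscape, syn$markers))
}

# random valid landscape + marker pair for round-trip property tests
random_landscape <- function() {
  n_chr <- sample(1:3, 1)
  g <- genome_spec(paste0("k", seq_len(n_chr)),
                   sample(5e5:5e6, n_chr))
  cp <- list(); fr <- list(); mk <- list()
  for (i in seq_len(n_chr)) {
    k <- sample(2:30, 1)
    pos <- sort(sample.int(g$length[i], k))
    mk[[i]] <- data.frame(chrom = g$chrom[i], pos = pos)
    p <- stats::runif(3); p <- p / sum(p)
    cp[[g$chrom[i]]] <- p
    f <- stats::runif(k); fr[[g$chrom[i]]] <- f / sum(f)
  }
  mk <- do.call(rbind, mk)
  list(
    landscape = recomb_landscape(g, cp, fr,
                                 gamma_shape = stats::runif(1, 0.5, 5),
                                 gamma_scale = stats::runif(1, 0.05, 0.5)),
    markers = marker_map(mk$chrom, mk$pos,
                         norm_weight = stats::runif(nrow(mk), 0.2, 3))
  )
}
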