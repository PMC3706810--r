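# Experiment orchestration: replicate runs of the full
# simulate -> sequence -> analyze pipeline, sweeps over pool size and
# coverage, and the foreground-genome study for direct sequencing.

#' Build a sweep configuration
#'
#' A plain list describing one family of simulated experiments. Can also be
#' read from YAML with [load_sweep_config()].
#'
#' @param scheme `"outcross"`, `"backcross"` or `"direct"`.
#' @param pool_sizes vector of pool sizes (mutant plants per pool; forced
#'   to 1 for the direct scheme).
#' @param coverages vector of mean genome-wide coverages.
#' @param backcross_rounds backcross generations before selfing.
#' @param parent_siblings independent carrier lineages per population.
#' @param n_mutations induced mutations per founder genome (700 and 1400
#'   bracket typical chemical-mutagenesis loads on a ~119 Mb genome).
#' @param misscore_rate fraction of mis-scored plants per pool.
#' @param replicates independent populations per pool-size/coverage cell.
#' @param seed root seed; every replicate derives its own child seed, so
#'   the whole sweep is a pure function of (config, seed).
#' @param species species preset used when no landscape files are given.
#' @param landscape_path,marker_path optional files for an empirical
#'   landscape (see [load_landscape()]).
#' @param markers_per_chrom,mean_crossovers,hotspot_profile overrides for
#'   the synthetic landscape (defaults from the species preset).
#' @param error_rate per-read sequencing error probability.
#' @param error_mode `"split"` or `"flip"` (see [seq_params()]).
#' @param total_reads fixed total read number per experiment, overriding
#'   the coverage target (the coverage value then only labels the cell).
#' @param enrichment logical; target-enrichment sequencing mode.
#' @param confidence mapping-interval confidence level.
#' @param window mapping-interval smoothing window (markers) or `"auto"`.
#' @param min_coverage callable-coverage floor for homozygous calling.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(scheme = c("outcross", "backcross", "direct"),
                         pool_sizes = 50, coverages = 25,
                         backcross_rounds = 1, parent_siblings = 1,
                         n_mutations = 1400, misscore_rate = 0,
                         replicates = 500, seed = 1,
                         species = "arabidopsis",
                         landscape_path = NULL, marker_path = NULL,
                         markers_per_chrom = NULL, mean_crossovers = NULL,
                         hotspot_profile = "uniform",
                         error_rate = 0.003, error_mode = "split",
                         total_reads = NULL, enrichment = NULL,
                         confidence = 0.99, window = "auto",
                         min_coverage = 2) {
  scheme <- match.arg(scheme)
  if (replicates < 1) stop("replicates must be >= 1")
  if (length(pool_sizes) == 0 || length(coverages) == 0) {
    stop("pool_sizes and coverages must be nonempty")
  }
  if (scheme == "direct") pool_sizes <- 1
  structure(
    list(scheme = scheme, pool_sizes = pool_sizes, coverages = coverages,
         backcross_rounds = backcross_rounds,
         parent_siblings = parent_siblings, n_mutations = n_mutations,
         misscore_rate = misscore_rate, replicates = replicates,
         seed = seed, species = species, landscape_path = landscape_path,
         marker_path = marker_path, markers_per_chrom = markers_per_chrom,
         mean_crossovers = mean_crossovers,
         hotspot_profile = hotspot_profile, error_rate = error_rate,
         error_mode = error_mode, total_reads = total_reads,
         enrichment = enrichment, confidence = confidence,
         window = window, min_coverage = min_coverage),
    class = "sweep_config"
  )
}

#' Read a sweep configuration from a YAML file
#'
#' Recognized keys are the arguments of [sweep_config()]; `coverage` and
#' `total_reads` are accepted as aliases for `coverages`, and `pool_size`
#' for `pool_sizes`. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return a `sweep_config`.
#' @export
load_sweep_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$pool_size) && is.null(y$pool_sizes)) {
    y$pool_sizes <- y$pool_size
  }
  if (!is.null(y$coverage) && is.null(y$coverages)) y$coverages <- y$coverage
  if (!is.null(y$generations) && is.null(y$backcross_rounds)) {
    y$backcross_rounds <- y$generations
  }
  y$pool_size <- y$coverage <- y$generations <- NULL
  known <- names(formals(sweep_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(sweep_config, y)
}

#' Prepare the shared simulation context of a sweep
#'
#' Loads or synthesizes the landscape and marker map and precomputes the
#' simulation plan. The synthetic landscape is seeded from the
#' configuration seed, so the context is reproducible.
#'
#' @param config a `sweep_config`.
#' @return list with `landscape`, `markers`, `plan`, `genome`,
#'   `enrichment`.
#' @export
prepare_context <- function(config) {
  if (!is.null(config$landscape_path)) {
    lm <- load_landscape(config$landscape_path, config$marker_path)
  } else {
    preset <- species_preset(config$species)
    lm <- synthesize_landscape(
      preset$genome,
      markers_per_chrom = config$markers_per_chrom %||%
        preset$markers_per_chrom,
      mean_crossovers = config$mean_crossovers %||% preset$mean_crossovers,
      hotspot_profile = config$hotspot_profile,
      seed = child_seed(config$seed, 0)
    )
    if (isTRUE(config$enrichment %||% preset$enrichment)) {
      # mark a contiguous block of markers per chromosome as enriched
      lm$markers$enriched <- enrichment_design(lm$markers)
    }
  }
  plan <- simulation_plan(lm$landscape, lm$markers)
  list(landscape = lm$landscape, markers = lm$markers, plan = plan,
       genome = lm$landscape$genome,
       enrichment = isTRUE(config$enrichment %||% FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default enrichment design: flag the middle half of each chromosome's
# markers as captured.
enrichment_design <- function(markers) {
  enr <- logical(nrow(markers))
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    k <- length(sel)
    enr[sel[seq.int(max(1, k %/% 4), min(k, k - k %/% 4))]] <- TRUE
  }
  enr
}

# Breed until the population holds at least `needed` phenotypic mutants.
breed_with_mutants <- function(config, context, needed) {
  pop_size <- ceiling(needed * 4.4) + 8
  pop <- breed_population(
    scheme = if (config$scheme == "outcross") "outcross" else "backcross",
    pop_size = pop_size, landscape = context$plan,
    mutations = context$mutations,
    backcross_rounds = config$backcross_rounds,
    n_parent_siblings = config$parent_siblings
  )
  reserve <- ceiling(needed * config$misscore_rate) + 1
  repeat {
    gt <- causal_genotypes(pop$individuals, context$mutations)
    if (sum(gt == 2L) >= needed && sum(gt < 2L) >= reserve) break
    top <- breed_population(
      scheme = pop$scheme, pop_size = max(16, ceiling(needed)),
      landscape = context$plan, mutations = context$mutations,
      backcross_rounds = config$backcross_rounds,
      n_parent_siblings = config$parent_siblings
    )
    pop$individuals <- c(pop$individuals, top$individuals)
    pop$lineage <- c(pop$lineage, top$lineage)
  }
  pop
}

#' Run one replicate of a mapping-by-sequencing experiment
#'
#' One full pass: mutagenize a founder, breed the mapping population under
#' the configured crossing scheme, select (and possibly mis-score) the
#' mutant pool, simulate sequencing, and analyze (mapping interval plus CAM
#' count for outcross pools; homozygous-mutation calling for backcross
#' pools; single-genome calling for the direct scheme). Deterministic given
#' `(config$seed, replicate_index, pool_size, coverage)`.
#'
#' @param config a `sweep_config`.
#' @param replicate_index replicate number (1-based).
#' @param context from [prepare_context()]; built on the fly when `NULL`.
#' @param pool_size,coverage cell coordinates; default to the first entries
#'   of the configured lists.
#' @return one-row data.frame with columns `replicate`, `scheme`,
#'   `pool_size`, `coverage`, `chrom`, `start`, `end`, `length_bp`,
#'   `cam_count`, `causal_inside`, `warning`.
#' @export
run_replicate <- function(config, replicate_index, context = NULL,
                          pool_size = NULL, coverage = NULL) {
  if (is.null(context)) context <- prepare_context(config)
  pool_size <- pool_size %||% config$pool_sizes[1]
  coverage <- coverage %||% config$coverages[1]
  set.seed(child_seed(config$seed, round(pool_size), round(100 * coverage),
                      replicate_index))
  context$mutations <- mutagenize(context$genome, config$n_mutations)
  cl <- causal_locus(context$mutations)

  pop <- breed_with_mutants(config, context, pool_size)
  pool <- select_pool(pop, context$mutations, pool_size,
                      config$misscore_rate)
  params <- seq_params(
    error_rate = config$error_rate, coverage = coverage,
    total_reads = config$total_reads,
    mode = if (context$enrichment) "enrichment" else "wgs",
    error_mode = config$error_mode
  )

  rec <- data.frame(
    replicate = replicate_index, scheme = config$scheme,
    pool_size = pool_size, coverage = coverage,
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    length_bp = NA_real_, cam_count = NA_integer_,
    causal_inside = NA, warning = FALSE, stringsAsFactors = FALSE
  )

  if (config$scheme == "outcross") {
    counts <- sequence_pool(pool, context$markers, context$mutations, params)
    iv <- map_interval(counts, confidence = config$confidence,
                       window = config$window, n_pool = pool_size,
                       genome = context$genome)
    rec$chrom <- iv$chrom
    rec$start <- iv$start
    rec$end <- iv$end
    rec$length_bp <- iv$length
    rec$cam_count <- count_cams(iv, context$mutations)
    rec$causal_inside <- interval_contains(iv, cl$chrom, cl$pos)
    rec$warning <- iv$warning
  } else if (config$scheme == "backcross") {
    counts <- sequence_pool(pool, NULL, context$mutations, params)
    tp <- threshold_params(pool_size, m_mis = pool$misscored_count,
                           error_rate = config$error_rate,
                           min_coverage = config$min_coverage)
    cams <- call_homozygous(counts, tp)
    rec$cam_count <- nrow(cams)
    rec$causal_inside <- any(cams$chrom == cl$chrom & cams$pos == cl$pos)
  } else {  # direct
    res <- direct_sequencing_cams(pool$individuals[[1]], context$mutations,
                                  params)
    rec$cam_count <- res$cam_count
    rec$causal_inside <- any(res$cams$chrom == cl$chrom &
                               res$cams$pos == cl$pos)
  }
  rec
}

#' Run a replicate sweep over pool sizes and coverages
#'
#' Runs `config$replicates` independent populations for every combination
#' of pool size and coverage and aggregates the per-cell mean and standard
#' deviation of the mapping-interval length (outcross) and CAM count, plus
#' the fraction of replicates whose interval contains the causal mutation.
#'
#' @param config a `sweep_config`.
#' @param out_dir optional directory; when given, `summary.tsv` and
#'   `replicates.tsv` are written there.
#' @param verbose print per-cell progress.
#' @return a `sweep_summary` list with `summary` and `replicates`
#'   data.frames and the `config`.
#' @export
run_sweep <- function(config, out_dir = NULL, verbose = FALSE) {
  context <- prepare_context(config)
  recs <- list()
  for (ps in config$pool_sizes) {
    for (cv in config$coverages) {
      if (verbose) {
        message(sprintf("sweep cell pool=%d coverage=%gx (%d replicates)",
                        ps, cv, config$replicates))
      }
      for (r in seq_len(config$replicates)) {
        recs[[length(recs) + 1L]] <-
          run_replicate(config, r, context, pool_size = ps, coverage = cv)
      }
    }
  }
  reps <- do.call(rbind, recs)
  cells <- unique(reps[, c("pool_size", "coverage")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- reps$pool_size == cells$pool_size[i] &
      reps$coverage == cells$coverage[i]
    x <- reps[sel, , drop = FALSE]
    data.frame(
      pool_size = cells$pool_size[i], coverage = cells$coverage[i],
      replicates = nrow(x),
      mean_interval_bp = mean(x$length_bp),
      sd_interval_bp = if (nrow(x) > 1) stats::sd(x$length_bp) else NA_real_,
      mean_cams = mean(x$cam_count),
      sd_cams = if (nrow(x) > 1) stats::sd(x$cam_count) else NA_real_,
      frac_causal_inside = mean(x$causal_inside),
      frac_warning = mean(x$warning)
    )
  }))
  out <- structure(list(summary = summ, replicates = reps, config = config),
                   class = "sweep_summary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(reps, file.path(out_dir, "replicates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Foreground-genome study of phenotype-selected backcross mutants
#'
#' Breeds independent backcross lineages (carrier selection at every
#' round), selfs the final backcross plant, and collects phenotypically
#' mutant (causal-homozygous) F2 individuals until `n_individuals` have
#' been sampled; each individual's foreground fraction (the base-pair
#' share of its diploid genome derived from the mutagenized founder) is
#' recorded. Every lineage starts from a freshly mutagenized founder, so
#' the causal locus varies across lineages. Phenotype selection at the
#' causal locus keeps the mean slightly above the unselected expectation
#' `2^-(rounds+1)`.
#'
#' @param landscape a `recomb_landscape` or [simulation_plan()].
#' @param markers marker map when `landscape` is not a plan.
#' @param rounds backcross generations before selfing.
#' @param n_individuals number of selected mutants to collect (>= 1).
#' @param n_mutations induced mutations per founder (default 1400).
#' @param f2_per_lineage F2 plants screened per lineage (default 16, about
#'   4 expected mutants each).
#' @param seed optional seed.
#' @return data.frame with columns `lineage`, `foreground` (fractions in
#'   `[0, 1]`).
#' @export
foreground_backcross_study <- function(landscape, markers = NULL, rounds,
                                       n_individuals = 500,
                                       n_mutations = 1400,
                                       f2_per_lineage = 16, seed = NULL) {
  plan <- as_sim_plan(landscape, markers)
  if (!is.null(seed)) set.seed(seed)
  genome <- plan$genome
  out_fg <- numeric(0)
  out_lin <- integer(0)
  lineage <- 0L
  while (length(out_fg) < n_individuals) {
    lineage <- lineage + 1L
    mut <- mutagenize(genome, n_mutations)
    cl <- causal_locus(mut)
    parent <- bc_lineage_parent(plan, cl, rounds, carrier = "het")
    for (j in seq_len(f2_per_lineage)) {
      g1 <- sample_gamete(parent, plan)
      g2 <- sample_gamete(parent, plan)
      if (hap_origin_A(g1[[cl$chrom]], cl$pos) &&
          hap_origin_A(g2[[cl$chrom]], cl$pos)) {
        ind <- new_individual(g1, g2)
        out_fg <- c(out_fg, foreground_fraction(ind, genome))
        out_lin <- c(out_lin, lineage)
      }
    }
  }
  data.frame(lineage = out_lin, foreground = out_fg)
}
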