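# Genomes, recombination landscapes and marker maps: containers, synthetic
# generation, marker filtering, and the tab-separated file dialects.

#' Create a genome specification
#'
#' A genome is an ordered set of named chromosomes with lengths in base
#' pairs. All simulation happens at marker resolution on these coordinates;
#' positions are 1-based and inclusive.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp (all > 0).
#' @return a `genome_spec`: a data.frame with columns `chrom` and `length`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(30e6, 20e6))
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    stop("`chrom` and `length` must have the same length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_spec", "data.frame")
  )
}

#' Species-like simulation presets
#'
#' Convenience presets with standard reference chromosome numbers and sizes
#' and field-typical recombination settings: an Arabidopsis-like genome
#' (5 chromosomes, ~119 Mb), a rice-like genome (12 chromosomes, ~380 Mb,
#' slightly elevated recombination) and a barley-like genome (7 chromosomes,
#' ~4.6 Gb, reduced recombination, target-enrichment sequencing by default).
#'
#' @param species one of `"arabidopsis"`, `"rice"`, `"barley"`.
#' @return a list with elements `genome` ([genome_spec]), `mean_crossovers`
#'   (expected crossovers per chromosome per meiosis), `markers_per_chrom`,
#'   and `enrichment` (logical, default sequencing mode).
#' @examples
#' species_preset("arabidopsis")$genome
#' @export
species_preset <- function(species = c("arabidopsis", "rice", "barley")) {
  species <- match.arg(species)
  switch(species,
    arabidopsis = list(
      genome = genome_spec(
        paste0("chr", 1:5),
        c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 26.9e6)
      ),
      mean_crossovers = 1.0,
      markers_per_chrom = 150L,
      enrichment = FALSE
    ),
    rice = list(
      genome = genome_spec(
        paste0("chr", 1:12),
        round(1e6 * c(44.1, 36.6, 37.1, 36.1, 30.5, 31.8, 30.2, 29.0,
                      23.4, 23.6, 29.5, 28.1))
      ),
      mean_crossovers = 1.2,
      markers_per_chrom = 120L,
      enrichment = FALSE
    ),
    barley = list(
      genome = genome_spec(
        paste0("chr", 1:7),
        round(1e6 * c(558, 768, 700, 647, 670, 583, 657))
      ),
      mean_crossovers = 0.8,
      markers_per_chrom = 200L,
      enrichment = TRUE
    )
  )
}

#' Create a marker map
#'
#' Ordered marker positions per chromosome with a coverage-normalization
#' weight per marker. The weight is the ratio of the expected sequencing
#' coverage at the marker to the genome-wide average (dimensionless,
#' genome-average 1); when coverage is allocated by a multinomial draw the
#' weights are renormalized to sum to 1. Optional columns carry a
#' resequencing quality score, a copy-number-variation flag and a
#' target-enrichment flag used by [filter_markers()] and enrichment-mode
#' sequencing.
#'
#' @param chrom chromosome name per marker.
#' @param pos 1-based position in bp; strictly increasing within chromosome.
#' @param norm_weight non-negative coverage-normalization weight (default 1).
#' @param quality optional resequencing quality score (`NA` = unknown).
#' @param cnv logical, marker overlaps a copy-number-variable region.
#' @param enriched logical, marker is covered by the enrichment design.
#' @return a `marker_map` data.frame with the above columns.
#' @export
marker_map <- function(chrom, pos, norm_weight = 1, quality = NA_real_,
                       cnv = FALSE, enriched = FALSE) {
  n <- length(pos)
  m <- data.frame(
    chrom = as.character(chrom), pos = as.numeric(pos),
    norm_weight = rep_len(as.numeric(norm_weight), n),
    quality = rep_len(as.numeric(quality), n),
    cnv = rep_len(as.logical(cnv), n),
    enriched = rep_len(as.logical(enriched), n),
    stringsAsFactors = FALSE
  )
  m <- m[order(match(m$chrom, unique(m$chrom)), m$pos), , drop = FALSE]
  rownames(m) <- NULL
  m <- structure(m, class = c("marker_map", "data.frame"))
  validate_marker_map(m)
  m
}

validate_marker_map <- function(m, genome = NULL) {
  stopifnot(is.data.frame(m))
  need <- c("chrom", "pos", "norm_weight")
  if (!all(need %in% names(m))) {
    stop("marker map must have columns chrom, pos, norm_weight")
  }
  if (any(m$pos < 1)) stop("marker positions must be >= 1")
  if (any(m$norm_weight < 0)) stop("norm_weight must be >= 0")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("marker positions must be strictly increasing on ", ch)
    }
    if (!is.null(genome)) {
      L <- genome$length[genome$chrom == ch]
      if (length(L) != 1) stop("marker chromosome ", ch, " not in genome")
      if (max(p) > L) stop("marker position beyond chromosome end on ", ch)
    }
  }
  invisible(m)
}

#' Create a recombination landscape
#'
#' Per chromosome, the landscape holds (i) the probabilities `(p1, p2, p3)`
#' of zero, one, and two-or-more crossovers per meiosis, (ii) one
#' recombination-placement frequency per marker, where entry `i` is the
#' probability that a crossover falls in the half-open interval between
#' marker `i - 1` and marker `i` (entry 1 covers chromosome start to the
#' first marker), and (iii) the shape and scale of the gamma model for the
#' genetic-distance spacing of successive crossovers (crossover
#' interference).
#'
#' @param genome a [genome_spec].
#' @param count_probs named list (or matrix rows) per chromosome of length-3
#'   probability vectors summing to 1.
#' @param interval_freqs named list per chromosome of non-negative placement
#'   frequencies (one per marker, summing to 1 per chromosome).
#' @param gamma_shape,gamma_scale positive gamma interference parameters;
#'   recycled across chromosomes. The scale is in normalized genetic
#'   distance (the per-chromosome placement frequencies sum to 1).
#' @param geom_continuation continuation probability of the geometric tail
#'   that resolves the "two or more" crossover category: a realized count in
#'   that category is `2 + G` with `G ~ Geometric(1 - geom_continuation)`.
#' @return a `recomb_landscape` object.
#' @seealso [synthesize_landscape()], [load_landscape()]
#' @export
recomb_landscape <- function(genome, count_probs, interval_freqs,
                             gamma_shape = 2, gamma_scale = 1 / 6,
                             geom_continuation = 0.1) {
  stopifnot(inherits(genome, "genome_spec"))
  n <- nrow(genome)
  gamma_shape <- rep_len(gamma_shape, n)
  gamma_scale <- rep_len(gamma_scale, n)
  chrom <- vector("list", n)
  names(chrom) <- genome$chrom
  for (i in seq_len(n)) {
    ch <- genome$chrom[i]
    cp <- as.numeric(count_probs[[ch]])
    fr <- as.numeric(interval_freqs[[ch]])
    chrom[[i]] <- list(
      count_probs = cp, interval_freqs = fr,
      gamma_shape = gamma_shape[i], gamma_scale = gamma_scale[i]
    )
  }
  ls <- structure(
    list(genome = genome, chrom = chrom,
         geom_continuation = geom_continuation),
    class = "recomb_landscape"
  )
  validate_landscape(ls)
  ls
}

validate_landscape <- function(ls, markers = NULL, tol = 1e-6) {
  stopifnot(inherits(ls, "recomb_landscape"))
  for (ch in names(ls$chrom)) {
    x <- ls$chrom[[ch]]
    if (length(x$count_probs) != 3 || any(x$count_probs < -1e-12)) {
      stop("count_probs for ", ch, " must be three non-negative values")
    }
    if (abs(sum(x$count_probs) - 1) > tol) {
      stop("count probabilities for ", ch, " must sum to 1 (got ",
           format(sum(x$count_probs)), ")")
    }
    if (any(x$interval_freqs < -1e-12)) {
      stop("interval frequencies for ", ch, " must be non-negative")
    }
    if (abs(sum(x$interval_freqs) - 1) > tol) {
      stop("interval frequencies for ", ch, " must sum to 1 (got ",
           format(sum(x$interval_freqs)), ")")
    }
    if (x$gamma_shape <= 0 || x$gamma_scale <= 0) {
      stop("gamma interference parameters for ", ch, " must be positive")
    }
    if (!is.null(markers)) {
      k <- sum(markers$chrom == ch)
      if (length(x$interval_freqs) != k) {
        stop("interval frequencies for ", ch, " (",
             length(x$interval_freqs), ") do not match marker count (", k, ")")
      }
    }
  }
  if (ls$geom_continuation < 0 || ls$geom_continuation >= 1) {
    stop("geom_continuation must be in [0, 1)")
  }
  invisible(ls)
}

#' Expected realized crossover count of a landscape chromosome
#'
#' `p2 + p3 * kbar` where `kbar = 2 + q/(1-q)` is the mean of the geometric
#' resolution of the two-or-more category with continuation probability `q`.
#'
#' @param landscape a `recomb_landscape`.
#' @param chrom chromosome name.
#' @return expected crossovers per meiosis.
#' @export
expected_crossovers <- function(landscape, chrom) {
  x <- landscape$chrom[[chrom]]
  q <- landscape$geom_continuation
  kbar <- 2 + q / (1 - q)
  x$count_probs[2] + x$count_probs[3] * kbar
}

# Map a mean crossover count to (p1, p2, p3) under the geometric tail.
count_probs_from_mean <- function(mean_crossovers, tail_mass = NULL,
                                  geom_continuation = 0.1) {
  c0 <- mean_crossovers
  if (c0 < 0) stop("mean_crossovers must be >= 0")
  kbar <- 2 + geom_continuation / (1 - geom_continuation)
  q <- if (is.null(tail_mass)) min(c0^2 / 4, 0.3) else tail_mass
  p3 <- q
  p2 <- c0 - kbar * p3
  p1 <- 1 - p2 - p3
  p <- c(p1, p2, p3)
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("mean_crossovers = ", format(c0), " is incompatible with the ",
         "three-category crossover model (tail mass ", format(q), "); ",
         "adjust `tail_mass`")
  }
  pmin(pmax(p, 0), 1)
}

#' Synthesize a species-like recombination landscape and marker map
#'
#' Generates a marker map with roughly evenly spaced (jittered) markers and
#' a recombination landscape whose per-chromosome crossover-count
#' probabilities are chosen so that the expected realized crossover count
#' equals `mean_crossovers`. Placement frequencies are uniform per interval
#' or concentrated in a few hotspot regions.
#'
#' @param genome a [genome_spec], e.g. from [species_preset()].
#' @param markers_per_chrom number of markers per chromosome (>= 2).
#' @param mean_crossovers expected crossovers per chromosome per meiosis;
#'   recycled across chromosomes. With the default tail mass the feasible
#'   range is approximately `[0, 1.33]`; larger means need `tail_mass`.
#' @param hotspot_profile `"uniform"` (equal placement probability per
#'   interval) or `"peaked"` (a few gaussian hotspot bumps over a uniform
#'   floor).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param gamma_shape interference strength (coefficient of variation of
#'   crossover spacing is `1/sqrt(gamma_shape)`).
#' @param gamma_scale gamma scale in normalized genetic distance; default
#'   `NULL` sets the mean spacing to 1/3 of the chromosome's genetic length
#'   (the expected spacing of two uniform crossovers).
#' @param tail_mass probability of the two-or-more category; default
#'   `min(mean_crossovers^2/4, 0.3)`.
#' @param geom_continuation see [recomb_landscape()].
#' @return a list with elements `landscape` and `markers`.
#' @examples
#' sp <- species_preset("arabidopsis")
#' syn <- synthesize_landscape(sp$genome, markers_per_chrom = 50,
#'                             mean_crossovers = 1, seed = 1)
#' @export
synthesize_landscape <- function(genome, markers_per_chrom = 100,
                                 mean_crossovers = 1,
                                 hotspot_profile = c("uniform", "peaked"),
                                 seed = NULL,
                                 gamma_shape = 2, gamma_scale = NULL,
                                 tail_mass = NULL, geom_continuation = 0.1) {
  stopifnot(inherits(genome, "genome_spec"))
  hotspot_profile <- match.arg(hotspot_profile)
  if (markers_per_chrom < 2) stop("markers_per_chrom must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genome)
  mean_crossovers <- rep_len(mean_crossovers, n)
  if (is.null(gamma_scale)) gamma_scale <- (1 / 3) / gamma_shape

  count_probs <- list()
  interval_freqs <- list()
  mk <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- genome$chrom[i]
    L <- genome$length[i]
    k <- markers_per_chrom
    # evenly spaced markers with mild jitter, kept strictly increasing
    base <- L * (seq_len(k) - 0.5) / k
    jit <- stats::runif(k, -0.3, 0.3) * L / k
    pos <- round(pmin(pmax(base + jit, 1), L))
    pos <- sort(unique(pos))
    while (length(pos) < k) {
      extra <- round(stats::runif(k - length(pos), 1, L))
      pos <- sort(unique(c(pos, extra)))
    }
    mk[[i]] <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)

    count_probs[[ch]] <- count_probs_from_mean(
      mean_crossovers[i], tail_mass, geom_continuation
    )
    kk <- length(pos)
    if (hotspot_profile == "uniform") {
      f <- rep(1, kk)
    } else {
      nb <- max(1L, round(kk / 40))
      centers <- sample.int(kk, nb)
      width <- kk / 20
      f <- rep(0.2, kk)
      for (cc in centers) {
        f <- f + 0.8 * exp(-0.5 * ((seq_len(kk) - cc) / width)^2)
      }
    }
    interval_freqs[[ch]] <- f / sum(f)
  }
  mk <- do.call(rbind, mk)
  markers <- marker_map(mk$chrom, mk$pos)
  landscape <- recomb_landscape(
    genome, count_probs, interval_freqs,
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    geom_continuation = geom_continuation
  )
  validate_landscape(landscape, markers)
  list(landscape = landscape, markers = markers)
}

#' Filter a raw marker set to high-quality, well-spaced markers
#'
#' Applies the standard high-quality marker selection: markers with a
#' resequencing quality score below `quality_min` are discarded (markers
#' with unknown quality are kept), markers flagged as overlapping
#' copy-number-variable regions are discarded, and markers closer than
#' `min_spacing` to their left neighbour are iteratively removed. The
#' spacing scan runs left to right and drops the right member of each
#' offending pair, repeating until no pair is closer than `min_spacing`;
#' the operation is idempotent.
#'
#' @param raw a [marker_map] with `quality` and `cnv` columns.
#' @param quality_min minimum retained quality score (default 25).
#' @param min_spacing minimum distance between adjacent markers in bp
#'   (default 50).
#' @return the filtered `marker_map` (possibly empty).
#' @examples
#' m <- marker_map("chr1", c(100, 140, 200), quality = 30)
#' filter_markers(m)$pos  # 140 is only 40 bp from 100 and is removed
#' @export
filter_markers <- function(raw, quality_min = 25, min_spacing = 50) {
  validate_marker_map(raw)
  keep <- (is.na(raw$quality) | raw$quality >= quality_min) & !raw$cnv
  m <- raw[keep, , drop = FALSE]
  # left-to-right scan dropping the right member of any pair closer than
  # min_spacing, iterated to a fixed point (a single greedy pass already is
  # one, but the loop makes idempotence explicit)
  repeat {
    if (nrow(m) < 2) break
    keep2 <- logical(nrow(m))
    last_pos <- -Inf
    last_chrom <- ""
    for (i in seq_len(nrow(m))) {
      if (m$chrom[i] != last_chrom || m$pos[i] - last_pos >= min_spacing) {
        keep2[i] <- TRUE
        last_pos <- m$pos[i]
        last_chrom <- m$chrom[i]
      }
    }
    if (all(keep2)) break
    m <- m[keep2, , drop = FALSE]
  }
  rownames(m) <- NULL
  structure(m, class = c("marker_map", "data.frame"))
}

# ---------------------------------------------------------------------------
# File dialects.
#
# Landscape file: two tab-separated tables in one file, separated by a blank
# line. Table 1: chrom, p1, p2, p3, gamma_shape, gamma_scale. Table 2:
# chrom, interval_index, p_mi. A comment line "#geom_continuation <q>" may
# precede table 1. Chromosome lengths travel in a "#chrom <name> <length>"
# comment per chromosome so a landscape file is self-contained.
#
# Marker file: tab-separated, columns chrom, pos, norm_weight and optional
# quality, cnv, enriched. Positions are 1-based inclusive (BED-adjacent but
# NOT 0-based).
# ---------------------------------------------------------------------------

#' Write a recombination landscape to its tab-separated file dialect
#'
#' @param landscape a `recomb_landscape`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_landscape()] for the dialect description.
#' @export
write_landscape <- function(landscape, path) {
  validate_landscape(landscape)
  con <- file(path, "w")
  on.exit(close(con))
  g <- landscape$genome
  writeLines(sprintf("#geom_continuation\t%.17g", landscape$geom_continuation),
             con)
  writeLines(sprintf("#chrom\t%s\t%.17g", g$chrom, g$length), con)
  writeLines("chrom\tp1\tp2\tp3\tgamma_shape\tgamma_scale", con)
  for (ch in g$chrom) {
    x <- landscape$chrom[[ch]]
    writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g\t%.17g\t%.17g", ch,
                       x$count_probs[1], x$count_probs[2], x$count_probs[3],
                       x$gamma_shape, x$gamma_scale), con)
  }
  writeLines("", con)
  writeLines("chrom\tinterval_index\tp_mi", con)
  for (ch in g$chrom) {
    f <- landscape$chrom[[ch]]$interval_freqs
    writeLines(sprintf("%s\t%d\t%.17g", ch, seq_along(f), f), con)
  }
  invisible(path)
}

#' Write a marker map to its tab-separated file dialect
#'
#' @param markers a [marker_map].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  validate_marker_map(markers)
  out <- data.frame(
    chrom = markers$chrom, pos = sprintf("%.0f", markers$pos),
    norm_weight = sprintf("%.17g", markers$norm_weight),
    quality = ifelse(is.na(markers$quality), "NA",
                     sprintf("%.17g", markers$quality)),
    cnv = as.integer(markers$cnv), enriched = as.integer(markers$enriched),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s, line %d: %s", path, line, msg), call. = FALSE)
}

#' Load a recombination landscape and marker map from files
#'
#' Reads the two tab-separated dialects written by [write_landscape()] and
#' [write_markers()]. The landscape file holds one table of per-chromosome
#' crossover-count probabilities and gamma interference parameters and a
#' second table of per-marker-interval placement frequencies, separated by
#' a blank line; `#chrom` comment lines carry chromosome lengths. The marker
#' file has columns `chrom`, `pos` (1-based, inclusive), `norm_weight` and
#' optionally `quality`, `cnv`, `enriched`.
#'
#' Both files are validated: probabilities must sum to 1 per chromosome
#' (tolerance 1e-6) and the number of placement frequencies must match the
#' marker count per chromosome.
#'
#' @param landscape_path path to the landscape file.
#' @param marker_path path to the marker file.
#' @return a list with elements `landscape` and `markers`.
#' @export
load_landscape <- function(landscape_path, marker_path) {
  if (!file.exists(landscape_path)) stop("no such file: ", landscape_path)
  if (!file.exists(marker_path)) stop("no such file: ", marker_path)

  lines <- readLines(landscape_path)
  geom_cont <- 0.1
  chrom_len <- character()
  body_idx <- which(!startsWith(lines, "#"))
  for (i in which(startsWith(lines, "#"))) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "#geom_continuation") geom_cont <- as.numeric(f[2])
    if (f[1] == "#chrom") chrom_len[f[2]] <- f[3]
  }
  if (length(chrom_len) == 0) {
    stop(landscape_path, ": no #chrom length lines found")
  }
  genome <- genome_spec(names(chrom_len), as.numeric(chrom_len))

  body <- lines[body_idx]
  blank <- which(body == "")
  if (length(blank) == 0) {
    stop(landscape_path, ": expected two tables separated by a blank line")
  }
  t1 <- body[seq_len(blank[1] - 1)]
  t2 <- body[seq(blank[1] + 1, length(body))]
  t2 <- t2[t2 != ""]

  hdr1 <- strsplit(t1[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr1, c("chrom", "p1", "p2", "p3", "gamma_shape",
                         "gamma_scale"))) {
    parse_error(landscape_path, 1, "bad header in count-probability table")
  }
  count_probs <- list(); shape <- c(); scale <- c()
  for (i in seq_along(t1)[-1]) {
    f <- strsplit(t1[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6) parse_error(landscape_path, i, "expected 6 fields")
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) parse_error(landscape_path, i, "non-numeric field")
    count_probs[[f[1]]] <- v[1:3]
    shape[f[1]] <- v[4]; scale[f[1]] <- v[5]
  }
  hdr2 <- strsplit(t2[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr2, c("chrom", "interval_index", "p_mi"))) {
    parse_error(landscape_path, 1, "bad header in interval-frequency table")
  }
  freq <- list()
  for (i in seq_along(t2)[-1]) {
    f <- strsplit(t2[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3) parse_error(landscape_path, i, "expected 3 fields")
    p <- suppressWarnings(as.numeric(f[3]))
    if (is.na(p)) parse_error(landscape_path, i, "non-numeric p_mi")
    freq[[f[1]]] <- c(freq[[f[1]]], p)
  }

  mtab <- utils::read.table(marker_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "norm_weight") %in% names(mtab))) {
    stop(marker_path, ": must have columns chrom, pos, norm_weight")
  }
  markers <- marker_map(
    mtab$chrom, mtab$pos, mtab$norm_weight,
    quality = if ("quality" %in% names(mtab)) mtab$quality else NA_real_,
    cnv = if ("cnv" %in% names(mtab)) as.logical(mtab$cnv) else FALSE,
    enriched = if ("enriched" %in% names(mtab)) {
      as.logical(mtab$enriched)
    } else FALSE
  )
  validate_marker_map(markers, genome)

  landscape <- recomb_landscape(
    genome, count_probs, freq,
    gamma_shape = shape[genome$chrom], gamma_scale = scale[genome$chrom],
    geom_continuation = geom_cont
  )
  validate_landscape(landscape, markers)
  list(landscape = landscape, markers = markers)
}

# Per-chromosome crossover placement profile: the marker intervals extended
# with a terminal interval from the last marker to the chromosome end,
# weighted by the last interval's per-bp rate, then renormalized. Interval i
# is (starts[i], ends[i]] with placement probability probs[i].
placement_profile <- function(landscape, markers, chrom) {
  L <- landscape$genome$length[landscape$genome$chrom == chrom]
  pos <- markers$pos[markers$chrom == chrom]
  p <- landscape$chrom[[chrom]]$interval_freqs
  stopifnot(length(p) == length(pos))
  starts <- c(0, pos)
  ends <- c(pos, L)
  probs <- p
  k <- length(pos)
  if (ends[k + 1] > starts[k + 1]) {
    width_last <- pos[k] - if (k > 1) pos[k - 1] else 0
    rate <- if (width_last > 0) p[k] / width_last else 0
    probs <- c(p, rate * (L - pos[k]))
  } else {
    starts <- starts[seq_len(k)]
    ends <- ends[seq_len(k)]
  }
  probs <- probs / sum(probs)
  list(
    starts = starts, ends = ends, widths = ends - starts,
    probs = probs, cum = cumsum(probs), L = L
  )
}
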