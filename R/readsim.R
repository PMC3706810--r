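# Single-end versus paired-end comparison: random read (pair) alignments
# over a genome, scored as informative when they overlap at least one
# marker.

#' Draw random read or read-pair alignments
#'
#' Start positions are uniform over the positions at which the full
#' alignment footprint fits on a chromosome (chromosomes weighted by their
#' allowed start space). For paired-end mode the insert length is fixed at
#' exactly three times the read length, so the two mates cover
#' `[start, start + len - 1]` and `[start + 2 len, start + 3 len - 1]`.
#' Draws whose reads overlap a region of an optional exclusion mask
#' (modelling repeat/multi-mapping regions) are flagged `excluded`; they
#' stay in the sample but can never be informative.
#'
#' @param genome a [genome_spec].
#' @param read_length read length in bp; a warning is emitted outside the
#'   typical short-read range of 50-750 bp.
#' @param mode `"SE"` or `"PE"`.
#' @param n_draws number of random alignments (default 100000).
#' @param excluded optional data.frame `chrom`, `start`, `end` of
#'   multi-mapping regions (1-based, inclusive, non-overlapping).
#' @return an `alignment_draws` data.frame with columns `chrom`, `start`,
#'   `end`, `mate_start`, `mate_end` (`NA` for SE) and `excluded`, plus
#'   attributes `mode` and `read_length`.
#' @export
draw_alignments <- function(genome, read_length, mode = c("SE", "PE"),
                            n_draws = 100000, excluded = NULL) {
  mode <- match.arg(mode)
  read_length <- as.integer(read_length)
  if (read_length < 50 || read_length > 750) {
    warning("read_length ", read_length,
            " is outside the typical 50-750 bp short-read range")
  }
  span <- if (mode == "PE") 3L * read_length else read_length
  allowed <- genome$length - span + 1
  if (any(allowed < 1)) {
    stop("alignment span ", span, " bp exceeds the shortest chromosome")
  }
  if (n_draws == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mate_start = numeric(0),
                      mate_end = numeric(0), excluded = logical(0))
    attr(out, "mode") <- mode
    attr(out, "read_length") <- read_length
    return(out)
  }
  ci <- sample.int(nrow(genome), n_draws, replace = TRUE, prob = allowed)
  start <- floor(stats::runif(n_draws) * allowed[ci]) + 1
  end <- start + read_length - 1
  if (mode == "PE") {
    mate_start <- start + 2 * read_length
    mate_end <- start + 3 * read_length - 1
  } else {
    mate_start <- rep(NA_real_, n_draws)
    mate_end <- rep(NA_real_, n_draws)
  }
  chrom <- genome$chrom[ci]
  excl <- logical(n_draws)
  if (!is.null(excluded) && nrow(excluded) > 0) {
    for (ch in unique(excluded$chrom)) {
      reg <- excluded[excluded$chrom == ch, , drop = FALSE]
      reg <- reg[order(reg$start), , drop = FALSE]
      sel <- which(chrom == ch)
      if (length(sel) == 0) next
      hit <- overlaps_regions(start[sel], end[sel], reg)
      if (mode == "PE") {
        hit <- hit | overlaps_regions(mate_start[sel], mate_end[sel], reg)
      }
      excl[sel] <- hit
    }
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    mate_start = mate_start, mate_end = mate_end,
                    excluded = excl, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "read_length") <- read_length
  out
}

# TRUE where [s, e] overlaps any of the sorted, disjoint regions.
overlaps_regions <- function(s, e, reg) {
  i <- findInterval(e, reg$start)
  hit <- i >= 1
  hit[hit] <- reg$end[i[hit]] >= s[hit]
  hit
}

#' Fraction of informative read (pair) alignments
#'
#' An alignment is informative when at least one marker position falls
#' inside the read (single-end) or inside either mate of the pair
#' (paired-end); a pair overlapping markers with both mates still counts
#' once, since the two mates share one genetic background and cannot
#' contribute twice to allele-frequency estimation. Markers inside the
#' unsequenced insert gap do not count. Excluded (multi-mapping) draws are
#' never informative.
#'
#' @param draws an `alignment_draws` data.frame from [draw_alignments()].
#' @param markers a [marker_map] (only `chrom`/`pos` are used).
#' @return fraction in `[0, 1]` of informative draws.
#' @export
informative_fraction <- function(draws, markers) {
  if (nrow(draws) == 0) return(NA_real_)
  info <- logical(nrow(draws))
  for (ch in unique(draws$chrom)) {
    mpos <- sort(markers$pos[markers$chrom == ch])
    sel <- which(draws$chrom == ch)
    if (length(mpos) == 0) next
    hit <- findInterval(draws$end[sel], mpos) -
      findInterval(draws$start[sel] - 1, mpos) >= 1
    ms <- draws$mate_start[sel]
    pe <- !is.na(ms)
    if (any(pe)) {
      hit[pe] <- hit[pe] |
        (findInterval(draws$mate_end[sel][pe], mpos) -
           findInterval(ms[pe] - 1, mpos) >= 1)
    }
    info[sel] <- hit
  }
  mean(info & !draws$excluded)
}

#' Compare single-end and paired-end informative-read fractions
#'
#' For each read length, draws `n_draws` random alignments in each mode and
#' reports the informative fractions and the paired-end excess, i.e. how
#' many percent more informative alignments paired-end sequencing yields
#' (equivalently, how many percent more single-end reads would be needed to
#' match it). Distinct marker sets per mode are supported since the two
#' modes have different mappability.
#'
#' @param genome a [genome_spec].
#' @param markers_se marker set for single-end scoring.
#' @param markers_pe marker set for paired-end scoring (defaults to
#'   `markers_se`).
#' @param read_lengths numeric vector of read lengths in bp.
#' @param n_draws random alignments per mode and length (default 100000).
#' @param excluded optional exclusion mask (see [draw_alignments()]).
#' @param seed optional seed.
#' @return data.frame `read_length`, `se_fraction`, `pe_fraction`,
#'   `pe_excess_pct` (NA when the SE fraction is 0), ordered by read
#'   length.
#' @export
compare_se_pe <- function(genome, markers_se, markers_pe = NULL,
                          read_lengths = c(50, 100, 250, 500, 750),
                          n_draws = 100000, excluded = NULL, seed = NULL) {
  if (is.null(markers_pe)) markers_pe <- markers_se
  if (nrow(markers_se) == 0 || nrow(markers_pe) == 0) {
    stop("marker sets must be nonempty")
  }
  if (!is.null(seed)) set.seed(seed)
  read_lengths <- sort(read_lengths)
  rows <- lapply(read_lengths, function(rl) {
    se <- informative_fraction(
      draw_alignments(genome, rl, "SE", n_draws, excluded), markers_se
    )
    pe <- informative_fraction(
      draw_alignments(genome, rl, "PE", n_draws, excluded), markers_pe
    )
    data.frame(
      read_length = rl, se_fraction = se, pe_fraction = pe,
      pe_excess_pct = if (se > 0) 100 * (pe / se - 1) else NA_real_
    )
  })
  do.call(rbind, rows)
}
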