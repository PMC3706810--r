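# Downstream analysis: allele-frequency thresholds for homozygous
# candidate-mutation calling in backcross pools, likelihood-ratio
# confidence mapping intervals for outcross pools, and CAM counting.

#' Threshold parameters for homozygous mutation calling
#'
#' @param n total number of mutants in the pool (>= 1).
#' @param m_mis assumed number of mis-scored (wild-type) plants in the pool
#'   (default 0). Experiments that study mis-scoring must set this; the
#'   genotype-frequency threshold exists precisely to absorb the wild-type
#'   alleles such plants introduce.
#' @param error_rate assumed per-read sequencing error frequency
#'   (default 0.003).
#' @param min_coverage minimum coverage for a locus to be callable
#'   (default 2; at coverage 1 the read-frequency threshold is vacuous).
#' @return a `threshold_params` list.
#' @export
threshold_params <- function(n, m_mis = 0, error_rate = 0.003,
                             min_coverage = 2) {
  if (n < 1) stop("n must be >= 1")
  if (m_mis < 0 || m_mis >= n) stop("m_mis must be in [0, n)")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(list(n = n, m_mis = m_mis, error_rate = error_rate,
                 min_coverage = min_coverage), class = "threshold_params")
}

#' Genotype-frequency threshold for homozygous calling
#'
#' The mutant allele frequency of a pool of `n` plants in which `m_mis`
#' mis-scored plants plus one further wild-type chromosome are present:
#' `g_f = 1 - (2 m_mis + 1) / (2 n)`. Mutations must exceed this frequency
#' to be considered fixed in the pool.
#'
#' @param params a [threshold_params()].
#' @return `g_f`, always < 1.
#' @examples
#' genotype_frequency_threshold(threshold_params(n = 50))            # 0.99
#' genotype_frequency_threshold(threshold_params(n = 50, m_mis = 1)) # 0.97
#' @export
genotype_frequency_threshold <- function(params) {
  1 - (2 * params$m_mis + 1) / (2 * params$n)
}

#' Read-frequency threshold for homozygous calling
#'
#' The mutant allele frequency observed when one read at a position of
#' coverage `c_p` samples a non-mutant chromosome or is a sequencing error:
#' `r_f = 1 - (c_p e + 1) / c_p = 1 - e - 1/c_p`.
#'
#' @param c_p coverage at the position (>= 1); vectorized.
#' @param error_rate estimated sequencing error frequency `e`.
#' @return `r_f` per position; positions with zero coverage return `NA`
#'   (no call possible).
#' @examples
#' read_frequency_threshold(100)  # 0.987
#' read_frequency_threshold(25)   # 0.957
#' @export
read_frequency_threshold <- function(c_p, error_rate = 0.003) {
  out <- 1 - error_rate - 1 / c_p
  out[c_p < 1] <- NA_real_
  out
}

#' Call homozygous candidate mutations in a backcross pool
#'
#' A mutation locus is called homozygous (a candidate mutation, CAM) iff
#' its coverage is at least `min_coverage` and its observed mutant allele
#' frequency exceeds both the genotype-frequency threshold `g_f` and the
#' read-frequency threshold `r_f`.
#'
#' @param counts a `pool_counts` data.frame (rows with
#'   `locus_type == "mutation"` are considered; if the column is absent all
#'   rows are).
#' @param params a [threshold_params()].
#' @return the called subset of `counts`, with columns `freq`, `g_f`,
#'   `r_f` appended.
#' @export
call_homozygous <- function(counts, params) {
  stopifnot(inherits(params, "threshold_params"))
  x <- counts
  if ("locus_type" %in% names(x)) {
    x <- x[x$locus_type == "mutation", , drop = FALSE]
  }
  gf <- genotype_frequency_threshold(params)
  rf <- read_frequency_threshold(x$cov, params$error_rate)
  freq <- ifelse(x$cov > 0, x$count_mut / x$cov, NA_real_)
  called <- !is.na(freq) & x$cov >= params$min_coverage &
    freq > gf & !is.na(rf) & freq > rf
  out <- x[called, , drop = FALSE]
  out$freq <- freq[called]
  out$g_f <- rep(gf, nrow(out))
  out$r_f <- rf[called]
  rownames(out) <- NULL
  out
}

rolling_sum <- function(x, w) {
  n <- length(x)
  if (n == 0) return(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

#' Confidence mapping interval for an outcross pool
#'
#' Converts pooled marker counts into a confidence mapping interval with a
#' likelihood-ratio test on window-aggregated allele frequencies. Per
#' chromosome, the observed mutant-allele frequency is aggregated over a
#' sliding window of `window` markers (coverage-weighted; the window
#' shrinks at chromosome ends), giving a smoothed frequency track
#' `f(pos)` and its window coverage `C(pos)`. The sampling variance of
#' `f(pos)` has two parts: read sampling, `f (1 - f) / C(pos)`, and pool
#' sampling, `f (1 - f) / (2 n_pool)` — the latter does not shrink with
#' window size because all markers of a window are read from the same
#' `2 n_pool` pooled chromosomes, and it is what makes mapping resolution
#' pool-size-limited rather than coverage-limited.
#'
#' The peak is the maximum of the smoothed frequency (ties broken by the
#' leftmost position) and a position belongs to the interval while the
#' Gaussian likelihood-ratio statistic of "same underlying frequency as
#' the peak",
#' `(f_peak - f(pos))^2 / (se_peak^2 + se(pos)^2)`, stays below the
#' `confidence` quantile of a chi-squared distribution with 1 df. The
#' interval is the maximal contiguous marker run around the peak
#' satisfying this; positions outside are rejected at level
#' `1 - confidence`. Treating the peak and candidate estimates as
#' independent ignores their positive correlation, which makes the
#' interval conservative (wider), in line with the design goal that the
#' causal mutation be contained at least at the nominal rate.
#'
#' If no region of elevated mutant frequency exists (smoothed peak
#' frequency below `min_peak_freq`), the data are considered
#' uninformative: the whole genome is returned as the interval and
#' `warning = TRUE` is set.
#'
#' @param counts a `pool_counts` data.frame at marker loci (rows with
#'   `locus_type == "marker"` are used when the column is present).
#' @param confidence confidence level `P` of the interval (default 0.99).
#' @param window odd sliding-window width in markers (default 201; capped
#'   per chromosome). `"auto"` chooses an odd window near one fifth of the
#'   mean per-chromosome marker count.
#' @param n_pool number of individuals in the pool; `NULL` drops the
#'   pool-sampling variance term (read-sampling only).
#' @param min_peak_freq smoothed-frequency floor below which the result is
#'   flagged uninformative (default 0.75).
#' @param genome optional [genome_spec]; used for the whole-genome fallback
#'   interval (otherwise the marker extent is used).
#' @return a `mapping_result` list with elements `chrom`, `start`, `end`,
#'   `length`, `peak_pos`, `peak_freq`, `warning`, `confidence`, `window`.
#' @export
map_interval <- function(counts, confidence = 0.99, window = 201,
                         n_pool = NULL, min_peak_freq = 0.75,
                         genome = NULL) {
  x <- counts
  if ("locus_type" %in% names(x)) {
    x <- x[x$locus_type == "marker", , drop = FALSE]
  }
  x <- x[x$cov > 0, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 covered markers")
  x <- x[order(match(x$chrom, unique(x$chrom)), x$pos), , drop = FALSE]

  chroms <- unique(x$chrom)
  k_mean <- nrow(x) / length(chroms)
  if (identical(window, "auto")) {
    window <- max(5, round(k_mean / 5))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L

  smf <- numeric(nrow(x))
  smc <- numeric(nrow(x))
  for (ch in chroms) {
    sel <- x$chrom == ch
    w <- max(1L, min(window, sum(sel)))
    k_w <- rolling_sum(x$count_mut[sel], w)
    c_w <- rolling_sum(x$cov[sel], w)
    smf[sel] <- k_w / c_w
    smc[sel] <- c_w
  }
  pool_var <- if (is.null(n_pool)) 0 else 1 / (2 * n_pool)
  vf <- pmax(smf * (1 - smf), 1e-8)
  se2 <- vf * (1 / smc + pool_var)

  peak <- which.max(smf)
  res <- list(confidence = confidence, window = window,
              peak_pos = x$pos[peak], peak_chrom = x$chrom[peak],
              peak_freq = smf[peak])
  if (smf[peak] < min_peak_freq) {
    ext <- if (!is.null(genome)) {
      data.frame(chrom = genome$chrom, start = 1, end = genome$length)
    } else {
      do.call(rbind, lapply(chroms, function(ch) {
        data.frame(chrom = ch, start = 1, end = max(x$pos[x$chrom == ch]))
      }))
    }
    res$warning <- TRUE
    res$chrom <- NA_character_
    res$start <- NA_real_
    res$end <- NA_real_
    res$whole_genome <- ext
    res$length <- sum(ext$end - ext$start + 1)
    class(res) <- "mapping_result"
    return(res)
  }

  sel <- which(x$chrom == x$chrom[peak])
  p_local <- which(sel == peak)
  lr <- (smf[peak] - smf[sel])^2 / (se2[peak] + se2[sel])
  cut <- lr <= stats::qchisq(confidence, 1)
  lo <- p_local
  while (lo > 1 && cut[lo - 1]) lo <- lo - 1
  hi <- p_local
  while (hi < length(sel) && cut[hi + 1]) hi <- hi + 1
  res$warning <- FALSE
  res$chrom <- x$chrom[peak]
  res$start <- x$pos[sel[lo]]
  res$end <- x$pos[sel[hi]]
  res$length <- res$end - res$start + 1
  class(res) <- "mapping_result"
  res
}

#' Count candidate mutations inside a mapping interval
#'
#' @param interval a `mapping_result` from [map_interval()].
#' @param mutations a `mutation_set`.
#' @return number of mutations with position inside the interval (all
#'   mutations if the interval is the whole-genome fallback).
#' @export
count_cams <- function(interval, mutations) {
  if (isTRUE(interval$warning)) return(nrow(mutations))
  sum(mutations$chrom == interval$chrom &
        mutations$pos >= interval$start & mutations$pos <= interval$end)
}

#' Is a locus inside a mapping interval?
#'
#' @param interval a `mapping_result`.
#' @param chrom,pos locus coordinates.
#' @return logical; `TRUE` for the whole-genome fallback interval.
#' @export
interval_contains <- function(interval, chrom, pos) {
  if (isTRUE(interval$warning)) return(TRUE)
  identical(chrom, interval$chrom) &&
    pos >= interval$start && pos <= interval$end
}

#' Candidate mutations from direct sequencing of one mutant genome
#'
#' Sequences a single backcrossed mutant individual (a pool of size one) at
#' the induced-mutation loci and calls homozygous mutations with the
#' pool-size-one thresholds (`g_f = 0.5` plus the coverage-dependent
#' `r_f`). The CAM count approaches the number of mutations retained
#' homozygously in the foreground segments of the genome.
#'
#' @param ind a `recombinant_genome` (typically a phenotypic mutant from a
#'   backcross population).
#' @param mutations the founder `mutation_set`.
#' @param params a [seq_params()].
#' @param calling a [threshold_params()] with `n = 1`; built automatically
#'   when `NULL`.
#' @return a list with `cam_count`, `cams` (called subset) and `counts`
#'   (the simulated pool counts).
#' @export
direct_sequencing_cams <- function(ind, mutations, params, calling = NULL) {
  if (is.null(calling)) {
    calling <- threshold_params(1, 0, params$error_rate)
  }
  pool <- list(individuals = list(ind))
  counts <- sequence_pool(pool, markers = NULL, mutations = mutations,
                          params = params)
  if (all(counts$cov == 0)) {
    warning("zero coverage everywhere; no calls possible")
    return(list(cam_count = 0L, cams = counts[0, ], counts = counts))
  }
  cams <- call_homozygous(counts, calling)
  list(cam_count = nrow(cams), cams = cams, counts = counts)
}
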