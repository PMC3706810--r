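# Sequencing simulation at marker resolution: multinomial coverage
# allocation over loci, per-read allele assignment with sequencing error,
# whole-genome and target-enrichment modes, and the pool-counts interchange
# format.

#' Sequencing parameters
#'
#' @param error_rate per-read sequencing error probability (default 0.003,
#'   a deliberately conservative genome-wide rate for quality-filtered
#'   short-read alignments).
#' @param coverage target mean coverage per sequenced locus; converted to a
#'   total read number `m = round(coverage * number of sequenced loci)`.
#' @param total_reads alternatively, the total read number directly
#'   (overrides `coverage`).
#' @param mode `"wgs"` (all loci sequenced) or `"enrichment"` (only loci
#'   with the `enriched` flag receive reads).
#' @param error_mode what happens to reads drawn in the error category of
#'   the trinomial: `"split"` (default) assigns each error read to one of
#'   the two parental alleles with probability 1/2; `"flip"` assigns error
#'   reads to the opposite allele in proportion to the allele frequencies
#'   (so at a fixed mutant locus all error reads surface as wild-type
#'   alleles).
#' @return a `seq_params` list.
#' @export
seq_params <- function(error_rate = 0.003, coverage = NULL,
                       total_reads = NULL, mode = c("wgs", "enrichment"),
                       error_mode = c("split", "flip")) {
  mode <- match.arg(mode)
  error_mode <- match.arg(error_mode)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(coverage) && is.null(total_reads)) {
    stop("one of `coverage` or `total_reads` is required")
  }
  structure(list(error_rate = error_rate, coverage = coverage,
                 total_reads = total_reads, mode = mode,
                 error_mode = error_mode), class = "seq_params")
}

#' Allocate total reads over loci by a multinomial draw
#'
#' Coverage at locus `i` is one multinomial draw of `m` reads with
#' probabilities proportional to the per-locus coverage-normalization
#' weights; coverages sum to `m` exactly.
#'
#' @param weights non-negative per-locus weights (at least one positive).
#' @param m total number of reads (>= 0).
#' @return integer coverage vector summing to `m`.
#' @export
assign_coverage <- function(weights, m) {
  if (length(weights) == 0 || all(weights <= 0)) {
    stop("coverage weights must contain a positive entry")
  }
  if (m < 0) stop("m must be >= 0")
  if (m == 0) return(integer(length(weights)))
  as.integer(stats::rmultinom(1, m, weights / sum(weights)))
}

#' True allele frequencies of a pool at loci
#'
#' The mutant-parent allele frequency `a1` at a locus is the number of
#' founder-derived ("A") alleles among the `2 n` chromosomes of the pool;
#' `a2 = 1 - a1` is the other-parent frequency.
#'
#' @param pool a pool from [select_pool()] (or any list of individuals in
#'   `$individuals`).
#' @param loci data.frame with columns `chrom`, `pos`.
#' @return numeric vector of `a1` values aligned with `loci`.
#' @export
true_allele_frequencies <- function(pool, loci) {
  inds <- pool$individuals
  if (length(inds) == 0) stop("pool is empty")
  acc <- numeric(nrow(loci))
  for (ch in unique(loci$chrom)) {
    sel <- which(loci$chrom == ch)
    x <- loci$pos[sel]
    s <- numeric(length(x))
    for (ind in inds) {
      h <- ind$haps[[ch]]
      s <- s + hap_origin_A(h$h1, x) + hap_origin_A(h$h2, x)
    }
    acc[sel] <- s
  }
  acc / (2 * length(inds))
}

#' Assign reads at loci to parental alleles
#'
#' Reads at a locus with coverage `c` are assigned by a trinomial draw with
#' probabilities `(a1 (1 - s), a2 (1 - s), s)`: mutant-parent allele,
#' other-parent allele, and sequencing error. Error-category reads are then
#' re-assigned to one of the two observable alleles according to
#' `error_mode` (see [seq_params()]), so the two counts always sum to the
#' coverage. Vectorized over loci.
#'
#' @param cov integer coverage per locus.
#' @param a1 mutant-parent allele frequency per locus.
#' @param error_rate per-read error probability `s`.
#' @param error_mode `"split"` or `"flip"`.
#' @return a two-column matrix `cbind(count_mut, count_wt)`.
#' @export
sample_allele_counts <- function(cov, a1, error_rate = 0.003,
                                 error_mode = c("split", "flip")) {
  error_mode <- match.arg(error_mode)
  k <- length(cov)
  a1 <- rep_len(a1, k)
  err <- stats::rbinom(k, cov, error_rate)
  clean <- cov - err
  mut <- stats::rbinom(k, clean, a1)
  p_err_mut <- if (error_mode == "split") rep(0.5, k) else 1 - a1
  mut <- mut + stats::rbinom(k, err, p_err_mut)
  cbind(count_mut = mut, count_wt = cov - mut)
}

#' Simulate sequencing of a pool at marker and mutation loci
#'
#' Combines the multinomial coverage allocation and the per-read allele
#' assignment. The sequenced loci are the markers plus the induced-mutation
#' positions; mutation loci absent from the marker map receive the
#' genome-average normalization weight 1. In enrichment mode only loci
#' flagged `enriched` in the marker map receive reads (mutation loci are
#' only sequenced if `enrich_mutations = TRUE`); everything else gets
#' coverage 0 and the total read number is spread over the enriched loci
#' alone.
#'
#' @param pool a pool from [select_pool()].
#' @param markers a [marker_map] (may be `NULL` for backcross pools, where
#'   only induced mutations serve as markers).
#' @param mutations a `mutation_set` (may be `NULL`).
#' @param params a [seq_params()].
#' @return a `pool_counts` data.frame with columns `chrom`, `pos`,
#'   `locus_type` (`"marker"`/`"mutation"`), `cov`, `count_mut`,
#'   `count_wt`.
#' @export
sequence_pool <- function(pool, markers = NULL, mutations = NULL, params) {
  stopifnot(inherits(params, "seq_params"))
  loci_list <- list()
  if (!is.null(markers) && nrow(markers) > 0) {
    loci_list$marker <- data.frame(
      chrom = markers$chrom, pos = markers$pos,
      locus_type = "marker", weight = markers$norm_weight,
      sequenced = if (params$mode == "enrichment") markers$enriched else TRUE,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(mutations) && nrow(mutations) > 0) {
    loci_list$mutation <- data.frame(
      chrom = mutations$chrom, pos = mutations$pos,
      locus_type = "mutation", weight = 1,
      sequenced = params$mode != "enrichment",
      stringsAsFactors = FALSE
    )
  }
  if (length(loci_list) == 0) stop("no loci to sequence")
  loci <- do.call(rbind, loci_list)
  rownames(loci) <- NULL
  n_seq <- sum(loci$sequenced)
  if (n_seq == 0) {
    stop("enrichment mode requires loci flagged as enriched")
  }
  m <- if (!is.null(params$total_reads)) {
    as.integer(params$total_reads)
  } else {
    as.integer(round(params$coverage * n_seq))
  }
  cov <- integer(nrow(loci))
  cov[loci$sequenced] <- assign_coverage(loci$weight[loci$sequenced], m)
  a1 <- true_allele_frequencies(pool, loci)
  counts <- sample_allele_counts(cov, a1, params$error_rate,
                                 params$error_mode)
  structure(
    data.frame(chrom = loci$chrom, pos = loci$pos,
               locus_type = loci$locus_type, cov = cov,
               count_mut = counts[, 1], count_wt = counts[, 2],
               stringsAsFactors = FALSE),
    class = c("pool_counts", "data.frame")
  )
}

#' Write/read pool counts in the tab-separated interchange format
#'
#' Columns: `chrom`, `pos`, `locus_type`, `cov`, `count_mut`, `count_wt`.
#'
#' @param counts a `pool_counts` data.frame.
#' @param path file path.
#' @return `path` (writer) or the `pool_counts` data.frame (reader).
#' @export
write_pool_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "locus_type", "cov", "count_mut", "count_wt")
  if (!all(need %in% names(x))) {
    stop(path, ": missing pool-counts columns")
  }
  structure(x, class = c("pool_counts", "data.frame"))
}

#' Export pool counts as a minimal VCF-like table
#'
#' Writes a minimal VCF (CHROM, POS, REF/ALT placeholders, and an AD-style
#' allele-depth field `other,mutant`) for interoperability with variant
#' tooling. No sequence context is simulated, so REF/ALT are reported as
#' `N`/`M` symbols.
#'
#' @param counts a `pool_counts` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_vcf <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (other,mutant)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool"
  ), con)
  writeLines(sprintf("%s\t%.0f\t.\tN\tM\t.\tPASS\t.\tAD\t%d,%d",
                     counts$chrom, counts$pos, counts$count_wt,
                     counts$count_mut), con)
  invisible(path)
}
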