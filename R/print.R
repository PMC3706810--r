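# Compact print methods for the main containers.

#' @export
print.recomb_landscape <- function(x, ...) {
  g <- x$genome
  cat(sprintf("Recombination landscape: %d chromosome(s), %.1f Mb total\n",
              nrow(g), sum(g$length) / 1e6))
  for (ch in g$chrom) {
    cc <- x$chrom[[ch]]
    cat(sprintf(
      "  %s: p=(%.3f, %.3f, %.3f), E[crossovers]=%.2f, %d intervals, gamma(%.2g, %.2g)\n",
      ch, cc$count_probs[1], cc$count_probs[2], cc$count_probs[3],
      expected_crossovers(x, ch), length(cc$interval_freqs),
      cc$gamma_shape, cc$gamma_scale))
  }
  invisible(x)
}

#' @export
print.mapping_result <- function(x, ...) {
  if (isTRUE(x$warning)) {
    cat("Mapping interval: uninformative (no elevated allele frequency);",
        "whole genome returned\n")
  } else {
    cat(sprintf(
      "Mapping interval (P=%.2f): %s:%.0f-%.0f (%.0f kb), peak %s:%.0f (freq %.3f)\n",
      x$confidence, x$chrom, x$start, x$end, x$length / 1e3,
      x$peak_chrom, x$peak_pos, x$peak_freq))
  }
  invisible(x)
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat(sprintf("Sweep: scheme=%s, %d cell(s) x %d replicate(s)\n",
              x$config$scheme, nrow(x$summary), x$config$replicates))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a sweep summary
#'
#' Draws the mean outcome (mapping-interval length for outcross sweeps,
#' CAM count otherwise) against coverage, one line per pool size, with
#' one-standard-deviation whiskers — the conventional way design sweeps
#' are inspected.
#'
#' @param x a `sweep_summary` from [run_sweep()].
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_summary <- function(x, ...) {
  s <- x$summary
  outcross <- identical(x$config$scheme, "outcross")
  val <- if (outcross) s$mean_interval_bp / 1e3 else s$mean_cams
  dev <- if (outcross) s$sd_interval_bp / 1e3 else s$sd_cams
  ylab <- if (outcross) "mapping interval (kb)" else "candidate mutations"
  pools <- sort(unique(s$pool_size))
  covs <- sort(unique(s$coverage))
  m <- matrix(NA_real_, length(covs), length(pools),
              dimnames = list(covs, pools))
  d <- m
  for (i in seq_len(nrow(s))) {
    m[as.character(s$coverage[i]), as.character(s$pool_size[i])] <- val[i]
    d[as.character(s$coverage[i]), as.character(s$pool_size[i])] <- dev[i]
  }
  graphics::matplot(covs, m, type = "b", pch = 19, lty = 1,
                    xlab = "coverage (x)", ylab = ylab, ...)
  for (j in seq_along(pools)) {
    ok <- !is.na(d[, j])
    graphics::arrows(covs[ok], m[ok, j] - d[ok, j], covs[ok],
                     m[ok, j] + d[ok, j], angle = 90, code = 3,
                     length = 0.03, col = j)
  }
  graphics::legend("topright", legend = paste("pool", pools), col =
                     seq_along(pools), lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' @export
print.seq_params <- function(x, ...) {
  depth <- if (!is.null(x$total_reads)) {
    sprintf("%d total reads", x$total_reads)
  } else {
    sprintf("%gx target coverage", x$coverage)
  }
  cat(sprintf("Sequencing: %s, error rate %.4g (%s), mode %s\n",
              depth, x$error_rate, x$error_mode, x$mode))
  invisible(x)
}
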