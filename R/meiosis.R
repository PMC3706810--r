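# Meiosis: crossover counts from the trinomial model, crossover placement
# from per-interval frequencies with gamma-modelled interference, and
# recombination of parental homologs into gametes.
#
# A haplotype is stored per chromosome as a sorted vector of breakpoints in
# (0, L] plus the parental-origin of the first segment (`startA`); segment
# origins alternate across breakpoints, so the full origin labelling is
# implied. Origin "A" is the mutagenized founder, "B" the crossing partner.

new_haplotype <- function(bp = numeric(0), startA = TRUE) {
  list(bp = bp, startA = startA)
}

# Origin (TRUE = founder "A") of haplotype `hap` at positions `x`.
# Segments are half-open (prev, next]: a breakpoint position itself still
# belongs to the segment it terminates.
hap_origin_A <- function(hap, x) {
  n <- findInterval(x, hap$bp, left.open = TRUE)
  (n %% 2L == 0L) == hap$startA
}

#' Sample a realized crossover count per meiosis
#'
#' Draws the crossover-count category from the per-chromosome probabilities
#' `(p1, p2, p3)` of zero, one, and two-or-more crossovers; a draw in the
#' third category is resolved to `2 + G` crossovers with
#' `G ~ Geometric(1 - geom_continuation)`, so under the default
#' `geom_continuation = 0.1` the realized count is almost always exactly 2.
#'
#' @param count_probs numeric length-3 probability vector.
#' @param n number of independent meioses to draw (default 1).
#' @param geom_continuation continuation probability of the geometric tail.
#' @return integer vector of realized crossover counts.
#' @examples
#' sample_crossover_count(c(1, 0, 0), n = 5)  # always 0
#' @export
sample_crossover_count <- function(count_probs, n = 1,
                                   geom_continuation = 0.1) {
  if (abs(sum(count_probs) - 1) > 1e-6 || any(count_probs < 0)) {
    stop("count_probs must be non-negative and sum to 1")
  }
  u <- stats::runif(n)
  cat3 <- u > count_probs[1] + count_probs[2]
  counts <- integer(n)
  counts[u > count_probs[1] & !cat3] <- 1L
  if (any(cat3)) {
    counts[cat3] <- 2L + stats::rgeom(sum(cat3), 1 - geom_continuation)
  }
  counts
}

# Normalized genetic coordinate (in [0, 1]) of base-pair positions on a
# placement profile; the coordinate is the cumulative placement probability.
genetic_position <- function(profile, x) {
  i <- findInterval(x, profile$starts, left.open = TRUE)
  i[i < 1L] <- 1L
  cum0 <- c(0, profile$cum)[i]
  cum0 + profile$probs[i] * (x - profile$starts[i]) / profile$widths[i]
}

# Inverse of genetic_position: base-pair position of genetic coordinates g.
bp_position <- function(profile, g) {
  i <- findInterval(g, profile$cum, left.open = TRUE) + 1L
  i[i > length(profile$probs)] <- length(profile$probs)
  cum0 <- c(0, profile$cum)[i]
  frac <- (g - cum0) / profile$probs[i]
  profile$starts[i] + frac * profile$widths[i]
}

#' Place crossovers along a chromosome
#'
#' The first crossover is drawn from the marginal placement density: an
#' inter-marker interval is chosen with its placement probability and the
#' base-pair position within the interval is uniform (density `p_mi / l_i`
#' per bp). When `interference = TRUE`, each additional crossover is placed
#' at a gamma-distributed genetic distance downstream of the previous one
#' (shape/scale from the profile's landscape), mapped back to base pairs; a
#' draw beyond the chromosome end is redrawn up to `max_retries` times and
#' then placed uniformly in the remaining genetic interval. With
#' `interference = FALSE` all crossovers are i.i.d. draws from the marginal
#' density.
#'
#' @param count realized crossover count (>= 0).
#' @param profile a placement profile as built internally from a landscape
#'   and marker map (see [simulation_plan()]).
#' @param gamma_shape,gamma_scale interference parameters.
#' @param interference logical; disable to place all crossovers i.i.d.
#' @param max_retries redraw budget for gamma draws beyond the chromosome.
#' @return sorted numeric vector of crossover positions in bp.
#' @export
place_crossovers <- function(count, profile, gamma_shape = 2,
                             gamma_scale = 1 / 6, interference = TRUE,
                             max_retries = 20L) {
  if (count <= 0) return(numeric(0))
  if (!interference || count == 1L) {
    i <- sample.int(length(profile$probs), count, replace = TRUE,
                    prob = profile$probs)
    x <- profile$starts[i] + stats::runif(count) * profile$widths[i]
    return(sort(unique(x)))
  }
  g <- numeric(count)
  i1 <- sample.int(length(profile$probs), 1, prob = profile$probs)
  x1 <- profile$starts[i1] + stats::runif(1) * profile$widths[i1]
  g[1] <- genetic_position(profile, x1)
  for (j in seq_len(count - 1L)) {
    prev <- g[j]
    d <- stats::rgamma(1, shape = gamma_shape, scale = gamma_scale)
    tries <- 0L
    while (prev + d >= 1 && tries < max_retries) {
      d <- stats::rgamma(1, shape = gamma_shape, scale = gamma_scale)
      tries <- tries + 1L
    }
    if (prev + d >= 1) {
      # truncation fallback: uniform in the remaining genetic interval
      d <- stats::runif(1) * (1 - prev)
    }
    g[j + 1L] <- prev + d
  }
  x <- bp_position(profile, g)
  sort(unique(x))
}

# Recombine two parental haplotypes into a gamete haplotype given crossover
# positions `xo` and the starting homolog (1 or 2).
cross_gamete <- function(h1, h2, xo, L, start_hom) {
  cand <- sort(unique(c(xo, h1$bp, h2$bp)))
  if (length(cand) == 0L) {
    return(if (start_hom == 1L) h1 else h2)
  }
  reps <- c(cand, L)  # right endpoint of each segment lies inside it
  hom1 <- ((start_hom - 1L) + findInterval(reps, xo, left.open = TRUE)) %%
    2L == 0L
  o1 <- hap_origin_A(h1, reps)
  o2 <- hap_origin_A(h2, reps)
  lab <- ifelse(hom1, o1, o2)
  r <- rle(lab)
  nb <- length(r$lengths)
  bp <- if (nb > 1L) cand[cumsum(r$lengths)[-nb]] else numeric(0)
  new_haplotype(bp, r$values[1])
}

#' Build a simulation plan from a landscape and marker map
#'
#' Precomputes, per chromosome, the crossover placement profile (marker
#' intervals extended to the chromosome ends), the count probabilities and
#' the interference parameters, so that repeated meioses avoid re-deriving
#' them. All breeding functions accept either a plan or a
#' landscape/markers pair.
#'
#' @param landscape a `recomb_landscape`.
#' @param markers the aligned [marker_map].
#' @param interference logical; disable gamma interference globally.
#' @return a `sim_plan` object.
#' @export
simulation_plan <- function(landscape, markers, interference = TRUE) {
  validate_landscape(landscape, markers)
  validate_marker_map(markers, landscape$genome)
  chrom <- lapply(landscape$genome$chrom, function(ch) {
    x <- landscape$chrom[[ch]]
    list(
      profile = placement_profile(landscape, markers, ch),
      count_probs = x$count_probs,
      gamma_shape = x$gamma_shape, gamma_scale = x$gamma_scale
    )
  })
  names(chrom) <- landscape$genome$chrom
  structure(
    list(genome = landscape$genome, chrom = chrom,
         geom_continuation = landscape$geom_continuation,
         interference = interference),
    class = "sim_plan"
  )
}

as_sim_plan <- function(x, markers = NULL) {
  if (inherits(x, "sim_plan")) return(x)
  if (inherits(x, "recomb_landscape")) {
    if (is.null(markers)) stop("markers required to build a simulation plan")
    return(simulation_plan(x, markers))
  }
  stop("expected a sim_plan or recomb_landscape")
}

#' Sample a gamete from a diploid individual
#'
#' Per chromosome, draws a crossover count from the trinomial model, places
#' the crossovers, picks the starting homolog with probability 1/2, and
#' alternates between the two parental homologs at each crossover. Mutation
#' genotypes are implied by segment origin (the founder is homozygous for
#' every induced mutation), so the gamete carries them automatically.
#'
#' @param parent a `recombinant_genome` (see [founder_genome()]).
#' @param plan a [simulation_plan()].
#' @return a gamete: a named list of haplotypes, one per chromosome.
#' @export
sample_gamete <- function(parent, plan) {
  chroms <- names(plan$chrom)
  g <- vector("list", length(chroms))
  names(g) <- chroms
  for (ch in chroms) {
    pc <- plan$chrom[[ch]]
    count <- sample_crossover_count(pc$count_probs, 1, plan$geom_continuation)
    xo <- place_crossovers(count, pc$profile, pc$gamma_shape, pc$gamma_scale,
                           interference = plan$interference)
    start_hom <- if (stats::runif(1) < 0.5) 1L else 2L
    g[[ch]] <- cross_gamete(parent$haps[[ch]]$h1, parent$haps[[ch]]$h2,
                            xo, pc$profile$L, start_hom)
  }
  g
}
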