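#' Parameters for Poisson-background island calling
#'
#' Defaults follow common broad-mark ChIP-Seq practice: 200 bp windows,
#' 400 bp gaps, E-value 100, 190 bp fragments.
#'
#' @param window_size Window width W in bp.
#' @param gap_size Maximum run of ineligible bp bridged inside one island;
#'   must be a non-negative integer multiple of `window_size`.
#' @param e_value Expected number of islands at or above the score threshold
#'   under the random-background null.
#' @param fragment_length Fragment length used for read extension, bp.
#' @param effective_genome_fraction Fraction of the genome that is mappable;
#'   scales the background rate denominator.
#' @param p_window Per-window Poisson tail probability below which a window
#'   count makes the window eligible (default 0.20).
#' @param score_step Discretization step, in score units, of the dynamic
#'   program that computes the null island-score distribution.
#' @return List of class `island_params`.
#' @export
island_params <- function(window_size = 200, gap_size = 400, e_value = 100,
                          fragment_length = 190,
                          effective_genome_fraction = 0.74,
                          p_window = 0.2, score_step = 0.1) {
  if (window_size <= 0) stop("window_size must be positive")
  if (gap_size < 0 || gap_size %% window_size != 0)
    stop("gap_size must be a non-negative integer multiple of window_size")
  if (e_value <= 0) stop("e_value must be positive")
  if (p_window <= 0 || p_window >= 1) stop("p_window must be in (0,1)")
  if (effective_genome_fraction <= 0 || effective_genome_fraction > 1)
    stop("effective_genome_fraction must be in (0,1]")
  structure(list(window_size = as.integer(window_size),
                 gap_size = as.integer(gap_size),
                 e_value = e_value,
                 fragment_length = as.integer(fragment_length),
                 effective_genome_fraction = effective_genome_fraction,
                 p_window = p_window,
                 score_step = score_step),
            class = "island_params")
}

#' Genome-average Poisson background rate per window
#'
#' lambda = reads * window_size / (effective_genome_fraction * genome length).
#'
#' @param track A raw `window_track`.
#' @param params An [island_params()].
#' @return The background rate lambda (expected reads per window).
#' @export
background_rate <- function(track, params) {
  stopifnot(inherits(track, "window_track"))
  if (track$normalized) stop("background rate requires a raw (unnormalized) track")
  if (track$n_summarized == 0) stop("empty track: no summarized reads")
  track$n_summarized * params$window_size /
    (params$effective_genome_fraction * genome_length(track$genome))
}

# Smallest integer count c such that P(Poisson(lambda) >= c) < p.
eligibility_threshold <- function(lambda, p_window) {
  stopifnot(lambda > 0)
  c0 <- 1L
  while (stats::ppois(c0 - 1, lambda, lower.tail = FALSE) >= p_window)
    c0 <- c0 + 1L
  c0
}

#' Mark windows whose count clears the Poisson background threshold
#'
#' A window is eligible iff its count is at least the smallest integer c with
#' P(Poisson(lambda) >= c) < p_window. Zero-count windows are never eligible.
#'
#' @param track A raw `window_track`.
#' @param lambda Background rate from [background_rate()].
#' @param p_window Eligibility tail probability (default 0.20).
#' @return Named list of logical vectors, one per chromosome.
#' @export
eligible_windows <- function(track, lambda, p_window = 0.2) {
  c0 <- eligibility_threshold(lambda, p_window)
  lapply(track$counts, function(v) v >= c0)
}

#' Join eligible windows into candidate islands
#'
#' Maximal runs of eligible windows, merged across gaps of at most
#' `gap_size / window_size` ineligible windows. The reported span is trimmed
#' to the first and last eligible window. The island read count sums ALL
#' windows in the span (interior gap windows included); the score sums
#' -ln P(Poisson(lambda) >= count) over the eligible windows only.
#'
#' @param mask Output of [eligible_windows()], aligned with `track`.
#' @param track The raw `window_track` the mask was computed from.
#' @param params An [island_params()].
#' @param lambda Background rate.
#' @return Data.frame of candidate islands: chrom, start, end, read_count,
#'   score, n_eligible; sorted and disjoint.
#' @export
aggregate_islands <- function(mask, track, params, lambda) {
  w <- params$window_size
  g <- params$gap_size %/% w
  out <- lapply(names(track$counts), function(chrom) {
    idx <- which(mask[[chrom]])
    if (!length(idx)) return(NULL)
    grp <- cumsum(c(1L, diff(idx) - 1L > g))
    v <- track$counts[[chrom]]
    first <- tapply(idx, grp, min)
    last <- tapply(idx, grp, max)
    score_w <- -stats::ppois(v[idx] - 1, lambda, lower.tail = FALSE, log.p = TRUE)
    data.frame(chrom = chrom,
               start = (first - 1L) * w,
               end = pmin(last * w, track$genome[[chrom]]),
               read_count = vapply(seq_along(first), function(i)
                 sum(v[first[i]:last[i]]), numeric(1)),
               score = as.numeric(tapply(score_w, grp, sum)),
               n_eligible = as.integer(tabulate(grp)),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      read_count = numeric(), score = numeric(),
                      n_eligible = integer())
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Island score threshold for a target E-value
#'
#' Computes the null distribution of island scores under iid
#' Poisson(lambda) window counts by a dynamic program over discretized
#' scores, then returns the smallest threshold s* such that the expected
#' number of random islands scoring >= s* over `genome_windows` windows is
#' at most `e_value`.
#'
#' The recursion: let q = P(window ineligible), W(s) the score distribution
#' of a single eligible window and gamma = sum_{j=0..g} q^j the within-island
#' gap factor (g = gap_size/window_size). Island-score mass satisfies
#' G = W + gamma (W * G); the expected island count at score s is
#' `genome_windows * q^(2(g+1)) * G(s)` (an island must be flanked by more
#' than g ineligible windows on each side).
#'
#' @param params An [island_params()].
#' @param lambda Background rate per window.
#' @param genome_windows Total number of windows in the (effective) genome.
#' @return The score threshold s*; `Inf` if no finite score meets the
#'   E-value within the resolved score range (e_value -> 0 limit).
#' @export
score_threshold <- function(params, lambda, genome_windows) {
  h <- params$score_step
  g <- params$gap_size %/% params$window_size
  c0 <- eligibility_threshold(lambda, params$p_window)
  q <- stats::ppois(c0 - 1, lambda)
  gamma <- sum(q^(0:g))
  rho <- gamma * (1 - q)
  if (rho >= 1)
    stop(sprintf(paste0("null island recursion does not converge ",
                        "(gap factor %.3f x eligible probability %.3f >= 1); ",
                        "decrease gap_size or p_window"), gamma, 1 - q))

  # single eligible-window score distribution
  m_max <- c0
  while (stats::ppois(m_max, lambda, lower.tail = FALSE) > 1e-16 &&
         m_max < c0 + 100000L)
    m_max <- m_max + 1L
  m <- c0:m_max
  pm <- stats::dpois(m, lambda)
  sm <- -stats::ppois(m - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  bm <- pmax(1L, as.integer(round(sm / h)))

  boundary <- q^(2 * (g + 1))
  # islands of n windows carry mass (1-q) * rho^(n-1); resolve terms until
  # the expected count of longer islands is negligible (capped: the
  # unresolved remainder is certified against e_value below)
  tiny <- min(1e-9, params$e_value * 1e-6)
  n_terms <- 2L
  while (genome_windows * boundary * (1 - q) * rho^(n_terms - 1) / (1 - rho) > tiny &&
         n_terms < 300L)
    n_terms <- n_terms + 1L
  B <- max(bm) * n_terms + 1L
  Wv <- numeric(B)
  for (i in seq_along(bm)) Wv[bm[i]] <- Wv[bm[i]] + pm[i]

  G <- Wv
  conv <- Wv
  n_used <- 1L
  for (n in seq_len(n_terms - 1L)) {
    nxt <- numeric(B)
    for (i in seq_along(bm)) {
      sh <- bm[i]
      nxt[(sh + 1L):B] <- nxt[(sh + 1L):B] + conv[seq_len(B - sh)] * pm[i]
    }
    conv <- gamma * nxt
    G <- G + conv
    n_used <- n_used + 1L
    if (genome_windows * boundary * sum(conv) < tiny) break
  }
  # upper bound on the expectation carried by unresolved longer islands
  rem_bound <- genome_windows * boundary * (1 - q) * rho^n_used / (1 - rho)

  e_cum <- rev(cumsum(rev(genome_windows * boundary * G)))
  ok <- which(e_cum + rem_bound <= params$e_value)
  if (!length(ok)) return(Inf)
  min(ok) * h
}

#' Call significantly enriched islands from a window track
#'
#' Composition of [background_rate()], [eligible_windows()],
#' [aggregate_islands()] and [score_threshold()]: candidate islands whose
#' score meets the E-value threshold, sorted and disjoint.
#'
#' @param track A raw `window_track`.
#' @param params An [island_params()].
#' @return Data.frame of islands (chrom, start, end, read_count, score,
#'   n_eligible) with the threshold and lambda attached as attributes.
#' @export
call_islands <- function(track, params = island_params()) {
  stopifnot(inherits(track, "window_track"))
  if (track$n_summarized == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      read_count = numeric(), score = numeric(),
                      n_eligible = integer()))
  lambda <- background_rate(track, params)
  mask <- eligible_windows(track, lambda, params$p_window)
  cand <- aggregate_islands(mask, track, params, lambda)
  gw <- params$effective_genome_fraction *
    genome_length(track$genome) / params$window_size
  s_star <- score_threshold(params, lambda, gw)
  out <- cand[cand$score >= s_star, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  attr(out, "score_threshold") <- s_star
  out
}

#' Compare island sets from two conditions
#'
#' An island in one condition is "shared" iff it overlaps (>= 1 bp) at least
#' one island of the other condition; shared counts may differ between the
#' two sides because one large island can overlap several small ones.
#'
#' @param islands_a,islands_b Island data.frames (chrom, start, end, ...).
#' @return List of class `peak_comparison`: total/shared/unique per side and
#'   a `pairings` data.frame of overlapping index pairs.
#' @export
compare_conditions <- function(islands_a, islands_b) {
  lv <- union(islands_a$chrom, islands_b$chrom)
  ga <- .df_to_granges(islands_a, use_strand = FALSE, seqlevels = lv)
  gb <- .df_to_granges(islands_b, use_strand = FALSE, seqlevels = lv)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  shared_a <- length(unique(S4Vectors::queryHits(hits)))
  shared_b <- length(unique(S4Vectors::subjectHits(hits)))
  structure(list(total_a = nrow(islands_a), total_b = nrow(islands_b),
                 shared_a = shared_a, shared_b = shared_b,
                 unique_a = nrow(islands_a) - shared_a,
                 unique_b = nrow(islands_b) - shared_b,
                 pairings = data.frame(index_a = S4Vectors::queryHits(hits),
                                       index_b = S4Vectors::subjectHits(hits))),
            class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat(sprintf("<peak_comparison> a: %d total = %d shared + %d unique; b: %d total = %d shared + %d unique\n",
              x$total_a, x$shared_a, x$unique_a,
              x$total_b, x$shared_b, x$unique_b))
  invisible(x)
}
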