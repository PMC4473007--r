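# Brute-force reference implementation of the island-aggregation step,
# written independently of the package internals: eligibility by direct
# Poisson pmf summation, grouping by an explicit window-by-window walk.

oracle_islands <- function(counts, lambda, p_window, gap_windows,
                           window_size = 200, chrom = "chr1") {
  chrom_len <- length(counts) * window_size
  tail_prob <- function(c) sum(stats::dpois(c:(c + 400), lambda))
  eligible <- vapply(counts, function(c) c >= 1 && tail_prob(c) < p_window,
                     logical(1))
  idx <- which(eligible)
  if (!length(idx))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      read_count = numeric(), score = numeric(),
                      n_eligible = integer()))
  groups <- list()
  cur <- idx[1]
  for (j in idx[-1]) {
    if (j - cur[length(cur)] - 1L <= gap_windows) cur <- c(cur, j)
    else { groups[[length(groups) + 1L]] <- cur; cur <- j }
  }
  groups[[length(groups) + 1L]] <- cur
  do.call(rbind, lapply(groups, function(grp) {
    lo <- min(grp); hi <- max(grp)
    data.frame(chrom = chrom,
               start = (lo - 1) * window_size,
               end = min(hi * window_size, chrom_len),
               read_count = sum(counts[lo:hi]),
               score = sum(vapply(counts[grp],
                                  function(c) -log(tail_prob(c)), numeric(1))),
               n_eligible = length(grp))
  }))
}

# One random oracle-vs-implementation instance; returns both island sets.
random_island_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:50, 1)
  lambda <- runif(1, 0.3, 2)
  p_window <- runif(1, 0.1, 0.3)
  g <- sample(0:3, 1)
  counts <- rpois(n, lambda)
  # sprinkle some enrichment so islands exist in most instances
  hot <- sample(n, max(1, n %/% 8))
  counts[hot] <- counts[hot] + rpois(length(hot), 6)
  params <- island_params(window_size = 200, gap_size = g * 200,
                          e_value = 1e9, p_window = p_window,
                          effective_genome_fraction = 1)
  track <- make_track(list(chr1 = counts))
  mask <- eligible_windows(track, lambda, p_window)
  list(got = aggregate_islands(mask, track, params, lambda),
       want = oracle_islands(counts, lambda, p_window, g))
}
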