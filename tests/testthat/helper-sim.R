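# Shared small simulation configs and track constructors.

small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 1e6, n_genes = 60,
         n_background_reads = 20000, enrichment_reads_per_active_gene = 80,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Build a window_track directly from per-chromosome count vectors.
make_track <- function(counts, window_size = 200) {
  counts <- lapply(counts, as.numeric)
  genome <- define_genome(setNames(lengths(counts) * window_size,
                                   names(counts)))
  structure(list(window_size = as.integer(window_size), counts = counts,
                 genome = genome, n_summarized = sum(unlist(counts)),
                 total_mapped_reads = sum(unlist(counts)),
                 normalized = FALSE, scale = NA_real_),
            class = "window_track")
}

# Intervals whose midpoints hit window i exactly counts[i] times, so that
# summarize_windows() reproduces `counts`.
counts_to_intervals <- function(counts, window_size = 200, chrom = "chr1") {
  idx <- rep(seq_along(counts), counts)
  mid <- (idx - 1L) * window_size + window_size %/% 2L
  data.frame(chrom = chrom, start = mid - 5L, end = mid + 6L,
             strand = "+")
}
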