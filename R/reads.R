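#' Remove PCR-duplicate reads
#'
#' Keeps at most one read per (chrom, start, strand) key, i.e. 5'-position
#' duplicates; the result does not depend on input order.
#'
#' @param reads Read data.frame (chrom, start, strand, ...).
#' @return The deduplicated data.frame, sorted by chrom, start, strand.
#' @export
deduplicate <- function(reads) {
  o <- order(reads$chrom, reads$start, reads$strand)
  reads <- reads[o, , drop = FALSE]
  keep <- !duplicated(reads[c("chrom", "start", "strand")])
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard multi-mapping reads
#'
#' @param reads Read data.frame with a logical `multimap` column.
#' @return Reads with `multimap == FALSE`. Warns (does not error) if nothing
#'   survives.
#' @export
drop_multimappers <- function(reads) {
  if (is.null(reads$multimap)) stop("'multimap' flag column missing")
  out <- reads[!reads$multimap, , drop = FALSE]
  if (nrow(out) == 0 && nrow(reads) > 0)
    warning("all reads were flagged multi-mapping; empty read set returned")
  rownames(out) <- NULL
  out
}

#' Extend reads to estimated fragment length
#'
#' A plus-strand read becomes `[start, start + fragment_length)`; a
#' minus-strand read `[end - fragment_length, end)`. Intervals are clipped to
#' chromosome bounds.
#'
#' @param reads Read data.frame (chrom, start, end, strand).
#' @param fragment_length Estimated ChIP fragment length in bp (default 190).
#' @param genome An `isl_genome` used for clipping.
#' @return Data.frame of fragment intervals (chrom, start, end, strand).
#' @export
extend_reads <- function(reads, fragment_length = 190, genome) {
  read_len <- reads$end - reads$start
  if (nrow(reads) && fragment_length < max(read_len))
    stop("fragment_length must be >= read length")
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - fragment_length)
  end <- start + fragment_length
  lens <- unclass(genome)[reads$chrom]
  out <- data.frame(chrom = reads$chrom,
                    start = as.integer(pmax(0, start)),
                    end = as.integer(pmin(end, lens)),
                    strand = reads$strand,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize intervals into a fixed-width window track
#'
#' Each interval contributes exactly one count, to the non-overlapping
#' window containing its midpoint.
#'
#' @param intervals Interval data.frame (chrom, start, end), clipped to
#'   chromosome bounds.
#' @param genome An `isl_genome`.
#' @param window_size Window width in bp (default 200).
#' @param total_mapped_reads Denominator for later per-million normalization;
#'   defaults to the number of intervals summarized.
#' @return A `window_track`: per-chromosome count vectors plus metadata.
#' @export
summarize_windows <- function(intervals, genome, window_size = 200,
                              total_mapped_reads = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  nw <- n_windows(genome, window_size)
  counts <- lapply(setNames(nm = names(genome)), function(chrom) {
    sel <- intervals$chrom == chrom
    if (!any(sel)) return(numeric(nw[[chrom]]))
    mid <- .interval_midpoint(intervals[sel, , drop = FALSE])
    as.numeric(tabulate(mid %/% window_size + 1L, nbins = nw[[chrom]]))
  })
  n_sum <- nrow(intervals)
  structure(list(window_size = as.integer(window_size),
                 counts = counts,
                 genome = genome,
                 n_summarized = n_sum,
                 total_mapped_reads = if (is.null(total_mapped_reads)) n_sum
                                      else total_mapped_reads,
                 normalized = FALSE,
                 scale = NA_real_),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("<window_track> W=%d bp, %d chromosomes, %d intervals%s\n",
              x$window_size, length(x$counts), x$n_summarized,
              if (x$normalized) sprintf(", normalized (x%.4g)", x$scale) else " (raw)"))
  invisible(x)
}

#' Normalize a window track to reads per million mapped reads
#'
#' Multiplies every window value by 1e6 / total_mapped_reads. Normalizing an
#' already-normalized track is an error, not a silent re-scaling.
#'
#' @param track A raw `window_track`.
#' @return The normalized track.
#' @export
normalize_per_million <- function(track) {
  stopifnot(inherits(track, "window_track"))
  if (track$normalized) stop("track is already normalized")
  if (is.null(track$total_mapped_reads) || track$total_mapped_reads <= 0)
    stop("total_mapped_reads must be positive")
  s <- 1e6 / track$total_mapped_reads
  track$counts <- lapply(track$counts, `*`, s)
  track$normalized <- TRUE
  track$scale <- s
  track
}

#' Filter, extend and summarize reads in one call
#'
#' The standard preprocessing path: drop multi-mappers, deduplicate, extend
#' to fragment length, summarize fragment midpoints into windows. Set
#' `extend = FALSE` to summarize raw read midpoints instead.
#'
#' @inheritParams extend_reads
#' @inheritParams summarize_windows
#' @param extend Whether to extend reads to `fragment_length` first.
#' @return A raw `window_track` whose `total_mapped_reads` is the
#'   post-filter unique read count.
#' @export
reads_to_track <- function(reads, genome, window_size = 200,
                           fragment_length = 190, extend = TRUE) {
  filtered <- deduplicate(drop_multimappers(reads))
  iv <- if (extend) extend_reads(filtered, fragment_length, genome) else filtered
  summarize_windows(iv, genome, window_size,
                    total_mapped_reads = nrow(filtered))
}
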