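#' Define a genome as a set of chromosome lengths
#'
#' All coordinates in this package are 0-based, half-open intervals
#' `[start, end)`; a chromosome of length L holds positions `0 .. L-1`.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @return A named integer-ish numeric vector of class `isl_genome`.
#' @export
#' @examples
#' g <- define_genome(c(chr1 = 1e6, chr2 = 5e5))
#' genome_length(g)
define_genome <- function(lengths) {
  if (is.null(names(lengths)) || anyNA(names(lengths)) || any(names(lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names")
  if (any(lengths <= 0))
    stop("chromosome lengths must be strictly positive")
  structure(as.numeric(lengths), names = names(lengths), class = "isl_genome")
}

#' @rdname define_genome
#' @param genome An `isl_genome`.
#' @export
genome_length <- function(genome) sum(unclass(genome))

#' Number of fixed-width windows per chromosome
#'
#' @param genome An `isl_genome`.
#' @param window_size Window width in bp.
#' @return Named integer vector, `ceiling(length / window_size)` per chromosome.
#' @export
n_windows <- function(genome, window_size) {
  stopifnot(window_size > 0)
  setNames(as.integer(ceiling(unclass(genome) / window_size)), names(genome))
}

# Internal: coerce a BED-like data.frame of intervals to GRanges.
# BED intervals are 0-based half-open; GRanges is 1-based closed.
.df_to_granges <- function(df, use_strand = TRUE, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = if (is.null(seqlevels)) df$chrom else factor(df$chrom, seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (use_strand && !is.null(df$strand)) df$strand else "*"
  )
}

# Internal: midpoint of [start, end) intervals (bp position, 0-based).
.interval_midpoint <- function(df) (df$start + df$end) %/% 2L
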