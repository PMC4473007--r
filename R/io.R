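#' Read and write aligned reads as BED6
#'
#' Reads are stored as BED6 with 0-based half-open coordinates. The score
#' column carries the multi-mapping flag (0 = unique, 1 = multi-mapping),
#' mirroring how the generator emits it; `read_bed6()` restores it as the
#' logical `multimap` column.
#'
#' @param path File path.
#' @return `read_bed6()`: a data.frame with columns chrom, start, end, name,
#'   strand, multimap.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  df$multimap <- df$score != 0L
  df$score <- NULL
  df
}

#' @rdname read_bed6
#' @param reads Data.frame of reads (chrom, start, end, name, strand and
#'   optionally multimap).
#' @export
write_bed6 <- function(reads, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  mm <- if (is.null(reads$multimap)) rep(0L, nrow(reads)) else as.integer(reads$multimap)
  nm <- if (is.null(reads$name)) sprintf("read_%d", seq_len(nrow(reads))) else reads$name
  out <- data.frame(reads$chrom, reads$start, reads$end, nm, mm, reads$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a WindowTrack as bedGraph
#'
#' Zero windows are omitted. Values are rounded to 4 decimals on export;
#' in-memory values keep full precision.
#'
#' @param track A `window_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "window_track"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  w <- track$window_size
  rows <- lapply(names(track$counts), function(chrom) {
    v <- track$counts[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.frame(chrom = chrom,
               start = (nz - 1L) * w,
               end = pmin(nz * w, track$genome[[chrom]]),
               value = round(v[nz], 4))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write gene models as a GFF3-like TSV
#'
#' One row per gene: gene_id, chrom, start, end, strand, source, thick_start,
#' thick_end (CDS span; exonic bp outside it are UTR), and comma-separated
#' exon_starts / exon_ends. Coordinates 0-based half-open.
#'
#' @param genes Gene-model data.frame.
#' @param path File path.
#' @export
write_gene_models <- function(genes, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(gene_id = "character", chrom = "character",
                                   strand = "character", source = "character",
                                   exon_starts = "character",
                                   exon_ends = "character"),
                    stringsAsFactors = FALSE)
}

#' Write gene models as BED12
#'
#' @param genes Gene-model data.frame as produced by [simulate_annotation()].
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  es <- strsplit(genes$exon_starts, ",")
  ee <- strsplit(genes$exon_ends, ",")
  sizes <- mapply(function(s, e) paste(as.integer(e) - as.integer(s), collapse = ","),
                  es, ee)
  rel <- mapply(function(s, g0) paste(as.integer(s) - g0, collapse = ","),
                es, genes$start)
  out <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                    genes$strand, genes$thick_start, genes$thick_end, "0,0,0",
                    lengths(es), sizes, rel)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: transcription start site as a 0-based point; for minus-strand
# genes this is the last covered base (end - 1).
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}
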