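#' Merge two gene-annotation sources with RefSeq precedence
#'
#' Every RefSeq gene is retained; an Ensembl gene is retained only if its
#' gene body overlaps no RefSeq gene on the same chromosome (and, by
#' default, strand).
#'
#' @param refseq,ensembl Gene-model data.frames (gene_id, chrom, start, end,
#'   strand, ... , source).
#' @param same_strand_only If TRUE (default), an overlap only suppresses an
#'   Ensembl gene when the two genes are on the same strand.
#' @return A single sorted gene-model data.frame; `source` records
#'   provenance.
#' @export
merge_annotations <- function(refseq, ensembl, same_strand_only = TRUE) {
  for (src in list(refseq, ensembl))
    if (anyDuplicated(src$gene_id))
      stop("duplicated gene_ids within one annotation source")
  lv <- union(refseq$chrom, ensembl$chrom)
  gr_ref <- .df_to_granges(refseq, use_strand = same_strand_only, seqlevels = lv)
  gr_ens <- .df_to_granges(ensembl, use_strand = same_strand_only, seqlevels = lv)
  hit <- IRanges::overlapsAny(gr_ens, gr_ref)
  out <- rbind(refseq, ensembl[!hit, , drop = FALSE])
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene regions used for enrichment calls
#'
#' @param genes Merged gene-model data.frame.
#' @param genome An `isl_genome` for clipping.
#' @param kind One of "promoter_2kb" (TSS +/- 2 kb), "promoter_1kb"
#'   (TSS +/- 1 kb) or "extended" (txStart - 5 kb to txEnd + 5 kb).
#' @return Data.frame gene_id, chrom, start, end (clipped).
#' @export
gene_regions <- function(genes, genome,
                         kind = c("promoter_2kb", "promoter_1kb", "extended")) {
  kind <- match.arg(kind)
  tss <- gene_tss(genes)
  reg <- switch(kind,
    promoter_2kb = cbind(tss - 2000, tss + 2000),
    promoter_1kb = cbind(tss - 1000, tss + 1000),
    extended = cbind(genes$start - 5000, genes$end + 5000))
  lens <- unclass(genome)[genes$chrom]
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, reg[, 1]), end = pmin(reg[, 2], lens),
             row.names = NULL)
}

#' Genes whose region overlaps at least one island
#'
#' A gene counts as enriched iff >= 1 island overlaps its chosen region by
#' >= 1 bp.
#'
#' @param islands Island data.frame.
#' @param genes Merged gene-model data.frame.
#' @param genome An `isl_genome`.
#' @param region_kind Passed to [gene_regions()]; default "promoter_2kb"
#'   (the TSS +/- 2 kb promoter definition).
#' @return Character vector of enriched gene_ids (sorted).
#' @export
enriched_genes <- function(islands, genes, genome,
                           region_kind = "promoter_2kb") {
  reg <- gene_regions(genes, genome, region_kind)
  lv <- union(reg$chrom, islands$chrom)
  hit <- IRanges::overlapsAny(
    .df_to_granges(reg, use_strand = FALSE, seqlevels = lv),
    .df_to_granges(islands, use_strand = FALSE, seqlevels = lv))
  sort(reg$gene_id[hit])
}

#' Enriched-gene set algebra for two conditions
#'
#' @param islands_a,islands_b Island sets of the two conditions.
#' @inheritParams enriched_genes
#' @return List: per-condition enriched genes, genes enriched in both, and
#'   genes enriched in exactly one condition.
#' @export
enriched_gene_sets <- function(islands_a, islands_b, genes, genome,
                               region_kind = "promoter_2kb") {
  a <- enriched_genes(islands_a, genes, genome, region_kind)
  b <- enriched_genes(islands_b, genes, genome, region_kind)
  list(a = a, b = b,
       both = intersect(a, b),
       only_a = setdiff(a, b),
       only_b = setdiff(b, a))
}

.FEATURE_LEVELS <- c("five_prime_utr", "three_prime_utr", "exon",
                     "first_intron", "last_intron", "other_intron",
                     "intergenic")

# Feature of a point within one gene, by precedence:
# 5'UTR > 3'UTR > exon > first intron > last intron > other intron.
# Returns the precedence rank (index into .FEATURE_LEVELS) or NA.
.point_feature_rank <- function(pos, gene) {
  es <- as.integer(strsplit(gene$exon_starts, ",")[[1]])
  ee <- as.integer(strsplit(gene$exon_ends, ",")[[1]])
  in_exon <- which(pos >= es & pos < ee)
  plus <- gene$strand == "+"
  if (length(in_exon)) {
    before_thick <- pos < gene$thick_start
    after_thick <- pos >= gene$thick_end
    if ((plus && before_thick) || (!plus && after_thick)) return(1L)  # 5' UTR
    if ((plus && after_thick) || (!plus && before_thick)) return(2L)  # 3' UTR
    return(3L)                                                        # exon
  }
  n_int <- length(es) - 1L
  if (n_int < 1L) return(NA_integer_)
  intron <- which(pos >= ee[-length(ee)] & pos < es[-1])
  if (!length(intron)) return(NA_integer_)
  # transcription-order intron index; a single intron counts as "first"
  ord <- if (plus) intron else n_int - intron + 1L
  if (ord == 1L) 4L else if (ord == n_int) 5L else 6L
}

#' Classify islands into genomic feature categories
#'
#' Each island is classified by its midpoint into one of seven categories:
#' 5' UTR, 3' UTR, exon, first intron, last intron, other intron or
#' intergenic. When the midpoint hits features of several genes the highest-
#' precedence feature wins (5'UTR > 3'UTR > exon > first > last > other
#' intron); a midpoint outside every gene body is intergenic. The categories
#' therefore partition any island set.
#'
#' @param islands Island data.frame.
#' @param genes Merged gene-model data.frame (with exon structure and thick
#'   span).
#' @return Factor of feature classes, one per island.
#' @export
classify_peaks <- function(islands, genes) {
  if (!nrow(islands))
    return(factor(character(), levels = .FEATURE_LEVELS))
  mids <- .interval_midpoint(islands)
  mid_gr <- GenomicRanges::GRanges(islands$chrom,
                                   IRanges::IRanges(mids + 1L, width = 1L))
  gene_gr <- .df_to_granges(genes, use_strand = FALSE,
                            seqlevels = union(islands$chrom, genes$chrom))
  hits <- GenomicRanges::findOverlaps(mid_gr, gene_gr)
  rank <- rep(NA_integer_, nrow(islands))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in seq_along(qh)) {
    r <- .point_feature_rank(mids[qh[i]], genes[sh[i], ])
    if (!is.na(r) && (is.na(rank[qh[i]]) || r < rank[qh[i]]))
      rank[qh[i]] <- r
  }
  rank[is.na(rank)] <- 7L
  factor(.FEATURE_LEVELS[rank], levels = .FEATURE_LEVELS)
}

#' Signed distance from island midpoints to the nearest TSS
#'
#' Negative distances are upstream of the TSS in the gene's own orientation
#' (5' of a plus-strand TSS, 3'-in-genomic-coordinates of a minus-strand
#' TSS). The nearest TSS on the island's chromosome wins; exact ties break
#' lexicographically by gene_id. Islands on chromosomes without genes are
#' skipped with a warning.
#'
#' @param islands Island data.frame.
#' @param genes Merged gene-model data.frame.
#' @return Data.frame: island row index, gene_id of the nearest TSS, signed
#'   distance in bp.
#' @export
distance_to_tss <- function(islands, genes) {
  tss <- gene_tss(genes)
  out <- vector("list", nrow(islands))
  skipped <- 0L
  for (i in seq_len(nrow(islands))) {
    sel <- genes$chrom == islands$chrom[i]
    if (!any(sel)) { skipped <- skipped + 1L; next }
    mid <- .interval_midpoint(islands[i, , drop = FALSE])
    d_gen <- mid - tss[sel]
    signed <- ifelse(genes$strand[sel] == "+", d_gen, -d_gen)
    o <- order(abs(signed), genes$gene_id[sel])
    out[[i]] <- data.frame(island = i,
                           gene_id = genes$gene_id[sel][o[1]],
                           distance = signed[o[1]])
  }
  if (skipped > 0)
    warning(sprintf("%d island(s) on chromosomes without genes were skipped",
                    skipped))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(island = integer(), gene_id = character(),
                      distance = numeric())
  res
}

#' Per-chromosome island counts and length-relative densities
#'
#' @param islands Island data.frame.
#' @param genome An `isl_genome`.
#' @return Data.frame: chrom, n islands, pct (percent of all islands; sums
#'   to 100 when islands exist) and rel_density, the percent of islands
#'   divided by the chromosome's percent of genome length (1 = proportional
#'   to length).
#' @export
chromosome_distribution <- function(islands, genome) {
  unknown <- setdiff(unique(islands$chrom), names(genome))
  if (length(unknown))
    stop(sprintf("islands on unknown chromosome(s): %s",
                 paste(unknown, collapse = ", ")))
  n <- vapply(names(genome), function(ch) sum(islands$chrom == ch), numeric(1))
  total <- sum(n)
  len_frac <- unclass(genome) / genome_length(genome)
  data.frame(chrom = names(genome), n = as.integer(n),
             pct = if (total > 0) 100 * n / total else rep(0, length(n)),
             rel_density = if (total > 0) (n / total) / len_frac
                           else rep(0, length(n)),
             row.names = NULL)
}
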