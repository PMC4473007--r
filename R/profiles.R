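#' Specification of an enrichment profile layout
#'
#' Two modes. `"tss_fine"`: fixed-width bins (default 5 bp) across
#' TSS +/- `tss_halfwidth` (default 2 kb), 800 columns at the defaults.
#' `"metagene"`: 5 upstream 1 kb bins, 20 gene-body bins of 5 percent of the
#' gene length each, 5 downstream 1 kb bins -- 30 columns. All profiles are
#' strand-oriented: column 1 is the most 5' bin in the gene's own frame.
#'
#' @param mode "tss_fine" or "metagene".
#' @param tss_halfwidth Half-width around the TSS, bp (tss_fine).
#' @param tss_bin Bin width, bp (tss_fine); must divide `tss_halfwidth`.
#' @param flank Flank length, bp (metagene).
#' @param flank_bin Flank bin width, bp (metagene); must divide `flank`.
#' @param body_bins Number of scaled gene-body bins (metagene; default 20,
#'   i.e. 5 percent of the gene length each).
#' @return List of class `profile_spec`.
#' @export
profile_spec <- function(mode = c("tss_fine", "metagene"),
                         tss_halfwidth = 2000, tss_bin = 5,
                         flank = 5000, flank_bin = 1000, body_bins = 20) {
  mode <- match.arg(mode)
  if (tss_halfwidth %% tss_bin != 0) stop("tss_bin must divide tss_halfwidth")
  if (flank %% flank_bin != 0) stop("flank_bin must divide flank")
  n_bins <- if (mode == "tss_fine") 2L * as.integer(tss_halfwidth / tss_bin)
            else 2L * as.integer(flank / flank_bin) + as.integer(body_bins)
  structure(list(mode = mode, tss_halfwidth = tss_halfwidth, tss_bin = tss_bin,
                 flank = flank, flank_bin = flank_bin, body_bins = body_bins,
                 n_bins = n_bins),
            class = "profile_spec")
}

# Oriented bin index (0-based) of midpoints for one gene, or NA when the
# midpoint falls outside the profiled span.
.profile_bin <- function(mids, gene, spec) {
  plus <- gene$strand == "+"
  if (spec$mode == "tss_fine") {
    tss <- if (plus) gene$start else gene$end - 1L
    rel <- if (plus) mids - (tss - spec$tss_halfwidth)
           else (tss + spec$tss_halfwidth) - mids
    b <- rel %/% spec$tss_bin
    ifelse(rel >= 0 & rel < 2 * spec$tss_halfwidth, b, NA_integer_)
  } else {
    L <- gene$end - gene$start
    t <- if (plus) mids - gene$start else (gene$end - 1L) - mids
    nf <- spec$flank %/% spec$flank_bin
    b <- rep(NA_real_, length(t))
    up <- t < 0 & t >= -spec$flank
    b[up] <- (t[up] + spec$flank) %/% spec$flank_bin
    body <- t >= 0 & t < L
    b[body] <- nf + pmin(spec$body_bins - 1, floor(spec$body_bins * t[body] / L))
    dn <- t >= L & t < L + spec$flank
    b[dn] <- nf + spec$body_bins + (t[dn] - L) %/% spec$flank_bin
    b
  }
}

#' Raw per-gene enrichment profile
#'
#' Counts fragment midpoints into the oriented bins of `spec` for one gene.
#' Metagene mode requires a gene body of at least `body_bins` bp so the
#' percent bins are non-degenerate.
#'
#' @param intervals Fragment interval data.frame (chrom, start, end).
#' @param gene One row of a gene-model data.frame.
#' @param spec A [profile_spec()].
#' @return Numeric vector of raw counts, length `spec$n_bins`, 5' to 3'.
#' @export
gene_profile <- function(intervals, gene, spec) {
  if (spec$mode == "metagene" && (gene$end - gene$start) < spec$body_bins)
    stop(sprintf("gene '%s' shorter than %d bp: metagene bins degenerate",
                 gene$gene_id, spec$body_bins))
  sel <- intervals$chrom == gene$chrom
  mids <- .interval_midpoint(intervals[sel, , drop = FALSE])
  b <- .profile_bin(mids, gene, spec)
  tabulate(b[!is.na(b)] + 1L, nbins = spec$n_bins)
}

#' Gene-by-bin profile matrix
#'
#' One strand-oriented row of raw midpoint counts per retained gene. Genes
#' failing the mode's minimum-length requirement (metagene: body shorter
#' than `body_bins` bp; or any `min_gene_length` you set) are excluded with
#' a message.
#'
#' @inheritParams gene_profile
#' @param genes Gene-model data.frame.
#' @param min_gene_length Additional minimum gene length, bp (default 0).
#' @param total_reads Stored as metadata for later normalization (defaults
#'   to `nrow(intervals)`).
#' @return Matrix (genes x bins) of raw counts with attributes `spec` and
#'   `total_reads`; rownames are gene_ids.
#' @export
profile_matrix <- function(intervals, genes, spec, min_gene_length = 0,
                           total_reads = NULL) {
  min_len <- max(min_gene_length,
                 if (spec$mode == "metagene") spec$body_bins else 0)
  keep <- (genes$end - genes$start) >= min_len
  if (any(!keep))
    message(sprintf("excluding %d gene(s) shorter than %d bp", sum(!keep), min_len))
  genes <- genes[keep, , drop = FALSE]
  nb <- spec$n_bins
  m <- matrix(0, nrow(genes), nb, dimnames = list(genes$gene_id, NULL))
  margin <- max(spec$tss_halfwidth, spec$flank) + 1
  for (chrom in unique(genes$chrom)) {
    mids <- sort(.interval_midpoint(intervals[intervals$chrom == chrom, , drop = FALSE]))
    for (i in which(genes$chrom == chrom)) {
      g <- genes[i, ]
      lo <- findInterval(g$start - margin - 0.5, mids) + 1L
      hi <- findInterval(g$end + margin - 0.5, mids)
      if (hi < lo) next
      b <- .profile_bin(mids[lo:hi], g, spec)
      m[i, ] <- tabulate(b[!is.na(b)] + 1L, nbins = nb)
    }
  }
  attr(m, "spec") <- spec
  attr(m, "total_reads") <- if (is.null(total_reads)) nrow(intervals) else total_reads
  m
}

#' Promoter signal matrix for clustering
#'
#' TSS +/- `halfwidth`, strand-oriented, in bins of `bin` bp (default 50 bp,
#' 80 columns), restricted to genes at least 2 kb long, normalized to reads
#' per million. Rows carry the gene's expression value (attribute
#' `expression`) when a gene table is supplied.
#'
#' @param intervals Fragment interval data.frame.
#' @param genes Gene-model data.frame.
#' @param halfwidth Half-width around the TSS, bp.
#' @param bin Bin width, bp.
#' @param min_gene_length Genes shorter than this are excluded (default
#'   2000 bp).
#' @param expression Optional data.frame gene_id, value.
#' @param total_reads Per-million denominator (defaults to
#'   `nrow(intervals)`).
#' @return Normalized matrix (genes x bins); attribute `expression` holds
#'   the matched expression values when provided.
#' @export
promoter_matrix <- function(intervals, genes, halfwidth = 2000, bin = 50,
                            min_gene_length = 2000, expression = NULL,
                            total_reads = NULL) {
  spec <- profile_spec("tss_fine", tss_halfwidth = halfwidth, tss_bin = bin)
  m <- profile_matrix(intervals, genes, spec,
                      min_gene_length = min_gene_length,
                      total_reads = total_reads)
  tr <- attr(m, "total_reads")
  out <- m * 1e6 / tr
  attr(out, "spec") <- spec
  attr(out, "total_reads") <- tr
  if (!is.null(expression))
    attr(out, "expression") <- setNames(
      expression$value[match(rownames(out), expression$gene_id)],
      rownames(out))
  out
}

#' Mean enrichment curve per expression category
#'
#' For each category: column-wise sum over its genes divided by
#' (number of genes in the category x total reads / 1e6) -- i.e. normalized
#' to the number of genes in the category and to the sample's sequencing
#' depth.
#'
#' @param mat Raw profile matrix from [profile_matrix()].
#' @param categories Vector of category labels, named by gene_id or aligned
#'   with the matrix rows.
#' @return Tidy data.frame (category, bin, value); bins are 1-based, 5' to
#'   3'. Empty categories yield zero curves with a warning.
#' @export
category_profile <- function(mat, categories) {
  if (!is.null(names(categories)))
    categories <- categories[rownames(mat)]
  if (length(categories) != nrow(mat))
    stop("categories must align with matrix rows")
  tr <- attr(mat, "total_reads")
  lv <- if (is.factor(categories)) levels(categories) else sort(unique(categories))
  out <- lapply(lv, function(cl) {
    rows <- which(!is.na(categories) & categories == cl)
    if (!length(rows)) {
      warning(sprintf("category '%s' is empty; zero curve emitted", cl))
      val <- numeric(ncol(mat))
    } else {
      val <- colSums(mat[rows, , drop = FALSE]) / (length(rows) * tr / 1e6)
    }
    data.frame(category = cl, bin = seq_len(ncol(mat)), value = val)
  })
  do.call(rbind, out)
}
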