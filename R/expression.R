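#' Collapse a probe-level expression table to gene level
#'
#' A gene's value is the arithmetic mean of its probes' values on the
#' provided (log) scale. Genes with no probe are absent from the result.
#'
#' @param probes Data.frame with columns probe_id, gene_id, value (the
#'   gene_id column doubles as the probe-to-gene map).
#' @param known_genes Optional character vector of valid gene identifiers;
#'   probes mapped to identifiers outside it raise an error listing the
#'   offenders.
#' @return Data.frame gene_id, value, n_probes; sorted by gene_id.
#' @export
probes_to_genes <- function(probes, known_genes = NULL) {
  if (!is.null(known_genes)) {
    bad <- setdiff(unique(probes$gene_id), known_genes)
    if (length(bad))
      stop(sprintf("probes mapped to unknown gene(s): %s",
                   paste(sort(bad), collapse = ", ")))
  }
  sp <- split(probes$value, probes$gene_id)
  data.frame(gene_id = names(sp),
             value = vapply(sp, mean, numeric(1), USE.NAMES = FALSE),
             n_probes = lengths(sp, use.names = FALSE),
             row.names = NULL)
}

#' Assign expression categories to genes
#'
#' Two schemes. `"deciles"`: genes ranked by value (ties broken by gene_id)
#' and split into 10 near-equal groups, category 1 the lowest, 10 the
#' highest; group sizes differ by at most one. `"four"`: genes at or below
#' `silent_floor` are "silent"; the remainder is split by rank into
#' equal-count "low"/"medium"/"high" tertiles. Both schemes depend only on
#' ranks, so any strictly monotone transform of the values leaves the
#' assignment unchanged.
#'
#' @param gene_table Data.frame gene_id, value (from [probes_to_genes()]).
#' @param scheme "deciles" or "four".
#' @param silent_floor Value at or below which a gene is silent (four-class
#'   scheme only).
#' @return The input with a `category` column added (integer 1-10 for
#'   deciles; factor silent < low < medium < high for the four-class scheme).
#' @export
assign_categories <- function(gene_table, scheme = c("deciles", "four"),
                              silent_floor = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(gene_table)
  o <- order(gene_table$value, gene_table$gene_id)
  out <- gene_table
  if (scheme == "deciles") {
    if (n < 10) stop("decile scheme needs at least 10 genes")
    # rank-order split into 10 groups whose sizes differ by at most one
    out$category <- integer(n)
    out$category[o] <- as.integer(ceiling(seq_len(n) * 10 / n))
  } else {
    if (is.null(silent_floor))
      silent_floor <- stats::quantile(gene_table$value, 0.25, names = FALSE)
    silent <- gene_table$value <= silent_floor
    if (all(silent)) stop("all genes are silent at this floor")
    lab <- rep(NA_character_, n)
    lab[silent] <- "silent"
    oe <- o[!silent[o]]  # expressed genes in rank order
    ne <- length(oe)
    tert <- as.integer(ceiling(seq_len(ne) * 3 / ne))
    lab[oe] <- c("low", "medium", "high")[tert]
    out$category <- factor(lab, levels = c("silent", "low", "medium", "high"),
                           ordered = TRUE)
  }
  out
}
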