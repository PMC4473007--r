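#' Configuration for the synthetic ChIP-Seq study generator
#'
#' The generator builds a small annotated genome, a probe-level expression
#' table and two-condition read sets with enrichment planted around the TSSs
#' of active genes, so that every downstream stage (filtering, island
#' calling, annotation, profiling, clustering) can be scored against known
#' ground truth.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome, bp.
#' @param n_genes Total number of distinct gene loci across the genome.
#' @param gene_length_range Length-2 vector, min/max gene length in bp.
#' @param exons_per_gene_range Length-2 vector, min/max exons per gene.
#' @param overlap_fraction Fraction of loci annotated in both the RefSeq-like
#'   and the Ensembl-like source (same coordinates, different identifiers);
#'   the remainder is split between the two sources.
#' @param n_background_reads Reads placed uniformly over the genome, per
#'   condition.
#' @param enrichment_reads_per_active_gene Mean of the Poisson draw for the
#'   number of reads planted around an active gene's TSS (scaled by the
#'   gene's intensity).
#' @param enrichment_halfwidth Planted reads fall within TSS +/- this many bp
#'   (truncated normal, sd = halfwidth/2).
#' @param expression_coupling In `[0,1]`: fraction of the planted enrichment
#'   intensity explained by expression rank. At 1 the intensity is a strictly
#'   monotone function of expression rank; at 0 it is independent of it.
#' @param duplicate_fraction Fraction (of primary reads) emitted again as
#'   exact PCR-duplicate copies.
#' @param multimap_fraction Fraction of primary reads flagged multi-mapping.
#' @param read_length Read length in bp (default 25).
#' @param silent_fraction Fraction of genes whose expression sits at the
#'   background floor (and which receive no planted enrichment).
#' @param active_fraction Fraction of expressed genes that are active
#'   (receive planted enrichment) in a given condition.
#' @param shared_active_fraction Fraction of each condition's active set that
#'   is common to both conditions.
#' @param expression_floor Log2 expression value assigned to silent genes.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 2.5e6,
                       n_genes = 300,
                       gene_length_range = c(2000, 20000),
                       exons_per_gene_range = c(1, 8),
                       overlap_fraction = 0.7,
                       n_background_reads = 100000,
                       enrichment_reads_per_active_gene = 100,
                       enrichment_halfwidth = 1000,
                       expression_coupling = 0.8,
                       duplicate_fraction = 0.1,
                       multimap_fraction = 0.05,
                       read_length = 25,
                       silent_fraction = 0.25,
                       active_fraction = 0.9,
                       shared_active_fraction = 0.8,
                       expression_floor = 2,
                       seed = 1L) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_range = gene_length_range,
              exons_per_gene_range = exons_per_gene_range,
              overlap_fraction = overlap_fraction,
              n_background_reads = n_background_reads,
              enrichment_reads_per_active_gene = enrichment_reads_per_active_gene,
              enrichment_halfwidth = enrichment_halfwidth,
              expression_coupling = expression_coupling,
              duplicate_fraction = duplicate_fraction,
              multimap_fraction = multimap_fraction,
              read_length = read_length,
              silent_fraction = silent_fraction,
              active_fraction = active_fraction,
              shared_active_fraction = shared_active_fraction,
              expression_floor = expression_floor,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("n_chromosomes", "chrom_length", "n_genes", "read_length",
           "enrichment_halfwidth")
  for (f in pos)
    if (cfg[[f]] <= 0) stop(sprintf("'%s' must be strictly positive", f))
  frac <- c("overlap_fraction", "expression_coupling", "duplicate_fraction",
            "multimap_fraction", "silent_fraction", "active_fraction",
            "shared_active_fraction")
  for (f in frac)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  if (cfg$n_background_reads < 0 || cfg$enrichment_reads_per_active_gene < 0)
    stop("read counts must be non-negative")
  if (length(cfg$gene_length_range) != 2 ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2] ||
      cfg$gene_length_range[1] <= 0)
    stop("'gene_length_range' must be a positive, ordered pair")
  if (length(cfg$exons_per_gene_range) != 2 ||
      cfg$exons_per_gene_range[1] < 1 ||
      cfg$exons_per_gene_range[1] > cfg$exons_per_gene_range[2])
    stop("'exons_per_gene_range' must be an ordered pair with min >= 1")
  invisible(cfg)
}

# Flank that every gene must keep clear of the chromosome edge so that the
# +/-5 kb extended gene region stays on-chromosome.
.GENE_FLANK <- 5000L

#' Simulate two gene-annotation sources over a toy genome
#'
#' Places `n_genes` non-overlapping gene loci (each fitting within its
#' chromosome including a +/-5 kb flank), gives each an exon/intron structure
#' with terminal-exon UTRs (first/last 10 percent of the terminal exons lie
#' outside the thick/CDS span), and reports each locus in a RefSeq-like
#' source, an Ensembl-like source, or both, according to `overlap_fraction`.
#' Adjacent loci are kept more than `enrichment_halfwidth` bp apart so that a
#' planted enrichment interval contains exactly one TSS.
#'
#' @param config A [sim_config()].
#' @return List with elements `refseq`, `ensembl` (gene-model data.frames:
#'   gene_id, chrom, start, end, strand, source, thick_start, thick_end,
#'   exon_starts, exon_ends), `genome` (an `isl_genome`) and `truth` (locus
#'   table mapping locus to its identifier in each source and in the merged,
#'   RefSeq-precedence annotation).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genome <- define_genome(setNames(rep(config$chrom_length, config$n_chromosomes),
                                   sprintf("chr%d", seq_len(config$n_chromosomes))))
  min_gap <- max(200L, as.integer(config$enrichment_halfwidth) + 1L)

  # round-robin assignment of loci to chromosomes
  chrom_of <- rep(names(genome), length.out = config$n_genes)
  loci <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    k <- sum(chrom_of == names(genome)[ci])
    if (k == 0) next
    lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                   k, replace = TRUE)
    usable <- config$chrom_length - 2 * .GENE_FLANK
    slack <- usable - sum(lens) - (k - 1) * min_gap
    if (slack < 0)
      stop(sprintf(paste0("cannot place %d non-overlapping genes on a %d bp ",
                          "chromosome: reduce n_genes or gene_length_range, ",
                          "or increase chrom_length"),
                   k, as.integer(config$chrom_length)))
    cuts <- sort(runif(k, 0, 1))
    gaps <- floor(diff(c(0, cuts)) * slack)
    starts <- .GENE_FLANK + cumsum(gaps) + c(0, cumsum(lens[-k] + min_gap))
    loci[[ci]] <- data.frame(chrom = names(genome)[ci],
                             start = as.integer(starts),
                             end = as.integer(starts + lens))
  }
  loci <- do.call(rbind, loci)
  loci$strand <- sample(c("+", "-"), nrow(loci), replace = TRUE)
  loci$locus_id <- sprintf("g%04d", seq_len(nrow(loci)))

  ex <- lapply(seq_len(nrow(loci)), function(i)
    .simulate_exons(loci$start[i], loci$end[i], config$exons_per_gene_range))
  loci$exon_starts <- vapply(ex, function(e) paste(e$starts, collapse = ","), "")
  loci$exon_ends <- vapply(ex, function(e) paste(e$ends, collapse = ","), "")
  loci$thick_start <- vapply(ex, function(e) e$thick[1], 0L)
  loci$thick_end <- vapply(ex, function(e) e$thick[2], 0L)

  n_shared <- round(config$overlap_fraction * nrow(loci))
  shared <- sort(sample.int(nrow(loci), n_shared))
  rest <- setdiff(seq_len(nrow(loci)), shared)
  ref_only <- rest[seq_along(rest) %% 2 == 1]
  ens_only <- rest[seq_along(rest) %% 2 == 0]

  mk <- function(idx, ids, source) {
    g <- loci[idx, c("chrom", "start", "end", "strand", "thick_start",
                     "thick_end", "exon_starts", "exon_ends")]
    g <- cbind(gene_id = ids, g, source = source)
    g[order(g$chrom, g$start), , drop = FALSE]
  }
  ref_idx <- sort(c(shared, ref_only))
  ens_idx <- sort(c(shared, ens_only))
  ref_ids <- setNames(sprintf("NM_%06d", seq_along(ref_idx)), loci$locus_id[ref_idx])
  ens_ids <- setNames(sprintf("ENSBTAG%08d", seq_along(ens_idx)), loci$locus_id[ens_idx])

  truth <- loci[, c("locus_id", "chrom", "start", "end", "strand")]
  truth$tss <- gene_tss(truth)
  truth$refseq_id <- unname(ref_ids[truth$locus_id])
  truth$ensembl_id <- unname(ens_ids[truth$locus_id])
  # merged annotation keeps the RefSeq record where both sources cover a locus
  truth$merged_id <- ifelse(is.na(truth$refseq_id), truth$ensembl_id,
                            truth$refseq_id)

  list(refseq = mk(ref_idx, unname(ref_ids), "refseq"),
       ensembl = mk(ens_idx, unname(ens_ids), "ensembl"),
       genome = genome,
       truth = truth)
}

# Partition [start, end) into alternating exon/intron segments.
.simulate_exons <- function(start, end, ex_range) {
  len <- end - start
  n_ex <- sample(seq(ex_range[1], ex_range[2]), 1)
  # every exon and intron needs >= 1 bp; shrink n_ex for very short genes
  while (n_ex > 1 && (2 * n_ex - 1) * 50 > len) n_ex <- n_ex - 1
  if (n_ex == 1) {
    starts <- start; ends <- end
  } else {
    cuts <- sort(sample.int(len - 1, 2 * n_ex - 2))
    segs <- diff(c(0, cuts, len))
    starts <- start + cumsum(c(0, segs[-length(segs)]))[seq(1, 2 * n_ex - 1, by = 2)]
    ends <- starts + segs[seq(1, 2 * n_ex - 1, by = 2)]
  }
  # UTRs: first/last 10% of the terminal exons fall outside the thick span
  thick <- c(as.integer(starts[1] + floor(0.1 * (ends[1] - starts[1]))),
             as.integer(ends[n_ex] - floor(0.1 * (ends[n_ex] - starts[n_ex]))))
  list(starts = as.integer(starts), ends = as.integer(ends), thick = thick)
}

#' Simulate a probe-level expression table
#'
#' A configurable fraction of genes is silent (value at the background
#' floor); the rest get log2 values drawn as floor + lognormal offsets. Each
#' gene is measured by 1-3 probes (gene value plus small noise); the stored
#' gene-level truth is the exact mean of its probe values, matching the
#' probe-averaging rule used downstream.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config The same [sim_config()].
#' @return List with `probes` (probe_id, gene_id, value; gene_id is the
#'   locus's merged identifier) and `truth` (gene_id, locus_id, value,
#'   silent).
#' @export
simulate_expression <- function(annotation, config) {
  loci <- annotation$truth
  if (!nrow(loci)) stop("empty gene set")
  set.seed(config$seed + 1L)
  n <- nrow(loci)
  silent <- rep(FALSE, n)
  silent[sample.int(n, round(config$silent_fraction * n))] <- TRUE
  value <- ifelse(silent, config$expression_floor,
                  config$expression_floor + stats::rlnorm(n, meanlog = 1, sdlog = 0.6))

  n_probes <- sample(1:3, n, replace = TRUE)
  gene_idx <- rep(seq_len(n), n_probes)
  pv <- value[gene_idx] + stats::rnorm(length(gene_idx), sd = 0.15)
  probes <- data.frame(probe_id = sprintf("probe_%05d", seq_along(gene_idx)),
                       gene_id = loci$merged_id[gene_idx],
                       value = pv)
  truth <- data.frame(gene_id = loci$merged_id, locus_id = loci$locus_id,
                      value = as.numeric(tapply(pv, gene_idx, mean)),
                      silent = silent)
  list(probes = probes, truth = truth)
}

#' Simulate two-condition ChIP-Seq read sets with planted TSS enrichment
#'
#' Background reads are uniform over the genome. Each active gene receives a
#' Poisson number of reads (mean `enrichment_reads_per_active_gene` times an
#' intensity in `(0, 2)`) whose midpoints follow a truncated normal around
#' the TSS. With `expression_coupling = 1` the intensity is a strictly
#' increasing function of the gene's expression rank among active genes. The
#' two conditions ("tender", "tough") share a core of active genes plus
#' condition-unique actives. PCR duplicates (exact copies) and multi-mapping
#' flags are added last; primary reads are guaranteed unique on
#' (chrom, start, strand) so deduplication recovers them exactly.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param expression Output of [simulate_expression()].
#' @param config The same [sim_config()].
#' @return List with `reads` (list of two read data.frames) and `truth`
#'   (class `ground_truth`): active gene sets, planted read counts, planted
#'   enrichment intervals, per-condition read accounting.
#' @export
simulate_reads <- function(annotation, expression, config) {
  set.seed(config$seed + 2L)
  loci <- annotation$truth
  expr <- expression$truth[match(loci$merged_id, expression$truth$gene_id), ]
  expressed <- loci$locus_id[!expr$silent]

  n_active <- round(config$active_fraction * length(expressed))
  n_core <- round(config$shared_active_fraction * n_active)
  core <- sample(expressed, min(n_core, length(expressed)))
  rest <- setdiff(expressed, core)
  n_uniq <- n_active - length(core)
  uniq_a <- if (n_uniq > 0 && length(rest)) sample(rest, min(n_uniq, length(rest))) else character()
  uniq_b_pool <- setdiff(rest, uniq_a)
  uniq_b <- if (n_uniq > 0 && length(uniq_b_pool)) sample(uniq_b_pool, min(n_uniq, length(uniq_b_pool))) else character()
  active <- list(tender = sort(c(core, uniq_a)), tough = sort(c(core, uniq_b)))

  conditions <- lapply(setNames(nm = c("tender", "tough")), function(cond) {
    .simulate_condition_reads(loci, expr, active[[cond]], annotation$genome, config)
  })

  truth <- structure(list(
    active_genes = lapply(active, function(a) loci$merged_id[match(a, loci$locus_id)]),
    active_loci = active,
    true_islands = lapply(conditions, `[[`, "true_islands"),
    planted_counts = lapply(conditions, `[[`, "planted_counts"),
    expression_values = setNames(expr$value, loci$merged_id),
    accounting = lapply(conditions, `[[`, "accounting"),
    genome = annotation$genome
  ), class = "ground_truth")

  list(reads = lapply(conditions, `[[`, "reads"), truth = truth)
}

.simulate_condition_reads <- function(loci, expr, active_ids, genome, config) {
  rl <- as.integer(config$read_length)
  chrom_len <- unclass(genome)

  # background: uniform read starts
  nbg <- config$n_background_reads
  bg_chrom <- sample(names(genome), nbg, replace = TRUE,
                     prob = chrom_len / sum(chrom_len))
  bg_start <- floor(runif(nbg, 0, chrom_len[bg_chrom] - rl))

  # planted enrichment around TSSs of active genes
  ai <- match(active_ids, loci$locus_id)
  n_act <- length(ai)
  planted <- integer(0); en_chrom <- character(0); en_start <- integer(0)
  true_islands <- NULL
  if (n_act > 0) {
    r <- rank(expr$value[ai], ties.method = "first")
    u_rank <- r / (n_act + 1)
    u_noise <- runif(n_act)
    intensity <- 2 * (config$expression_coupling * u_rank +
                        (1 - config$expression_coupling) * u_noise)
    planted <- stats::rpois(n_act, config$enrichment_reads_per_active_gene * intensity)
    tss <- loci$tss[ai]
    h <- config$enrichment_halfwidth
    gi <- rep(seq_len(n_act), planted)
    # truncated normal via inverse CDF, sd = halfwidth / 2
    lo <- stats::pnorm(-h, 0, h / 2); hi <- stats::pnorm(h, 0, h / 2)
    delta <- stats::qnorm(runif(length(gi), lo, hi), 0, h / 2)
    en_chrom <- loci$chrom[ai][gi]
    en_start <- as.integer(round(tss[gi] + delta - rl / 2))
    en_start <- pmax(0L, pmin(en_start, as.integer(chrom_len[en_chrom]) - rl))
    true_islands <- data.frame(chrom = loci$chrom[ai],
                               start = pmax(0L, as.integer(tss - h)),
                               end = pmin(as.integer(tss + h),
                                          as.integer(chrom_len[loci$chrom[ai]])),
                               gene_id = loci$merged_id[ai])
  }

  reads <- data.frame(chrom = c(bg_chrom, en_chrom),
                      start = as.integer(c(bg_start, en_start)),
                      stringsAsFactors = FALSE)
  reads$end <- reads$start + rl
  reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)
  # enforce unique primaries on the dedup key so ground truth is exact
  reads <- reads[!duplicated(reads[c("chrom", "start", "strand")]), ]
  n_primary <- nrow(reads)
  reads$multimap <- FALSE
  reads$multimap[sample.int(n_primary, round(config$multimap_fraction * n_primary))] <- TRUE

  n_dup <- round(config$duplicate_fraction * n_primary)
  if (n_dup > 0)
    reads <- rbind(reads, reads[sample.int(n_primary, n_dup, replace = TRUE), ])
  reads <- reads[sample.int(nrow(reads)), ]
  reads$name <- sprintf("read_%07d", seq_len(nrow(reads)))
  rownames(reads) <- NULL
  reads <- reads[c("chrom", "start", "end", "name", "strand", "multimap")]

  list(reads = reads,
       true_islands = true_islands,
       planted_counts = if (n_act) setNames(planted, loci$merged_id[ai]) else integer(0),
       accounting = list(n_background = nbg,
                         n_planted = sum(planted),
                         n_primary = n_primary,
                         n_duplicates = n_dup,
                         n_emitted = n_primary + n_dup,
                         n_multimap_primary = sum(reads$multimap[!duplicated(
                           reads[c("chrom", "start", "strand")])]),
                         n_after_filters = sum(!reads$multimap[!duplicated(
                           reads[c("chrom", "start", "strand")])])))
}

#' Simulate a full synthetic study in one call
#'
#' Runs [simulate_annotation()], [simulate_expression()] and
#' [simulate_reads()] with one config and returns all pieces.
#'
#' @param config A [sim_config()].
#' @return List: annotation, expression, reads, truth, genome.
#' @export
simulate_dataset <- function(config) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(ann, config)
  rd <- simulate_reads(ann, expr, config)
  list(annotation = ann, expression = expr, reads = rd$reads,
       truth = rd$truth, genome = ann$genome)
}

#' Simulate promoter-signal archetypes for clustering benchmarks
#'
#' Builds a gene-by-bin promoter signal matrix directly from three planted
#' archetypes: flat (no enrichment), a Gaussian peak upstream of the TSS and
#' a Gaussian peak downstream, with the flat group assigned the lowest
#' expression. Used to benchmark [cluster_promoters()] against known labels.
#'
#' @param n_per_group Genes per archetype.
#' @param n_bins Columns of the matrix (promoter bins, 5' to 3').
#' @param peak_height Mean peak amplitude, in units of the noise SD
#'   (separation; default 8).
#' @param seed Integer seed.
#' @return List: `matrix`, `labels` (1 = flat, 2 = upstream, 3 = downstream),
#'   `expression` (named log2 values, flat group lowest).
#' @export
simulate_promoter_archetypes <- function(n_per_group = 100, n_bins = 80,
                                         peak_height = 8, seed = 1L) {
  set.seed(seed)
  n <- 3 * n_per_group
  labels <- rep(1:3, each = n_per_group)
  bins <- seq_len(n_bins)
  up_mu <- n_bins * 0.3; dn_mu <- n_bins * 0.7; sdb <- n_bins * 0.08
  shape <- rbind(rep(0, n_bins),
                 exp(-(bins - up_mu)^2 / (2 * sdb^2)),
                 exp(-(bins - dn_mu)^2 / (2 * sdb^2)))
  amp <- ifelse(labels == 1, 0, peak_height * runif(n, 0.8, 1.2))
  m <- shape[labels, ] * amp + matrix(stats::rnorm(n * n_bins), n, n_bins)
  m[m < 0] <- 0
  rownames(m) <- sprintf("g%04d", seq_len(n))
  expr <- ifelse(labels == 1, stats::rnorm(n, 3, 0.5), stats::rnorm(n, 8, 1))
  list(matrix = m, labels = labels,
       expression = setNames(expr, rownames(m)))
}
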