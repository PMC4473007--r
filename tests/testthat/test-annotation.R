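mk_gene <- function(gene_id, chrom, start, end, strand, source = "refseq",
                    exon_starts = NULL, exon_ends = NULL,
                    thick_start = NULL, thick_end = NULL) {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand,
             thick_start = if (is.null(thick_start)) start else thick_start,
             thick_end = if (is.null(thick_end)) end else thick_end,
             exon_starts = if (is.null(exon_starts)) as.character(start) else exon_starts,
             exon_ends = if (is.null(exon_ends)) as.character(end) else exon_ends,
             source = source)
}

test_that("annotation merging keeps RefSeq genes and non-overlapping Ensembl genes", {
  ref <- mk_gene("NM_1", "chr1", 1000, 5000, "+")
  ens_same <- mk_gene("ENS1", "chr1", 1000, 5000, "+", "ensembl")
  merged <- merge_annotations(ref, ens_same)
  expect_equal(merged$gene_id, "NM_1")

  ens_elsewhere <- mk_gene("ENS2", "chr9", 1000, 5000, "+", "ensembl")
  merged2 <- merge_annotations(ref, ens_elsewhere)
  expect_setequal(merged2$gene_id, c("NM_1", "ENS2"))

  # opposite strand overlap is retained by default, dropped when disabled
  ens_opp <- mk_gene("ENS3", "chr1", 2000, 4000, "-", "ensembl")
  expect_setequal(merge_annotations(ref, ens_opp)$gene_id, c("NM_1", "ENS3"))
  expect_equal(merge_annotations(ref, ens_opp, same_strand_only = FALSE)$gene_id,
               "NM_1")

  dup <- rbind(ref, ref)
  expect_error(merge_annotations(dup, ens_same), "duplicated gene_id")
})

test_that("merged size equals loci with both-source loci collapsed to RefSeq", {
  cfg <- small_config(overlap_fraction = 0.5, n_genes = 100, chrom_length = 3e6)
  ann <- simulate_annotation(cfg)
  merged <- merge_annotations(ann$refseq, ann$ensembl)
  expect_equal(nrow(merged), 100)
  n_ens_only <- sum(is.na(ann$truth$refseq_id))
  expect_equal(nrow(merged), nrow(ann$refseq) + n_ens_only)
  expect_setequal(merged$gene_id, ann$truth$merged_id)
  # retained Ensembl genes overlap no RefSeq gene
  expect_true(all(merged$gene_id[merged$source == "ensembl"] %in%
                    ann$truth$ensembl_id[is.na(ann$truth$refseq_id)]))
})

test_that("enriched-gene calls use half-open overlap with the chosen region", {
  g <- define_genome(c(chr1 = 1e5))
  gene <- mk_gene("NM_1", "chr1", 50000, 60000, "+")
  # promoter_2kb = [48000, 52000)
  exact <- data.frame(chrom = "chr1", start = 48000, end = 52000)
  expect_equal(enriched_genes(exact, gene, g), "NM_1")
  outside <- data.frame(chrom = "chr1", start = 52000, end = 53000)
  expect_equal(length(enriched_genes(outside, gene, g)), 0)
  touching <- data.frame(chrom = "chr1", start = 51999, end = 52100)
  expect_equal(enriched_genes(touching, gene, g), "NM_1")
  expect_error(gene_regions(gene, g, "bogus"))
  # extended region reaches 5 kb past both ends
  far <- data.frame(chrom = "chr1", start = 64000, end = 64500)
  expect_equal(enriched_genes(far, gene, g, "extended"), "NM_1")
})

test_that("enriched-gene recall on synthetic truth and set accounting hold", {
  cfg <- small_config(n_genes = 40, chrom_length = 2e6,
                      enrichment_reads_per_active_gene = 120)
  ds <- simulate_dataset(cfg)
  merged <- merge_annotations(ds$annotation$refseq, ds$annotation$ensembl)
  p <- island_params(effective_genome_fraction = 1)
  isl_a <- call_islands(reads_to_track(ds$reads$tender, ds$genome), p)
  isl_b <- call_islands(reads_to_track(ds$reads$tough, ds$genome), p)
  sets <- enriched_gene_sets(isl_a, isl_b, merged, ds$genome)
  recall <- mean(ds$truth$active_genes$tender %in% sets$a)
  expect_gte(recall, 0.9)
  expect_equal(length(sets$only_a) + length(sets$both), length(sets$a))
  expect_equal(length(sets$only_b) + length(sets$both), length(sets$b))
})

test_that("peak classification respects feature precedence and partitions", {
  # gene with 3 exons: [1000,2000) [3000,4000) [5000,6000); thick [1500,5500)
  gene <- mk_gene("NM_1", "chr1", 1000, 6000, "+",
                  exon_starts = "1000,3000,5000", exon_ends = "2000,4000,6000",
                  thick_start = 1500, thick_end = 5500)
  cls <- function(mid) as.character(classify_peaks(
    data.frame(chrom = "chr1", start = mid - 10, end = mid + 10), gene))
  expect_equal(cls(1200), "five_prime_utr")
  expect_equal(cls(5800), "three_prime_utr")
  expect_equal(cls(3500), "exon")
  expect_equal(cls(2500), "first_intron")
  expect_equal(cls(4500), "last_intron")
  expect_equal(cls(8000), "intergenic")

  # minus strand flips the UTR ends and intron order
  gene_m <- mk_gene("NM_2", "chr1", 1000, 6000, "-",
                    exon_starts = "1000,3000,5000", exon_ends = "2000,4000,6000",
                    thick_start = 1500, thick_end = 5500)
  clsm <- function(mid) as.character(classify_peaks(
    data.frame(chrom = "chr1", start = mid - 10, end = mid + 10), gene_m))
  expect_equal(clsm(5800), "five_prime_utr")
  expect_equal(clsm(1200), "three_prime_utr")
  expect_equal(clsm(4500), "first_intron")
  expect_equal(clsm(2500), "last_intron")

  # 4 exons: middle intron is "other"; single intron counts as first
  gene4 <- mk_gene("NM_3", "chr2", 0, 8000, "+",
                   exon_starts = "0,2000,4000,6000",
                   exon_ends = "1000,3000,5000,7000",
                   thick_start = 100, thick_end = 6900)
  expect_equal(as.character(classify_peaks(
    data.frame(chrom = "chr2", start = 3400, end = 3600), gene4)),
    "other_intron")
  gene2 <- mk_gene("NM_4", "chr3", 0, 4000, "+",
                   exon_starts = "0,3000", exon_ends = "1000,4000",
                   thick_start = 100, thick_end = 3900)
  expect_equal(as.character(classify_peaks(
    data.frame(chrom = "chr3", start = 1900, end = 2100), gene2)),
    "first_intron")

  # partition: every island gets exactly one category
  set.seed(4)
  cfg <- small_config()
  ann <- simulate_annotation(cfg)
  merged <- merge_annotations(ann$refseq, ann$ensembl)
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                    start = sample.int(9e5, 500))
  rnd$end <- rnd$start + sample(c(200, 600, 1000), 500, TRUE)
  fc <- classify_peaks(rnd, merged)
  expect_equal(length(fc), 500)
  expect_false(anyNA(fc))
  expect_equal(sum(table(fc) / 500), 1.0)
})

test_that("TSS distances are signed in the gene's own orientation", {
  genes <- rbind(mk_gene("NM_1", "chr1", 10000, 20000, "+"),
                 mk_gene("NM_2", "chr2", 10000, 20000, "-"))
  # midpoint 500 bp 5' of the + strand TSS (at 10000) -> -500
  isl <- data.frame(chrom = "chr1", start = 9400, end = 9600)
  expect_equal(distance_to_tss(isl, genes)$distance, -500)
  # 500 bp 5' of the - strand TSS (at 19999): genomically downstream
  isl_m <- data.frame(chrom = "chr2", start = 20399, end = 20599)
  d <- distance_to_tss(isl_m, genes)
  expect_equal(d$distance, -500)
  expect_equal(d$gene_id, "NM_2")
  # chromosome without genes: skipped with warning
  orphan <- data.frame(chrom = "chr9", start = 0, end = 200)
  expect_warning(res <- distance_to_tss(orphan, genes), "skipped")
  expect_equal(nrow(res), 0)
  # nearest-by-absolute-distance wins
  two <- rbind(mk_gene("NM_A", "chr1", 1000, 3000, "+"),
               mk_gene("NM_B", "chr1", 9000, 12000, "+"))
  mid_isl <- data.frame(chrom = "chr1", start = 3900, end = 4100)
  expect_equal(distance_to_tss(mid_isl, two)$gene_id, "NM_A")
})

test_that("planted enrichment lands within the halfwidth of the TSS", {
  # all genes active, 20x-background sites, default caller parameters
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 2.5e6, n_genes = 40,
                    n_background_reads = 5000,
                    enrichment_reads_per_active_gene = 40,
                    silent_fraction = 0, active_fraction = 1,
                    shared_active_fraction = 1, duplicate_fraction = 0,
                    multimap_fraction = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  merged <- merge_annotations(ds$annotation$refseq, ds$annotation$ensembl)
  isl <- call_islands(reads_to_track(ds$reads$tender, ds$genome),
                      island_params())
  d <- distance_to_tss(isl, merged)
  expect_gte(mean(abs(d$distance) <= 1000), 0.8)
  # symmetric planting: distances are centred near zero
  expect_lt(abs(median(d$distance)), 500)
})

test_that("chromosome distribution percentages sum to 100 and track length", {
  g <- define_genome(c(chr1 = 2e6, chr2 = 1e6))
  one_chrom <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(200, 1200))
  cd <- chromosome_distribution(one_chrom, g)
  expect_equal(cd$pct, c(100, 0))
  expect_equal(sum(cd$pct), 100)
  expect_equal(nrow(chromosome_distribution(one_chrom[0, ], g)), 2)
  expect_error(chromosome_distribution(
    data.frame(chrom = "chrX", start = 0, end = 100), g), "unknown chromosome")
  set.seed(8)
  unif <- data.frame(chrom = sample(c("chr1", "chr2"), 6000, TRUE,
                                    prob = c(2, 1) / 3),
                     start = sample.int(9e5, 6000))
  unif$end <- unif$start + 200
  cdu <- chromosome_distribution(unif, g)
  expect_equal(cdu$rel_density, c(1, 1), tolerance = 0.06)
})
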