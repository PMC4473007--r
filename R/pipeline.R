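#' Default pipeline configuration
#'
#' All analysis parameters surfaced in one nested list, with the standard
#' values as defaults: 200 bp windows, 400 bp gaps, E-value 100, 190 bp
#' fragments, TSS +/- 2 kb promoters in 5 bp bins, 5 kb metagene flanks in
#' 1 kb bins with 20 gene-body bins, k = 3 promoter clusters.
#'
#' @param reads Named list of BED6 paths, one per condition.
#' @param refseq,ensembl Gene-model TSV paths (see [write_gene_models()]).
#' @param probes Probe-level expression TSV path (probe_id, gene_id, value).
#' @param genome Named list/vector of chromosome lengths.
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param ... Overrides for the nested `island`, `profile`, `promoter`,
#'   `clustering` parameter lists.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(reads, refseq, ensembl, probes, genome, outdir,
                            seed = 1L, ...) {
  cfg <- list(
    reads = reads, refseq = refseq, ensembl = ensembl, probes = probes,
    genome = genome, outdir = outdir, seed = as.integer(seed),
    island = list(window_size = 200, gap_size = 400, e_value = 100,
                  fragment_length = 190, effective_genome_fraction = 1.0,
                  p_window = 0.2),
    profile = list(tss_halfwidth = 2000, tss_bin = 5, flank = 5000,
                   flank_bin = 1000, body_bins = 20),
    promoter = list(halfwidth = 2000, bin = 50, min_gene_length = 2000),
    clustering = list(k = 3, n_restarts = 10))
  dots <- list(...)
  for (nm in names(dots))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  cfg
}

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

.stage_out <- function(outdir, ...) file.path(outdir, ...)

.write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    ...)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: read filtering and window summarization; island
#' calling and two-condition comparison; annotation merging, enriched-gene
#' calling, feature classification, TSS distances and chromosome
#' distribution; probe-to-gene expression with category assignment; TSS and
#' metagene profiles by expression decile; promoter-matrix k-means
#' clustering. Inputs are validated before any stage runs. Each stage's
#' outputs are cached on disk: a stage whose outputs all exist (and whose
#' upstream stages were not recomputed) is loaded from cache rather than
#' recomputed. A JSON manifest (stage, parameters, outputs, md5 checksums)
#' is written at the end.
#'
#' @param config A configuration list from [pipeline_config()] or the path
#'   to a YAML file holding one.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- .read_config(config)
  conds <- names(cfg$reads)
  inputs <- c(unlist(cfg$reads), cfg$refseq, cfg$ensembl, cfg$probes)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  genome <- define_genome(unlist(cfg$genome))
  od <- cfg$outdir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  ip <- do.call(island_params, cfg$island)
  manifest <- list()
  dirty <- FALSE  # becomes TRUE once any stage recomputes

  run_stage <- function(name, params, outputs, compute, load) {
    t0 <- Sys.time()
    cached <- !dirty && all(file.exists(outputs))
    result <- if (cached) load() else { dirty <<- TRUE; compute() }
    manifest[[name]] <<- list(
      stage = name, cached = cached, parameters = params,
      outputs = as.list(setNames(unname(tools::md5sum(outputs)), outputs)),
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message(sprintf("[%s] %s (%.1fs)", name,
                    if (cached) "cached" else "computed",
                    manifest[[name]]$seconds))
    result
  }

  ## stage 1: reads -> filtered fragments + window tracks
  frag_paths <- setNames(.stage_out(od, "fragments",
                                    paste0(conds, "_fragments.tsv")), conds)
  frags <- run_stage("reads", cfg$island, c(
    frag_paths,
    .stage_out(od, "tracks", paste0(conds, c("_raw.bedgraph"))),
    .stage_out(od, "tracks", paste0(conds, c("_normalized.bedgraph")))),
    compute = function() {
      lapply(setNames(nm = conds), function(cc) {
        rd <- read_bed6(cfg$reads[[cc]])
        filtered <- deduplicate(drop_multimappers(rd))
        iv <- extend_reads(filtered, ip$fragment_length, genome)
        track <- summarize_windows(iv, genome, ip$window_size,
                                   total_mapped_reads = nrow(filtered))
        write_bedgraph(track, .stage_out(od, "tracks",
                                         paste0(cc, "_raw.bedgraph")))
        write_bedgraph(normalize_per_million(track),
                       .stage_out(od, "tracks",
                                  paste0(cc, "_normalized.bedgraph")))
        .write_tsv(iv, frag_paths[[cc]])
        list(intervals = iv, track = track)
      })
    },
    load = function() {
      lapply(setNames(nm = conds), function(cc) {
        iv <- .read_tsv(frag_paths[[cc]])
        list(intervals = iv,
             track = summarize_windows(iv, genome, ip$window_size,
                                       total_mapped_reads = nrow(iv)))
      })
    })

  ## stage 2: island calling + comparison
  isl_paths <- setNames(.stage_out(od, "islands",
                                   paste0(conds, "_islands.tsv")), conds)
  cmp_path <- .stage_out(od, "islands", "comparison.tsv")
  islands <- run_stage("islands", cfg$island, c(isl_paths, cmp_path),
    compute = function() {
      isl <- lapply(setNames(nm = conds), function(cc) {
        x <- call_islands(frags[[cc]]$track, ip)
        .write_tsv(x, isl_paths[[cc]])
        x
      })
      cmp <- compare_conditions(isl[[1]], isl[[2]])
      .write_tsv(data.frame(condition = conds,
                            total_peaks = c(cmp$total_a, cmp$total_b),
                            shared_peaks = c(cmp$shared_a, cmp$shared_b),
                            unique_peaks = c(cmp$unique_a, cmp$unique_b)),
                 cmp_path)
      isl
    },
    load = function() lapply(setNames(nm = conds),
                             function(cc) .read_tsv(isl_paths[[cc]])))

  ## stage 3: annotation
  ann_out <- .stage_out(od, "annotation",
                        c("merged_genes.tsv", "enriched_genes.tsv",
                          "feature_classes.tsv", "tss_distances.tsv",
                          "chromosome_distribution.tsv"))
  merged <- run_stage("annotation", list(region_kind = "promoter_2kb"), ann_out,
    compute = function() {
      mg <- merge_annotations(read_gene_models(cfg$refseq),
                              read_gene_models(cfg$ensembl))
      .write_tsv(mg, ann_out[1])
      sets <- enriched_gene_sets(islands[[1]], islands[[2]], mg, genome)
      all_ids <- sort(union(sets$a, sets$b))
      .write_tsv(data.frame(gene_id = all_ids,
                            enriched = ifelse(all_ids %in% sets$both, "both",
                                       ifelse(all_ids %in% sets$a, conds[1],
                                              conds[2]))),
                 ann_out[2])
      fc <- do.call(rbind, lapply(conds, function(cc) {
        cl <- classify_peaks(islands[[cc]], mg)
        data.frame(condition = cc, class = levels(cl),
                   n = as.integer(table(cl)),
                   fraction = as.numeric(table(cl)) / max(1L, length(cl)))
      }))
      .write_tsv(fc, ann_out[3])
      td <- do.call(rbind, lapply(conds, function(cc)
        cbind(condition = cc, distance_to_tss(islands[[cc]], mg))))
      .write_tsv(td, ann_out[4])
      pooled <- rbind(islands[[1]][c("chrom", "start", "end")],
                      islands[[2]][c("chrom", "start", "end")])
      .write_tsv(chromosome_distribution(pooled, genome), ann_out[5])
      mg
    },
    load = function() read_gene_models(ann_out[1]))

  ## stage 4: expression
  expr_path <- .stage_out(od, "expression", "gene_expression.tsv")
  expr <- run_stage("expression", list(scheme = "deciles"), expr_path,
    compute = function() {
      gt <- probes_to_genes(.read_tsv(cfg$probes,
                                      colClasses = c(probe_id = "character",
                                                     gene_id = "character")),
                            known_genes = merged$gene_id)
      gt <- assign_categories(gt, "deciles")
      .write_tsv(gt, expr_path)
      gt
    },
    load = function() .read_tsv(expr_path,
                                colClasses = c(gene_id = "character")))

  ## stage 5: profiles (conditions pooled)
  prof_out <- .stage_out(od, "profiles",
                         c("tss_decile_curves.tsv", "metagene_decile_curves.tsv",
                           "promoter_matrix.tsv"))
  pooled_iv <- NULL
  profs <- run_stage("profiles", cfg$profile, prof_out,
    compute = function() {
      iv <- do.call(rbind, lapply(conds, function(cc) frags[[cc]]$intervals))
      pooled_iv <<- iv
      cats <- setNames(expr$category, expr$gene_id)
      fine <- profile_matrix(iv, merged,
                             profile_spec("tss_fine",
                                          tss_halfwidth = cfg$profile$tss_halfwidth,
                                          tss_bin = cfg$profile$tss_bin))
      .write_tsv(category_profile(fine, cats), prof_out[1])
      meta <- profile_matrix(iv, merged,
                             profile_spec("metagene", flank = cfg$profile$flank,
                                          flank_bin = cfg$profile$flank_bin,
                                          body_bins = cfg$profile$body_bins))
      .write_tsv(category_profile(meta, cats), prof_out[2])
      pm <- promoter_matrix(iv, merged, halfwidth = cfg$promoter$halfwidth,
                            bin = cfg$promoter$bin,
                            min_gene_length = cfg$promoter$min_gene_length,
                            expression = expr)
      .write_tsv(data.frame(gene_id = rownames(pm), as.data.frame(unclass(pm))),
                 prof_out[3])
      pm
    },
    load = function() {
      df <- .read_tsv(prof_out[3], colClasses = c(gene_id = "character"))
      pm <- as.matrix(df[, -1, drop = FALSE])
      rownames(pm) <- df$gene_id
      attr(pm, "expression") <- setNames(
        expr$value[match(df$gene_id, expr$gene_id)], df$gene_id)
      pm
    })

  ## stage 6: clustering
  clus_out <- .stage_out(od, "clustering",
                         c("assignments.tsv", "centroids.tsv",
                           "expression_summary.tsv"))
  run_stage("clustering", cfg$clustering, clus_out,
    compute = function() {
      res <- cluster_promoters(profs, k = cfg$clustering$k, seed = cfg$seed,
                               n_restarts = cfg$clustering$n_restarts)
      rendered <- sort_and_render(profs, res,
                                  setNames(expr$value, expr$gene_id))
      .write_tsv(data.frame(gene_id = names(res$assignments),
                            cluster = unname(res$assignments)), clus_out[1])
      .write_tsv(data.frame(cluster = seq_len(res$k), res$centroids),
                 clus_out[2])
      .write_tsv(rendered$expression_summary, clus_out[3])
      res
    },
    load = function() .read_tsv(clus_out[1], colClasses = c(gene_id = "character")))

  manifest_path <- .stage_out(od, "manifest.json")
  jsonlite::write_json(unname(manifest), manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf("manifest: %s", manifest_path))
  invisible(manifest)
}

#' Generate a self-contained demo dataset
#'
#' Simulates a small study (two 2.5 Mb chromosomes, 300 genes, roughly
#' 10^5 background reads per condition), writes its inputs (reads as BED6,
#' both gene-model sources, the probe table, chromosome sizes), the ground
#' truth as JSON, and a ready-to-run pipeline YAML config.
#'
#' @param outdir Directory to create the demo in.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override.
#' @return List: `config_path` (YAML for [run_pipeline()]), `truth`, and
#'   the simulated dataset (invisible components).
#' @export
make_demo <- function(outdir, seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(file.path(outdir, "input"), recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(config)
  paths <- list(
    tender = file.path(outdir, "input", "tender.bed"),
    tough = file.path(outdir, "input", "tough.bed"),
    refseq = file.path(outdir, "input", "refseq_genes.tsv"),
    ensembl = file.path(outdir, "input", "ensembl_genes.tsv"),
    probes = file.path(outdir, "input", "probes.tsv"),
    truth = file.path(outdir, "input", "ground_truth.json"))
  write_bed6(ds$reads$tender, paths$tender)
  write_bed6(ds$reads$tough, paths$tough)
  write_gene_models(ds$annotation$refseq, paths$refseq)
  write_gene_models(ds$annotation$ensembl, paths$ensembl)
  .write_tsv(ds$expression$probes, paths$probes)
  jsonlite::write_json(
    list(active_genes = ds$truth$active_genes,
         true_islands = ds$truth$true_islands,
         planted_counts = ds$truth$planted_counts,
         expression_values = as.list(ds$truth$expression_values),
         accounting = ds$truth$accounting),
    paths$truth, auto_unbox = TRUE, digits = NA)
  cfg <- pipeline_config(reads = list(tender = paths$tender,
                                      tough = paths$tough),
                         refseq = paths$refseq, ensembl = paths$ensembl,
                         probes = paths$probes,
                         genome = as.list(unclass(ds$genome)),
                         outdir = file.path(outdir, "results"),
                         seed = config$seed)
  config_path <- file.path(outdir, "pipeline.yaml")
  yaml::write_yaml(cfg, config_path)
  invisible(list(config_path = config_path, truth = ds$truth,
                 dataset = ds, paths = paths))
}
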