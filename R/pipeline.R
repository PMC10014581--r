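# End-to-end orchestration: a declarative config, a workspace writer for the
# synthetic generators, and the staged pipeline runner.

#' Pipeline configuration
#'
#' Collects every input path and threshold. All thresholds are surfaced here
#' with their standard defaults; a snapshot of the config is written into
#' every output directory.
#'
#' @param atlas_bed,counts_tsv,samples_tsv,genes_tsv,de_tsv Input paths
#'   (atlas BED; peak x sample counts TSV; sample sheet TSV; gene annotation
#'   TSV; DE table TSV).
#' @param tissue_beds Named list: tissue -> character vector of replicate
#'   BED paths (optional).
#' @param lineage_map Named character vector: tissue -> germ layer
#'   (required with `tissue_beds`).
#' @param stage_order Ordered stage labels.
#' @param seed Pipeline seed (c-means initialisation etc.).
#' @param lfc_threshold,padj_threshold Dynamic-peak thresholds (2, 0.005).
#' @param k Number of c-means clusters (8).
#' @param fuzzifier_m Fuzzy c-means fuzzifier (1.25).
#' @param tss_pad Promoter exclusion half-width in bp (2000).
#' @param windows Peak-gene assignment windows in bp (25000, 200000).
#' @param de_base_mean_min,de_lfc_min,de_padj_max DE gene-set filters
#'   (1000, 1.5, 0.05).
#' @param run_pairwise Also compute the OPEN/CLOSE transition classes.
#' @param scrna Optional list with elements `a`, `b` ([cell_matrix()]
#'   objects) to run the cluster alignment stage.
#' @param n_boot Bootstrap replicates for cluster alignment (1000).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(atlas_bed, counts_tsv, samples_tsv, genes_tsv,
                            de_tsv, tissue_beds = NULL, lineage_map = NULL,
                            stage_order = c("ESC", "ADE", "VFGp3", "VFGp6", "PE"),
                            seed = 1,
                            lfc_threshold = 2, padj_threshold = 0.005,
                            k = 8, fuzzifier_m = 1.25, tss_pad = 2000,
                            windows = c(25000, 200000),
                            de_base_mean_min = 1000, de_lfc_min = 1.5,
                            de_padj_max = 0.05,
                            run_pairwise = TRUE, scrna = NULL, n_boot = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Materialize a synthetic workspace on disk
#'
#' Runs every generator under one master seed and writes exactly the file
#' formats the pipeline consumes (BED, TSV), plus the ground-truth tables.
#'
#' @param dir Output directory (created).
#' @param cfg A [sim_config()].
#' @return A [pipeline_config()] pointing at the written files, with the
#'   ground truth attached as attribute `truth` and the in-memory scRNA
#'   datasets in `$scrna`.
#' @export
simulate_workspace <- function(dir, cfg = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_atac_timecourse(cfg)
  gl <- simulate_gene_links(cfg, sim)
  de <- simulate_de_table(cfg, gl$truth)
  tis <- simulate_tissue_h3k27ac(cfg, sim)
  sc <- simulate_scrna(cfg)

  p <- function(...) file.path(dir, ...)
  write_bed(sim$atlas, p("atlas.bed"))
  counts <- tibble::as_tibble(sim$counts, rownames = "peak")
  readr::write_tsv(counts, p("counts.tsv"))
  readr::write_tsv(sim$samples, p("samples.tsv"))
  genes_tbl <- tibble::tibble(
    gene_id = gl$genes$gene_id, chrom = gl$genes$chrom,
    start = ifelse(gl$genes$strand == "+", gl$genes$tss,
                   pmax(gl$genes$tss - 1000, 0)),
    end = ifelse(gl$genes$strand == "+", gl$genes$tss + 1000, gl$genes$tss),
    strand = gl$genes$strand
  )
  readr::write_tsv(genes_tbl, p("genes.tsv"))
  readr::write_tsv(
    tibble::tibble(gene = de$de$gene_id, baseMean = de$de$baseMean,
                   log2FoldChange = de$de$log2fc, padj = de$de$padj),
    p("de_table.tsv"))
  tissue_beds <- lapply(names(tis$replicates), function(tn) {
    vapply(seq_along(tis$replicates[[tn]]), function(i) {
      path <- p(sprintf("h3k27ac_%s_rep%d.bed", tn, i))
      write_bed(tis$replicates[[tn]][[i]], path)
      path
    }, character(1))
  })
  names(tissue_beds) <- names(tis$replicates)
  readr::write_tsv(sim$truth, p("truth_peaks.tsv"))
  readr::write_tsv(gl$truth, p("truth_genes.tsv"))
  readr::write_tsv(de$truth, p("truth_de.tsv"))
  readr::write_tsv(tis$truth, p("truth_tissues.tsv"))
  readr::write_tsv(sc$truth, p("truth_scrna.tsv"))

  out <- pipeline_config(
    atlas_bed = p("atlas.bed"), counts_tsv = p("counts.tsv"),
    samples_tsv = p("samples.tsv"), genes_tsv = p("genes.tsv"),
    de_tsv = p("de_table.tsv"), tissue_beds = tissue_beds,
    lineage_map = tis$lineage_map, stage_order = cfg$stages,
    seed = cfg$seed, scrna = sc[c("a", "b")]
  )
  attr(out, "truth") <- list(peaks = sim$truth, genes = gl$truth,
                             de = de$truth, tissues = tis$truth,
                             scrna = sc$truth)
  out
}

#' Run the full analysis pipeline
#'
#' Stages execute in dependency order: interval ingestion, dynamic-peak
#' detection, temporal classification, peak-gene linking, enrichment
#' scoring, and (when scRNA data are configured) cluster alignment. All
#' tables, per-class BEDs and a JSON run manifest (seed, thresholds, input
#' checksums) are written under `outdir`.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created).
#' @return Invisibly, a list of the in-memory results (`dynamics`,
#'   `classification`, `links`, `enrichment`, `pairwise`, `alignment`,
#'   `manifest`).
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("atlas_bed", "counts_tsv", "samples_tsv", "genes_tsv", "de_tsv")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline input missing [", f, "]: ", cfg[[f]], call. = FALSE)
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  # -- intervals ------------------------------------------------------------
  atlas <- read_bed(cfg$atlas_bed)
  genes <- read_gene_annotation(cfg$genes_tsv)
  m <- read_accessibility(cfg$counts_tsv, cfg$samples_tsv, atlas,
                          stage_order = cfg$stage_order)

  # -- dynamics -------------------------------------------------------------
  distal <- filter_promoter_distal(atlas, genes, tss_pad = cfg$tss_pad)
  m_distal <- accessibility_matrix(
    m$counts[rownames(m$counts) %in% distal$name, , drop = FALSE],
    m$samples, atlas, stage_order = cfg$stage_order)
  dyn <- detect_dynamic_peaks(m_distal, lfc_threshold = cfg$lfc_threshold,
                              padj_threshold = cfg$padj_threshold)
  readr::write_tsv(dyn, p("dynamic_peaks.tsv"))

  # -- temporal classes -----------------------------------------------------
  dyn_peaks <- dyn$peak[dyn$is_dynamic]
  traj <- standardize_trajectories(m_distal, peaks = dyn_peaks)
  cl <- cmeans_cluster(traj, k = cfg$k, fuzzifier_m = cfg$fuzzifier_m,
                       seed = cfg$seed)
  cl <- assign_groups(cl)
  cls_tbl <- tidy(cl)
  readr::write_tsv(cls_tbl, p("classification.tsv"))
  class_atlases <- split_atlas_by_group(
    atlas, stats::setNames(cls_tbl$group, cls_tbl$peak))
  for (g in names(class_atlases)) {
    write_bed(class_atlases[[g]],
              p(paste0("class_", gsub("[^A-Za-z0-9]+", "_", g), ".bed")))
  }

  pairwise <- NULL
  if (isTRUE(cfg$run_pairwise) && length(cfg$stage_order) >= 4) {
    pairwise <- pairwise_open_close(m_distal,
                                    lfc_threshold = cfg$lfc_threshold,
                                    padj_threshold = cfg$padj_threshold)
    readr::write_tsv(pairwise, p("pairwise_classes.tsv"))
  }

  # -- linking --------------------------------------------------------------
  links <- lapply(cfg$windows, function(w) {
    nearest_tss_assignment(atlas, genes, window = w)
  })
  names(links) <- paste0("window_", cfg$windows)
  link_tbl <- dplyr::bind_rows(links)
  readr::write_tsv(link_tbl, p("peak_gene_links.tsv"))

  # -- enrichment -----------------------------------------------------------
  de <- read_de_table(cfg$de_tsv)
  labels <- stats::setNames(cls_tbl$group, cls_tbl$peak)
  enr <- dplyr::bind_rows(lapply(names(links), function(lw) {
    dplyr::bind_rows(lapply(c("up", "down"), function(dir) {
      gs <- filter_de_genes(de, base_mean_min = cfg$de_base_mean_min,
                            lfc_min = cfg$de_lfc_min,
                            padj_max = cfg$de_padj_max, direction = dir)
      class_geneset_enrichment(links[[lw]], labels, gs,
                               set_name = paste0(dir, "_", lw))
    }))
  }))
  tissue_enr <- NULL
  if (!is.null(cfg$tissue_beds)) {
    reps <- lapply(cfg$tissue_beds, function(paths) lapply(paths, read_bed))
    ts <- build_tissue_sets(reps, cfg$lineage_map)
    tissue_enr <- dplyr::bind_rows(
      class_region_enrichment(class_atlases, ts$tissue, atlas),
      class_region_enrichment(class_atlases, ts$lineage_unique, atlas)
    )
  }
  enrichment <- dplyr::bind_rows(enr, tissue_enr)
  readr::write_tsv(enrichment, p("enrichment.tsv"))

  # -- cluster alignment ----------------------------------------------------
  alignment <- NULL
  if (!is.null(cfg$scrna)) {
    panel <- select_gene_panel(cfg$scrna$a, cfg$scrna$b)
    prof <- lapply(cfg$scrna, function(d) {
      z <- zscore_genes(lognormalize(d))
      bootstrap_cluster_profiles(z, d$meta$cluster, panel,
                                 n_boot = cfg$n_boot, seed = cfg$seed)
    })
    alignment <- align_clusters(prof$a, prof$b)
    readr::write_tsv(alignment$pairs, p("cat_alignment.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("atacdyn")),
    seed = cfg$seed,
    thresholds = cfg[c("lfc_threshold", "padj_threshold", "k", "fuzzifier_m",
                       "tss_pad", "windows", "de_base_mean_min",
                       "de_lfc_min", "de_padj_max", "n_boot")],
    stage_order = cfg$stage_order,
    groups = sort(unique(cls_tbl$group)),
    n_dynamic = sum(dyn$is_dynamic),
    input_md5 = as.list(tools::md5sum(unlist(
      cfg[c("atlas_bed", "counts_tsv", "samples_tsv", "genes_tsv", "de_tsv")]
    )))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dynamics = dyn, classification = cl, pairwise = pairwise,
                 links = link_tbl, enrichment = enrichment,
                 alignment = alignment, manifest = manifest))
}
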