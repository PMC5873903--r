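# End-to-end pipeline runner: one YAML (or list) config drives
# design -> simulate -> decode -> annotate -> rarefy -> essentiality ->
# mgwa -> enrich -> loads, writing TSV outputs plus a machine-readable JSON
# report. One master seed determines every stage seed, so reruns are
# byte-identical.

default_config <- function() {
  list(
    master_seed = 1L,
    out_dir = "tnpool_run",
    stages = c("design", "simulate", "decode", "annotate", "rarefy",
               "essentiality", "mgwa", "enrich", "loads"),
    design = list(n_plates = 10L, n_pools = 24L, weights = c(10L, 12L, 14L),
                  subset_free = FALSE, min_distance = 0L),
    simulate = list(n_genes = 300L, genome_length = 300000L,
                    n_pathways = 8L, pathway_size = 20L,
                    n_mutants = 900L, n_essential = 60L,
                    intergenic_fraction = 0.134, sister_clone_rate = 0.05,
                    mean_depth = 200, dispersion = 0.3, dropout_p = 0.02,
                    noise_mean = 0.5, spurious_site_rate = 0.1,
                    n_strains = 41L, n_ogs = 60L, effect_og_size = 2,
                    n_effect_ogs = 4L,
                    treatments = c("WT", "lpxB", "lpxC", "gmhD", "lpxK"),
                    deltas = c(lpxB = -2, lpxC = -2)),
    decode = list(threshold = 50),
    rarefy = list(n_permutations = 100L),
    essentiality = list(B = 2000L, min_count = 4L),
    mgwa = list(cutoff = 0.001, use_corrected = FALSE),
    enrich = list(B = 2000L, min_count = 4L),
    loads = list(control = "WT", alpha = 0.05)
  )
}

# deep-merge user config over defaults
merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a pipeline config from YAML
#' @param path YAML file; keys override the defaults of [run_pipeline()]
#' @return config list
#' @export
read_run_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

# stage seeds derived from one master seed (kept far below 2^31)
stage_seed <- function(master, offset) as.integer(master %% 2000000L * 1000L + offset)

#' Run the full synthetic pipeline from one config
#'
#' Executes the enabled stages in dependency order: build the pooling
#' design, simulate the annotation/library/pooled reads/strain panel/load
#' table, decode the reads, assign insertions to genes, rarefy, test
#' pathway essentiality, run the association scan, test top-hit enrichment,
#' and compare mutant loads. All tabular outputs are written as TSV under
#' `out_dir`, together with `report.json`.
#'
#' @param config a config list (see `tnpool:::default_config()` for the full
#'   set of keys), or a path to a YAML file
#' @return the run report (named list of per-stage counts), invisibly;
#'   classed `pipeline_report` with a print method
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- merge_config(default_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  on <- function(s) s %in% config$stages
  ms <- config$master_seed
  report <- list(master_seed = ms)
  t0 <- Sys.time()
  banner <- function(stage) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), stage))
  }

  design <- annotation <- library <- counts <- decoded <- hits <- NULL
  panel <- loadtab <- mgwa <- NULL

  if (on("design")) {
    banner("design")
    dc <- config$design
    design <- build_design(n_plates = dc$n_plates, n_pools = dc$n_pools,
                           weights = dc$weights,
                           subset_free = isTRUE(dc$subset_free),
                           min_distance = dc$min_distance,
                           seed = stage_seed(ms, 1L))
    write_design_tsv(design, out("design.tsv"))
    report$design <- list(wells = nrow(design$assignments),
                          plates = dc$n_plates, n_pools = dc$n_pools)
  }

  if (on("simulate")) {
    banner("simulate")
    sc <- config$simulate
    pathway_sizes <- stats::setNames(
      as.list(rep(sc$pathway_size, sc$n_pathways)),
      sprintf("ko%05d", seq_len(sc$n_pathways)))
    annotation <- gen_annotation(sc$n_genes, sc$genome_length,
                                 pathway_sizes = pathway_sizes,
                                 seed = stage_seed(ms, 2L))
    essential <- utils::head(annotation$genes$gene_id, sc$n_essential)
    library <- gen_library(annotation, n_mutants = sc$n_mutants,
                           essential_genes = essential,
                           intergenic_fraction = sc$intergenic_fraction,
                           sister_clone_rate = sc$sister_clone_rate,
                           seed = stage_seed(ms, 3L))
    if (is.null(design)) stop("simulate stage needs the design stage",
                              call. = FALSE)
    counts <- gen_pool_reads(library, design, mean_depth = sc$mean_depth,
                             dispersion = sc$dispersion,
                             dropout_p = sc$dropout_p,
                             noise_mean = sc$noise_mean,
                             spurious_site_rate = sc$spurious_site_rate,
                             seed = stage_seed(ms, 4L))
    effect_ogs <- stats::setNames(
      rep(sc$effect_og_size, sc$n_effect_ogs),
      sprintf("OG_%04d", seq_len(sc$n_effect_ogs)))
    panel <- gen_strain_panel(n_strains = sc$n_strains, n_ogs = sc$n_ogs,
                              effect_ogs = effect_ogs,
                              seed = stage_seed(ms, 5L))
    loadtab <- gen_load_table(sc$treatments,
                              true_deltas = unlist(sc$deltas),
                              control = config$loads$control,
                              seed = stage_seed(ms, 6L))
    write_annotation_tsv(annotation, out("annotation_genes.tsv"),
                         out("annotation_pathways.tsv"))
    write_annotation_gff3(annotation, out("annotation.gff3"))
    write_library_tsv(library, out("library_truth.tsv"))
    write_counts_tsv(counts, out("pool_counts.tsv"))
    write_presence_tsv(panel, out("og_presence.tsv"))
    write_phenotypes_tsv(panel, out("phenotypes.tsv"))
    write_load_tsv(loadtab, out("loads.tsv"))
    report$simulate <- list(
      genes = nrow(annotation$genes), mutants = nrow(library),
      sites = nrow(counts), sister_clones = sum(library$is_sister_clone),
      strains = sc$n_strains, ogs = sc$n_ogs)
  }

  if (on("decode")) {
    banner("decode")
    if (is.null(counts) || is.null(design)) {
      stop("decode stage needs counts and a design (enable design + simulate, or load inputs)",
           call. = FALSE)
    }
    decoded <- decode_library(counts, design,
                              threshold = config$decode$threshold)
    write_decoded_tsv(decoded, out("decoded.tsv"))
    hist <- pool_count_histogram(decoded)
    write_tsv_commented(data.frame(weight = names(hist), sites = hist),
                        out("pool_histogram.tsv"))
    report$decode <- c(list(sites = nrow(decoded$records),
                            mapped = decoded$mapped_count),
                       as.list(decoded$summary))
  }

  if (on("annotate")) {
    banner("annotate")
    if (is.null(decoded) || is.null(annotation)) {
      stop("annotate stage needs the decode and simulate stages", call. = FALSE)
    }
    hits <- assign_insertions(decoded, annotation)
    write_gene_hits_tsv(hits, out("gene_hits.tsv"))
    report$annotate <- hits$totals
  }

  if (on("rarefy")) {
    banner("rarefy")
    curve <- rarefaction(mutant_gene_sequence(hits),
                         n_permutations = config$rarefy$n_permutations,
                         seed = stage_seed(ms, 7L))
    write_tsv_commented(as.data.frame(curve), out("rarefaction.tsv"))
    report$rarefy <- list(mutants = nrow(curve),
                          genes_final = curve$genes[nrow(curve)])
  }

  if (on("essentiality")) {
    banner("essentiality")
    zero <- zero_insertion_genes(hits, annotation)
    ess <- pathway_essentiality_enrichment(
      zero, annotation, B = config$essentiality$B,
      min_count = config$essentiality$min_count, seed = stage_seed(ms, 8L))
    write_enrichment_tsv(ess, out("essentiality.tsv"))
    report$essentiality <- list(zero_insertion_genes = length(zero),
                                pathways_tested = nrow(ess))
  }

  if (on("mgwa")) {
    banner("mgwa")
    mgwa <- run_mgwa(panel, cutoff = config$mgwa$cutoff,
                     use_corrected = isTRUE(config$mgwa$use_corrected))
    write_mgwa_tsv(mgwa, out("mgwa.tsv"))
    report$mgwa <- list(ogs = nrow(mgwa$results), tested = mgwa$m_tested,
                        top_hits = length(mgwa$top_ogs))
  }

  if (on("enrich")) {
    banner("enrich")
    # OG pathway labels in contiguous blocks of 4 pathways, so the simulated
    # effect OGs (the first OG ids) share a pathway and enrichment is visible
    ogs <- colnames(panel$og_presence)
    og_pathways <- data.frame(
      og = ogs,
      pathway = sprintf("ko%05d", (seq_along(ogs) - 1L) %/%
                          ceiling(length(ogs) / 4) + 1L),
      stringsAsFactors = FALSE)
    enr <- top_hit_enrichment(mgwa$top_ogs, og_pathways,
                              reference_ogs = ogs,
                              B = config$enrich$B,
                              min_count = config$enrich$min_count,
                              seed = stage_seed(ms, 10L))
    write_enrichment_tsv(enr, out("top_hit_enrichment.tsv"))
    report$enrich <- list(pathways_tested = nrow(enr))
  }

  if (on("loads")) {
    banner("loads")
    cmp <- compare_loads(loadtab, control = config$loads$control,
                         alpha = config$loads$alpha)
    write_tsv_commented(as.data.frame(cmp), out("load_comparison.tsv"),
                        params = list(control = attr(cmp, "control")))
    report$loads <- list(treatments = nrow(cmp),
                         significant = sum(cmp$significant, na.rm = TRUE))
  }

  report$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")), 2)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA)
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (master seed", x$master_seed, ")\n")
  for (stage in setdiff(names(x), c("master_seed", "elapsed_sec"))) {
    vals <- unlist(x[[stage]])
    cat(sprintf("  %-12s %s\n", stage,
                paste(names(vals), vals, sep = "=", collapse = ", ")))
  }
  cat("  elapsed:", x$elapsed_sec, "s\n")
  invisible(x)
}
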