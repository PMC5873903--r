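# Shared fixture builders: everything is generated in code, no stored data.

# hand-built annotation with known intervals
make_annotation <- function(genes, pathways = NULL, genome_length = NULL) {
  if (is.null(pathways)) {
    pathways <- data.frame(gene_id = character(0), pathway = character(0),
                           stringsAsFactors = FALSE)
  }
  if (is.null(genome_length)) {
    genome_length <- tapply(genes$end, genes$contig, function(e) max(e) + 500L)
  }
  structure(list(genes = genes, pathways = pathways,
                 genome_length = genome_length),
            class = "genome_annotation")
}

# hand-built arrayed library (true_library-shaped data frame)
make_library <- function(plate, well, position, strand = "+",
                         contig = "contig_1", is_sister = FALSE,
                         sister_group = NA_character_) {
  n <- length(plate)
  structure(data.frame(
    mutant_id = sprintf("mut_%05d", seq_len(n)),
    plate = plate, well = well,
    well_label = tnpool:::well_label(well),
    contig = contig, position = position,
    strand = rep_len(strand, n),
    is_sister_clone = rep_len(is_sister, n),
    sister_group_id = rep_len(sister_group, n),
    stringsAsFactors = FALSE
  ), class = c("true_library", "data.frame"))
}

# small end-to-end fixture: design + annotation + library + noiseless reads
noiseless_fixture <- function(n_plates = 2L, n_genes = 60L,
                              genome_length = 80000L, n_mutants = 150L,
                              sister_clone_rate = 0, seed = 101L) {
  design <- build_design(n_plates = n_plates, seed = seed)
  annotation <- gen_annotation(n_genes, genome_length,
                               pathway_sizes = list(koA = 8L, koB = 12L),
                               seed = seed + 1L)
  library <- gen_library(annotation, n_mutants = n_mutants,
                         sister_clone_rate = sister_clone_rate,
                         seed = seed + 2L)
  counts <- gen_pool_reads(library, design, exact_depth = TRUE,
                           seed = seed + 3L)
  list(design = design, annotation = annotation, library = library,
       counts = counts)
}

site_keys_of <- function(library) {
  paste(library$contig, library$position, library$strand, sep = ":")
}
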