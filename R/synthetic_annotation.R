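# Synthetic genome annotation: non-overlapping gene intervals on a single
# contig with KEGG-style pathway labels. Emulates a RAST-like gene call
# table; coordinates are 1-based and inclusive at both ends.

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping gene intervals along a contig, with gene
#' lengths drawn uniformly from `gene_length_range` and the leftover space
#' distributed randomly as intergenic gaps. Pathway labels are assigned to
#' genes sampled without replacement within each pathway; a gene may belong
#' to several pathways.
#'
#' @param n_genes number of genes
#' @param genome_length contig length in bp
#' @param pathway_sizes named integer vector/list: pathway id -> number of
#'   member genes
#' @param gene_length_range min/max gene length in bp
#' @param contig contig name
#' @param seed RNG seed
#' @return object of class `genome_annotation`: `genes` data frame (gene_id,
#'   contig, start, end, strand), `pathways` long data frame (gene_id,
#'   pathway), `genome_length` named vector (bp per contig)
#' @export
gen_annotation <- function(n_genes, genome_length,
                           pathway_sizes = list(),
                           gene_length_range = c(300L, 1500L),
                           contig = "contig_1", seed = 1L) {
  set.seed(seed)
  n_genes <- as.integer(n_genes)
  if (n_genes == 0L) {
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    return(structure(list(
      genes = genes,
      pathways = data.frame(gene_id = character(0), pathway = character(0),
                            stringsAsFactors = FALSE),
      genome_length = stats::setNames(as.integer(genome_length), contig)),
      class = "genome_annotation"))
  }
  lens <- sample(gene_length_range[1L]:gene_length_range[2L], n_genes,
                 replace = TRUE)
  if (sum(lens) > genome_length) {
    stop(sprintf(
      "sizing error: %d genes need %d bp but genome_length is %d",
      n_genes, sum(lens), as.integer(genome_length)), call. = FALSE)
  }
  # distribute leftover bp as random gaps before/between/after genes
  leftover <- genome_length - sum(lens)
  cuts <- sort(sample.int(leftover + 1L, n_genes, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts))  # gap before each gene; remainder trails
  start <- cumsum(gaps) + cumsum(c(0L, lens[-n_genes])) + 1L
  end <- start + lens - 1L

  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  genes <- data.frame(
    gene_id = gene_id, contig = contig,
    start = as.integer(start), end = as.integer(end),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  pw <- lapply(names(pathway_sizes), function(p) {
    k <- as.integer(pathway_sizes[[p]])
    if (k > n_genes) {
      stop(sprintf("sizing error: pathway %s wants %d genes of %d", p, k,
                   n_genes), call. = FALSE)
    }
    data.frame(gene_id = sample(gene_id, k), pathway = p,
               stringsAsFactors = FALSE)
  })
  pathways <- if (length(pw)) do.call(rbind, pw) else
    data.frame(gene_id = character(0), pathway = character(0),
               stringsAsFactors = FALSE)
  rownames(pathways) <- NULL

  structure(list(genes = genes, pathways = pathways,
                 genome_length = stats::setNames(as.integer(genome_length),
                                                 contig)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("Genome annotation: %d genes on %d contig(s) (%s bp), %d pathway labels\n",
              nrow(x$genes), length(x$genome_length),
              format(sum(x$genome_length), big.mark = ","),
              length(unique(x$pathways$pathway))))
  invisible(x)
}

# GRanges view of the gene table (strand-agnostic uses ignore.strand later)
annotation_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    gene_id = g$gene_id,
    seqlengths = annotation$genome_length
  )
}

#' Write an annotation as GFF3
#' @param annotation a `genome_annotation`
#' @param path output .gff3 file
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- annotation_granges(annotation)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation from GFF3
#' @param path .gff3 file with gene features carrying an ID or gene_id
#' @param pathways optional long data frame (gene_id, pathway) or path to a
#'   two-column TSV of pathway labels
#' @return a `genome_annotation`
#' @export
read_annotation_gff3 <- function(path, pathways = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("gene", NA)]
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids)) ids <- S4Vectors::mcols(gr)$ID
  genes <- data.frame(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) {
    sl <- tapply(genes$end, genes$contig, max)
  }
  if (is.character(pathways)) pathways <- read_pathways_tsv(pathways)
  if (is.null(pathways)) {
    pathways <- data.frame(gene_id = character(0), pathway = character(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, pathways = pathways,
                 genome_length = sl),
            class = "genome_annotation")
}

#' Write annotation gene and pathway tables as TSV
#' @param annotation a `genome_annotation`
#' @param genes_path TSV for the gene table
#' @param pathways_path optional TSV for the (gene_id, pathway) labels
#' @export
write_annotation_tsv <- function(annotation, genes_path,
                                 pathways_path = NULL) {
  write_tsv_commented(annotation$genes, genes_path,
                      params = list(genome_length =
                                      paste(names(annotation$genome_length),
                                            annotation$genome_length,
                                            sep = "=", collapse = ",")))
  if (!is.null(pathways_path)) {
    write_tsv_commented(annotation$pathways, pathways_path)
  }
  invisible(genes_path)
}

#' Read annotation gene table (and optional pathway labels) from TSV
#' @param genes_path TSV with gene_id, contig, start, end, strand
#' @param pathways_path optional TSV with gene_id, pathway
#' @param genome_length named bp per contig; defaults to max gene end per contig
#' @return a `genome_annotation`
#' @export
read_annotation_tsv <- function(genes_path, pathways_path = NULL,
                                genome_length = NULL) {
  genes <- utils::read.delim(genes_path, comment.char = "#",
                             stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "contig", "start", "end") %in% names(genes)))
  pathways <- if (!is.null(pathways_path)) read_pathways_tsv(pathways_path)
  else data.frame(gene_id = character(0), pathway = character(0),
                  stringsAsFactors = FALSE)
  if (is.null(genome_length)) {
    genome_length <- tapply(genes$end, genes$contig, max)
  }
  structure(list(genes = genes, pathways = pathways,
                 genome_length = genome_length),
            class = "genome_annotation")
}

read_pathways_tsv <- function(path) {
  p <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "pathway") %in% names(p)))
  p[, c("gene_id", "pathway")]
}
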