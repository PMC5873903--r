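# Gene-level interpretation of a decoded library: which genes carry
# insertions, how saturated the library is (rarefaction), and which genes
# were never hit (candidate essential genes).

parse_site_keys <- function(site) {
  parts <- strsplit(site, ":", fixed = TRUE)
  data.frame(
    contig = vapply(parts, `[`, character(1), 1L),
    position = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Assign mapped insertions to genes
#'
#' Considers MAPPED sites only. A site at 1-based position p lies inside
#' gene g iff `start_g <= p <= end_g` on the same contig, regardless of
#' strand. A site inside several overlapping genes increments each gene's
#' insertion count but counts once toward `mutants_in_orfs`; sites inside no
#' gene are intergenic.
#'
#' @param decoded a `decoded_library`
#' @param annotation a `genome_annotation`
#' @return object of class `gene_hit_table`: `genes` data frame (gene_id,
#'   n_insertions), `assignments` data frame (site, gene_id; NA gene_id =
#'   intergenic, one row per site x overlapping gene), `totals` list
#'   (genes_hit, genes_total, mutants_in_orfs, intergenic)
#' @export
assign_insertions <- function(decoded, annotation) {
  rec <- decoded$records[decoded$records$status == "MAPPED", , drop = FALSE]
  sites <- parse_site_keys(rec$site)
  unknown <- setdiff(unique(sites$contig), names(annotation$genome_length))
  if (length(unknown)) {
    stop("sites on unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  genes <- annotation$genes
  n_sites <- nrow(sites)

  if (n_sites > 0L && nrow(genes) > 0L) {
    site_gr <- GenomicRanges::GRanges(
      sites$contig, IRanges::IRanges(sites$position, width = 1L))
    gene_gr <- GenomicRanges::GRanges(
      genes$contig, IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
    hit_site <- S4Vectors::queryHits(ov)
    hit_gene <- S4Vectors::subjectHits(ov)
  } else {
    hit_site <- integer(0)
    hit_gene <- integer(0)
  }

  n_insertions <- tabulate(hit_gene, nbins = nrow(genes))
  genic <- unique(hit_site)
  intergenic_idx <- setdiff(seq_len(n_sites), genic)

  assignments <- rbind(
    if (length(hit_site)) data.frame(site = rec$site[hit_site],
                                     gene_id = genes$gene_id[hit_gene],
                                     stringsAsFactors = FALSE),
    if (length(intergenic_idx)) data.frame(site = rec$site[intergenic_idx],
                                           gene_id = NA_character_,
                                           stringsAsFactors = FALSE)
  )
  if (is.null(assignments)) {
    assignments <- data.frame(site = character(0), gene_id = character(0),
                              stringsAsFactors = FALSE)
  }
  structure(list(
    genes = data.frame(gene_id = genes$gene_id, n_insertions = n_insertions,
                       stringsAsFactors = FALSE),
    assignments = assignments,
    totals = list(genes_hit = sum(n_insertions > 0L),
                  genes_total = nrow(genes),
                  mutants_in_orfs = length(genic),
                  intergenic = length(intergenic_idx))),
    class = "gene_hit_table")
}

#' @export
print.gene_hit_table <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Gene hit table: %d/%d genes hit; %d insertions in ORFs, %d intergenic\n",
              t$genes_hit, t$genes_total, t$mutants_in_orfs, t$intergenic))
  invisible(x)
}

#' Per-mutant gene id sequence for rarefaction
#'
#' One entry per mapped insertion site: the id of the gene it falls in, or
#' NA for intergenic sites. Sites spanning overlapping genes contribute
#' their first overlapping gene.
#'
#' @param hits a `gene_hit_table`
#' @return character vector (NA = intergenic)
#' @export
mutant_gene_sequence <- function(hits) {
  a <- hits$assignments
  a$gene_id[!duplicated(a$site)]
}

#' Rarefaction curve of genes hit as mutants accumulate
#'
#' Mean cumulative number of distinct genes carrying an insertion after k
#' mutants, averaged over random orderings of the mutant list. Intergenic
#' mutants (NA entries) occupy draws but add no genes.
#'
#' @param gene_hits character vector of per-mutant gene ids (NA = intergenic)
#' @param n_permutations random orderings to average over (default 100)
#' @param seed RNG seed
#' @return data frame (n_mutants, genes) of class `rarefaction_curve`
#' @export
rarefaction <- function(gene_hits, n_permutations = 100L, seed = 1L) {
  stopifnot(n_permutations >= 1L)
  set.seed(seed)
  n <- length(gene_hits)
  acc <- numeric(n)
  for (b in seq_len(n_permutations)) {
    perm <- gene_hits[sample.int(n)]
    new_gene <- !duplicated(perm, incomparables = NA) & !is.na(perm)
    acc <- acc + cumsum(new_gene)
  }
  structure(data.frame(n_mutants = seq_len(n), genes = acc / n_permutations),
            class = c("rarefaction_curve", "data.frame"))
}

#' Expected rarefaction curve in closed form
#'
#' Hypergeometric expectation of the number of distinct genes among k
#' mutants drawn without replacement:
#' `E[distinct at k] = sum_g (1 - choose(N - m_g, k) / choose(N, k))` with
#' m_g insertions in gene g out of N mutants. Used as the analytic
#' counterpart of [rarefaction()].
#'
#' @param gene_hits character vector of per-mutant gene ids (NA = intergenic)
#' @return data frame (n_mutants, genes)
#' @export
rarefaction_expected <- function(gene_hits) {
  n <- length(gene_hits)
  m <- table(gene_hits[!is.na(gene_hits)])
  k <- seq_len(n)
  genes <- vapply(k, function(kk) {
    # lchoose handles N - m_g < kk (term = 1) via -Inf
    sum(1 - exp(lchoose(n - m, kk) - lchoose(n, kk)))
  }, numeric(1))
  data.frame(n_mutants = k, genes = genes)
}

#' Plot a rarefaction curve
#' @param x a `rarefaction_curve`
#' @param ... passed to [plot()]
#' @export
plot.rarefaction_curve <- function(x, ...) {
  plot(x$n_mutants, x$genes, type = "l",
       xlab = "mutants sampled", ylab = "distinct genes with insertions", ...)
  invisible(x)
}

#' Genes with no recovered insertions
#'
#' Complement of the hit genes within the annotation; with a near-saturated
#' library these are candidates for essentiality (or polar proximity to an
#' essential gene).
#'
#' @param hits a `gene_hit_table`
#' @param annotation a `genome_annotation`
#' @return character vector of gene ids
#' @export
zero_insertion_genes <- function(hits, annotation) {
  hit <- hits$genes$gene_id[hits$genes$n_insertions > 0L]
  setdiff(annotation$genes$gene_id, hit)
}

#' Write the gene hit table as TSV
#' @param hits a `gene_hit_table`
#' @param path output file
#' @export
write_gene_hits_tsv <- function(hits, path) {
  write_tsv_commented(hits$genes, path, params = hits$totals)
}
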