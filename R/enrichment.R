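# Pathway enrichment by Monte-Carlo chi-square on 2x2 tables with fixed
# margins. Used twice in the pipeline: (i) are zero-insertion genes over- or
# under-represented in a pathway (essentiality prediction), and (ii) are top
# association hits enriched in a pathway. Both reduce to the same table
#   [[a, n_path - a], [A - a, (G - n_path) - (A - a)]]
# where a = pathway members in the focal set, n_path = pathway size,
# A = focal-set size, G = universe size.

#' Pearson chi-square statistic of a contingency table
#'
#' Plain `sum((O - E)^2 / E)` without continuity correction.
#' @param tab integer matrix
#' @return the statistic (NA when a margin is zero)
#' @export
pearson_chisq <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) return(NA_real_)
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

#' Monte-Carlo chi-square test with fixed margins
#'
#' Resamples `B` tables with the observed margins (via [stats::r2dtable()]),
#' and reports `p = (k + 1) / (B + 1)` where k is the number of resampled
#' tables whose Pearson statistic is at least the observed one. The smallest
#' attainable p is therefore `1 / (B + 1)` (0.0005 at the default B = 2000,
#' to four decimals).
#'
#' @param tab 2x2 (or r x c) integer contingency table
#' @param B number of resamples (default 2000)
#' @param seed optional RNG seed; NULL leaves the RNG state alone
#' @return list with `statistic`, `p`, `B`
#' @export
mc_chisq_test <- function(tab, B = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- pearson_chisq(tab)
  if (is.na(obs)) {
    return(list(statistic = NA_real_, p = NA_real_, B = as.integer(B)))
  }
  sims <- stats::r2dtable(B, rowSums(tab), colSums(tab))
  stat <- vapply(sims, pearson_chisq, numeric(1))
  k <- sum(stat >= obs - sqrt(.Machine$double.eps))
  list(statistic = obs, p = (k + 1) / (B + 1), B = as.integer(B))
}

#' Pathway enrichment over a set of 2x2 tables
#'
#' The workhorse behind [pathway_essentiality_enrichment()] and
#' [top_hit_enrichment()]; it can also be fed literal published counts. For
#' each pathway it tests the 2x2 table of focal-set membership against
#' pathway membership by Monte-Carlo chi-square, adjusts p-values by
#' Benjamini-Hochberg across the tested pathways, and calls a direction:
#' the first label when the focal fraction inside the pathway exceeds the
#' background focal fraction `A / G`, the second otherwise.
#'
#' @param counts data frame with columns `pathway`, `focal` (pathway members
#'   in the focal set, a), `total` (pathway size, n_path)
#' @param A focal-set size
#' @param G universe size
#' @param B Monte-Carlo resamples (default 2000)
#' @param min_count_total exclude pathways with `total` below this (NULL = no
#'   filter)
#' @param min_count_focal exclude pathways with `focal` below this (NULL = no
#'   filter)
#' @param direction_labels length-2 character: labels when the focal fraction
#'   is above / not above background
#' @param seed RNG seed
#' @return data frame of class `enrichment_result`: pathway, focal, total,
#'   statistic, p, fdr, direction, ordered by p
#' @export
pathway_enrichment <- function(counts, A, G, B = 2000L,
                               min_count_total = 4L, min_count_focal = NULL,
                               direction_labels = c("enriched", "depleted"),
                               seed = 1L) {
  stopifnot(all(c("pathway", "focal", "total") %in% names(counts)),
            all(counts$focal <= counts$total), A <= G,
            all(counts$total <= G), all(counts$focal <= A))
  set.seed(seed)
  keep <- rep(TRUE, nrow(counts))
  if (!is.null(min_count_total)) keep <- keep & counts$total >= min_count_total
  if (!is.null(min_count_focal)) keep <- keep & counts$focal >= min_count_focal
  degenerate <- counts$total == 0L | counts$total == G
  if (any(degenerate & keep)) {
    warning(sprintf("%d pathway(s) with degenerate margins excluded",
                    sum(degenerate & keep)), call. = FALSE)
    keep <- keep & !degenerate
  }
  counts <- counts[keep, , drop = FALSE]

  res <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$focal[i]
    np <- counts$total[i]
    tab <- matrix(c(a, A - a, np - a, (G - np) - (A - a)), nrow = 2L)
    mc <- mc_chisq_test(tab, B = B)
    data.frame(pathway = counts$pathway[i], focal = a, total = np,
               statistic = mc$statistic, p = mc$p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pathway = character(0), focal = integer(0), total = integer(0),
               statistic = numeric(0), p = numeric(0),
               stringsAsFactors = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$focal / out$total > A / G,
                          direction_labels[1L], direction_labels[2L])
  out <- out[order(out$p, -out$statistic), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "A") <- A
  attr(out, "G") <- G
  attr(out, "B") <- as.integer(B)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, digits = 4, ...) {
  cat(sprintf("Pathway enrichment: %d pathways tested (focal %d of %d, B = %d)\n",
              nrow(x), attr(x, "A"), attr(x, "G"), attr(x, "B")))
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 2)
  df$p <- round(df$p, digits)
  df$fdr <- round(df$fdr, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pathway-level essentiality prediction
#'
#' Tests, per pathway, whether genes without any transposon insertion are
#' over-represented ("essential": disruptions were never recovered) or
#' under-represented ("nonessential") relative to the gene universe.
#' Pathways smaller than `min_count` genes are excluded before testing.
#'
#' @param zero_set character vector of zero-insertion gene ids
#' @param annotation a `genome_annotation` with pathway labels
#' @param B Monte-Carlo resamples (default 2000)
#' @param min_count minimum pathway size to test (default 4)
#' @param seed RNG seed
#' @return an `enrichment_result` with directions essential/nonessential
#' @export
pathway_essentiality_enrichment <- function(zero_set, annotation, B = 2000L,
                                            min_count = 4L, seed = 1L) {
  pw <- annotation$pathways
  if (nrow(pw) == 0L) stop("annotation carries no pathway labels", call. = FALSE)
  G <- nrow(annotation$genes)
  zero_set <- intersect(zero_set, annotation$genes$gene_id)
  A <- length(zero_set)
  per <- split(pw$gene_id, pw$pathway)
  counts <- data.frame(
    pathway = names(per),
    focal = vapply(per, function(g) sum(unique(g) %in% zero_set), integer(1)),
    total = vapply(per, function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE
  )
  pathway_enrichment(counts, A = A, G = G, B = B,
                     min_count_total = min_count, min_count_focal = NULL,
                     direction_labels = c("essential", "nonessential"),
                     seed = seed)
}

#' Pathway enrichment among top association hits
#'
#' Tests, per pathway, whether OGs in the top association set are enriched
#' relative to the full reference set of OGs. Following the published
#' filter, pathways need at least `min_count` members in both the top set
#' and the reference set to be tested.
#'
#' @param top_ogs character vector of top-hit OG ids
#' @param og_pathways long data frame (og, pathway) labelling the reference
#'   OGs (OGs may carry several labels; unlabelled OGs still count in G)
#' @param reference_ogs character vector of all OG ids (the universe);
#'   defaults to the OGs appearing in `og_pathways`
#' @param B Monte-Carlo resamples (default 2000)
#' @param min_count minimum pathway count in both sets (default 4)
#' @param seed RNG seed
#' @return an `enrichment_result` with directions enriched/depleted
#' @export
top_hit_enrichment <- function(top_ogs, og_pathways,
                               reference_ogs = unique(og_pathways$og),
                               B = 2000L, min_count = 4L, seed = 1L) {
  stopifnot(all(c("og", "pathway") %in% names(og_pathways)))
  if (!all(top_ogs %in% reference_ogs)) {
    stop("top_ogs must be a subset of reference_ogs", call. = FALSE)
  }
  G <- length(unique(reference_ogs))
  A <- length(unique(top_ogs))
  pw <- og_pathways[og_pathways$og %in% reference_ogs, , drop = FALSE]
  per <- split(pw$og, pw$pathway)
  counts <- data.frame(
    pathway = names(per),
    focal = vapply(per, function(g) sum(unique(g) %in% top_ogs), integer(1)),
    total = vapply(per, function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE
  )
  pathway_enrichment(counts, A = A, G = G, B = B,
                     min_count_total = min_count, min_count_focal = min_count,
                     direction_labels = c("enriched", "depleted"),
                     seed = seed)
}

#' Write an enrichment table as TSV
#' @param enrichment an `enrichment_result`
#' @param path output file
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  write_tsv_commented(as.data.frame(enrichment), path,
                      params = list(A = attr(enrichment, "A"),
                                    G = attr(enrichment, "G"),
                                    B = attr(enrichment, "B")))
}
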