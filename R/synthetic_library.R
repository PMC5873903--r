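# Synthetic arrayed transposon library and pooled read counts with known
# ground truth: true well assignments, sister clones, per-pool depths with
# dropout, index-bleed noise, and spurious low-pool-count sites.

#' Generate a synthetic arrayed transposon insertion library
#'
#' Draws one insertion site per mutant and arrays the mutants plate-by-plate
#' (96 wells per plate, row-major A1..H12). Insertions never fall inside a
#' designated essential gene. With probability `sister_clone_rate` a mutant
#' is a sister clone: it re-uses the insertion site of a uniformly chosen
#' earlier mutant but occupies its own well.
#'
#' @param annotation a `genome_annotation`
#' @param n_mutants number of arrayed mutants
#' @param essential_genes character vector of gene ids that cannot be hit
#' @param intergenic_fraction probability an insertion is intergenic
#' @param sister_clone_rate probability a mutant duplicates an earlier site
#' @param wells_per_plate wells per plate (default 96)
#' @param seed RNG seed
#' @return object of class `true_library`: data frame with mutant_id, plate,
#'   well, well_label, contig, position, strand, is_sister_clone,
#'   sister_group_id
#' @export
gen_library <- function(annotation, n_mutants,
                        essential_genes = character(0),
                        intergenic_fraction = 0.134,
                        sister_clone_rate = 0.05,
                        wells_per_plate = 96L, seed = 1L) {
  stopifnot(intergenic_fraction >= 0, intergenic_fraction <= 1,
            sister_clone_rate >= 0, sister_clone_rate <= 1)
  if (!all(essential_genes %in% annotation$genes$gene_id)) {
    stop("essential_genes must be a subset of annotation gene ids",
         call. = FALSE)
  }
  set.seed(seed)
  n_mutants <- as.integer(n_mutants)
  contig <- names(annotation$genome_length)[1L]
  glen <- annotation$genome_length[[1L]]

  genes <- annotation$genes
  target <- genes[!(genes$gene_id %in% essential_genes), , drop = FALSE]
  gene_bp <- sum(target$end - target$start + 1L)

  # intergenic space = complement of all gene intervals (essential included)
  gr <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  inter <- IRanges::gaps(gr, start = 1L, end = glen)
  inter_bp <- sum(IRanges::width(inter))

  if (intergenic_fraction < 1 && gene_bp == 0L) {
    stop("sizing error: no nonessential gene space to place genic insertions",
         call. = FALSE)
  }
  if (intergenic_fraction > 0 && inter_bp == 0L) {
    stop("sizing error: no intergenic space available", call. = FALSE)
  }
  avail <- inter_bp * (intergenic_fraction > 0) +
    gene_bp * (intergenic_fraction < 1)
  if (n_mutants > avail) {
    stop(sprintf(
      "sizing error: %d mutants requested but only %d target bp available",
      n_mutants, avail), call. = FALSE)
  }

  inter_starts <- IRanges::start(inter)
  inter_w <- IRanges::width(inter)
  gene_w <- target$end - target$start + 1L

  draw_site <- function() {
    if (stats::runif(1L) < intergenic_fraction) {
      i <- sample.int(length(inter_w), 1L, prob = inter_w)
      inter_starts[i] + sample.int(inter_w[i], 1L) - 1L
    } else {
      i <- sample.int(nrow(target), 1L, prob = gene_w)
      target$start[i] + sample.int(gene_w[i], 1L) - 1L
    }
  }

  position <- integer(n_mutants)
  strand <- character(n_mutants)
  is_sister <- logical(n_mutants)
  group <- rep(NA_integer_, n_mutants)
  seen <- new.env(parent = emptyenv())
  for (m in seq_len(n_mutants)) {
    if (m > 1L && stats::runif(1L) < sister_clone_rate) {
      src <- sample.int(m - 1L, 1L)
      position[m] <- position[src]
      strand[m] <- strand[src]  # sisters share the full insertion site
      is_sister[m] <- TRUE
      if (is.na(group[src])) group[src] <- src
      group[m] <- group[src]
      is_sister[src] <- TRUE
    } else {
      repeat {
        p <- draw_site()
        key <- as.character(p)
        if (is.null(seen[[key]])) {
          seen[[key]] <- m
          break
        }
      }
      position[m] <- p
      strand[m] <- sample(c("+", "-"), 1L)
    }
  }

  idx <- seq_len(n_mutants) - 1L
  structure(data.frame(
    mutant_id = sprintf("mut_%05d", seq_len(n_mutants)),
    plate = idx %/% wells_per_plate + 1L,
    well = idx %% wells_per_plate,
    well_label = well_label(idx %% wells_per_plate),
    contig = contig,
    position = position,
    strand = strand,
    is_sister_clone = is_sister,
    sister_group_id = ifelse(is.na(group), NA_character_,
                             sprintf("sis_%05d", group)),
    stringsAsFactors = FALSE
  ), class = c("true_library", "data.frame"))
}

site_key <- function(contig, position, strand) {
  paste(contig, position, strand, sep = ":")
}

#' Simulate pooled sequencing read counts for an arrayed library
#'
#' Each unique insertion site receives reads in the pools named by the
#' codeword(s) of the well(s) that carry it: read depth per positive pool is
#' Negative-Binomial with mean `mean_depth` and dispersion `dispersion`
#' (variance mu + dispersion * mu^2), independently zeroed with probability
#' `dropout_p`. Sister clones occupying several wells contribute the sum of
#' their wells' pool patterns. Pools where a site is absent receive Poisson
#' index-bleed noise with mean `noise_mean`. Spurious sites (sequencing
#' artifacts) are added at `spurious_site_rate` per real site and appear in
#' 1-2 random pools each.
#'
#' @param library a `true_library`
#' @param design a `pooling_design` covering every (plate, well) used
#' @param mean_depth mean reads per positive site x pool cell
#' @param dispersion Negative-Binomial dispersion (0 gives Poisson-like;
#'   exactly 0 uses the mean deterministically only when `mean_depth` is
#'   integer -- use `exact_depth = TRUE` for noiseless counts)
#' @param dropout_p probability a truly positive pool yields zero reads
#' @param noise_mean Poisson mean for absent-pool noise (0 disables)
#' @param spurious_site_rate expected spurious sites per real site
#' @param exact_depth if TRUE, every positive pool gets exactly `mean_depth`
#'   reads (noiseless mode for round-trip checks)
#' @param seed RNG seed
#' @return object of class `read_count_matrix`: integer matrix sites x pools
#'   with rownames "contig:position:strand" and columns pool_01..pool_NN
#' @export
gen_pool_reads <- function(library, design, mean_depth = 200,
                           dispersion = 0.3, dropout_p = 0.02,
                           noise_mean = 0.5, spurious_site_rate = 0.1,
                           exact_depth = FALSE, seed = 1L) {
  set.seed(seed)
  a <- design$assignments
  key_lib <- paste(library$plate, library$well)
  key_des <- paste(a$plate, a$well)
  idx <- match(key_lib, key_des)
  if (anyNA(idx)) {
    stop("library wells missing from design: ",
         paste(utils::head(key_lib[is.na(idx)], 5L), collapse = "; "),
         call. = FALSE)
  }
  codes <- a$code[idx]
  n_pools <- design$n_pools

  skey <- site_key(library$contig, library$position, library$strand)
  groups <- split(seq_len(nrow(library)), skey)
  site_ids <- names(groups)

  draw_depth <- function(n) {
    if (exact_depth) rep(as.integer(round(mean_depth)), n)
    else if (dispersion > 0) {
      stats::rnbinom(n, mu = mean_depth, size = 1 / dispersion)
    } else stats::rpois(n, mean_depth)
  }

  counts <- matrix(0L, nrow = length(groups), ncol = n_pools)
  for (g in seq_along(groups)) {
    row <- numeric(n_pools)
    for (m in groups[[g]]) {
      pos_pools <- which(bitwAnd(codes[m], bitwShiftL(1L, 0:(n_pools - 1L))) != 0L)
      depth <- draw_depth(length(pos_pools))
      if (dropout_p > 0 && !exact_depth) {
        depth[stats::runif(length(depth)) < dropout_p] <- 0L
      }
      row[pos_pools] <- row[pos_pools] + depth
    }
    if (noise_mean > 0 && !exact_depth) {
      absent <- row == 0
      row[absent] <- row[absent] + stats::rpois(sum(absent), noise_mean)
    }
    counts[g, ] <- as.integer(row)
  }
  rownames(counts) <- site_ids

  if (spurious_site_rate > 0 && !exact_depth) {
    n_spur <- stats::rpois(1L, spurious_site_rate * length(groups))
    if (n_spur > 0L) {
      glen <- max(library$position) + 10000L
      spur <- matrix(0L, nrow = n_spur, ncol = n_pools)
      pos <- sample.int(glen, n_spur) + glen  # outside real coordinates
      for (s in seq_len(n_spur)) {
        k <- sample(1:2, 1L)
        spur[s, sample.int(n_pools, k)] <- draw_depth(k)
      }
      rownames(spur) <- site_key(library$contig[1L], pos,
                                 sample(c("+", "-"), n_spur, replace = TRUE))
      counts <- rbind(counts, spur)
    }
  }
  colnames(counts) <- sprintf("pool_%02d", seq_len(n_pools))
  structure(counts, class = c("read_count_matrix", class(counts)))
}

#' @export
print.read_count_matrix <- function(x, ...) {
  cat(sprintf("Pooled read counts: %d insertion sites x %d pools (total %s reads)\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Write a read-count matrix as TSV
#'
#' Rows are "contig:position:strand" site keys; columns pool_01..pool_NN.
#' @param counts a `read_count_matrix` (or plain integer matrix)
#' @param path output file
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(site = rownames(counts),
                   as.data.frame(unclass(counts), row.names = NULL),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
}

#' Read a read-count matrix from TSV
#' @param path file written by [write_counts_tsv()] or of the same layout
#' @return a `read_count_matrix`
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot("site" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "site"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$site
  structure(m, class = c("read_count_matrix", class(m)))
}

#' Write the ground-truth library table as TSV
#' @param library a `true_library`
#' @param path output file
#' @export
write_library_tsv <- function(library, path) {
  write_tsv_commented(as.data.frame(library), path)
}
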