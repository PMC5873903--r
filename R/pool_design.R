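# Combinatorial pooling designs: each (plate, well) receives one constant-
# weight binary codeword over n_pools sequencing pools. Because the allowed
# weights (by default 10, 12, 14) differ by two, losing or gaining signal in
# any single pool produces a weight outside the allowed set, so single-pool
# errors are always detectable at decode time.

#' Number of distinct codewords available under a weight constraint
#'
#' Sums the binomial coefficients choose(n_pools, w) over the allowed
#' weights; this is the number of wells a design can address before any
#' subset-freeness or distance filtering.
#'
#' @param n_pools code length (number of sequencing pools)
#' @param weights integer vector of allowed Hamming weights
#' @return total number of codewords (numeric, exact for n_pools <= 30)
#' @examples
#' capacity(24, c(10, 12, 14))
#' @export
capacity <- function(n_pools, weights) {
  weights <- as.integer(weights)
  if (any(weights < 0L | weights > n_pools)) {
    stop("all weights must lie in 0..n_pools", call. = FALSE)
  }
  if (anyDuplicated(weights)) stop("weights must be distinct", call. = FALSE)
  sum(choose(n_pools, weights))
}

# well index 0..95 (row-major A1..H12) -> label like "A1"
well_label <- function(well, wells_per_plate = 96L, n_cols = 12L) {
  row <- well %/% n_cols
  col <- well %% n_cols + 1L
  paste0(LETTERS[row + 1L], col)
}

# label like "A1" -> 0-based row-major well index
well_index <- function(label, n_cols = 12L) {
  row <- match(toupper(substr(label, 1L, 1L)), LETTERS) - 1L
  col <- as.integer(substring(label, 2L))
  row * n_cols + col - 1L
}

#' Construct a combinatorial pooling design
#'
#' Assigns one constant-weight codeword to every well of `n_plates` 96-well
#' plates. Codewords are drawn without replacement from each weight class by
#' seeded uniform sampling of colexicographic ranks, and the weight classes
#' are interleaved round-robin, so the design is deterministic given the
#' seed and the codewords are spread uniformly over the code space (naive
#' sequential enumeration would concentrate early codewords on the same
#' pools, making merged sister-clone signals collide with assigned
#' codewords). Optional greedy filters enforce subset-freeness (no assigned
#' codeword is a strict bitwise subset of another) and a minimum pairwise
#' Hamming distance.
#'
#' @param n_plates number of 96-well plates to address
#' @param wells_per_plate wells per plate (default 96)
#' @param n_pools code length (default 24)
#' @param weights allowed Hamming weights (default c(10, 12, 14))
#' @param subset_free if TRUE, reject codewords bitwise comparable to an
#'   already assigned one
#' @param min_distance minimum pairwise Hamming distance (0 disables the
#'   filter; distinct constant-weight words already differ by >= 2)
#' @param batch_size_plates plates pooled together per intermediate batch
#' @param seed RNG seed for the rank sampling; identical seeds give
#'   byte-identical designs
#' @return object of class `pooling_design` with an `assignments` data frame
#'   (plate, well, well_label, code, codeword)
#' @examples
#' d <- build_design(n_plates = 2)
#' summary(d)
#' @export
build_design <- function(n_plates, wells_per_plate = 96L, n_pools = 24L,
                         weights = c(10L, 12L, 14L), subset_free = FALSE,
                         min_distance = 0L, batch_size_plates = 5L,
                         seed = 1L) {
  weights <- sort(as.integer(weights))
  n_wells <- as.integer(n_plates) * as.integer(wells_per_plate)
  cap <- capacity(n_pools, weights)
  if (n_wells > cap) {
    stop(sprintf(
      "capacity error: %d wells requested but only %.0f codewords of weight {%s} over %d pools exist",
      n_wells, cap, paste(weights, collapse = ","), n_pools), call. = FALSE)
  }

  # per-weight-class streams: colex ranks in seeded random order, unranked
  # to codewords on demand
  set.seed(seed)
  caps <- choose(n_pools, weights)
  rank_perm <- lapply(caps, sample.int)
  ptr <- rep(1L, length(weights))

  draw <- function(i) {
    # returns next codeword of weight class i, or NA when exhausted
    if (ptr[i] > caps[i]) return(NA_integer_)
    r <- rank_perm[[i]][ptr[i]]
    ptr[i] <<- ptr[i] + 1L
    unrank_colex(r - 1, weights[i], n_pools)
  }

  accepted <- integer(n_wells)
  n_acc <- 0L
  filters_on <- isTRUE(subset_free) || min_distance > 2L
  i_class <- 0L
  exhausted <- 0L
  while (n_acc < n_wells) {
    i_class <- i_class %% length(weights) + 1L
    cand <- draw(i_class)
    if (is.na(cand)) {
      exhausted <- exhausted + 1L
      if (exhausted >= length(weights)) {
        constraint <- if (isTRUE(subset_free) && min_distance > 2L) {
          "subset_free + min_distance"
        } else if (isTRUE(subset_free)) "subset_free" else if (min_distance > 2L) {
          "min_distance"
        } else "capacity"
        stop(sprintf(
          "capacity error: code space exhausted after %d of %d wells (binding constraint: %s)",
          n_acc, n_wells, constraint), call. = FALSE)
      }
      next
    }
    exhausted <- 0L
    if (filters_on && n_acc > 0L) {
      acc <- accepted[seq_len(n_acc)]
      if (min_distance > 2L &&
          any(popcount(bitwXor(cand, acc)) < min_distance)) next
      if (isTRUE(subset_free)) {
        ints <- bitwAnd(cand, acc)
        if (any(ints == acc | ints == cand)) next
      }
    }
    n_acc <- n_acc + 1L
    accepted[n_acc] <- cand
  }

  plate <- rep(seq_len(n_plates), each = wells_per_plate)
  well <- rep(seq_len(wells_per_plate) - 1L, times = n_plates)
  assignments <- data.frame(
    plate = plate,
    well = well,
    well_label = well_label(well),
    code = accepted,
    codeword = codeword_to_string(accepted, n_pools),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_pools = as.integer(n_pools), weights = weights,
         wells_per_plate = as.integer(wells_per_plate),
         batch_size_plates = as.integer(batch_size_plates),
         subset_free = isTRUE(subset_free),
         min_distance = as.integer(min_distance),
         assignments = assignments),
    class = "pooling_design"
  )
}

#' @export
print.pooling_design <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("Combinatorial pooling design: %d wells on %d plates\n",
              n, max(x$assignments$plate)))
  cat(sprintf("  %d pools, allowed weights {%s}%s%s\n",
              x$n_pools, paste(x$weights, collapse = ","),
              if (x$subset_free) ", subset-free" else "",
              if (x$min_distance > 0L)
                sprintf(", min Hamming distance %d", x$min_distance) else ""))
  invisible(x)
}

#' @export
summary.pooling_design <- function(object, ...) {
  w <- popcount(object$assignments$code)
  print(object)
  cat("  weight distribution:\n")
  print(table(weight = w))
  invisible(object)
}

#' Look up the well assigned to a codeword
#'
#' Inverse of the design's assignment map; exact match only.
#'
#' @param design a `pooling_design`
#' @param codeword codeword as integer, 0/1 string, or 0/1 vector
#' @return one-row data frame (plate, well, well_label) or NULL if unassigned
#' @export
design_lookup <- function(design, codeword) {
  code <- normalize_codeword(codeword, design$n_pools)
  i <- match(code, design$assignments$code)
  if (is.na(i)) return(NULL)
  design$assignments[i, c("plate", "well", "well_label")]
}

normalize_codeword <- function(codeword, n_pools) {
  if (is.character(codeword)) {
    string_to_codeword(codeword)
  } else if (length(codeword) == n_pools && all(codeword %in% c(0L, 1L)) &&
             n_pools > 1L) {
    bits_to_codeword(codeword)
  } else {
    as.integer(codeword)
  }
}

#' Two-stage pooling plan for a design
#'
#' Plates are pooled in batches of `batch_size_plates` into intermediate
#' sets of `n_pools` tubes; a final set of pools is then made by merging all
#' intermediate tubes that share a pool position.
#'
#' @param design a `pooling_design`
#' @return object of class `batch_plan`: `batches` (data frame batch, plate),
#'   `instructions` (data frame batch, pool, plate, well, well_label: which
#'   wells to pipette into each intermediate pool), `final_merge` (data frame
#'   pool, batch: which intermediate tubes combine into each final pool)
#' @export
batch_plan <- function(design) {
  a <- design$assignments
  plates <- sort(unique(a$plate))
  bsize <- design$batch_size_plates
  batch_of <- setNames(ceiling(seq_along(plates) / bsize), plates)
  n_batches <- max(batch_of)

  bits <- codeword_to_bits(a$code, design$n_pools)
  idx <- which(bits == 1L, arr.ind = TRUE)
  instructions <- data.frame(
    batch = unname(batch_of[as.character(a$plate[idx[, 1L]])]),
    pool = idx[, 2L],
    plate = a$plate[idx[, 1L]],
    well = a$well[idx[, 1L]],
    well_label = a$well_label[idx[, 1L]],
    stringsAsFactors = FALSE
  )
  instructions <- instructions[order(instructions$batch, instructions$pool,
                                     instructions$plate, instructions$well), ]
  rownames(instructions) <- NULL
  final_merge <- expand.grid(pool = seq_len(design$n_pools),
                             batch = seq_len(n_batches))
  structure(
    list(batches = data.frame(batch = unname(batch_of), plate = plates),
         instructions = instructions,
         final_merge = final_merge,
         n_pools = design$n_pools),
    class = "batch_plan"
  )
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("Two-stage pooling plan: %d plates in %d batches, %d pools\n",
              nrow(x$batches), max(x$batches$batch), x$n_pools))
  cat(sprintf("  %d pipetting steps into intermediate pools\n",
              nrow(x$instructions)))
  invisible(x)
}

#' Validate a pooling design
#'
#' Report-only integrity check: duplicate codewords, weight violations,
#' bitwise subset pairs, and the minimum pairwise Hamming distance.
#'
#' @param design a `pooling_design`
#' @return list with `duplicates`, `weight_violations`, `subset_pairs`,
#'   `min_hamming_distance`, and logical `ok`
#' @export
validate_design <- function(design) {
  a <- design$assignments
  codes <- a$code
  dup <- a[duplicated(codes) | duplicated(codes, fromLast = TRUE), , drop = FALSE]
  w <- popcount(codes)
  wviol <- a[!(w %in% design$weights), , drop = FALSE]

  subset_pairs <- data.frame(i = integer(0), j = integer(0))
  min_d <- if (length(codes) > 1L) design$n_pools else NA_integer_
  if (length(codes) > 1L) {
    for (i in seq_len(length(codes) - 1L)) {
      rest <- codes[(i + 1L):length(codes)]
      d <- popcount(bitwXor(codes[i], rest))
      min_d <- min(min_d, min(d))
      ints <- bitwAnd(codes[i], rest)
      hit <- which(ints == codes[i] | ints == rest)
      if (length(hit)) {
        subset_pairs <- rbind(subset_pairs,
                              data.frame(i = i, j = i + hit))
      }
    }
  }
  list(
    duplicates = dup,
    weight_violations = wviol,
    subset_pairs = subset_pairs,
    min_hamming_distance = min_d,
    ok = nrow(dup) == 0L && nrow(wviol) == 0L
  )
}

#' Write a pooling design as TSV
#'
#' Columns: plate, well (A1-style label), codeword (0/1 string).
#' @param design a `pooling_design`
#' @param path output file
#' @export
write_design_tsv <- function(design, path) {
  a <- design$assignments
  out <- data.frame(plate = a$plate, well = a$well_label,
                    codeword = a$codeword, stringsAsFactors = FALSE)
  write_tsv_commented(out, path, params = list(
    n_pools = design$n_pools,
    weights = paste(design$weights, collapse = ","),
    batch_size_plates = design$batch_size_plates))
}

#' Read a pooling design from TSV
#' @param path file written by [write_design_tsv()] or of the same layout
#' @param n_pools code length; inferred from the codeword strings if NULL
#' @param weights allowed weights; inferred from the codewords if NULL
#' @param batch_size_plates plates per pooling batch
#' @return a `pooling_design`
#' @export
read_design_tsv <- function(path, n_pools = NULL, weights = NULL,
                            batch_size_plates = 5L) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = c(codeword = "character"))
  stopifnot(all(c("plate", "well", "codeword") %in% names(d)))
  if (is.null(n_pools)) n_pools <- nchar(d$codeword[1L])
  code <- string_to_codeword(d$codeword)
  if (is.null(weights)) weights <- sort(unique(popcount(code)))
  assignments <- data.frame(
    plate = as.integer(d$plate),
    well = well_index(d$well),
    well_label = d$well,
    code = code,
    codeword = d$codeword,
    stringsAsFactors = FALSE
  )
  structure(
    list(n_pools = as.integer(n_pools), weights = as.integer(weights),
         wells_per_plate = 96L,
         batch_size_plates = as.integer(batch_size_plates),
         subset_free = FALSE, min_distance = 0L,
         assignments = assignments),
    class = "pooling_design"
  )
}

# TSV writer with '# key: value' header comments (version + parameters)
write_tsv_commented <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tnpool %s",
                     as.character(utils::packageVersion("tnpool"))), con)
  for (k in names(params)) {
    writeLines(sprintf("# %s: %s", k, params[[k]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
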