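# Pooled-read decoding: threshold per-pool read counts into a presence
# barcode, classify each site by its pool weight, and map valid barcodes
# back to (plate, well) through the pooling design.
#
# Classification by weight w over 24 pools with allowed weights {10,12,14}:
#   w in allowed          -> CANDIDATE, then exact design match -> MAPPED
#                            (no match -> UNMATCHED)
#   w in {1,2}            -> SEQUENCING_ERROR (spurious signal)
#   w > max(allowed)      -> SISTER_CLONE_SUSPECT (merged sister-clone signal)
#   anything else (0, 3..9, 11, 13) -> LOW_COVERAGE (signal dropout)
# Because allowed weights differ by two, any single-pool error shifts a
# valid barcode to an odd weight and is always detected.

#' Threshold per-pool read counts into a presence barcode
#'
#' Bit i is 1 iff the site has at least `threshold` reads in pool i. The
#' boundary is inclusive: exactly `threshold` reads count as present.
#'
#' @param count_row numeric vector of per-pool read counts
#' @param threshold reads required to call presence (default 50)
#' @return integer 0/1 vector of the same length
#' @examples
#' call_presence(c(200, 3, 60, 0), threshold = 50)  # 1 0 1 0
#' @export
call_presence <- function(count_row, threshold = 50) {
  stopifnot(threshold > 0)
  as.integer(count_row >= threshold)
}

#' Classify a presence barcode by its pool weight
#'
#' @param barcode integer 0/1 vector (length = number of pools)
#' @param allowed_weights weights that decode to a well (default c(10,12,14))
#' @return one of "CANDIDATE", "SEQUENCING_ERROR", "LOW_COVERAGE",
#'   "SISTER_CLONE_SUSPECT"
#' @export
classify_barcode <- function(barcode, allowed_weights = c(10L, 12L, 14L)) {
  classify_weight(sum(barcode), allowed_weights)
}

# vectorized weight -> status
classify_weight <- function(w, allowed_weights = c(10L, 12L, 14L)) {
  out <- rep("LOW_COVERAGE", length(w))
  out[w %in% allowed_weights] <- "CANDIDATE"
  out[w %in% c(1L, 2L)] <- "SEQUENCING_ERROR"
  out[w > max(allowed_weights)] <- "SISTER_CLONE_SUSPECT"
  out
}

#' Match a candidate barcode to its well in the design
#'
#' Exact codeword match only; near-misses are not rescued.
#'
#' @param barcode integer 0/1 vector, codeword string, or codeword integer
#' @param design a `pooling_design`
#' @return one-row data frame (plate, well, well_label), or NULL when the
#'   barcode is not an assigned codeword
#' @export
match_barcode <- function(barcode, design) {
  if (anyDuplicated(design$assignments$code)) {
    stop("integrity error: design contains duplicate codewords", call. = FALSE)
  }
  design_lookup(design, barcode)
}

#' Decode a pooled read-count matrix into well assignments
#'
#' Applies [call_presence()], [classify_barcode()] and [match_barcode()] to
#' every insertion site. A site is MAPPED iff its barcode weight is allowed
#' and the barcode is an assigned codeword. If two different sites decode to
#' the same well, both are demoted to UNMATCHED with a warning (duplicate
#' insertion signals cannot be attributed to a single clone).
#'
#' @param counts a `read_count_matrix` (sites x pools)
#' @param design a `pooling_design` with `n_pools == ncol(counts)`
#' @param threshold reads per pool required to call presence (default 50)
#' @return object of class `decoded_library`: `records` data frame (site,
#'   barcode, weight, status, plate, well, well_label), `summary` named
#'   status counts, `mapped_count`, `n_pools`, `threshold`
#' @export
decode_library <- function(counts, design, threshold = 50) {
  if (ncol(counts) != design$n_pools) {
    stop(sprintf("dimension mismatch: %d count columns vs %d design pools",
                 ncol(counts), design$n_pools), call. = FALSE)
  }
  if (anyDuplicated(design$assignments$code)) {
    stop("integrity error: design contains duplicate codewords", call. = FALSE)
  }
  statuses <- c("MAPPED", "LOW_COVERAGE", "SEQUENCING_ERROR",
                "SISTER_CLONE_SUSPECT", "UNMATCHED")
  n <- nrow(counts)
  if (n == 0L) {
    records <- data.frame(site = character(0), barcode = character(0),
                          weight = integer(0), status = character(0),
                          plate = integer(0), well = integer(0),
                          well_label = character(0), stringsAsFactors = FALSE)
    return(structure(list(records = records,
                          summary = stats::setNames(integer(5), statuses),
                          mapped_count = 0L, n_pools = design$n_pools,
                          threshold = threshold),
                     class = "decoded_library"))
  }
  bits <- matrix(as.integer(unclass(counts) >= threshold), nrow = n)
  weight <- as.integer(rowSums(bits))
  code <- bits_to_codeword(bits)
  status <- classify_weight(weight, design$weights)

  hit <- match(code, design$assignments$code)
  cand <- status == "CANDIDATE"
  plate <- ifelse(cand & !is.na(hit), design$assignments$plate[hit], NA_integer_)
  well <- ifelse(cand & !is.na(hit), design$assignments$well[hit], NA_integer_)
  status[cand & is.na(hit)] <- "UNMATCHED"
  status[cand & !is.na(hit)] <- "MAPPED"

  # two sites claiming the same well: conservative demotion of both
  mapped_idx <- which(status == "MAPPED")
  dup_codes <- code[mapped_idx][duplicated(code[mapped_idx])]
  if (length(dup_codes)) {
    demote <- mapped_idx[code[mapped_idx] %in% dup_codes]
    warning(sprintf(
      "%d sites share %d well barcode(s); all demoted to UNMATCHED",
      length(demote), length(unique(dup_codes))), call. = FALSE)
    status[demote] <- "UNMATCHED"
    plate[demote] <- NA_integer_
    well[demote] <- NA_integer_
  }

  records <- data.frame(
    site = rownames(counts),
    barcode = codeword_to_string(code, design$n_pools),
    weight = weight,
    status = status,
    plate = as.integer(plate),
    well = as.integer(well),
    well_label = ifelse(is.na(well), NA_character_, well_label(well)),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  summary <- stats::setNames(
    vapply(statuses, function(s) sum(status == s), integer(1)), statuses)
  structure(list(records = records, summary = summary,
                 mapped_count = unname(summary["MAPPED"]),
                 n_pools = design$n_pools, threshold = threshold),
            class = "decoded_library")
}

#' @export
print.decoded_library <- function(x, ...) {
  cat(sprintf("Decoded library: %d insertion sites, %d mapped to wells (threshold %g reads)\n",
              nrow(x$records), x$mapped_count, x$threshold))
  invisible(x)
}

#' @export
summary.decoded_library <- function(object, ...) {
  print(object)
  cat("  status counts:\n")
  s <- object$summary
  for (k in names(s)) cat(sprintf("    %-22s %d\n", k, s[[k]]))
  invisible(object)
}

#' Histogram of pool weights across decoded sites
#'
#' Counts how many insertion sites were present in 0, 1, ..., n_pools
#' sequencing pools (mapped or not); total equals the number of sites.
#'
#' @param decoded a `decoded_library`
#' @return named integer vector over weights 0..n_pools
#' @export
pool_count_histogram <- function(decoded) {
  w <- factor(decoded$records$weight, levels = 0:decoded$n_pools)
  stats::setNames(as.integer(table(w)), 0:decoded$n_pools)
}

#' Write a decoded library as TSV
#' @param decoded a `decoded_library`
#' @param path output file
#' @export
write_decoded_tsv <- function(decoded, path) {
  write_tsv_commented(decoded$records, path,
                      params = list(threshold = decoded$threshold,
                                    n_pools = decoded$n_pools))
}

#' Read a decoded library from TSV
#' @param path file written by [write_decoded_tsv()]
#' @param n_pools code length (inferred from barcodes if NULL)
#' @return a `decoded_library`
#' @export
read_decoded_tsv <- function(path, n_pools = NULL) {
  records <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE,
                               colClasses = c(barcode = "character"))
  if (is.null(n_pools)) n_pools <- nchar(records$barcode[1L])
  statuses <- c("MAPPED", "LOW_COVERAGE", "SEQUENCING_ERROR",
                "SISTER_CLONE_SUSPECT", "UNMATCHED")
  summary <- stats::setNames(
    vapply(statuses, function(s) sum(records$status == s), integer(1)),
    statuses)
  structure(list(records = records, summary = summary,
                 mapped_count = unname(summary["MAPPED"]),
                 n_pools = as.integer(n_pools), threshold = NA_real_),
            class = "decoded_library")
}
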