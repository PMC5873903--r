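# Decoding pooled read counts back to wells: thresholding, weight
# classification, matching, and the decoder-vs-simulator identity.

test_that("presence calls threshold at >= 50 reads", {
  expect_equal(call_presence(c(200, 3, 60, 0), 50), c(1L, 0L, 1L, 0L))
  expect_equal(call_presence(rep(0, 24)), rep(0L, 24))
  expect_equal(call_presence(c(50, 49), 50), c(1L, 0L))
  expect_error(call_presence(c(1, 2), threshold = 0))
})

test_that("barcodes classify by weight into the four pre-match classes", {
  bc <- function(w) c(rep(1L, w), rep(0L, 24 - w))
  expect_equal(classify_barcode(bc(10)), "CANDIDATE")
  expect_equal(classify_barcode(bc(12)), "CANDIDATE")
  expect_equal(classify_barcode(bc(14)), "CANDIDATE")
  expect_equal(classify_barcode(bc(16)), "SISTER_CLONE_SUSPECT")
  expect_equal(classify_barcode(bc(15)), "SISTER_CLONE_SUSPECT")
  expect_equal(classify_barcode(bc(1)), "SEQUENCING_ERROR")
  expect_equal(classify_barcode(bc(2)), "SEQUENCING_ERROR")
  for (w in c(0, 3:9, 11, 13)) {
    expect_equal(classify_barcode(bc(w)), "LOW_COVERAGE")
  }
})

test_that("candidate barcodes match their unique well or none", {
  d <- build_design(n_plates = 1, seed = 61)
  a <- d$assignments
  hit <- match_barcode(a$codeword[40], d)
  expect_equal(hit$plate, a$plate[40])
  expect_equal(hit$well, a$well[40])
  # valid weight but unassigned: first weight-10 colex word not in the design
  r <- 0
  repeat {
    cand <- tnpool:::unrank_colex(r, 10, 24)
    if (!cand %in% a$code) break
    r <- r + 1
  }
  expect_null(match_barcode(cand, d))
  dd <- d
  dd$assignments$code[2] <- dd$assignments$code[1]
  expect_error(match_barcode(a$codeword[1], dd), "integrity")
})

test_that("noiseless decoding recovers every unique-site well (simulator identity)", {
  fx <- noiseless_fixture(n_plates = 3, n_mutants = 250)
  dec <- decode_library(fx$counts, fx$design)
  expect_equal(dec$mapped_count, 250)
  rec <- dec$records
  m <- match(site_keys_of(fx$library), rec$site)
  expect_true(all(rec$status[m] == "MAPPED"))
  expect_equal(rec$plate[m], fx$library$plate)
  expect_equal(rec$well[m], fx$library$well)
})

test_that("decoding agrees with a linear-scan matching oracle", {
  fx <- noiseless_fixture(n_plates = 1, n_mutants = 60)
  dec <- decode_library(fx$counts, fx$design)
  a <- fx$design$assignments
  for (i in seq_len(nrow(dec$records))) {
    bc <- dec$records$barcode[i]
    scan <- which(a$codeword == bc)  # brute-force scan over all assignments
    if (length(scan) == 1 && dec$records$weight[i] %in% fx$design$weights) {
      expect_equal(dec$records$plate[i], a$plate[scan])
      expect_equal(dec$records$well[i], a$well[scan])
    } else {
      expect_true(is.na(dec$records$plate[i]))
    }
  }
})

test_that("merged sister signals are flagged when their union exceeds weight 14", {
  d <- build_design(n_plates = 1, seed = 62)
  # find two wells whose codeword union has weight > 14
  codes <- d$assignments$code
  pick <- NULL
  for (i in 1:20) {
    for (j in (i + 1):21) {
      if (tnpool:::popcount(bitwOr(codes[i], codes[j])) > 14) {
        pick <- c(i, j)
        break
      }
    }
    if (!is.null(pick)) break
  }
  lib <- make_library(plate = c(1L, 1L),
                      well = d$assignments$well[pick],
                      position = c(900L, 900L), is_sister = TRUE,
                      sister_group = "sis_1")
  cnt <- gen_pool_reads(lib, d, exact_depth = TRUE, seed = 63)
  dec <- decode_library(cnt, d)
  expect_equal(dec$records$status, "SISTER_CLONE_SUSPECT")
})

test_that("empty matrices decode to empty libraries", {
  d <- build_design(n_plates = 1)
  empty <- matrix(integer(0), nrow = 0, ncol = 24,
                  dimnames = list(NULL, sprintf("pool_%02d", 1:24)))
  dec <- decode_library(empty, d)
  expect_equal(nrow(dec$records), 0)
  expect_equal(sum(dec$summary), 0)
  expect_equal(dec$mapped_count, 0)
})

test_that("pool-count mismatch raises a dimension error", {
  d <- build_design(n_plates = 1)
  m <- matrix(100L, nrow = 2, ncol = 20)
  rownames(m) <- c("c:1:+", "c:2:+")
  expect_error(decode_library(m, d), "dimension mismatch")
})

test_that("two sites claiming one well are both demoted with a warning", {
  d <- build_design(n_plates = 1, seed = 64)
  bits <- tnpool:::codeword_to_bits(d$assignments$code[7], 24)
  m <- rbind(bits, bits) * 200L
  rownames(m) <- c("c:10:+", "c:99:-")
  colnames(m) <- sprintf("pool_%02d", 1:24)
  expect_warning(dec <- decode_library(m, d), "demoted")
  expect_equal(dec$records$status, c("UNMATCHED", "UNMATCHED"))
  expect_equal(dec$mapped_count, 0)
})

test_that("status is a partition and the histogram conserves sites", {
  fx <- noiseless_fixture(n_plates = 2, n_mutants = 150,
                          sister_clone_rate = 0.08)
  dec <- decode_library(fx$counts, fx$design)
  expect_equal(sum(dec$summary), nrow(dec$records))
  h <- pool_count_histogram(dec)
  expect_equal(sum(h), nrow(dec$records))
  expect_equal(names(h), as.character(0:24))

  # noiseless: mass only at allowed weights and above (merged sisters)
  nonzero <- as.integer(names(h)[h > 0])
  expect_true(all(nonzero %in% c(10, 12, 14) | nonzero > 14))
})

test_that("dropout shifts mass to odd weights below the allowed set", {
  fx <- noiseless_fixture(n_plates = 2, n_mutants = 180)
  cnt <- gen_pool_reads(fx$library, fx$design, dispersion = 0,
                        dropout_p = 0.15, noise_mean = 0,
                        spurious_site_rate = 0, seed = 65)
  dec <- decode_library(cnt, fx$design)
  h <- pool_count_histogram(dec)
  expect_gt(sum(h[as.character(c(9, 11, 13))]), 0)
  expect_gt(dec$summary[["LOW_COVERAGE"]], 0)
})

test_that("raising the threshold is monotone on presence bits and weights", {
  fx <- noiseless_fixture(n_plates = 1, n_mutants = 80)
  cnt <- gen_pool_reads(fx$library, fx$design, dropout_p = 0.05, seed = 66)
  dec50 <- decode_library(cnt, fx$design, threshold = 50)
  dec120 <- decode_library(cnt, fx$design, threshold = 120)
  expect_true(all(dec120$records$weight <= dec50$records$weight))
  # bitwise: every 1 at the high threshold is 1 at the low threshold
  b50 <- do.call(rbind, strsplit(dec50$records$barcode, ""))
  b120 <- do.call(rbind, strsplit(dec120$records$barcode, ""))
  expect_true(all(b120 <= b50))
})

test_that("a single pool dropout always evicts a mapped site", {
  fx <- noiseless_fixture(n_plates = 1, n_mutants = 40)
  dec <- decode_library(fx$counts, fx$design)
  mapped <- which(dec$records$status == "MAPPED")
  for (i in mapped[1:10]) {
    pos <- which(unclass(fx$counts)[i, ] > 0)
    for (j in pos) {
      cnt2 <- fx$counts
      cnt2[i, j] <- 0L
      dec2 <- suppressWarnings(decode_library(cnt2, fx$design))
      expect_false(dec2$records$status[i] == "MAPPED")
    }
  }
})
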