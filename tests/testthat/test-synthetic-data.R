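# Ground-truth generators: determinism, conservation laws, and the
# statistical structure they are supposed to realize.

test_that("gen_annotation respects counts, bounds and determinism", {
  empty <- gen_annotation(0, 10000)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$pathways), 0)

  ann <- gen_annotation(100, 150000, pathway_sizes = list(ko1 = 10), seed = 4)
  expect_equal(nrow(ann$genes), 100)
  expect_equal(sum(ann$pathways$pathway == "ko1"), 10)
  expect_false(anyDuplicated(ann$pathways$gene_id[ann$pathways$pathway == "ko1"]) > 0)
  expect_false(anyDuplicated(ann$genes$gene_id) > 0)

  # byte-identical rerun
  expect_identical(ann, gen_annotation(100, 150000,
                                       pathway_sizes = list(ko1 = 10), seed = 4))

  # intervals: ordered, non-overlapping, inside the contig
  g <- ann$genes
  expect_true(all(g$start <= g$end))
  expect_true(all(g$start >= 1) && all(g$end <= ann$genome_length))
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
})

test_that("gen_annotation refuses infeasible packing", {
  expect_error(gen_annotation(100, 5000), "sizing error")
  expect_error(gen_annotation(10, 1e6, pathway_sizes = list(ko1 = 11)),
               "sizing error")
})

test_that("gen_library avoids essential genes and fills plates in order", {
  ann <- gen_annotation(80, 120000, seed = 9)
  ess <- ann$genes$gene_id[seq(1, 80, by = 2)]
  lib <- gen_library(ann, 500, essential_genes = ess,
                     sister_clone_rate = 0, seed = 10)
  expect_equal(nrow(lib), 500)

  ess_iv <- ann$genes[ann$genes$gene_id %in% ess, ]
  inside_essential <- vapply(lib$position, function(p) {
    any(p >= ess_iv$start & p <= ess_iv$end)
  }, logical(1))
  expect_false(any(inside_essential))

  # plate-by-plate fill, 96 wells each
  expect_equal(lib$plate, (seq_len(500) - 1) %/% 96 + 1)
  expect_equal(lib$well, (seq_len(500) - 1) %% 96)

  # no sisters -> all sites unique
  expect_false(anyDuplicated(site_keys_of(lib)) > 0)

  lib960 <- gen_library(ann, 960, sister_clone_rate = 0, seed = 11)
  expect_equal(max(lib960$plate), 10)
  expect_equal(as.integer(table(lib960$plate)), rep(96L, 10))
})

test_that("forced intergenic and all-essential settings behave", {
  ann <- gen_annotation(30, 60000, seed = 12)
  lib <- gen_library(ann, 100, essential_genes = ann$genes$gene_id,
                     intergenic_fraction = 1, seed = 13)
  iv <- ann$genes
  genic <- vapply(lib$position, function(p) any(p >= iv$start & p <= iv$end),
                  logical(1))
  expect_false(any(genic))
})

test_that("gen_library enforces target-space sizing", {
  ann <- gen_annotation(3, 3000, gene_length_range = c(200, 300), seed = 14)
  expect_error(gen_library(ann, 50000, sister_clone_rate = 0, seed = 1),
               "sizing error")
})

test_that("sister clones share sites but occupy distinct wells at the stated rate", {
  ann <- gen_annotation(100, 200000, seed = 15)
  lib <- gen_library(ann, 2000, sister_clone_rate = 0.1, seed = 16)
  sis <- lib[lib$is_sister_clone, ]
  expect_gt(nrow(sis), 0)
  # members of a group share contig:position:strand but not wells
  for (g in unique(sis$sister_group_id)) {
    grp <- sis[sis$sister_group_id == g, ]
    expect_equal(length(unique(site_keys_of(grp))), 1)
    expect_false(anyDuplicated(grp[, c("plate", "well")]) > 0)
  }
  # duplication events ~ Binomial(n-1, rate): 3.5 sigma band around 0.1
  n_dup <- sum(duplicated(site_keys_of(lib)))
  expect_lt(abs(n_dup / 2000 - 0.1), 3.5 * sqrt(0.1 * 0.9 / 2000))
})

test_that("noiseless pooled reads reproduce each well's codeword exactly", {
  fx <- noiseless_fixture(n_plates = 2, n_mutants = 120)
  a <- fx$design$assignments
  key <- paste(a$plate, a$well)
  codes <- a$code[match(paste(fx$library$plate, fx$library$well), key)]
  m <- match(site_keys_of(fx$library), rownames(fx$counts))
  bits <- unclass(fx$counts) > 0
  observed <- as.integer(bits %*% bitwShiftL(1L, 0:23))
  expect_equal(observed[m], codes)
})

test_that("sister-clone sites carry the bitwise OR of their wells' codewords", {
  d <- build_design(n_plates = 1, seed = 21)
  lib <- make_library(plate = c(1L, 1L), well = c(0L, 1L),
                      position = c(500L, 500L), is_sister = TRUE,
                      sister_group = "sis_1")
  cnt <- gen_pool_reads(lib, d, exact_depth = TRUE, seed = 22)
  expect_equal(nrow(cnt), 1)
  observed <- as.integer(unclass(cnt)[1, ] > 0)
  c1 <- tnpool:::codeword_to_bits(d$assignments$code[1], 24)[1, ]
  c2 <- tnpool:::codeword_to_bits(d$assignments$code[2], 24)[1, ]
  expect_equal(observed, as.integer(c1 | c2))
})

test_that("spurious sites land in one or two pools", {
  fx <- noiseless_fixture(n_plates = 1, n_mutants = 90)
  cnt <- gen_pool_reads(fx$library, fx$design, dispersion = 0, dropout_p = 0,
                        noise_mean = 0, spurious_site_rate = 0.5, seed = 23)
  spur <- setdiff(rownames(cnt), site_keys_of(fx$library))
  expect_gt(length(spur), 0)
  pools_hit <- rowSums(unclass(cnt)[spur, , drop = FALSE] > 0)
  expect_true(all(pools_hit %in% c(1L, 2L)))
})

test_that("strain panel: degenerate settings give identical counts", {
  p <- gen_strain_panel(n_strains = 6, n_ogs = 4, sd_experiment = 0,
                        sd_strain = 0, sd_residual = 0, seed = 31)
  expect_equal(length(unique(p$phenotypes$cfu_count)), 1)
  expect_equal(nrow(p$phenotypes), 6 * 3 * 3)
  expect_true(all(rownames(p$og_presence) %in% p$phenotypes$strain_id))
})

test_that("a +2 log-CFU OG effect shows up as a ~2 carrier/non-carrier gap", {
  p <- gen_strain_panel(n_strains = 300, n_ogs = 1,
                        effect_ogs = c(OG_0001 = 2),
                        n_experiments = 2, reps_per_cell = 2,
                        sd_experiment = 0, sd_strain = 0.05,
                        sd_residual = 0.05, seed = 32)
  log_cfu <- log(pmax(p$phenotypes$cfu_count, 1))
  carrier <- p$og_presence[p$phenotypes$strain_id, "OG_0001"] == 1
  gap <- mean(log_cfu[carrier]) - mean(log_cfu[!carrier])
  # MC error: sd ~0.07 per strain, ~150 strains per class
  expect_lt(abs(gap - 2), 0.05)
})

test_that("variance components match the generating SDs (coarse)", {
  # isolate each component by zeroing the others
  p_res <- gen_strain_panel(n_strains = 40, n_ogs = 1, n_experiments = 5,
                            reps_per_cell = 10, sd_experiment = 0,
                            sd_strain = 0, sd_residual = 0.6,
                            baseline_log_cfu = 12, seed = 33)
  expect_lt(abs(stats::sd(log(p_res$phenotypes$cfu_count)) - 0.6), 0.1)

  p_str <- gen_strain_panel(n_strains = 400, n_ogs = 1, n_experiments = 2,
                            reps_per_cell = 2, sd_experiment = 0,
                            sd_strain = 0.8, sd_residual = 0,
                            baseline_log_cfu = 12, seed = 34)
  strain_means <- tapply(log(p_str$phenotypes$cfu_count),
                         p_str$phenotypes$strain_id, mean)
  expect_lt(abs(stats::sd(strain_means) - 0.8), 0.12)

  p_exp <- gen_strain_panel(n_strains = 30, n_ogs = 1, n_experiments = 60,
                            reps_per_cell = 2, sd_experiment = 0.7,
                            sd_strain = 0, sd_residual = 0,
                            baseline_log_cfu = 12, seed = 35)
  exp_means <- tapply(log(p_exp$phenotypes$cfu_count),
                      p_exp$phenotypes$experiment_id, mean)
  expect_lt(abs(stats::sd(exp_means) - 0.7), 0.2)
})

test_that("load tables have the stated layout and effects", {
  lt <- gen_load_table(c("WT", "a", "b", "c", "d"), seed = 41,
                       sd_experiment = 0, sd_residual = 0)
  expect_equal(nrow(lt), 5 * 3 * 3)
  expect_equal(length(unique(lt$cfu_count)), 1)
  expect_equal(attr(lt, "control"), "WT")

  lt2 <- gen_load_table(c("WT", "lpxC"), true_deltas = c(lpxC = -2),
                        n_experiments = 10, reps = 30,
                        sd_experiment = 0.1, sd_residual = 0.3, seed = 42)
  gap <- mean(log(lt2$cfu_count[lt2$treatment_id == "lpxC"])) -
    mean(log(lt2$cfu_count[lt2$treatment_id == "WT"]))
  expect_lt(abs(gap + 2), 0.1)
  expect_error(gen_load_table(c("WT", "x"), true_deltas = c(WT = 1)),
               "control")
})

test_that("generators are deterministic under a fixed seed", {
  ann <- gen_annotation(40, 60000, seed = 51)
  expect_identical(gen_library(ann, 100, seed = 52),
                   gen_library(ann, 100, seed = 52))
  d <- build_design(n_plates = 2, seed = 53)
  lib <- gen_library(ann, 100, seed = 52)
  expect_identical(gen_pool_reads(lib, d, seed = 54),
                   gen_pool_reads(lib, d, seed = 54))
  expect_identical(gen_strain_panel(n_strains = 10, n_ogs = 5, seed = 55),
                   gen_strain_panel(n_strains = 10, n_ogs = 5, seed = 55))
  expect_identical(gen_load_table(c("WT", "m1"), seed = 56),
                   gen_load_table(c("WT", "m1"), seed = 56))
})
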