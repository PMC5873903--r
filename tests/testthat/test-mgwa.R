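# Mixed-model association between OG presence and log CFU load, and the
# mutant-vs-control load comparison.

test_that("monomorphic OGs are returned untested", {
  pres <- matrix(1L, nrow = 10, ncol = 1)
  p <- gen_strain_panel(n_strains = 10, n_ogs = 1, presence = pres, seed = 1)
  f <- fit_og_association(p, "OG_0001")
  expect_equal(f$status, "monomorphic")
  expect_true(is.na(f$p))
  expect_true(is.na(f$effect))

  # a single strain in one class is also untestable
  pres2 <- matrix(c(1L, rep(0L, 9)), ncol = 1)
  p2 <- gen_strain_panel(n_strains = 10, n_ogs = 1, presence = pres2, seed = 2)
  expect_equal(fit_og_association(p2, "OG_0001")$status, "monomorphic")
})

test_that("a strong OG effect is recovered with the right size and sign", {
  p <- gen_strain_panel(n_strains = 41, n_ogs = 3,
                        effect_ogs = c(OG_0001 = 2), seed = 3)
  f <- fit_og_association(p, "OG_0001")
  expect_equal(f$status, "tested")
  expect_lt(abs(f$effect - 2), 0.5)
  expect_lt(f$p, 0.001)
  expect_equal(unname(coef(f)), f$effect)

  neg <- gen_strain_panel(n_strains = 41, n_ogs = 3,
                          effect_ogs = c(OG_0002 = -1.5), seed = 4)
  expect_lt(fit_og_association(neg, "OG_0002")$effect, 0)
})

test_that("effect sign equals the presence-class mean difference on clean data", {
  p <- gen_strain_panel(n_strains = 30, n_ogs = 2,
                        effect_ogs = c(OG_0001 = 1),
                        sd_experiment = 0, sd_strain = 0.001,
                        sd_residual = 0.001, seed = 5)
  f <- fit_og_association(p, "OG_0001")
  log_cfu <- log(pmax(p$phenotypes$cfu_count, 1))
  carrier <- p$og_presence[p$phenotypes$strain_id, "OG_0001"] == 1
  expect_equal(sign(f$effect),
               sign(mean(log_cfu[carrier]) - mean(log_cfu[!carrier])))
  expect_lt(abs(f$effect - 1), 0.05)
})

test_that("LRT deviance is nonnegative and p lies in (0, 1]", {
  p <- gen_strain_panel(n_strains = 20, n_ogs = 10, seed = 6)
  m <- run_mgwa(p)
  tested <- m$results[m$results$status == "tested", ]
  expect_true(all(tested$p > 0 & tested$p <= 1))
})

test_that("Wald and LRT give concordant answers on a clear effect", {
  p <- gen_strain_panel(n_strains = 41, n_ogs = 2,
                        effect_ogs = c(OG_0001 = 2), seed = 7)
  lrt <- fit_og_association(p, "OG_0001", test = "lrt")
  wald <- fit_og_association(p, "OG_0001", test = "wald")
  expect_lt(lrt$p, 0.001)
  expect_lt(wald$p, 0.001)
  expect_equal(lrt$effect, wald$effect, tolerance = 1e-6)
})

test_that("run_mgwa applies Bonferroni over the tested count and the raw-p cutoff", {
  p <- gen_strain_panel(n_strains = 41, n_ogs = 20,
                        effect_ogs = c(OG_0001 = 2), seed = 8)
  m <- run_mgwa(p, cutoff = 0.001)
  r <- m$results
  tested <- r[r$status == "tested", ]
  expect_equal(tested$p_bonferroni, pmin(1, tested$p * m$m_tested))
  expect_true(all(tested$p_bonferroni <= 1))
  # idempotence: correcting the corrected values only saturates
  expect_true(all(pmin(1, tested$p_bonferroni * m$m_tested) >=
                    tested$p_bonferroni))
  expect_true("OG_0001" %in% m$top_ogs)
  expect_equal(m$top_ogs, tested$og[tested$p < 0.001])

  m2 <- run_mgwa(p, cutoff = 0.001, use_corrected = TRUE)
  expect_true(all(m2$top_ogs %in% m$top_ogs))
})

test_that("duplicate OG presence columns receive identical p-values", {
  pres <- matrix(stats::rbinom(30 * 2, 1, 0.5), nrow = 30)
  pres[, 2] <- pres[, 1]
  p <- gen_strain_panel(n_strains = 30, n_ogs = 2, presence = pres, seed = 9)
  m <- run_mgwa(p)
  expect_equal(m$results$p[1], m$results$p[2])
  expect_equal(m$results$effect[1], m$results$effect[2])
})

test_that("null OGs are not over-selected at the cutoff (coarse calibration)", {
  p <- gen_strain_panel(n_strains = 41, n_ogs = 60, seed = 10)
  m <- run_mgwa(p, cutoff = 0.05)
  rate <- length(m$top_ogs) / m$m_tested
  # expected 5%; allow a wide binomial band for 60 draws
  expect_lt(rate, 0.18)
})

test_that("compare_loads recovers which treatments are depressed", {
  flagged <- matrix(NA, nrow = 10, ncol = 4)
  colnames(flagged) <- c("gmhD", "lpxB", "lpxC", "lpxK")
  for (r in 1:10) {
    lt <- gen_load_table(c("WT", "lpxB", "lpxC", "gmhD", "lpxK"),
                         true_deltas = c(lpxB = -2, lpxC = -2),
                         sd_experiment = 0.3, sd_residual = 0.4,
                         seed = 100 + r)
    cmp <- compare_loads(lt)
    flagged[r, ] <- cmp$significant[match(colnames(flagged), cmp$treatment)]
  }
  expect_gte(mean(flagged[, "lpxB"]), 0.9)
  expect_gte(mean(flagged[, "lpxC"]), 0.9)
  # null treatments flagged at most occasionally
  expect_lte(mean(flagged[, c("gmhD", "lpxK")]), 0.25)
})

test_that("null load tables produce no excess significance", {
  n_sig <- 0L
  n_tests <- 0L
  for (r in 1:100) {
    lt <- gen_load_table(c("WT", "a", "b"), sd_experiment = 0.3,
                         sd_residual = 0.4, seed = 200 + r)
    cmp <- compare_loads(lt)
    n_sig <- n_sig + sum(cmp$significant, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(cmp$significant))
  }
  # nominal 5%; the Wald z is mildly liberal at 9 replicates per arm and
  # the two contrasts share the control arm (positively correlated)
  expect_lte(n_sig / n_tests, 0.16)
})

test_that("the control row is pinned at zero and a lone experiment falls back", {
  lt <- gen_load_table(c("WT", "mut"), true_deltas = c(mut = -1), seed = 11)
  cmp <- compare_loads(lt)
  expect_equal(cmp$effect[cmp$treatment == "WT"], 0)
  expect_true(is.na(cmp$p[cmp$treatment == "WT"]))

  lt1 <- gen_load_table(c("WT", "mut"), true_deltas = c(mut = -1),
                        n_experiments = 1, seed = 12)
  expect_warning(cmp1 <- compare_loads(lt1), "single experiment")
  expect_equal(nrow(cmp1), 2)
})

test_that("effect estimates are unbiased across a grid of effect sizes (coarse)", {
  for (beta in c(0.5, 1)) {
    est <- vapply(1:8, function(r) {
      p <- gen_strain_panel(n_strains = 41, n_ogs = 1,
                            effect_ogs = c(OG_0001 = beta),
                            seed = 300 + 10 * beta + r)
      fit_og_association(p, "OG_0001")$effect
    }, numeric(1))
    expect_lt(abs(mean(est) - beta), 0.25)
  }
})
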