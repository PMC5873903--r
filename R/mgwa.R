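# Metagenome-wide association: per-OG linear mixed model relating OG
# presence/absence across strains to natural-log CFU load, with experiment
# and strain (bacterial treatment) as independent random intercepts:
#   log(CFU) = intercept + beta * presence + u_experiment + u_strain + eps
# The presence term is tested by a likelihood-ratio test of maximum-
# likelihood fits of the nested models (Wald available via `test`).
# Zero CFU counts are replaced by 1 before logging and flagged.

.lmer_quiet_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = lme4::.makeCC("ignore", tol = 2e-3),
                    check.conv.hess = lme4::.makeCC("ignore", tol = 1e-6),
                    calc.derivs = FALSE)
}

# shared data prep: natural-log CFU with zero replacement
mgwa_model_frame <- function(phenotypes) {
  n_zero <- sum(phenotypes$cfu_count == 0)
  data.frame(
    log_cfu = log(pmax(phenotypes$cfu_count, 1)),
    strain_id = factor(phenotypes$strain_id),
    experiment_id = factor(phenotypes$experiment_id),
    n_zero_replaced = n_zero,
    stringsAsFactors = FALSE
  )
}

#' Mixed-model association between one OG and log CFU load
#'
#' @param panel a `strain_panel`
#' @param og OG id (column of `panel$og_presence`)
#' @param test "lrt" (likelihood ratio of nested ML fits, default) or "wald"
#' @param null_loglik optional pre-computed log-likelihood of the null ML
#'   model (shared across OGs of a panel); computed if NULL
#' @return object of class `og_association`: og, n_present, n_absent,
#'   effect (difference in mean log CFU, presence minus absence), p, status
#'   ("tested", "monomorphic", "failed"), boundary (TRUE when a variance
#'   component hit zero), note
#' @export
fit_og_association <- function(panel, og, test = c("lrt", "wald"),
                               null_loglik = NULL) {
  test <- match.arg(test)
  if (!og %in% colnames(panel$og_presence)) {
    stop("unknown OG: ", og, call. = FALSE)
  }
  d <- mgwa_model_frame(panel$phenotypes)
  pres <- panel$og_presence[, og]
  d$presence <- pres[as.character(d$strain_id)]
  n_present <- length(unique(d$strain_id[d$presence == 1L]))
  n_absent <- length(unique(d$strain_id[d$presence == 0L]))

  base <- list(og = og, n_present = n_present, n_absent = n_absent,
               effect = NA_real_, p = NA_real_, boundary = FALSE,
               n_zero_replaced = d$n_zero_replaced[1L], note = "")
  if (min(n_present, n_absent) < 2L) {
    base$status <- "monomorphic"
    base$note <- "fewer than 2 strains in a presence class"
    return(structure(base, class = "og_association"))
  }

  fit <- tryCatch({
    full <- lme4::lmer(
      log_cfu ~ presence + (1 | experiment_id) + (1 | strain_id),
      data = d, REML = FALSE, control = .lmer_quiet_control())
    beta <- unname(lme4::fixef(full)["presence"])
    boundary <- lme4::isSingular(full, tol = 1e-5)
    if (test == "lrt") {
      if (is.null(null_loglik)) {
        null <- lme4::lmer(
          log_cfu ~ 1 + (1 | experiment_id) + (1 | strain_id),
          data = d, REML = FALSE, control = .lmer_quiet_control())
        null_loglik <- as.numeric(stats::logLik(null))
      }
      dev <- max(0, 2 * (as.numeric(stats::logLik(full)) - null_loglik))
      p <- stats::pchisq(dev, df = 1L, lower.tail = FALSE)
    } else {
      se <- sqrt(diag(as.matrix(stats::vcov(full)))["presence"])
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
    list(effect = beta, p = unname(p), boundary = boundary)
  }, error = function(e) e)

  if (inherits(fit, "error")) {
    base$status <- "failed"
    base$note <- conditionMessage(fit)
  } else {
    base$status <- "tested"
    base$effect <- fit$effect
    base$p <- fit$p
    base$boundary <- fit$boundary
  }
  structure(base, class = "og_association")
}

#' @export
print.og_association <- function(x, ...) {
  cat(sprintf("OG association %s [%s]: %d present / %d absent strains\n",
              x$og, x$status, x$n_present, x$n_absent))
  if (x$status == "tested") {
    cat(sprintf("  effect (log CFU, presence - absence) = %.3f, p = %.3g%s\n",
                x$effect, x$p,
                if (x$boundary) " (variance component at boundary)" else ""))
  } else if (nzchar(x$note)) cat("  ", x$note, "\n", sep = "")
  invisible(x)
}

#' @export
coef.og_association <- function(object, ...) {
  c(effect = object$effect)
}

#' Run the metagenome-wide association scan
#'
#' Fits [fit_og_association()] for every polymorphic OG in the panel (the
#' null model is fitted once and shared), applies Bonferroni correction over
#' the number of OGs actually tested, and selects the top set by the raw
#' p-value cutoff (or the corrected one with `use_corrected = TRUE`).
#'
#' @param panel a `strain_panel`
#' @param cutoff p-value cutoff for the top set (default 0.001)
#' @param use_corrected select the top set on Bonferroni-corrected p instead
#'   of raw p (default FALSE)
#' @param test "lrt" or "wald", passed to the per-OG fit
#' @return object of class `mgwa_result`: `results` data frame (og,
#'   n_present, n_absent, effect, p, p_bonferroni, status), `top_ogs`,
#'   `m_tested`, `cutoff`
#' @export
run_mgwa <- function(panel, cutoff = 0.001, use_corrected = FALSE,
                     test = c("lrt", "wald")) {
  test <- match.arg(test)
  ogs <- colnames(panel$og_presence)
  null_ll <- NULL
  if (test == "lrt") {
    d <- mgwa_model_frame(panel$phenotypes)
    null <- lme4::lmer(log_cfu ~ 1 + (1 | experiment_id) + (1 | strain_id),
                       data = d, REML = FALSE,
                       control = .lmer_quiet_control())
    null_ll <- as.numeric(stats::logLik(null))
  }
  rows <- lapply(ogs, function(og) {
    f <- fit_og_association(panel, og, test = test, null_loglik = null_ll)
    data.frame(og = f$og, n_present = f$n_present, n_absent = f$n_absent,
               effect = f$effect, p = f$p, status = f$status,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  m <- sum(results$status == "tested")
  results$p_bonferroni <- pmin(1, results$p * m)
  sel_p <- if (use_corrected) results$p_bonferroni else results$p
  top <- results$og[results$status == "tested" & !is.na(sel_p) & sel_p < cutoff]
  structure(list(results = results, top_ogs = top, m_tested = m,
                 cutoff = cutoff, use_corrected = use_corrected),
            class = "mgwa_result")
}

#' @export
print.mgwa_result <- function(x, ...) {
  cat(sprintf("MGWA scan: %d OGs (%d tested, %d monomorphic/failed)\n",
              nrow(x$results), x$m_tested, nrow(x$results) - x$m_tested))
  cat(sprintf("  top set: %d OGs at %s p < %g\n", length(x$top_ogs),
              if (x$use_corrected) "Bonferroni" else "raw", x$cutoff))
  invisible(x)
}

#' @export
summary.mgwa_result <- function(object, n = 10L, ...) {
  print(object)
  r <- object$results[object$results$status == "tested", , drop = FALSE]
  r <- r[order(r$p), , drop = FALSE]
  cat("  strongest associations:\n")
  print(utils::head(r, n), row.names = FALSE)
  invisible(object)
}

#' Write MGWA results as TSV
#' @param mgwa an `mgwa_result`
#' @param path output file
#' @export
write_mgwa_tsv <- function(mgwa, path) {
  write_tsv_commented(mgwa$results, path,
                      params = list(m_tested = mgwa$m_tested,
                                    cutoff = mgwa$cutoff))
}

#' Compare mutant loads against a control treatment
#'
#' Linear mixed model `log(CFU) = intercept + treatment + u_experiment +
#' eps` (experiment as random intercept), with per-treatment Wald contrasts
#' against the control. With a single experiment the random effect is not
#' estimable and a fixed-effects linear model is used instead, with a
#' warning.
#'
#' @param loads a `load_table`
#' @param control control treatment id (default: the table's `control`
#'   attribute)
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @return object of class `load_comparison`: data frame (treatment, effect,
#'   se, p, significant); the control row has effect 0 and NA p
#' @export
compare_loads <- function(loads, control = attr(loads, "control"),
                          alpha = 0.05) {
  stopifnot(!is.null(control), control %in% loads$treatment_id)
  d <- data.frame(
    log_cfu = log(pmax(loads$cfu_count, 1)),
    treatment = stats::relevel(factor(loads$treatment_id), ref = control),
    experiment_id = factor(loads$experiment_id)
  )
  n_exp <- nlevels(d$experiment_id)
  if (n_exp >= 2L) {
    fit <- lme4::lmer(log_cfu ~ treatment + (1 | experiment_id), data = d,
                      REML = TRUE, control = .lmer_quiet_control())
    b <- lme4::fixef(fit)
    v <- diag(as.matrix(stats::vcov(fit)))
  } else {
    warning("single experiment: falling back to a fixed-effects linear model",
            call. = FALSE)
    fit <- stats::lm(log_cfu ~ treatment, data = d)
    b <- stats::coef(fit)
    v <- diag(stats::vcov(fit))
  }
  trt_levels <- levels(d$treatment)[-1L]
  nm <- paste0("treatment", trt_levels)
  eff <- unname(b[nm])
  se <- unname(sqrt(v[nm]))
  p <- 2 * stats::pnorm(-abs(eff / se))
  out <- data.frame(
    treatment = c(control, trt_levels),
    effect = c(0, eff),
    se = c(NA_real_, se),
    p = c(NA_real_, p),
    significant = c(NA, p < alpha),
    stringsAsFactors = FALSE
  )
  attr(out, "control") <- control
  attr(out, "n_experiments") <- n_exp
  class(out) <- c("load_comparison", "data.frame")
  out
}

#' @export
print.load_comparison <- function(x, ...) {
  cat(sprintf("Mutant load comparison vs control '%s' (%d experiments):\n",
              attr(x, "control"), attr(x, "n_experiments")))
  df <- as.data.frame(x)
  df$effect <- round(df$effect, 3)
  df$se <- round(df$se, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
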