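# Synthetic strain panels (OG presence/absence + replicate log-CFU
# phenotypes) and mutant load tables, realizing the variance structure of a
# monoassociation experiment: experiment-level and strain-level random
# effects plus residual noise on the natural-log CFU scale.

#' Generate a synthetic strain panel for association testing
#'
#' Latent log CFU for strain s, experiment e, replicate r:
#' `baseline + sum(effects of OGs present in s) + u_e + u_s + eps`, with
#' `u_e ~ N(0, sd_experiment^2)`, `u_s ~ N(0, sd_strain^2)`,
#' `eps ~ N(0, sd_residual^2)`. Reported CFU counts are `round(exp(log CFU))`.
#' OG presence is Bernoulli(0.5) per strain x OG unless `presence` is given.
#'
#' @param n_strains number of strains (study scale: 41)
#' @param n_ogs number of orthologous groups
#' @param effect_ogs named numeric: OG id -> additive effect on natural-log CFU
#' @param n_experiments number of experiments (default 3)
#' @param reps_per_cell replicates per strain x experiment (default 3)
#' @param sd_experiment sd of the experiment random effect (log units)
#' @param sd_strain sd of the strain random effect (log units)
#' @param sd_residual residual sd (log units)
#' @param baseline_log_cfu intercept on the natural-log CFU scale
#' @param presence optional strains x OGs 0/1 matrix to use instead of
#'   Bernoulli(0.5)
#' @param detection_limit optional CFU left-censoring floor (counts below it
#'   are reported at the floor); NULL disables censoring
#' @param seed RNG seed
#' @return object of class `strain_panel`: `og_presence` (strains x OGs 0/1
#'   matrix), `phenotypes` data frame (strain_id, experiment_id,
#'   replicate_id, cfu_count), `true_effect` named vector
#' @export
gen_strain_panel <- function(n_strains = 41L, n_ogs = 100L,
                             effect_ogs = numeric(0),
                             n_experiments = 3L, reps_per_cell = 3L,
                             sd_experiment = 0.5, sd_strain = 0.5,
                             sd_residual = 0.5, baseline_log_cfu = 9.2,
                             presence = NULL, detection_limit = NULL,
                             seed = 1L) {
  stopifnot(sd_experiment >= 0, sd_strain >= 0, sd_residual >= 0)
  set.seed(seed)
  og_ids <- sprintf("OG_%04d", seq_len(n_ogs))
  strain_ids <- sprintf("strain_%02d", seq_len(n_strains))
  if (length(effect_ogs) && !all(names(effect_ogs) %in% og_ids)) {
    stop("effect_ogs names must be OG ids (OG_0001 ...)", call. = FALSE)
  }
  if (is.null(presence)) {
    presence <- matrix(stats::rbinom(n_strains * n_ogs, 1L, 0.5),
                       nrow = n_strains, ncol = n_ogs)
  } else {
    stopifnot(nrow(presence) == n_strains, ncol(presence) == n_ogs)
  }
  dimnames(presence) <- list(strain_ids, og_ids)

  eff <- stats::setNames(numeric(n_ogs), og_ids)
  eff[names(effect_ogs)] <- as.numeric(effect_ogs)
  strain_shift <- as.numeric(presence %*% eff)

  u_exp <- stats::rnorm(n_experiments, 0, sd_experiment)
  u_str <- stats::rnorm(n_strains, 0, sd_strain)

  grid <- expand.grid(replicate_id = seq_len(reps_per_cell),
                      experiment_id = seq_len(n_experiments),
                      strain = seq_len(n_strains))
  log_cfu <- baseline_log_cfu + strain_shift[grid$strain] +
    u_exp[grid$experiment_id] + u_str[grid$strain] +
    stats::rnorm(nrow(grid), 0, sd_residual)
  cfu <- round(exp(log_cfu))
  if (!is.null(detection_limit)) cfu <- pmax(cfu, detection_limit)

  phenotypes <- data.frame(
    strain_id = strain_ids[grid$strain],
    experiment_id = sprintf("exp_%02d", grid$experiment_id),
    replicate_id = grid$replicate_id,
    cfu_count = cfu,
    stringsAsFactors = FALSE
  )
  structure(list(og_presence = presence, phenotypes = phenotypes,
                 true_effect = eff[eff != 0]),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat(sprintf("Strain panel: %d strains x %d OGs; %d phenotype rows (%d with true effects)\n",
              nrow(x$og_presence), ncol(x$og_presence), nrow(x$phenotypes),
              length(x$true_effect)))
  invisible(x)
}

#' Generate a synthetic mutant load table
#'
#' Same mixed structure as [gen_strain_panel()] but with treatments as fixed
#' shifts: log CFU = baseline + delta(treatment) + u_experiment + residual.
#' The default layout mirrors a three-experiment, triplicate design.
#'
#' @param treatments character vector of treatment ids (mutants + control)
#' @param true_deltas named numeric log-CFU shifts vs control (control 0;
#'   missing treatments default to 0)
#' @param control control treatment id (default first element of treatments)
#' @param n_experiments number of experiments (default 3)
#' @param reps replicates per treatment x experiment (default 3)
#' @param sd_experiment sd of the experiment random effect
#' @param sd_residual residual sd
#' @param baseline_log_cfu intercept on the natural-log CFU scale
#' @param detection_limit optional CFU left-censoring floor; NULL disables
#' @param seed RNG seed
#' @return object of class `load_table`: data frame (treatment_id,
#'   experiment_id, replicate_id, cfu_count) with attribute `control`
#' @export
gen_load_table <- function(treatments, true_deltas = numeric(0),
                           control = treatments[1L], n_experiments = 3L,
                           reps = 3L, sd_experiment = 0.5,
                           sd_residual = 0.5, baseline_log_cfu = 9.2,
                           detection_limit = NULL, seed = 1L) {
  stopifnot(control %in% treatments)
  if (length(true_deltas) && !all(names(true_deltas) %in% treatments)) {
    stop("true_deltas names must be treatment ids", call. = FALSE)
  }
  if (control %in% names(true_deltas) && true_deltas[[control]] != 0) {
    stop("the control treatment must have delta 0", call. = FALSE)
  }
  set.seed(seed)
  delta <- stats::setNames(numeric(length(treatments)), treatments)
  delta[names(true_deltas)] <- as.numeric(true_deltas)

  u_exp <- stats::rnorm(n_experiments, 0, sd_experiment)
  grid <- expand.grid(replicate_id = seq_len(reps),
                      experiment_id = seq_len(n_experiments),
                      treatment_id = treatments,
                      stringsAsFactors = FALSE)
  log_cfu <- baseline_log_cfu + delta[grid$treatment_id] +
    u_exp[grid$experiment_id] + stats::rnorm(nrow(grid), 0, sd_residual)
  cfu <- round(exp(log_cfu))
  if (!is.null(detection_limit)) cfu <- pmax(cfu, detection_limit)

  out <- data.frame(
    treatment_id = grid$treatment_id,
    experiment_id = sprintf("exp_%02d", grid$experiment_id),
    replicate_id = grid$replicate_id,
    cfu_count = cfu,
    stringsAsFactors = FALSE
  )
  attr(out, "control") <- control
  class(out) <- c("load_table", "data.frame")
  out
}

#' Write the OG presence matrix as TSV (strains x OGs)
#' @param panel a `strain_panel`
#' @param path output file
#' @export
write_presence_tsv <- function(panel, path) {
  df <- data.frame(strain_id = rownames(panel$og_presence),
                   as.data.frame(panel$og_presence, row.names = NULL),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_commented(df, path)
}

#' Read an OG presence matrix from TSV
#' @param path file with a strain_id column and one 0/1 column per OG
#' @return strains x OGs integer matrix
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot("strain_id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "strain_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$strain_id
  m
}

#' Read an OrthoMCL-style groups file into a presence matrix
#'
#' Parses lines of the form `OG_name: strainA|gene1 strainB|gene2 ...` into
#' a strains x OGs 0/1 matrix (presence = the strain contributes at least
#' one gene to the group).
#'
#' @param path groups file
#' @return strains x OGs integer matrix
#' @export
read_orthomcl_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  ogs <- trimws(vapply(parts, `[`, character(1), 1L))
  members <- lapply(parts, function(p) {
    toks <- strsplit(trimws(paste(p[-1L], collapse = ":")), "\\s+")[[1L]]
    unique(vapply(strsplit(toks, "|", fixed = TRUE), `[`, character(1), 1L))
  })
  strains <- sort(unique(unlist(members)))
  m <- matrix(0L, nrow = length(strains), ncol = length(ogs),
              dimnames = list(strains, ogs))
  for (j in seq_along(ogs)) m[members[[j]], j] <- 1L
  m
}

#' Write phenotype rows (strain, experiment, replicate, cfu) as TSV
#' @param panel a `strain_panel`
#' @param path output file
#' @export
write_phenotypes_tsv <- function(panel, path) {
  write_tsv_commented(panel$phenotypes, path)
}

#' Read a phenotype table from TSV
#' @param path TSV with strain_id, experiment_id, replicate_id, cfu_count
#' @return data frame
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("strain_id", "experiment_id", "cfu_count") %in% names(df)))
  df
}

#' Assemble a strain panel from a presence matrix and a phenotype table
#' @param og_presence strains x OGs 0/1 matrix
#' @param phenotypes data frame (strain_id, experiment_id, replicate_id,
#'   cfu_count)
#' @return a `strain_panel`
#' @export
strain_panel <- function(og_presence, phenotypes) {
  missing <- setdiff(unique(phenotypes$strain_id), rownames(og_presence))
  if (length(missing)) {
    stop("phenotype strains missing from og_presence: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(og_presence = og_presence, phenotypes = phenotypes,
                 true_effect = numeric(0)),
            class = "strain_panel")
}

#' Write a mutant load table as TSV
#' @param loads a `load_table`
#' @param path output file
#' @export
write_load_tsv <- function(loads, path) {
  write_tsv_commented(as.data.frame(loads), path,
                      params = list(control = attr(loads, "control")))
}

#' Read a mutant load table from TSV
#' @param path TSV with treatment_id, experiment_id, replicate_id, cfu_count
#' @param control control treatment id
#' @return a `load_table`
#' @export
read_load_tsv <- function(path, control) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("treatment_id", "experiment_id", "cfu_count") %in% names(df)),
            control %in% df$treatment_id)
  attr(df, "control") <- control
  class(df) <- c("load_table", "data.frame")
  df
}
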