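# End-to-end orchestration: one JSON config, subcommands writing a
# standard file surface, all randomness derived from a single root seed.

#' Default run configuration
#'
#' Returns the full configuration schema with defaults mirroring the
#' reference study design: 215 discovery patients and 173 controls, a
#' 128-region / nine-network parcellation, K = 4 factors, 10,000
#' permutations, top-10% edge fraction, FDR 0.05.
#'
#' @return nested named list (the RunConfig schema).
#' @export
default_config <- function() {
  list(
    paths = list(out_dir = "connlda_run", parcellation = NULL,
                 matrices_dir = NULL, phenotypes = NULL,
                 scale_manifest = NULL),
    cohort = list(n_patients = 215, n_controls = 173, n_regions = 128,
                  n_sites = 3, dirichlet_alpha = 1, noise_sd = 0.5,
                  sparsity = 0.25, block_bias = 2, site_effect_sd = 0),
    model = list(K = 4, alpha = NULL, eta = 0.01, n_restarts = 10,
                 max_iter = 500, tol = 1e-5),
    encoding = list(scale = 10, clip = 3, fisher_z = FALSE,
                    reference = "normalized"),
    stats = list(n_perm = 10000, n_boot = 50, fdr_alpha = 0.05,
                 fraction_top = 0.10, site_column = "site",
                 covariate_columns = c("age", "sex", "fd")),
    seed = 1
  )
}

# strict validation: unknown keys are rejected, known numeric keys checked
validate_config <- function(config) {
  ref <- default_config()
  chk <- function(cfg, tmpl, path = "") {
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra))
      stopf("unknown config key(s): %s",
            paste0(path, extra, collapse = ", "))
    for (nm in names(cfg))
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]])))
        chk(cfg[[nm]], tmpl[[nm]], paste0(path, nm, "."))
  }
  chk(config, ref)
  out <- utils::modifyList(ref, config)
  with(out$cohort, {
    check_scalar(noise_sd, "cohort.noise_sd", lower = 0, open_lower = TRUE)
    check_scalar(sparsity, "cohort.sparsity", 0, 1, open_lower = TRUE)
  })
  check_scalar(out$model$K, "model.K", lower = 2)
  check_scalar(out$stats$fraction_top, "stats.fraction_top", 0, 1,
               open_lower = TRUE)
  check_scalar(out$stats$fdr_alpha, "stats.fdr_alpha", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  out
}

#' Read and validate a JSON run configuration
#' @param path JSON file; missing keys fall back to [default_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

run_id <- function(config) {
  # deterministic id: config + seed, no timestamps
  key <- jsonlite::toJSON(config, auto_unbox = TRUE)
  sprintf("run-%08x", sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% .Machine$integer.max)
}

log_line <- function(out_dir, ...) {
  cat(sprintf(...), "\n", sep = "",
      file = file.path(out_dir, "run.log"), append = TRUE)
}

start_cmd <- function(config, name) {
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  id <- run_id(config)
  log_line(out_dir, "[%s] %s %s seed=%d connlda %s", Sys.time(), name, id,
           config$seed, as.character(utils::packageVersion("connlda")))
  log_line(out_dir, "config: %s",
           jsonlite::toJSON(config, auto_unbox = TRUE))
  id
}

write_matrix_csv <- function(M, path) {
  utils::write.table(format(M, digits = 10, trim = TRUE), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}

#' Simulate a synthetic study cohort to disk
#'
#' Writes per-subject R x R connectivity CSVs, a subjects manifest, an
#' item-level phenotype CSV with its scale manifest, the parcellation
#' TSV, and a ground-truth archive (factor profiles and true loadings)
#' for recovery testing.
#'
#' @param config a validated config (see [default_config()]).
#' @return invisibly, the output directory.
#' @export
cmd_simulate <- function(config = default_config()) {
  config <- validate_config(config)
  id <- start_cmd(config, "simulate")
  out <- config$paths$out_dir
  co <- config$cohort
  parc <- default_parcellation(co$n_regions)
  profiles <- generate_factor_profiles(config$model$K, parc,
                                       sparsity = co$sparsity,
                                       block_bias = co$block_bias,
                                       seed = derive_seed(config$seed, 1))
  truth <- ground_truth(profiles, parc, n_sites = co$n_sites,
                        site_effect_sd = co$site_effect_sd)
  cohort <- sample_cohort(truth, co$n_patients, co$dirichlet_alpha,
                          co$noise_sd, seed = derive_seed(config$seed, 2))
  controls <- sample_controls(co$n_controls, parc, co$noise_sd,
                              seed = derive_seed(config$seed, 3))
  K <- config$model$K
  coupling <- list(
    scaleA = list(n_items = 5, factor = 1, items = 1:2, effect = 2),
    scaleB = list(n_items = 5, factor = min(3, K), items = 1:3, effect = 2))
  phen <- sample_phenotypes(cohort$loadings, coupling, noise_sd = 1,
                            seed = derive_seed(config$seed, 4),
                            site = cohort$site,
                            covariates = cohort$covariates)

  mat_dir <- file.path(out, "matrices")
  ctl_dir <- file.path(out, "controls")
  dir.create(mat_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(ctl_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$matrices))
    write_matrix_csv(cohort$matrices[[i]],
                     file.path(mat_dir, sprintf("sub%04d.csv", i)))
  for (i in seq_along(controls$matrices))
    write_matrix_csv(controls$matrices[[i]],
                     file.path(ctl_dir, sprintf("ctl%04d.csv", i)))
  write_parcellation(parc, file.path(out, "parcellation.tsv"))
  manifest <- data.frame(id = sprintf("sub%04d", seq_len(co$n_patients)),
                         group = "patient", site = cohort$site,
                         run = id, cohort$covariates)
  write.csv(manifest, file.path(out, "subjects.csv"), row.names = FALSE)
  write.csv(phen, file.path(out, "phenotypes.csv"), row.names = FALSE)
  jsonlite::write_json(attr(phen, "scales"),
                       file.path(out, "scales.json"))
  write.csv(as.data.frame(unclass(as.matrix(profiles))),
            file.path(out, "truth_profiles.csv"), row.names = FALSE)
  write.csv(as.data.frame(cohort$loadings),
            file.path(out, "truth_loadings.csv"), row.names = FALSE)
  log_line(out, "simulate: wrote %d patients, %d controls",
           co$n_patients, co$n_controls)
  invisible(out)
}

# read all subject matrices in a directory -> deviation documents
load_deviations <- function(dir, reference = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stopf("no matrix CSVs found in %s", dir)
  vecs <- t(vapply(files, function(f) vectorize(read_matrix_csv(f)),
                   numeric(length(vectorize(read_matrix_csv(files[1]))))))
  rownames(vecs) <- sub("\\.csv$", "", basename(files))
  vecs
}

#' Fit the factor model on a simulated or user-supplied cohort directory
#'
#' Reads control and patient matrices from the run directory, fits the
#' covariate-free control reference, deviation-scores and count-encodes
#' the patients, fits the LDA model (with bootstrap profile significance
#' when `stats.n_boot > 0`), and writes the model archive, loadings CSV,
#' and bootstrap CI tables.
#'
#' @param config a validated config whose `paths.out_dir` holds a
#'   [cmd_simulate()] layout (or equivalent user files).
#' @return invisibly, the fitted `factor_profile_ci` (or fit list when
#'   bootstrapping is disabled).
#' @export
cmd_fit <- function(config = default_config()) {
  config <- validate_config(config)
  start_cmd(config, "fit")
  out <- config$paths$out_dir
  parc <- read_parcellation(file.path(out, "parcellation.tsv"))
  ctl <- load_deviations(file.path(out, "controls"))
  pat <- load_deviations(file.path(out, "matrices"))
  reference <- fit_reference(ctl)
  docs <- encode_cohort(pat, reference, parc,
                        scale = config$encoding$scale,
                        clip = config$encoding$clip)
  saveref <- data.frame(edge = edge_labels(parc),
                        mean = reference$coef[1, ],
                        resid_sd = reference$resid_sd)
  write.csv(saveref, file.path(out, "reference.csv"), row.names = FALSE)
  md <- config$model
  alpha <- md$alpha %||% (50 / md$K)
  if (config$stats$n_boot > 0) {
    ci <- bootstrap_profiles(docs, md$K, B = config$stats$n_boot,
                             seed = derive_seed(config$seed, 5),
                             fdr_alpha = config$stats$fdr_alpha,
                             alpha = alpha, eta = md$eta,
                             n_restarts = md$n_restarts,
                             max_iter = md$max_iter, tol = md$tol)
    model <- ci$model; expressions <- ci$expressions
    write.csv(data.frame(factor = rep(seq_len(md$K), each = ncol(ci$z)),
                         edge = rep(edge_labels(parc), md$K),
                         mean = as.vector(t(ci$mean)),
                         sd = as.vector(t(ci$sd)),
                         z = as.vector(t(ci$z)), q = as.vector(t(ci$q)),
                         significant = as.vector(t(ci$mask))),
              file.path(out, "profile_ci.csv"), row.names = FALSE)
  } else {
    fit <- fit_lda(docs, md$K, alpha = alpha, eta = md$eta,
                   n_restarts = md$n_restarts, max_iter = md$max_iter,
                   tol = md$tol, seed = derive_seed(config$seed, 5))
    ci <- fit; model <- fit$model; expressions <- fit$expressions
  }
  save_model(model, file.path(out, "model.json"))
  ld <- as.data.frame(expressions)
  names(ld) <- paste0("factor", seq_len(md$K))
  ld <- cbind(id = rownames(pat), ld)
  write.csv(ld, file.path(out, "loadings.csv"), row.names = FALSE)
  log_line(out, "fit: restart objectives %s",
           paste(sprintf("%.2f", model$restart_elbos), collapse = " "))
  invisible(ci)
}

# deviation-score + encode a matrix of subject edge vectors
encode_cohort <- function(vecs, reference, parc, scale = 10, clip = 3,
                          covariates = NULL) {
  docs <- lapply(seq_len(nrow(vecs)), function(i) {
    cv <- if (is.null(covariates)) NULL else covariates[i, ]
    encode_counts(deviation_score(vecs[i, ], cv, reference),
                  scale = scale, clip = clip)
  })
  attr(docs, "vocabulary") <- edge_vocabulary(parc)
  docs
}

#' Serialize / load a fitted factor model
#'
#' The archive is JSON with a format version, the hyperparameters, the
#' vocabulary labels, and the factor-word matrix. Loading validates the
#' structure; [infer_expression()] additionally validates vocabulary
#' size against supplied documents.
#'
#' @param model a `factor_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(
    list(format = "connlda-model", version = 1L,
         K = model$K, V = model$V, alpha = model$alpha, eta = model$eta,
         vocabulary = model$vocabulary,
         restart_elbos = model$restart_elbos,
         converged = model$converged,
         beta = model$beta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `factor_model`.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "connlda-model"))
    stopf("not a connlda model archive: %s", path)
  beta <- as.matrix(x$beta)
  structure(list(beta = beta, alpha = x$alpha, eta = x$eta, K = x$K,
                 V = x$V, vocabulary = x$vocabulary,
                 fit_log = numeric(0), restart_elbos = x$restart_elbos,
                 best_restart = NA_integer_, converged = x$converged),
            class = "factor_model")
}

#' Infer loadings for unseen subjects from a saved model
#'
#' @param config validated config; `paths.matrices_dir` points at the new
#'   subjects' matrix CSVs (defaults to `<out_dir>/matrices`).
#' @param model_path model archive (defaults to `<out_dir>/model.json`).
#' @return invisibly, the loadings matrix written to
#'   `<out_dir>/inferred_loadings.csv`.
#' @export
cmd_infer <- function(config = default_config(), model_path = NULL) {
  config <- validate_config(config)
  start_cmd(config, "infer")
  out <- config$paths$out_dir
  model <- load_model(model_path %||% file.path(out, "model.json"))
  parc <- read_parcellation(file.path(out, "parcellation.tsv"))
  if (!identical(model$vocabulary, edge_vocabulary(parc)))
    stopf("vocabulary mismatch between model archive and parcellation")
  ref_tab <- read.csv(file.path(out, "reference.csv"))
  reference <- structure(list(coef = matrix(ref_tab$mean, nrow = 1),
                              resid_sd = ref_tab$resid_sd,
                              covariates = character(0),
                              n = NA_integer_),
                         class = "fc_reference")
  dir <- config$paths$matrices_dir %||% file.path(out, "matrices")
  vecs <- load_deviations(dir)
  docs <- encode_cohort(vecs, reference, parc,
                        scale = config$encoding$scale,
                        clip = config$encoding$clip)
  expr <- infer_expression(model, docs)
  ld <- as.data.frame(expr)
  names(ld) <- paste0("factor", seq_len(model$K))
  ld <- cbind(id = rownames(vecs), ld)
  write.csv(ld, file.path(out, "inferred_loadings.csv"), row.names = FALSE)
  invisible(expr)
}

#' Associate fitted loadings with the phenotype table
#'
#' Reads `loadings.csv`, `phenotypes.csv` and the scale manifest from the
#' run directory, runs the CCA + site-permutation + FDR pipeline, and
#' writes `cca_results.csv` and `structural_coefficients.csv`.
#'
#' @param config validated config.
#' @return invisibly, the association result list.
#' @export
cmd_associate <- function(config = default_config()) {
  config <- validate_config(config)
  start_cmd(config, "associate")
  out <- config$paths$out_dir
  ld <- read.csv(file.path(out, "loadings.csv"))
  phen <- read.csv(file.path(out, "phenotypes.csv"))
  scales <- jsonlite::read_json(config$paths$scale_manifest %||%
                                  file.path(out, "scales.json"),
                                simplifyVector = TRUE)
  expr <- as.matrix(ld[, grep("^factor", names(ld)), drop = FALSE])
  covcols <- intersect(config$stats$covariate_columns, names(phen))
  covs <- if (length(covcols)) phen[, covcols, drop = FALSE] else NULL
  site <- phen[[config$stats$site_column]]
  res <- associate_factors(expr, phen, scales, covariates = covs,
                           site = site, n_perm = config$stats$n_perm,
                           seed = derive_seed(config$seed, 6))
  write.csv(res$results, file.path(out, "cca_results.csv"),
            row.names = FALSE)
  write.csv(res$structural,
            file.path(out, "structural_coefficients.csv"),
            row.names = FALSE)
  invisible(res)
}

#' Per-subject Dice overlap against the fitted factor profiles
#'
#' @param config validated config; requires `profile_ci.csv` (i.e.,
#'   [cmd_fit()] with bootstrapping) and the cohort matrices.
#' @param ci optionally, the in-memory `factor_profile_ci` from
#'   [cmd_fit()] (avoids refitting).
#' @return invisibly, the Dice table written to `<out_dir>/dice.csv`.
#' @export
cmd_dice <- function(config = default_config(), ci = NULL) {
  config <- validate_config(config)
  start_cmd(config, "dice")
  out <- config$paths$out_dir
  if (is.null(ci))
    stopf("cmd_dice needs the factor_profile_ci returned by cmd_fit()")
  parc <- read_parcellation(file.path(out, "parcellation.tsv"))
  ref_tab <- read.csv(file.path(out, "reference.csv"))
  reference <- structure(list(coef = matrix(ref_tab$mean, nrow = 1),
                              resid_sd = ref_tab$resid_sd,
                              covariates = character(0), n = NA_integer_),
                         class = "fc_reference")
  vecs <- load_deviations(file.path(out, "matrices"))
  dev <- t(apply(vecs, 1L, deviation_score, covariates = NULL,
                 reference = reference))
  ld <- read.csv(file.path(out, "loadings.csv"))
  expr <- as.matrix(ld[, grep("^factor", names(ld)), drop = FALSE])
  tab <- dice_by_subject(dev, expr, ci,
                         fraction = config$stats$fraction_top)
  tab$subject <- ld$id[tab$subject]
  write.csv(tab, file.path(out, "dice.csv"), row.names = FALSE)
  invisible(tab)
}

#' Summarize a run directory into a markdown report
#'
#' Collects whatever result CSVs exist in the run directory into
#' `report.md` (factor x scale association table, group comparisons,
#' Dice summaries) and lists any missing upstream outputs. Idempotent.
#'
#' @param out_dir run directory.
#' @return invisibly, the report path.
#' @export
cmd_report <- function(out_dir) {
  path <- file.path(out_dir, "report.md")
  lines <- c("# connlda run report", "")
  expect <- c(loadings = "loadings.csv", cca = "cca_results.csv",
              dice = "dice.csv")
  missing <- character(0)
  for (nm in names(expect)) {
    f <- file.path(out_dir, expect[[nm]])
    if (!file.exists(f)) { missing <- c(missing, expect[[nm]]); next }
    tab <- read.csv(f)
    lines <- c(lines, sprintf("## %s (%d rows)", expect[[nm]], nrow(tab)),
               "", "```",
               utils::capture.output(print(head(tab, 20))), "```", "")
  }
  if (length(missing))
    lines <- c(lines, "## Missing upstream outputs", "",
               paste("-", missing), "")
  writeLines(lines, path)
  invisible(path)
}

#' Command-line entry point
#'
#' `connlda_cli(c("simulate", "--config", "cfg.json", "--seed", "7"))`.
#' Subcommands: simulate, fit, infer, associate, report. Flags override
#' config values.
#'
#' @param args character vector (defaults to the process arguments).
#' @return exit status, invisibly.
#' @export
connlda_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: connlda <simulate|fit|infer|associate|report> [--config cfg.json] [--seed N] [--out DIR]\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]; rest <- args[-1L]
  getopt <- function(flag) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1L] + 1L] else NULL
  }
  config <- if (!is.null(getopt("--config"))) read_config(getopt("--config"))
            else default_config()
  if (!is.null(getopt("--seed"))) config$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--out"))) config$paths$out_dir <- getopt("--out")
  switch(cmd,
         simulate = cmd_simulate(config),
         fit = cmd_fit(config),
         infer = cmd_infer(config),
         associate = cmd_associate(config),
         report = cmd_report(config$paths$out_dir),
         stopf("unknown subcommand '%s'", cmd))
  invisible(0L)
}
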