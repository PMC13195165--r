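# End-to-end orchestration: simulate -> aggregate -> downsample ->
# adjust -> varcomp -> arm-assoc -> disease, with a manifest that makes
# the run reproducible.

pipeline_config_keys <- c("simulation", "downsample", "adjust",
                          "analysis", "seed")

#' Read and validate a pipeline configuration file
#'
#' YAML with top-level sections \code{simulation} (fields of
#' \code{\link{sim_config}}), \code{downsample} (\code{targets}),
#' \code{adjust} (\code{k_grid_max}), \code{analysis}
#' (\code{batch_mode}), and \code{seed}. Unknown keys are rejected by
#' name.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  sim_args <- cfg$simulation %||% list()
  known_sim <- names(formals(sim_config))
  unknown_sim <- setdiff(names(sim_args), known_sim)
  if (length(unknown_sim))
    stop("unknown simulation key(s): ",
         paste(unknown_sim, collapse = ", "))
  if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
  if (!is.null(sim_args$variance_fractions))
    sim_args$variance_fractions <- unlist(sim_args$variance_fractions)
  if (!is.null(sim_args$coverage_model))
    sim_args$coverage_model <- unlist(sim_args$coverage_model)
  cfg$sim_config <- do.call(sim_config, sim_args)
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic csTL analysis pipeline
#'
#' Executes all stages in dependency order, writing each stage's table
#' as TSV into \code{outdir}, and returns a manifest (also written as
#' \code{manifest.yaml}) with the config checksum, per-stage seeds,
#' output files, record counts and file checksums; identical
#' configurations yield identical manifests. A failure stops the run
#' with the stage name.
#'
#' @param config Path to a YAML configuration, or a list from
#'   \code{\link{read_pipeline_config}}, or a \code{\link{sim_config}}.
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    config_md5 <- unname(tools::md5sum(config))
    config <- read_pipeline_config(config)
  } else config_md5 <- NA_character_
  if (inherits(config, "sim_config")) config <- list(sim_config = config)
  scfg <- config$sim_config
  stopifnot(inherits(scfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  master <- scfg$seed
  manifest <- list(package_version = as.character(
                     utils::packageVersion("armtel")),
                   config_md5 = config_md5, master_seed = master,
                   stages = list())
  files <- character(0)

  add_stage <- function(name, outputs, counts, seed = NA) {
    manifest$stages[[name]] <<- list(seed = seed, outputs = outputs,
                                     records = counts)
    files <<- c(files, outputs)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # simulate
  cohort <- run_stage("simulate", {
    coh <- make_cohort(scfg)
    coh <- assign_disease(coh)
    f <- file.path(outdir, "metadata.tsv")
    write_tsv(coh$individuals, f)
    add_stage("simulate", f, nrow(coh$individuals), seed = scfg$seed)
    coh
  })

  # reads + calls
  reads_seed <- stage_seed(master, "reads")
  reads <- run_stage("reads", {
    rd <- emit_reads(cohort, seed = reads_seed)
    f <- file.path(outdir, "reads.tsv")
    write_tsv(rd, f)
    add_stage("reads", f, nrow(rd), seed = reads_seed)
    rd
  })

  # aggregate
  thresholds <- scfg$min_reads_per_cluster[
    cohort$individuals$tier]
  names(thresholds) <- cohort$individuals$sample_id
  arm_tab <- run_stage("aggregate", {
    calls <- reads_to_calls(reads, min_reads = thresholds)
    calls <- qc_filter(calls)
    tab <- collapse_to_arm(calls)
    tab <- exclude_arms(tab, "analysis")
    tab <- merge(tab, cohort$individuals[, c("sample_id", "age", "sex",
                                             "ancestry", "smoking",
                                             "bmi", "batch")],
                 by = "sample_id", sort = TRUE)
    tab$arm <- factor(tab$arm, levels = analysis_arms())
    summ <- sample_summaries(tab)
    f1 <- file.path(outdir, "arm_table.tsv")
    f2 <- file.path(outdir, "sample_summaries.tsv")
    write_tsv(tab, f1); write_tsv(summ, f2)
    add_stage("aggregate", c(f1, f2), c(nrow(tab), nrow(summ)))
    tab
  })

  # downsample
  ds_seed <- stage_seed(master, "downsample")
  run_stage("downsample", {
    targets <- config$downsample$targets %||% c(25, 20, 15, 10, 5)
    cur <- min(table(reads$sample_id)) / 92
    targets <- targets[targets <= cur]
    if (length(targets)) {
      prof <- run_downsampling(reads, targets = targets, seed = ds_seed)
      f <- file.path(outdir, "downsample_profile.tsv")
      write_tsv(as.data.frame(prof), f)
      add_stage("downsample", f, nrow(prof), seed = ds_seed)
    }
    invisible(NULL)
  })

  # adjust (depth PCs + batch residualization)
  adj_seed <- stage_seed(master, "depth")
  run_stage("adjust", {
    dep <- emit_depth_and_average_tl(cohort, seed = adj_seed)
    pcs <- depth_pcs(dep$depth)
    kmax <- config$adjust$k_grid_max %||% 50
    ind <- cohort$individuals
    adj <- select_k_and_adjust(dep$average_tl$telseq_tl, pcs, ind$age,
                               k_grid = 0:kmax)
    out <- data.frame(sample_id = ind$sample_id,
                      telseq_tl = dep$average_tl$telseq_tl,
                      adjusted_tl = adj$adjusted,
                      k_used = adj$k_used)
    f1 <- file.path(outdir, "adjusted_tl.tsv")
    f2 <- file.path(outdir, "k_selection.tsv")
    write_tsv(out, f1); write_tsv(adj$curve, f2)
    add_stage("adjust", c(f1, f2), c(nrow(out), nrow(adj$curve)),
              seed = adj_seed)
    invisible(NULL)
  })

  # varcomp
  decomposition <- run_stage("varcomp", {
    bm <- config$analysis$batch_mode %||% "fixed"
    dec <- variance_decomposition(arm_tab, batch_mode = bm)
    f <- file.path(outdir, "variance_decomposition.tsv")
    write_tsv(as.data.frame(dec), f)
    add_stage("varcomp", f, nrow(dec))
    dec
  })

  # arm association
  run_stage("arm_assoc", {
    assoc <- per_arm_ols(arm_tab, "age",
                         adjusters = c("sex", "ancestry", "smoking",
                                       "bmi", "batch"))
    st <- sign_binomial(assoc, "negative")
    anova_res <- arm_anova(arm_tab)
    assoc$mean_cstl <- as.vector(anova_res$means[assoc$arm])
    f <- file.path(outdir, "arm_associations.tsv")
    write_tsv(as.data.frame(assoc), f)
    sign_tab <- data.frame(test = "age_negative", n_arms = st$n_arms,
                           n_in_direction = st$n_in_direction,
                           p_hat = st$p_hat, ci_lower = st$ci[["lower"]],
                           p_value = st$p_value,
                           anova_F = anova_res$F,
                           anova_df1 = anova_res$df1)
    f2 <- file.path(outdir, "sign_tests.tsv")
    write_tsv(sign_tab, f2)
    add_stage("arm_assoc", c(f, f2), c(nrow(assoc), 1L))
    invisible(NULL)
  })

  # disease
  run_stage("disease", {
    summ <- sample_summaries(arm_tab)
    met <- tl_metrics_with_exclusion(summ)
    dat <- merge(met, cohort$individuals, by = "sample_id")
    rows <- list()
    for (dz in intersect(names(scfg$disease_params),
                         names(cohort$individuals))) {
      for (m in c("mean_tl_kb", "shortest_tl_kb")) {
        res <- try(logistic_or(dat, dz, m,
                               adjusters = c("age", "sex", "bmi",
                                             "smoking", "ancestry",
                                             "batch")), silent = TRUE)
        if (inherits(res, "try-error")) {
          # separation can occur in small cohorts; record and move on
          rows[[paste(dz, m)]] <- data.frame(
            outcome = dz, metric = m, or = NA_real_,
            ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
            n_cases = sum(dat[[dz]], na.rm = TRUE),
            n_excluded = attr(met, "n_excluded"))
          next
        }
        rows[[paste(dz, m)]] <- data.frame(
          outcome = dz, metric = m, or = res$or,
          ci_lower = res$ci[["lower"]], ci_upper = res$ci[["upper"]],
          p = res$p, n_cases = res$n_cases,
          n_excluded = attr(met, "n_excluded"))
      }
    }
    dtab <- do.call(rbind, rows)
    f <- file.path(outdir, "disease_associations.tsv")
    write_tsv(dtab, f)
    add_stage("disease", f, nrow(dtab))
    invisible(NULL)
  })

  manifest$files <- data.frame(file = basename(files),
                               md5 = unname(tools::md5sum(files)),
                               stringsAsFactors = FALSE)
  yaml::write_yaml(list(
    package_version = manifest$package_version,
    config_md5 = manifest$config_md5,
    master_seed = manifest$master_seed,
    stages = manifest$stages,
    files = stats::setNames(as.list(manifest$files$md5),
                            manifest$files$file)),
    file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
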