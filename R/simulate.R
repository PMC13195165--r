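#' Default sequencing batch design
#'
#' Six batches spanning three platforms (Sequel IIe, Revio, ONT), two
#' coverage tiers (high-pass, mid-pass) and several centers, with
#' per-batch ancestry mixing weights. Batch is deliberately confounded
#' with ancestry (one batch is single-ancestry), emulating cohorts in
#' which sequencing site and recruitment population overlap.
#'
#' @return data.frame with one row per batch: \code{batch_id},
#'   \code{center}, \code{platform}, \code{tier} (\code{"high"} or
#'   \code{"mid"}), sampling \code{weight}, and ancestry mixing weights
#'   \code{AFR}, \code{AMR}, \code{EUR}, \code{Other}.
#' @export
default_batch_design <- function() {
  data.frame(
    batch_id = c("HA_SequelIIe_mid", "BI_Revio_mid", "BCM_ONT_mid",
                 "BCM_SequelIIe_high", "UW_Revio_high", "BI_SequelIIe_high"),
    center   = c("HA", "BI", "BCM", "BCM", "UW", "BI"),
    platform = c("SequelIIe", "Revio", "ONT", "SequelIIe", "Revio",
                 "SequelIIe"),
    tier     = c("mid", "mid", "mid", "high", "high", "high"),
    weight   = c(0.38, 0.28, 0.10, 0.09, 0.06, 0.09),
    AFR      = c(0.85, 0.27, 0.00, 0.28, 0.24, 0.25),
    AMR      = c(0.06, 0.26, 1.00, 0.45, 0.70, 0.44),
    EUR      = c(0.06, 0.27, 0.00, 0.17, 0.00, 0.17),
    Other    = c(0.03, 0.20, 0.00, 0.10, 0.06, 0.14),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic csTL cohorts
#'
#' Defines the data-generating conditions for synthetic chromosome-
#' specific telomere length (csTL) cohorts. Total csTL variance
#' (\code{total_sd}^2) is partitioned by \code{variance_fractions} among
#' an individual random intercept, a chromosome-arm effect, batch
#' offsets, covariate effects (age, sex, smoking, BMI, ancestry) and an
#' allele-shared residual; the remainder of the unit is absorbed by the
#' residual. Arm-specific age slopes are coupled to arm mean TL via
#' \code{age_slope_coupling} (slope_a proportional to
#' (mean_a/grand mean)^coupling), so longer arms decline faster with age
#' when coupling is positive.
#'
#' @param n_individuals Number of simulated participants.
#' @param age_range Uniform age range in years.
#' @param variance_fractions Named non-negative fractions of total csTL
#'   variance for components \code{individual}, \code{arm}, \code{batch},
#'   \code{age}, \code{sex}, \code{smoking}, \code{bmi}, \code{ancestry};
#'   must sum to at most 1 (residual takes the remainder).
#' @param total_sd Total csTL standard deviation, bp.
#' @param grand_mean_tl Cohort grand mean csTL, bp.
#' @param arm_mean_profile Named length-48 profile giving the relative
#'   ordering of arm mean TLs (bp scale; deviations are rescaled to the
#'   configured arm fraction).
#' @param age_slope_coupling Unitless exponent linking arm-specific age
#'   slope magnitude to arm mean TL (0 = homogeneous slopes).
#' @param coverage_model Mean supporting reads per allele site (Poisson
#'   rate) by coverage tier, e.g. \code{c(high = 8, mid = 4)}.
#' @param read_noise_sd Per-read TL measurement noise SD, bp.
#' @param allele_sd SD of the symmetric split between the two allele TLs
#'   of an autosomal arm, bp.
#' @param min_reads_per_cluster Minimum supporting reads required to emit
#'   an allele estimate, by tier (default 4 for high-coverage batches,
#'   3 otherwise, mirroring common long-read TL calling practice).
#' @param batch_design Batch table as \code{\link{default_batch_design}}.
#' @param p_female,p_never_smoker Covariate prevalences.
#' @param bmi_mean,bmi_sd BMI distribution, kg/m^2.
#' @param disease_params Named list of disease generators; each element
#'   has \code{metric} (\code{"shortest_tl"} or \code{"mean_tl"}),
#'   \code{or_per_kb} (odds ratio per 1 kb of the metric) and either
#'   \code{prevalence} (target prevalence at the metric mean) or an
#'   explicit logistic \code{intercept}.
#' @param seed Master seed; all randomness in the generator flows through
#'   seeds derived from it, so identical configs give identical cohorts.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 500,
                       age_range = c(18, 90),
                       variance_fractions = c(individual = 0.089,
                                              arm = 0.091,
                                              batch = 0.146,
                                              age = 0.037,
                                              sex = 0.011,
                                              smoking = 0.004,
                                              bmi = 0.002,
                                              ancestry = 0),
                       total_sd = 1500,
                       grand_mean_tl = 4200,
                       arm_mean_profile = default_arm_profile(),
                       age_slope_coupling = 1,
                       coverage_model = c(high = 8, mid = 4),
                       read_noise_sd = 500,
                       allele_sd = 200,
                       min_reads_per_cluster = c(high = 4, mid = 3),
                       batch_design = default_batch_design(),
                       p_female = 0.648,
                       p_never_smoker = 0.644,
                       bmi_mean = 30.8,
                       bmi_sd = 7.8,
                       disease_params = list(
                         CVD = list(metric = "shortest_tl",
                                    or_per_kb = 0.94, prevalence = 0.30),
                         T2D = list(metric = "mean_tl",
                                    or_per_kb = 1.00, prevalence = 0.12)),
                       seed = 1L) {
  comp <- c("individual", "arm", "batch", "age", "sex", "smoking", "bmi",
            "ancestry")
  vf <- rep(0, length(comp))
  names(vf) <- comp
  if (length(variance_fractions)) {
    unknown <- setdiff(names(variance_fractions), comp)
    if (length(unknown))
      stop("unknown variance component(s): ", paste(unknown, collapse = ", "))
    vf[names(variance_fractions)] <- variance_fractions
  }
  if (any(vf < 0))
    stop("configuration error: variance fractions must be non-negative")
  if (sum(vf) > 1 + 1e-12)
    stop("configuration error: variance fractions sum to ",
         signif(sum(vf), 4), " > 1")
  if (!all(arm_labels() %in% names(arm_mean_profile)))
    stop("arm_mean_profile must cover all 48 collapsed arm labels")
  if (any(coverage_model <= 0))
    stop("configuration error: coverage rates must be > 0")
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2],
            total_sd > 0, n_individuals >= 1)
  cfg <- list(n_individuals = as.integer(n_individuals),
              age_range = age_range,
              variance_fractions = vf,
              total_sd = total_sd,
              grand_mean_tl = grand_mean_tl,
              arm_mean_profile = arm_mean_profile[arm_labels()],
              age_slope_coupling = age_slope_coupling,
              coverage_model = coverage_model,
              read_noise_sd = read_noise_sd,
              allele_sd = allele_sd,
              min_reads_per_cluster = min_reads_per_cluster,
              batch_design = batch_design,
              p_female = p_female,
              p_never_smoker = p_never_smoker,
              bmi_mean = bmi_mean,
              bmi_sd = bmi_sd,
              disease_params = disease_params,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic csTL cohort configuration\n")
  cat(sprintf("  individuals: %d, ages %g-%g yr, seed %d\n",
              x$n_individuals, x$age_range[1], x$age_range[2], x$seed))
  cat(sprintf("  total SD: %g bp, grand mean: %g bp\n",
              x$total_sd, x$grand_mean_tl))
  vf <- x$variance_fractions
  cat("  variance fractions:",
      paste(sprintf("%s %.3f", names(vf), vf), collapse = ", "),
      sprintf("(residual %.3f)\n", 1 - sum(vf)))
  invisible(x)
}

# Arm-level building blocks derived from a config: arm means (bp) and
# arm-specific age slopes (bp/yr), both calibrated so that the configured
# fractions of total variance are met across the 39 analysis arms.
arm_effect_profile <- function(config, age_var) {
  arms <- arm_labels()
  ana <- analysis_arms()
  Tvar <- config$total_sd^2
  f <- config$variance_fractions
  prof <- config$arm_mean_profile[arms]
  dev <- prof - mean(prof[ana])
  s <- stats::sd(dev[ana])
  scale <- if (f[["arm"]] > 0 && s > 0) sqrt(f[["arm"]] * Tvar) / s else 0
  arm_mean <- config$grand_mean_tl + scale * dev
  # age slopes: negative, magnitude coupled to arm mean
  rel <- (pmax(arm_mean, 1) / mean(arm_mean[ana]))^config$age_slope_coupling
  if (f[["age"]] > 0 && age_var > 0) {
    b <- sqrt(f[["age"]] * Tvar / (mean(rel[ana]^2) * age_var))
  } else b <- 0
  list(arm_mean = arm_mean, age_slope = -b * rel)
}

#' Simulate a cohort of true chromosome-specific telomere lengths
#'
#' Draws participant covariates, batch membership (with batch-ancestry
#' confounding), and true telomere lengths at all 92 telomeric sites per
#' individual. The true collapsed csTL of individual i at arm a is
#' \deqn{grand mean + arm_a + ind_i + batch_{b(i)} + covariate effects +
#'   slope_a (age_i - mean age) + e_{ia},}
#' and the two allele TLs of an autosomal arm are csTL +/- d with
#' d ~ N(0, allele_sd). Each drawn component is centered and rescaled to
#' its exact configured share of total variance across the analysis-arm
#' records, so the configured fractions hold in-sample, not merely in
#' expectation. True TLs are floored at 50 bp (rarely binding at the
#' default scale).
#'
#' @param config A \code{\link{sim_config}}.
#' @return Object of class \code{cstl_cohort}: list with
#'   \code{individuals} (one row per participant: covariates, batch,
#'   true individual intercept and batch offset), \code{sites} (92 rows
#'   per participant: \code{sample_id}, \code{arm}, \code{allele},
#'   \code{tl_true}), \code{arm_means}, \code{age_slopes} and the config.
#' @examples
#' coh <- make_cohort(sim_config(n_individuals = 20, seed = 7))
#' table(table(coh$sites$sample_id))  # 92 sites each
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_individuals
    Tvar <- config$total_sd^2
    f <- config$variance_fractions
    bd <- config$batch_design
    arms <- arm_labels()
    ana <- analysis_arms()

    ids <- sprintf("S%05d", seq_len(n))
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- factor(ifelse(stats::runif(n) < config$p_female,
                         "female", "male"), levels = c("female", "male"))
    smoking <- factor(ifelse(stats::runif(n) < config$p_never_smoker,
                             "never", "ever"), levels = c("never", "ever"))
    bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
    batch <- sample(bd$batch_id, n, replace = TRUE,
                    prob = bd$weight / sum(bd$weight))
    bi <- match(batch, bd$batch_id)
    anc_levels <- c("AFR", "AMR", "EUR", "Other")
    mix <- as.matrix(bd[, anc_levels])
    ancestry <- vapply(bi, function(i) {
      sample(anc_levels, 1L, prob = mix[i, ])
    }, character(1))
    ancestry <- factor(ancestry, levels = anc_levels)
    # reference level for batch = largest realized batch
    batch <- factor(batch,
                    levels = names(sort(table(batch), decreasing = TRUE)))

    # individual-level effect columns, each scaled to its exact variance
    ind_eff <- scale_to_sd(stats::rnorm(n), sqrt(f[["individual"]] * Tvar))
    b_raw <- stats::rnorm(nrow(bd))
    batch_eff <- scale_to_sd(b_raw[bi], sqrt(f[["batch"]] * Tvar))
    age_c <- age - mean(age)
    sex_eff <- -scale_to_sd(as.numeric(sex == "male"),
                            sqrt(f[["sex"]] * Tvar))
    smoke_eff <- -scale_to_sd(as.numeric(smoking == "ever"),
                              sqrt(f[["smoking"]] * Tvar))
    bmi_eff <- -scale_to_sd(bmi, sqrt(f[["bmi"]] * Tvar))
    anc_base <- c(AFR = 0, AMR = -1, EUR = -1.5, Other = -0.5)
    anc_eff <- scale_to_sd(anc_base[as.character(ancestry)],
                           sqrt(f[["ancestry"]] * Tvar))

    prof <- arm_effect_profile(config, stats::var(age_c))
    arm_mean <- prof$arm_mean
    slope <- prof$age_slope

    # residual, shared by the two alleles of an arm
    f_res <- max(0, 1 - sum(f))
    E <- matrix(stats::rnorm(n * length(arms)), n, length(arms),
                dimnames = list(ids, arms))
    E[, ] <- scale_to_sd(as.vector(E), sqrt(f_res * Tvar))

    # true collapsed csTL: n x 48
    person <- ind_eff + batch_eff + sex_eff + smoke_eff + bmi_eff + anc_eff
    cstl <- outer(person, rep(1, length(arms))) +
      outer(rep(1, n), arm_mean) +
      outer(age_c, rep(1, length(arms))) *
        outer(rep(1, n), slope) + E
    cstl <- pmax(cstl, 50)

    # allele split (autosomal arms carry two copies)
    auto <- setdiff(arms, sex_chromosome_arms())
    d <- matrix(stats::rnorm(n * length(auto), 0, config$allele_sd),
                n, length(auto), dimnames = list(ids, auto))
    sites <- rbind(
      data.frame(sample_id = rep(ids, length(auto)),
                 arm = rep(auto, each = n),
                 allele = 1L,
                 tl_true = pmax(as.vector(cstl[, auto] + d), 50)),
      data.frame(sample_id = rep(ids, length(auto)),
                 arm = rep(auto, each = n),
                 allele = 2L,
                 tl_true = pmax(as.vector(cstl[, auto] - d), 50)),
      data.frame(sample_id = rep(ids, length(sex_chromosome_arms())),
                 arm = rep(sex_chromosome_arms(), each = n),
                 allele = 1L,
                 tl_true = pmax(as.vector(
                   cstl[, sex_chromosome_arms()]), 50))
    )
    sites <- sites[order(sites$sample_id, match(sites$arm, arms),
                         sites$allele), , drop = FALSE]
    rownames(sites) <- NULL

    individuals <- data.frame(
      sample_id = ids, age = age, sex = sex, ancestry = ancestry,
      smoking = smoking, bmi = bmi, batch = batch,
      tier = bd$tier[bi],
      true_ind_effect = ind_eff, true_batch_effect = batch_eff,
      stringsAsFactors = FALSE)

    out <- list(individuals = individuals, sites = sites,
                arm_means = arm_mean, age_slopes = slope,
                config = config)
    class(out) <- "cstl_cohort"
    out
  })
}

#' @export
print.cstl_cohort <- function(x, ...) {
  cat(sprintf("Synthetic csTL cohort: %d individuals, %d telomeric sites\n",
              nrow(x$individuals), nrow(x$sites)))
  cat(sprintf("  batches: %s\n",
              paste(levels(x$individuals$batch), collapse = ", ")))
  if (!is.null(x$individuals$CVD))
    cat(sprintf("  disease flags: %s\n",
                paste(intersect(c("CVD", "T2D", names(x$config$disease_params)),
                                names(x$individuals)), collapse = ", ")))
  invisible(x)
}

#' True collapsed csTL table from a simulated cohort
#'
#' Collapses the cohort's true allele TLs to one csTL per individual and
#' arm (the arithmetic mean of allele values; the symmetric allele split
#' cancels so this equals the generative csTL), applies the requested arm
#' exclusions and attaches covariates. This is the noise-free modeling
#' substrate used to validate variance-component recovery; the read-level
#' path (\code{\link{emit_reads}} + \code{\link{collapse_to_arm}}) adds
#' the measurement layer.
#'
#' @param cohort A \code{cstl_cohort}.
#' @param mode Arm exclusion mode as in \code{\link{exclude_arms}}, or
#'   \code{"none"}.
#' @return data.frame with columns \code{sample_id}, \code{arm} (factor),
#'   \code{cstl}, \code{n_allele_estimates} and the covariates.
#' @export
true_arm_table <- function(cohort, mode = c("analysis", "acrocentric_p",
                                            "none")) {
  stopifnot(inherits(cohort, "cstl_cohort"))
  mode <- match.arg(mode)
  s <- cohort$sites
  uids <- unique(s$sample_id)
  arms <- arm_labels()
  code <- (match(s$sample_id, uids) - 1L) * length(arms) +
    match(s$arm, arms)
  sums <- rowsum(s$tl_true, code)
  counts <- rowsum(rep(1L, nrow(s)), code)
  ucode <- as.integer(rownames(sums))
  tab <- data.frame(
    sample_id = uids[(ucode - 1L) %/% length(arms) + 1L],
    arm = arms[(ucode - 1L) %% length(arms) + 1L],
    cstl = as.vector(sums) / as.vector(counts),
    n_allele_estimates = as.integer(counts),
    stringsAsFactors = FALSE)
  if (mode != "none") tab <- exclude_arms(tab, mode)
  tab <- merge(tab, cohort$individuals[, c("sample_id", "age", "sex",
                                           "ancestry", "smoking", "bmi",
                                           "batch")],
               by = "sample_id", sort = TRUE)
  keep <- if (mode == "analysis") analysis_arms()
          else if (mode == "acrocentric_p") setdiff(arm_labels(),
                                                    acrocentric_p_arms())
          else arm_labels()
  tab$arm <- factor(tab$arm, levels = keep)
  tab[order(tab$sample_id, as.integer(tab$arm)), , drop = FALSE]
}

#' Emit a synthetic read-level telomere call table
#'
#' For each telomeric site the number of supporting reads is Poisson with
#' the batch tier's coverage rate; each read's TL is the site's true TL
#' plus Gaussian measurement noise, floored at 0. Total read length adds
#' a subtelomeric anchor segment.
#'
#' @param cohort A \code{cstl_cohort}.
#' @param config Optional \code{sim_config} overriding the cohort's.
#' @param seed Seed (default derived from the config seed).
#' @return data.frame: \code{sample_id}, \code{arm}, \code{allele},
#'   \code{read_tl_bp}, \code{read_len_bp}.
#' @export
emit_reads <- function(cohort, config = cohort$config, seed = NULL) {
  stopifnot(inherits(cohort, "cstl_cohort"))
  seed <- seed %||% stage_seed(config$seed, "reads")
  with_seed(seed, {
    s <- cohort$sites
    tier <- cohort$individuals$tier[match(s$sample_id,
                                          cohort$individuals$sample_id)]
    rate <- unname(config$coverage_model[tier])
    if (anyNA(rate)) stop("coverage_model missing a tier present in cohort")
    nreads <- stats::rpois(nrow(s), rate)
    idx <- rep.int(seq_len(nrow(s)), nreads)
    if (!length(idx)) {
      return(data.frame(sample_id = character(), arm = character(),
                        allele = integer(), read_tl_bp = numeric(),
                        read_len_bp = numeric()))
    }
    tl <- pmax(s$tl_true[idx] +
                 stats::rnorm(length(idx), 0, config$read_noise_sd), 0)
    anchor <- stats::runif(length(idx), 3000, 15000)
    data.frame(sample_id = s$sample_id[idx], arm = s$arm[idx],
               allele = s$allele[idx], read_tl_bp = tl,
               read_len_bp = tl + anchor, stringsAsFactors = FALSE)
  })
}

#' Emit a synthetic binned depth matrix and average-TL table
#'
#' The depth matrix carries a low-rank batch structure: three latent
#' factors with batch-level scores and random bin loadings, plus i.i.d.
#' noise. The short-read-style average TL per sample is the mean of the
#' individual's true arm TLs plus a linear artifact in the same latent
#' factors (weight \code{artifact_sd}) and measurement noise, emulating
#' batch contamination of k-mer-based average TL estimates.
#'
#' @param cohort A \code{cstl_cohort}.
#' @param n_bins Number of depth bins (columns).
#' @param artifact_sd SD (bp) of the batch artifact added to average TL;
#'   0 gives an artifact-free average TL.
#' @param depth_noise_sd,tl_noise_sd Noise SDs for depth and average TL.
#' @param rank Number of latent batch factors.
#' @param seed Seed (default derived from the config seed).
#' @return list with \code{depth} (samples x bins matrix),
#'   \code{average_tl} (data.frame: \code{sample_id}, \code{telseq_tl},
#'   \code{true_mean_tl}) and the latent \code{scores}.
#' @export
emit_depth_and_average_tl <- function(cohort, n_bins = 200,
                                      artifact_sd = 500,
                                      depth_noise_sd = 1,
                                      tl_noise_sd = 200,
                                      rank = 3, seed = NULL) {
  stopifnot(inherits(cohort, "cstl_cohort"))
  seed <- seed %||% stage_seed(cohort$config$seed, "depth")
  with_seed(seed, {
    ind <- cohort$individuals
    n <- nrow(ind)
    bd <- cohort$config$batch_design
    bi <- match(as.character(ind$batch), bd$batch_id)
    # batch-level factor scores: each latent factor takes one value per batch
    batch_scores <- matrix(stats::rnorm(nrow(bd) * rank), nrow(bd), rank)
    S <- batch_scores[bi, , drop = FALSE]
    L <- matrix(stats::rnorm(rank * n_bins, 0, 2), rank, n_bins)
    depth <- 30 + S %*% L +
      matrix(stats::rnorm(n * n_bins, 0, depth_noise_sd), n, n_bins)
    rownames(depth) <- ind$sample_id
    colnames(depth) <- sprintf("bin%04d", seq_len(n_bins))

    tab <- true_arm_table(cohort, mode = "none")
    mean_true <- tapply(tab$cstl, tab$sample_id, mean)[ind$sample_id]
    w <- stats::rnorm(rank)
    art <- as.vector(S %*% w)
    art <- if (artifact_sd > 0) scale_to_sd(art, artifact_sd) else 0 * art
    telseq <- as.numeric(mean_true) + art +
      stats::rnorm(n, 0, tl_noise_sd)
    list(depth = depth,
         average_tl = data.frame(sample_id = ind$sample_id,
                                 telseq_tl = telseq,
                                 true_mean_tl = as.numeric(mean_true),
                                 stringsAsFactors = FALSE),
         scores = S)
  })
}

#' Assign disease status by a logistic model on a TL metric
#'
#' Case probability follows a logistic link on the chosen per-individual
#' TL metric in kb: P(case) = plogis(intercept + log(or_per_kb) * metric).
#' When no explicit intercept is given it is chosen so prevalence at the
#' metric mean equals the configured target.
#'
#' @param cohort A \code{cstl_cohort}.
#' @param summaries Optional \code{\link{sample_summaries}} table; by
#'   default computed from the cohort's true csTLs (analysis arms).
#' @param disease_params As in \code{\link{sim_config}}.
#' @param seed Seed (default derived from the config seed).
#' @return The cohort with one logical flag column per disease added to
#'   \code{individuals}.
#' @export
assign_disease <- function(cohort, summaries = NULL,
                           disease_params = cohort$config$disease_params,
                           seed = NULL) {
  stopifnot(inherits(cohort, "cstl_cohort"))
  seed <- seed %||% stage_seed(cohort$config$seed, "disease")
  if (is.null(summaries)) {
    tab <- true_arm_table(cohort, mode = "analysis")
    summaries <- sample_summaries(tab)
  }
  ind <- cohort$individuals
  m <- match(ind$sample_id, summaries$sample_id)
  with_seed(seed, {
    for (dz in names(disease_params)) {
      p <- disease_params[[dz]]
      metric_kb <- summaries[[p$metric]][m] / 1000
      slope <- log(p$or_per_kb)
      a <- if (!is.null(p$intercept)) p$intercept
           else stats::qlogis(p$prevalence) - slope * mean(metric_kb,
                                                           na.rm = TRUE)
      pr <- stats::plogis(a + slope * metric_kb)
      pr[is.na(pr)] <- 0
      ind[[dz]] <- stats::runif(nrow(ind)) < pr
    }
    cohort$individuals <- ind
    cohort
  })
}
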