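#' Simulation configuration
#'
#' Generative settings for the synthetic cohorts used to validate every
#' pipeline stage against known ground truth. Defaults emulate the study
#' conditions of the human blood cohorts: per-sample true rDNA copy
#' number uniform on 150-600 copies per diploid genome, 14x single-copy
#' exome depth with per-base Poisson noise, a copy-number/methylation
#' Spearman coupling of 0.74 at n = 63 imposed through a Gaussian copula
#' with a Beta methylation marginal, multinomial-style RRBS read
#' allocation out of 5 million alignments, and a weak negative BMI/copy-
#' number correlation. The `two_group` design instead draws a lean and an
#' obese group (31/32) whose true copy numbers differ by
#' `cn_group_shift_sd` cohort standard deviations.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_samples Cohort size (continuous design).
#' @param design `"continuous"` or `"two_group"`.
#' @param n_lean,n_obese Group sizes for the two-group design.
#' @param cn_group_shift_sd Downward shift of obese-group true copy
#'   number, in units of the copy-number SD (default 0.8).
#' @param cn_min,cn_max Range of the uniform true copy-number law.
#' @param exome_depth Mean per-base exome depth (default 14).
#' @param exome_bases,len_18s Simulated region sizes in bases (desk-scale
#'   stand-ins for the exome reference and the 18S interval).
#' @param rho_cm Target Spearman correlation between true copy number and
#'   per-sample mean rDNA methylation (default 0.74).
#' @param meth_mean,meth_concentration Beta marginal of the per-sample
#'   mean methylation fraction (mean and concentration a+b).
#' @param cpg_dispersion Beta dispersion of per-CpG methylation around
#'   the sample mean (larger = tighter).
#' @param n_cpgs CpGs laid out evenly across the simulated rDNA interval.
#' @param rrbs_total_reads Total alignments per RRBS library.
#' @param rrbs_prob_per_copy Per-copy probability that an alignment hits
#'   the rDNA contig (so rDNA fraction = CN times this).
#' @param bmi_cn_r Standardised slope (correlation) of BMI on true copy
#'   number in the continuous design (default -0.18).
#' @param bmi_mean,bmi_sd BMI marginal (kg/m^2).
#' @param age_min,age_max Uniform age range (years).
#' @param ddpcr_noise_cv,ddpcr_reference_concentration,lambda_meanlog,lambda_sdlog
#'   Droplet-PCR well generation: multiplicative concentration noise,
#'   VIC-channel reference concentration, and the log-normal law of
#'   Lambda (copies per partition).
#' @param emit Which observation layers to generate (subset of
#'   `"depth"`, `"cpg"`, `"rrbs"`, `"ddpcr"`, `"metrics"`); replicated
#'   power studies can skip the expensive per-base layers they do not
#'   read.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_samples = 63L,
                       design = c("continuous", "two_group"),
                       n_lean = 31L, n_obese = 32L,
                       cn_group_shift_sd = 0.8,
                       cn_min = 150, cn_max = 600,
                       exome_depth = 14,
                       exome_bases = 50000L, len_18s = 1874L,
                       rho_cm = 0.74,
                       meth_mean = 0.25, meth_concentration = 25,
                       cpg_dispersion = 60,
                       n_cpgs = 200L,
                       rrbs_total_reads = 5e6,
                       rrbs_prob_per_copy = 1.2e-5,
                       bmi_cn_r = -0.18,
                       bmi_mean = 27, bmi_sd = 4,
                       age_min = 25, age_max = 65,
                       ddpcr_noise_cv = 0.05,
                       ddpcr_reference_concentration = 100,
                       lambda_meanlog = log(0.5), lambda_sdlog = 0.5,
                       emit = c("depth", "cpg", "rrbs", "ddpcr",
                                "metrics")) {
  design <- match.arg(design)
  emit <- match.arg(emit, several.ok = TRUE)
  stopifnot(cn_min > 0, cn_max > cn_min, exome_depth > 0,
            meth_mean > 0, meth_mean < 1, meth_concentration > 0,
            rrbs_prob_per_copy > 0, abs(bmi_cn_r) <= 1)
  if (abs(rho_cm) > 0.99) {
    stop("infeasible copy-number/methylation correlation target: |rho| ",
         "must be <= 0.99 for the chosen marginals")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Spearman target -> Gaussian copula correlation (exact for continuous
# marginals): rho_z = 2 sin(pi rho_s / 6).
copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a ground-truthed bisulfite cohort
#'
#' Draws latent per-sample truth (copy number, mean rDNA methylation,
#' active copy number, BMI, age) and emits observation-level inputs for
#' every estimator: per-base depth tables over the rDNA 18S and exome
#' intervals (Poisson around depth proportional to copy number),
#' bismark-style CpG count tables (beta-binomial around the sample mean
#' methylation), RRBS read-count summaries (binomial allocation with
#' rDNA probability proportional to copy number), droplet-PCR wells, and
#' nominal per-sample QC metrics.
#'
#' @param config A [sim_config()].
#' @return List with `truth` (`data.frame` keyed by `sample_id`),
#'   `depth` (list of per-sample depth tables), `regions` (region table
#'   for [depth_from_alignments()]), `cpg` (list of per-sample CpG
#'   record tables), `rrbs` (read-count summary `data.frame`), `ddpcr`
#'   (well table), `metrics` (QC metrics table), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    if (config$design == "two_group") {
      n <- config$n_lean + config$n_obese
      group <- c(rep("lean", config$n_lean), rep("obese", config$n_obese))
    } else {
      n <- config$n_samples
      group <- rep(NA_character_, n)
    }
    ids <- sprintf("S%03d", seq_len(n))

    rho_z <- copula_rho(config$rho_cm)
    z1 <- stats::rnorm(n)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
    cn <- stats::qunif(stats::pnorm(z1), config$cn_min, config$cn_max)
    if (config$design == "two_group") {
      sd_cn <- (config$cn_max - config$cn_min) / sqrt(12)
      cn <- cn - (group == "obese") * config$cn_group_shift_sd * sd_cn
      cn <- pmax(cn, 10)
    }
    a <- config$meth_mean * config$meth_concentration
    b <- (1 - config$meth_mean) * config$meth_concentration
    m <- stats::qbeta(stats::pnorm(z2), a, b)

    if (config$design == "two_group") {
      bmi <- ifelse(group == "lean",
                    stats::runif(n, 19, 24.9), stats::runif(n, 30.1, 42))
    } else {
      bmi <- config$bmi_mean +
        config$bmi_cn_r * config$bmi_sd * z1 +
        sqrt(1 - config$bmi_cn_r^2) * config$bmi_sd * stats::rnorm(n)
    }
    age <- stats::runif(n, config$age_min, config$age_max)

    regions <- data.frame(
      name = c("18S", "exome"),
      contig = c("rDNA_looped", "exome"),
      start = c(0L, 0L),
      end = c(config$len_18s, config$exome_bases))

    depth <- NULL
    cpg <- NULL
    cpg_pos <- as.integer(round(seq(0, config$len_18s - 1,
                                    length.out = config$n_cpgs)))
    if ("depth" %in% config$emit) {
      depth <- lapply(seq_len(n), function(i) {
        d18 <- stats::rpois(config$len_18s,
                            cn[i] / 2 * config$exome_depth)
        dex <- stats::rpois(config$exome_bases, config$exome_depth)
        data.frame(
          contig = c(rep("rDNA_looped", config$len_18s),
                     rep("exome", config$exome_bases)),
          pos = c(seq_len(config$len_18s) - 1L,
                  seq_len(config$exome_bases) - 1L),
          depth = c(d18, dex),
          stringsAsFactors = FALSE)
      })
      names(depth) <- ids
    }
    if ("cpg" %in% config$emit) {
      cpg <- lapply(seq_len(n), function(i) {
        cov <- stats::rpois(config$n_cpgs,
                            cn[i] / 2 * config$exome_depth)
        p <- stats::rbeta(config$n_cpgs,
                          m[i] * config$cpg_dispersion,
                          (1 - m[i]) * config$cpg_dispersion)
        meth <- stats::rbinom(config$n_cpgs, cov, p)
        data.frame(contig = "rDNA_looped", pos = cpg_pos,
                   methylated = meth, unmethylated = cov - meth,
                   stringsAsFactors = FALSE)
      })
      names(cpg) <- ids
    }

    rrbs <- NULL
    if ("rrbs" %in% config$emit) {
      p_rdna <- cn * config$rrbs_prob_per_copy
      if (any(p_rdna >= 1)) {
        stop("rrbs_prob_per_copy too large for CN range")
      }
      rrbs <- data.frame(
        sample_id = ids,
        rdna_aligned_reads = stats::rbinom(n, config$rrbs_total_reads,
                                           p_rdna),
        total_alignments = rep(config$rrbs_total_reads, n),
        stringsAsFactors = FALSE)
    }

    ddpcr <- NULL
    if ("ddpcr" %in% config$emit) {
      ref <- config$ddpcr_reference_concentration
      ddpcr <- data.frame(
        sample_id = ids,
        target_concentration = ref * cn / 2 *
          exp(stats::rnorm(n, 0, config$ddpcr_noise_cv)),
        reference_concentration = rep(ref, n),
        lambda_cp_per_rxn = stats::rlnorm(n, config$lambda_meanlog,
                                          config$lambda_sdlog),
        stringsAsFactors = FALSE)
    }

    metrics <- NULL
    if ("metrics" %in% config$emit) {
      metrics <- data.frame(
        sample_id = ids,
        uniquely_mapped_reads = round(stats::rnorm(n, 5e7, 4e6)),
        mapping_efficiency = stats::runif(n, 0.75, 0.9),
        non_cpg_methylation = stats::runif(n, 0.002, 0.008),
        total_cpg_methylation = stats::rnorm(n, 0.75, 0.02),
        assay = "wgbs",
        stringsAsFactors = FALSE)
    }

    truth <- data.frame(
      sample_id = ids, group = group,
      true_cn = cn, true_meth = m,
      true_active_cn = cn * (1 - m),
      bmi = bmi, age = age,
      stringsAsFactors = FALSE)

    list(truth = truth, depth = depth, regions = regions, cpg = cpg,
         rrbs = rrbs, ddpcr = ddpcr, metrics = metrics, config = config)
  })
}

#' Run the WGBS estimator across a simulated cohort
#'
#' @param sim Output of [simulate_cohort()].
#' @return Copy-number table (one `wgbs_absolute` row per sample).
#' @export
cohort_wgbs_estimates <- function(sim) {
  rows <- lapply(names(sim$depth), function(id) {
    estimate_cn_wgbs(depth_from_alignments(sim$depth[[id]], sim$regions,
                                           sample_id = id))
  })
  do.call(rbind, rows)
}

#' Run the methylation summariser across a simulated cohort
#'
#' @param sim Output of [simulate_cohort()].
#' @param min_coverage Per-CpG coverage filter (default 50).
#' @return `data.frame` with `sample_id`, `mean_methylation`,
#'   `n_cpgs_used`.
#' @export
cohort_methylation_estimates <- function(sim, min_coverage = 50L) {
  region <- data.frame(contig = "rDNA_looped", start = 0L,
                       end = sim$config$len_18s)
  rows <- lapply(names(sim$cpg), function(id) {
    s <- region_methylation(sim$cpg[[id]], region,
                            min_coverage = min_coverage, sample_id = id)
    data.frame(sample_id = id, mean_methylation = s$mean_methylation,
               n_cpgs_used = s$n_cpgs_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate labelled read records for down-sampling analysis
#'
#' Read-level generator used by the down-sampling robustness check:
#' emits read records (contig, 0-based start, width) over the 18S and
#' exome intervals, with read counts Poisson around the target mean
#' depths and uniform placement wholly inside each interval.
#'
#' @param true_cn True rDNA copy number (default 400).
#' @param exome_depth Mean exome depth (default 14).
#' @param exome_bases,len_18s Interval sizes (defaults 600 kb and 1874).
#' @param read_length Read length in bases (default 100).
#' @param seed Integer seed.
#' @return List with `reads` (`data.frame`), `regions`, `true_cn`.
#' @export
simulate_reads <- function(true_cn = 400, exome_depth = 14,
                           exome_bases = 600000L, len_18s = 1874L,
                           read_length = 100L, seed = NULL) {
  stopifnot(read_length < len_18s, read_length < exome_bases)
  with_seed(seed, {
    d18 <- true_cn / 2 * exome_depth
    n_rdna <- stats::rpois(1, d18 * len_18s / read_length)
    n_ex <- stats::rpois(1, exome_depth * exome_bases / read_length)
    reads <- data.frame(
      contig = c(rep("rDNA_looped", n_rdna), rep("exome", n_ex)),
      start = c(sample.int(len_18s - read_length + 1L, n_rdna,
                           replace = TRUE),
                sample.int(exome_bases - read_length + 1L, n_ex,
                           replace = TRUE)) - 1L,
      width = read_length,
      stringsAsFactors = FALSE)
    regions <- data.frame(name = c("18S", "exome"),
                          contig = c("rDNA_looped", "exome"),
                          start = c(0L, 0L),
                          end = c(len_18s, exome_bases))
    list(reads = reads, regions = regions, true_cn = true_cn)
  })
}

#' Simulate BMI-discordant monozygotic twin pairs
#'
#' Co-twins share their true rDNA copy number exactly (germline
#' inheritance); observed copy numbers differ only by multiplicative
#' measurement noise. BMI is discordant by construction: the heavier
#' co-twin exceeds the leaner one by a positive discordance drawn around
#' `discordance_mean`.
#'
#' @param n_pairs Number of twin pairs (default 24).
#' @param cn_min,cn_max Range of pair-level true copy number.
#' @param cn_noise_cv Coefficient of variation of copy-number
#'   measurement noise (default 0.03; set 0 for noise-free co-twins).
#' @param bmi_leaner_mean,bmi_leaner_sd BMI law of the leaner co-twin.
#' @param discordance_mean,discordance_sd Within-pair BMI discordance
#'   (kg/m^2, truncated positive).
#' @param meth_mean,meth_concentration,rho_cm,meth_noise_sd Methylation
#'   marginal, its copy-number coupling, and individual-level noise.
#' @param age_min,age_max Pair age range (years).
#' @param seed Integer seed.
#' @return List with `records` (two rows per pair: `sample_id`,
#'   `twin_pair_id`, `bmi`, `cn`, `methylation`, `age`) and `truth`
#'   (per-pair true values).
#' @export
simulate_twins <- function(n_pairs = 24L, cn_min = 150, cn_max = 600,
                           cn_noise_cv = 0.03,
                           bmi_leaner_mean = 24, bmi_leaner_sd = 2.5,
                           discordance_mean = 3, discordance_sd = 1,
                           meth_mean = 0.25, meth_concentration = 25,
                           rho_cm = 0.74, meth_noise_sd = 0.01,
                           age_min = 20, age_max = 45, seed = NULL) {
  if (n_pairs < 3L) stop("need at least 3 twin pairs")
  with_seed(seed, {
    rho_z <- copula_rho(rho_cm)
    z1 <- stats::rnorm(n_pairs)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n_pairs)
    cn_pair <- stats::qunif(stats::pnorm(z1), cn_min, cn_max)
    a <- meth_mean * meth_concentration
    b <- (1 - meth_mean) * meth_concentration
    m_pair <- stats::qbeta(stats::pnorm(z2), a, b)

    bmi_lean <- stats::rnorm(n_pairs, bmi_leaner_mean, bmi_leaner_sd)
    disc <- abs(stats::rnorm(n_pairs, discordance_mean, discordance_sd))
    age <- stats::runif(n_pairs, age_min, age_max)

    obs_cn <- function() cn_pair *
      (1 + stats::rnorm(n_pairs, 0, cn_noise_cv))
    obs_m <- function() pmin(pmax(
      m_pair + stats::rnorm(n_pairs, 0, meth_noise_sd), 0), 1)

    pid <- sprintf("P%02d", seq_len(n_pairs))
    records <- rbind(
      data.frame(sample_id = paste0(pid, "_heavier"), twin_pair_id = pid,
                 bmi = bmi_lean + disc, cn = obs_cn(),
                 methylation = obs_m(), age = age,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pid, "_leaner"), twin_pair_id = pid,
                 bmi = bmi_lean, cn = obs_cn(),
                 methylation = obs_m(), age = age,
                 stringsAsFactors = FALSE))
    truth <- data.frame(twin_pair_id = pid, true_cn = cn_pair,
                        true_meth = m_pair, bmi_discordance = disc,
                        age = age, stringsAsFactors = FALSE)
    list(records = records[order(records$twin_pair_id,
                                 records$sample_id), ],
         truth = truth)
  })
}

#' Simulate longitudinal growth with a copy-number effect on gain
#'
#' Each animal grows along an exponential-plateau trajectory between
#' `week_first` and `week_last`. The starting weight is independent of
#' copy number; the total gain over the window decreases with true copy
#' number by `cn_gain_effect` grams per copy-number SD, so the
#' association with body mass is absent at the first week and emerges as
#' the gain accrues — the late-emergence pattern. Observation noise is
#' multiplicative log-normal, keeping weights positive.
#'
#' @param n_animals Number of animals (default 44).
#' @param weeks Observation weeks (default 8:19, weekly).
#' @param w_first_mean,w_first_sd Weight at the first week (grams).
#' @param gain_mean,gain_sd Mean and residual SD of the window gain (g).
#' @param cn_gain_effect Reduction of gain per SD of true copy number
#'   (grams; default 12, sized so the latent gain/copy-number
#'   correlation is near -0.4).
#' @param k Plateau rate per week (default 0.3).
#' @param obs_noise_cv Multiplicative observation noise SD (default
#'   0.03; 0 gives noise-free trajectories).
#' @param cn_min,cn_max True copy-number range.
#' @param cn_noise_cv Copy-number measurement noise CV (default 0.03).
#' @param seed Integer seed.
#' @return List with `weights` (long `data.frame`: `sample_id`, `week`,
#'   `weight`), `cn` (observed copy-number table), and `truth`
#'   (per-animal `true_cn`, `w_first`, `gain`, plus the plateau
#'   parameters `ym`, `y0`, `k` of the latent curve).
#' @export
simulate_growth <- function(n_animals = 44L, weeks = 8:19,
                            w_first_mean = 185, w_first_sd = 12,
                            gain_mean = 95, gain_sd = 25,
                            cn_gain_effect = 12, k = 0.3,
                            obs_noise_cv = 0.03,
                            cn_min = 150, cn_max = 600,
                            cn_noise_cv = 0.03, seed = NULL) {
  stopifnot(length(weeks) >= 4L, all(diff(weeks) > 0))
  with_seed(seed, {
    ids <- sprintf("R%03d", seq_len(n_animals))
    cn <- stats::runif(n_animals, cn_min, cn_max)
    zc <- (cn - mean(c(cn_min, cn_max))) / ((cn_max - cn_min) / sqrt(12))
    w_first <- stats::rnorm(n_animals, w_first_mean, w_first_sd)
    gain <- gain_mean - cn_gain_effect * zc +
      stats::rnorm(n_animals, 0, gain_sd)
    gain <- pmax(gain, 5)

    t0 <- weeks[1]; t1 <- weeks[length(weeks)]
    span <- 1 - exp(-k * (t1 - t0))
    # latent curve: w(t) = w_first + gain*(1-e^{-k(t-t0)})/span, an
    # exponential plateau with ym = w_first + gain/span
    frac <- (1 - exp(-k * (weeks - t0))) / span
    rows <- lapply(seq_len(n_animals), function(i) {
      mu <- w_first[i] + gain[i] * frac
      w <- mu * exp(stats::rnorm(length(weeks), 0, obs_noise_cv))
      data.frame(sample_id = ids[i], week = weeks, weight = w,
                 stringsAsFactors = FALSE)
    })
    weights <- do.call(rbind, rows)

    ym <- w_first + gain / span
    y0 <- ym - (ym - w_first) * exp(k * t0)  # value extrapolated to t=0
    cn_obs <- cn * (1 + stats::rnorm(n_animals, 0, cn_noise_cv))
    truth <- data.frame(sample_id = ids, true_cn = cn,
                        w_first = w_first, gain = gain,
                        ym = ym, y0 = y0, k = k,
                        stringsAsFactors = FALSE)
    list(weights = weights,
         cn = cn_table(ids, "rrbs_relative", pmax(cn_obs, 0)),
         truth = truth)
  })
}

#' Write a simulated cohort to disk in the consumed formats
#'
#' Emits, under `dir`: per-sample depth TSVs (`<id>.depth.tsv`, 0-based
#' positions), per-sample bismark-style coverage files
#' (`<id>.cov.tsv`), `rrbs_counts.tsv`, `ddpcr.csv`, `metrics.tsv`,
#' `cohort.tsv` (phenotypes), `regions.bed`, and `truth.json`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(x, f, ...) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, ...)
    paths <<- c(paths, p)
  }
  for (id in names(sim$depth)) {
    wt(sim$depth[[id]], paste0(id, ".depth.tsv"), col.names = FALSE)
  }
  for (id in names(sim$cpg)) {
    p <- file.path(dir, paste0(id, ".cov.tsv"))
    write_cpg_calls(sim$cpg[[id]], p)
    paths <- c(paths, p)
  }
  wt(sim$rrbs, "rrbs_counts.tsv", col.names = TRUE)
  p <- file.path(dir, "ddpcr.csv")
  utils::write.csv(sim$ddpcr, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  wt(sim$metrics, "metrics.tsv", col.names = TRUE)
  wt(sim$truth, "cohort.tsv", col.names = TRUE)
  bed <- data.frame(sim$regions$contig, sim$regions$start,
                    sim$regions$end, sim$regions$name)
  wt(bed, "regions.bed", col.names = FALSE)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, p, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
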