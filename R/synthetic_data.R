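#' Cohort and summary-statistic simulator
#'
#' Generates genotype dosages in Hardy-Weinberg proportions with block LD,
#' a continuous nutrient-intake exposure driven by small per-SNP effects,
#' an incident-CKD outcome with a configurable causal effect and optional
#' direct (pleiotropic) SNP effects, longitudinal creatinine consistent with
#' the case labels, and GWAS summary statistics from per-SNP regressions —
#' so the whole analysis pipeline runs and can be calibrated without any
#' restricted cohort data.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the cohort analysis this package
#' reproduces: per-SNP exposure effects of magnitude 0.015-0.1 (the range of
#' the published instrument tables), instruments jointly explaining about 2%
#' of exposure variance (a typical dietary-intake GWAS signal), and an
#' incident-CKD fraction of 0.14 (708 cases / 5,078 subjects), ascertained
#' over biennial visits spanning 12 years of follow-up.
#'
#' @param n_subjects cohort size, default 5078.
#' @param m_snps number of variants, default 100.
#' @param maf_range minor-allele-frequency range, default `c(0.01, 0.5)`.
#' @param ld_block_size SNPs per LD block, default 1 (independent SNPs).
#' @param ld_r within-block latent correlation, default 0.
#' @param gamma_range magnitude range of per-SNP exposure effects,
#'   default `c(0.015, 0.1)`; signs are random.
#' @param exposure_r2 fraction of exposure variance explained by the SNPs,
#'   default 0.02.
#' @param beta_causal true exposure-to-outcome effect on the liability scale,
#'   default 0.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_prop fraction of SNPs with direct outcome effects,
#'   default 0.3 (used when pleiotropy != "none").
#' @param pleiotropy_scale SD (balanced) or mean (directional) of the direct
#'   effects, default 0.1.
#' @param confounder_strength loading of a shared confounder on exposure and
#'   liability, default 0.
#' @param case_fraction_target incident-CKD fraction, default 0.14.
#' @param visit_times visit schedule in years from baseline,
#'   default `seq(0, 12, by = 2)`.
#' @param liability_noise_sd residual SD of the outcome liability, default 1.
#' @param seed RNG seed, default 1.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5078, m_snps = 100,
                       maf_range = c(0.01, 0.5),
                       ld_block_size = 1, ld_r = 0,
                       gamma_range = c(0.015, 0.1),
                       exposure_r2 = 0.02,
                       beta_causal = 0,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_prop = 0.3, pleiotropy_scale = 0.1,
                       confounder_strength = 0,
                       case_fraction_target = 0.14,
                       visit_times = seq(0, 12, by = 2),
                       liability_noise_sd = 1,
                       seed = 1) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            exposure_r2 > 0, exposure_r2 < 1,
            pleiotropy_prop >= 0, pleiotropy_prop <= 1,
            ld_block_size >= 1, ld_r >= 0, ld_r < 1,
            visit_times[1] == 0, !is.unsorted(visit_times, strictly = TRUE))
  if (case_fraction_target <= 0 || case_fraction_target >= 1) {
    stop("case_fraction_target must lie strictly between 0 and 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotype dosages in Hardy-Weinberg proportions
#'
#' Haplotypes are drawn through a latent Gaussian copula: within each LD
#' block the latent normals share an exchangeable correlation `ld_r` and are
#' thresholded at the allele frequency, so each SNP is in exact
#' Hardy-Weinberg proportions marginally while neighbouring SNPs are
#' correlated. Blocks are independent.
#'
#' @param config a [sim_config].
#' @return list of class `sim_genotypes`: `dosages` (n x m matrix, dimnames
#'   set) and `snps` (data.frame: `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `maf`).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$m_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  blocks <- split(seq_len(m),
                  ceiling(seq_len(m) / config$ld_block_size))
  dos <- matrix(0L, n, m)
  for (idx in blocks) {
    bsize <- length(idx)
    for (hap in 1:2) {
      if (config$ld_r > 0 && bsize > 1) {
        shared <- rnorm(n)
        z <- sqrt(config$ld_r) * matrix(shared, n, bsize) +
          sqrt(1 - config$ld_r) * matrix(rnorm(n * bsize), n, bsize)
      } else {
        z <- matrix(rnorm(n * bsize), n, bsize)
      }
      allele <- sweep(z, 2, qnorm(maf[idx]), "<")
      dos[, idx] <- dos[, idx] + allele
    }
  }
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = sort(rep_len(1:22, m)),
    pos = 1e6 + 5e4 * seq_len(m),
    effect_allele = ea, other_allele = unname(oa),
    maf = maf, stringsAsFactors = FALSE)
  dimnames(dos) <- list(sprintf("subj%05d", seq_len(n)), snps$snp_id)
  structure(list(dosages = dos, snps = snps, config = config),
            class = "sim_genotypes")
}

#' Simulate exposure, outcome and creatinine trajectories
#'
#' Exposure: `sum_j gamma_j g_j + lambda * confounder + noise`, with the
#' noise variance set so the SNPs explain `exposure_r2` of the exposure
#' variance. Outcome liability: `beta_causal * exposure + direct SNP effects
#' + lambda * confounder + noise`; the case indicator thresholds the
#' liability at the quantile giving exactly
#' `round(case_fraction_target * n)` cases. Creatinine trajectories are
#' built by inverting the CKD-EPI equation at target eGFR values (cases
#' cross below 60 at a random follow-up visit; non-cases stay above 65)
#' with small lognormal measurement noise, so the phenotyping module
#' recovers the simulated case labels.
#'
#' @param genotypes a `sim_genotypes` object.
#' @param config a [sim_config] (defaults to the one inside `genotypes`).
#' @return list of class `sim_cohort`: `dosages`, `snps`, `exposure`,
#'   `confounder`, `liability`, `case` (0/1), `gamma` (true per-SNP exposure
#'   effects), `delta` (direct outcome effects), `visits` (long data.frame:
#'   `subject_id`, `sex`, `time`, `age`, `scr`), `config`.
#' @export
simulate_traits <- function(genotypes, config = genotypes$config) {
  set.seed(config$seed + 1L)
  g <- genotypes$dosages
  n <- nrow(g); m <- ncol(g)
  gamma <- runif(m, config$gamma_range[1], config$gamma_range[2]) *
    sample(c(-1, 1), m, replace = TRUE)
  genetic <- as.vector(g %*% gamma)
  var_g <- var(genetic)
  lambda <- config$confounder_strength
  confounder <- rnorm(n)
  # var(exposure) = var_g + lambda^2 + sigma^2 ; var_g / var(exposure) = r2
  sigma2 <- var_g * (1 - config$exposure_r2) / config$exposure_r2 - lambda^2
  if (sigma2 <= 0) stop("exposure_r2 infeasible given confounder_strength")
  exposure <- genetic + lambda * confounder + rnorm(n, 0, sqrt(sigma2))

  delta <- rep(0, m)
  if (config$pleiotropy != "none" && config$pleiotropy_prop > 0) {
    which_pl <- sample(m, max(1, round(config$pleiotropy_prop * m)))
    delta[which_pl] <- if (config$pleiotropy == "balanced") {
      rnorm(length(which_pl), 0, config$pleiotropy_scale)
    } else {
      abs(rnorm(length(which_pl), config$pleiotropy_scale,
                config$pleiotropy_scale / 2))
    }
  }
  liability <- config$beta_causal * exposure + as.vector(g %*% delta) +
    lambda * confounder + rnorm(n, 0, config$liability_noise_sd)
  n_cases <- round(config$case_fraction_target * n)
  if (n_cases < 1 || n_cases >= n) stop("infeasible case fraction")
  cutoff <- sort(liability, decreasing = TRUE)[n_cases]
  case <- as.integer(liability >= cutoff)
  # ties at the cutoff could overshoot; resolve deterministically
  if (sum(case) > n_cases) {
    extra <- which(liability == cutoff)
    case[extra[seq_len(sum(case) - n_cases)]] <- 0L
  }

  visits <- simulate_creatinine(case, config)
  structure(list(dosages = g, snps = genotypes$snps, exposure = exposure,
                 confounder = confounder, liability = liability, case = case,
                 gamma = gamma, delta = delta, visits = visits,
                 config = config),
            class = "sim_cohort")
}

# creatinine trajectories consistent with the case labels: baseline eGFR
# 75-110 for everyone; cases drop below 60 (target 40-57) from a random
# follow-up visit onward, non-cases never fall below 65. 1% lognormal
# creatinine noise cannot move either group across the 60 threshold.
simulate_creatinine <- function(case, config) {
  n <- length(case)
  times <- config$visit_times
  v <- length(times)
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "female", "male")
  age0 <- runif(n, 40, 69)
  baseline_egfr <- runif(n, 75, 110)
  cross_at <- sample(2:v, n, replace = TRUE)  # first sub-60 visit for cases
  low_egfr <- runif(n, 40, 57)
  rows <- vector("list", v)
  for (j in seq_len(v)) {
    target <- ifelse(case == 1 & j >= cross_at,
                     low_egfr,
                     pmax(65, baseline_egfr -
                            (baseline_egfr - 68) * times[j] / max(times[v], 1)))
    age <- age0 + times[j]
    scr <- scr_for_egfr(target, age, sex) * exp(rnorm(n, 0, 0.01))
    rows[[j]] <- data.frame(subject_id = sprintf("subj%05d", seq_len(n)),
                            sex = sex, time = times[j], age = age, scr = scr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$time), ]
}

#' Per-SNP GWAS scan
#'
#' Continuous traits: closed-form simple linear regression per SNP
#' (slope = cov/var, SE from the residual variance, two-sided t p-value
#' reported from the normal reference at GWAS sample sizes). Binary traits:
#' per-SNP logistic Wald fit via `glm.fit` with a score-test fallback when
#' the fit does not converge (e.g. separation). Monomorphic SNPs are emitted
#' with missing effect fields.
#'
#' @param genotypes a `sim_genotypes` or `sim_cohort` object, or a dosage
#'   matrix with column names (then `snps` metadata is minimal).
#' @param trait numeric vector (continuous) or 0/1 vector (binary if exactly
#'   two distinct values 0 and 1).
#' @param trait_name label stored on the result.
#' @return a [summary_stats] object with one record per SNP.
#' @export
gwas_scan <- function(genotypes, trait, trait_name = "trait") {
  if (is.matrix(genotypes)) {
    g <- genotypes
    snps <- data.frame(snp_id = colnames(g) %||% sprintf("snp%04d", seq_len(ncol(g))),
                       chrom = NA, pos = NA,
                       effect_allele = NA, other_allele = NA,
                       stringsAsFactors = FALSE)
  } else {
    g <- genotypes$dosages
    snps <- genotypes$snps
  }
  if (var(trait) == 0) stop("trait is constant")
  n <- nrow(g)
  binary <- all(trait %in% c(0, 1)) && length(unique(trait)) == 2
  mono <- apply(g, 2, function(col) var(col) == 0)
  if (binary) {
    res <- t(vapply(seq_len(ncol(g)), function(j) {
      if (mono[j]) return(c(NA_real_, NA_real_, NA_real_))
      logistic_assoc(g[, j], trait)
    }, numeric(3)))
  } else {
    # vectorized closed form over all SNPs
    y <- trait
    gc <- sweep(g, 2, colMeans(g))
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    beta <- as.vector(crossprod(gc, yc)) / sxx
    sse <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(pmax(sse, 0) / (n - 2) / sxx)
    res <- cbind(beta, se, two_sided_p(beta / se))
    res[mono, ] <- NA_real_
  }
  df <- data.frame(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
                   effect_allele = snps$effect_allele,
                   other_allele = snps$other_allele,
                   eaf = colMeans(g) / 2,
                   beta = res[, 1], se = res[, 2], pvalue = res[, 3],
                   stringsAsFactors = FALSE)
  ok <- !is.na(df$se)
  out <- summary_stats(df[ok, , drop = FALSE], trait_name = trait_name,
                       n_samples = n)
  attr(out, "monomorphic") <- df$snp_id[!ok]
  out
}

# single-SNP logistic regression: Wald beta/se/p, score-test fallback
logistic_assoc <- function(g, y) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, g), y, family = stats::binomial(),
            control = list(maxit = 50, epsilon = 1e-8)))
  if (fit$converged && all(abs(fit$coefficients) < 20)) {
    # Wald SE from the inverse Fisher information
    p_hat <- fit$fitted.values
    X <- cbind(1, g)
    info <- crossprod(X * sqrt(p_hat * (1 - p_hat)))
    se <- sqrt(diag(solve(info)))[2]
    beta <- fit$coefficients[2]
    c(beta, se, two_sided_p(beta / se))
  } else {
    # score test under beta = 0
    p0 <- mean(y)
    u <- sum(g * (y - p0))
    v <- p0 * (1 - p0) * sum((g - mean(g))^2)
    z <- u / sqrt(v)
    c(NA_real_, NA_real_, two_sided_p(z))
  }
}

#' Genotype quality-control filter
#'
#' Drops SNPs with call rate below `call_rate_min`, minor allele frequency
#' below `maf_min`, or a Hardy-Weinberg chi-square (1 df) test p-value below
#' `hwe_p_min` (observed vs expected genotype counts among called subjects).
#'
#' @param dosages n x m dosage matrix with `NA` for missing calls (integer
#'   dosages 0/1/2 are required for the HWE genotype counts).
#' @param call_rate_min default 0.95.
#' @param maf_min default 0.01.
#' @param hwe_p_min default 5e-5.
#' @return list: `dosages` (retained columns) and `drop_log` (data.frame
#'   `snp_id`, `reason`).
#' @export
qc_filter <- function(dosages, call_rate_min = 0.95, maf_min = 0.01,
                      hwe_p_min = 5e-5) {
  stopifnot(is.matrix(dosages))
  m <- ncol(dosages)
  ids <- colnames(dosages) %||% sprintf("snp%04d", seq_len(m))
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    col <- dosages[, j]
    called <- col[!is.na(col)]
    if (length(called) / nrow(dosages) < call_rate_min) {
      reason[j] <- "call_rate"
      next
    }
    af <- mean(called) / 2
    maf <- min(af, 1 - af)
    if (maf < maf_min) {
      reason[j] <- "maf"
      next
    }
    if (hwe_chisq_p(called) < hwe_p_min) reason[j] <- "hwe"
  }
  drop <- !is.na(reason)
  list(dosages = dosages[, !drop, drop = FALSE],
       drop_log = data.frame(snp_id = ids[drop], reason = reason[drop],
                             stringsAsFactors = FALSE))
}

#' Hardy-Weinberg chi-square test p-value
#'
#' 1-df chi-square of observed genotype counts against Hardy-Weinberg
#' expectations at the sample allele frequency.
#'
#' @param genotypes integer dosages 0/1/2 (no missing values).
#' @return p-value (1 if the SNP is monomorphic).
#' @export
hwe_chisq_p <- function(genotypes) {
  n <- length(genotypes)
  obs <- c(sum(genotypes == 0), sum(genotypes == 1), sum(genotypes == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Write a self-contained simulated study directory
#'
#' Runs the generator end to end and writes plain-text artifacts: dosages,
#' visit-level phenotypes, exposure/outcome GWAS summary statistics, the
#' case table, and a JSON echo of the configuration and seed.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config].
#' @param outcome one of `"case"` (binary logistic GWAS) or `"liability"`
#'   (continuous outcome GWAS; faster and collapsibility-free).
#' @return invisibly, the `sim_cohort` object.
#' @export
simulate_study <- function(dir, config = sim_config(),
                           outcome = c("case", "liability")) {
  outcome <- match.arg(outcome)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config)
  cohort <- simulate_traits(geno, config)
  y <- if (outcome == "case") cohort$case else cohort$liability
  expo_stats <- gwas_scan(cohort, cohort$exposure, "exposure")
  out_stats <- gwas_scan(cohort, y, paste0("outcome_", outcome))
  write_summary_stats_file <- function(stats, path) {
    write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_summary_stats_file(expo_stats, file.path(dir, "exposure_gwas.tsv"))
  write_summary_stats_file(out_stats, file.path(dir, "outcome_gwas.tsv"))
  write.table(data.frame(subject_id = rownames(cohort$dosages),
                         exposure = cohort$exposure, case = cohort$case),
              file.path(dir, "phenotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$visits, file.path(dir, "visits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cbind(subject_id = rownames(cohort$dosages), cohort$dosages),
              file.path(dir, "dosages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- cohort$config
  cfg$visit_times <- as.numeric(cfg$visit_times)
  jsonlite::write_json(cfg[!vapply(cfg, is.function, logical(1))],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(cohort)
}
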