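#' Horizontal-pleiotropy diagnostics
#'
#' The Egger intercept test, the MR-PRESSO global residual-sum-of-squares
#' test with per-SNP outlier statistics, and funnel-plot data.
#'
#' @name pleiotropy
NULL

#' MR-Egger intercept test
#'
#' The intercept of the MR-Egger regression estimates the average directional
#' pleiotropic effect across instruments; a non-zero intercept indicates
#' directional horizontal pleiotropy. Re-exports the intercept component of
#' [mr_egger()].
#'
#' @inheritParams mr_egger
#' @return list: `estimate`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(instruments, residual_floor = 1) {
  mr_egger(instruments, residual_floor = residual_floor)$intercept
}

#' MR-PRESSO global test
#'
#' For each SNP j the leave-one-out IVW estimate `beta_(-j)` gives the
#' expected outcome beta `beta_(-j) * bx_j`; the observed residual sum of
#' squares is `RSS_obs = sum_j d_j^2 / sy_j^2` with
#' `d_j = by_j - beta_(-j) * bx_j`. The null distribution is simulated by
#' drawing `by*_j ~ Normal(beta_(-j) * bx_j, sy_j)` and recomputing the RSS
#' (including the leave-one-out estimates) `nsim` times; the global p-value
#' is `(1 + #[RSS_sim >= RSS_obs]) / (nsim + 1)`. Each SNP's simulated
#' weighted squared residual distribution yields a per-SNP outlier p, flagged
#' after Bonferroni correction.
#'
#' @param instruments harmonized instrument data.frame (>= 4 rows).
#' @param nsim simulated null datasets, default 10000 (warning below 100).
#' @param seed RNG seed; recorded in the result and mandatory for
#'   reproducible reports.
#' @param outlier_alpha family-wise level for Bonferroni outlier flags,
#'   default 0.05.
#' @return list: `rss_obs`, `global_p`, `nsim`, `seed`, `outlier_p`
#'   (named per-SNP), `outlier_flags` (named logical).
#' @export
mr_presso_global <- function(instruments, nsim = 10000, seed = 1,
                             outlier_alpha = 0.05) {
  check_instruments(instruments, min_n = 4L)
  if (nsim < 100) warning("nsim < 100 gives a very coarse p-value lattice")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  k <- nrow(instruments)
  bx <- instruments$bx
  by <- instruments$by
  sy <- instruments$sy
  w_rss <- 1 / sy^2             # first-order outcome weights in the RSS
  w_ivw <- bx^2 / sy^2
  r <- by / bx
  sum_wr <- sum(w_ivw * r)
  sum_w <- sum(w_ivw)
  beta_loo <- (sum_wr - w_ivw * r) / (sum_w - w_ivw)
  expected <- beta_loo * bx
  d_obs <- by - expected
  rss_contrib_obs <- w_rss * d_obs^2
  rss_obs <- sum(rss_contrib_obs)

  # simulate by* under the per-SNP leave-one-out null, recomputing the
  # leave-one-out estimates within each simulated dataset (vectorized
  # over simulations)
  sim <- matrix(rnorm(nsim * k, mean = rep(expected, each = nsim),
                      sd = rep(sy, each = nsim)), nsim, k)
  r_sim <- sweep(sim, 2, bx, "/")
  sum_wr_sim <- as.vector(r_sim %*% w_ivw)
  beta_loo_sim <- (matrix(sum_wr_sim, nsim, k) -
                     sweep(r_sim, 2, w_ivw, "*")) /
    matrix(sum_w - w_ivw, nsim, k, byrow = TRUE)
  d_sim <- sim - beta_loo_sim * matrix(bx, nsim, k, byrow = TRUE)
  contrib_sim <- sweep(d_sim^2, 2, w_rss, "*")
  rss_sim <- rowSums(contrib_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nsim + 1)
  outlier_p <- (1 + colSums(contrib_sim >=
                              matrix(rss_contrib_obs, nsim, k, byrow = TRUE))) /
    (nsim + 1)
  ids <- instruments$snp_id %||% as.character(seq_len(k))
  names(outlier_p) <- ids
  list(rss_obs = rss_obs, global_p = global_p, nsim = nsim, seed = seed,
       outlier_p = outlier_p,
       outlier_flags = outlier_p < outlier_alpha / k,
       outlier_statistic = setNames(rss_contrib_obs, ids))
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against instrument precision `1/s_j = |bx_j|/sy_j`,
#' with the IVW and Egger estimates as reference lines. Symmetry of the
#' funnel around the causal estimate argues against directional pleiotropy.
#'
#' @inheritParams wald_ratios
#' @return list: `data` (data.frame `snp_id`, `ratio`, `precision`),
#'   `ivw_beta`, `egger_beta` (`NA` with fewer than 3 instruments).
#' @export
funnel_data <- function(instruments) {
  wr <- wald_ratios(instruments)
  ivw_beta <- if (nrow(instruments) >= 1)
    suppressWarnings(mr_ivw(instruments)$beta) else NA_real_
  egger_beta <- if (nrow(instruments) >= 3)
    mr_egger(instruments)$slope$beta else NA_real_
  list(data = data.frame(snp_id = wr$snp_id, ratio = wr$ratio,
                         precision = 1 / wr$se, stringsAsFactors = FALSE),
       ivw_beta = ivw_beta, egger_beta = egger_beta)
}

#' Combined pleiotropy report for one instrument set
#'
#' One row of a pleiotropy results table: Egger intercept with SE and p,
#' and the MR-PRESSO observed RSS and global p.
#'
#' @inheritParams mr_presso_global
#' @return data.frame with one row.
#' @export
pleiotropy_report <- function(instruments, nsim = 10000, seed = 1) {
  egger <- egger_intercept_test(instruments)
  presso <- mr_presso_global(instruments, nsim = nsim, seed = seed)
  data.frame(n_snp = nrow(instruments),
             egger_intercept = egger$estimate,
             egger_se = egger$se,
             egger_p = egger$pvalue,
             presso_rss_obs = presso$rss_obs,
             presso_global_p = presso$global_p,
             presso_nsim = nsim, presso_seed = seed,
             stringsAsFactors = FALSE)
}
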