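#' Polygenic-score validation of instruments
#'
#' A per-nutrient polygenic risk score is the weighted sum of effect-allele
#' dosages, PRS_s = sum_i beta_i * dosage_si, with beta_i the GWAS effect
#' sizes of the selected instruments. A linear regression of measured intake
#' on the score checks that the instruments jointly predict the exposure.
#'
#' @name prs_validation
NULL

#' Compute per-subject polygenic scores
#'
#' @param dosages numeric matrix, subjects x SNPs, effect-allele dosages in
#'   \[0, 2\]; column names are SNP ids; `NA` marks missing dosages.
#' @param weights data.frame with `snp_id` and `beta` (and optionally
#'   `effect_allele`, carried along); `snp_id` must be unique.
#' @param missing one of `"mean"` (default: per-SNP mean-dosage imputation,
#'   count reported via attribute `n_imputed`) or `"strict"` (any missing
#'   dosage or absent weight SNP is an error).
#' @return named numeric vector of scores, one per subject.
#' @export
compute_prs <- function(dosages, weights, missing = c("mean", "strict")) {
  missing <- match.arg(missing)
  stopifnot(is.matrix(dosages), is.data.frame(weights),
            all(c("snp_id", "beta") %in% names(weights)))
  if (anyDuplicated(weights$snp_id)) stop("duplicate snp_id in weights")
  absent <- setdiff(weights$snp_id, colnames(dosages))
  if (length(absent)) {
    if (missing == "strict") {
      stop("weight SNP(s) absent from dosage matrix: ",
           paste(absent, collapse = ", "))
    }
    weights <- weights[!weights$snp_id %in% absent, , drop = FALSE]
  }
  g <- dosages[, weights$snp_id, drop = FALSE]
  rng <- range(g, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  n_imputed <- 0L
  if (anyNA(g)) {
    if (missing == "strict") stop("missing dosages under strict policy")
    n_imputed <- sum(is.na(g))
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  scores <- as.vector(g %*% weights$beta)
  names(scores) <- rownames(dosages)
  attr(scores, "n_imputed") <- n_imputed
  scores
}

#' Association between a polygenic score and measured intake
#'
#' Closed-form simple least squares of the trait on the score:
#' slope = cov(score, trait)/var(score), SE from the residual variance,
#' two-sided p from the t(n-2) reference.
#'
#' @param scores per-subject polygenic scores (non-constant, n >= 3).
#' @param trait per-subject measured intake values.
#' @return list: `slope`, `se`, `pvalue`, `r_squared`, `intercept`, `n`.
#' @export
prs_trait_association <- function(scores, trait) {
  stopifnot(length(scores) == length(trait))
  keep <- is.finite(scores) & is.finite(trait)
  x <- as.numeric(scores[keep]); y <- trait[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 subjects")
  if (var(x) == 0) stop("constant scores: association is degenerate")
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- slope / se
  syy <- sum((y - mean(y))^2)
  list(slope = slope, se = se,
       pvalue = if (syy == 0) 1 else two_sided_t_p(tstat, n - 2),
       r_squared = if (syy == 0) 0 else 1 - sum(resid^2) / syy,
       intercept = intercept, n = n)
}
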