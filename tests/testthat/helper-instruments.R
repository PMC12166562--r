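# shared test fixtures, all generated in code

# random harmonized instrument set with positive SEs
random_instruments <- function(k, seed) {
  set.seed(seed)
  data.frame(snp_id = sprintf("rs%03d", seq_len(k)),
             bx = runif(k, 0.015, 0.1) * sample(c(-1, 1), k, replace = TRUE),
             sx = runif(k, 0.003, 0.02),
             by = rnorm(k, 0, 0.2),
             sy = runif(k, 0.08, 0.4),
             eaf = runif(k, 0.05, 0.95),
             stringsAsFactors = FALSE)
}

# summary-level instruments under a pure causal model: bx ~ N(gamma, sx),
# by ~ N(beta * gamma, sy). The generating truth for null-calibration tests.
causal_model_instruments <- function(k, beta, seed,
                                     sx = 0.004, sy = 0.1) {
  set.seed(seed)
  gamma <- runif(k, 0.02, 0.1) * sample(c(-1, 1), k, replace = TRUE)
  data.frame(snp_id = sprintf("rs%03d", seq_len(k)),
             bx = rnorm(k, gamma, sx), sx = sx,
             by = rnorm(k, beta * gamma, sy), sy = sy,
             stringsAsFactors = FALSE)
}

# tiny summary_stats pair with explicit alleles for harmonization tests
make_stats <- function(df, trait = "t") {
  summary_stats(df, trait_name = trait)
}

# brute-force weighted median: scan the piecewise-linear cumulative-weight
# function on a fine grid of candidate crossings (independent of the
# package's interpolation code path)
oracle_weighted_median <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] < 0.5) return(r[length(r)])
  k <- findInterval(0.5 - 1e-15, s)
  # linear interpolation between the bracketing knots
  stats::approx(s, r, xout = 0.5)$y
}
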