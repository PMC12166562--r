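b6 <- micronutrient_instruments("vitamin_b6")

test_that("Wald ratios, SEs and weights follow their definitions", {
  wr <- wald_ratios(data.frame(snp_id = "x", bx = 0.5, sx = 0.05,
                               by = 1.0, sy = 0.2))
  expect_equal(wr$ratio, 2.0)
  expect_equal(wr$se, 0.4)
  expect_equal(wr$weight, 6.25)
  expect_equal(wr$weight, 1 / wr$se^2)
  # rs145928548: ratio of the printed betas
  r1 <- wald_ratios(b6)$ratio[b6$snp_id == "rs145928548"]
  expect_equal(r1, 0.319 / -0.072, tolerance = 1e-12)
  expect_equal(r1, -4.4306, tolerance = 1e-4)
  # joint sign flip leaves ratio and weight unchanged
  flipped <- b6
  flipped$bx <- -flipped$bx; flipped$by <- -flipped$by
  expect_equal(wald_ratios(flipped)$ratio, wald_ratios(b6)$ratio)
  expect_equal(wald_ratios(flipped)$weight, wald_ratios(b6)$weight)
  degen <- b6; degen$bx[3] <- 0
  expect_error(wald_ratios(degen), degen$snp_id[3])
})

test_that("IVW equals weighted least squares through the origin", {
  for (seed in 1:25) {
    inst <- random_instruments(5, seed)
    est <- mr_ivw(inst)
    fit <- lm(by ~ 0 + bx, data = inst, weights = 1 / inst$sy^2)
    expect_equal(est$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(est$se, 1 / sqrt(sum(inst$bx^2 / inst$sy^2)),
                 tolerance = 1e-12)
    # weighted mean of ratios stays inside their range
    r <- inst$by / inst$bx
    expect_true(est$beta >= min(r) && est$beta <= max(r))
  }
  expect_warning(mr_ivw(b6[1, ]), "single instrument")
  expect_error(mr_ivw(b6[0, ]), "at least")
})

test_that("first-order radial slope is the IVW slope; SE uses residual variance", {
  for (seed in 1:10) {
    inst <- random_instruments(6, seed + 100)
    ivw <- mr_ivw(inst)
    rad <- mr_radial_ivw(inst, weight_order = "first")
    expect_equal(rad$beta, ivw$beta, tolerance = 1e-12)
    # radial SE / IVW SE = sqrt(Q / (k - 1)) under first-order weights
    k <- nrow(inst)
    expect_equal(rad$se / ivw$se, sqrt(rad$Q / (k - 1)), tolerance = 1e-10)
    expect_equal(sum(rad$q_contributions), rad$Q, tolerance = 1e-12)
    expect_true(rad$Q >= 0)
    # agrees with lm on the radial transform
    w <- inst$bx^2 / inst$sy^2
    fit <- lm(I(sqrt(w) * (inst$by / inst$bx)) ~ 0 + sqrt(w))
    expect_equal(rad$beta, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(rad$se, summary(fit)$coefficients[1, 2], tolerance = 1e-10)
  }
})

test_that("Egger recovers exact affine structure and matches normal equations", {
  # exact line by = 0.1 + 2 * bx with all bx > 0: zero residuals
  inst <- data.frame(snp_id = letters[1:5], bx = c(.02, .04, .05, .07, .09),
                     sx = 0.004, by = 0.1 + 2 * c(.02, .04, .05, .07, .09),
                     sy = c(.1, .12, .2, .15, .3))
  fit <- suppressWarnings(mr_egger(inst))  # zero-residual fit
  expect_equal(fit$intercept$estimate, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope$beta, 2, tolerance = 1e-10)
  # generic input: matches weighted normal equations with design (1, |bx|)
  for (seed in 1:10) {
    rnd <- random_instruments(7, seed + 200)
    bx <- abs(rnd$bx); by <- rnd$by * sign(rnd$bx)
    w <- 1 / rnd$sy^2
    X <- cbind(1, bx)
    coefs <- as.numeric(solve(t(X) %*% (w * X), t(X) %*% (w * by)))
    fit <- mr_egger(rnd)
    expect_equal(fit$intercept$estimate, coefs[1], tolerance = 1e-10)
    expect_equal(fit$slope$beta, coefs[2], tolerance = 1e-10)
  }
  expect_error(mr_egger(b6[1:2, ]), "at least 3")
})

test_that("median estimators follow the stated conventions", {
  mk <- function(ratios) {
    data.frame(snp_id = as.character(seq_along(ratios)), bx = 1, sx = 0.01,
               by = ratios, sy = 0.1)
  }
  expect_equal(mr_simple_median(mk(c(1, 2, 9)), boot_reps = 0)$beta, 2)
  expect_equal(mr_simple_median(mk(c(1, 3, 5, 7)), boot_reps = 0)$beta, 4)
  # equal weights reduce the weighted median to the simple median
  eq <- mk(c(1, 2, 9))
  expect_equal(mr_weighted_median(eq, boot_reps = 0)$beta, 2)
  # brute-force interpolation oracle on random weights
  for (seed in 1:25) {
    set.seed(seed)
    inst <- random_instruments(4, seed + 300)
    est <- mr_weighted_median(inst, boot_reps = 0)
    wr <- inst$by / inst$bx
    w <- inst$bx^2 / inst$sy^2
    expect_equal(est$beta, oracle_weighted_median(wr, w), tolerance = 1e-10)
  }
})

test_that("penalization is inert without outliers and shrinks their influence", {
  # tight instruments all near ratio 2: penalty inactive
  clean <- data.frame(snp_id = as.character(1:6),
                      bx = rep(0.05, 6), sx = 0.002,
                      by = 0.05 * c(1.98, 2.01, 2.0, 1.99, 2.02, 2.0),
                      sy = 0.01)
  wm <- mr_weighted_median(clean, boot_reps = 0)$beta
  pwm <- mr_penalized_weighted_median(clean, boot_reps = 0)$beta
  expect_equal(pwm, wm, tolerance = 1e-12)
  # one gross outlier: penalized estimate moves toward the clean value
  outlier <- rbind(clean,
                   data.frame(snp_id = "out", bx = 0.05, sx = 0.002,
                              by = 0.05 * 20, sy = 0.01))
  wm_out <- mr_weighted_median(outlier, boot_reps = 0)$beta
  pwm_out <- mr_penalized_weighted_median(outlier, boot_reps = 0)$beta
  expect_lte(abs(pwm_out - wm), abs(wm_out - wm))
})

test_that("estimators are invariant under joint per-SNP sign flips", {
  inst <- random_instruments(9, 42)
  flip <- inst
  idx <- c(2, 5, 7)
  flip$bx[idx] <- -flip$bx[idx]; flip$by[idx] <- -flip$by[idx]
  expect_equal(mr_ivw(flip)$beta, mr_ivw(inst)$beta, tolerance = 1e-12)
  expect_equal(mr_radial_ivw(flip)$beta, mr_radial_ivw(inst)$beta,
               tolerance = 1e-10)
  expect_equal(mr_simple_median(flip, boot_reps = 0)$beta,
               mr_simple_median(inst, boot_reps = 0)$beta)
  expect_equal(mr_weighted_median(flip, boot_reps = 0)$beta,
               mr_weighted_median(inst, boot_reps = 0)$beta)
  # Egger's orientation step makes the reported fit flip-invariant too
  expect_equal(mr_egger(flip)$slope$beta, mr_egger(inst)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(flip)$intercept$estimate,
               mr_egger(inst)$intercept$estimate, tolerance = 1e-12)
})

test_that("bootstrap SEs are seeded, reproducible and stable in replicates", {
  a <- mr_simple_median(b6, boot_reps = 2000, seed = 9)
  b <- mr_simple_median(b6, boot_reps = 2000, seed = 9)
  expect_equal(a$se, b$se)
  big <- mr_simple_median(b6, boot_reps = 10000, seed = 9)$se
  bigger <- mr_simple_median(b6, boot_reps = 20000, seed = 10)$se
  expect_lt(abs(bigger - big) / big, 0.05)
})

test_that("run_all_methods emits one deterministic row per method", {
  tab1 <- run_all_methods(b6, boot_reps = 500, seed = 3)
  tab2 <- run_all_methods(b6, boot_reps = 500, seed = 3)
  expect_identical(tab1, tab2)
  expect_setequal(tab1$method,
                  c("ivw", "ivw_radial", "egger", "penalized_weighted_median",
                    "weighted_median", "simple_median"))
  expect_true(all(tab1$n_snp == 11))
  expect_true(all(tab1$se > 0))
  # p-values match the two-sided normal reference for normal-reference methods
  norm_rows <- tab1$method %in% c("ivw", "ivw_radial", "simple_median",
                                  "weighted_median", "penalized_weighted_median")
  expect_equal(tab1$pvalue[norm_rows],
               2 * pnorm(-abs(tab1$beta[norm_rows] / tab1$se[norm_rows])),
               tolerance = 1e-12)
  # methods with unmet preconditions are skipped with a warning
  warns <- capture_warnings(small <- run_all_methods(b6[1:2, ], boot_reps = 0))
  expect_true(any(grepl("failed", warns)))
  expect_true(all(c("ivw", "ivw_radial") %in% small$method))
  expect_false("egger" %in% small$method)
})
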