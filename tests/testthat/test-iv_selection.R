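fixture_stats <- function(nutrient) {
  inst <- micronutrient_instruments(nutrient)
  summary_stats(data.frame(snp_id = inst$snp_id, chrom = inst$chrom,
                           eaf = inst$eaf, beta = inst$bx, se = inst$sx,
                           pvalue = inst$px),
                trait_name = nutrient)
}

test_that("suggestive filter uses strict inequality and preserves order", {
  b6 <- fixture_stats("vitamin_b6")
  kept <- filter_by_exposure_p(b6, 1e-5)
  expect_equal(nrow(kept), 11)  # max exposure p is 9.5e-6
  expect_equal(kept$snp_id, b6$snp_id)
  expect_equal(nrow(filter_by_exposure_p(b6, 1.0)), nrow(b6))
  boundary <- summary_stats(data.frame(snp_id = "rs1", beta = 0.02,
                                       se = 0.004, pvalue = 1e-5))
  expect_equal(nrow(filter_by_exposure_p(boundary, 1e-5)), 0)
})

test_that("ld_clump keeps the most significant variant per linked region", {
  stats <- summary_stats(data.frame(
    snp_id = c("a", "b", "c"), chrom = 1, pos = c(1e6, 1.05e6, 1.1e6),
    beta = 0.02, se = 0.004, pvalue = c(1e-8, 1e-7, 1e-6)))
  full_ld <- list(snp_ids = c("a", "b", "c"),
                  r2 = matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3))
  expect_equal(ld_clump(stats, full_ld)$snp_id, "a")
  no_ld <- list(snp_ids = c("a", "b", "c"), r2 = diag(3))
  expect_equal(nrow(ld_clump(stats, no_ld)), 3)
  expect_equal(nrow(ld_clump(stats, NULL)), 3)
  bad <- full_ld; bad$r2[1, 2] <- 0.2
  expect_error(ld_clump(stats, bad), "symmetric")
  bad2 <- full_ld; bad2$r2[1, 2] <- bad2$r2[2, 1] <- 1.4
  expect_error(ld_clump(stats, bad2), "0,1")
})

test_that("ld_clump agrees with the exhaustive pairwise oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- 5
    pos <- sort(runif(k, 1e6, 1.6e6))
    r2 <- matrix(runif(k * k), k)
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ids <- letters[1:k]
    stats <- summary_stats(data.frame(
      snp_id = ids, chrom = 1, pos = pos, beta = 0.02, se = 0.004,
      pvalue = runif(k, 1e-9, 1e-5)))
    ld <- list(snp_ids = ids, r2 = r2)
    cfg <- selection_config(clump_r2 = 0.5, clump_window_kb = 250)
    kept <- ld_clump(stats, ld, cfg)
    # no surviving pair may be linked and within window
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      a <- match(kept$snp_id[i], ids); b <- match(kept$snp_id[j], ids)
      expect_false(r2[a, b] >= 0.5 && abs(pos[a] - pos[b]) <= 250e3)
    }
    # every dropped SNP is linked to a kept SNP with smaller p
    dropped <- setdiff(ids, kept$snp_id)
    for (d in dropped) {
      a <- match(d, ids)
      linked_better <- any(vapply(kept$snp_id, function(kid) {
        b <- match(kid, ids)
        r2[a, b] >= 0.5 && abs(pos[a] - pos[b]) <= 250e3 &&
          stats$pvalue[b] <= stats$pvalue[a]
      }, logical(1)))
      expect_true(linked_better, info = paste("seed", seed, "snp", d))
    }
    # input order invariance
    perm <- sample(k)
    kept2 <- ld_clump(stats[perm, ], ld, cfg)
    expect_setequal(kept2$snp_id, kept$snp_id)
  }
})

test_that("outcome screen drops only outcome-associated instruments", {
  b6 <- micronutrient_instruments("vitamin_b6")
  sc <- screen_outcome_association(b6, 1e-5)
  expect_equal(nrow(sc$instruments), 11)  # min outcome p is 0.045
  strong <- rbind(b6[1, ], b6[1, ])
  strong$snp_id <- c("hit", "ok")
  strong$by <- c(1.0, 0.01); strong$sy <- c(0.1, 0.1)
  sc2 <- screen_outcome_association(strong, 1e-3)
  expect_equal(sc2$exclusions$snp_id, "hit")
  expect_equal(sc2$exclusions$reason, "outcome_associated")
  # threshold 0: nothing is strictly below 0
  expect_equal(nrow(screen_outcome_association(strong, 0)$instruments), 2)
})

test_that("phenotype screen keeps dietary-intake and unannotated SNPs", {
  inst <- data.frame(snp_id = c("s1", "s2", "s3"),
                     bx = 0.02, sx = 0.005, by = 0.1, sy = 0.1,
                     mapped_phenotypes = c("Phosphorus intake;HDL",
                                           "Height", ""),
                     stringsAsFactors = FALSE)
  sc <- screen_mapped_phenotypes(inst, config = selection_config())
  expect_setequal(sc$instruments$snp_id, c("s1", "s3"))
  expect_equal(sc$exclusions$snp_id, "s2")
  # annotations supplied separately take effect for unannotated instruments
  inst2 <- inst; inst2$mapped_phenotypes <- ""
  ann <- data.frame(snp_id = "s2", phenotypes = "Height")
  sc2 <- screen_mapped_phenotypes(inst2, ann)
  expect_setequal(sc2$instruments$snp_id, c("s1", "s3"))
  # empty annotation table: identity under keep-unannotated default
  sc3 <- screen_mapped_phenotypes(inst2, NULL)
  expect_equal(nrow(sc3$instruments), 3)
})

test_that("fixture instrument sets survive the outcome and phenotype screens intact", {
  ann <- instrument_annotations()
  expected <- c(phosphorus = 11, vitamin_b2 = 13, vitamin_b6 = 11,
                vitamin_c = 10)
  for (tr in micronutrient_traits()) {
    inst <- micronutrient_instruments(tr)
    s1 <- screen_outcome_association(inst, 1e-5)
    s2 <- screen_mapped_phenotypes(s1$instruments, ann)
    expect_equal(nrow(s2$instruments), unname(expected[tr]), info = tr)
  }
})

test_that("the cascade is monotone: each stage returns a subset", {
  cfg <- sim_config(n_subjects = 600, m_snps = 60, seed = 21,
                    exposure_r2 = 0.1, ld_block_size = 3, ld_r = 0.6)
  cohort <- simulate_traits(simulate_genotypes(cfg), cfg)
  expo <- gwas_scan(cohort, cohort$exposure, "exposure")
  outc <- gwas_scan(cohort, cohort$liability, "outcome")
  sel <- select_instruments(expo, outc,
                            config = selection_config(exposure_p_threshold = 0.05))
  counts <- sel$counts
  expect_true(all(diff(counts[c("input", "exposure_p", "ld_clump")]) <= 0))
  expect_true(counts["harmonized"] <= counts["ld_clump"])
  expect_true(counts["outcome_screen"] <= counts["harmonized"])
  expect_true(counts["phenotype_screen"] <= counts["outcome_screen"])
  expect_true(all(sel$instruments$snp_id %in% expo$snp_id))
})
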