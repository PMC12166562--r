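#' Instrument-selection cascade
#'
#' Four stages turn exposure GWAS hits into MR instruments: (1) the suggestive
#' significance filter p < 1e-5; (2) greedy LD clumping so one index variant
#' represents each linkage region; (3) an outcome-association screen dropping
#' variants themselves associated with CKD (such variants may act on the
#' outcome directly); (4) a mapped-phenotype screen dropping variants whose
#' prior GWAS associations include no dietary-intake trait (potential
#' pleiotropy). Each stage returns a subset of its input and logs every drop.
#'
#' @name iv_selection
NULL

#' Selection cascade configuration
#'
#' @param exposure_p_threshold suggestive GWAS threshold; records with
#'   p strictly below it are retained. Default 1e-5.
#' @param clump_r2 LD r-squared at or above which two variants are clumped.
#'   Default 0.1.
#' @param clump_window_kb clumping window in kilobases. Default 250.
#' @param outcome_p_exclusion instruments with outcome-association p strictly
#'   below this are dropped. Default 1e-5.
#' @param allowed_phenotype_patterns substrings identifying dietary-intake
#'   phenotypes; an instrument is kept if any mapped phenotype matches any
#'   pattern (case-insensitive, fixed strings). Default `"intake"`.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(exposure_p_threshold = 1e-5,
                             clump_r2 = 0.1,
                             clump_window_kb = 250,
                             outcome_p_exclusion = 1e-5,
                             allowed_phenotype_patterns = "intake") {
  stopifnot(exposure_p_threshold > 0, exposure_p_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_kb > 0,
            outcome_p_exclusion >= 0, outcome_p_exclusion <= 1)
  structure(list(exposure_p_threshold = exposure_p_threshold,
                 clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 outcome_p_exclusion = outcome_p_exclusion,
                 allowed_phenotype_patterns = allowed_phenotype_patterns),
            class = "selection_config")
}

#' Suggestive-significance filter
#'
#' Retains records with `pvalue` strictly below `threshold`; order preserved.
#'
#' @param stats a [summary_stats] object (or compatible data.frame).
#' @param threshold p-value cutoff, default 1e-5.
#' @export
filter_by_exposure_p <- function(stats, threshold = 1e-5) {
  out <- stats[stats$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_ld_matrix <- function(ld) {
  stopifnot(is.list(ld), !is.null(ld$snp_ids), !is.null(ld$r2))
  r2 <- as.matrix(ld$r2)
  k <- length(ld$snp_ids)
  if (!all(dim(r2) == c(k, k))) stop("r2 matrix dimensions do not match snp_ids")
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE)) stop("r2 values must lie in [0,1]")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must equal 1")
  dimnames(r2) <- list(ld$snp_ids, ld$snp_ids)
  r2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining record with the smallest p-value as an index
#' variant and discards all remaining records on the same chromosome within
#' `clump_window_kb` whose r-squared with the index is at least `clump_r2`.
#' Ties in p are broken by (chrom, pos, snp_id) so the result does not depend
#' on input order. Records absent from the LD matrix are treated as unlinked;
#' records with missing position are treated as within-window (conservative).
#'
#' @param stats [summary_stats] object with `chrom`, `pos`, `pvalue`.
#' @param ld list with `snp_ids` and symmetric `r2` matrix (unit diagonal),
#'   or `NULL` for no linkage information (identity).
#' @param config a [selection_config].
#' @return the retained subset, in the original record order.
#' @export
ld_clump <- function(stats, ld = NULL, config = selection_config()) {
  if (nrow(stats) == 0L) return(stats)
  r2 <- if (is.null(ld)) NULL else validate_ld_matrix(ld)
  ord <- order(stats$pvalue, stats$chrom, stats$pos, stats$snp_id)
  remaining <- stats$snp_id[ord]
  info <- stats[match(remaining, stats$snp_id), ]
  keep <- character(0)
  while (length(remaining)) {
    index <- remaining[1]
    keep <- c(keep, index)
    i <- match(index, info$snp_id)
    linked <- rep(FALSE, length(remaining))
    if (!is.null(r2) && index %in% rownames(r2)) {
      j <- match(remaining, rownames(r2))
      rr <- ifelse(is.na(j), 0, r2[i_ld <- match(index, rownames(r2)), j])
      same_chr <- !is.na(info$chrom[i]) &
        as.character(info$chrom[match(remaining, info$snp_id)]) ==
        as.character(info$chrom[i])
      same_chr[is.na(same_chr)] <- FALSE
      pos_i <- info$pos[i]
      pos_j <- info$pos[match(remaining, info$snp_id)]
      within <- is.na(pos_i) | is.na(pos_j) |
        abs(pos_j - pos_i) <= config$clump_window_kb * 1000
      linked <- rr >= config$clump_r2 & same_chr & within
    }
    linked[1] <- TRUE  # always remove the index itself
    remaining <- remaining[!linked]
  }
  out <- stats[stats$snp_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Outcome-association screen
#'
#' Drops instruments whose outcome association is itself significant: the
#' two-sided normal p of |by/sy| strictly below `outcome_p_exclusion`.
#' Instruments are meant to act on CKD only through the exposure, so a strong
#' direct outcome association disqualifies a variant.
#'
#' @param instruments harmonized instrument data.frame.
#' @param outcome_p_exclusion default 1e-5.
#' @return list with `instruments` (kept) and `exclusions` (snp_id, reason).
#' @export
screen_outcome_association <- function(instruments, outcome_p_exclusion = 1e-5) {
  if (nrow(instruments) == 0L) {
    return(list(instruments = instruments,
                exclusions = data.frame(snp_id = character(), reason = character())))
  }
  p_out <- two_sided_p(instruments$by / instruments$sy)
  drop <- p_out < outcome_p_exclusion
  list(instruments = {x <- instruments[!drop, , drop = FALSE]; rownames(x) <- NULL; x},
       exclusions = data.frame(snp_id = instruments$snp_id[drop],
                               reason = rep("outcome_associated", sum(drop)),
                               stringsAsFactors = FALSE))
}

#' Mapped-phenotype pleiotropy screen
#'
#' Keeps an instrument iff at least one of its previously reported mapped
#' phenotypes matches an allowed dietary-intake pattern. Unannotated SNPs are
#' kept under the default policy: absence of prior associations is absence of
#' evidence of pleiotropy, not evidence of it.
#'
#' @param instruments harmonized instrument data.frame.
#' @param annotations data.frame (`snp_id`, `phenotypes` semicolon-separated);
#'   `NULL` or empty means no SNP is annotated.
#' @param config a [selection_config] supplying the allowed patterns.
#' @param keep_unannotated default TRUE.
#' @return list with `instruments` and `exclusions`.
#' @export
screen_mapped_phenotypes <- function(instruments, annotations = NULL,
                                     config = selection_config(),
                                     keep_unannotated = TRUE) {
  if (nrow(instruments) == 0L) {
    return(list(instruments = instruments,
                exclusions = data.frame(snp_id = character(), reason = character())))
  }
  phen <- instruments$mapped_phenotypes
  if ((is.null(phen) || all(!nzchar(phen) | is.na(phen))) &&
      !is.null(annotations) && nrow(annotations)) {
    idx <- match(instruments$snp_id, annotations$snp_id)
    phen <- ifelse(is.na(idx), "", annotations$phenotypes[idx])
  }
  phen[is.na(phen)] <- ""
  keep <- vapply(phen, function(p) {
    if (!nzchar(p)) return(keep_unannotated)
    traits <- trimws(strsplit(p, ";", fixed = TRUE)[[1]])
    any(vapply(config$allowed_phenotype_patterns, function(pat) {
      any(grepl(pat, traits, ignore.case = TRUE, fixed = FALSE))
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  out <- instruments[keep, , drop = FALSE]
  out$mapped_phenotypes <- phen[keep]
  rownames(out) <- NULL
  list(instruments = out,
       exclusions = data.frame(snp_id = instruments$snp_id[!keep],
                               reason = rep("no_dietary_phenotype", sum(!keep)),
                               stringsAsFactors = FALSE))
}

#' Run the full instrument-selection cascade
#'
#' suggestive filter -> LD clumping -> harmonization -> outcome screen ->
#' mapped-phenotype screen, with per-stage record counts and exclusion logs.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param ld optional LD list for [ld_clump()].
#' @param annotations optional annotation data.frame.
#' @param config a [selection_config].
#' @return list with `instruments`, `exclusions` (combined, with stage
#'   labels), and `counts` (records surviving each stage).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               annotations = NULL,
                               config = selection_config()) {
  n0 <- nrow(exposure)
  s1 <- filter_by_exposure_p(exposure, config$exposure_p_threshold)
  s2 <- ld_clump(s1, ld, config)
  h <- harmonize(s2, outcome, annotations = annotations)
  s3 <- screen_outcome_association(h$instruments, config$outcome_p_exclusion)
  s4 <- screen_mapped_phenotypes(s3$instruments, annotations, config)
  excl <- rbind(
    if (nrow(h$exclusions)) cbind(h$exclusions, stage = "harmonize"),
    if (nrow(s3$exclusions)) cbind(s3$exclusions, stage = "outcome_screen"),
    if (nrow(s4$exclusions)) cbind(s4$exclusions, stage = "phenotype_screen"))
  list(instruments = s4$instruments,
       exclusions = excl %||% data.frame(snp_id = character(),
                                         reason = character(),
                                         stage = character()),
       counts = c(input = n0, exposure_p = nrow(s1), ld_clump = nrow(s2),
                  harmonized = nrow(h$instruments),
                  outcome_screen = nrow(s3$instruments),
                  phenotype_screen = nrow(s4$instruments)))
}
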