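#' GWAS summary statistics: containers, I/O and harmonization
#'
#' A `summary_stats` object is a data.frame with one row per SNP association
#' (columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`) plus attributes `trait_name` and `n_samples`.
#' Harmonized exposure/outcome pairs are data.frames with columns `snp_id`,
#' `bx`, `sx`, `by`, `sy`, `eaf`, `mapped_phenotypes` — the per-instrument
#' quadruple all MR estimators consume.
#'
#' @name summary_data
NULL

#' Construct a summary_stats object from a data.frame
#'
#' Validates per-SNP association records: positive standard errors, allele
#' frequencies in \[0, 1\], p-values in (0, 1\], distinct alleles, unique SNP
#' ids. `other_allele` and `pos` may be `NA` (e.g. published instrument tables
#' that print only the effect allele); when present they are validated.
#'
#' @param df data.frame with columns `snp_id`, `beta`, `se`, `pvalue` and
#'   optionally `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`.
#' @param trait_name label for the trait the statistics describe.
#' @param n_samples optional GWAS sample size.
#' @return A `summary_stats` data.frame.
#' @export
summary_stats <- function(df, trait_name = "trait", n_samples = NA_integer_) {
  stopifnot(is.data.frame(df))
  needed <- c("snp_id", "beta", "se", "pvalue")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("chrom", "pos", "effect_allele", "other_allele", "eaf")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))
  }
  df$snp_id <- as.character(df$snp_id)
  dup <- unique(df$snp_id[duplicated(df$snp_id)])
  if (length(dup)) stop("duplicate snp_id: ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(df$se) | df$se <= 0)
  if (length(bad)) {
    stop("non-positive se in row(s) ", paste(bad, collapse = ", "),
         " (", paste(df$snp_id[bad], collapse = ", "), ")")
  }
  bad <- which(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  if (length(bad)) stop("eaf outside [0,1] in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1)
  if (length(bad)) stop("pvalue outside (0,1] in row(s) ", paste(bad, collapse = ", "))
  has_both <- !is.na(df$effect_allele) & !is.na(df$other_allele)
  bad <- which(has_both & df$effect_allele == df$other_allele)
  if (length(bad)) stop("effect_allele equals other_allele in row(s) ", paste(bad, collapse = ", "))
  out <- df[c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue")]
  rownames(out) <- NULL
  attr(out, "trait_name") <- trait_name
  attr(out, "n_samples") <- n_samples
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path tab- or comma-delimited file with a header row.
#' @param dialect named character vector mapping the canonical column names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`) to the file's header names. Only mapped columns
#'   are renamed; unmapped canonical columns are taken verbatim if present.
#' @param trait_name,n_samples stored as attributes on the result.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [summary_stats] object. Rows whose numeric fields fail coercion
#'   are rejected with an error naming the row numbers.
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_name = NULL,
                               n_samples = NA_integer_, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(raw)) {
        stop("dialect maps '", canon, "' to missing column '", src, "'")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  needed <- c("snp_id", "beta", "se", "pvalue")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    empty <- data.frame(snp_id = character(), beta = numeric(),
                        se = numeric(), pvalue = numeric())
    return(summary_stats(empty, trait_name = trait_name %||% basename(path),
                         n_samples = n_samples))
  }
  num_cols <- intersect(c("pos", "eaf", "beta", "se", "pvalue"), names(raw))
  for (col in num_cols) {
    coerced <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(coerced) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      stop("column '", col, "' fails numeric coercion in row(s): ",
           paste(bad, collapse = ", "))
    }
    raw[[col]] <- coerced
  }
  summary_stats(raw, trait_name = trait_name %||% basename(path),
                n_samples = n_samples)
}

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single characters in A/C/G/T.
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(as.character(effect_allele))
  a2 <- toupper(as.character(other_allele))
  ok <- a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
  if (any(!ok & !is.na(a1) & !is.na(a2))) {
    stop("non-ACGT allele: ",
         paste(unique(c(a1, a2)[!c(ok, ok)]), collapse = ", "))
  }
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[toupper(a)]
}

#' Harmonize exposure and outcome summary statistics into MR instruments
#'
#' Aligns every SNP present in both sets to the exposure's effect allele.
#' If the outcome's alleles are swapped relative to the exposure, the outcome
#' beta's sign is flipped and its allele frequency complemented; if they match
#' only after strand complement (A<->T, C<->G), the complement is applied
#' first. Palindromic SNPs whose exposure effect-allele frequency lies inside
#' `intermediate_af_band` (or is missing) are excluded: for them the strand is
#' unresolvable exactly when the frequency carries no information.
#' Irreconcilable allele pairs are excluded. Every exclusion is logged with a
#' reason code so the selection cascade stays auditable.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param intermediate_af_band numeric length-2, sub-interval of \[0,1\]
#'   containing 0.5; default `c(0.40, 0.60)`.
#' @param annotations optional data.frame (`snp_id`, `phenotypes`
#'   semicolon-separated) used to fill `mapped_phenotypes`.
#' @return list with `instruments` (data.frame: `snp_id`, `bx`, `sx`, `by`,
#'   `sy`, `eaf`, `mapped_phenotypes`, plus `chrom`/`pos` carried from the
#'   exposure) and `exclusions` (data.frame: `snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      intermediate_af_band = c(0.40, 0.60),
                      annotations = NULL) {
  stopifnot(length(intermediate_af_band) == 2,
            intermediate_af_band[1] <= 0.5, intermediate_af_band[2] >= 0.5,
            intermediate_af_band[1] >= 0, intermediate_af_band[2] <= 1)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) {
    warning("no overlapping SNPs between exposure and outcome")
    return(list(instruments = empty_instruments(),
                exclusions = data.frame(snp_id = character(),
                                        reason = character())))
  }
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]
  n <- length(shared)
  by <- ou$beta
  eaf_out <- ou$eaf
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  pal[is.na(pal)] <- FALSE
  in_band <- !is.na(ex$eaf) &
    ex$eaf >= intermediate_af_band[1] & ex$eaf <= intermediate_af_band[2]
  drop_pal <- pal & (in_band | is.na(ex$eaf))
  keep[drop_pal] <- FALSE
  reason[drop_pal] <- "palindromic_intermediate"

  for (i in which(keep)) {
    e_ea <- ex$effect_allele[i]; e_oa <- ex$other_allele[i]
    o_ea <- ou$effect_allele[i]; o_oa <- ou$other_allele[i]
    if (is.na(o_ea) || is.na(o_oa) || is.na(e_ea)) next  # assume pre-aligned
    if (identical(o_ea, e_ea) && (is.na(e_oa) || identical(o_oa, e_oa))) next
    if (!is.na(e_oa) && identical(o_ea, e_oa) && identical(o_oa, e_ea)) {
      by[i] <- -by[i]
      eaf_out[i] <- 1 - eaf_out[i]
      next
    }
    c_ea <- unname(complement_allele(o_ea))
    c_oa <- unname(complement_allele(o_oa))
    if (identical(c_ea, e_ea) && (is.na(e_oa) || identical(c_oa, e_oa))) next
    if (!is.na(e_oa) && identical(c_ea, e_oa) && identical(c_oa, e_ea)) {
      by[i] <- -by[i]
      eaf_out[i] <- 1 - eaf_out[i]
      next
    }
    keep[i] <- FALSE
    reason[i] <- "incompatible_alleles"
  }

  inst <- data.frame(snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
                     bx = ex$beta, sx = ex$se, by = by, sy = ou$se,
                     eaf = ex$eaf, mapped_phenotypes = "",
                     stringsAsFactors = FALSE)[keep, ]
  rownames(inst) <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    idx <- match(inst$snp_id, annotations$snp_id)
    inst$mapped_phenotypes <- ifelse(is.na(idx), "", annotations$phenotypes[idx])
  }
  list(instruments = inst,
       exclusions = data.frame(snp_id = shared[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

empty_instruments <- function() {
  data.frame(snp_id = character(), chrom = character(), pos = numeric(),
             bx = numeric(), sx = numeric(), by = numeric(), sy = numeric(),
             eaf = numeric(), mapped_phenotypes = character(),
             stringsAsFactors = FALSE)
}

check_instruments <- function(instruments, min_n = 1L, need = c("bx", "sx", "by", "sy")) {
  stopifnot(is.data.frame(instruments))
  missing_cols <- setdiff(need, names(instruments))
  if (length(missing_cols)) {
    stop("instruments lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(instruments) < min_n) {
    stop("need at least ", min_n, " instrument(s), got ", nrow(instruments))
  }
  if (any(instruments$sx <= 0) || any(instruments$sy <= 0)) {
    stop("instrument standard errors must be positive")
  }
  invisible(instruments)
}

#' Write / read harmonized instruments as tab-delimited text
#'
#' The written table round-trips losslessly through [read_instruments()].
#'
#' @param instruments instrument data.frame from [harmonize()].
#' @param path output file path.
#' @export
write_instruments <- function(instruments, path) {
  cols <- c("snp_id", "bx", "sx", "by", "sy", "eaf", "mapped_phenotypes")
  extra <- intersect(c("chrom", "pos"), names(instruments))
  out <- instruments[c(cols[1], extra, cols[-1])]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instruments
#' @export
read_instruments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("snp_id", "bx", "sx", "by", "sy")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("instrument file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"mapped_phenotypes" %in% names(df)) df$mapped_phenotypes <- ""
  df$mapped_phenotypes[is.na(df$mapped_phenotypes)] <- ""
  df$snp_id <- as.character(df$snp_id)
  check_instruments(df, min_n = 0L)
  df
}
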