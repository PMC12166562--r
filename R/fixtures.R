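#' Packaged instrument sets
#'
#' Per-SNP instrument tables for dietary phosphorus and vitamins B2, B6 and C
#' from a published Korean population-cohort (KoGES/KARE) GWAS of dietary
#' micronutrient intake and incident CKD, shipped as plain-text fixtures:
#' for each instrument the exposure beta/SE/p, the CKD outcome beta/SE/p on
#' the same effect allele, the effect-allele frequency, and the previously
#' reported mapped phenotypes. These are already harmonized — both betas
#' refer to the listed effect allele.
#'
#' @param nutrient one of `"phosphorus"`, `"vitamin_b2"`, `"vitamin_b6"`,
#'   `"vitamin_c"`.
#' @return instrument data.frame (`snp_id`, `chrom`, `bx`, `sx`, `by`, `sy`,
#'   `eaf`, `mapped_phenotypes`, plus `gene`, exposure/outcome p-values).
#' @export
micronutrient_instruments <- function(nutrient = c("phosphorus", "vitamin_b2",
                                                   "vitamin_b6", "vitamin_c")) {
  nutrient <- match.arg(nutrient)
  path <- system.file("extdata",
                      paste0("instruments_", nutrient, ".tsv"),
                      package = "nutrimr", mustWork = TRUE)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(snp_id = raw$snp_id, chrom = raw$chrom, pos = NA_real_,
                    gene = raw$gene,
                    effect_allele = raw$effect_allele,
                    bx = raw$beta_exposure, sx = raw$se_exposure,
                    px = raw$p_exposure,
                    by = raw$beta_outcome, sy = raw$se_outcome,
                    py = raw$p_outcome,
                    eaf = raw$eaf,
                    mapped_phenotypes = raw$mapped_phenotypes,
                    stringsAsFactors = FALSE)
  check_instruments(out)
  out
}

#' @rdname micronutrient_instruments
#' @export
micronutrient_traits <- function() {
  c("phosphorus", "vitamin_b2", "vitamin_b6", "vitamin_c")
}

#' Packaged SNP-to-phenotype annotation table
#'
#' Union of the previously reported mapped phenotypes across the four
#' instrument sets (stand-in for a GWAS-Catalog lookup), with phenotypes
#' semicolon-separated per SNP.
#'
#' @return data.frame: `snp_id`, `phenotypes`.
#' @export
instrument_annotations <- function() {
  path <- system.file("extdata", "snp_annotations.tsv",
                      package = "nutrimr", mustWork = TRUE)
  ann <- read.delim(path, stringsAsFactors = FALSE)
  names(ann) <- c("snp_id", "phenotypes")
  ann
}

#' Write the packaged instrument fixtures into a directory
#'
#' Copies the four per-nutrient instrument tables and the annotation table
#' as tab-delimited files; output is byte-stable across calls.
#'
#' @param dir destination directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
write_instrument_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(paste0("instruments_", micronutrient_traits(), ".tsv"),
             "snp_annotations.tsv")
  src <- vapply(files, function(f)
    system.file("extdata", f, package = "nutrimr", mustWork = TRUE),
    character(1))
  dest <- file.path(dir, files)
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}

# reference MR estimates with tolerance bands, for the comparison report
reference_estimates <- function() {
  path <- system.file("extdata", "reference_estimates.tsv",
                      package = "nutrimr", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
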