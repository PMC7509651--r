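# cfDNA quantification: conversion of Q-PCR mass concentrations into copy
# numbers per mL of plasma, derived ratios (MNR, DII), and the sample-level
# quality-control filters applied before any cohort analysis.

#' Constants used in cfDNA copy-number calculations
#'
#' `haploid_genome_pg` is the mass of one human haploid genome in picograms
#' (3.3 pg); `avogadro` is Avogadro's number in molecules per mole.
#'
#' @return A named list with elements `haploid_genome_pg` and `avogadro`.
#' @export
cfdna_constants <- function() {
  list(haploid_genome_pg = 3.3, avogadro = 6.02e23)
}

#' Nuclear cfDNA copy number per mL of plasma
#'
#' Converts a Q-PCR nuclear cfDNA mass concentration into genome-equivalent
#' copies per mL of plasma (or culture supernatant):
#' \deqn{Q = (c / 3.3) \times V_{elution} / V_{plasma}}
#' where \eqn{c} is in pg/uL, 3.3 pg is the mass of one haploid human genome,
#' \eqn{V_{elution}} is the extract elution volume in uL and
#' \eqn{V_{plasma}} the plasma volume in mL.
#'
#' @param concentration Nuclear cfDNA concentration in pg per uL (vectorised).
#' @param elution_volume Elution volume of the cfDNA extract, uL.
#' @param plasma_volume Plasma (or supernatant) volume used for extraction, mL.
#' @return Copies per mL, same length as `concentration`.
#' @examples
#' nuclear_copies_per_ml(3.3, elution_volume = 80, plasma_volume = 0.2) # 400
#' @export
nuclear_copies_per_ml <- function(concentration, elution_volume = 80,
                                  plasma_volume = 0.2) {
  check_number(concentration, "concentration", nonneg = TRUE)
  check_number(elution_volume, "elution_volume", positive = TRUE)
  check_number(plasma_volume, "plasma_volume", positive = TRUE)
  (concentration / cfdna_constants()$haploid_genome_pg) *
    (elution_volume / plasma_volume)
}

#' Mitochondrial cfDNA copy number per mL of plasma
#'
#' Converts a Q-PCR mitochondrial cfDNA mass concentration, quantified against
#' a double-stranded plasmid standard, into copies per mL of plasma:
#' \deqn{Q = \frac{c \, N_a}{2 \, MW \, L_{vector}} \times
#'       V_{elution} / V_{plasma}}
#' with \eqn{c} in g/uL, \eqn{N_a} Avogadro's number, \eqn{MW} the molecular
#' weight of one nucleotide (g/mol), \eqn{L_{vector}} the standard plasmid
#' length in nucleotides, and the factor 2 accounting for the double strand.
#'
#' @param concentration Mitochondrial cfDNA concentration in g per uL.
#' @param vector_length Length of the plasmid standard, nucleotides.
#' @param nucleotide_mw Molecular weight of one nucleotide, g/mol.
#' @param elution_volume Elution volume, uL.
#' @param plasma_volume Plasma volume, mL.
#' @return Copies per mL, same length as `concentration`.
#' @export
mito_copies_per_ml <- function(concentration, vector_length,
                               nucleotide_mw = 330, elution_volume = 80,
                               plasma_volume = 0.2) {
  check_number(concentration, "concentration", nonneg = TRUE)
  check_number(vector_length, "vector_length", positive = TRUE)
  check_number(nucleotide_mw, "nucleotide_mw", positive = TRUE)
  check_number(elution_volume, "elution_volume", positive = TRUE)
  check_number(plasma_volume, "plasma_volume", positive = TRUE)
  copies_per_ul <- concentration * cfdna_constants()$avogadro /
    (2 * nucleotide_mw * vector_length)
  copies_per_ul * (elution_volume / plasma_volume)
}

#' Mitochondrial-to-nuclear ratio (MNR)
#'
#' MNR = Ref M 67 / Ref A 67. Lower in cancer in this panel.
#'
#' @param ref_m67 Mitochondrial copies per mL (67 bp amplicon).
#' @param ref_a67 Nuclear copies per mL (67 bp amplicon); must be > 0 where
#'   both values are present (zero-denominator samples should already have
#'   been removed by QC).
#' @return `ref_m67 / ref_a67`; `NA` where either input is missing.
#' @export
compute_mnr <- function(ref_m67, ref_a67) {
  both <- !is.na(ref_m67) & !is.na(ref_a67)
  if (any(both & ref_a67 <= 0)) {
    stop_invalid("compute_mnr: ref_a67 must be > 0 (undefined ratio)")
  }
  ifelse(both, ref_m67 / ref_a67, NA_real_)
}

#' cfDNA integrity index (DII)
#'
#' DII = Ref A 320 / Ref A 67. High values flag contamination by long
#' genomic DNA fragments from white blood cells; samples with DII > 0.4 are
#' excluded by [apply_qc_filters()].
#'
#' @param ref_a320 Nuclear copies per mL, 320 bp amplicon.
#' @param ref_a67 Nuclear copies per mL, 67 bp amplicon; must be > 0 where
#'   both values are present.
#' @return `ref_a320 / ref_a67`; `NA` where either input is missing. Values
#'   above 1 are possible for contaminated samples and are not clamped.
#' @export
compute_dii <- function(ref_a320, ref_a67) {
  both <- !is.na(ref_a320) & !is.na(ref_a67)
  if (any(both & ref_a67 <= 0)) {
    stop_invalid("compute_dii: ref_a67 must be > 0 (undefined ratio)")
  }
  ifelse(both, ref_a320 / ref_a67, NA_real_)
}

#' Relative mitochondrial quantification from Cq values
#'
#' Fold ratio of mitochondrial to nuclear DNA from quantification cycles:
#' \eqn{2^{-dCq}} with \eqn{dCq = Cq_{mito} - Cq_{nuc}}. Used for murine
#' samples where absolute plasmid standards are not available.
#'
#' @param cq_mito Mitochondrial Cq (cycles).
#' @param cq_nuc Nuclear Cq (cycles).
#' @return Fold ratio, `2^-(cq_mito - cq_nuc)`.
#' @export
relative_mito_quant <- function(cq_mito, cq_nuc) {
  check_number(cq_mito, "cq_mito")
  check_number(cq_nuc, "cq_nuc")
  2^(-(cq_mito - cq_nuc))
}

#' Add derived ratio columns to a cohort
#'
#' Computes `mnr` and `dii` from the measured marker columns, overwriting any
#' existing values: the ratios are always derived, never read from file.
#'
#' @param cohort Cohort data frame with columns `ref_a67`, `ref_a145`,
#'   `ref_a320`, `ref_m67`.
#' @return The cohort with `mnr` and `dii` columns.
#' @export
add_derived_markers <- function(cohort) {
  cohort$mnr <- compute_mnr(cohort$ref_m67, cohort$ref_a67)
  cohort$dii <- compute_dii(cohort$ref_a320, cohort$ref_a67)
  cohort
}

#' Sample-level quality-control filters
#'
#' Excludes samples with too little total cfDNA (`ref_a67 < min_ref_a67`,
#' strict, so exactly 450 copies/mL is retained) and samples whose integrity
#' index indicates genomic-DNA contamination (`dii > max_dii`, strict, so
#' exactly 0.4 is retained). A sample failing both rules is recorded under the
#' low-`ref_a67` reason only (one primary reason per exclusion). Samples whose
#' DII cannot be computed because `ref_a320` is missing pass the DII rule and
#' are flagged in the report: QC never imputes.
#'
#' @param cohort Cohort data frame; every subject must have `ref_a67` present
#'   (subjects missing `ref_a67` are a missing-data question for
#'   [remove_missing()], not a QC one).
#' @param min_ref_a67 Lower bound on `ref_a67`, copies/mL (default 450).
#' @param max_dii Upper bound on `dii` (default 0.4).
#' @return A list with `cohort` (survivors, original order preserved) and
#'   `report`, a `qc_report` object with counts and per-subject reasons.
#' @export
apply_qc_filters <- function(cohort, min_ref_a67 = 450, max_dii = 0.4) {
  if (nrow(cohort) > 0 && anyNA(cohort$ref_a67)) {
    stop_invalid("apply_qc_filters: all subjects must have ref_a67 present")
  }
  if (!"dii" %in% names(cohort)) cohort <- add_derived_markers(cohort)
  low_a67 <- cohort$ref_a67 < min_ref_a67
  high_dii <- !is.na(cohort$dii) & cohort$dii > max_dii & !low_a67
  dii_unevaluable <- is.na(cohort$dii) & !low_a67
  excluded <- low_a67 | high_dii
  ids <- if ("subject_id" %in% names(cohort)) {
    as.character(cohort$subject_id)
  } else {
    as.character(seq_len(nrow(cohort)))
  }
  report <- structure(
    list(
      n_input = nrow(cohort),
      n_excluded_low_refa67 = sum(low_a67),
      n_excluded_high_dii = sum(high_dii),
      n_dii_unevaluable = sum(dii_unevaluable),
      min_ref_a67 = min_ref_a67,
      max_dii = max_dii,
      excluded = data.frame(
        subject_id = ids[excluded],
        reason = ifelse(low_a67[excluded], "low_ref_a67", "high_dii"),
        stringsAsFactors = FALSE
      ),
      dii_unevaluable_ids = ids[dii_unevaluable]
    ),
    class = "qc_report"
  )
  list(cohort = cohort[!excluded, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("cfDNA QC report\n")
  cat(sprintf("  input:               %d samples\n", x$n_input))
  cat(sprintf("  excluded low RefA67: %d (< %g copies/mL)\n",
              x$n_excluded_low_refa67, x$min_ref_a67))
  cat(sprintf("  excluded high DII:   %d (> %g)\n",
              x$n_excluded_high_dii, x$max_dii))
  cat(sprintf("  DII not evaluable:   %d (ref_a320 missing; retained)\n",
              x$n_dii_unevaluable))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [apply_qc_filters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Expected columns: `subject_id`, `group` (healthy / crc / breast / other),
#' `stage`, `age`, `sex`, and the measured markers `ref_a67`, `ref_a145`,
#' `ref_a320`, `ref_m67` in copies/mL (empty cell = missing). The derived
#' ratios `mnr` and `dii` are computed on read and never taken from the file.
#' Lines starting with `#` are treated as comments.
#'
#' @param path CSV file path.
#' @return Cohort data frame with derived markers attached.
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       na.strings = c("", "NA"))
  required <- c("subject_id", "group", "age", measured_markers())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_invalid("cohort CSV missing columns: ",
                 paste(missing_cols, collapse = ", "))
  }
  if (!"stage" %in% names(x)) x$stage <- NA_character_
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  x$subject_id <- as.character(x$subject_id)
  x$stage <- as.character(x$stage)
  for (m in measured_markers()) x[[m]] <- as.numeric(x[[m]])
  add_derived_markers(x)
}

#' Write a cohort CSV
#'
#' Writes the measured columns only (derived ratios are recomputed on read).
#' A provenance comment line with the package version and, when available,
#' the generator seed is prepended.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- intersect(c("subject_id", "group", "stage", "age", "sex",
                      measured_markers()), names(cohort))
  prov <- attr(cohort, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  seed_txt <- if (!is.null(prov$seed)) paste0(" seed=", prov$seed) else ""
  src_txt <- if (!is.null(prov$source)) paste0(" source=", prov$source) else ""
  writeLines(sprintf("# cfscreen %s cohort%s%s",
                     as.character(utils::packageVersion("cfscreen")),
                     src_txt, seed_txt), con)
  utils::write.csv(cohort[, cols, drop = FALSE], con, row.names = FALSE)
  invisible(path)
}
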