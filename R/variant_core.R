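#' Per-genotype quality-control filter
#'
#' A genotype passes QC when the site has FILTER `PASS`, the genotype quality
#' is at least `min_gq` (default 99), and the read depth of the called
#' allele(s) is at least `min_ad` (default 10): alternate-supporting reads
#' for alternate-carrying genotypes, reference reads for homozygous- or
#' hemizygous-reference calls. With `depth_mode = "total"` the ref+alt sum is
#' used instead. Filtering is per genotype: the same site may pass in one
#' sample and fail in another.
#'
#' @param filter site FILTER string(s).
#' @param gq genotype quality value(s).
#' @param ad_ref,ad_alt allelic depths.
#' @param geno genotype code(s) (see [gt_label()]).
#' @param min_gq,min_ad thresholds.
#' @param depth_mode `"called_allele"` (default) or `"total"`.
#' @return logical vector; missing genotypes fail.
#' @examples
#' qc_pass("PASS", 99, 15, 10, 1)   # boundary het: TRUE
#' qc_pass("PASS", 98, 15, 10, 1)   # GQ below threshold: FALSE
#' qc_pass("LowQual", 99, 0, 50, 2) # non-PASS: FALSE
#' @export
qc_pass <- function(filter, gq, ad_ref, ad_alt, geno,
                    min_gq = 99, min_ad = 10,
                    depth_mode = c("called_allele", "total")) {
  depth_mode <- match.arg(depth_mode)
  depth_ok <- if (depth_mode == "total") {
    (ad_ref + ad_alt) >= min_ad
  } else {
    ifelse(gt_carries_alt(geno), ad_alt >= min_ad, ad_ref >= min_ad)
  }
  out <- (filter == "PASS") & !is.na(gq) & gq >= min_gq &
    !is.na(depth_ok) & depth_ok & !is.na(geno)
  out & !is.na(out)
}

#' QC-pass matrix for a variant table
#'
#' @param vt a [variant_table()].
#' @param ... passed to [qc_pass()].
#' @return logical matrix aligned with `vt$geno`.
#' @export
qc_matrix <- function(vt, ...) {
  m <- qc_pass(matrix(vt$sites$filter, nrow = nrow(vt$geno),
                      ncol = ncol(vt$geno)),
               vt$gq, vt$ad_ref, vt$ad_alt, vt$geno, ...)
  dim(m) <- dim(vt$geno)
  dimnames(m) <- dimnames(vt$geno)
  m
}

#' Classify variants by population allele frequency
#'
#' A variant is *rare* when its allele frequency is below `maf_rare`
#' (default 1%) in all three population databases (1000G, gnomAD, GME);
#' *ultra-rare* when it is 0 (or absent, treated as unobserved) in all
#' three; and *private* when ultra-rare and carried by exactly one cohort
#' individual. Absent database frequencies are interpreted as 0; the
#' `observed` flag distinguishes "reported as 0" from "absent".
#'
#' @param af_1kg,af_gnomad,af_gme database allele frequencies (NA = absent).
#' @param cohort_carriers number of cohort individuals carrying the allele.
#' @param maf_rare rarity threshold.
#' @return tibble with `class` (`common`/`rare`/`ultra_rare`), `private`,
#'   and `observed` (TRUE when all three databases reported a frequency).
#' @examples
#' classify_frequency(0.009, 0.005, 0, 5)     # rare
#' classify_frequency(0, 0, 0, 1)             # ultra_rare, private
#' classify_frequency(0.02, 0, 0, 1)          # common: fails one database
#' @export
classify_frequency <- function(af_1kg, af_gnomad, af_gme, cohort_carriers,
                               maf_rare = 0.01) {
  observed <- !is.na(af_1kg) & !is.na(af_gnomad) & !is.na(af_gme)
  a1 <- ifelse(is.na(af_1kg), 0, af_1kg)
  a2 <- ifelse(is.na(af_gnomad), 0, af_gnomad)
  a3 <- ifelse(is.na(af_gme), 0, af_gme)
  rare <- a1 < maf_rare & a2 < maf_rare & a3 < maf_rare
  ultra <- a1 == 0 & a2 == 0 & a3 == 0
  tibble::tibble(
    class = ifelse(ultra, "ultra_rare", ifelse(rare, "rare", "common")),
    private = ultra & cohort_carriers == 1,
    observed = observed)
}

#' Export a (filtered) variant table as TSV
#'
#' Writes one row per site-sample genotype with the site annotations, the
#' genotype label, GQ, allelic depths, and the QC verdict. Subset `vt`
#' upstream to export only filtered sites.
#'
#' @param vt a [variant_table()].
#' @param path output TSV path.
#' @param ... passed to [qc_pass()] via [qc_matrix()].
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(vt, path, ...) {
  qm <- qc_matrix(vt, ...)
  samples <- colnames(vt$geno)
  long <- dplyr::bind_rows(lapply(samples, function(s) {
    d <- vt$sites
    d$sample_id <- s
    d$genotype <- gt_label(vt$geno[, s])
    d$gq <- vt$gq[, s]
    d$ad_ref <- vt$ad_ref[, s]
    d$ad_alt <- vt$ad_alt[, s]
    d$qc_pass <- qm[, s]
    d
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rarity helper over a variant table
#'
#' Adds `freq_class`, `private`, and `n_carriers` (cohort individuals whose
#' genotype carries the alternate allele) columns to the site tibble.
#'
#' @param vt a [variant_table()].
#' @param maf_rare rarity threshold.
#' @return the site tibble with classification columns.
#' @export
classify_table_frequency <- function(vt, maf_rare = 0.01) {
  carriers <- rowSums(gt_carries_alt(vt$geno))
  cls <- classify_frequency(vt$sites$af_1kg, vt$sites$af_gnomad,
                            vt$sites$af_gme, carriers, maf_rare)
  out <- vt$sites
  out$freq_class <- cls$class
  out$private <- cls$private
  out$n_carriers <- carriers
  out
}
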