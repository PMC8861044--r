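# helpers shared by the inheritance callers

.trio_ids <- function(ped, child) {
  i <- match(child, ped$sample_id)
  if (is.na(i)) stop("unknown child ", child)
  fa <- ped$father_id[i]
  mo <- ped$mother_id[i]
  if (is.na(fa) || is.na(mo)) stop(child, " has no recorded parents")
  sibs <- ped$sample_id[!is.na(ped$father_id) & ped$father_id == fa &
                          !is.na(ped$mother_id) & ped$mother_id == mo &
                          ped$sample_id != child]
  list(fa = fa, mo = mo, sibs = sibs)
}

.allele_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(tot > 0, ad_alt / tot, NA_real_)
}

# TRUE for X-chromosome rows of a site tibble
.is_x_site <- function(sites, x_chrom = "chrX") sites$chrom == x_chrom

#' Call de novo variants in an affected child
#'
#' A site is called de novo when the child carries the alternate allele, the
#' father, mother (and sibling, when available) do not, and all of the
#' following hold: allele balance alt/(ref+alt) within \[`min_ab`, `max_ab`\]
#' for autosomal and pseudoautosomal sites (and all sites in females), or
#' at least `max_ab` for X/Y sites in a male child; QD >= 4 and
#' ReadPosRankSum >= -2.5; allele frequency below 0.1% in all three
#' population databases; no other cohort individual carries the allele;
#' indel length below 50 bp; and the site lies outside segmental
#' duplications and simple repeats. All trio genotypes must pass QC; sites
#' with a missing parental genotype are skipped with a reason, not silently
#' dropped.
#'
#' @param vt a [variant_table()] covering the whole cohort.
#' @param ped pedigree tibble.
#' @param child affected child sample id.
#' @param model optional [genome_model()] used to flag pseudoautosomal
#'   positions; when `NULL`, GRCh37 PAR coordinates are assumed for `chrX`.
#' @param min_ab,max_ab heterozygous allele-balance window (default 0.3-0.7).
#' @param min_qd,min_rprs site-quality thresholds (default 4 and -2.5).
#' @param max_af de novo population-frequency ceiling (default 0.001).
#' @param max_indel_bp maximum indel length (default 50).
#' @return tibble with one row per site: `site_id`, per-criterion evidence
#'   columns, `skipped` (reason or NA), and `call`.
#' @export
call_de_novo <- function(vt, ped, child, model = NULL,
                         min_ab = 0.3, max_ab = 0.7, min_qd = 4,
                         min_rprs = -2.5, max_af = 0.001, max_indel_bp = 50) {
  tr <- .trio_ids(ped, child)
  sx <- ped$sex[match(child, ped$sample_id)]
  s <- vt$sites
  qc <- qc_matrix(vt)
  g_child <- vt$geno[, child]
  g_fa <- vt$geno[, tr$fa]
  g_mo <- vt$geno[, tr$mo]
  sib_clear <- rep(TRUE, nrow(s))
  for (sb in tr$sibs) sib_clear <- sib_clear & !gt_carries_alt(vt$geno[, sb])

  on_x <- if (!is.null(model)) {
    s$chrom %in% model$chromosomes$chrom[model$chromosomes$is_x]
  } else .is_x_site(s)
  in_par <- if (!is.null(model)) {
    on_x & .in_par(model, s$pos)
  } else {
    on_x & ((s$pos >= 60001 & s$pos <= 2699520) |
              (s$pos >= 154931044 & s$pos <= 155260560))
  }
  hemi_rule <- on_x & !in_par & sx == "male"

  ab <- .allele_balance(vt$ad_ref[, child], vt$ad_alt[, child])
  ab_ok <- ifelse(hemi_rule, ab >= max_ab, ab >= min_ab & ab <= max_ab)

  child_alt <- gt_carries_alt(g_child)
  parents_ref <- !gt_carries_alt(g_fa) & !gt_carries_alt(g_mo) &
    !is.na(g_fa) & !is.na(g_mo)
  other <- setdiff(colnames(vt$geno), c(child, tr$fa, tr$mo, tr$sibs))
  cohort_clear <- if (length(other)) {
    rowSums(gt_carries_alt(vt$geno[, other, drop = FALSE])) == 0
  } else rep(TRUE, nrow(s))
  af_ok <- classify_frequency(s$af_1kg, s$af_gnomad, s$af_gme, 1,
                              maf_rare = max_af)$class != "common"
  indel_len <- abs(nchar(s$ref) - nchar(s$alt))
  indel_ok <- indel_len < max_indel_bp
  repeat_ok <- !s$segdup & !s$simple_repeat
  qd_ok <- !is.na(s$qd) & s$qd >= min_qd
  rprs_ok <- !is.na(s$rprs) & s$rprs >= min_rprs
  qc_ok <- qc[, child] & qc[, tr$fa] & qc[, tr$mo]

  skipped <- rep(NA_character_, nrow(s))
  skipped[is.na(g_fa) | is.na(g_mo)] <- "missing_parent_genotype"
  skipped[is.na(g_child)] <- "missing_child_genotype"

  call <- child_alt & parents_ref & sib_clear & cohort_clear &
    !is.na(ab_ok) & ab_ok & qd_ok & rprs_ok & af_ok & indel_ok & repeat_ok &
    qc_ok & is.na(skipped)
  tibble::tibble(site_id = s$site_id, sample_id = child,
                 child_alt = child_alt, parents_ref = parents_ref,
                 sibling_clear = sib_clear, cohort_clear = cohort_clear,
                 allele_balance = ab, ab_ok = ab_ok, qd_ok = qd_ok,
                 rprs_ok = rprs_ok, af_ok = af_ok, indel_ok = indel_ok,
                 repeat_ok = repeat_ok, qc_ok = qc_ok, skipped = skipped,
                 call = call & !is.na(call))
}

#' Call compound-heterozygous variant pairs in an affected child
#'
#' From rare coding (exonic or splicing) QC-passing heterozygous sites in
#' the child, selects those heterozygous in exactly one parent and absent
#' from the other, then pairs paternally-only with maternally-only
#' transmitted sites within the same gene. Sites carried by both parents are
#' phase-ambiguous by transmission and excluded from pairing.
#'
#' @param vt a [variant_table()].
#' @param ped pedigree tibble.
#' @param child affected child sample id.
#' @param maf_rare rarity threshold (default 1%).
#' @param coding_effects effect classes treated as coding.
#' @return tibble of pairs: `gene`, `site_paternal`, `site_maternal`.
#' @export
call_compound_het <- function(vt, ped, child, maf_rare = 0.01,
                              coding_effects = c("synonymous_SNV",
                                "nonsynonymous_SNV", "stopgain", "stoploss",
                                "frameshift_indel", "nonframeshift_indel",
                                "splicing")) {
  tr <- .trio_ids(ped, child)
  s <- vt$sites
  qc <- qc_matrix(vt)
  carriers <- rowSums(gt_carries_alt(vt$geno))
  rare <- classify_frequency(s$af_1kg, s$af_gnomad, s$af_gme, carriers,
                             maf_rare)$class != "common"
  coding <- !is.na(s$effect) & s$effect %in% coding_effects
  child_het <- !is.na(vt$geno[, child]) & vt$geno[, child] == GT_HET
  fa_het <- !is.na(vt$geno[, tr$fa]) & vt$geno[, tr$fa] == GT_HET
  mo_het <- !is.na(vt$geno[, tr$mo]) & vt$geno[, tr$mo] == GT_HET
  fa_carrier <- gt_carries_alt(vt$geno[, tr$fa])
  mo_carrier <- gt_carries_alt(vt$geno[, tr$mo])
  ok <- rare & coding & child_het & qc[, child] & qc[, tr$fa] & qc[, tr$mo] &
    !is.na(s$gene)
  paternal <- ok & fa_het & !mo_carrier
  maternal <- ok & mo_het & !fa_carrier
  genes <- intersect(unique(s$gene[paternal]), unique(s$gene[maternal]))
  out <- lapply(genes, function(g) {
    expand.grid(site_paternal = s$site_id[paternal & s$gene == g],
                site_maternal = s$site_id[maternal & s$gene == g],
                stringsAsFactors = FALSE)
  })
  pairs <- dplyr::bind_rows(out)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(sample_id = character(), gene = character(),
                          site_paternal = character(),
                          site_maternal = character()))
  }
  gene_of <- stats::setNames(s$gene, s$site_id)
  tibble::tibble(sample_id = child,
                 gene = unname(gene_of[pairs$site_paternal]),
                 site_paternal = pairs$site_paternal,
                 site_maternal = pairs$site_maternal)
}

#' Call inherited homozygous variants in an affected child
#'
#' A site qualifies when the child is homozygous for the alternate allele and
#' both parents are heterozygous; sites homozygous in either parent are
#' excluded (full-penetrance assumption), as are sites homozygous-alternate
#' in an unaffected sibling.
#'
#' @param vt a [variant_table()].
#' @param ped pedigree tibble.
#' @param child affected child sample id.
#' @return tibble per site with evidence columns and `call`.
#' @export
call_hom_inherited <- function(vt, ped, child) {
  tr <- .trio_ids(ped, child)
  qc <- qc_matrix(vt)
  g_child <- vt$geno[, child]
  g_fa <- vt$geno[, tr$fa]
  g_mo <- vt$geno[, tr$mo]
  unaff_sibs <- tr$sibs[!ped$affected[match(tr$sibs, ped$sample_id)]]
  sib_clear <- rep(TRUE, nrow(vt$sites))
  for (sb in unaff_sibs) {
    sib_clear <- sib_clear & !(!is.na(vt$geno[, sb]) &
                                 vt$geno[, sb] == GT_HOM_ALT)
  }
  child_hom <- !is.na(g_child) & g_child == GT_HOM_ALT
  fa_het <- !is.na(g_fa) & g_fa == GT_HET
  mo_het <- !is.na(g_mo) & g_mo == GT_HET
  qc_ok <- qc[, child] & qc[, tr$fa] & qc[, tr$mo]
  call <- child_hom & fa_het & mo_het & sib_clear & qc_ok
  tibble::tibble(site_id = vt$sites$site_id, sample_id = child,
                 child_hom_alt = child_hom, father_het = fa_het,
                 mother_het = mo_het, sibling_clear = sib_clear,
                 qc_ok = qc_ok, call = call)
}

#' Call X-linked recessive variants in an affected male child
#'
#' A non-pseudoautosomal X site qualifies when the male child is hemizygous
#' for the alternate allele, the mother is heterozygous, and the (unaffected)
#' father does not carry the allele. Pseudoautosomal sites heterozygous in
#' the male child are excluded.
#'
#' @param vt a [variant_table()].
#' @param ped pedigree tibble.
#' @param child affected male child sample id.
#' @param model optional [genome_model()] for X/PAR coordinates; GRCh37 PARs
#'   on `chrX` assumed when `NULL`.
#' @return tibble per X site with evidence columns and `call`; errors if the
#'   child is not male.
#' @export
call_x_linked <- function(vt, ped, child, model = NULL) {
  if (ped$sex[match(child, ped$sample_id)] != "male")
    stop("X-linked recessive calling requires a male child")
  tr <- .trio_ids(ped, child)
  s <- vt$sites
  on_x <- if (!is.null(model)) {
    s$chrom %in% model$chromosomes$chrom[model$chromosomes$is_x]
  } else .is_x_site(s)
  if (!any(on_x)) {
    return(tibble::tibble(site_id = character(), sample_id = character(),
                          child_hemi_alt = logical(), mother_het = logical(),
                          father_clear = logical(), par_excluded = logical(),
                          qc_ok = logical(), call = logical()))
  }
  idx <- which(on_x)
  pos <- s$pos[idx]
  in_par <- if (!is.null(model)) .in_par(model, pos) else {
    (pos >= 60001 & pos <= 2699520) | (pos >= 154931044 & pos <= 155260560)
  }
  qc <- qc_matrix(vt)
  g_child <- vt$geno[idx, child]
  g_fa <- vt$geno[idx, tr$fa]
  g_mo <- vt$geno[idx, tr$mo]
  child_hemi <- !is.na(g_child) & g_child == GT_HEMI_ALT
  child_par_carrier <- in_par & gt_carries_alt(g_child)
  par_excluded <- in_par & !is.na(g_child) & g_child == GT_HET
  mother_het <- !is.na(g_mo) & g_mo == GT_HET
  father_clear <- !is.na(g_fa) & !gt_carries_alt(g_fa)
  qc_ok <- qc[idx, child] & qc[idx, tr$fa] & qc[idx, tr$mo]
  call <- (child_hemi | (child_par_carrier & !par_excluded)) & mother_het &
    father_clear & qc_ok & !par_excluded
  tibble::tibble(site_id = s$site_id[idx], sample_id = child,
                 child_hemi_alt = child_hemi, mother_het = mother_het,
                 father_clear = father_clear, par_excluded = par_excluded,
                 qc_ok = qc_ok, call = call)
}
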