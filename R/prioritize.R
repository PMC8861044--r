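#' Missense deleteriousness by damage-predictor vote
#'
#' A nonsynonymous variant is considered deleterious when it meets at least
#' `min_criteria` (default 2) of: SIFT < 0.05, PolyPhen-2 HumVar > 0.15,
#' PROVEAN < -2.5, MutationAssessor > 2.26. Missing scores count as failed.
#'
#' @param sift,pp2_hvar,provean,mut_assessor predictor scores (vectors).
#' @param min_criteria votes required (default 2).
#' @return tibble with per-criterion logicals (`sift_hit`, `pp2_hit`,
#'   `provean_hit`, `ma_hit`), `n_criteria`, and `deleterious`.
#' @examples
#' is_deleterious_missense(0.04, NA, -3.0, NA)$deleterious # TRUE (2 of 4)
#' is_deleterious_missense(NA, NA, NA, 2.3)$deleterious    # FALSE (1 of 4)
#' @export
is_deleterious_missense <- function(sift, pp2_hvar, provean, mut_assessor,
                                    min_criteria = 2) {
  hit <- function(x) !is.na(x) & x
  s <- hit(sift < 0.05)
  p <- hit(pp2_hvar > 0.15)
  v <- hit(provean < -2.5)
  m <- hit(mut_assessor > 2.26)
  n <- s + p + v + m
  tibble::tibble(sift_hit = s, pp2_hit = p, provean_hit = v, ma_hit = m,
                 n_criteria = n, deleterious = n >= min_criteria)
}

#' Filter inheritance calls to potentially pathogenic candidates
#'
#' Retains rare calls whose effect is frameshift indel, stopgain, stoploss,
#' splicing, unknown (kept to retain splice-site variants with unannotated
#' protein effect), or nonsynonymous-and-deleterious. Everything else is
#' dropped with a recorded reason.
#'
#' @param calls tibble with at least `effect`, `rare` (logical), and the four
#'   damage-score columns (`sift`, `pp2_hvar`, `provean`, `mut_assessor`).
#' @return `calls` with logical `retained` and character `drop_reason`.
#' @export
candidate_filter <- function(calls) {
  keep_effects <- c("frameshift_indel", "stopgain", "stoploss", "splicing",
                    "unknown")
  del <- is_deleterious_missense(calls$sift, calls$pp2_hvar, calls$provean,
                                 calls$mut_assessor)$deleterious
  effect_ok <- calls$effect %in% keep_effects |
    (calls$effect == "nonsynonymous_SNV" & del)
  retained <- calls$rare & effect_ok & !is.na(calls$effect)
  reason <- rep(NA_character_, nrow(calls))
  reason[!calls$rare] <- "not_rare"
  reason[calls$rare & !effect_ok] <- "effect_not_candidate"
  out <- calls
  out$retained <- retained
  out$drop_reason <- reason
  out
}

#' Subpopulation-based deprioritization
#'
#' A variant is deprioritized when any subpopulation relevant to the family's
#' ancestry shows MAF >= 1% for coding variants, or MAF > 0.1% or at least
#' one homozygote for noncoding variants.
#'
#' @param subpop encoded subpopulation string (see [parse_subpop()]) or a
#'   tibble with `subpop`, `af`, `hom`.
#' @param is_coding logical.
#' @param relevant_subpops character vector of subpopulation codes to
#'   consider; missing subpopulations provide no evidence.
#' @param coding_maf,noncoding_maf thresholds (defaults 0.01 and 0.001).
#' @return TRUE when the variant should be deprioritized.
#' @export
subpop_deprioritize <- function(subpop, is_coding, relevant_subpops,
                                coding_maf = 0.01, noncoding_maf = 0.001) {
  sp <- if (is.character(subpop)) parse_subpop(subpop) else subpop
  sp <- sp[sp$subpop %in% relevant_subpops, , drop = FALSE]
  if (nrow(sp) == 0) return(FALSE)
  if (is_coding) {
    any(sp$af >= coding_maf)
  } else {
    any(sp$af > noncoding_maf) || any(sp$hom >= 1)
  }
}

#' Cross-reference a gene against evidence tables
#'
#' Exact case-insensitive symbol matching against the SFARI gene table, the
#' neurodevelopmental-disease gene list, OMIM phenotype rows, and a brain
#' expression table. An optional alias map (tibble `alias`, `gene`) is
#' applied before matching.
#'
#' @param gene gene symbol.
#' @param sfari_table tibble with `gene` (and optionally `score`).
#' @param ndd_table tibble with `gene`.
#' @param omim_table tibble with `gene`, `phenotype`.
#' @param expression_table tibble with `gene`, `brain_expressed`.
#' @param alias_table optional tibble `alias`, `gene`.
#' @return one-row tibble (`GeneEvidence`): `gene`, `sfari_listed`,
#'   `sfari_score`, `ndd_listed`, `omim_phenotypes` (comma-joined),
#'   `brain_expressed`.
#' @export
cross_reference <- function(gene, sfari_table, ndd_table, omim_table,
                            expression_table, alias_table = NULL) {
  g <- toupper(gene)
  if (!is.null(alias_table)) {
    i <- match(g, toupper(alias_table$alias))
    if (!is.na(i)) g <- toupper(alias_table$gene[i])
  }
  in_tab <- function(tab) !is.null(tab) && g %in% toupper(tab$gene)
  sfari <- in_tab(sfari_table)
  score <- if (sfari && "score" %in% names(sfari_table)) {
    sfari_table$score[match(g, toupper(sfari_table$gene))]
  } else NA_character_
  omim <- if (!is.null(omim_table)) {
    omim_table$phenotype[toupper(omim_table$gene) == g]
  } else character(0)
  expr <- if (!is.null(expression_table) &&
                g %in% toupper(expression_table$gene)) {
    isTRUE(expression_table$brain_expressed[
      match(g, toupper(expression_table$gene))])
  } else FALSE
  tibble::tibble(gene = gene, sfari_listed = sfari,
                 sfari_score = as.character(score),
                 ndd_listed = in_tab(ndd_table),
                 omim_phenotypes = paste(omim, collapse = ","),
                 brain_expressed = expr)
}

#' Filter CNV calls against known ASD CNV loci
#'
#' Retains copy-number calls that intersect a SFARI CNV locus and are larger
#' than that locus's median size in ASD cases; each retained CNV is annotated
#' with its matched locus.
#'
#' @param cnvs tibble `sample_id`, `chrom`, `start`, `end`, `direction`.
#' @param sfari_cnv_table tibble `chrom`, `start`, `end`, `locus`,
#'   `median_size_bp`.
#' @return retained CNVs with `matched_locus` and `locus_median_bp`.
#' @export
cnv_overlap_filter <- function(cnvs, sfari_cnv_table) {
  if (!"median_size_bp" %in% names(sfari_cnv_table))
    stop("SFARI CNV table lacks median_size_bp")
  out <- list()
  for (i in seq_len(nrow(cnvs))) {
    len <- cnvs$end[i] - cnvs$start[i]
    hit <- sfari_cnv_table$chrom == cnvs$chrom[i] &
      sfari_cnv_table$start <= cnvs$end[i] &
      sfari_cnv_table$end >= cnvs$start[i]
    for (j in which(hit)) {
      if (len > sfari_cnv_table$median_size_bp[j]) {
        row <- cnvs[i, ]
        row$matched_locus <- sfari_cnv_table$locus[j]
        row$locus_median_bp <- sfari_cnv_table$median_size_bp[j]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    empty <- cnvs[0, ]
    empty$matched_locus <- character(0)
    empty$locus_median_bp <- numeric(0)
    return(empty)
  }
  dplyr::bind_rows(out)
}

#' Default priority-tier rule table
#'
#' Tiers are a pure function of a rationale vector of named logical criteria:
#' `deprioritized`, `known_gene` (SFARI- or NDD-listed), `brain_expressed`,
#' `deleterious` (coding damage vote, or conservation support),
#' `brain_specific_element` (noncoding category), `interaction_validated`
#' (promoter-enhancer link confirmed), `is_coding`. Default reading:
#' deprioritized variants are excluded; high priority requires a known gene,
#' or for coding variants brain expression plus deleteriousness, or for
#' noncoding variants a brain-specific element with a validated interaction;
#' medium requires at least one of those evidence lines; otherwise low. The
#' table is an editable list so alternative readings are testable.
#'
#' @return a list with a `tier` function (rationale -> tier string).
#' @export
default_tier_rules <- function() {
  list(
    tier = function(r) {
      if (isTRUE(r[["deprioritized"]])) return("excluded")
      coding_path <- isTRUE(r[["is_coding"]]) && isTRUE(r[["brain_expressed"]]) &&
        isTRUE(r[["deleterious"]])
      noncoding_path <- !isTRUE(r[["is_coding"]]) &&
        isTRUE(r[["brain_specific_element"]]) &&
        isTRUE(r[["interaction_validated"]])
      if (isTRUE(r[["known_gene"]]) || coding_path || noncoding_path)
        return("high")
      partial <- isTRUE(r[["brain_expressed"]]) || isTRUE(r[["deleterious"]]) ||
        isTRUE(r[["brain_specific_element"]])
      if (partial) return("medium")
      "low"
    })
}

#' Recompute a priority tier from an emitted rationale vector
#'
#' @param rationale named logical vector (see [default_tier_rules()]).
#' @param rules rule table.
#' @return tier string.
#' @export
tier_from_rationale <- function(rationale, rules = default_tier_rules()) {
  rules$tier(as.list(rationale))
}

#' Assign a priority tier to a candidate call
#'
#' Builds the rationale vector from the supplied evidence and derives the
#' tier with [tier_from_rationale()], so the emitted call is auditably
#' recomputable from its own rationale.
#'
#' @param call one-row tibble with at least `site_id` (or a pair id),
#'   `sample_id`, `mode`, and `effect`.
#' @param gene_evidence a [cross_reference()] row.
#' @param deleterious logical: damage/conservation support (coding).
#' @param regulatory_call optional [annotate_roh_noncoding()] row for
#'   noncoding variants (`NULL` for coding).
#' @param deprioritized logical from [subpop_deprioritize()].
#' @param rules tier rule table.
#' @return a `PriorityCall` tibble row: identifiers, `tier`, and the
#'   rationale as a packed `criterion=value` string (`rationale`).
#' @export
assign_tier <- function(call, gene_evidence, deleterious, regulatory_call,
                        deprioritized, rules = default_tier_rules()) {
  coding_effects <- c("synonymous_SNV", "nonsynonymous_SNV", "stopgain",
                      "stoploss", "frameshift_indel", "nonframeshift_indel",
                      "splicing", "unknown")
  is_coding <- isTRUE(call$effect %in% coding_effects)
  brain_specific <- FALSE
  interaction_validated <- FALSE
  if (!is.null(regulatory_call) && nrow(regulatory_call) == 1) {
    brain_specific <- regulatory_call$promoter_category ==
      "brain_specific_promoter" ||
      regulatory_call$enhancer_category == "brain_specific_enhancer"
    interaction_validated <- nzchar(regulatory_call$linked_genes)
  }
  rationale <- c(deprioritized = isTRUE(deprioritized),
                 known_gene = isTRUE(gene_evidence$sfari_listed) ||
                   isTRUE(gene_evidence$ndd_listed),
                 brain_expressed = isTRUE(gene_evidence$brain_expressed),
                 deleterious = isTRUE(deleterious),
                 brain_specific_element = brain_specific,
                 interaction_validated = interaction_validated,
                 is_coding = is_coding)
  tibble::tibble(site_id = call$site_id, sample_id = call$sample_id,
                 mode = call$mode, gene = gene_evidence$gene,
                 tier = tier_from_rationale(rationale, rules),
                 rationale = paste(names(rationale), rationale, sep = "=",
                                   collapse = ";"))
}

#' Unpack a rationale string back into a named logical vector
#'
#' @param s rationale string from [assign_tier()].
#' @return named logical vector.
#' @export
parse_rationale <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(parts, function(x) as.logical(x[2]), logical(1)),
                  vapply(parts, `[`, character(1), 1))
}

#' Per-sample candidate report
#'
#' Selects the high-priority calls of each affected individual; when an
#' individual carries none, their medium-priority calls are reported instead.
#'
#' @param priority_calls tibble of [assign_tier()] rows.
#' @return the selected subset, with a `report_rule` column (`"high"` or
#'   `"medium_fallback"`).
#' @export
select_candidates <- function(priority_calls) {
  out <- list()
  for (s in unique(priority_calls$sample_id)) {
    pc <- priority_calls[priority_calls$sample_id == s, , drop = FALSE]
    hi <- pc[pc$tier == "high", , drop = FALSE]
    if (nrow(hi)) {
      hi$report_rule <- "high"
      out[[length(out) + 1L]] <- hi
    } else {
      med <- pc[pc$tier == "medium", , drop = FALSE]
      if (nrow(med)) {
        med$report_rule <- "medium_fallback"
        out[[length(out) + 1L]] <- med
      }
    }
  }
  if (!length(out)) {
    empty <- priority_calls[0, ]
    empty$report_rule <- character(0)
    return(empty)
  }
  dplyr::bind_rows(out)
}
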