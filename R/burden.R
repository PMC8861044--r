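#' Classify variant effects into ND / MD / LoF
#'
#' Loss-of-function (LoF): splice site variants and exonic variants predicted
#' to result in a stopgain, stoploss, or frameshift indel. Nondisrupting
#' (ND): exonic synonymous SNVs and non-frameshift indels. Missense damaging
#' (MD): nonsynonymous SNVs meeting at least two of SIFT < 0.05,
#' PolyPhen-2 HumVar > 0.15, PROVEAN < -2.5, MutationAssessor > 2.26
#' (missing scores cannot support MD). Everything else (noncoding,
#' nonsynonymous failing the MD rule) is `unclassified`.
#'
#' @param effect effect annotation vector.
#' @param sift,pp2_hvar,provean,mut_assessor damage predictor scores.
#' @return character vector: `"ND"`, `"MD"`, `"LoF"`, `"unclassified"`.
#' @export
classify_effect <- function(effect, sift = NA, pp2_hvar = NA, provean = NA,
                            mut_assessor = NA) {
  lof <- effect %in% c("splicing", "stopgain", "stoploss", "frameshift_indel")
  nd <- effect %in% c("synonymous_SNV", "nonframeshift_indel")
  md <- effect == "nonsynonymous_SNV" &
    is_deleterious_missense(sift, pp2_hvar, provean, mut_assessor)$deleterious
  out <- rep("unclassified", length(effect))
  out[md] <- "MD"
  out[nd] <- "ND"
  out[lof] <- "LoF"
  out[is.na(effect)] <- "unclassified"
  out
}

# per-sample inside/outside counts per effect class
.burden_counts <- function(variants) {
  ag <- stats::aggregate(list(n = rep(1L, nrow(variants))),
                         by = list(sample_id = variants$sample_id,
                                   burden_class = variants$burden_class,
                                   in_roh = variants$in_roh),
                         FUN = sum)
  tibble::as_tibble(ag)
}

#' Rare-variant burden rates inside versus outside ROHs
#'
#' For every individual, the inside rate is the variant count inside ROHs
#' divided by that individual's total ROH length, and the outside rate is
#' the remaining count divided by the remaining genome, both expressed per
#' 1e8 bp. Inside-versus-outside contrasts are tested per class with an
#' unpaired t-test across individuals (Welch by default).
#'
#' @param variants tibble with `sample_id`, `in_roh` (from
#'   [variants_in_roh()]), and `burden_class` (`ND`, `MD`, `LoF`;
#'   `unclassified` rows are dropped with a message). MD and LoF are also
#'   pooled into a combined `LoF/MD` class.
#' @param roh_bp named numeric: total ROH bp per sample.
#' @param genome_bp callable genome length (single number or named per
#'   sample).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `rates` (per sample x class: `n_inside`, `n_outside`,
#'   `rate_inside`, `rate_outside`) and `tests` (per class: t statistic,
#'   p-value, means).
#' @export
roh_burden_rates <- function(variants, roh_bp, genome_bp, var_equal = FALSE) {
  stopifnot(all(roh_bp > 0), all(genome_bp > roh_bp))
  drop_n <- sum(variants$burden_class == "unclassified")
  if (drop_n > 0) {
    message(drop_n, " unclassified variants excluded from burden rates")
    variants <- variants[variants$burden_class != "unclassified", ,
                         drop = FALSE]
  }
  pooled <- variants
  pooled$burden_class[pooled$burden_class %in% c("MD", "LoF")] <- "LoF/MD"
  variants <- dplyr::bind_rows(variants, pooled[pooled$burden_class == "LoF/MD", ])
  samples <- names(roh_bp)
  gbp <- if (length(genome_bp) == 1) stats::setNames(rep(genome_bp,
    length(samples)), samples) else genome_bp
  grid <- expand.grid(sample_id = samples,
                      burden_class = unique(variants$burden_class),
                      stringsAsFactors = FALSE)
  cnt <- .burden_counts(variants)
  rates <- dplyr::left_join(tibble::as_tibble(grid),
    tidyr_pivot(cnt), by = c("sample_id", "burden_class"))
  rates$n_inside[is.na(rates$n_inside)] <- 0L
  rates$n_outside[is.na(rates$n_outside)] <- 0L
  rates$rate_inside <- unname(rates$n_inside / roh_bp[rates$sample_id] * 1e8)
  rates$rate_outside <- unname(rates$n_outside /
    (gbp[rates$sample_id] - roh_bp[rates$sample_id]) * 1e8)
  tests <- dplyr::bind_rows(lapply(unique(rates$burden_class), function(cl) {
    r <- rates[rates$burden_class == cl, ]
    tt <- .safe_t(r$rate_inside, r$rate_outside, var_equal)
    tibble::tibble(burden_class = cl, mean_inside = mean(r$rate_inside),
                   mean_outside = mean(r$rate_outside),
                   t = tt$t, p_value = tt$p)
  }))
  list(rates = tibble::as_tibble(rates), tests = tests)
}

# counts long -> wide without importing tidyr
tidyr_pivot <- function(cnt) {
  inside <- cnt[cnt$in_roh, c("sample_id", "burden_class", "n")]
  outside <- cnt[!cnt$in_roh, c("sample_id", "burden_class", "n")]
  names(inside)[3] <- "n_inside"
  names(outside)[3] <- "n_outside"
  dplyr::full_join(inside, outside, by = c("sample_id", "burden_class"))
}

.safe_t <- function(x, y, var_equal = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = NA_real_, p = NA_real_))
  # degenerate inputs t.test rejects: equal constants -> no evidence (p = 1);
  # distinct constants -> perfect separation (p = 0)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (same) 0 else Inf, p = if (same) 1 else 0))
  }
  tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) return(list(t = NA_real_, p = NA_real_))
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Fraction of rare homozygous variants falling inside ROHs
#'
#' Per sample and per class (`all`, `LoF/MD`, `ND`), the percentage of rare
#' homozygous variants located inside ROHs, contrasted (unpaired t-test)
#' against the percentage of the genome inside ROHs and between classes.
#' Samples with no variants in a class are excluded from that class with a
#' note.
#'
#' @param variants tibble with `sample_id`, `in_roh`, `burden_class`.
#' @param genome_fraction named numeric: per-sample fraction (0-1) of the
#'   genome inside ROHs.
#' @return list with `fractions` (per sample x class, in percent, including
#'   `genome_pct`), `tests`, and `excluded` (sample/class cells with no
#'   variants).
#' @export
hom_fraction_in_roh <- function(variants, genome_fraction) {
  classes <- list(all = c("ND", "MD", "LoF", "unclassified"),
                  `LoF/MD` = c("MD", "LoF"), ND = "ND")
  samples <- names(genome_fraction)
  rows <- list()
  excluded <- list()
  for (cl in names(classes)) {
    for (s in samples) {
      v <- variants[variants$sample_id == s &
                      variants$burden_class %in% classes[[cl]], ]
      if (nrow(v) == 0) {
        excluded[[length(excluded) + 1L]] <- tibble::tibble(
          sample_id = s, class = cl, note = "no variants; excluded")
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = s, class = cl, n = nrow(v),
        pct_in_roh = 100 * mean(v$in_roh),
        genome_pct = 100 * genome_fraction[[s]])
    }
  }
  fr <- dplyr::bind_rows(rows)
  tests <- dplyr::bind_rows(lapply(names(classes), function(cl) {
    f <- fr[fr$class == cl, ]
    tt <- .safe_t(f$pct_in_roh, f$genome_pct)
    tibble::tibble(contrast = paste0(cl, "_vs_genome"),
                   mean_pct = mean(f$pct_in_roh),
                   mean_genome_pct = mean(f$genome_pct),
                   t = tt$t, p_value = tt$p)
  }))
  a <- fr[fr$class == "LoF/MD", ]
  b <- fr[fr$class == "ND", ]
  tt <- .safe_t(a$pct_in_roh, b$pct_in_roh)
  tests <- dplyr::bind_rows(tests, tibble::tibble(
    contrast = "LoF/MD_vs_ND", mean_pct = mean(a$pct_in_roh),
    mean_genome_pct = mean(b$pct_in_roh), t = tt$t, p_value = tt$p))
  list(fractions = fr, tests = tests,
       excluded = dplyr::bind_rows(excluded))
}

#' Compare constraint scores of ROH versus non-ROH gene sets
#'
#' Mean pLI, pRec, and pNull for genes carrying rare inherited homozygous
#' variants inside versus outside ROHs, with an unpaired t-test per score.
#' Genes absent from the constraint table are dropped and counted.
#'
#' @param genes_roh,genes_non_roh character vectors of gene symbols.
#' @param constraint_table tibble `gene`, `pli`, `prec`, `pnull`.
#' @return list with `summary` (one row per gene set: means and `n_genes`),
#'   `tests` (per score), `n_dropped`.
#' @export
constraint_comparison <- function(genes_roh, genes_non_roh, constraint_table) {
  if (length(genes_roh) == 0 || length(genes_non_roh) == 0)
    stop("both gene sets must be non-empty")
  pick <- function(genes) {
    constraint_table[constraint_table$gene %in% genes, , drop = FALSE]
  }
  a <- pick(genes_roh)
  b <- pick(genes_non_roh)
  n_dropped <- (length(unique(genes_roh)) - nrow(a)) +
    (length(unique(genes_non_roh)) - nrow(b))
  summarize <- function(x, tag) {
    tibble::tibble(gene_set = tag, mean_pli = mean(x$pli),
                   mean_prec = mean(x$prec), mean_pnull = mean(x$pnull),
                   n_genes = nrow(x))
  }
  tests <- dplyr::bind_rows(lapply(c(pli = "pli", prec = "prec",
                                     pnull = "pnull"), function(sc) {
    tt <- .safe_t(a[[sc]], b[[sc]])
    tibble::tibble(score = sc, t = tt$t, p_value = tt$p)
  }))
  list(summary = dplyr::bind_rows(summarize(a, "ROH"),
                                  summarize(b, "non_ROH")),
       tests = tests, n_dropped = n_dropped)
}

#' Affected-versus-unaffected burden comparison
#'
#' Per effect class, compares rare-variant counts per individual between
#' affected and unaffected individuals with an unpaired t-test.
#'
#' @param counts tibble `sample_id`, `burden_class`, `n`.
#' @param affected named logical: affection status per sample.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return tibble per class: group means, t, p-value.
#' @export
group_burden <- function(counts, affected, var_equal = FALSE) {
  if (sum(affected) < 2 || sum(!affected) < 2)
    stop("need at least two individuals per group")
  dplyr::bind_rows(lapply(unique(counts$burden_class), function(cl) {
    cc <- counts[counts$burden_class == cl, ]
    x <- cc$n[affected[cc$sample_id]]
    y <- cc$n[!affected[cc$sample_id]]
    tt <- .safe_t(x, y, var_equal)
    tibble::tibble(burden_class = cl, mean_affected = mean(x),
                   mean_unaffected = mean(y), t = tt$t, p_value = tt$p)
  }))
}
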