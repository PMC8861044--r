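# variant footprint: an SNV occupies its position; an indel the REF footprint
.variant_footprint <- function(pos, ref) {
  w <- pmax(1L, nchar(ref))
  list(start = pos, end = pos + w - 1L)
}

# TRUE where a variant footprint overlaps any interval of a track
.overlaps_track <- function(chrom, start, end, track) {
  hit <- rep(FALSE, length(chrom))
  if (is.null(track) || nrow(track) == 0) return(hit)
  for (cn in intersect(unique(chrom), unique(track$chrom))) {
    vi <- which(chrom == cn)
    ti <- which(track$chrom == cn)
    q <- IRanges::IRanges(start = start[vi], end = end[vi])
    subj <- IRanges::IRanges(start = track$start[ti], end = track$end[ti])
    hit[vi] <- IRanges::overlapsAny(q, subj)
  }
  hit
}

#' Classify variants as brain / brain-specific promoter variants
#'
#' A variant inside any brain H3K4me3 peak is a *predicted human brain
#' promoter* variant; it is upgraded to *brain-specific* when no chromatin
#' state labeled `1_Active_Promoter` in any of the non-neuronal cell lines
#' overlaps its position. Tracks are expected 1-based inclusive in memory
#' (see [read_bed()] for the on-disk BED convention).
#'
#' @param variants tibble with `chrom`, `pos`, `ref` (ref optional; indel
#'   overlap uses the REF footprint).
#' @param h3k4me3 peak tibble (`chrom`, `start`, `end`).
#' @param chromatin_states tibble (`chrom`, `start`, `end`, `cell_line`,
#'   `state`); fewer than 9 distinct cell lines triggers a warning.
#' @return character vector: `"brain_specific_promoter"`,
#'   `"brain_promoter"`, or `"none"` per variant.
#' @export
classify_promoter <- function(variants, h3k4me3, chromatin_states) {
  .check_cell_lines(chromatin_states)
  fp <- .variant_footprint(variants$pos,
                           if ("ref" %in% names(variants)) variants$ref else "N")
  in_peak <- .overlaps_track(variants$chrom, fp$start, fp$end, h3k4me3)
  ap <- chromatin_states[chromatin_states$state == "1_Active_Promoter", ,
                         drop = FALSE]
  in_active <- .overlaps_track(variants$chrom, fp$start, fp$end, ap)
  ifelse(in_peak & !in_active, "brain_specific_promoter",
         ifelse(in_peak, "brain_promoter", "none"))
}

#' Classify variants as brain / brain-specific enhancer variants
#'
#' A variant inside a predicted regulatory element (pRE) from developmental
#' brain is a *predicted human brain enhancer* variant; brain-specific when
#' no `4_Strong_Enhancer` or `5_Strong_Enhancer` chromatin state of any
#' non-neuronal cell line overlaps it.
#'
#' @inheritParams classify_promoter
#' @param pre pRE interval tibble.
#' @return character vector: `"brain_specific_enhancer"`,
#'   `"brain_enhancer"`, or `"none"` per variant.
#' @export
classify_enhancer <- function(variants, pre, chromatin_states) {
  .check_cell_lines(chromatin_states)
  fp <- .variant_footprint(variants$pos,
                           if ("ref" %in% names(variants)) variants$ref else "N")
  in_pre <- .overlaps_track(variants$chrom, fp$start, fp$end, pre)
  se <- chromatin_states[chromatin_states$state %in%
                           c("4_Strong_Enhancer", "5_Strong_Enhancer"), ,
                         drop = FALSE]
  in_strong <- .overlaps_track(variants$chrom, fp$start, fp$end, se)
  ifelse(in_pre & !in_strong, "brain_specific_enhancer",
         ifelse(in_pre, "brain_enhancer", "none"))
}

.check_cell_lines <- function(chromatin_states) {
  n <- length(unique(chromatin_states$cell_line))
  if (n < 9) {
    warning("chromatin-state track covers ", n,
            " cell lines (9 expected); specificity calls use the ",
            "provided lines only")
  }
  invisible(n)
}

#' Link a regulatory variant to target genes via interaction pairs
#'
#' Returns the genes of all promoter-enhancer interaction pairs where one
#' anchor contains the variant (or its regulatory element) and the other
#' anchor overlaps that gene's promoter.
#'
#' @param variant one-row tibble (`chrom`, `pos`, optionally `ref`).
#' @param pairs interaction tibble (`chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`, `gene`), 1-based inclusive.
#' @param gene_promoters tibble (`gene`, `chrom`, `start`, `end`).
#' @return character vector of linked gene symbols (possibly empty).
#' @export
link_to_genes <- function(variant, pairs, gene_promoters) {
  if (nrow(pairs) == 0) return(character(0))
  fp <- .variant_footprint(variant$pos,
                           if ("ref" %in% names(variant)) variant$ref else "N")
  hit1 <- pairs$chrom1 == variant$chrom &
    pairs$start1 <= fp$end & pairs$end1 >= fp$start
  hit2 <- pairs$chrom2 == variant$chrom &
    pairs$start2 <= fp$end & pairs$end2 >= fp$start
  linked <- character(0)
  for (i in which(hit1 | hit2)) {
    g <- pairs$gene[i]
    gp <- gene_promoters[gene_promoters$gene == g, , drop = FALSE]
    if (nrow(gp) == 0) next
    # the anchor NOT containing the variant must overlap the gene's promoter
    other <- if (hit1[i]) {
      list(chrom = pairs$chrom2[i], start = pairs$start2[i],
           end = pairs$end2[i])
    } else {
      list(chrom = pairs$chrom1[i], start = pairs$start1[i],
           end = pairs$end1[i])
    }
    prom_hit <- any(gp$chrom == other$chrom & gp$start <= other$end &
                      gp$end >= other$start, na.rm = TRUE)
    if (isTRUE(prom_hit)) linked <- c(linked, g)
  }
  unique(linked)
}

#' Regulatory annotation of rare inherited homozygous noncoding ROH variants
#'
#' For each input variant (expected: noncoding, rare, inherited-homozygous,
#' inside an ROH), reports the promoter and enhancer category, linked target
#' genes via interaction pairs, and overlapping activating marks
#' (H3K4me1/H3K27ac). A variant overlapping both promoter- and
#' enhancer-defining tracks receives both calls.
#'
#' @param variants tibble with `site_id`, `sample_id`, `chrom`, `pos`,
#'   `ref` (optional).
#' @param tracks a [generate_tracks()]-shaped list (`h3k4me3`, `pre`,
#'   `chromatin_states`, `marks`, `interactions`, `gene_promoters`).
#' @return tibble: inputs plus `promoter_category`, `enhancer_category`,
#'   `linked_genes` (comma-joined), `supporting_marks` (comma-joined).
#' @export
annotate_roh_noncoding <- function(variants, tracks) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(site_id = character(), sample_id = character(),
                          chrom = character(), pos = numeric(),
                          promoter_category = character(),
                          enhancer_category = character(),
                          linked_genes = character(),
                          supporting_marks = character()))
  }
  prom <- classify_promoter(variants, tracks$h3k4me3, tracks$chromatin_states)
  enh <- classify_enhancer(variants, tracks$pre, tracks$chromatin_states)
  fp <- .variant_footprint(variants$pos,
                           if ("ref" %in% names(variants)) variants$ref else "N")
  marks <- vapply(seq_len(nrow(variants)), function(i) {
    mk <- tracks$marks
    hit <- mk$chrom == variants$chrom[i] & mk$start <= fp$end[i] &
      mk$end >= fp$start[i]
    paste(sort(unique(mk$mark[hit])), collapse = ",")
  }, character(1))
  linked <- vapply(seq_len(nrow(variants)), function(i) {
    g <- link_to_genes(variants[i, ], tracks$interactions,
                       tracks$gene_promoters)
    paste(g, collapse = ",")
  }, character(1))
  tibble::tibble(site_id = variants$site_id, sample_id = variants$sample_id,
                 chrom = variants$chrom, pos = variants$pos,
                 promoter_category = prom, enhancer_category = enh,
                 linked_genes = linked, supporting_marks = marks)
}
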