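#' Cohort-level site filter for homozygosity mapping
#'
#' Retains sites with Hardy-Weinberg exact p-value >= `hwe_p` (default
#' 0.001), cohort minor-allele frequency above `min_maf` (default 5%), and a
#' missing-genotype rate no greater than `max_missing_rate` (default 25%).
#' Hemizygous calls are excluded from the genotype counts.
#'
#' @param geno integer genotype matrix (sites x samples, package codes).
#' @param hwe_p,min_maf,max_missing_rate thresholds.
#' @return logical vector of retained sites; errors when nothing survives.
#' @export
roh_site_filter <- function(geno, hwe_p = 0.001, min_maf = 0.05,
                            max_missing_rate = 0.25) {
  n_samp <- ncol(geno)
  is_dip <- !is.na(geno) & geno <= GT_HOM_ALT
  n_het <- rowSums(geno == GT_HET & is_dip, na.rm = TRUE)
  n_hom_alt <- rowSums(geno == GT_HOM_ALT & is_dip, na.rm = TRUE)
  n_hom_ref <- rowSums(geno == GT_HOM_REF & is_dip, na.rm = TRUE)
  n_called <- n_het + n_hom_alt + n_hom_ref
  miss_rate <- 1 - rowSums(!is.na(geno)) / n_samp
  alt_count <- 2 * n_hom_alt + n_het
  maf <- ifelse(n_called > 0,
                pmin(alt_count, 2 * n_called - alt_count) / (2 * n_called), 0)
  keep_basic <- maf > min_maf & miss_rate <= max_missing_rate & n_called > 0
  p <- rep(1, nrow(geno))
  if (any(keep_basic)) {
    p[keep_basic] <- hwe_exact_p(n_het[keep_basic],
                                 pmin(n_hom_alt, n_hom_ref)[keep_basic],
                                 pmax(n_hom_alt, n_hom_ref)[keep_basic])
  }
  keep <- keep_basic & p >= hwe_p
  if (!any(keep)) {
    stop("no sites retained by the ROH site filter; increase site density ",
         "or relax the thresholds")
  }
  keep
}

#' Detect runs of homozygosity in one genome
#'
#' Sliding-window scan over position-sorted, filter-passing sites: each
#' window of `window_sites` consecutive sites qualifies when it contains at
#' most `max_het` heterozygous and `max_missing` missing genotypes. Sites
#' covered by at least one qualifying window form candidate runs; each
#' maximal run is trimmed to its first and last homozygous site, kept when
#' its fraction of homozygous calls among non-missing calls (PHOM) reaches
#' `phom` and its length exceeds `min_length_bp`. Chromosomes with fewer
#' sites than one window yield no segments.
#'
#' Segment ends are refined so they meet the homozygosity threshold locally:
#' each end is trimmed inward to the outermost homozygous site whose
#' inward-facing window of `edge_sites` sites contains at most
#' `floor((1 - phom) * edge_sites)` heterozygotes. Without this, the
#' permissive window allowance (30 heterozygotes per 100 sites) lets runs
#' extend tens of sites into flanking heterozygote-dense sequence before the
#' first/last-homozygous-site trim, inflating segment ends.
#'
#' @param geno integer genotype vector for one sample, aligned with `sites`.
#' @param sites tibble with `chrom` and `pos`, position-sorted.
#' @param sample_id label for the output.
#' @param window_sites window size in variants (default 100).
#' @param max_het,max_missing per-window allowances (default 30 each).
#' @param phom homozygosity threshold (default 0.75).
#' @param min_length_bp minimum emitted segment length (default 1 Mb).
#' @param edge_sites terminal-window size for end refinement (default 30;
#'   0 disables refinement).
#' @return tibble of `ROHSegment`s: `sample_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_sites`, `n_het`, `n_missing`, `phom`.
#' @export
detect_roh <- function(geno, sites, sample_id = "sample",
                       window_sites = 100, max_het = 30, max_missing = 30,
                       phom = 0.75, min_length_bp = 1e6, edge_sites = 30) {
  stopifnot(length(geno) == nrow(sites))
  out <- list()
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    if (any(diff(sites$pos[idx]) < 0)) stop("sites are not position-sorted")
    g <- geno[idx]
    n <- length(g)
    if (n < window_sites) next
    het <- as.integer(!is.na(g) & g == GT_HET)
    mis <- as.integer(is.na(g))
    hom <- !is.na(g) & gt_is_hom(g)
    ch <- c(0, cumsum(het))
    cm <- c(0, cumsum(mis))
    nw <- n - window_sites + 1
    w_het <- ch[(window_sites + 1):(n + 1)] - ch[1:nw]
    w_mis <- cm[(window_sites + 1):(n + 1)] - cm[1:nw]
    ok <- w_het <= max_het & w_mis <= max_missing
    # coverage: site i is in a run if any qualifying window covers it
    cov <- integer(n + 1)
    wi <- which(ok)
    if (!length(wi)) next
    cov[wi] <- cov[wi] + 1L
    cov[wi + window_sites] <- cov[wi + window_sites] - 1L
    in_run <- cumsum(cov[1:n]) > 0
    r <- rle(in_run)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts_i[k]; b <- ends_i[k]
      if (edge_sites > 1 && b - a + 1 > edge_sites) {
        e <- min(edge_sites, b - a + 1)
        max_edge_het <- floor((1 - phom) * e)
        che <- c(0, cumsum(het[a:b]))
        nr <- b - a + 1
        # heterozygotes in the inward-facing window at each candidate end
        left_het <- che[pmin(nr, seq_len(nr) + e - 1) + 1] - che[seq_len(nr)]
        right_het <- che[seq_len(nr) + 1] - che[pmax(1, seq_len(nr) - e + 1)]
        la <- which(left_het <= max_edge_het & hom[a:b])
        lb <- which(right_het <= max_edge_het & hom[a:b])
        if (!length(la) || !length(lb)) next
        a <- a + la[1] - 1
        b_new <- ends_i[k] - (nr - lb[length(lb)])
        if (b_new <= a) next
        b <- b_new
      }
      hom_idx <- which(hom[a:b]) + a - 1
      if (!length(hom_idx)) next
      a2 <- hom_idx[1]; b2 <- hom_idx[length(hom_idx)]
      nn <- b2 - a2 + 1
      n_het_run <- sum(het[a2:b2])
      n_mis_run <- sum(mis[a2:b2])
      ph <- sum(hom[a2:b2]) / max(1, nn - n_mis_run)
      len <- sites$pos[idx[b2]] - sites$pos[idx[a2]] + 1
      if (ph >= phom && len > min_length_bp) {
        out[[length(out) + 1L]] <- tibble::tibble(
          sample_id = sample_id, chrom = cn,
          start = sites$pos[idx[a2]], end = sites$pos[idx[b2]],
          n_sites = nn, n_het = n_het_run, n_missing = n_mis_run, phom = ph)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_sites = integer(), n_het = integer(),
                          n_missing = integer(), phom = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Detect ROHs for every sample of a genotype matrix
#'
#' @param geno sites x samples genotype matrix.
#' @param sites site tibble aligned with `geno`.
#' @param ... passed to [detect_roh()].
#' @return combined segment tibble over samples.
#' @export
detect_roh_cohort <- function(geno, sites, ...) {
  dplyr::bind_rows(lapply(colnames(geno), function(s) {
    detect_roh(geno[, s], sites, sample_id = s, ...)
  }))
}

#' Per-genome ROH metrics
#'
#' Computed from autosomal segments only. The genome fraction is the ratio
#' of total ROH length to the callable-base denominator (for synthetic data
#' the simulated genome length; for real data, bases sequenced at 1x).
#'
#' @param segments segment tibble from [detect_roh()] (one sample, or use
#'   `dplyr::group_by` upstream).
#' @param callable_bases denominator in bp (> 0).
#' @param autosomes chromosome names to keep; `NULL` keeps all.
#' @return one-row tibble: `n_segments`, `mean_length_bp`, `max_length_bp`,
#'   `total_length_bp`, `genome_fraction`.
#' @export
roh_metrics <- function(segments, callable_bases, autosomes = NULL) {
  if (callable_bases <= 0) stop("callable_bases must be positive")
  if (!is.null(autosomes)) {
    segments <- segments[segments$chrom %in% autosomes, , drop = FALSE]
  }
  len <- segments$end - segments$start + 1
  tot <- sum(len)
  tibble::tibble(n_segments = nrow(segments),
                 mean_length_bp = if (nrow(segments)) mean(len) else 0,
                 max_length_bp = if (nrow(segments)) max(len) else 0,
                 total_length_bp = tot,
                 genome_fraction = tot / callable_bases)
}

#' Merge ROHs shared by at least two affected individuals
#'
#' Overlapping segments from distinct affected individuals are unified by
#' single-linkage chaining into merged intervals (the union of the
#' contributing segments); only merged intervals carried by at least
#' `min_carriers` distinct individuals are emitted.
#'
#' @param segments combined segment tibble (affected individuals only).
#' @param min_carriers minimum number of distinct carriers (default 2).
#' @return tibble of `MergedROH`s: `chrom`, `start`, `end`,
#'   `carrier_samples` (comma-joined), `n_carriers`.
#' @export
merge_shared_roh <- function(segments, min_carriers = 2) {
  out <- list()
  for (cn in unique(segments$chrom)) {
    seg <- segments[segments$chrom == cn, , drop = FALSE]
    seg <- seg[order(seg$start, seg$end), , drop = FALSE]
    cl_start <- seg$start[1]; cl_end <- seg$end[1]
    members <- seg$sample_id[1]
    flush <- function(s, e, mem) {
      u <- sort(unique(mem))
      if (length(u) >= min_carriers) {
        out[[length(out) + 1L]] <<- tibble::tibble(
          chrom = cn, start = s, end = e,
          carrier_samples = paste(u, collapse = ","),
          n_carriers = length(u))
      }
    }
    if (nrow(seg) > 1) {
      for (i in 2:nrow(seg)) {
        if (seg$start[i] <= cl_end) {
          cl_end <- max(cl_end, seg$end[i])
          members <- c(members, seg$sample_id[i])
        } else {
          flush(cl_start, cl_end, members)
          cl_start <- seg$start[i]; cl_end <- seg$end[i]
          members <- seg$sample_id[i]
        }
      }
    }
    flush(cl_start, cl_end, members)
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), carrier_samples = character(),
                          n_carriers = integer()))
  }
  dplyr::bind_rows(out)
}

#' Remove child ROHs overlapping any parental ROH
#'
#' Any-overlap semantics: a child segment sharing even a single base with a
#' parental segment is removed; non-overlapping segments are retained intact.
#'
#' @param child_segments,parent_segments segment tibbles from the same
#'   family.
#' @return retained child segments.
#' @export
subtract_parental_roh <- function(child_segments, parent_segments) {
  if (nrow(child_segments) == 0 || nrow(parent_segments) == 0)
    return(child_segments)
  keep <- rep(TRUE, nrow(child_segments))
  for (cn in unique(child_segments$chrom)) {
    ci <- which(child_segments$chrom == cn)
    pp <- parent_segments[parent_segments$chrom == cn, , drop = FALSE]
    if (nrow(pp) == 0) next
    q <- IRanges::IRanges(start = child_segments$start[ci],
                          end = child_segments$end[ci])
    subj <- IRanges::IRanges(start = pp$start, end = pp$end)
    hit <- IRanges::overlapsAny(q, subj)
    keep[ci[hit]] <- FALSE
  }
  child_segments[keep, , drop = FALSE]
}

#' Partition variants by ROH membership
#'
#' A variant is inside iff its position lies within a segment of the same
#' sample (bounds inclusive). The partition is exhaustive and exclusive.
#'
#' @param segments segment tibble.
#' @param variants tibble with `sample_id`, `chrom`, `pos`.
#' @return `variants` with a logical `in_roh` column.
#' @export
variants_in_roh <- function(segments, variants) {
  in_roh <- rep(FALSE, nrow(variants))
  if (nrow(segments) && nrow(variants)) {
    key_v <- paste(variants$sample_id, variants$chrom)
    key_s <- paste(segments$sample_id, segments$chrom)
    for (k in intersect(unique(key_v), unique(key_s))) {
      vi <- which(key_v == k)
      si <- which(key_s == k)
      q <- IRanges::IRanges(start = variants$pos[vi], width = 1)
      subj <- IRanges::IRanges(start = segments$start[si],
                               end = segments$end[si])
      in_roh[vi] <- IRanges::overlapsAny(q, subj)
    }
  }
  out <- variants
  out$in_roh <- in_roh
  out
}
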