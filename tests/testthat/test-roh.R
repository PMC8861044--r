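test_that("HWE exact test matches a direct enumeration oracle (n <= 50)", {
  # oracle: log-factorial formula for every possible heterozygote count
  hwe_oracle <- function(n_het, n_hom_rare, n_hom_common) {
    n <- n_het + n_hom_rare + n_hom_common
    n1 <- 2 * min(n_hom_rare, n_hom_common) + n_het
    n1 <- min(n1, 2 * n - n1)
    if (n1 == 0) return(1)
    hets <- seq(n1 %% 2, n1, by = 2)
    lp <- vapply(hets, function(h) {
      naa <- (n1 - h) / 2
      nAA <- n - naa - h
      lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
        h * log(2) + lfactorial(n1) + lfactorial(2 * n - n1) -
        lfactorial(2 * n)
    }, numeric(1))
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    obs <- p[match(n_het, hets)]
    min(1, sum(p[p <= obs + 1e-12]))
  }
  set.seed(42)
  for (i in 1:300) {
    n <- sample(2:50, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_lt(abs(hwe_exact_test(counts[1], counts[2], counts[3]) -
                    hwe_oracle(counts[1], counts[2], counts[3])), 1e-9)
  }
  # all-heterozygote configuration at cohort scale is strongly rejected
  expect_lt(hwe_exact_test(40, 0, 28), 0.001)
  # near-HWE proportions survive the P < 0.001 filter comfortably
  expect_gt(hwe_exact_test(30, 7, 31), 0.05)
})

test_that("the ROH site filter applies HWE, MAF, and missingness rules", {
  n <- 68
  mk_geno <- function(n_het, n_hom_alt, n_missing = 0) {
    g <- c(rep(1L, n_het), rep(2L, n_hom_alt),
           rep(NA_integer_, n_missing),
           rep(0L, n - n_het - n_hom_alt - n_missing))
    matrix(g, nrow = 1)
  }
  # near-HWE at MAF ~0.3, fully called -> retained
  good <- mk_geno(29, 6)
  # all carriers heterozygous (het excess) -> HWE-removed
  het_excess <- mk_geno(40, 0)
  # MAF 4% -> removed
  low_maf <- mk_geno(5, 0)
  # 30% missing -> removed
  holey <- mk_geno(20, 4, n_missing = 21)
  geno <- rbind(good, het_excess, low_maf, holey)
  keep <- roh_site_filter(geno)
  expect_identical(keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(roh_site_filter(rbind(low_maf)), "no sites retained")
})

test_that("a fully homozygous 2 Mb stretch yields exactly one covering segment", {
  set.seed(7)
  # 6 Mb chromosome, 1 site/kb: dense heterozygosity flanking a homozygous core
  pos <- sort(sample.int(6e6, 6000))
  core <- pos >= 2e6 & pos <= 4e6
  g <- ifelse(core, ifelse(runif(6000) < 0.5, 0L, 2L), 1L)
  sites <- tibble::tibble(chrom = "chr1", pos = pos)
  segs <- detect_roh(g, sites)
  expect_equal(nrow(segs), 1)
  # boundaries at the first/last homozygous sites of the core (within the
  # local site spacing)
  expect_lt(abs(segs$start - 2e6), 5e3)
  expect_lt(abs(segs$end - 4e6), 5e3)
  expect_equal(segs$n_het, 0L)
  expect_gte(segs$phom, 0.75)
})

test_that("segments below the minimum length or PHOM threshold are not emitted", {
  set.seed(8)
  pos <- sort(sample.int(3e6, 3000))
  # 0.5 Mb fully homozygous core only
  core <- pos >= 1e6 & pos <= 1.5e6
  g <- ifelse(core, 0L, ifelse(runif(3000) < 0.5, 1L, 0L))
  expect_equal(nrow(detect_roh(g, tibble::tibble(chrom = "chr1", pos = pos))), 0)
  # 40% heterozygous stretch: PHOM < 0.75 by construction
  g2 <- ifelse(runif(3000) < 0.4, 1L, 0L)
  segs2 <- detect_roh(g2, tibble::tibble(chrom = "chr1", pos = pos))
  expect_equal(nrow(segs2), 0)
})

test_that("chromosomes with fewer sites than one window yield no segments", {
  sites <- tibble::tibble(chrom = "chr1", pos = seq(1e5, 9.9e6, by = 1e5))
  g <- rep(0L, nrow(sites))
  expect_equal(nrow(detect_roh(g, sites)), 0)
})

test_that("total ROH length is invariant under chromosome processing order", {
  model <- small_model(site_density = 100, rare_prop = 0)
  ped <- build_pedigree("double_first_cousin")
  co <- sim_cohort(ped, model, seed = 55)
  auto <- co$sites$chrom != "chrX"
  keep <- roh_site_filter(co$geno[auto, ])
  sites <- co$sites[auto, ][keep, ]
  g <- co$geno[auto, "FAM1_c1"][keep]
  fwd <- detect_roh(g, sites)
  ord <- order(match(sites$chrom, rev(unique(sites$chrom))), sites$pos)
  rev_segs <- detect_roh(g[ord], sites[ord, ])
  expect_equal(sum(fwd$end - fwd$start + 1),
               sum(rev_segs$end - rev_segs$start + 1))
  expect_setequal(paste(fwd$chrom, fwd$start, fwd$end),
                  paste(rev_segs$chrom, rev_segs$start, rev_segs$end))
})

test_that("ROH metrics reproduce the reported cohort arithmetic", {
  # 278.7 Mb of autosomal ROH over 2,888 Mb callable is 9.65% of the genome
  segs <- tibble::tibble(sample_id = "p", chrom = "chr1",
                         start = 1, end = 278.7e6)
  m <- roh_metrics(segs, 2888e6)
  expect_equal(round(100 * m$genome_fraction, 2), 9.65)
  expect_equal(m$total_length_bp, 278.7e6)
  # degenerate cases
  empty <- roh_metrics(segs[0, ], 1e9)
  expect_equal(empty$genome_fraction, 0)
  expect_equal(empty$n_segments, 0)
  whole <- roh_metrics(tibble::tibble(sample_id = "p", chrom = "chr1",
                                      start = 1, end = 1e9), 1e9)
  expect_equal(whole$genome_fraction, 1)
  expect_error(roh_metrics(segs, 0), "positive")
  # X segments are excluded from autosomal metrics
  segs_x <- dplyr::bind_rows(segs, tibble::tibble(
    sample_id = "p", chrom = "chrX", start = 1, end = 50e6))
  m2 <- roh_metrics(segs_x, 2888e6, autosomes = paste0("chr", 1:22))
  expect_equal(m2$total_length_bp, 278.7e6)
})

test_that("shared-ROH merging unifies overlaps from >= 2 affected carriers", {
  segs <- tibble::tibble(
    sample_id = c("p1", "p2", "p1", "p2", "p3", "p3"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2", "chr3"),
    start = c(1e6, 1e6, 5e6, 5.5e6, 6.2e6, 1e6),
    end = c(2e6, 2e6, 6e6, 6.5e6, 7e6, 2e6))
  merged <- merge_shared_roh(segs)
  expect_equal(nrow(merged), 2)
  m1 <- merged[merged$chrom == "chr1", ]
  expect_equal(c(m1$start, m1$end, m1$n_carriers), c(1e6, 2e6, 2))
  m2 <- merged[merged$chrom == "chr2", ]
  expect_equal(c(m2$start, m2$end, m2$n_carriers), c(5e6, 7e6, 3))
  # chr3 segment is private to p3 -> not emitted
  expect_false("chr3" %in% merged$chrom)
})

test_that("merging equals a brute-force interval-union oracle on random input", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    segs <- tibble::tibble(
      sample_id = paste0("p", sample(1:6, n, replace = TRUE)),
      chrom = "chr1",
      start = sample.int(5e6, n))
    segs$end <- segs$start + sample.int(1e6, n)
    merged <- merge_shared_roh(segs)
    # oracle: per-bp carrier painting at 1 kb resolution
    L <- ceiling(6.1e6 / 1e3)
    paint <- matrix(FALSE, nrow = 6, ncol = L)
    for (i in seq_len(nrow(segs))) {
      p <- as.integer(sub("p", "", segs$sample_id[i]))
      paint[p, ceiling(segs$start[i] / 1e3):floor(segs$end[i] / 1e3)] <- TRUE
    }
    covered <- colSums(paint) > 0
    # merged intervals must cover exactly the union of cluster regions with
    # >= 2 distinct carriers anywhere in the cluster
    in_merged <- rep(FALSE, L)
    for (i in seq_len(nrow(merged))) {
      in_merged[ceiling(merged$start[i] / 1e3):floor(merged$end[i] / 1e3)] <- TRUE
    }
    # clusters = runs of covered bins; a cluster is emitted iff it has >= 2 carriers
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      carriers <- sum(rowSums(paint[, starts[k]:ends[k], drop = FALSE]) > 0)
      expect_equal(all(in_merged[starts[k]:ends[k]]), carriers >= 2)
    }
  }
})

test_that("parental ROH subtraction removes any-overlap segments", {
  child <- tibble::tibble(sample_id = "c", chrom = c("chr1", "chr1", "chr2"),
                          start = c(1e6, 5e6, 1e6), end = c(2e6, 6e6, 2e6))
  parent <- tibble::tibble(sample_id = "f", chrom = c("chr1", "chr2"),
                           start = c(1e6, 2e6), end = c(2e6, 3e6))
  kept <- subtract_parental_roh(child, parent)
  # identical overlap removed; 1 bp overlap (chr2: child ends at 2e6,
  # parent starts at 2e6) removed; disjoint segment kept
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 5e6)
  expect_equal(nrow(subtract_parental_roh(child, parent[0, ])), 3)
})

test_that("variant partition matches a brute-force point-in-interval scan", {
  set.seed(13)
  segs <- tibble::tibble(sample_id = sample(c("a", "b"), 30, replace = TRUE),
                         chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                         start = sample.int(9e6, 30))
  segs$end <- segs$start + sample.int(1e6, 30)
  variants <- tibble::tibble(
    sample_id = sample(c("a", "b"), 1000, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(1e7, 1000))
  res <- variants_in_roh(segs, variants)
  oracle <- vapply(seq_len(nrow(variants)), function(i) {
    any(segs$sample_id == variants$sample_id[i] &
          segs$chrom == variants$chrom[i] &
          segs$start <= variants$pos[i] & segs$end >= variants$pos[i])
  }, logical(1))
  expect_identical(res$in_roh, oracle)
  # inclusive bounds at both segment ends
  one <- tibble::tibble(sample_id = "a", chrom = "chr1",
                        start = 100, end = 200)
  pts <- tibble::tibble(sample_id = "a", chrom = "chr1",
                        pos = c(100, 200, 201, 99))
  expect_identical(variants_in_roh(one, pts)$in_roh,
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("emitted segments recover planted truth autozygosity (Jaccard)", {
  model <- default_genome("test", include_x = FALSE, site_density = 100,
                          af_spec = default_af_spec(0))
  sites <- synthesize_sites(model, seed = 17)
  ped <- build_pedigree("first_cousin", n_children = 4)
  drop <- gene_drop(ped, model, 18)
  al <- draw_founder_alleles(sites, drop$founder_haps, 18)
  g <- genotype_cohort(drop, sites, al, samples = ped_children(ped))
  keep <- roh_site_filter(g)
  fs <- sites[keep, ]
  inter <- 0; uni <- 0
  for (s in colnames(g)) {
    segs <- detect_roh(g[keep, s], fs, sample_id = s)
    truth <- drop$autozygous[drop$autozygous$sample_id == s &
                               drop$autozygous$end - drop$autozygous$start + 1 > 1e6, ]
    for (cn in unique(c(segs$chrom, truth$chrom))) {
      L <- model$chromosomes$length_bp[model$chromosomes$chrom == cn] / 1e3
      a <- logical(L); b <- logical(L)
      sg <- segs[segs$chrom == cn, ]; tr <- truth[truth$chrom == cn, ]
      for (i in seq_len(nrow(sg)))
        a[ceiling(sg$start[i] / 1e3):floor(sg$end[i] / 1e3)] <- TRUE
      for (i in seq_len(nrow(tr)))
        b[ceiling(tr$start[i] / 1e3):floor(tr$end[i] / 1e3)] <- TRUE
      inter <- inter + sum(a & b); uni <- uni + sum(a | b)
    }
  }
  expect_gte(inter / uni, 0.95)
})
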