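nine_lines <- function(states) {
  cells <- c("GM12878", "H1hESC", "HepG2", "HMEC", "HSMM", "HUVEC", "K562",
             "NHEK", "NHLF")
  dplyr::bind_rows(lapply(cells, function(cl) {
    s <- states
    s$cell_line <- cl
    s
  }))
}

test_that("promoter classification follows the peak + specificity rule", {
  peaks <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  # active-promoter state overlapping position 1500 in one cell line only
  cs <- nine_lines(tibble::tibble(chrom = "chr1", start = 5000, end = 6000,
                                  state = "1_Active_Promoter"))
  cs <- dplyr::bind_rows(cs, tibble::tibble(
    chrom = "chr1", start = 1400, end = 1600, state = "1_Active_Promoter",
    cell_line = "HepG2"))
  v <- tibble::tibble(chrom = "chr1", pos = c(1200, 1500, 9000), ref = "A")
  got <- classify_promoter(v, peaks, cs)
  expect_equal(got, c("brain_specific_promoter", "brain_promoter", "none"))
})

test_that("enhancer classification follows the pRE + strong-enhancer rule", {
  pre <- tibble::tibble(chrom = "chr2", start = 100, end = 300)
  cs <- nine_lines(tibble::tibble(chrom = "chr2", start = 9000, end = 9500,
                                  state = "7_Weak_Enhancer"))
  cs <- dplyr::bind_rows(cs, tibble::tibble(
    chrom = "chr2", start = 250, end = 260, state = "4_Strong_Enhancer",
    cell_line = "K562"))
  v <- tibble::tibble(chrom = "chr2", pos = c(150, 255, 400), ref = "A")
  got <- classify_enhancer(v, pre, cs)
  expect_equal(got, c("brain_specific_enhancer", "brain_enhancer", "none"))
  # a weak/other state does not break specificity
  v2 <- tibble::tibble(chrom = "chr2", pos = 150, ref = "A")
  cs2 <- nine_lines(tibble::tibble(chrom = "chr2", start = 100, end = 300,
                                   state = "13_Heterochrom"))
  expect_equal(classify_enhancer(v2, pre, cs2), "brain_specific_enhancer")
})

test_that("fewer than nine cell lines warns but still classifies", {
  pre <- tibble::tibble(chrom = "chr2", start = 100, end = 300)
  cs <- tibble::tibble(chrom = "chr2", start = 1, end = 2,
                       state = "13_Heterochrom", cell_line = "K562")
  expect_warning(got <- classify_enhancer(tibble::tibble(chrom = "chr2",
                                                         pos = 150, ref = "A"),
                                          pre, cs), "9")
  expect_equal(got, "brain_specific_enhancer")
})

test_that("indel overlap uses the REF footprint", {
  peaks <- tibble::tibble(chrom = "chr1", start = 1010, end = 1050)
  cs <- nine_lines(tibble::tibble(chrom = "chr1", start = 1, end = 2,
                                  state = "13_Heterochrom"))
  # 15 bp deletion starting at 1000 spans into the peak
  v_del <- tibble::tibble(chrom = "chr1", pos = 1000,
                          ref = paste(rep("A", 15), collapse = ""))
  expect_equal(classify_promoter(v_del, peaks, cs),
               "brain_specific_promoter")
  # SNV at 1000 does not reach the peak
  v_snv <- tibble::tibble(chrom = "chr1", pos = 1000, ref = "A")
  expect_equal(classify_promoter(v_snv, peaks, cs), "none")
})

test_that("classification equals a brute-force overlap oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:4) {
    n_iv <- 40
    track <- tibble::tibble(chrom = sample(c("chr1", "chr2"), n_iv, TRUE),
                            start = sample.int(1e5, n_iv))
    track$end <- track$start + sample.int(3000, n_iv)
    states <- c("1_Active_Promoter", "4_Strong_Enhancer", "5_Strong_Enhancer",
                "13_Heterochrom")
    cs <- nine_lines(tibble::tibble(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                                    start = sample.int(1e5, 20),
                                    state = sample(states, 20, TRUE)))
    cs$end <- cs$start + sample.int(3000, nrow(cs))
    v <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                        pos = sample.int(1.05e5, 300), ref = "A")
    got <- classify_promoter(v, track, cs)
    in_peak <- brute_overlap(v$chrom, v$pos, v$pos, track)
    ap <- cs[cs$state == "1_Active_Promoter", ]
    in_ap <- brute_overlap(v$chrom, v$pos, v$pos, ap)
    want <- ifelse(in_peak & !in_ap, "brain_specific_promoter",
                   ifelse(in_peak, "brain_promoter", "none"))
    expect_identical(got, want)
    # order invariance: shuffling track records changes nothing
    got2 <- classify_promoter(v, track[sample.int(n_iv), ],
                              cs[sample.int(nrow(cs)), ])
    expect_identical(got2, got)
  }
})

test_that("specific calls always satisfy the general brain-level condition", {
  set.seed(100)
  track <- tibble::tibble(chrom = "chr1", start = sample.int(5e4, 30))
  track$end <- track$start + 500
  cs <- nine_lines(tibble::tibble(chrom = "chr1",
                                  start = sample.int(5e4, 10),
                                  state = "4_Strong_Enhancer"))
  cs$end <- cs$start + 800
  v <- tibble::tibble(chrom = "chr1", pos = sample.int(5.1e4, 500), ref = "A")
  got <- classify_enhancer(v, track, cs)
  in_pre <- brute_overlap(v$chrom, v$pos, v$pos, track)
  expect_true(all(got[got == "brain_specific_enhancer"] != "none"))
  expect_true(all((got != "none") == in_pre))
})

test_that("interaction linking returns genes whose promoter the far anchor hits", {
  pairs <- tibble::tibble(
    chrom1 = c("chr1", "chr1", "chr1"), start1 = c(100, 100, 5000),
    end1 = c(200, 200, 5100),
    chrom2 = c("chr1", "chr1", "chr1"), start2 = c(9000, 7000, 9000),
    end2 = c(9100, 7100, 9100),
    gene = c("G1", "G2", "G3"))
  gp <- tibble::tibble(gene = c("G1", "G2", "G3"),
                       chrom = "chr1",
                       start = c(9050, 8000, 9050), end = c(9060, 8100, 9060))
  v <- tibble::tibble(chrom = "chr1", pos = 150, ref = "A")
  # G1: anchor2 overlaps its promoter; G2: anchor2 misses its promoter;
  # G3: variant not in either anchor
  expect_setequal(link_to_genes(v, pairs, gp), "G1")
  expect_equal(link_to_genes(tibble::tibble(chrom = "chr1", pos = 4e6,
                                            ref = "A"), pairs, gp),
               character(0))
  # variant hit by two pairs -> both genes (brute-force scan agreement)
  pairs2 <- dplyr::bind_rows(pairs[1, ], pairs[1, ])
  pairs2$gene <- c("GA", "GB")
  gp2 <- tibble::tibble(gene = c("GA", "GB"), chrom = "chr1",
                        start = 9050, end = 9060)
  expect_setequal(link_to_genes(v, pairs2, gp2), c("GA", "GB"))
})

test_that("annotation of planted regulatory variants recovers the truth ledger", {
  model <- small_model(site_density = 5)
  ped <- build_pedigree("first_cousin")
  suppressWarnings(co <- sim_cohort(ped, model, seed = 17, plant = list(
    plant_spec("hom_in_roh", "FAM1_c1", regulatory = "enhancer",
               gene = "TARGET1"),
    plant_spec("hom_in_roh", "FAM1_c1", regulatory = "promoter",
               gene = "TARGET2"))))
  tracks <- generate_tracks(co, seed = 17)
  led <- co$ledger
  v <- co$sites[match(led$site_id, co$sites$site_id),
                c("site_id", "chrom", "pos", "ref")]
  v$sample_id <- led$sample_id
  ann <- annotate_roh_noncoding(v, tracks)
  enh <- ann[led$regulatory == "enhancer", ]
  expect_equal(enh$enhancer_category, "brain_specific_enhancer")
  expect_match(enh$linked_genes, "TARGET1")
  expect_setequal(strsplit(enh$supporting_marks, ",")[[1]],
                  c("H3K27ac", "H3K4me1"))
  prom <- ann[led$regulatory == "promoter", ]
  expect_equal(prom$promoter_category, "brain_specific_promoter")
  expect_match(prom$linked_genes, "TARGET2")
  # empty input gives an empty table
  expect_equal(nrow(annotate_roh_noncoding(v[0, ], tracks)), 0)
})

test_that("a variant in both a peak and a pRE receives both category calls", {
  co_like <- tibble::tibble(site_id = "s1", sample_id = "p", chrom = "chr1",
                            pos = 500, ref = "A")
  tracks <- list(
    h3k4me3 = tibble::tibble(chrom = "chr1", start = 400, end = 600),
    pre = tibble::tibble(chrom = "chr1", start = 450, end = 550),
    chromatin_states = nine_lines(tibble::tibble(
      chrom = "chr1", start = 1, end = 2, state = "13_Heterochrom")),
    marks = tibble::tibble(chrom = character(), start = numeric(),
                           end = numeric(), mark = character()),
    interactions = tibble::tibble(chrom1 = character(), start1 = numeric(),
                                  end1 = numeric(), chrom2 = character(),
                                  start2 = numeric(), end2 = numeric(),
                                  gene = character()),
    gene_promoters = tibble::tibble(gene = character(), chrom = character(),
                                    start = numeric(), end = numeric()))
  ann <- annotate_roh_noncoding(co_like, tracks)
  expect_equal(ann$promoter_category, "brain_specific_promoter")
  expect_equal(ann$enhancer_category, "brain_specific_enhancer")
})
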