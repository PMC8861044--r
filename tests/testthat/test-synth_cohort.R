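test_that("pedigree construction yields the expected kinship structure", {
  fc <- build_pedigree("first_cousin")
  expect_equal(kinship(fc, ped_father(fc), ped_mother(fc)), 1 / 16)
  dfc <- build_pedigree("double_first_cousin")
  expect_equal(kinship(dfc, ped_father(dfc), ped_mother(dfc)), 1 / 8)
  tr <- build_pedigree("trio")
  expect_equal(kinship(tr, ped_father(tr), ped_mother(tr)), 0)
  # child inbreeding F equals parental kinship
  expect_equal(kinship(fc, ped_children(fc)[1], ped_children(fc)[1]),
               0.5 * (1 + 1 / 16))
  expect_error(build_pedigree("uncle_niece"))
})

test_that("pedigree invariants are enforced", {
  ped <- build_pedigree("first_cousin", n_children = 2,
                        child_sexes = c("male", "female"))
  expect_false(anyDuplicated(ped$sample_id) > 0)
  expect_silent(validate_pedigree(ped))
  bad <- ped
  bad$father_id[bad$role == "child"][1] <- bad$mother_id[bad$role == "child"][1]
  expect_error(validate_pedigree(bad), "non-male")
})

test_that("gene drop with zero recombination transmits unbroken founder chromosomes", {
  model <- small_model(rate = 0)
  ped <- build_pedigree("trio", n_children = 2)
  drop <- gene_drop(ped, model, seed = 42)
  for (s in ped_children(ped)) {
    for (cn in paste0("chr", 1:4)) {
      expect_equal(nrow(drop$haplotypes[[s]][[cn]]$hap1), 1)
      expect_equal(nrow(drop$haplotypes[[s]][[cn]]$hap2), 1)
    }
  }
  expect_true(all(drop$crossovers$n_xo == 0))
})

test_that("trio children have zero truth autozygosity", {
  drop <- gene_drop(build_pedigree("trio", n_children = 3), small_model(),
                    seed = 9)
  expect_equal(nrow(drop$autozygous), 0)
  expect_true(all(autozygous_fraction(drop)$fraction == 0))
})

test_that("crossover counts match the Poisson expectation", {
  model <- small_model(rate = 2)  # 10 Mb at 2 cM/Mb -> mean 0.2 per meiosis
  ped <- build_pedigree("trio", n_children = 40)
  xo <- dplyr::bind_rows(lapply(1:5, function(k) {
    gene_drop(ped, model, seed = 100 + k)$crossovers
  }))
  # autosomal paternal+maternal meioses
  n <- nrow(xo)
  lambda <- 10 * 2 / 100
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(xo$n_xo) - lambda), 3 * se)
})

test_that("first-cousin truth autozygosity recovers the analytic kinship", {
  # 200 children of first-cousin unions on a 40 Mb-autosome genome;
  # oracle = analytic inbreeding coefficient 1/16
  fr <- unlist(lapply(1:10, function(k) {
    ped <- build_pedigree("first_cousin", n_children = 20,
                          family_id = paste0("F", k))
    autozygous_fraction(gene_drop(ped, small_model(), seed = 200 + k))$fraction
  }))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / 16), 3 * se)
})

test_that("synthesized sites are position-sorted with class-consistent AF stamps", {
  model <- small_model(site_density = 50)
  sites <- synthesize_sites(model, seed = 3)
  for (cn in unique(sites$chrom)) {
    expect_false(is.unsorted(sites$pos[sites$chrom == cn]))
  }
  rare <- sites$class == "rare"
  expect_true(all(sites$af_1kg[rare] < 0.01 & sites$af_gnomad[rare] < 0.01 &
                    sites$af_gme[rare] < 0.01))
  expect_true(all(sites$founder_af >= 0.0005))
})

test_that("constant founder AF yields matching carriage and planted class is absent", {
  model <- small_model()
  model$af_spec <- tibble::tibble(class = "fixed", prop = 1,
                                  af_min = 0.5, af_max = 0.5)
  sites <- synthesize_sites(model, seed = 4)
  ped <- build_pedigree("trio")
  drop <- gene_drop(ped, model, seed = 4)
  al <- draw_founder_alleles(sites, drop$founder_haps, seed = 4)
  expect_lt(abs(mean(al) - 0.5), 3 * sqrt(0.25 / length(al)))
  # zero-frequency class: absent from founders until planted
  model$af_spec$af_min <- model$af_spec$af_max <- 0
  sites0 <- synthesize_sites(model, seed = 4)
  al0 <- draw_founder_alleles(sites0, drop$founder_haps, seed = 4)
  expect_true(all(al0 == 0))
})

test_that("genotypes are Mendelian-consistent absent planting", {
  model <- small_model(site_density = 30)
  ped <- build_pedigree("first_cousin", n_children = 2,
                        child_sexes = c("male", "female"))
  co <- sim_cohort(ped, model, seed = 21)
  sites <- co$sites
  g <- co$geno
  auto <- sites$chrom != "chrX"
  for (child in ped_children(ped)) {
    i <- match(child, ped$sample_id)
    gf <- g[auto, ped$father_id[i]]
    gm <- g[auto, ped$mother_id[i]]
    gc <- g[auto, child]
    # allele count in child bounded by transmissible alleles per parent
    min_tx <- function(gp) ifelse(gp == 2, 1L, 0L)
    max_tx <- function(gp) ifelse(gp >= 1, 1L, 0L)
    expect_true(all(gc >= min_tx(gf) + min_tx(gm)))
    expect_true(all(gc <= max_tx(gf) + max_tx(gm)))
  }
})

test_that("planted events are stamped per mode and conserved in the ledger", {
  model <- small_model(site_density = 10)
  ped <- build_pedigree("first_cousin", n_children = 1)
  child <- paste0("FAM1_c1")
  co <- sim_cohort(ped, model, seed = 32, plant = list(
    plant_spec("de_novo", child),
    plant_spec("compound_het", child),
    plant_spec("hom_in_roh", child),
    plant_spec("x_linked", child)))
  led <- co$ledger
  expect_equal(nrow(led), 5) # compound het contributes two sites
  expect_setequal(unique(led$mode),
                  c("de_novo", "compound_het", "hom_in_roh", "x_linked"))
  g <- co$geno
  ped_df <- co$pedigree
  fa <- ped_df$sample_id[ped_df$role == "father"]
  mo <- ped_df$sample_id[ped_df$role == "mother"]
  for (k in seq_len(nrow(led))) {
    sid <- led$site_id[k]
    expect_true(sid %in% co$sites$site_id)
    row <- co$sites[co$sites$site_id == sid, ]
    expect_identical(row$filter, "PASS")
    expect_equal(row$af_1kg + row$af_gnomad + row$af_gme, 0)
    gc <- g[sid, led$sample_id[k]]
    if (led$mode[k] == "de_novo") {
      expect_equal(gc, 1L)
      expect_equal(unname(g[sid, c(fa, mo)]), c(0L, 0L))
    } else if (led$mode[k] == "compound_het") {
      expect_equal(gc, 1L)
      carrier <- if (led$role[k] == "paternal") fa else mo
      other <- if (led$role[k] == "paternal") mo else fa
      expect_equal(unname(g[sid, carrier]), 1L)
      expect_equal(unname(g[sid, other]), 0L)
    } else if (led$mode[k] == "hom_in_roh") {
      expect_equal(gc, 2L)
      expect_equal(unname(g[sid, c(fa, mo)]), c(1L, 1L))
      # inside a truth autozygous segment of the child
      segs <- co$drops[[1]]$autozygous
      segs <- segs[segs$sample_id == child, ]
      expect_true(any(segs$chrom == row$chrom & segs$start <= row$pos &
                        segs$end >= row$pos))
    } else if (led$mode[k] == "x_linked") {
      expect_equal(gc, 4L)
      expect_equal(unname(g[sid, mo]), 1L)
      expect_equal(unname(g[sid, fa]), 3L)
    }
  }
  # no extra alt alleles at planted loci beyond the stamped carriers
  for (sid in led$site_id) {
    stamped <- switch(led$mode[match(sid, led$site_id)],
                      de_novo = 1, compound_het = 2, hom_in_roh = 3,
                      x_linked = 2)
    expect_equal(sum(gt_carries_alt(g[sid, ])), stamped)
  }
})

test_that("hom_in_roh planting errors when the child has no long autozygous segment", {
  model <- small_model()
  ped <- build_pedigree("trio") # outbred: no autozygosity at all
  co <- sim_cohort(ped, model, seed = 5)
  expect_error(plant_variants(co, plant_spec("hom_in_roh", "FAM1_c1"), 5),
               "no autozygous segment")
})

test_that("x_linked planting rejects female targets", {
  model <- small_model()
  ped <- build_pedigree("first_cousin", child_sexes = "female")
  co <- sim_cohort(ped, model, seed = 6)
  expect_error(plant_variants(co, plant_spec("x_linked", "FAM1_c1"), 6),
               "male")
})

test_that("fixture bundle round-trips through the package readers", {
  model <- small_model(site_density = 5)
  ped <- build_pedigree("first_cousin")
  # low density draws the short-ROH-window warning by contract
  expect_warning(co <- sim_cohort(ped, model, seed = 33, plant = list(
    plant_spec("de_novo", "FAM1_c1"),
    plant_spec("hom_in_roh", "FAM1_c1", regulatory = "enhancer",
               known_gene = TRUE))), "undetectable")
  d <- withr::local_tempdir()
  write_fixture_bundle(co, d, seed = 33)
  vt <- read_cohort_vcf(file.path(d, "cohort.vcf"), co$pedigree)
  expect_identical(unname(vt$geno[co$sites$site_id, colnames(co$geno)]),
                   unname(co$geno))
  expect_equal(vt$sites$pos, co$sites$pos)
  expect_equal(vt$sites$af_gme, co$sites$af_gme, tolerance = 1e-7)
  expect_identical(vt$sites$effect, co$sites$effect)
  # every planted event is present in the VCF
  expect_true(all(co$ledger$site_id %in% vt$sites$site_id))
  # pedigree round-trip
  ped2 <- read_pedigree(file.path(d, "pedigree.tsv"))
  expect_setequal(ped2$sample_id, co$pedigree$sample_id)
  expect_identical(ped2$affected[match(co$pedigree$sample_id,
                                       ped2$sample_id)],
                   co$pedigree$affected)
  # BED round-trip preserves 1-based inclusive coordinates
  b <- read_bed(file.path(d, "h3k4me3.bed"))
  expect_true(all(b$start >= 1 & b$end >= b$start))
  # planted gene is in the SFARI table
  sf <- read.table(file.path(d, "sfari_genes.tsv"), header = TRUE, sep = "\t")
  expect_true(co$ledger$gene[co$ledger$regulatory == "enhancer"] %in% sf$gene)
})

test_that("an empty cohort writes a valid zero-record VCF", {
  model <- small_model()
  model$site_density <- 0.0001 # rounds to zero sites everywhere
  ped <- build_pedigree("trio")
  suppressWarnings(co <- sim_cohort(ped, model, seed = 8))
  expect_equal(nrow(co$sites), 0)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(as_variant_table(co), f)
  lines <- readLines(f)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  expect_equal(sum(!grepl("^#", lines)), 0)
})
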