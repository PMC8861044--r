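# shared small fixtures built in code

# small genome: 4 autosomes of 10 Mb + 10 Mb X, dense sites
small_model <- function(site_density = 20, rare_prop = 0.1, rate = 1) {
  genome_model(
    tibble::tibble(chrom = c(paste0("chr", 1:4), "chrX"),
                   length_bp = rep(10e6, 5),
                   is_x = c(rep(FALSE, 4), TRUE)),
    recombination_rate = rate, site_density = site_density,
    af_spec = default_af_spec(rare_prop))
}

# hand-built variant table: one trio (child/father/mother), explicit sites
make_trio_vt <- function(sites, geno, gq = NULL, ad_ref = NULL, ad_alt = NULL,
                         sexes = c(child = "male", fa = "male", mo = "female")) {
  samples <- c("child", "fa", "mo")
  n <- nrow(sites)
  # geno: either a length-3 vector (one site) or a sites x 3 matrix whose
  # columns are (child, fa, mo)
  g <- if (is.matrix(geno)) {
    stopifnot(nrow(geno) == n, ncol(geno) == 3)
    geno
  } else {
    stopifnot(n == 1, length(geno) == 3)
    matrix(geno, nrow = 1)
  }
  dimnames(g) <- list(sites$site_id, samples)
  storage.mode(g) <- "integer"
  dflt <- autozyg:::.default_ad(g)
  if (is.null(gq)) { gq <- g; gq[] <- 99L }
  if (is.null(ad_ref)) ad_ref <- dflt$ref
  if (is.null(ad_alt)) ad_alt <- dflt$alt
  ped <- tibble::tibble(
    sample_id = samples,
    father_id = c("fa", NA, NA), mother_id = c("mo", NA, NA),
    sex = unname(sexes[samples]), affected = c(TRUE, FALSE, FALSE),
    role = c("child", "father", "mother"), family_id = "T")
  list(vt = variant_table(sites, g, gq, ad_ref, ad_alt, ped), ped = ped)
}

# default site row filled with passing annotations
site_row <- function(site_id, chrom = "chr1", pos = 1e6, ref = "A", alt = "G",
                     filter = "PASS", qd = 10, rprs = 0, gene = "G1",
                     effect = "nonsynonymous_SNV", af = 0, sift = NA,
                     pp2 = NA, provean = NA, ma = NA,
                     segdup = FALSE, simple_repeat = FALSE, subpop = "") {
  tibble::tibble(site_id = site_id, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, filter = filter, qd = qd, rprs = rprs,
                 gene = gene, effect = effect, af_1kg = af, af_gnomad = af,
                 af_gme = af, sift = sift, pp2_hvar = pp2, provean = provean,
                 mut_assessor = ma, cadd = NA_real_, phastcons = NA_real_,
                 phylop = NA_real_, gerp = NA_real_, segdup = segdup,
                 simple_repeat = simple_repeat, subpop = subpop)
}

# brute-force point-in-interval oracle used against IRanges-backed code
brute_overlap <- function(chrom, start, end, track) {
  vapply(seq_along(chrom), function(i) {
    any(track$chrom == chrom[i] & track$start <= end[i] &
          track$end >= start[i])
  }, logical(1))
}
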