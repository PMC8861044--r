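#' Synthesize variant sites for a genome model
#'
#' Draws `site_density` variant sites per Mb, position-sorted within each
#' chromosome, assigns each to an allele-frequency class from the model's
#' `af_spec`, draws a founder alternate-allele frequency per site, and stamps
#' the three population-database allele frequencies (1000G, gnomAD, GME)
#' consistently with the simulated class (a `db_concordance` below 1 makes
#' one database discordant with the others for a random subset of sites).
#'
#' Genes are modeled as 100 kb bins; each non-intergenic site is assigned the
#' gene of its bin. Functional effect annotations are sampled from a fixed
#' mixture dominated by noncoding classes, mirroring WGS annotation output.
#'
#' @param model a [genome_model()].
#' @param seed integer seed.
#' @return tibble of sites, position-sorted by (chromosome, position), with
#'   columns `site_id`, `chrom`, `pos`, `ref`, `alt`, `filter`, `qd`, `rprs`
#'   (ReadPosRankSum), `gene`, `effect`, `af_1kg`, `af_gnomad`, `af_gme`,
#'   damage-score columns (`sift`, `pp2_hvar`, `provean`, `mut_assessor`),
#'   conservation columns (`cadd`, `phastcons`, `phylop`, `gerp`), `segdup`,
#'   `simple_repeat`, `subpop` (encoded string, see [parse_subpop()]),
#'   `class`, and `founder_af`.
#' @export
synthesize_sites <- function(model, seed = 1L) {
  stopifnot(model$site_density > 0)
  set.seed(.substream(seed, "sites"))
  chroms <- model$chromosomes
  effects <- c(intergenic = 0.50, intronic = 0.30, UTR = 0.05,
               synonymous_SNV = 0.07, nonsynonymous_SNV = 0.05,
               splicing = 0.005, stopgain = 0.004, stoploss = 0.001,
               frameshift_indel = 0.005, nonframeshift_indel = 0.005,
               unknown = 0.03)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(chroms)), function(ci) {
    len <- chroms$length_bp[ci]
    n <- round(len / 1e6 * model$site_density)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n))
    cls_i <- sample.int(nrow(model$af_spec), n, replace = TRUE,
                        prob = model$af_spec$prop)
    af <- stats::runif(n, model$af_spec$af_min[cls_i],
                       model$af_spec$af_max[cls_i])
    cls <- model$af_spec$class[cls_i]
    eff <- sample(names(effects), n, replace = TRUE, prob = effects)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    gene <- paste0("G_", chroms$chrom[ci], "_", (pos - 1) %/% 1e5)
    gene[eff == "intergenic"] <- NA_character_
    # database AF stamps: concordant with the class, with optional discordance
    db <- .stamp_db_afs(af, cls, model$db_concordance)
    nonsyn <- eff == "nonsynonymous_SNV"
    sift <- ifelse(nonsyn, stats::runif(n, 0, 1), NA_real_)
    pp2 <- ifelse(nonsyn, stats::runif(n, 0, 1), NA_real_)
    prov <- ifelse(nonsyn, stats::runif(n, -8, 2), NA_real_)
    ma <- ifelse(nonsyn, stats::runif(n, 0, 4), NA_real_)
    tibble::tibble(
      chrom = chroms$chrom[ci], pos = pos, ref = ref, alt = unname(alt),
      filter = "PASS", qd = stats::runif(n, 10, 30),
      rprs = stats::rnorm(n, 0, 1), gene = gene, effect = eff,
      af_1kg = db$af1, af_gnomad = db$af2, af_gme = db$af3,
      sift = sift, pp2_hvar = pp2, provean = prov, mut_assessor = ma,
      cadd = stats::runif(n, 0, 40), phastcons = stats::runif(n),
      phylop = stats::rnorm(n, 0, 2), gerp = stats::runif(n, -5, 6),
      segdup = stats::runif(n) < 0.01, simple_repeat = stats::runif(n) < 0.01,
      subpop = "", class = cls, founder_af = af)
  })
  sites <- dplyr::bind_rows(out)
  if (nrow(sites) == 0) sites <- .empty_sites()
  sites$site_id <- paste0("s", seq_len(nrow(sites)))
  win_mb <- 1 / max(model$site_density, 1e-9) * 100
  if (model$site_density < 10) {
    warning("site density ", model$site_density, "/Mb is low; a 100-site ",
            "ROH window spans ~", round(win_mb), " Mb and short ROHs will be ",
            "undetectable")
  }
  sites[, c("site_id", setdiff(names(sites), "site_id"))]
}

.empty_sites <- function() {
  tibble::tibble(chrom = character(), pos = numeric(), ref = character(),
                 alt = character(), filter = character(), qd = numeric(),
                 rprs = numeric(), gene = character(), effect = character(),
                 af_1kg = numeric(), af_gnomad = numeric(),
                 af_gme = numeric(), sift = numeric(), pp2_hvar = numeric(),
                 provean = numeric(), mut_assessor = numeric(),
                 cadd = numeric(), phastcons = numeric(), phylop = numeric(),
                 gerp = numeric(), segdup = logical(),
                 simple_repeat = logical(), subpop = character(),
                 class = character(), founder_af = numeric())
}

# stamp 1000G/gnomAD/GME frequencies consistent with the frequency class
.stamp_db_afs <- function(af, cls, concordance) {
  n <- length(af)
  jitter <- function(x) pmax(0, pmin(1, x * stats::runif(n, 0.7, 1.3)))
  base <- ifelse(cls == "common", af, pmin(af, 0.009))
  af1 <- jitter(base); af2 <- jitter(base); af3 <- jitter(base)
  disc <- stats::runif(n) >= concordance
  if (any(disc)) {
    which_db <- sample.int(3, sum(disc), replace = TRUE)
    high <- stats::runif(sum(disc), 0.02, 0.2)
    af1[disc][which_db == 1] <- high[which_db == 1]
    af2[disc][which_db == 2] <- high[which_db == 2]
    af3[disc][which_db == 3] <- high[which_db == 3]
  }
  list(af1 = af1, af2 = af2, af3 = af3)
}

#' Draw founder haplotype alleles at synthesized sites
#'
#' Each founder haplotype carries the alternate allele at a site
#' independently with the site's `founder_af`.
#'
#' @param sites tibble from [synthesize_sites()].
#' @param founder_haps founder-haplotype allocation from [gene_drop()]
#'   (`founder_haps` element).
#' @param seed integer seed.
#' @return integer matrix (sites x haplotype ids); column names are the
#'   haplotype ids.
#' @export
draw_founder_alleles <- function(sites, founder_haps, seed = 1L) {
  set.seed(.substream(seed, "founder_alleles"))
  ids <- sort(c(founder_haps$hap1, founder_haps$hap2))
  n <- nrow(sites)
  if (n == 0) {
    m <- matrix(integer(0), nrow = 0, ncol = length(ids))
    colnames(m) <- as.character(ids)
    return(m)
  }
  m <- matrix(stats::rbinom(n * length(ids), 1L, rep(sites$founder_af, length(ids))),
              nrow = n, ncol = length(ids))
  colnames(m) <- as.character(ids)
  m
}

# founder-haplotype id at given positions for one haplotype segment table;
# NA where the haplotype is undefined (male X outside the PARs)
.hap_at <- function(hap, pos) {
  if (is.null(hap) || nrow(hap) == 0) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, hap$start)
  out <- rep(NA_integer_, length(pos))
  ok <- i >= 1
  ok[ok] <- pos[ok] <= hap$end[i[ok]]
  out[ok] <- hap$hap[i[ok]]
  out
}

#' Genotype pedigree members at synthesized sites
#'
#' Looks up, for every sample and site, the founder haplotype carried by each
#' of the sample's chromosomes and sums the founder alleles. Male X genotypes
#' outside the pseudoautosomal regions are hemizygous (codes 3/4).
#'
#' @param drop a [gene_drop()] result.
#' @param sites tibble from [synthesize_sites()].
#' @param alleles matrix from [draw_founder_alleles()].
#' @param samples samples to genotype (default: all pedigree members).
#' @param missing_rate per-genotype missingness probability (default 0).
#' @param seed seed used only when `missing_rate > 0`.
#' @return integer genotype matrix (sites x samples) in the package's
#'   genotype codes (see [gt_label()]).
#' @export
genotype_cohort <- function(drop, sites, alleles, samples = NULL,
                            missing_rate = 0, seed = 1L) {
  ped <- drop$pedigree
  model <- drop$model
  if (is.null(samples)) samples <- ped$sample_id
  sex_of <- stats::setNames(ped$sex, ped$sample_id)
  is_x_chrom <- stats::setNames(model$chromosomes$is_x, model$chromosomes$chrom)
  geno <- matrix(NA_integer_, nrow = nrow(sites), ncol = length(samples),
                 dimnames = list(sites$site_id, samples))
  col_of <- function(id) match(as.character(id), colnames(alleles))
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    pos <- sites$pos[idx]
    xc <- isTRUE(is_x_chrom[[cn]])
    par_mask <- if (xc) .in_par(model, pos) else rep(FALSE, length(pos))
    for (s in samples) {
      h <- drop$haplotypes[[s]][[cn]]
      h1 <- .hap_at(h$hap1, pos)
      h2 <- .hap_at(h$hap2, pos)
      a1 <- alleles[cbind(idx, col_of(h1))]
      a2 <- alleles[cbind(idx, col_of(h2))]
      if (xc && sex_of[s] == "male") {
        g <- ifelse(par_mask & !is.na(a2), a1 + a2, 3L + a1)
      } else {
        g <- a1 + a2
      }
      geno[idx, s] <- as.integer(g)
    }
  }
  if (missing_rate > 0) {
    set.seed(.substream(seed, "missingness"))
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }
  geno
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: gene-drops one or more pedigrees through a shared
#' genome model (each family with independent founder alleles at a shared
#' site panel), genotypes the requested samples, and optionally plants
#' candidate variants.
#'
#' @param pedigrees a single [build_pedigree()] pedigree or a list of them
#'   (family ids must make sample ids globally unique).
#' @param model a [genome_model()].
#' @param seed integer seed, expanded deterministically into per-stage
#'   substreams.
#' @param plant list of [plant_spec()]s applied after genotyping.
#' @param samples which pedigree members to genotype: `"all"` (default),
#'   `"children"`, or a character vector of sample ids.
#' @param missing_rate per-genotype missingness probability.
#' @return object of class `synth_cohort`: list with `pedigree` (combined
#'   tibble), `model`, `sites`, `geno` (sites x samples integer matrix),
#'   `drops` (per-family [gene_drop()] results), `ledger` (planted-event
#'   truth tibble), and `overrides` (per-genotype GQ/AD overrides used by
#'   [as_variant_table()]).
#' @export
sim_cohort <- function(pedigrees, model, seed = 1L, plant = list(),
                       samples = "all", missing_rate = 0) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  sites <- synthesize_sites(model, seed)
  ped_all <- dplyr::bind_rows(lapply(pedigrees, function(p) {
    tibble::as_tibble(p)
  }))
  if (anyDuplicated(ped_all$sample_id) > 0)
    stop("sample ids collide across families; use distinct family_id values")
  genos <- list()
  drops <- list()
  for (k in seq_along(pedigrees)) {
    ped <- pedigrees[[k]]
    fam_seed <- .substream(seed, paste0("family", k))
    drop <- gene_drop(ped, model, fam_seed)
    alleles <- draw_founder_alleles(sites, drop$founder_haps, fam_seed)
    want <- if (identical(samples, "all")) ped$sample_id
            else if (identical(samples, "children")) ped_children(ped)
            else intersect(samples, ped$sample_id)
    genos[[k]] <- genotype_cohort(drop, sites, alleles, want,
                                  missing_rate, fam_seed)
    drops[[k]] <- drop
  }
  geno <- do.call(cbind, genos)
  cohort <- structure(list(pedigree = ped_all, model = model, sites = sites,
                           geno = geno, drops = drops,
                           ledger = .empty_ledger(),
                           overrides = .empty_overrides()),
                      class = "synth_cohort")
  if (length(plant)) cohort <- plant_variants(cohort, plant, seed)
  cohort
}

.empty_ledger <- function() {
  tibble::tibble(event = integer(), mode = character(),
                 sample_id = character(), chrom = character(), pos = numeric(),
                 site_id = character(), gene = character(), role = character(),
                 regulatory = character())
}

.empty_overrides <- function() {
  tibble::tibble(site_id = character(), sample_id = character(),
                 gq = integer(), ad_ref = integer(), ad_alt = integer())
}
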