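#' Simulate an autozygosity study across replicate consanguineous families
#'
#' Gene-drops `n_families` independent families of the requested
#' consanguinity type through a shared genome model and returns, per child,
#' the truth autozygous genome fraction (both haplotypes descending from the
#' same founder chromosome) and, optionally, the fraction recovered by the
#' ROH detector run on synthesized genotypes (site filter at the
#' homozygosity-mapping defaults, then the sliding-window caller with the
#' standard parameters: 100-variant windows, 30 heterozygotes and 30 missing
#' allowed, PHOM 0.75, segments > 1 Mb).
#'
#' The site filter is applied within each family: founder allele content is
#' drawn per family, so a site that is polymorphic in the population can be
#' monomorphic in one family's founders; filtering on the pooled cohort
#' would retain such family-uninformative sites and inflate that family's
#' homozygosity-by-state, biasing the recovered fraction upward.
#'
#' The expectation of both fractions is the child's inbreeding coefficient:
#' 6.25% for first-cousin and 12.5% for double-first-cousin offspring.
#'
#' @param kind `"first_cousin"` or `"double_first_cousin"`.
#' @param n_families number of independent families.
#' @param children_per_family replicate children per family.
#' @param model a [genome_model()]; defaults to the full-scale profile
#'   (22 autosomes, ~2,700 Mb, 1 cM/Mb, 100 sites/Mb, no X) with a
#'   common-allele founder spectrum.
#' @param seed integer seed.
#' @param detect also run the ROH detector (slower).
#' @return tibble with one row per child: `sample_id`, `truth_fraction`,
#'   and (when `detect`) `detected_fraction`.
#' @export
simulate_autozygosity_study <- function(kind = c("first_cousin",
                                                 "double_first_cousin"),
                                        n_families = 25,
                                        children_per_family = 4,
                                        model = NULL, seed = 1L,
                                        detect = TRUE) {
  kind <- match.arg(kind)
  if (is.null(model)) {
    model <- default_genome("full", include_x = FALSE, site_density = 100,
                            af_spec = default_af_spec(rare_prop = 0))
  }
  sites <- if (detect) synthesize_sites(model, seed) else NULL
  denom <- autosome_length(model)
  truth <- list()
  det <- c()
  for (k in seq_len(n_families)) {
    ped <- build_pedigree(kind, n_children = children_per_family,
                          family_id = sprintf("F%03d", k))
    fam_seed <- .substream(seed, paste0(kind, k))
    drop <- gene_drop(ped, model, fam_seed)
    truth[[k]] <- autozygous_fraction(drop)
    if (detect) {
      alleles <- draw_founder_alleles(sites, drop$founder_haps, fam_seed)
      geno <- genotype_cohort(drop, sites, alleles,
                              samples = ped_children(ped))
      keep <- roh_site_filter(geno)
      fsites <- sites[keep, ]
      det <- c(det, vapply(colnames(geno), function(s) {
        segs <- detect_roh(geno[keep, s], fsites, sample_id = s)
        roh_metrics(segs, denom)$genome_fraction
      }, numeric(1)))
    }
  }
  out <- dplyr::bind_rows(truth)
  out <- tibble::tibble(sample_id = out$sample_id,
                        truth_fraction = out$fraction)
  if (detect) out$detected_fraction <- det[out$sample_id]
  out
}
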