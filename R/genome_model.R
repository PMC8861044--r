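#' Genome model for the synthetic-cohort generator
#'
#' Describes the simulated genome: chromosome names and lengths, which
#' chromosome is X (with its pseudoautosomal intervals), a uniform
#' recombination rate in cM/Mb, the variant site density, and the
#' founder allele-frequency spectrum (`af_spec`).
#'
#' @param chromosomes tibble with columns `chrom`, `length_bp`, `is_x`.
#' @param recombination_rate uniform genetic map, cM per Mb (default 1, the
#'   genome-wide human average; with no crossover interference, crossover
#'   counts per transmission are Poisson(length_Mb * rate / 100)).
#' @param site_density variant sites per Mb.
#' @param af_spec tibble with columns `class`, `prop`, `af_min`, `af_max`:
#'   founder alternate-allele frequencies per site class are drawn uniformly
#'   from \[af_min, af_max\]. See [default_af_spec()].
#' @param par tibble with columns `start`, `end` (1-based, on the X) giving
#'   pseudoautosomal intervals; defaults scale the GRCh37 PAR1/PAR2
#'   convention to the model's X length.
#' @param db_concordance probability that all three population databases
#'   (1000G, gnomAD, GME) are stamped with frequencies concordant with the
#'   site's simulated class; with probability `1 - db_concordance` one
#'   database receives a discordant (common-range) frequency.
#' @return object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, recombination_rate = 1,
                         site_density = 100, af_spec = default_af_spec(),
                         par = NULL, db_concordance = 1) {
  stopifnot(all(chromosomes$length_bp > 0), recombination_rate >= 0,
            sum(chromosomes$is_x) <= 1)
  if (is.null(par) && any(chromosomes$is_x)) {
    xlen <- chromosomes$length_bp[chromosomes$is_x]
    # GRCh37 PAR1 (X:60001-2699520) and PAR2 (X:154931044-155260560),
    # rescaled to the model X
    sc <- xlen / 155270560
    par <- tibble::tibble(start = pmax(1, round(c(60001, 154931044) * sc)),
                          end = round(c(2699520, 155260560) * sc))
  }
  if (!is.null(par) && any(chromosomes$is_x)) {
    xlen <- chromosomes$length_bp[chromosomes$is_x]
    stopifnot(all(par$start >= 1), all(par$end <= xlen), all(par$start < par$end))
  }
  structure(list(chromosomes = chromosomes,
                 recombination_rate = recombination_rate,
                 site_density = site_density,
                 af_spec = af_spec,
                 par = par,
                 db_concordance = db_concordance),
            class = "genome_model")
}

#' @rdname genome_model
#' @details `default_af_spec()` mixes a common class (founder AF uniform on
#'   0.1-0.5, stamped as common in the population databases) with a rare
#'   class (AF 0.0005-0.005, stamped below 1% in all three databases).
#'   Setting `rare_prop = 0` yields a background with no rare founder
#'   alleles, useful for noise-free recovery experiments where the only rare
#'   variants are planted ones.
#' @param rare_prop proportion of sites in the rare class.
#' @export
default_af_spec <- function(rare_prop = 0.1) {
  tibble::tibble(class = c("common", "rare"),
                 prop = c(1 - rare_prop, rare_prop),
                 af_min = c(0.10, 0.0005),
                 af_max = c(0.50, 0.0050))
}

#' @rdname genome_model
#' @details `default_genome()` provides two profiles: `"test"` (22 autosomes
#'   totalling ~300 Mb plus a 17 Mb X) for fast unit tests, and `"full"`
#'   (22 autosomes totalling ~2,700 Mb plus a 155 Mb X, lengths proportional
#'   to GRCh37) for the cohort-scale autozygosity experiments.
#' @param scale `"test"` or `"full"`.
#' @param include_x include an X chromosome.
#' @param ... passed to `genome_model()`.
#' @export
default_genome <- function(scale = c("test", "full"), include_x = TRUE, ...) {
  scale <- match.arg(scale)
  grch37_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
                 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  len <- switch(scale,
    full = round(grch37_mb * 2700 / sum(grch37_mb)) * 1e6,
    test = round(grch37_mb * 300 / sum(grch37_mb)) * 1e6)
  xlen <- switch(scale, full = 155e6, test = 17e6)
  chroms <- tibble::tibble(chrom = paste0("chr", seq_len(22)),
                           length_bp = len, is_x = FALSE)
  if (include_x) {
    chroms <- dplyr::bind_rows(chroms,
      tibble::tibble(chrom = "chrX", length_bp = xlen, is_x = TRUE))
  }
  genome_model(chroms, ...)
}

#' @rdname genome_model
#' @param model a `genome_model`.
#' @export
autosome_length <- function(model) {
  sum(model$chromosomes$length_bp[!model$chromosomes$is_x])
}

# TRUE for positions on the X that fall in a pseudoautosomal interval
.in_par <- function(model, pos) {
  if (is.null(model$par) || nrow(model$par) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(model$par))) {
    out <- out | (pos >= model$par$start[i] & pos <= model$par$end[i])
  }
  out
}
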