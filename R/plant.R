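#' Specification of a planted candidate variant
#'
#' Describes one candidate event to stamp into a synthetic cohort:
#' a de novo variant (alternate allele in the child only), a
#' compound-heterozygous pair (two heterozygous sites in one gene, one
#' transmitted from each parent), an inherited homozygous variant inside a
#' truth autozygous segment (child homozygous, both parents heterozygous),
#' or an X-linked recessive variant (hemizygous in a male child,
#' heterozygous in the mother, absent from the father).
#'
#' @param mode one of `"de_novo"`, `"compound_het"`, `"hom_in_roh"`,
#'   `"x_linked"`.
#' @param target_sample child sample id carrying the event.
#' @param effect functional annotation to stamp (default: `"stopgain"` for
#'   de novo, `"nonsynonymous_SNV"` for compound het and hom-in-ROH,
#'   `"intronic"` for X-linked and for regulatory events).
#' @param damage named numeric vector with any of `sift`, `pp2_hvar`,
#'   `provean`, `mut_assessor`; defaults pass at least two of the four
#'   missense-damaging thresholds when the effect is nonsynonymous.
#' @param regulatory `"none"`, `"promoter"`, or `"enhancer"`: when not
#'   `"none"`, [write_fixture_bundle()] emits a brain H3K4me3 peak (promoter)
#'   or predicted regulatory element (enhancer) over the site, with no
#'   overlapping non-neuronal active-promoter / strong-enhancer state and a
#'   promoter-enhancer interaction pair linking it to `gene`.
#' @param gene gene symbol to stamp (default: the gene bin of the chosen
#'   locus).
#' @param known_gene if TRUE the stamped gene is added to the SFARI gene
#'   table of the fixture bundle.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(mode = c("de_novo", "compound_het", "hom_in_roh", "x_linked"),
                       target_sample, effect = NULL, damage = NULL,
                       regulatory = c("none", "promoter", "enhancer"),
                       gene = NULL, known_gene = FALSE) {
  mode <- match.arg(mode)
  regulatory <- match.arg(regulatory)
  if (is.null(effect)) {
    effect <- switch(mode, de_novo = "stopgain",
                     compound_het = "nonsynonymous_SNV",
                     hom_in_roh = "nonsynonymous_SNV", x_linked = "intronic")
    if (regulatory != "none") effect <- "intronic"
  }
  if (is.null(damage) && effect == "nonsynonymous_SNV") {
    damage <- c(sift = 0.01, pp2_hvar = 0.9, provean = -5, mut_assessor = 3)
  }
  structure(list(mode = mode, target_sample = target_sample, effect = effect,
                 damage = damage, regulatory = regulatory, gene = gene,
                 known_gene = known_gene),
            class = "plant_spec")
}

#' Plant candidate variants into a synthetic cohort
#'
#' Adds new variant sites (ultra-rare: population-database frequencies 0,
#' absent from all founder haplotypes) with genotypes stamped according to
#' each [plant_spec()], and records every planted event in the cohort's
#' truth ledger. Site-level QC annotations (PASS, QD, ReadPosRankSum) and
#' per-genotype GQ/allelic depths are stamped inside passing ranges; the de
#' novo child genotype gets an allele balance inside \[0.3, 0.7\] (or >= 0.7
#' for a hemizygous X call in a male).
#'
#' @param cohort a [sim_cohort()] cohort.
#' @param specs list of [plant_spec()]s.
#' @param seed integer seed.
#' @return the cohort with planted sites added (site table re-sorted by
#'   position), genotypes set, and the `ledger` extended.
#' @export
plant_variants <- function(cohort, specs, seed = 1L) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  set.seed(.substream(seed, "plant"))
  ped <- cohort$pedigree
  model <- cohort$model
  samples <- colnames(cohort$geno)
  sex_of <- stats::setNames(ped$sex, ped$sample_id)
  fam_of <- stats::setNames(ped$family_id, ped$sample_id)
  autos <- model$chromosomes[!model$chromosomes$is_x, ]
  xchr <- model$chromosomes[model$chromosomes$is_x, ]
  next_event <- max(0L, cohort$ledger$event) + 1L

  trio_of <- function(child) {
    i <- match(child, ped$sample_id)
    list(fa = ped$father_id[i], mo = ped$mother_id[i])
  }
  occupied <- function(chrom, pos) {
    any(cohort$sites$chrom == chrom & cohort$sites$pos == pos)
  }
  pick_free <- function(chrom, lo, hi) {
    for (try in 1:100) {
      p <- floor(stats::runif(1, lo, hi))
      if (!occupied(chrom, p)) return(p)
    }
    stop("could not find an unoccupied locus")
  }

  new_sites <- list()
  new_geno <- list()
  for (spec in specs) {
    child <- spec$target_sample
    if (!child %in% samples)
      stop("target sample ", child, " is not genotyped in this cohort")
    tr <- trio_of(child)
    fam_drop <- cohort$drops[[match(fam_of[child],
                                    vapply(cohort$drops, function(d)
                                      d$pedigree$family_id[1], character(1)))]]
    loci <- switch(spec$mode,
      de_novo = , compound_het = {
        ci <- sample.int(nrow(autos), 1)
        n_loci <- if (spec$mode == "compound_het") 2L else 1L
        # compound het sites share one 100 kb gene bin
        bin <- floor(stats::runif(1, 0, autos$length_bp[ci] / 1e5 - 1))
        sapply(seq_len(n_loci), function(k)
          pick_free(autos$chrom[ci], bin * 1e5 + 1, (bin + 1) * 1e5)) |>
          (\(p) tibble::tibble(chrom = autos$chrom[ci], pos = p))()
      },
      hom_in_roh = {
        segs <- fam_drop$autozygous
        segs <- segs[segs$sample_id == child &
                       segs$end - segs$start + 1 >= 1e6, , drop = FALSE]
        if (nrow(segs) == 0)
          stop("hom_in_roh requested but ", child,
               " has no autozygous segment >= 1 Mb")
        k <- sample.int(nrow(segs), 1)
        tibble::tibble(chrom = segs$chrom[k],
                       pos = pick_free(segs$chrom[k], segs$start[k] + 1,
                                       segs$end[k] - 1))
      },
      x_linked = {
        if (nrow(xchr) == 0) stop("model has no X chromosome")
        if (sex_of[child] != "male")
          stop("x_linked plant requires a male child")
        repeat {
          p <- pick_free(xchr$chrom[1], 1, xchr$length_bp[1])
          if (!.in_par(model, p)) break
        }
        tibble::tibble(chrom = xchr$chrom[1], pos = p)
      })

    for (k in seq_len(nrow(loci))) {
      sid <- paste0("p", next_event, if (nrow(loci) > 1) letters[k] else "")
      gene <- spec$gene
      if (is.null(gene)) gene <- paste0("G_", loci$chrom[k], "_",
                                        (loci$pos[k] - 1) %/% 1e5)
      site <- tibble::tibble(
        site_id = sid, chrom = loci$chrom[k], pos = loci$pos[k],
        ref = "A", alt = "G", filter = "PASS", qd = 15, rprs = 0,
        gene = gene, effect = spec$effect,
        af_1kg = 0, af_gnomad = 0, af_gme = 0,
        sift = NA_real_, pp2_hvar = NA_real_, provean = NA_real_,
        mut_assessor = NA_real_, cadd = 25, phastcons = 0.95, phylop = 2.5,
        gerp = 4.5, segdup = FALSE, simple_repeat = FALSE, subpop = "",
        class = "planted", founder_af = 0)
      for (nm in names(spec$damage)) site[[nm]] <- spec$damage[[nm]]
      g <- rep(GT_HOM_REF, length(samples))
      names(g) <- samples
      if (loci$chrom[k] == if (nrow(xchr)) xchr$chrom[1] else "") {
        g[sex_of[samples] == "male"] <- GT_HEMI_REF
      }
      role <- "single"
      if (spec$mode == "de_novo") {
        g[child] <- GT_HET
      } else if (spec$mode == "compound_het") {
        g[child] <- GT_HET
        role <- c("paternal", "maternal")[k]
        g[if (k == 1) tr$fa else tr$mo] <- GT_HET
      } else if (spec$mode == "hom_in_roh") {
        g[child] <- GT_HOM_ALT
        g[tr$fa] <- GT_HET
        g[tr$mo] <- GT_HET
      } else if (spec$mode == "x_linked") {
        g[child] <- GT_HEMI_ALT
        g[tr$mo] <- GT_HET
        g[tr$fa] <- GT_HEMI_REF
      }
      new_sites[[length(new_sites) + 1L]] <- site
      new_geno[[length(new_geno) + 1L]] <- g
      cohort$ledger <- dplyr::bind_rows(cohort$ledger, tibble::tibble(
        event = next_event, mode = spec$mode, sample_id = child,
        chrom = loci$chrom[k], pos = loci$pos[k], site_id = sid, gene = gene,
        role = role, regulatory = spec$regulatory))
      if (isTRUE(spec$known_gene)) {
        attr(cohort, "known_genes") <- union(attr(cohort, "known_genes"), gene)
      }
    }
    next_event <- next_event + 1L
  }
  if (length(new_sites)) {
    add_sites <- dplyr::bind_rows(new_sites)
    add_geno <- do.call(rbind, new_geno)
    rownames(add_geno) <- add_sites$site_id
    sites <- dplyr::bind_rows(cohort$sites, add_sites)
    geno <- rbind(cohort$geno, add_geno[, colnames(cohort$geno), drop = FALSE])
    ord <- order(match(sites$chrom, model$chromosomes$chrom), sites$pos)
    cohort$sites <- sites[ord, ]
    cohort$geno <- geno[ord, , drop = FALSE]
  }
  cohort
}
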