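#' Generate synthetic regulatory interval tracks for a cohort
#'
#' Produces the epigenome fixture tracks the noncoding-annotation stage
#' consumes: chromatin-state segmentations for 9 non-neuronal cell lines
#' (with `1_Active_Promoter`, `4_Strong_Enhancer`, `5_Strong_Enhancer` among
#' the state labels), brain H3K4me3 peaks, predicted regulatory elements
#' (pREs) from developmental brain, activating-mark (H3K4me1/H3K27ac)
#' intervals, and promoter-enhancer interaction pairs.
#'
#' Planted variants whose [plant_spec()] requested `regulatory = "promoter"`
#' are guaranteed an H3K4me3 peak overlapping the site and no overlapping
#' `1_Active_Promoter` state in any cell line (so they classify as
#' brain-specific promoter variants); `regulatory = "enhancer"` likewise gets
#' a pRE, no strong-enhancer state, activating marks, and an interaction pair
#' linking the element to the promoter of the stamped gene.
#'
#' @param cohort a [sim_cohort()] cohort.
#' @param seed integer seed.
#' @param n_per_chrom random background intervals per chromosome per track.
#' @return list of tibbles (`chromatin_states` with `cell_line` and `state`,
#'   `h3k4me3`, `pre`, `marks` with `mark`, `interactions`, `gene_promoters`);
#'   all intervals 1-based inclusive in memory.
#' @export
generate_tracks <- function(cohort, seed = 1L, n_per_chrom = 30) {
  set.seed(.substream(seed, "tracks"))
  model <- cohort$model
  chroms <- model$chromosomes
  cells <- c("GM12878", "H1hESC", "HepG2", "HMEC", "HSMM", "HUVEC", "K562",
             "NHEK", "NHLF")
  states <- c("1_Active_Promoter", "4_Strong_Enhancer", "5_Strong_Enhancer",
              "7_Weak_Enhancer", "9_Txn_Transition", "10_Txn_Elongation",
              "13_Heterochrom")
  rand_ivl <- function(n, width_lo = 500, width_hi = 5000) {
    ci <- sample.int(nrow(chroms), n, replace = TRUE)
    w <- floor(stats::runif(n, width_lo, width_hi))
    s <- floor(stats::runif(n, 1, chroms$length_bp[ci] - w))
    tibble::tibble(chrom = chroms$chrom[ci], start = s, end = s + w)
  }
  # keep background intervals clear of planted regulatory loci so the
  # specificity guarantee holds
  reg <- cohort$ledger[cohort$ledger$regulatory != "none", , drop = FALSE]
  clear_of_planted <- function(iv) {
    if (nrow(reg) == 0 || nrow(iv) == 0) return(iv)
    bad <- rep(FALSE, nrow(iv))
    for (j in seq_len(nrow(reg))) {
      bad <- bad | (iv$chrom == reg$chrom[j] & iv$start <= reg$pos[j] &
                      iv$end >= reg$pos[j])
    }
    iv[!bad, , drop = FALSE]
  }
  cs <- dplyr::bind_rows(lapply(cells, function(cl) {
    iv <- clear_of_planted(rand_ivl(n_per_chrom * nrow(chroms)))
    iv$cell_line <- cl
    iv$state <- sample(states, nrow(iv), replace = TRUE)
    iv
  }))
  h3k4me3 <- clear_of_planted(rand_ivl(n_per_chrom * nrow(chroms), 300, 2000))
  pre <- clear_of_planted(rand_ivl(n_per_chrom * nrow(chroms), 300, 2000))
  marks <- dplyr::bind_rows(lapply(c("H3K4me1", "H3K27ac"), function(mk) {
    iv <- rand_ivl(n_per_chrom * nrow(chroms), 500, 3000)
    iv$mark <- mk
    iv
  }))
  gene_prom <- .gene_promoters(cohort$sites)
  inter <- tibble::tibble(chrom1 = character(), start1 = numeric(),
                          end1 = numeric(), chrom2 = character(),
                          start2 = numeric(), end2 = numeric(),
                          gene = character())
  if (nrow(reg)) {
    for (j in seq_len(nrow(reg))) {
      el <- tibble::tibble(chrom = reg$chrom[j], start = reg$pos[j] - 250,
                           end = reg$pos[j] + 250)
      if (reg$regulatory[j] == "promoter") {
        h3k4me3 <- dplyr::bind_rows(h3k4me3, el)
      } else {
        pre <- dplyr::bind_rows(pre, el)
        marks <- dplyr::bind_rows(marks,
          tibble::tibble(chrom = el$chrom, start = el$start, end = el$end,
                         mark = c("H3K4me1", "H3K27ac")))
      }
      gp <- gene_prom[gene_prom$gene == reg$gene[j], , drop = FALSE]
      if (nrow(gp) == 0) {
        gp <- tibble::tibble(gene = reg$gene[j], chrom = reg$chrom[j],
                             start = max(1, reg$pos[j] - 50000),
                             end = max(2000, reg$pos[j] - 48000))
        gene_prom <- dplyr::bind_rows(gene_prom, gp)
      }
      inter <- dplyr::bind_rows(inter, tibble::tibble(
        chrom1 = el$chrom, start1 = el$start, end1 = el$end,
        chrom2 = gp$chrom[1], start2 = gp$start[1], end2 = gp$end[1],
        gene = reg$gene[j]))
    }
  }
  list(chromatin_states = cs, h3k4me3 = h3k4me3, pre = pre, marks = marks,
       interactions = inter, gene_promoters = gene_prom)
}

# promoter interval per gene bin: first 2 kb of the 100 kb bin; gene symbols
# not following the bin naming scheme (e.g. stamped on planted variants) get
# their promoter interval from generate_tracks() instead
.gene_promoters <- function(sites) {
  g <- unique(stats::na.omit(sites$gene))
  g <- g[grepl("^G_.+_[0-9]+$", g)]
  if (length(g) == 0) {
    return(tibble::tibble(gene = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  parts <- strsplit(sub("^G_", "", g), "_")
  chrom <- vapply(parts, function(x) paste(x[-length(x)], collapse = "_"),
                  character(1))
  bin <- as.numeric(vapply(parts, function(x) x[length(x)], character(1)))
  tibble::tibble(gene = g, chrom = chrom, start = bin * 1e5 + 1,
                 end = bin * 1e5 + 2000)
}

#' Write / read BED interval files
#'
#' On disk the package uses standard BED: 0-based half-open intervals; in
#' memory all intervals are 1-based inclusive. `write_bed()` converts
#' accordingly; `read_bed()` goes through `rtracklayer::import()` and
#' converts back. An optional 4th column carries a name (e.g. a chromatin
#' state label).
#'
#' @param iv tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @param path file path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` a tibble
#'   `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
write_bed <- function(iv, path) {
  df <- data.frame(chrom = iv$chrom,
                   start = format(iv$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(iv$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(iv)) df$name <- iv$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr))
  nm <- gr$name
  out$name <- if (is.null(nm)) NA_character_ else as.character(nm)
  out
}

#' Write a complete pipeline input bundle for a synthetic cohort
#'
#' Emits, under `out_dir`: the multi-sample VCF (`cohort.vcf`), the pedigree
#' TSV (`pedigree.tsv`: sample, father, mother, sex, affected), BED tracks
#' (9 chromatin-state files plus `manifest.tsv` naming each file's cell
#' line, `h3k4me3.bed`, `pre.bed`, `h3k4me1.bed`, `h3k27ac.bed`,
#' `segdup.bed`, `simple_repeat.bed`), the promoter-enhancer interaction
#' pair TSV (`interactions.tsv`), gene promoter intervals
#' (`gene_promoters.tsv`), and gene tables (`sfari_genes.tsv`,
#' `ndd_genes.tsv`, `constraint.tsv`, `brain_expression.tsv`, `omim.tsv`,
#' `sfari_cnv.tsv`). Files round-trip through the package readers.
#'
#' @param cohort a [sim_cohort()] cohort.
#' @param out_dir output directory (created if needed).
#' @param tracks optional [generate_tracks()] result (generated with
#'   `seed` when omitted).
#' @param seed integer seed for track/table generation.
#' @return named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(cohort, out_dir, tracks = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir)
  if (is.null(tracks)) tracks <- generate_tracks(cohort, seed)
  paths <- list()
  p <- function(f) file.path(out_dir, f)

  vt <- as_variant_table(cohort)
  paths$vcf <- write_vcf(vt, p("cohort.vcf"),
                         contigs = cohort$model$chromosomes)

  ped <- cohort$pedigree
  utils::write.table(
    data.frame(sample = ped$sample_id,
               father = ifelse(is.na(ped$father_id), "0", ped$father_id),
               mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
               sex = ped$sex, affected = as.integer(ped$affected)),
    p("pedigree.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths$pedigree <- p("pedigree.tsv")

  manifest <- list()
  for (cl in unique(tracks$chromatin_states$cell_line)) {
    f <- paste0("chromstate_", cl, ".bed")
    cs <- tracks$chromatin_states[tracks$chromatin_states$cell_line == cl, ]
    write_bed(tibble::tibble(chrom = cs$chrom, start = cs$start,
                             end = cs$end, name = cs$state), p(f))
    manifest[[length(manifest) + 1L]] <- data.frame(file = f, cell_line = cl)
  }
  utils::write.table(do.call(rbind, manifest), p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$manifest <- p("manifest.tsv")
  write_bed(tracks$h3k4me3, p("h3k4me3.bed"))
  write_bed(tracks$pre, p("pre.bed"))
  for (mk in c("H3K4me1", "H3K27ac")) {
    write_bed(tracks$marks[tracks$marks$mark == mk, ],
              p(paste0(tolower(mk), ".bed")))
  }
  sd <- cohort$sites[cohort$sites$segdup, c("chrom", "pos")]
  write_bed(tibble::tibble(chrom = sd$chrom, start = pmax(1, sd$pos - 100),
                           end = sd$pos + 100), p("segdup.bed"))
  sr <- cohort$sites[cohort$sites$simple_repeat, c("chrom", "pos")]
  write_bed(tibble::tibble(chrom = sr$chrom, start = pmax(1, sr$pos - 50),
                           end = sr$pos + 50), p("simple_repeat.bed"))

  utils::write.table(tracks$interactions, p("interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tracks$gene_promoters, p("gene_promoters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$interactions <- p("interactions.tsv")

  set.seed(.substream(seed, "gene_tables"))
  genes <- unique(stats::na.omit(cohort$sites$gene))
  known <- attr(cohort, "known_genes")
  sfari <- unique(c(known, sample(genes, min(20, length(genes)))))
  utils::write.table(data.frame(gene = sfari,
                                score = sample(c("1", "2", "3", "S"),
                                               length(sfari), replace = TRUE)),
                     p("sfari_genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ndd <- sample(genes, min(20, length(genes)))
  utils::write.table(data.frame(gene = ndd), p("ndd_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = genes, pli = round(stats::runif(length(genes)), 4),
               prec = round(stats::runif(length(genes)), 4),
               pnull = round(stats::runif(length(genes)), 4)),
    p("constraint.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = genes,
               brain_expressed = stats::runif(length(genes)) < 0.5 |
                 genes %in% known),
    p("brain_expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  omim_g <- sample(genes, min(10, length(genes)))
  utils::write.table(
    data.frame(gene = omim_g,
               phenotype = paste0("phenotype_", seq_along(omim_g))),
    p("omim.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  chroms <- cohort$model$chromosomes
  ci <- sample.int(nrow(chroms), 5, replace = TRUE)
  w <- floor(stats::runif(5, 2e5, 2e6))
  s <- floor(stats::runif(5, 1, pmax(2, chroms$length_bp[ci] - w)))
  utils::write.table(
    data.frame(chrom = chroms$chrom[ci], start = s, end = s + w,
               locus = paste0("sfari_cnv_", 1:5),
               median_size_bp = floor(stats::runif(5, 1e5, 1e6))),
    p("sfari_cnv.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths$tables <- p("sfari_genes.tsv")
  invisible(paths)
}

#' Read the promoter-enhancer interaction pair table
#'
#' @param path `interactions.tsv` written by [write_fixture_bundle()]:
#'   columns `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`, `gene`
#'   (1-based inclusive intervals).
#' @return tibble of interaction pairs.
#' @export
read_interactions <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read a pedigree TSV (sample, father, mother, sex, affected)
#'
#' `0` in the parent columns denotes a founder.
#'
#' @param path pedigree TSV path.
#' @return a pedigree tibble compatible with the calling functions.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  ped <- tibble::tibble(sample_id = as.character(d$sample),
                        father_id = ifelse(d$father == "0", NA_character_,
                                           as.character(d$father)),
                        mother_id = ifelse(d$mother == "0", NA_character_,
                                           as.character(d$mother)),
                        sex = d$sex,
                        affected = as.logical(d$affected),
                        role = NA_character_,
                        family_id = NA_character_)
  class(ped) <- c("pedigree", class(ped))
  ped
}
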