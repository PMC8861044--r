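#' Site-by-sample variant table
#'
#' The central in-memory container of the pipeline: a site annotation tibble
#' aligned with integer genotype, GQ, and allelic-depth matrices
#' (sites x samples). Produced by [read_cohort_vcf()] or, for synthetic
#' cohorts, by [as_variant_table()].
#'
#' @param sites site tibble (see [synthesize_sites()] for the column set).
#' @param geno integer genotype matrix in the package codes ([gt_label()]).
#' @param gq integer GQ matrix.
#' @param ad_ref,ad_alt integer allelic-depth matrices (reference- and
#'   alternate-supporting reads).
#' @param pedigree optional pedigree tibble.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, gq, ad_ref, ad_alt, pedigree = NULL) {
  stopifnot(nrow(sites) == nrow(geno),
            identical(dim(geno), dim(gq)),
            identical(dim(geno), dim(ad_ref)),
            identical(dim(geno), dim(ad_alt)))
  structure(list(sites = sites, geno = geno, gq = gq,
                 ad_ref = ad_ref, ad_alt = ad_alt, pedigree = pedigree),
            class = "variant_table")
}

# default GQ/AD stamps per genotype code: all pass the GQ>=99 / depth>=10 QC
.default_gq <- function(geno) {
  gq <- geno
  gq[] <- 99L
  gq[is.na(geno)] <- NA_integer_
  gq
}

.default_ad <- function(geno) {
  ref <- geno
  alt <- geno
  ref[] <- 0L; alt[] <- 0L
  ref[geno %in% c(GT_HOM_REF)] <- 25L
  ref[geno %in% c(GT_HEMI_REF)] <- 20L
  ref[geno %in% c(GT_HET)] <- 12L
  alt[geno %in% c(GT_HET)] <- 13L
  alt[geno %in% c(GT_HOM_ALT)] <- 25L
  alt[geno %in% c(GT_HEMI_ALT)] <- 20L
  ref[is.na(geno)] <- NA_integer_
  alt[is.na(geno)] <- NA_integer_
  list(ref = ref, alt = alt)
}

#' Materialize a synthetic cohort as a variant table
#'
#' Expands the cohort's genotype matrix with default GQ (99) and allelic
#' depths consistent with each genotype (heterozygotes 12 ref / 13 alt reads,
#' allele balance 0.52), applying any per-genotype overrides recorded on the
#' cohort.
#'
#' @param cohort a [sim_cohort()] cohort.
#' @return a [variant_table()].
#' @export
as_variant_table <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  geno <- cohort$geno
  gq <- .default_gq(geno)
  ad <- .default_ad(geno)
  ov <- cohort$overrides
  if (nrow(ov)) {
    i <- cbind(match(ov$site_id, cohort$sites$site_id),
               match(ov$sample_id, colnames(geno)))
    gq[i] <- ov$gq
    ad$ref[i] <- ov$ad_ref
    ad$alt[i] <- ov$ad_alt
  }
  variant_table(cohort$sites, geno, gq, ad$ref, ad$alt, cohort$pedigree)
}

# INFO keys used by the fixture VCF dialect
.info_keys <- tibble::tibble(
  key = c("QD", "ReadPosRankSum", "GENE", "EFFECT", "AF_1KG", "AF_GNOMAD",
          "AF_GME", "SIFT", "PP2_HVAR", "PROVEAN", "MA", "CADD", "PHASTCONS",
          "PHYLOP", "GERP", "SUBPOP", "SEGDUP", "SIMPLEREP"),
  col = c("qd", "rprs", "gene", "effect", "af_1kg", "af_gnomad", "af_gme",
          "sift", "pp2_hvar", "provean", "mut_assessor", "cadd", "phastcons",
          "phylop", "gerp", "subpop", "segdup", "simple_repeat"),
  type = c("Float", "Float", "String", "String", "Float", "Float", "Float",
           "Float", "Float", "Float", "Float", "Float", "Float", "Float",
           "Float", "String", "Flag", "Flag"))

# genotype code -> VCF GT string
.gt_string <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == GT_HOM_REF] <- "0/0"
  out[!is.na(code) & code == GT_HET] <- "0/1"
  out[!is.na(code) & code == GT_HOM_ALT] <- "1/1"
  out[!is.na(code) & code == GT_HEMI_REF] <- "0"
  out[!is.na(code) & code == GT_HEMI_ALT] <- "1"
  out
}

#' Write a variant table as a VCF v4.2 file
#'
#' Emits one record per site with FORMAT `GT:GQ:AD` and the package's INFO
#' annotation keys (QD, ReadPosRankSum, GENE, EFFECT, the three population
#' allele frequencies, four damage-predictor and four conservation scores,
#' SUBPOP, SEGDUP/SIMPLEREP flags). Positions are 1-based per VCF.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param contigs optional tibble `chrom`, `length_bp` for contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, contigs = NULL) {
  sites <- vt$sites
  samples <- colnames(vt$geno)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=autozyg",
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           "##FILTER=<ID=LowQual,Description=\"Low quality\">")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
                          as.integer(contigs$length_bp)))
  }
  for (i in seq_len(nrow(.info_keys))) {
    n <- if (.info_keys$type[i] == "Flag") "0" else "1"
    hdr <- c(hdr, sprintf("##INFO=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
                          .info_keys$key[i], n, .info_keys$type[i],
                          .info_keys$col[i]))
  }
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  info <- vapply(seq_len(nrow(sites)), function(i) {
    parts <- character(0)
    for (k in seq_len(nrow(.info_keys))) {
      v <- sites[[.info_keys$col[k]]][i]
      key <- .info_keys$key[k]
      if (.info_keys$type[k] == "Flag") {
        if (isTRUE(v)) parts <- c(parts, key)
      } else if (!is.na(v) && !(is.character(v) && v == "")) {
        val <- if (is.numeric(v)) format(v, digits = 10, scientific = FALSE,
                                         trim = TRUE) else as.character(v)
        parts <- c(parts, paste0(key, "=", val))
      }
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  lines <- character(0)
  if (nrow(sites) > 0) {
    gt <- .gt_string(vt$geno)
    dim(gt) <- dim(vt$geno)
    gq <- ifelse(is.na(vt$gq), ".", as.character(vt$gq))
    adr <- ifelse(is.na(vt$ad_ref), ".", as.character(vt$ad_ref))
    ada <- ifelse(is.na(vt$ad_alt), ".", as.character(vt$ad_alt))
    calls <- matrix(paste0(gt, ":", gq, ":", adr, ",", ada),
                    nrow = nrow(sites))
    body <- cbind(sites$chrom, as.integer(sites$pos), sites$site_id,
                  sites$ref, sites$alt, ".", sites$filter, info, "GT:GQ:AD",
                  calls)
    lines <- apply(body, 1, paste, collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a multi-sample cohort VCF into a variant table
#'
#' Parses a VCF v4.2 with `vcfR`, decomposes multi-allelic records into one
#' site per alternate allele (genotypes and allelic depths re-projected per
#' alternate; alleles other than the current alternate count as reference),
#' and maps the package's INFO annotation keys onto site columns. Record
#' order is preserved; decomposed alternates stay adjacent.
#'
#' @param path VCF path.
#' @param pedigree optional pedigree tibble; when given, the VCF sample set
#'   must contain every pedigree sample.
#' @return a [variant_table()].
#' @export
read_cohort_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  if (!is.null(pedigree) && !all(pedigree$sample_id %in% samples)) {
    stop("VCF is missing pedigree samples: ",
         paste(setdiff(pedigree$sample_id, samples), collapse = ", "))
  }
  fmt <- strsplit(gt_raw[, "FORMAT"], ":")
  get_field <- function(row_idx, field) {
    pos <- match(field, fmt[[row_idx]])
    if (is.na(pos)) return(rep(NA_character_, length(samples)))
    vapply(strsplit(gt_raw[row_idx, -1], ":"), function(x)
      if (length(x) >= pos) x[pos] else NA_character_, character(1))
  }
  info_parse <- function(info, key, flag = FALSE) {
    if (flag) {
      grepl(paste0("(^|;)", key, "(;|$)"), info)
    } else {
      m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]*)"), info))
      vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_,
             character(1))
    }
  }
  n_rec <- nrow(fix)
  out_sites <- list()
  out_geno <- list()
  out_gq <- list()
  out_adr <- list()
  out_ada <- list()
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) == 0 || any(is.na(alts)))
      stop("malformed record at VCF data line ", i)
    gts <- get_field(i, "GT")
    gqs <- suppressWarnings(as.integer(get_field(i, "GQ")))
    ads <- strsplit(get_field(i, "AD"), ",", fixed = TRUE)
    info <- fix$INFO[i]
    allele_lists <- strsplit(gts, "[/|]")
    for (a in seq_along(alts)) {
      code <- vapply(allele_lists, function(al) {
        if (length(al) == 0 || any(al == ".")) return(NA_integer_)
        al <- as.integer(al)
        n_alt <- sum(al == a)
        if (length(al) == 1) {
          if (n_alt == 1) GT_HEMI_ALT else GT_HEMI_REF
        } else {
          as.integer(n_alt)
        }
      }, integer(1))
      adr <- vapply(ads, function(x) {
        if (all(is.na(x))) return(NA_integer_)
        suppressWarnings(as.integer(x[1]))
      }, integer(1))
      ada <- vapply(ads, function(x) {
        if (all(is.na(x)) || length(x) < a + 1) return(NA_integer_)
        suppressWarnings(as.integer(x[a + 1]))
      }, integer(1))
      num <- function(key) suppressWarnings(as.numeric(info_parse(info, key)))
      chr_ <- function(key) info_parse(info, key)
      site <- tibble::tibble(
        site_id = if (!is.na(fix$ID[i]) && fix$ID[i] != ".")
            paste0(fix$ID[i], if (length(alts) > 1) paste0("_", a) else "")
          else paste0("v", i, "_", a),
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        filter = ifelse(is.na(fix$FILTER[i]), ".", fix$FILTER[i]),
        qd = num("QD"), rprs = num("ReadPosRankSum"),
        gene = chr_("GENE"), effect = chr_("EFFECT"),
        af_1kg = num("AF_1KG"), af_gnomad = num("AF_GNOMAD"),
        af_gme = num("AF_GME"), sift = num("SIFT"),
        pp2_hvar = num("PP2_HVAR"), provean = num("PROVEAN"),
        mut_assessor = num("MA"), cadd = num("CADD"),
        phastcons = num("PHASTCONS"), phylop = num("PHYLOP"),
        gerp = num("GERP"),
        segdup = info_parse(info, "SEGDUP", flag = TRUE),
        simple_repeat = info_parse(info, "SIMPLEREP", flag = TRUE),
        subpop = ifelse(is.na(chr_("SUBPOP")), "", chr_("SUBPOP")))
      out_sites[[length(out_sites) + 1L]] <- site
      out_geno[[length(out_geno) + 1L]] <- code
      out_gq[[length(out_gq) + 1L]] <- gqs
      out_adr[[length(out_adr) + 1L]] <- adr
      out_ada[[length(out_ada) + 1L]] <- ada
    }
  }
  sites <- dplyr::bind_rows(out_sites)
  mk <- function(lst) {
    m <- do.call(rbind, lst)
    colnames(m) <- samples
    rownames(m) <- sites$site_id
    m
  }
  variant_table(sites, mk(out_geno), mk(out_gq), mk(out_adr), mk(out_ada),
                pedigree)
}

#' Encode / decode the SUBPOP annotation
#'
#' Subpopulation allele frequencies and homozygote counts are carried as a
#' compact string (`"SAS:0.001:0|EUR:0.002:1"`), VCF-INFO safe.
#'
#' @param subpop tibble with columns `subpop`, `af`, `hom`.
#' @return `encode_subpop()` a string; `parse_subpop()` the tibble.
#' @export
encode_subpop <- function(subpop) {
  if (is.null(subpop) || nrow(subpop) == 0) return("")
  paste(sprintf("%s:%s:%d", subpop$subpop,
                format(subpop$af, digits = 8, scientific = FALSE, trim = TRUE),
                as.integer(subpop$hom)), collapse = "|")
}

#' @rdname encode_subpop
#' @param s encoded string.
#' @export
parse_subpop <- function(s) {
  if (is.na(s) || s == "") {
    return(tibble::tibble(subpop = character(), af = numeric(),
                          hom = integer()))
  }
  parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble::tibble(subpop = vapply(parts, `[`, character(1), 1),
                 af = as.numeric(vapply(parts, `[`, character(1), 2)),
                 hom = as.integer(vapply(parts, `[`, character(1), 3)))
}
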