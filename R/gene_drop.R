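#' Gene-drop a pedigree through a genome model
#'
#' Assigns every founder chromosome a unique ancestry label and transmits
#' recombinant mosaics down the pedigree. Crossovers per meiosis are
#' Poisson(length_Mb * rate_cM_Mb / 100) with positions uniform along the
#' chromosome (uniform genetic map, no interference). The X is transmitted
#' hemizygously to males outside the pseudoautosomal regions: a male carries
#' one full maternal X plus a paternal PAR-only haplotype; a female receives
#' her father's X intact.
#'
#' The returned truth includes, per child, the maximal autosomal intervals
#' where both haplotypes descend from the same founder chromosome
#' (autozygous segments), and the crossover count of every meiosis.
#'
#' @param ped a [build_pedigree()] pedigree.
#' @param model a [genome_model()].
#' @param seed integer seed.
#' @return object of class `gene_drop`: list with `haplotypes` (nested list
#'   sample -> chromosome -> list(hap1, hap2); each haplotype a data.frame
#'   with `start`, `end`, `hap` founder-haplotype id; `hap2` is `NULL` for
#'   the male X and PAR-only segments are stored in `hap2` for males),
#'   `autozygous` (tibble `sample_id`, `chrom`, `start`, `end`),
#'   `crossovers` (tibble `sample_id`, `chrom`, `parent`, `n_xo`),
#'   `founder_haps` (tibble `sample_id`, `hap1`, `hap2` id allocation),
#'   plus the pedigree and model.
#' @export
gene_drop <- function(ped, model, seed = 1L) {
  validate_pedigree(ped)
  stopifnot(nrow(model$chromosomes) >= 1)
  set.seed(.substream(seed, "gene_drop"))
  chroms <- model$chromosomes
  founders <- ped_founders(ped)
  fh <- tibble::tibble(sample_id = founders,
                       hap1 = 2L * seq_along(founders) - 1L,
                       hap2 = 2L * seq_along(founders))
  sex_of <- stats::setNames(ped$sex, ped$sample_id)
  haps <- list()
  xo_log <- list()

  one_seg <- function(len, id) data.frame(start = 1, end = len, hap = id)

  for (f in founders) {
    ids <- fh[fh$sample_id == f, ]
    haps[[f]] <- lapply(seq_len(nrow(chroms)), function(ci) {
      len <- chroms$length_bp[ci]
      if (chroms$is_x[ci] && sex_of[f] == "male") {
        h2 <- if (!is.null(model$par)) {
          data.frame(start = model$par$start, end = model$par$end,
                     hap = ids$hap2)
        } else NULL
        list(hap1 = one_seg(len, ids$hap1), hap2 = h2)
      } else {
        list(hap1 = one_seg(len, ids$hap1), hap2 = one_seg(len, ids$hap2))
      }
    })
    names(haps[[f]]) <- chroms$chrom
  }

  # process non-founders in dependency order
  todo <- setdiff(ped$sample_id, founders)
  while (length(todo)) {
    ready <- todo[vapply(todo, function(s) {
      i <- match(s, ped$sample_id)
      all(c(ped$father_id[i], ped$mother_id[i]) %in% names(haps))
    }, logical(1))]
    if (!length(ready)) stop("pedigree is not resolvable")
    for (s in ready) {
      i <- match(s, ped$sample_id)
      fa <- ped$father_id[i]; mo <- ped$mother_id[i]
      haps[[s]] <- vector("list", nrow(chroms))
      names(haps[[s]]) <- chroms$chrom
      for (ci in seq_len(nrow(chroms))) {
        cn <- chroms$chrom[ci]; len <- chroms$length_bp[ci]
        if (!chroms$is_x[ci]) {
          mp <- .meiosis(haps[[fa]][[cn]], len, model$recombination_rate)
          mm <- .meiosis(haps[[mo]][[cn]], len, model$recombination_rate)
          haps[[s]][[cn]] <- list(hap1 = mp$hap, hap2 = mm$hap)
          xo_log[[length(xo_log) + 1L]] <- tibble::tibble(
            sample_id = s, chrom = cn, parent = c(fa, mo),
            n_xo = c(mp$n_xo, mm$n_xo))
        } else {
          # maternal X always recombines between the mother's two Xs
          mm <- .meiosis(haps[[mo]][[cn]], len, model$recombination_rate)
          xo_log[[length(xo_log) + 1L]] <- tibble::tibble(
            sample_id = s, chrom = cn, parent = mo, n_xo = mm$n_xo)
          if (sex_of[s] == "male") {
            # paternal contribution restricted to the PARs, no crossover
            haps[[s]][[cn]] <- list(hap1 = mm$hap,
                                    hap2 = haps[[fa]][[cn]]$hap2)
          } else {
            haps[[s]][[cn]] <- list(hap1 = haps[[fa]][[cn]]$hap1,
                                    hap2 = mm$hap)
          }
        }
      }
    }
    todo <- setdiff(todo, ready)
  }

  kids <- ped_children(ped)
  auto <- lapply(kids, function(s) {
    segs <- lapply(which(!chroms$is_x), function(ci) {
      cn <- chroms$chrom[ci]
      a <- .equal_label_segments(haps[[s]][[cn]]$hap1, haps[[s]][[cn]]$hap2)
      if (nrow(a)) tibble::tibble(sample_id = s, chrom = cn,
                                  start = a$start, end = a$end)
    })
    dplyr::bind_rows(segs)
  })
  auto <- dplyr::bind_rows(auto)
  if (nrow(auto) == 0) {
    auto <- tibble::tibble(sample_id = character(), chrom = character(),
                           start = numeric(), end = numeric())
  }

  structure(list(haplotypes = haps, autozygous = auto,
                 crossovers = dplyr::bind_rows(xo_log),
                 founder_haps = fh, pedigree = ped, model = model),
            class = "gene_drop")
}

# one meiosis: recombine a parent's two haplotypes over [1, len]
.meiosis <- function(parent, len, rate_cM_Mb) {
  n_xo <- stats::rpois(1, len / 1e6 * rate_cM_Mb / 100)
  cuts <- if (n_xo > 0) sort(unique(floor(stats::runif(n_xo, 1, len)))) else numeric(0)
  starts <- c(1, cuts + 1)
  ends <- c(cuts, len)
  phases <- (sample(0:1, 1) + seq_along(starts) - 1L) %% 2L + 1L
  pieces <- lapply(seq_along(starts), function(k) {
    src <- if (phases[k] == 1L) parent$hap1 else parent$hap2
    .clip_segments(src, starts[k], ends[k])
  })
  hap <- do.call(rbind, pieces)
  hap <- .merge_adjacent(hap)
  list(hap = hap, n_xo = length(cuts))
}

# restrict a segment table to [s, e]
.clip_segments <- function(segs, s, e) {
  keep <- segs$end >= s & segs$start <= e
  out <- segs[keep, , drop = FALSE]
  if (nrow(out)) {
    out$start <- pmax(out$start, s)
    out$end <- pmin(out$end, e)
  }
  out
}

# merge adjacent segments with the same label
.merge_adjacent <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  keep <- c(TRUE, !(segs$hap[-1] == segs$hap[-nrow(segs)] &
                      segs$start[-1] == segs$end[-nrow(segs)] + 1))
  grp <- cumsum(keep)
  data.frame(start = tapply(segs$start, grp, min),
             end = tapply(segs$end, grp, max),
             hap = segs$hap[keep], row.names = NULL)
}

# maximal intervals where two segment partitions carry the same label
.equal_label_segments <- function(h1, h2) {
  if (is.null(h1) || is.null(h2)) return(data.frame(start = numeric(0), end = numeric(0)))
  b <- sort(unique(c(h1$start, h2$start)))
  ends <- c(b[-1] - 1, max(h1$end))
  i1 <- findInterval(b, h1$start)
  i2 <- findInterval(b, h2$start)
  same <- h1$hap[i1] == h2$hap[i2]
  if (!any(same)) return(data.frame(start = numeric(0), end = numeric(0)))
  segs <- data.frame(start = b[same], end = ends[same], hap = 1)
  out <- .merge_adjacent_any(segs)
  out[, c("start", "end")]
}

# merge book-ended intervals regardless of label
.merge_adjacent_any <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  keep <- c(TRUE, segs$start[-1] > segs$end[-nrow(segs)] + 1)
  grp <- cumsum(keep)
  data.frame(start = tapply(segs$start, grp, min),
             end = tapply(segs$end, grp, max),
             hap = segs$hap[keep], row.names = NULL)
}

#' Truth autozygous genome fraction per child
#'
#' Fraction of the autosomal genome where both of a child's haplotypes
#' descend from the same founder chromosome. The expectation equals the
#' inbreeding coefficient: 6.25% for first-cousin offspring, 12.5% for
#' double-first-cousin offspring.
#'
#' @param drop a [gene_drop()] result.
#' @param min_length_bp count only segments of at least this length
#'   (default 0, i.e. all).
#' @return tibble `sample_id`, `autozygous_bp`, `fraction`.
#' @export
autozygous_fraction <- function(drop, min_length_bp = 0) {
  denom <- autosome_length(drop$model)
  kids <- ped_children(drop$pedigree)
  segs <- drop$autozygous
  segs <- segs[segs$end - segs$start + 1 >= min_length_bp, , drop = FALSE]
  bp <- vapply(kids, function(s) {
    sum(segs$end[segs$sample_id == s] - segs$start[segs$sample_id == s] + 1)
  }, numeric(1))
  tibble::tibble(sample_id = kids, autozygous_bp = unname(bp),
                 fraction = unname(bp) / denom)
}
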