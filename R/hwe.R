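#' Exact test of Hardy-Weinberg equilibrium on genotype counts
#'
#' Exact conditional test: given the minor-allele count, the probability of
#' each possible heterozygote count is computed by the standard recurrence
#' (stable ratios between adjacent configurations), and the two-sided p-value
#' sums the probabilities of all configurations no more probable than the
#' observed one.
#'
#' @param n_het observed heterozygote count.
#' @param n_hom_rare observed count of homozygotes for the rarer allele.
#' @param n_hom_common observed count of homozygotes for the commoner allele.
#' @return p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  if (n == 0) return(1)
  rare <- 2 * n_hom_rare + n_het
  if (2 * n_hom_common + n_het < rare) {
    # ensure 'rare' is the minor allele
    tmp <- n_hom_rare; n_hom_rare <- n_hom_common; n_hom_common <- tmp
    rare <- 2 * n_hom_rare + n_het
  }
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start from the mid-range configuration and apply the recurrence
  # P(h+2)/P(h) = 4 * n_aa(h) * n_AA(h) / ((h+2) * (h+1))
  mid <- hets[which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))]
  k0 <- match(mid, hets)
  probs[k0] <- 1
  h <- mid
  while (h + 2 <= rare) {
    naa <- (rare - h) / 2
    nAA <- n - naa - h
    k <- match(h, hets)
    probs[k + 1] <- probs[k] * 4 * naa * nAA / ((h + 2) * (h + 1))
    h <- h + 2
  }
  h <- mid
  while (h - 2 >= hets[1]) {
    naa <- (rare - h) / 2
    nAA <- n - naa - h
    k <- match(h, hets)
    probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (naa + 1) * (nAA + 1))
    h <- h - 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Vectorized HWE exact p-values for genotype-count triples
#'
#' @param n_het,n_hom_rare,n_hom_common integer vectors.
#' @return numeric p-value vector (memoized over unique triples).
#' @export
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  key <- paste(n_het, n_hom_rare, n_hom_common, sep = "_")
  uk <- unique(key)
  parts <- strsplit(uk, "_", fixed = TRUE)
  up <- vapply(parts, function(x) {
    x <- as.integer(x)
    hwe_exact_test(x[1], x[2], x[3])
  }, numeric(1))
  up[match(key, uk)]
}
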