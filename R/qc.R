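#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test: given the observed allele counts, every possible
#' heterozygote count of matching parity is enumerated and the p-value is the
#' total probability of all configurations whose conditional probability does
#' not exceed that of the observed one (probability-mass ordering, two-sided).
#' Weights are computed on the log scale so large samples do not overflow.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total
#'   at least 1).
#' @return The exact p-value in `[0, 1]`.
#' @examples
#' hwe_exact_test(3, 0, 2)  # 10/210
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotype required")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  h <- seq(n_minor %% 2L, n_minor, by = 2L)
  hom_minor <- (n_minor - h) / 2
  hom_major <- n - h - hom_minor
  logw <- lgamma(n + 1) - lgamma(hom_minor + 1) - lgamma(h + 1) -
    lgamma(hom_major + 1) + h * log(2)
  logw <- logw - max(logw)
  p <- exp(logw) / sum(exp(logw))
  p_obs <- p[h == n_het]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Genotype quality control
#'
#' Applies the standard pre-scan filters to a panel, in a fixed order so the
#' report is deterministic: animals with too many missing genotypes are
#' dropped first, then markers are removed for (1) unknown map position,
#' (2) low call rate, (3) minor allele frequency at or below the threshold
#' (the frequency must exceed `min_maf` to be kept), and (4) departure from
#' Hardy-Weinberg proportions below `hwe_min_p` by [hwe_exact_test()]. Each
#' marker is counted once, in the first filter that removes it.
#'
#' @param panel A [phased_panel()].
#' @param max_sample_missing Animals with a larger missing-genotype fraction
#'   are removed (default 0.15).
#' @param min_call_rate Minimum marker call rate (default 0.85).
#' @param min_maf Markers are kept only when MAF strictly exceeds this value
#'   (default 0.01).
#' @param hwe_min_p HWE exact-test floor (default 1e-12).
#' @return A list with elements `panel` (the filtered [phased_panel()]) and
#'   `report` (a one-row tibble tallying removals per category).
#' @export
apply_qc <- function(panel, max_sample_missing = 0.15, min_call_rate = 0.85,
                     min_maf = 0.01, hwe_min_p = 1e-12) {
  stopifnot(inherits(panel, "phased_panel"))
  n <- length(panel$animals)
  m <- nrow(panel$markers)
  if (n == 0 || m == 0) abort("empty panel")
  hap <- panel$haplotypes
  odd <- seq(1L, 2L * n, by = 2L)
  miss_animal <- (is.na(hap[odd, , drop = FALSE]) |
                    is.na(hap[odd + 1L, , drop = FALSE]))
  frac_animal <- rowMeans(miss_animal)
  keep_animal <- frac_animal <= max_sample_missing
  if (!any(keep_animal)) abort("QC removed every animal")
  rows_keep <- rep(keep_animal, each = 2L)
  hap <- hap[rows_keep, , drop = FALSE]
  animals <- panel$animals[keep_animal]
  n <- length(animals)
  odd <- seq(1L, 2L * n, by = 2L)
  g1 <- hap[odd, , drop = FALSE]
  g2 <- hap[odd + 1L, , drop = FALSE]
  g <- g1 + g2                        # animals x markers dosage, NA if missing
  called <- colSums(!is.na(g))
  removed <- rep(NA_character_, m)
  removed[is.na(panel$markers$pos)] <- "position"
  call_rate <- called / n
  low_call <- is.na(removed) & call_rate < min_call_rate
  removed[low_call] <- "callrate"
  p_alt <- colSums(g, na.rm = TRUE) / (2 * called)
  maf <- pmin(p_alt, 1 - p_alt)
  low_maf <- is.na(removed) & (is.nan(maf) | maf <= min_maf)
  removed[low_maf] <- "maf"
  for (j in which(is.na(removed))) {
    gj <- g[, j]
    cnt <- c(sum(gj == 0, na.rm = TRUE), sum(gj == 1, na.rm = TRUE),
             sum(gj == 2, na.rm = TRUE))
    if (hwe_exact_test(cnt[1], cnt[2], cnt[3]) < hwe_min_p) {
      removed[j] <- "hwe"
    }
  }
  keep <- is.na(removed)
  if (!any(keep)) abort("QC removed every marker")
  out <- phased_panel(panel$markers[keep, , drop = FALSE], animals,
                      hap[, keep, drop = FALSE], phased = panel$phased)
  report <- tibble(
    n_animals_removed = sum(!keep_animal),
    n_markers_removed_position = sum(removed == "position", na.rm = TRUE),
    n_markers_removed_callrate = sum(removed == "callrate", na.rm = TRUE),
    n_markers_removed_maf = sum(removed == "maf", na.rm = TRUE),
    n_markers_removed_hwe = sum(removed == "hwe", na.rm = TRUE),
    n_markers_kept = sum(keep)
  )
  list(panel = out, report = report)
}
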