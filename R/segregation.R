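#' Mendelian segregation test for genotyped carrier-mating progeny
#'
#' Goodness-of-fit of genotype counts from carrier-by-carrier litters
#' against the Mendelian expectation. Two expectations are supported:
#' `"birth_1_2_1"` (wild type : carrier : homozygote = 1:2:1 among all
#' genotyped piglets, including dead ones) and `"survivors_1_2"` (1:2 for
#' wild type : carrier among survivors, when homozygotes die before
#' genotyping age). Counts pooled over litters are sufficient, so summed
#' counts and per-litter pooling give the same test. Alongside the
#' chi-squared statistic an exact multinomial p-value (probability-mass
#' ordering, as in [hwe_exact_test()]) is reported for totals up to
#' `exact_max`.
#'
#' @param n_wt,n_het,n_hom Genotype counts. `n_hom` is ignored (and must be
#'   zero or `NULL`) under the survivor expectation.
#' @param expectation `"survivors_1_2"` or `"birth_1_2_1"`.
#' @param exact_max Largest total for which the exact multinomial p-value is
#'   enumerated (default 100).
#' @return A one-row tibble: `chisq`, `df`, `p_chisq`, `p_exact` (NA when
#'   not enumerated), `n`.
#' @examples
#' segregation_test(27, 46, expectation = "survivors_1_2")
#' segregation_test(8, 26, 19, expectation = "birth_1_2_1")
#' @export
segregation_test <- function(n_wt, n_het, n_hom = NULL,
                             expectation = c("survivors_1_2", "birth_1_2_1"),
                             exact_max = 100) {
  expectation <- match.arg(expectation)
  if (expectation == "survivors_1_2") {
    if (!is.null(n_hom) && isTRUE(n_hom > 0)) {
      abort("survivor expectation requires n_hom = 0 (homozygotes excluded)")
    }
    counts <- c(n_wt, n_het)
    probs <- c(1, 2) / 3
  } else {
    if (is.null(n_hom)) abort("birth expectation needs all three counts")
    counts <- c(n_wt, n_het, n_hom)
    probs <- c(1, 2, 1) / 4
  }
  if (any(counts < 0)) abort("negative genotype count")
  n <- sum(counts)
  if (n == 0) abort("no genotyped progeny")
  expected <- n * probs
  if (any(expected < 1)) {
    warn("expected cell below 1; rely on the exact p-value")
    chisq <- NA_real_; df <- NA_integer_; p_chisq <- NA_real_
  } else {
    ht <- suppressWarnings(stats::chisq.test(counts, p = probs))
    chisq <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p_chisq <- ht$p.value
  }
  p_exact <- if (n <= exact_max) exact_multinomial_test(counts, probs) else NA_real_
  tibble(chisq = chisq, df = df, p_chisq = p_chisq, p_exact = p_exact, n = n)
}

#' Exact multinomial goodness-of-fit p-value
#'
#' Enumerates every outcome of `n` draws over the categories and sums the
#' probability of all outcomes no more probable than the observed one
#' (probability-mass ordering).
#'
#' @param counts Observed counts.
#' @param probs Category probabilities (summing to 1).
#' @return Exact p-value in `[0, 1]`.
#' @export
exact_multinomial_test <- function(counts, probs) {
  stopifnot(length(counts) == length(probs), abs(sum(probs) - 1) < 1e-9)
  n <- sum(counts)
  k <- length(counts)
  outcomes <- compositions(n, k)
  logp <- lgamma(n + 1) -
    rowSums(lgamma(outcomes + 1)) +
    as.vector(outcomes %*% log(probs))
  lp_obs <- lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(counts * log(probs))
  min(1, sum(exp(logp[logp <= lp_obs + 1e-9])))
}

# all k-part compositions of n as a matrix (rows)
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  do.call(rbind, lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1), deparse.level = 0)
  }))
}

#' Penetrance of the homozygous genotype in genotyped litters
#'
#' Given fully genotyped litters with per-piglet fates, estimates penetrance
#' as the fraction of homozygotes dying within the death window, and the
#' matching background rate among non-homozygous littermates.
#'
#' @param piglets A tibble with `genotype` (0/1/2 dosage of the lethal
#'   allele), `fate` and `age_hours`.
#' @param death_window_hours Deaths at or before this age count (default
#'   48); stillbirths always count.
#' @return A one-row tibble: `n_hom`, `n_hom_dead`, `penetrance` (NA when
#'   there are no homozygotes), `n_other`, `n_other_dead`, `background_rate`.
#' @export
penetrance_summary <- function(piglets, death_window_hours = 48) {
  piglets <- as_tibble(piglets)
  stopifnot(all(c("genotype", "fate") %in% names(piglets)))
  dead_in <- piglets$fate == "stillborn" |
    (piglets$fate == "died" & piglets$age_hours <= death_window_hours)
  hom <- piglets$genotype == 2L
  n_hom <- sum(hom, na.rm = TRUE)
  n_other <- sum(!hom, na.rm = TRUE)
  tibble(
    n_hom = n_hom,
    n_hom_dead = sum(dead_in & hom, na.rm = TRUE),
    penetrance = if (n_hom > 0) sum(dead_in & hom, na.rm = TRUE) / n_hom
                 else NA_real_,
    n_other = n_other,
    n_other_dead = sum(dead_in & !hom, na.rm = TRUE),
    background_rate = if (n_other > 0) sum(dead_in & !hom, na.rm = TRUE) /
                        n_other else NA_real_
  )
}
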