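#' Classify litters by parental carrier status
#'
#' Labels each litter by the carrier status of its parents, sire letter
#' first: `CxN` is a carrier sire mated to a non-carrier dam, `NxC` the
#' reverse. A parent is a carrier (`C`) when its haplotype dosage is 1 or 2.
#' Litters with a parent of unknown status are excluded and tallied in the
#' `n_excluded` attribute.
#'
#' @param litters A data frame with at least `litter_id`, `sire_id`,
#'   `dam_id`.
#' @param carriers A data frame with `animal_id` and `dosage` (e.g. from
#'   [assign_carrier_status()]).
#' @return The litters tibble with an added `mating_class` column, unknown
#'   parents removed; attribute `n_excluded` counts removed litters.
#' @export
classify_matings <- function(litters, carriers) {
  litters <- as_tibble(litters)
  status <- setNames(carriers$dosage >= 1L, carriers$animal_id)
  sire_c <- status[litters$sire_id]
  dam_c <- status[litters$dam_id]
  known <- !is.na(sire_c) & !is.na(dam_c)
  out <- litters[known, , drop = FALSE]
  out$mating_class <- paste0(ifelse(sire_c[known], "C", "N"), "x",
                             ifelse(dam_c[known], "C", "N"))
  attr(out, "n_excluded") <- sum(!known)
  out
}

#' Litter phenotype summary per mating class
#'
#' Reproduces the carrier-mating contrast table: litter counts, mean litter
#' sizes and aggregate survival rates per class. Survival percentages are
#' pooled ratios of sums (total live born over total born; total weaned over
#' total live born), which weights piglets rather than litters.
#'
#' @param litters A classified litter tibble from [classify_matings()], with
#'   columns `total_born`, `live_born`, `n_weaned` (or a `piglets` companion,
#'   see `piglets`).
#' @param piglets Optional per-piglet tibble (`litter_id`, `fate`) from which
#'   weaned counts are derived when `litters` lacks `n_weaned`.
#' @return A tibble with one row per mating class: `mating_class`,
#'   `n_litters`, `mean_total_born`, `mean_live_born`,
#'   `farrowing_survival_pct`, `lactation_survival_pct` (NA when a class has
#'   no live-born piglets).
#' @export
summarize_by_class <- function(litters, piglets = NULL) {
  litters <- as_tibble(litters)
  if (!"mating_class" %in% names(litters)) {
    abort("litters must carry a mating_class column; see classify_matings()")
  }
  if (!"n_weaned" %in% names(litters)) {
    if (is.null(piglets)) abort("need n_weaned column or a piglets table")
    wn <- piglets |>
      dplyr::group_by(.data$litter_id) |>
      dplyr::summarise(n_weaned = sum(.data$fate == "weaned"))
    litters <- dplyr::left_join(litters, wn, by = "litter_id")
    litters$n_weaned[is.na(litters$n_weaned)] <- 0L
  }
  litters |>
    dplyr::group_by(.data$mating_class) |>
    dplyr::summarise(
      n_litters = dplyr::n(),
      mean_total_born = mean(.data$total_born),
      mean_live_born = mean(.data$live_born),
      farrowing_survival_pct = 100 * sum(.data$live_born) / sum(.data$total_born),
      lactation_survival_pct = ifelse(sum(.data$live_born) > 0,
                                      100 * sum(.data$n_weaned) /
                                        sum(.data$live_born), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$mating_class, c("NxN", "CxN", "NxC", "CxC")))
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around [stats::t.test()] returning a tidy one-row tibble;
#' used to contrast per-litter phenotypes between carrier-by-carrier and
#' carrier-by-non-carrier litters.
#'
#' @param sample_a,sample_b Numeric vectors (each of length >= 2).
#' @return A tibble with `statistic` (t), `df` (Welch-Satterthwaite) and
#'   `p.value` (two-sided), plus the two sample means.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("each sample needs at least two observations")
  }
  va <- var(sample_a); vb <- var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(tibble(statistic = 0, df = NA_real_, p.value = 1,
                    mean_a = mean(sample_a), mean_b = mean(sample_b)))
    }
    abort("zero variance in both samples with unequal means")
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value,
         mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Contrast litter phenotypes between mating classes
#'
#' Welch-tests per-litter phenotype values of one class against a reference
#' class. The default contrast is carrier-by-carrier against carrier-sire
#' litters only (`CxN`); set `pool_reciprocal = TRUE` to pool `CxN` with
#' `NxC`.
#'
#' @param litters Classified litters (see [classify_matings()]) with
#'   phenotype columns.
#' @param phenotypes Character vector of litter columns to test; defaults to
#'   the litter-size and survival phenotypes. Per-litter survival values are
#'   derived as ratios when not already columns.
#' @param class_a,class_b The two classes contrasted (defaults `CxC` vs
#'   `CxN`).
#' @param pool_reciprocal Pool `CxN` and `NxC` as the reference (default
#'   `FALSE`).
#' @return A tibble, one row per phenotype, with the Welch statistic, df,
#'   p-value and class means.
#' @export
contrast_mating_classes <- function(litters,
                                    phenotypes = c("total_born", "live_born",
                                                   "farrowing_survival",
                                                   "lactation_survival"),
                                    class_a = "CxC", class_b = "CxN",
                                    pool_reciprocal = FALSE) {
  litters <- as_tibble(litters)
  if (!"farrowing_survival" %in% names(litters) &&
        "farrowing_survival" %in% phenotypes) {
    litters$farrowing_survival <- 100 * litters$live_born / litters$total_born
  }
  if (!"lactation_survival" %in% names(litters) &&
        "lactation_survival" %in% phenotypes) {
    litters$lactation_survival <- ifelse(litters$live_born > 0,
                                         100 * litters$n_weaned /
                                           litters$live_born, NA_real_)
  }
  cls_b <- if (pool_reciprocal && class_b %in% c("CxN", "NxC")) {
    c("CxN", "NxC")
  } else {
    class_b
  }
  a <- litters[litters$mating_class == class_a, , drop = FALSE]
  b <- litters[litters$mating_class %in% cls_b, , drop = FALSE]
  purrr::map_dfr(phenotypes, function(ph) {
    xa <- a[[ph]]; xb <- b[[ph]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    res <- welch_t_test(xa, xb)
    tibble(phenotype = ph, class_a = class_a,
           class_b = paste(cls_b, collapse = "+"),
           mean_a = res$mean_a, mean_b = res$mean_b,
           statistic = res$statistic, df = res$df, p.value = res$p.value,
           significant = res$p.value < 0.05)
  })
}

#' Timing of piglet deaths, optionally stratified by genotype
#'
#' Tabulates deaths by age window (within 24 h, 24-48 h, after 48 h) plus
#' weaned and stillborn counts. When piglet genotypes are available the
#' table is stratified, which summarises penetrance: a fully penetrant
#' neonatal lethal puts all homozygotes in the first two windows.
#'
#' @param piglets A tibble with `fate` (`stillborn`/`died`/`weaned`) and
#'   `age_hours` for deaths; optional `genotype` column (0/1/2 dosage).
#' @return A tibble of counts per stratum, one row per genotype (or a single
#'   `all` row), with columns `stillborn`, `d24h` (died within 24 h),
#'   `d48h` (died 24-48 h), `later` (died after 48 h), `weaned`.
#' @export
mortality_timing <- function(piglets) {
  piglets <- as_tibble(piglets)
  if (!"genotype" %in% names(piglets)) piglets$genotype <- "all"
  piglets |>
    dplyr::group_by(genotype = .data$genotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      stillborn = sum(.data$fate == "stillborn"),
      d24h = sum(.data$fate == "died" & .data$age_hours <= 24),
      d48h = sum(.data$fate == "died" & .data$age_hours > 24 &
                   .data$age_hours <= 48),
      later = sum(.data$fate == "died" & .data$age_hours > 48),
      weaned = sum(.data$fate == "weaned"),
      .groups = "drop"
    )
}
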