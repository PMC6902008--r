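#' Haplotype frequencies within a marker window
#'
#' Counts the `2N` window haplotypes of a phased panel and returns their
#' frequencies (which sum to one by construction).
#'
#' @param panel A phased [phased_panel()].
#' @param first,last Global marker column indices (inclusive) delimiting the
#'   window; both must fall on the same chromosome.
#' @return A tibble with columns `haplotype` (allele string over the window
#'   markers), `count` and `freq`, sorted by decreasing count.
#' @export
window_haplotype_frequencies <- function(panel, first, last) {
  check_window(panel, first, last)
  key <- window_keys(panel, first, last)
  tab <- sort(table(key), decreasing = TRUE)
  tibble(haplotype = names(tab), count = as.integer(tab),
         freq = as.integer(tab) / length(key))
}

check_window <- function(panel, first, last) {
  stopifnot(inherits(panel, "phased_panel"))
  if (!panel$phased) abort("panel must be phased for haplotype analysis")
  m <- nrow(panel$markers)
  if (first < 1 || last > m || first > last) abort("window out of marker bounds")
  ch <- unique(panel$markers$chrom[first:last])
  if (length(ch) != 1) {
    abort("window spans a chromosome boundary")
  }
  invisible(ch)
}

window_keys <- function(panel, first, last) {
  h <- panel$haplotypes[, first:last, drop = FALSE]
  do.call(paste0, lapply(seq_len(ncol(h)), function(j) h[, j]))
}

#' Lower-tail exact binomial test for a deficit of homozygotes
#'
#' Under random mating a haplotype at frequency `f` yields
#' `X ~ Binomial(N, f^2)` homozygous animals among `N` scored diplotypes.
#' The test returns `P(X <= observed_hom)`, accumulated on the log scale so
#' probabilities near 1e-30 — the regime where a truly lethal haplotype
#' lives — are computed accurately.
#'
#' @param n_diplotypes Number of animals scored, `N`.
#' @param hap_freq Haplotype frequency `f` in `[0, 1]`.
#' @param observed_hom Observed homozygote count (at most `N`).
#' @return `P(X <= observed_hom)`.
#' @examples
#' depletion_test(100, 0.2, 0)    # 0.96^100
#' @export
depletion_test <- function(n_diplotypes, hap_freq, observed_hom) {
  if (hap_freq < 0 || hap_freq > 1) abort("hap_freq must lie in [0, 1]")
  if (observed_hom < 0 || observed_hom > n_diplotypes) {
    abort("observed_hom must lie in [0, n_diplotypes]")
  }
  if (observed_hom >= n_diplotypes) return(1)
  lp <- dbinom(0:observed_hom, n_diplotypes, hap_freq^2, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

log10_depletion_test <- function(n_diplotypes, hap_freq, observed_hom) {
  if (observed_hom >= n_diplotypes) return(0)
  lp <- dbinom(0:observed_hom, n_diplotypes, hap_freq^2, log = TRUE)
  mx <- max(lp)
  (mx + log(sum(exp(lp - mx)))) / log(10)
}

#' Genome-wide deficit-of-homozygotes scan
#'
#' Slides windows of `window_markers` consecutive markers along each
#' chromosome of a phased panel. In every window, every haplotype whose
#' Hardy-Weinberg expected homozygote count `N * f^2` reaches
#' `min_expected_hom` is tested for a deficit of homozygotes with
#' [depletion_test()]. Overlapping significant windows whose focal haplotypes
#' agree on the shared markers are merged into regions, reported by their
#' outermost marker positions.
#'
#' @param panel A phased [phased_panel()] that has passed QC.
#' @param window_markers Markers per window (default 20).
#' @param step Step between window starts in markers (default 1).
#' @param min_expected_hom Minimum expected homozygotes for a haplotype to be
#'   tested (default 10); guards against powerless tests on rare haplotypes.
#' @param p_threshold Significance threshold on the raw p-value
#'   (default 5e-3). A Bonferroni-adjusted p over the number of tested
#'   haplotypes is reported alongside for transparency but plays no part in
#'   the significance call.
#' @return A tibble of class `lethal_scan`, one row per tested haplotype,
#'   sorted by p-value, with columns `chrom`, `first`, `last` (global marker
#'   indices), `start_pos`, `end_pos`, `n_markers`, `haplotype`,
#'   `n_diplotypes`, `hap_freq`, `expected_hom`, `observed_hom`, `p_value`,
#'   `p_bonferroni`, `significant`. Merged significant regions are available
#'   via [scan_regions()].
#' @export
scan_genome <- function(panel, window_markers = 20, step = 1,
                        min_expected_hom = 10, p_threshold = 5e-3) {
  stopifnot(inherits(panel, "phased_panel"))
  if (!panel$phased) abort("panel must be phased")
  mk <- panel$markers
  n_animal <- length(panel$animals)
  chroms <- unique(mk$chrom)
  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    cols <- which(mk$chrom == chroms[ci])
    if (length(cols) < window_markers) {
      warn(sprintf("chromosome %s has %d markers (< window of %d); skipped",
                   chroms[ci], length(cols), window_markers))
      next
    }
    # one string per haplotype row covering the whole chromosome; windows
    # are substrings, so the per-window cost is a vectorised substr + match
    chr_str <- do.call(paste0,
                       lapply(cols, function(j) panel$haplotypes[, j]))
    starts <- seq(1L, length(cols) - window_markers + 1L, by = step)
    out <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]
      key <- substr(chr_str, s, s + window_markers - 1L)
      uk <- unique(key)
      cnt <- tabulate(match(key, uk), nbins = length(uk))
      freq <- cnt / (2 * n_animal)
      exp_hom <- n_animal * freq^2
      test <- which(exp_hom >= min_expected_hom)
      if (length(test) == 0) next
      obs <- vapply(uk[test], function(hh) {
        idx <- which(key == hh)
        sum(idx[c(diff(idx) == 1L, FALSE)] %% 2L == 1L)
      }, 0L)
      pv <- vapply(seq_along(test), function(t) {
        depletion_test(n_animal, freq[test[t]], obs[t])
      }, 0.0)
      out[[k]] <- tibble(
        chrom = chroms[ci],
        first = cols[s], last = cols[s + window_markers - 1L],
        start_pos = mk$pos[cols[s]], end_pos = mk$pos[cols[s + window_markers - 1L]],
        n_markers = window_markers,
        haplotype = uk[test],
        n_diplotypes = n_animal,
        hap_freq = freq[test],
        expected_hom = exp_hom[test],
        observed_hom = as.integer(obs),
        p_value = pv
      )
    }
    res[[ci]] <- dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    warn("no haplotype reached the minimum expected homozygote count")
    res$p_bonferroni <- numeric(0)
    res$significant <- logical(0)
  } else {
    res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
    res$significant <- res$p_value < p_threshold
    res <- dplyr::arrange(res, .data$p_value, .data$chrom, .data$first,
                          .data$haplotype)
  }
  regions <- merge_scan_regions(res)
  structure(res, class = c("lethal_scan", class(res)),
            regions = regions, p_threshold = p_threshold)
}

#' Merged significant regions of a scan
#'
#' Significant windows overlapping by at least one marker, with focal
#' haplotypes identical on the shared markers, are merged; each region is
#' reported by the outermost marker positions of its member windows and the
#' smallest member p-value.
#'
#' @param scan A `lethal_scan` tibble from [scan_genome()] (or any tibble
#'   with its columns, in which case rows flagged `significant` are merged).
#' @return A tibble with columns `chrom`, `first`, `last`, `start_pos`,
#'   `end_pos`, `n_markers`, `n_windows`, `min_p`, `top_haplotype`.
#' @export
scan_regions <- function(scan) {
  attr(scan, "regions") %||% merge_scan_regions(scan)
}

merge_scan_regions <- function(res) {
  empty <- tibble(chrom = character(), first = integer(), last = integer(),
                  start_pos = integer(), end_pos = integer(),
                  n_markers = integer(), n_windows = integer(),
                  min_p = numeric(), top_haplotype = character())
  sig <- res[res$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sig <- dplyr::arrange(as_tibble(sig), .data$chrom, .data$first, .data$last)
  groups <- integer(nrow(sig))
  g <- 0L
  reg_last <- -Inf; reg_chrom <- ""
  reg_rows <- integer(0)
  compatible <- function(i, rows) {
    # haplotypes must agree on markers shared with at least one member window
    any(vapply(rows, function(r) {
      lo <- max(sig$first[i], sig$first[r])
      hi <- min(sig$last[i], sig$last[r])
      if (lo > hi) return(FALSE)
      substr(sig$haplotype[i], lo - sig$first[i] + 1L, hi - sig$first[i] + 1L) ==
        substr(sig$haplotype[r], lo - sig$first[r] + 1L, hi - sig$first[r] + 1L)
    }, TRUE))
  }
  for (i in seq_len(nrow(sig))) {
    if (sig$chrom[i] == reg_chrom && sig$first[i] <= reg_last &&
        compatible(i, reg_rows)) {
      groups[i] <- g
      reg_rows <- c(reg_rows, i)
      reg_last <- max(reg_last, sig$last[i])
    } else {
      g <- g + 1L
      groups[i] <- g
      reg_rows <- i
      reg_chrom <- sig$chrom[i]
      reg_last <- sig$last[i]
    }
  }
  sig$.group <- groups
  sig |>
    dplyr::group_by(.data$.group) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      first = min(.data$first), last = max(.data$last),
      start_pos = min(.data$start_pos), end_pos = max(.data$end_pos),
      n_markers = max(.data$last) - min(.data$first) + 1L,
      n_windows = dplyr::n(),
      min_p = min(.data$p_value),
      top_haplotype = .data$haplotype[which.min(.data$p_value)],
      .groups = "drop"
    ) |>
    dplyr::select(-".group") |>
    dplyr::arrange(.data$min_p)
}

#' Carrier status for a focal window haplotype
#'
#' Scores every animal's dosage (0/1/2) of the focal haplotype over a scan
#' window.
#'
#' @param panel A phased [phased_panel()].
#' @param window A one-row data frame (e.g. a row of a [scan_genome()]
#'   result) with columns `first`, `last` and `haplotype`, or a list with
#'   those elements.
#' @return A tibble with columns `animal_id` and `dosage`; the attribute
#'   `carrier_fraction` holds the share of animals with dosage >= 1.
#' @export
assign_carrier_status <- function(panel, window) {
  first <- window$first[1]; last <- window$last[1]
  focal <- window$haplotype[1]
  check_window(panel, first, last)
  key <- window_keys(panel, first, last)
  hit <- key == focal
  n <- length(panel$animals)
  odd <- seq(1L, 2L * n, by = 2L)
  dosage <- as.integer(hit[odd]) + as.integer(hit[odd + 1L])
  out <- tibble(animal_id = panel$animals, dosage = dosage)
  attr(out, "carrier_fraction") <- mean(dosage >= 1L)
  out
}

#' Random-mating expectation of carrier-by-carrier litters
#'
#' With a carrier fraction `c` among breeding animals and random mating, a
#' fraction `c^2` of litters has two carrier parents.
#'
#' @param carrier_freq Carrier fraction in `[0, 1]`.
#' @return `carrier_freq^2`.
#' @examples
#' expected_cxc_litter_fraction(0.09)  # 0.0081
#' @export
expected_cxc_litter_fraction <- function(carrier_freq) {
  if (any(carrier_freq < 0 | carrier_freq > 1)) {
    abort("carrier_freq must lie in [0, 1]")
  }
  carrier_freq^2
}

#' Manhattan-style plot of a deficit-of-homozygotes scan
#'
#' @param object A `lethal_scan` from [scan_genome()].
#' @param ... Unused.
#' @return A ggplot: -log10 p of the best haplotype per window midpoint,
#'   faceted by chromosome, with the significance threshold drawn.
#' @export
autoplot.lethal_scan <- function(object, ...) {
  thr <- attr(object, "p_threshold") %||% 5e-3
  df <- as_tibble(object) |>
    dplyr::group_by(.data$chrom, .data$first) |>
    dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(mid = (.data$start_pos + .data$end_pos) / 2e6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = -log10(.data$p_value))) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(P))),
                  title = "Deficit-of-homozygotes scan") +
    ggplot2::theme_minimal()
}

#' Export merged scan regions as BED
#'
#' Converts the 1-based inclusive marker positions of merged regions to
#' 0-based half-open BED intervals.
#'
#' @param scan A `lethal_scan` from [scan_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_bed <- function(scan, path) {
  reg <- scan_regions(scan)
  lines <- sprintf("%s\t%d\t%d\tregion_%d\t%g", reg$chrom,
                   reg$start_pos - 1L, reg$end_pos, seq_len(nrow(reg)),
                   -log10(reg$min_p))
  writeLines(lines, path)
  invisible(path)
}
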