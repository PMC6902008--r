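test_that("window haplotype frequencies count correctly and sum to one", {
  p <- panel_from(list(c("00", "00"), c("00", "00")))
  f <- window_haplotype_frequencies(p, 1, 2)
  expect_equal(f$haplotype, "00")
  expect_equal(f$count, 4L)
  expect_equal(f$freq, 1)

  p2 <- panel_from(list(c("01", "01"), c("01", "10")))
  f2 <- window_haplotype_frequencies(p2, 1, 2)
  expect_equal(setNames(f2$count, f2$haplotype), c("01" = 3L, "10" = 1L))
  expect_equal(sum(f2$freq), 1)

  set.seed(1)
  for (i in 1:5) {
    pairs <- replicate(7, c(paste(rbinom(6, 1, 0.5), collapse = ""),
                            paste(rbinom(6, 1, 0.5), collapse = "")),
                       simplify = FALSE)
    fr <- window_haplotype_frequencies(panel_from(pairs), 2, 5)
    expect_equal(sum(fr$freq), 1)
    expect_equal(sum(fr$count), 14L)
  }
})

test_that("windows may not span chromosomes or exceed bounds", {
  mk <- tibble::tibble(marker_id = paste0("m", 1:4),
                       chrom = c("1", "1", "2", "2"),
                       pos = c(1L, 2L, 1L, 2L))
  hap <- matrix(0L, nrow = 4, ncol = 4)
  p <- phased_panel(mk, c("a1", "a2"), hap)
  expect_error(window_haplotype_frequencies(p, 2, 3), "chromosome")
  expect_error(window_haplotype_frequencies(p, 3, 5), "bounds")
})

test_that("depletion test matches closed form and plain summation", {
  expect_equal(depletion_test(100, 0.2, 0), 0.96^100, tolerance = 1e-12)
  expect_equal(depletion_test(10, 0.37, 10), 1)
  # closed form at zero observed
  for (f in c(0.01, 0.045, 0.2, 0.6)) {
    expect_equal(depletion_test(5000, f, 0), (1 - f^2)^5000,
                 tolerance = 1e-10)
  }
  # plain-summation oracle over a grid up to n = 1000
  set.seed(2)
  for (n in c(10, 100, 1000)) {
    for (f in c(0.05, 0.3, 0.8)) {
      for (k in unique(c(0L, 1L, as.integer(n * f^2), n - 1L))) {
        expect_equal(depletion_test(n, f, k), binom_lower_oracle(n, f, k),
                     tolerance = 1e-9, info = sprintf("n=%d f=%g k=%d", n, f, k))
      }
    }
  }
})

test_that("depletion p at zero observed decreases strictly in frequency", {
  # keep (1 - f^2)^N above the double-precision floor
  f <- seq(0.02, 0.38, by = 0.02)
  p <- vapply(f, function(ff) depletion_test(2000, ff, 0), 0.0)
  expect_true(all(diff(p) < 0))
})

test_that("depletion test stays accurate at lethal-haplotype magnitudes", {
  # expected homozygotes ~60 in ~30k animals: p ~ 1e-27 territory
  p <- depletion_test(31800, sqrt(61.07 / 31800), 0)
  expect_equal(p, (1 - 61.07 / 31800)^31800, tolerance = 1e-10)
  expect_true(p > 1e-28 && p < 1e-26)
})

test_that("scan localizes an embedded lethal and merges regions", {
  ds <- sim_small()
  sc <- scan_genome(ds$panel, window_markers = 15, min_expected_hom = 2)
  top <- tibble::as_tibble(sc)[1, ]
  lc <- attr(ds$truth, "lethal_chrom")
  lp <- attr(ds$truth, "lethal_pos_bp")
  expect_equal(top$chrom, lc)
  expect_true(top$start_pos <= lp && top$end_pos >= lp)
  expect_true(top$p_value < 5e-3)
  expect_equal(top$observed_hom, 0L)
  reg <- scan_regions(sc)
  expect_gt(nrow(reg), 0)
  expect_equal(reg$chrom[1], lc)
  expect_true(reg$start_pos[1] <= lp && reg$end_pos[1] >= lp)
  # results sorted by p
  expect_true(!is.unsorted(tibble::as_tibble(sc)$p_value))
})

test_that("null panels flag haplotypes at no more than the nominal rate", {
  # independent diplotypes in Hardy-Weinberg proportions (founders only):
  # the binomial null of the test; family structure is examined separately
  ds0 <- cached("sim_founders_null", simulate_population(simulation_config(
    n_founders = 3000, n_generations = 0, markers_per_chromosome = 150,
    n_chromosomes = 2, lethal_allele_freq = 0, seed = 19)))
  sc <- scan_genome(ds0$panel, window_markers = 10, min_expected_hom = 5)
  n_tests <- nrow(sc)
  expect_gt(n_tests, 200)
  n_sig <- sum(sc$significant)
  # discrete lower-tail test is conservative; allow binomial noise at 0.005
  expect_lte(n_sig, stats::qbinom(0.999, n_tests, 0.005))
})

test_that("carrier status counts focal-haplotype dosage per animal", {
  p <- panel_from(list(c("01", "01"), c("01", "10"), c("10", "10")))
  w <- list(first = 1, last = 2, haplotype = "01")
  cs <- assign_carrier_status(p, w)
  expect_equal(cs$dosage, c(2L, 1L, 0L))
  expect_equal(attr(cs, "carrier_fraction"), 2 / 3)
  none <- assign_carrier_status(p, list(first = 1, last = 2, haplotype = "11"))
  expect_equal(none$dosage, c(0L, 0L, 0L))
  expect_equal(attr(none, "carrier_fraction"), 0)
})

test_that("carrier fraction on simulated data follows Hardy-Weinberg", {
  ds <- sim_small()
  sc <- scan_genome(ds$panel, window_markers = 15, min_expected_hom = 2)
  top <- tibble::as_tibble(sc)[1, ]
  cs <- assign_carrier_status(ds$panel, top)
  f <- top$hap_freq
  expected <- 2 * f * (1 - f)
  n <- length(ds$panel$animals)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(attr(cs, "carrier_fraction") - expected), 4 * se + 1 / n)
})

test_that("the top hit recovers the configured lethal frequency", {
  # founders only: no purging of the lethal across generations and no
  # recombination erosion of the tag haplotype, so the estimated frequency
  # is a plain binomial draw around the configured value
  ds <- cached("sim_founders_lethal", simulate_population(simulation_config(
    n_founders = 3000, n_generations = 0, markers_per_chromosome = 150,
    n_chromosomes = 1, seed = 23)))
  sc <- scan_genome(ds$panel, window_markers = 19, min_expected_hom = 2)
  top <- tibble::as_tibble(sc)[1, ]
  expect_equal(top$observed_hom, 0L)
  f0 <- 0.045
  se <- sqrt(f0 * (1 - f0) / (2 * 3000))
  expect_lt(abs(top$hap_freq - f0), 1.96 * se)
  # and the focal haplotype is the carrier tag
  expect_equal(top$haplotype, attr(ds$truth, "tag_template"))
})

test_that("random-mating CxC litter expectation is the carrier fraction squared", {
  expect_equal(expected_cxc_litter_fraction(0.09), 0.0081)
  expect_equal(expected_cxc_litter_fraction(0), 0)
  expect_equal(expected_cxc_litter_fraction(1), 1)
  expect_error(expected_cxc_litter_fraction(1.2), "\\[0, 1\\]")
})

test_that("scan plots and BED export work", {
  ds <- sim_small()
  sc <- scan_genome(ds$panel, window_markers = 15, min_expected_hom = 2)
  gg <- ggplot2::autoplot(sc)
  expect_s3_class(gg, "ggplot")
  bed <- tempfile(fileext = ".bed")
  write_scan_bed(sc, bed)
  lines <- readLines(bed)
  expect_gt(length(lines), 0)
  flds <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(flds[3]) - as.integer(flds[2]),
               scan_regions(sc)$end_pos[1] - (scan_regions(sc)$start_pos[1] - 1L))
})
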