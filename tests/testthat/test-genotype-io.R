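test_that("VCF panels read with phasing, skipping multi-allelic records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\tm2\tC\tA,T\t.\tPASS\t.\tGT\t0/1\t0/0",
    "1\t300\tm3\tT\tC\t.\tPASS\t.\tGT\t1|0\t0|0"
  ), vcf)
  p <- read_panel(vcf, format = "vcf")
  expect_equal(dim(p), c(2L, 2L))
  expect_true(p$phased)
  expect_equal(attr(p, "skipped_records"), 1L)
  expect_equal(p$haplotypes[1, ], c(0L, 1L))  # s1 hap A: 0|1, 1|0
  expect_equal(p$haplotypes[2, ], c(1L, 0L))
  expect_equal(p$haplotypes[3, ], c(1L, 0L))  # s2
  expect_equal(p$markers$marker_id, c("m1", "m3"))
})

test_that("mixed-ploidy VCF records are rejected", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0|1|1"
  ), vcf)
  expect_error(read_panel(vcf, format = "vcf"), "ploidy")
})

test_that("ped/map panels read as unphased with letter alleles", {
  base <- tempfile()
  writeLines(c("1 m1 0 100", "1 m2 0 200"), paste0(base, ".map"))
  writeLines(c("F a1 0 0 0 -9 A A C C",
               "F a2 0 0 0 -9 A G 0 0"), paste0(base, ".ped"))
  p <- read_panel(base, format = "ped_map")
  expect_false(p$phased)
  expect_equal(p$haplotypes[1:2, 1], c(0L, 0L))  # a1 "A A", first-seen A = 0
  expect_equal(p$haplotypes[3:4, 1], c(0L, 1L))  # a2 "A G"
  expect_true(all(is.na(p$haplotypes[3:4, 2])))  # "0 0" missing
})

test_that("panels round-trip through both formats", {
  set.seed(42)
  pairs <- replicate(6, c(paste(rbinom(8, 1, 0.4), collapse = ""),
                          paste(rbinom(8, 1, 0.4), collapse = "")),
                     simplify = FALSE)
  p <- panel_from(pairs)
  vcf <- tempfile(fileext = ".vcf")
  write_panel(p, vcf, format = "vcf")
  p2 <- read_panel(vcf, format = "vcf")
  expect_equal(unname(p2$haplotypes), unname(p$haplotypes))
  expect_equal(p2$animals, p$animals)
  expect_equal(p2$markers$pos, p$markers$pos)

  base <- tempfile()
  write_panel(p, base, format = "ped_map")
  p3 <- read_panel(base, format = "ped_map", allele_key = "AB")
  expect_equal(unname(p3$haplotypes), unname(p$haplotypes))
  # a second round trip is byte-identical
  base2 <- tempfile()
  write_panel(p3, base2, format = "ped_map")
  expect_identical(readLines(paste0(base, ".ped")),
                   readLines(paste0(base2, ".ped")))
})

test_that("HWE exact test reproduces enumerated values", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 0, 2), 10 / 210)
  expect_equal(hwe_exact_test(2, 2, 1), 1)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("HWE exact test matches the brute-force oracle for all small counts", {
  for (n in c(2, 5, 9, 14, 20)) {
    grid <- compositions_for_test(n)
    for (r in seq_len(nrow(grid))) {
      cnt <- grid[r, ]
      expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                   hwe_oracle(cnt[1], cnt[2], cnt[3]),
                   tolerance = 1e-10,
                   info = paste(cnt, collapse = ","))
    }
  }
})

test_that("QC leaves a clean panel untouched and reports zero removals", {
  p <- panel_from(list(c("01", "10"), c("10", "01"), c("01", "10"),
                       c("10", "01")))
  res <- apply_qc(p)
  expect_equal(dim(res$panel), dim(p))
  expect_equal(res$report$n_markers_kept, 2L)
  expect_equal(sum(unlist(res$report[1, 1:5])), 0)
  # idempotent
  res2 <- apply_qc(res$panel)
  expect_identical(res2$panel$haplotypes, res$panel$haplotypes)
})

test_that("QC removes markers in order: position, call rate, MAF, HWE", {
  # 5 animals, unphased so missing is representable
  mk <- tibble::tibble(marker_id = paste0("m", 1:5), chrom = "1",
                       pos = c(NA, 200L, 300L, 400L, 500L))
  hap <- rbind(
    # m1 (pos NA), m2 (1 of 5 animals missing -> call rate 0.8),
    # m3 MAF 0 (monomorphic), m4 counts (3,0,2), m5 healthy
    c(0L, NA, 0L, 0L, 0L), c(0L, NA, 0L, 0L, 1L),
    c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 1L),
    c(0L, 0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L, 0L),
    c(0L, 1L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L, 1L),
    c(0L, 1L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L, 1L)
  )
  p <- phased_panel(mk, paste0("a", 1:5), hap, phased = FALSE)
  res <- apply_qc(p, max_sample_missing = 0.5, min_call_rate = 0.85,
                  min_maf = 0.01, hwe_min_p = 0.05)
  expect_equal(res$report$n_markers_removed_position, 1L)
  expect_equal(res$report$n_markers_removed_callrate, 1L)
  expect_equal(res$report$n_markers_removed_maf, 1L)
  expect_equal(res$report$n_markers_removed_hwe, 1L)  # P = 0.0476 < 0.05
  expect_equal(res$report$n_markers_kept, 0L + nrow(res$panel$markers))
})

test_that("QC MAF boundary removes frequency exactly at the threshold", {
  # 50 animals, one alt allele -> MAF = 0.01 exactly
  hap <- matrix(0L, nrow = 100, ncol = 2)
  hap[1, 1] <- 1L
  # companion marker in Hardy-Weinberg-ish proportions (12 hom, 25 het,
  # 13 hom) so only the rare one falls to the MAF filter
  g2 <- c(rep(c(0L, 0L), 12), rep(c(0L, 1L), 25), rep(c(1L, 1L), 13))
  hap[, 2] <- g2
  mk <- tibble::tibble(marker_id = c("rare", "common"), chrom = "1",
                       pos = c(100L, 200L))
  p <- phased_panel(mk, paste0("a", 1:50), hap)
  res <- apply_qc(p, min_maf = 0.01)
  expect_equal(res$report$n_markers_removed_maf, 1L)
  expect_equal(res$panel$markers$marker_id, "common")
})

test_that("QC errors when nothing survives", {
  p <- panel_from(list(c("00", "00"), c("00", "00")))
  expect_error(apply_qc(p), "every marker")
})
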