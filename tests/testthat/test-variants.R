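long_geno <- function(mat, animals) {
  # mat: variants x animals
  g <- tidyr::expand_grid(variant_id = rownames(mat), animal_id = animals)
  g$dosage <- as.integer(as.vector(t(mat)))
  g
}

test_that("haplotype LD reproduces the dosage correlation", {
  animals <- paste0("a", 1:6)
  carriers <- tibble::tibble(animal_id = animals,
                             dosage = c(0L, 1L, 0L, 1L, 2L, 2L))
  mat <- rbind(ident = c(0L, 1L, 0L, 1L, 2L, 2L),
               mixed = c(0L, 0L, 1L, 1L, 2L, 2L),
               flat = c(1L, 1L, 1L, 1L, 1L, 1L))
  ld <- haplotype_ld(long_geno(mat, animals), carriers)
  ld <- ld[order(ld$variant_id), ]
  expect_equal(ld$r_squared[ld$variant_id == "ident"], 1)
  expect_equal(ld$r_squared[ld$variant_id == "mixed"], 0.5625)
  expect_true(is.na(ld$r_squared[ld$variant_id == "flat"]))
  expect_true(ld$zero_variance[ld$variant_id == "flat"])
})

test_that("haplotype LD equals a brute-force correlation on random inputs", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    animals <- paste0("a", seq_len(n))
    x <- sample(0:2, n, replace = TRUE)
    y <- sample(0:2, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    carriers <- tibble::tibble(animal_id = animals, dosage = y)
    mat <- matrix(x, nrow = 1, dimnames = list("v", NULL))
    ld <- haplotype_ld(long_geno(mat, animals), carriers)
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ld$r_squared, (num / den)^2, tolerance = 1e-12)
  }
})

test_that("missing dosages are dropped and small n excluded", {
  animals <- paste0("a", 1:4)
  carriers <- tibble::tibble(animal_id = animals, dosage = c(0L, 1L, 2L, 0L))
  g <- tibble::tibble(variant_id = "v", animal_id = animals,
                      dosage = c(0L, 1L, NA, NA))
  expect_warning(ld <- haplotype_ld(g, carriers), "fewer than 3")
  expect_equal(nrow(ld), 0)
})

test_that("prioritization ranks high-impact perfect-LD variants first", {
  animals <- paste0("a", 1:8)
  hap <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L)
  carriers <- tibble::tibble(animal_id = animals, dosage = hap)
  mat <- rbind(
    causal = hap,                                  # r2 = 1, frameshift
    mis_bad = c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 1L),   # high LD missense, low score
    mis_tol = c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L),   # high LD missense, tolerated
    noncoding = c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L), # high LD, no annotation
    faraway = c(2L, 1L, 0L, 0L, 1L, 0L, 0L, 2L)    # low LD
  )
  ann <- tibble::tibble(
    variant_id = c("causal", "mis_bad", "mis_tol"),
    consequence = c("frameshift", "missense", "missense"),
    score = c(NA, 0.01, 0.18))
  ranked <- prioritize_variants(long_geno(mat, animals), carriers, ann)
  expect_equal(ranked$variant_id[1], "causal")
  expect_true(ranked$perfect_ld[1])
  expect_lt(which(ranked$variant_id == "mis_bad"),
            which(ranked$variant_id == "mis_tol"))
  expect_true(ranked$tolerated[ranked$variant_id == "mis_tol"])
  # subset of the input: nothing invented, nothing duplicated, low LD gone
  expect_false("faraway" %in% ranked$variant_id)
  expect_true(all(ranked$variant_id %in% rownames(mat)))
  expect_equal(anyDuplicated(ranked$variant_id), 0L)
  expect_true(all(ranked$r_squared > 0.8))
})

test_that("an empty prioritization is reported, not fabricated", {
  animals <- paste0("a", 1:6)
  carriers <- tibble::tibble(animal_id = animals,
                             dosage = c(0L, 0L, 1L, 1L, 2L, 2L))
  mat <- matrix(c(2L, 0L, 1L, 0L, 0L, 1L), nrow = 1,
                dimnames = list("v", NULL))
  expect_message(ranked <- prioritize_variants(long_geno(mat, animals),
                                               carriers),
                 "no variant")
  expect_equal(nrow(ranked), 0)
})

test_that("HGVS deletion identifiers parse and validate", {
  p <- parse_hgvs_del("6:g.48801280delGACGGTGTACGCCGGT")
  expect_equal(p$chrom, "6")
  expect_equal(p$start, 48801280L)
  expect_equal(p$end, 48801280L + 15L)
  expect_equal(nchar(p$deleted), 16L)
  expect_error(parse_hgvs_del("6:48801280del"), "cannot parse")
})

test_that("CDS models are validated", {
  expect_error(cds_model("t", "ATGCATTA"), "multiple of 3")
  expect_error(cds_model("t", "CATCATTAG"), "start with ATG")
  expect_error(cds_model("t", "ATGCATCAT"), "stop codon")
  m <- cds_model("t", "ATGCATCATCATTAG")
  expect_s3_class(m, "cds_model")
  expect_error(cds_model("t", "ATGCATCATCATTAG",
                         exons = data.frame(start = 1, end = 10)),
               "sum to the CDS length")
})

test_that("the toy frameshift translates exactly", {
  toy <- cds_model("toy", cds = "ATGCATCATCATTAG", trailing = "GTAAA")
  res <- apply_deletion_and_translate(toy, 4, 4, coords = "cds")
  expect_equal(res$kind, "frameshift")
  expect_equal(res$shared_prefix_aa, 1L)
  expect_equal(res$novel_aa, 4L)
  expect_equal(res$mutant_length_aa, 5L)
  expect_equal(res$lost_wt_aa, 3L)
  expect_equal(res$wt_length_aa, 4L)
})

test_that("codon-aligned deletions are in-frame with no novel residues", {
  toy <- cds_model("toy", cds = "ATGCATCATCATTAG", trailing = "GTAAA")
  res <- apply_deletion_and_translate(toy, 4, 6, coords = "cds")
  expect_equal(res$kind, "inframe_deletion")
  expect_equal(res$novel_aa, 0L)
  expect_equal(res$mutant_length_aa, 3L)
})

test_that("frameshifts of k and k+3 bases share the novel tail", {
  # body free of T so no stop can arise inside the CDS in any frame; the
  # trailing sequence supplies the first in-frame stop for the shifted read
  cds <- paste0("ATG", "GCAGCCAAGGGACAGACC", "TAA")
  m <- cds_model("crafted", cds, trailing = paste0("G", strrep("TAA", 10)))
  r1 <- apply_deletion_and_translate(m, 10, 10, coords = "cds")      # k = 1
  r2 <- apply_deletion_and_translate(m, 10, 13, coords = "cds")      # k = 4
  expect_equal(r1$kind, "frameshift")
  expect_equal(r2$kind, "frameshift")
  # both shifts (1 and 4 = 1 mod 3) read the same frame; the k = 1 mutant
  # keeps one extra junction codon before the common novel tail
  expect_equal(r1$shared_prefix_aa, 3L)
  expect_equal(r2$shared_prefix_aa, 3L)
  expect_equal(r1$novel_aa, r2$novel_aa + 1L)
  # a codon-aligned deletion at the same spot is in-frame instead
  r0 <- apply_deletion_and_translate(m, 10, 12, coords = "cds")
  expect_equal(r0$kind, "inframe_deletion")
})

test_that("genomic coordinates map through exons on both strands", {
  # CDS of 18 nt split over two exons
  cds <- "ATGAAACCCGGGTTTTAG"
  plus <- cds_model("p", cds,
                    exons = data.frame(start = c(101, 121),
                                       end = c(110, 128)), strand = "+")
  # genomic 105 is CDS position 5
  res_g <- apply_deletion_and_translate(plus, 105, 105,
                                        deleted = substr(cds, 5, 5))
  res_c <- apply_deletion_and_translate(plus, 5, 5, coords = "cds")
  expect_equal(res_g$novel_aa, res_c$novel_aa)
  expect_equal(res_g$shared_prefix_aa, res_c$shared_prefix_aa)

  minus <- cds_model("m", cds,
                     exons = data.frame(start = c(201, 181),
                                        end = c(210, 188)), strand = "-")
  # genomic 206 on the minus strand is CDS position 210 - 206 + 1 = 5
  res_m <- apply_deletion_and_translate(minus, 206, 206,
                                        deleted = revcomp_for_test(substr(cds, 5, 5)))
  expect_equal(res_m$shared_prefix_aa, res_c$shared_prefix_aa)

  expect_error(apply_deletion_and_translate(plus, 50, 52), "non-coding")
  expect_error(apply_deletion_and_translate(plus, 108, 123), "splice")
  # mismatched deleted sequence is caught
  expect_error(apply_deletion_and_translate(plus, 105, 105, deleted = "G"),
               "mismatch")
})
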