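#' Phased genotype panels
#'
#' A `phased_panel` bundles a marker map with a per-animal haplotype matrix.
#' Haplotypes are coded over `{0, 1, NA}`: 0 is the reference (or first-seen)
#' allele, 1 the alternate, `NA` a missing call. Each animal owns two
#' consecutive rows of the matrix, so the matrix has `2 * length(animals)`
#' rows and one column per marker. A panel flagged `phased = TRUE` must be
#' complete: phasing pipelines impute missing sites, so downstream haplotype
#' counting assumes no `NA`.
#'
#' @param markers A data frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp; `NA` allowed for markers with unknown placement). Optional
#'   `ref`/`alt` columns carry allele labels for VCF round-trips.
#' @param animals Character vector of animal identifiers.
#' @param haplotypes Integer matrix of 0/1/`NA`, `2 * length(animals)` rows.
#' @param phased Logical; `TRUE` when the two rows per animal are true
#'   haplotypes rather than arbitrarily ordered genotype calls.
#'
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(markers, animals, haplotypes, phased = TRUE) {
  markers <- as_tibble(markers)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(markers)))
  if (anyDuplicated(markers$marker_id)) {
    abort("duplicate marker_id in marker map")
  }
  if (anyDuplicated(animals)) abort("duplicate animal ids")
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * length(animals)) {
    abort("haplotype matrix must have exactly two rows per animal")
  }
  if (ncol(haplotypes) != nrow(markers)) {
    abort("haplotype matrix columns must match the marker map")
  }
  known <- !is.na(markers$pos)
  bad <- markers |>
    dplyr::filter(!is.na(.data$pos)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("marker positions not strictly increasing on chromosome ",
                 paste(bad$chrom, collapse = ", ")))
  }
  if (isTRUE(phased) && anyNA(haplotypes)) {
    abort("a phased panel may not contain missing alleles")
  }
  structure(
    list(markers = markers, animals = as.character(animals),
         haplotypes = haplotypes, phased = isTRUE(phased)),
    class = "phased_panel"
  )
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("<phased_panel> %d animals x %d markers (%s)\n",
              length(x$animals), nrow(x$markers),
              if (x$phased) "phased" else "unphased"))
  chroms <- unique(x$markers$chrom)
  cat("  chromosomes:", paste(utils::head(chroms, 8), collapse = ", "),
      if (length(chroms) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.phased_panel <- function(x) c(length(x$animals), nrow(x$markers))

#' Per-animal genotype dosages for one marker
#'
#' Sums the two haplotype rows of each animal; `NA` if either allele is
#' missing.
#'
#' @param panel A [phased_panel()].
#' @param j Marker column index.
#' @return Integer vector of 0/1/2/`NA`, one per animal.
#' @keywords internal
marker_dosage <- function(panel, j) {
  h <- panel$haplotypes[, j]
  odd <- seq(1L, nrow(panel$haplotypes), by = 2L)
  h[odd] + h[odd + 1L]
}

#' Read a genotype panel from VCF or PLINK text files
#'
#' Supports the two interchange formats the pipeline touches: VCF v4.x using
#' the GT field ("|"-separated genotypes are treated as phased, "/" as
#' unphased) and the PLINK text `.ped`/`.map` pair. Only biallelic sites are
#' kept; multi-allelic VCF records are skipped and tallied in the
#' `skipped_records` attribute of the result.
#'
#' @param path For `format = "vcf"`, the VCF file. For `format = "ped_map"`,
#'   either the `.ped` file or the common prefix of the `.ped`/`.map` pair.
#' @param format `"vcf"` or `"ped_map"`.
#' @param allele_key For `.ped` input: how to map allele letters to 0/1.
#'   Either `NULL` (first-seen letter per marker becomes 0) or a character
#'   vector of two-letter strings, one per marker, e.g. `"AB"` meaning
#'   A is 0 and B is 1 at every marker (a single string is recycled).
#' @return A [phased_panel()]; attribute `skipped_records` counts rejected
#'   multi-allelic records.
#' @export
read_panel <- function(path, format = c("vcf", "ped_map"), allele_key = NULL) {
  format <- match.arg(format)
  switch(format,
         vcf = read_panel_vcf(path),
         ped_map = read_panel_ped(path, allele_key))
}

read_panel_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "") | is.na(fix$ALT)
  n_skip <- sum(multi)
  if (all(multi)) abort("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  animals <- colnames(gt)
  gt_chr <- as.vector(gt)  # marker-major columns per sample
  gt_chr[is.na(gt_chr)] <- ".|."
  phased_sep <- grepl("|", gt_chr, fixed = TRUE)
  unphased_sep <- grepl("/", gt_chr, fixed = TRUE)
  parts <- strsplit(gt_chr, "[|/]")
  lens <- lengths(parts)
  if (any(lens != 2L)) {
    abort(sprintf("mixed ploidy: GT '%s' is not diploid",
                  gt_chr[which(lens != 2L)[1]]))
  }
  al <- suppressWarnings(as.integer(unlist(parts)))
  if (any(!is.na(al) & al > 1L)) abort("GT allele index > 1 at biallelic site")
  a1 <- al[c(TRUE, FALSE)]
  a2 <- al[c(FALSE, TRUE)]
  m <- nrow(gt); n <- length(animals)
  # columns of `gt` vectorise marker-fastest
  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  for (i in seq_len(n)) {
    idx <- (i - 1L) * m + seq_len(m)
    hap[2L * i - 1L, ] <- a1[idx]
    hap[2L * i, ] <- a2[idx]
  }
  phased <- all(phased_sep | !unphased_sep) && !anyNA(hap)
  markers <- tibble(
    marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  out <- phased_panel(markers, animals, hap, phased = phased)
  attr(out, "skipped_records") <- n_skip
  out
}

read_panel_ped <- function(path, allele_key = NULL) {
  ped_path <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(ped_path)) abort(paste0("no such file: ", ped_path))
  if (!file.exists(map_path)) abort(paste0("no such file: ", map_path))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) abort(paste0("malformed .map: expected 4 columns in ",
                                  map_path))
  markers <- tibble(
    marker_id = map[[2]],
    chrom = map[[1]],
    pos = suppressWarnings(as.integer(map[[4]]))
  )
  markers$pos[!is.na(markers$pos) & markers$pos <= 0] <- NA_integer_
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(markers)
  want <- 6L + 2L * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    abort(sprintf(".ped parse error at line %d: %d fields, expected %d",
                  which(lens != want)[1], lens[lens != want][1], want))
  }
  n <- length(toks)
  animals <- vapply(toks, `[[`, "", 2L)
  # .ped lists the two alleles of each marker side by side
  raw <- matrix(NA_character_, nrow = 2L * n, ncol = m)
  for (i in seq_len(n)) {
    tt <- toks[[i]][-(1:6)]
    raw[2L * i - 1L, ] <- tt[c(TRUE, FALSE)]
    raw[2L * i, ] <- tt[c(FALSE, TRUE)]
  }
  raw[raw == "0"] <- NA_character_
  if (!is.null(allele_key)) {
    key <- rep_len(allele_key, m)
    ref <- substr(key, 1, 1); alt <- substr(key, 2, 2)
  } else {
    ref <- alt <- character(m)
    for (j in seq_len(m)) {
      seen <- unique(raw[, j])
      seen <- seen[!is.na(seen)]
      if (length(seen) > 2) {
        abort(sprintf("marker %s has %d alleles; .ped input must be biallelic",
                      markers$marker_id[j], length(seen)))
      }
      ref[j] <- if (length(seen) >= 1) seen[1] else "A"
      alt[j] <- if (length(seen) == 2) seen[2] else "B"
    }
  }
  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  for (j in seq_len(m)) {
    hap[, j] <- ifelse(is.na(raw[, j]), NA_integer_,
                       ifelse(raw[, j] == ref[j], 0L,
                              ifelse(raw[, j] == alt[j], 1L, NA_integer_)))
    if (any(!is.na(raw[, j]) & is.na(hap[, j]))) {
      abort(sprintf("marker %s: allele not in key '%s%s'",
                    markers$marker_id[j], ref[j], alt[j]))
    }
  }
  markers$ref <- ref
  markers$alt <- alt
  out <- phased_panel(markers, animals, hap, phased = FALSE)
  attr(out, "skipped_records") <- 0L
  out
}

#' Write a genotype panel
#'
#' Inverse of [read_panel()]. VCF output writes a minimal v4.2 file with a GT
#' field, using the panel's `ref`/`alt` labels when present (defaulting to
#' A/B); `.ped`/`.map` output writes allele letters with `0` for missing.
#'
#' @param panel A [phased_panel()].
#' @param path Output file (VCF) or prefix (ped_map; `.ped` and `.map` are
#'   appended).
#' @param format `"vcf"` or `"ped_map"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("vcf", "ped_map")) {
  format <- match.arg(format)
  mk <- panel$markers
  ref <- mk[["ref"]] %||% rep("A", nrow(mk))
  alt <- mk[["alt"]] %||% rep("B", nrow(mk))
  ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "B"
  if (format == "vcf") {
    sep <- if (panel$phased) "|" else "/"
    n <- length(panel$animals)
    odd <- seq(1L, 2L * n, by = 2L)
    h1 <- panel$haplotypes[odd, , drop = FALSE]
    h2 <- panel$haplotypes[odd + 1L, , drop = FALSE]
    gt1 <- ifelse(is.na(h1), ".", h1)
    gt2 <- ifelse(is.na(h2), ".", h2)
    gt <- matrix(paste0(gt1, sep, gt2), nrow = n)  # animals x markers
    body <- vapply(seq_len(nrow(mk)), function(j) {
      paste(c(mk$chrom[j], mk$pos[j] %|na|% ".", mk$marker_id[j], ref[j],
              alt[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
    }, "")
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", panel$animals), collapse = "\t"))
    writeLines(c(header, body), path)
    return(invisible(path))
  }
  ped_path <- paste0(sub("\\.ped$", "", path), ".ped")
  map_path <- paste0(sub("\\.ped$", "", path), ".map")
  letters_for <- function(h, j) {
    ifelse(is.na(h), "0", ifelse(h == 0L, ref[j], alt[j]))
  }
  n <- length(panel$animals)
  rows <- vapply(seq_len(n), function(i) {
    h1 <- panel$haplotypes[2L * i - 1L, ]
    h2 <- panel$haplotypes[2L * i, ]
    gl <- character(2L * nrow(mk))
    for (j in seq_len(nrow(mk))) {
      gl[2L * j - 1L] <- letters_for(h1[j], j)
      gl[2L * j] <- letters_for(h2[j], j)
    }
    paste(c("FAM", panel$animals[i], "0", "0", "0", "-9", gl), collapse = " ")
  }, "")
  writeLines(rows, ped_path)
  writeLines(paste(mk$chrom, mk$marker_id, "0", mk$pos %|na|% "0"), map_path)
  invisible(path)
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
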