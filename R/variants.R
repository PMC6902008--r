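#' LD between variants and the focal haplotype
#'
#' Squared Pearson correlation between per-animal variant genotype dosage and
#' focal-haplotype dosage, computed over animals with a non-missing call.
#' This reproduces the usual pseudo-marker r-squared of LD tools on the
#' sequenced subset. Variants with no dosage variance among the scored
#' animals get `NA` (undefined, not zero) and `zero_variance = TRUE`.
#'
#' @param genotypes A long tibble with `variant_id`, `animal_id` and `dosage`
#'   (0/1/2 or `NA`).
#' @param carriers A tibble with `animal_id` and haplotype `dosage` (e.g.
#'   from [assign_carrier_status()]).
#' @param min_animals Variants scored in fewer animals are dropped with a
#'   warning (default 3).
#' @return A tibble with `variant_id`, `r_squared`, `n_animals`,
#'   `zero_variance`.
#' @export
haplotype_ld <- function(genotypes, carriers, min_animals = 3) {
  genotypes <- as_tibble(genotypes)
  hap <- setNames(carriers$dosage, carriers$animal_id)
  df <- genotypes |>
    dplyr::mutate(hap_dosage = unname(hap[.data$animal_id])) |>
    dplyr::filter(!is.na(.data$dosage), !is.na(.data$hap_dosage))
  out <- df |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      zero_variance = var(.data$dosage) == 0 || var(.data$hap_dosage) == 0,
      r_squared = if (var(.data$dosage) == 0 || var(.data$hap_dosage) == 0) {
        NA_real_
      } else {
        cor(.data$dosage, .data$hap_dosage)^2
      },
      .groups = "drop"
    )
  too_few <- out$n_animals < min_animals
  if (any(too_few)) {
    warn(sprintf("%d variant(s) scored in fewer than %d animals dropped",
                 sum(too_few), min_animals))
  }
  out[!too_few, , drop = FALSE]
}

#' Rank candidate causal variants by LD and predicted consequence
#'
#' Keeps variants whose r-squared with the focal haplotype exceeds the
#' threshold and ranks them: high-impact consequences first (frameshift,
#' stop gained, splice acceptor/donor), then missense predicted deleterious,
#' then missense predicted tolerated (deleteriousness score above
#' `tolerated_score_above`), then everything else; within a stratum by
#' decreasing r-squared. Variants in complete LD (r-squared within 1e-9
#' of 1) are flagged `perfect_ld`.
#'
#' @param genotypes Long dosage tibble, as for [haplotype_ld()].
#' @param carriers Haplotype carrier tibble.
#' @param annotations Optional tibble with `variant_id`, `consequence`
#'   (e.g. `frameshift`, `stop_gained`, `splice_acceptor`, `splice_donor`,
#'   `missense`, `synonymous`, `other`) and `score` (deleteriousness in
#'   `[0, 1]`, smaller = more deleterious).
#' @param r2_threshold Keep variants with `r_squared > r2_threshold`
#'   (default 0.8).
#' @param tolerated_score_above Missense variants scoring above this are
#'   flagged tolerated (default 0.05).
#' @return A tibble ranked by priority with columns `rank`, `variant_id`,
#'   `r_squared`, `n_animals`, `perfect_ld`, `consequence`, `score`,
#'   `impact_class`, `tolerated`. Empty (with a message) when nothing passes
#'   the threshold.
#' @export
prioritize_variants <- function(genotypes, carriers, annotations = NULL,
                                r2_threshold = 0.8,
                                tolerated_score_above = 0.05) {
  ld <- haplotype_ld(genotypes, carriers)
  keep <- ld |>
    dplyr::filter(!is.na(.data$r_squared),
                  .data$r_squared > r2_threshold)
  if (nrow(keep) == 0) {
    inform(sprintf("no variant exceeds r^2 > %g with the haplotype",
                   r2_threshold))
    return(tibble(rank = integer(), variant_id = character(),
                  r_squared = numeric(), n_animals = integer(),
                  perfect_ld = logical(), consequence = character(),
                  score = numeric(), impact_class = character(),
                  tolerated = logical()))
  }
  if (is.null(annotations)) {
    annotations <- tibble(variant_id = character(), consequence = character(),
                          score = numeric())
  }
  high <- c("frameshift", "stop_gained", "splice_acceptor", "splice_donor")
  keep |>
    dplyr::left_join(as_tibble(annotations), by = "variant_id") |>
    dplyr::mutate(
      consequence = dplyr::coalesce(.data$consequence, "other"),
      perfect_ld = .data$r_squared >= 1 - 1e-9,
      tolerated = .data$consequence == "missense" &
        !is.na(.data$score) & .data$score > tolerated_score_above,
      impact_class = dplyr::case_when(
        .data$consequence %in% high ~ "high",
        .data$consequence == "missense" & !.data$tolerated ~ "missense",
        .data$consequence == "missense" ~ "missense_tolerated",
        TRUE ~ "other"
      ),
      .priority = match(.data$impact_class,
                        c("high", "missense", "missense_tolerated", "other"))
    ) |>
    dplyr::arrange(.data$.priority, dplyr::desc(.data$r_squared),
                   .data$variant_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "variant_id", "r_squared", "n_animals",
                  "perfect_ld", "consequence", "score", "impact_class",
                  "tolerated")
}

#' Parse an HGVS-style genomic deletion identifier
#'
#' Handles identifiers of the form `"6:g.48801280delGACGGTGTACGCCGGT"`:
#' chromosome, 1-based start of the deleted run, and the deleted sequence.
#'
#' @param id The identifier string.
#' @return A list with `chrom`, `start`, `end` (inclusive), `deleted`.
#' @export
parse_hgvs_del <- function(id) {
  m <- regmatches(id, regexec("^([^:]+):g\\.(\\d+)del([ACGT]+)$", id))[[1]]
  if (length(m) != 4) abort(paste0("cannot parse deletion identifier: ", id))
  start <- as.integer(m[3])
  list(chrom = m[2], start = start,
       end = start + nchar(m[4]) - 1L, deleted = m[4])
}

#' Coding-sequence model for consequence prediction
#'
#' Holds a spliced CDS (start codon through stop codon, 5'-to-3' on the
#' coding strand), the genomic exon intervals mapping genomic coordinates
#' into CDS coordinates, and the transcript sequence trailing the stop codon
#' so frameshifts can be read through into the 3' UTR.
#'
#' @param transcript_id Identifier.
#' @param cds Character CDS sequence; length must be a multiple of 3,
#'   beginning with ATG and ending in a stop codon.
#' @param exons A data frame of genomic CDS intervals with columns `start`,
#'   `end` (1-based inclusive), ordered in transcription order. May be
#'   omitted for transcripts addressed in CDS coordinates only, in which
#'   case a single exon spanning the CDS at genomic position 1 is assumed.
#' @param strand `"+"` or `"-"`.
#' @param trailing Sequence 3' of the stop codon (coding strand), default
#'   `""`.
#' @return An object of class `cds_model`.
#' @export
cds_model <- function(transcript_id, cds, exons = NULL, strand = "+",
                      trailing = "") {
  cds <- toupper(cds)
  trailing <- toupper(trailing)
  if (nchar(cds) %% 3 != 0) abort("CDS length must be a multiple of 3")
  if (substr(cds, 1, 3) != "ATG") abort("CDS must start with ATG")
  if (!substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")) {
    abort("CDS must end with a stop codon")
  }
  if (is.null(exons)) {
    exons <- data.frame(start = 1L, end = nchar(cds))
    strand <- "+"
  }
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  if (sum(exons$end - exons$start + 1) != nchar(cds)) {
    abort("exon intervals do not sum to the CDS length")
  }
  structure(list(transcript_id = transcript_id, cds = cds, exons = exons,
                 strand = strand, trailing = trailing),
            class = "cds_model")
}

# genomic position -> CDS coordinate (1-based); NA outside the CDS
genomic_to_cds <- function(model, gpos) {
  off <- 0L
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    if (gpos >= s && gpos <= e) {
      return(if (model$strand == "+") off + (gpos - s + 1L)
             else off + (e - gpos + 1L))
    }
    off <- off + (e - s + 1L)
  }
  NA_integer_
}

translate_to_stop <- function(nt) {
  nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
  if (nchar(nt) < 3) return(list(protein = "", stopped = FALSE))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1, stop_at - 1), stopped = TRUE)
  } else {
    list(protein = aa, stopped = FALSE)
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Protein consequence of a genomic deletion in a coding sequence
#'
#' Maps a genomic deletion into CDS coordinates (strand-aware), applies it,
#' and translates the result. A deletion of length divisible by 3 is an
#' in-frame deletion (no novel residues); otherwise the shifted frame is
#' translated through the trailing transcript sequence until the first stop
#' codon, yielding the number of wild-type residues retained
#' (`shared_prefix_aa`), the novel residues before the premature stop
#' (`novel_aa`) and the wild-type residues lost (`lost_wt_aa`).
#'
#' @param model A [cds_model()].
#' @param start,end Genomic interval deleted (1-based inclusive), or CDS
#'   coordinates when `coords = "cds"`.
#' @param deleted Optional deleted sequence (genomic forward strand) to
#'   validate against the CDS, e.g. from [parse_hgvs_del()].
#' @param coords `"genomic"` (default) or `"cds"`.
#' @return A one-row tibble: `transcript_id`, `kind` (`frameshift`,
#'   `inframe_deletion` or `no_stop_found`), `shared_prefix_aa`, `novel_aa`,
#'   `mutant_length_aa`, `lost_wt_aa`, `wt_length_aa`.
#' @examples
#' toy <- cds_model("toy", cds = "ATGCATCATCATTAG", trailing = "GTAAA")
#' apply_deletion_and_translate(toy, 4, 4, coords = "cds")
#' @export
apply_deletion_and_translate <- function(model, start, end, deleted = NULL,
                                         coords = c("genomic", "cds")) {
  stopifnot(inherits(model, "cds_model"))
  coords <- match.arg(coords)
  if (end < start) abort("end before start")
  if (coords == "genomic") {
    in_one_exon <- any(model$exons$start <= start & model$exons$end >= end)
    c1 <- genomic_to_cds(model, start)
    c2 <- genomic_to_cds(model, end)
    if (is.na(c1) || is.na(c2)) {
      if (is.na(c1) && is.na(c2)) abort("deletion is non-coding")
      abort("deletion spans a splice site: unsupported")
    }
    if (!in_one_exon) abort("deletion spans a splice site: unsupported")
    cds_start <- min(c1, c2)
    cds_end <- max(c1, c2)
  } else {
    cds_start <- start; cds_end <- end
    if (cds_end > nchar(model$cds) || cds_start < 1) {
      abort("deletion is non-coding")
    }
  }
  if (!is.null(deleted)) {
    expect <- if (coords == "genomic" && model$strand == "-") {
      revcomp(deleted)
    } else {
      toupper(deleted)
    }
    have <- substr(model$cds, cds_start, cds_end)
    if (have != expect) {
      abort(sprintf("deleted sequence mismatch: CDS has %s, identifier says %s",
                    have, expect))
    }
  }
  del_len <- cds_end - cds_start + 1L
  wt <- translate_to_stop(model$cds)$protein
  if (del_len == 0L) {
    return(tibble(transcript_id = model$transcript_id, kind = "none",
                  shared_prefix_aa = nchar(wt), novel_aa = 0L,
                  mutant_length_aa = nchar(wt), lost_wt_aa = 0L,
                  wt_length_aa = nchar(wt)))
  }
  mut_nt <- paste0(substr(model$cds, 1, cds_start - 1L),
                   substr(model$cds, cds_end + 1L, nchar(model$cds)),
                   model$trailing)
  if (del_len %% 3 == 0) {
    mut <- translate_to_stop(mut_nt)
    return(tibble(transcript_id = model$transcript_id,
                  kind = "inframe_deletion",
                  shared_prefix_aa = common_prefix(wt, mut$protein),
                  novel_aa = 0L,
                  mutant_length_aa = nchar(mut$protein),
                  lost_wt_aa = nchar(wt) - common_prefix(wt, mut$protein),
                  wt_length_aa = nchar(wt)))
  }
  mut <- translate_to_stop(mut_nt)
  shared <- common_prefix(wt, mut$protein)
  tibble(transcript_id = model$transcript_id,
         kind = if (mut$stopped) "frameshift" else "no_stop_found",
         shared_prefix_aa = shared,
         novel_aa = nchar(mut$protein) - shared,
         mutant_length_aa = nchar(mut$protein),
         lost_wt_aa = nchar(wt) - shared,
         wt_length_aa = nchar(wt))
}

common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Read variant genotype dosages from a VCF
#'
#' Extracts per-animal alternate-allele dosage from the GT field of a
#' (possibly unphased) VCF; multi-allelic records are skipped with a count.
#'
#' @param path VCF file.
#' @return A list with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `genotypes` (long tibble: `variant_id`, `animal_id`,
#'   `dosage`).
#' @export
read_variant_genotypes <- function(path) {
  panel <- read_panel(path, format = "vcf")
  n <- length(panel$animals)
  odd <- seq(1L, 2L * n, by = 2L)
  dose <- panel$haplotypes[odd, , drop = FALSE] +
    panel$haplotypes[odd + 1L, , drop = FALSE]
  variants <- panel$markers |>
    dplyr::rename(variant_id = "marker_id")
  genotypes <- tidyr::expand_grid(variant_id = variants$variant_id,
                                  animal_id = panel$animals)
  # dose is animals x variants; expand_grid rows are variant-major
  genotypes$dosage <- as.integer(as.vector(dose))
  list(variants = variants, genotypes = genotypes)
}

#' Read a consequence-annotation sidecar table
#'
#' Tab-separated annotation output with columns `variant_id`, `consequence`
#' and optional `score`, as produced by standard consequence-annotation
#' tools after reshaping.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
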