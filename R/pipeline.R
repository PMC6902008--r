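#' Write a synthetic dataset to the pipeline's file formats
#'
#' Materialises a [simulate_population()] result as the standard files the
#' pipeline consumes: the genotyped panel (VCF or `.ped`/`.map`), pedigree,
#' litter and piglet tables as CSV, trait records as CSV, the sequenced
#' subset as VCF plus a consequence-annotation TSV sidecar, and the
#' simulation truth as CSV. Piglets of carrier-by-carrier litters carry
#' their true genotype in the piglet table, emulating targeted follow-up
#' genotyping of suspect litters (other piglets have `NA`).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param panel_format `"vcf"` or `"ped_map"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, panel_format = c("vcf", "ped_map")) {
  panel_format <- match.arg(panel_format)
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (panel_format == "vcf") {
    write_panel(dataset$panel, p("panel.vcf"), format = "vcf")
  } else {
    write_panel(dataset$panel, p("panel"), format = "ped_map")
  }
  readr::write_csv(dataset$pedigree, p("pedigree.csv"))
  readr::write_csv(dataset$litters, p("litters.csv"))
  dosage_of <- setNames(dataset$truth$lethal_dosage, dataset$truth$animal_id)
  cxc <- dataset$litters$litter_id[
    dosage_of[dataset$litters$sire_id] >= 1 &
      dosage_of[dataset$litters$dam_id] >= 1]
  piglets <- dataset$piglets |>
    dplyr::mutate(genotype = ifelse(.data$litter_id %in% cxc,
                                    dosage_of[.data$piglet_id], NA_integer_))
  readr::write_csv(piglets, p("piglets.csv"))
  readr::write_csv(dataset$trait_records, p("traits.csv"))
  readr::write_csv(dataset$truth, p("truth.csv"))
  wgs_panel_from(dataset$wgs) |> write_panel(p("wgs.vcf"), format = "vcf")
  readr::write_tsv(dplyr::select(dataset$wgs$variants, "variant_id",
                                 "consequence", "score"),
                   p("annotations.tsv"))
  invisible(dir)
}

# sequenced-subset dosages as an unphased panel so the VCF writer applies
wgs_panel_from <- function(wgs) {
  v <- wgs$variants
  nv <- nrow(v)
  na <- length(wgs$animals)
  d <- matrix(wgs$genotypes$dosage, nrow = na)  # variant-major input
  hap <- matrix(NA_integer_, nrow = 2L * na, ncol = nv)
  odd <- seq(1L, 2L * na, by = 2L)
  hap[odd, ] <- (d >= 1L) + 0L
  hap[odd + 1L, ] <- (d == 2L) + 0L
  mk <- tibble(marker_id = v$variant_id, chrom = v$chrom, pos = v$pos,
               ref = v$ref, alt = v$alt)
  phased_panel(mk, wgs$animals, hap, phased = FALSE)
}

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Can be
#' loaded from a YAML file with [read_pipeline_config()].
#'
#' @param panel Path to the genotyped panel (VCF or ped/map prefix).
#' @param pedigree,litters,piglets,traits,variants,annotations Paths to the
#'   respective CSV/TSV/VCF inputs; `variants`, `annotations`, `traits`,
#'   `piglets` are optional (`NULL` skips the dependent stages).
#' @param panel_format `"vcf"` or `"ped_map"`.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stage randomness.
#' @param max_sample_missing,min_call_rate,min_maf,hwe_min_p QC thresholds,
#'   see [apply_qc()].
#' @param window_markers,p_threshold,min_expected_hom Scan parameters, see
#'   [scan_genome()].
#' @param r2_threshold LD threshold for [prioritize_variants()].
#' @param heritability Named list/vector of per-trait heritabilities for
#'   [run_association()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, pedigree, litters, out_dir,
                            piglets = NULL, traits = NULL, variants = NULL,
                            annotations = NULL, panel_format = "vcf",
                            seed = 1L, max_sample_missing = 0.15,
                            min_call_rate = 0.85, min_maf = 0.01,
                            hwe_min_p = 1e-12, window_markers = 20,
                            p_threshold = 5e-3, min_expected_hom = 10,
                            r2_threshold = 0.8, heritability = 0.2) {
  cfg <- as.list(environment())
  req <- c("panel", "pedigree", "litters")
  for (f in req) {
    if (!is.character(cfg[[f]])) abort(paste0(f, " path required"))
  }
  for (f in c(req, "piglets", "traits", "variants", "annotations")) {
    pth <- cfg[[f]]
    if (!is.null(pth) && f != "panel" && !file.exists(pth)) {
      abort(paste0(f, " file not found: ", pth))
    }
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]. Relative input paths are resolved against the YAML
#'   file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  for (f in c("panel", "pedigree", "litters", "piglets", "traits",
              "variants", "annotations")) {
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full discovery-and-validation pipeline
#'
#' Executes the stages in the order of the analysis: genotype QC, the
#' deficit-of-homozygotes scan, carrier assignment from the top region,
#' litter classification and survival contrasts, then (when inputs are
#' present) variant prioritization, segregation/penetrance validation on
#' genotyped litters, and the carrier association model. All tabular
#' outputs are TSV, sorted deterministically; a `manifest.json` records the
#' package version, parameters, seed and input checksums so a run can be
#' reproduced exactly.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages (default `FALSE`).
#' @return Invisibly, a named list of the stage results; files are written
#'   to `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  out <- list()
  outfile <- function(f) file.path(config$out_dir, f)

  say("qc", "reading panel")
  panel <- read_panel(config$panel, format = config$panel_format)
  qc <- apply_qc(panel, config$max_sample_missing, config$min_call_rate,
                 config$min_maf, config$hwe_min_p)
  readr::write_tsv(qc$report, outfile("qc_report.tsv"))
  out$qc <- qc$report
  say("qc", sprintf("%d markers kept", qc$report$n_markers_kept))

  say("scan", "running deficit-of-homozygotes scan")
  scan <- scan_genome(qc$panel, window_markers = config$window_markers,
                      p_threshold = config$p_threshold,
                      min_expected_hom = config$min_expected_hom)
  readr::write_tsv(as_tibble(scan), outfile("scan_results.tsv"))
  regions <- scan_regions(scan)
  readr::write_tsv(regions, outfile("scan_regions.tsv"))
  write_scan_bed(scan, outfile("scan_regions.bed"))
  out$scan <- scan
  say("scan", sprintf("%d significant region(s)", nrow(regions)))

  if (nrow(scan) == 0) {
    abort("scan produced no testable haplotype; pipeline halted")
  }
  top <- as_tibble(scan)[1, ]
  carriers <- assign_carrier_status(qc$panel, top)
  readr::write_tsv(carriers, outfile("carriers.tsv"))
  out$carriers <- carriers
  say("carriers", sprintf("carrier fraction %.3f",
                          attr(carriers, "carrier_fraction")))

  say("litters", "classifying matings")
  litters <- readr::read_csv(config$litters, show_col_types = FALSE)
  classified <- classify_matings(litters, carriers)
  piglets <- if (!is.null(config$piglets)) {
    readr::read_csv(config$piglets, show_col_types = FALSE)
  } else {
    NULL
  }
  summary <- summarize_by_class(classified, piglets)
  readr::write_tsv(summary, outfile("litter_summary.tsv"))
  out$litter_summary <- summary
  contrasts <- tryCatch(
    contrast_mating_classes(classified),
    error = function(e) {
      warn(paste0("mating-class contrast skipped: ", conditionMessage(e)))
      NULL
    })
  if (!is.null(contrasts)) {
    readr::write_tsv(contrasts, outfile("litter_contrasts.tsv"))
    out$litter_contrasts <- contrasts
  }

  if (!is.null(config$variants)) {
    say("prioritize", "ranking candidate variants")
    vg <- read_variant_genotypes(config$variants)
    ann <- if (!is.null(config$annotations)) {
      read_annotations(config$annotations)
    } else {
      NULL
    }
    ranked <- prioritize_variants(vg$genotypes, carriers, ann,
                                  r2_threshold = config$r2_threshold)
    readr::write_tsv(ranked, outfile("prioritized_variants.tsv"))
    out$prioritized <- ranked
  } else {
    say("prioritize", "no variant file; stage skipped")
  }

  if (!is.null(piglets) && "genotype" %in% names(piglets) &&
        any(!is.na(piglets$genotype))) {
    say("segregate", "testing genotyped litters")
    gt <- piglets[!is.na(piglets$genotype), , drop = FALSE]
    seg <- segregation_test(sum(gt$genotype == 0), sum(gt$genotype == 1),
                            sum(gt$genotype == 2),
                            expectation = "birth_1_2_1")
    pen <- penetrance_summary(gt)
    readr::write_tsv(dplyr::bind_cols(seg, pen), outfile("segregation.tsv"))
    out$segregation <- dplyr::bind_cols(seg, pen)
  } else {
    say("segregate", "no genotyped piglets; stage skipped")
  }

  if (!is.null(config$traits)) {
    say("assoc", "fitting carrier association")
    traits <- readr::read_csv(config$traits, show_col_types = FALSE)
    pedigree <- readr::read_csv(config$pedigree, show_col_types = FALSE)
    h2 <- unlist(config$heritability)
    assoc <- run_association(traits, carriers, pedigree, h2)
    readr::write_tsv(assoc, outfile("association.tsv"))
    out$association <- assoc
  } else {
    say("assoc", "no trait file; stage skipped")
  }

  inputs <- purrr::compact(config[c("panel", "pedigree", "litters",
                                    "piglets", "traits", "variants",
                                    "annotations")])
  manifest <- list(
    package = "lethalscan",
    version = as.character(utils::packageVersion("lethalscan")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir", names(inputs)))],
    inputs = lapply(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done", paste0("outputs in ", config$out_dir))
  invisible(out)
}
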