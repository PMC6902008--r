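#' Configuration for the gene-drop population simulator
#'
#' Defaults emulate an intensively recorded commercial boar line in which a
#' single fully penetrant recessive lethal segregates on a marker haplotype:
#' a founder allele frequency of 4.5%, litters of about ten piglets, baseline
#' farrowing and lactation survival of 91.4% and 90.0%, and homozygote death
#' before genotyping age (stillborn, or dead within 48 h of birth). With the
#' default pedigree sizes the simulator yields a genotyped panel of roughly
#' 25,000 weaned animals over four generations.
#'
#' @param n_founders Number of founder animals (default 1000, half of each
#'   sex).
#' @param n_generations Number of bred generations after the founders
#'   (default 4).
#' @param litter_size_mean Mean total born per litter, Poisson (default
#'   10.08).
#' @param markers_per_chromosome,n_chromosomes SNP-panel shape (defaults 400
#'   markers on each of 3 chromosomes).
#' @param chromosome_length_cM Genetic length per chromosome; Haldane
#'   crossovers, 1 cM corresponds to 1 Mb of physical map (default 100).
#' @param lethal_allele_freq Target lethal-allele frequency among founder
#'   haplotypes (default 0.045).
#' @param lethal_chrom Index of the chromosome carrying the lethal
#'   (default 1).
#' @param lethal_pos_cM Genetic position of the lethal locus (default mid
#'   chromosome).
#' @param tag_markers Carrier founder haplotypes share an identical marker
#'   haplotype over this many markers centred on the lethal locus, so the
#'   lethal is in complete LD with a taggable window (default 19).
#' @param p_stillborn_given_homozygote,p_death_48h_given_homozygote Fate
#'   probabilities for lethal homozygotes; they sum to 1 under full
#'   penetrance (defaults 1/3 and 2/3). Any remainder survives as a normal
#'   piglet (partial penetrance).
#' @param baseline_farrowing_survival,baseline_lactation_survival Survival
#'   rates for piglets that are not dying lethal homozygotes (defaults
#'   0.9137 and 0.8997).
#' @param carrier_effect_on_trait Additive effect of one lethal-haplotype
#'   copy on the simulated pseudo-phenotype (default -0.39).
#' @param trait_heritability Heritability of the simulated trait on a unit
#'   phenotypic-variance scale (default 0.2).
#' @param sire_dam_ratio Dams mated per sire (default 10).
#' @param max_litters_per_generation Cap on litters farrowed per generation
#'   (default 850), which keeps the population near a constant size.
#' @param n_wgs,n_wgs_carriers Sequenced-subset size and the number of
#'   haplotype carriers it includes (defaults 71 and 5).
#' @param n_wgs_variants Variants simulated around the lethal locus for the
#'   sequenced subset (default 60).
#' @param seed Integer seed; the seed fully determines the dataset.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_founders = 1000,
                              n_generations = 4,
                              litter_size_mean = 10.08,
                              markers_per_chromosome = 400,
                              n_chromosomes = 3,
                              chromosome_length_cM = 100,
                              lethal_allele_freq = 0.045,
                              lethal_chrom = 1,
                              lethal_pos_cM = chromosome_length_cM / 2,
                              tag_markers = 19,
                              p_stillborn_given_homozygote = 1 / 3,
                              p_death_48h_given_homozygote = 2 / 3,
                              baseline_farrowing_survival = 0.9137,
                              baseline_lactation_survival = 0.8997,
                              carrier_effect_on_trait = -0.39,
                              trait_heritability = 0.2,
                              sire_dam_ratio = 10,
                              max_litters_per_generation = 850,
                              n_wgs = 71,
                              n_wgs_carriers = 5,
                              n_wgs_variants = 60,
                              seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("lethal_allele_freq", "p_stillborn_given_homozygote",
          "p_death_48h_given_homozygote", "baseline_farrowing_survival",
          "baseline_lactation_survival", "trait_heritability")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  if (cfg$p_stillborn_given_homozygote + cfg$p_death_48h_given_homozygote >
        1 + 1e-12) {
    abort("homozygote fate probabilities exceed 1")
  }
  if (cfg$litter_size_mean <= 0) abort("litter_size_mean must be positive")
  if (cfg$chromosome_length_cM <= 0) abort("chromosome_length_cM must be positive")
  if (cfg$n_founders < 2) abort("need at least 2 founders")
  if (cfg$lethal_chrom > cfg$n_chromosomes) abort("lethal_chrom out of range")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# One gamete from a parent's two chromosome haplotypes (2 x M matrix),
# Haldane model: Poisson crossover count, uniform positions on [0, L] cM.
make_gamete <- function(H, cM, L) {
  k <- rpois(1L, L / 100)
  if (k == 0L) {
    return(H[sample.int(2L, 1L), ])
  }
  xo <- sort(runif(k, 0, L))
  seg <- findInterval(cM, xo)
  row <- (sample.int(2L, 1L) + seg) %% 2L + 1L
  H[row + 2L * (seq_along(cM) - 1L)]
}

#' Simulate a pedigreed population segregating a recessive lethal haplotype
#'
#' Gene-drop simulation: founder haplotypes are drawn marker-wise with allele
#' frequencies uniform on (0.05, 0.95); a fraction of founder haplotypes
#' carries an (unobserved) lethal allele and shares an identical marker
#' haplotype over a tagging window around it. Haplotypes are transmitted
#' through discrete generations with Haldane recombination, litters are
#' farrowed by randomly mated survivors, and every piglet receives a fate:
#' lethal homozygotes are stillborn or die within 48 h (full penetrance),
#' other piglets die at baseline farrowing/lactation rates. Only piglets
#' surviving to weaning (and the founders) enter the genotyped SNP panel, so
#' homozygotes are absent from it — the signature the downstream scan
#' detects. The simulator also draws a sequenced subset with a causal-variant
#' neighbourhood in graded LD with the lethal haplotype, and per-animal
#' pseudo-phenotype records (deregressed-breeding-value-like response with
#' reliability and weight) with a pedigree-correlated polygenic term and a
#' carrier dosage effect.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with elements `panel`
#'   ([phased_panel()] of genotyped survivors), `pedigree` (tibble
#'   `animal_id`, `sire_id`, `dam_id`, `sex`, `generation`), `litters`,
#'   `piglets`, `truth` (per conceived animal: lethal dosage, fate,
#'   survival), `wgs` (list `variants`, `genotypes`, `animals`),
#'   `trait_records`, and `config`. The attributes of `truth` record the
#'   lethal locus (`lethal_chrom`, `lethal_pos_bp`) and the tag-window
#'   marker indices and template haplotype.
#' @export
simulate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$n_chromosomes
  M <- cfg$markers_per_chromosome
  L <- cfg$chromosome_length_cM
  # marker maps; the lethal locus is carried as a hidden pseudo-marker
  marker_cM <- lapply(seq_len(K), function(k) (seq_len(M) - 0.5) * L / M)
  lethal_k <- cfg$lethal_chrom
  ins <- findInterval(cfg$lethal_pos_cM, marker_cM[[lethal_k]]) + 1L
  cM_full <- marker_cM
  cM_full[[lethal_k]] <- append(marker_cM[[lethal_k]], cfg$lethal_pos_cM,
                                after = ins - 1L)
  lethal_col <- ins  # column index of the hidden locus on its chromosome
  ncol_full <- vapply(cM_full, length, 0L)

  founder_freq <- lapply(seq_len(K), function(k) runif(M, 0.05, 0.95))
  nf <- cfg$n_founders
  H <- lapply(seq_len(K), function(k) {
    h <- matrix(rbinom(2L * nf * M, 1L, rep(founder_freq[[k]], each = 2L * nf)),
                nrow = 2L * nf)
    if (k == lethal_k) {
      lethal <- rbinom(2L * nf, 1L, cfg$lethal_allele_freq)
      if (cfg$lethal_allele_freq > 0 && sum(lethal) == 0) {
        abort(paste("no founder haplotype carries the lethal allele;",
                    "increase n_founders or lethal_allele_freq"))
      }
      # founders are live breeding animals: no founder may be homozygous
      # for the lethal; surplus copies move to non-carrier animals so the
      # founder allele count is preserved
      odd <- seq(1L, 2L * nf, by = 2L)
      hom_f <- which(lethal[odd] == 1L & lethal[odd + 1L] == 1L)
      for (i in hom_f) {
        free <- which(lethal[odd] == 0L & lethal[odd + 1L] == 0L)
        if (length(free) == 0) break
        lethal[2L * i] <- 0L
        lethal[2L * sample(free, 1L) - 1L] <- 1L
      }
      h <- cbind(h[, seq_len(lethal_col - 1L), drop = FALSE], lethal,
                 h[, lethal_col:M, drop = FALSE], deparse.level = 0)
    }
    storage.mode(h) <- "integer"
    h
  })
  # carrier founder haplotypes share one marker haplotype around the lethal
  cand <- setdiff(seq_len(ncol_full[lethal_k]), lethal_col)
  cand <- cand[order(abs(cand - lethal_col), cand)]
  tag_cols <- sort(utils::head(cand, cfg$tag_markers))
  tag_template <- rbinom(length(tag_cols), 1L, 0.5)
  car <- H[[lethal_k]][, lethal_col] == 1L
  if (any(car)) {
    H[[lethal_k]][car, tag_cols] <- matrix(tag_template, nrow = sum(car),
                                           ncol = length(tag_cols),
                                           byrow = TRUE)
  }

  h2 <- cfg$trait_heritability
  pool <- list(
    ids = sprintf("G0_%05d", seq_len(nf)),
    sex = rep_len(c("M", "F"), nf),
    a = rnorm(nf, 0, sqrt(h2)),
    hap = H
  )
  ped <- list(tibble(animal_id = pool$ids, sire_id = NA_character_,
                     dam_id = NA_character_, sex = pool$sex, generation = 0L))
  truth <- list(tibble(animal_id = pool$ids,
                       lethal_dosage = marker_pair_sum(H[[lethal_k]], lethal_col),
                       fate = "weaned", age_hours = NA_real_, generation = 0L,
                       litter_id = NA_character_))
  panel_gens <- list(list(ids = pool$ids, hap = H, a = pool$a))
  litters <- list()
  piglets <- list()

  for (g in seq_len(cfg$n_generations)) {
    dams <- which(pool$sex == "F")
    sires <- which(pool$sex == "M")
    if (length(dams) == 0 || length(sires) == 0) {
      abort("breeding pool lost one sex; increase founder or litter numbers")
    }
    if (length(dams) > cfg$max_litters_per_generation) {
      dams <- sort(sample(dams, cfg$max_litters_per_generation))
    }
    n_litter <- length(dams)
    n_sire <- max(1L, ceiling(n_litter / cfg$sire_dam_ratio))
    use_sires <- if (length(sires) > n_sire) sort(sample(sires, n_sire)) else sires
    litter_sire <- sample(use_sires, n_litter, replace = TRUE)
    sizes <- rpois(n_litter, cfg$litter_size_mean)
    keep_l <- sizes > 0
    dams <- dams[keep_l]; litter_sire <- litter_sire[keep_l]
    sizes <- sizes[keep_l]
    n_litter <- length(sizes)
    n_pig <- sum(sizes)
    lit_id <- sprintf("L%d_%04d", g, seq_len(n_litter))
    pid <- sprintf("G%d_%05d", g, seq_len(n_pig))
    pig_lit <- rep(seq_len(n_litter), sizes)
    pig_sire <- litter_sire[pig_lit]
    pig_dam <- dams[pig_lit]

    hap_off <- lapply(seq_len(K), function(k) {
      out <- matrix(0L, nrow = 2L * n_pig, ncol = ncol_full[k])
      Hk <- pool$hap[[k]]
      cMk <- cM_full[[k]]
      for (i in seq_len(n_pig)) {
        rs <- 2L * pig_sire[i] - 1L
        rd <- 2L * pig_dam[i] - 1L
        out[2L * i - 1L, ] <- make_gamete(Hk[rs:(rs + 1L), , drop = FALSE], cMk, L)
        out[2L * i, ] <- make_gamete(Hk[rd:(rd + 1L), , drop = FALSE], cMk, L)
      }
      out
    })
    dosage <- marker_pair_sum(hap_off[[lethal_k]], lethal_col)
    sex <- ifelse(runif(n_pig) < 0.5, "M", "F")
    a_val <- 0.5 * (pool$a[pig_sire] + pool$a[pig_dam]) +
      rnorm(n_pig, 0, sqrt(0.5 * h2))

    # fates
    fate <- character(n_pig)
    age <- rep(NA_real_, n_pig)
    u <- runif(n_pig)
    hom <- dosage == 2L
    still_h <- hom & u < cfg$p_stillborn_given_homozygote
    die48_h <- hom & !still_h &
      u < cfg$p_stillborn_given_homozygote + cfg$p_death_48h_given_homozygote
    normal <- !still_h & !die48_h
    u2 <- runif(n_pig)
    still_b <- normal & u2 > cfg$baseline_farrowing_survival
    u3 <- runif(n_pig)
    die_lact <- normal & !still_b & u3 > cfg$baseline_lactation_survival
    fate[still_h | still_b] <- "stillborn"
    fate[die48_h] <- "died"
    # most homozygote deaths fall in the first day of life
    age[die48_h] <- ifelse(runif(sum(die48_h)) < 18 / 19,
                           runif(sum(die48_h), 0, 24),
                           runif(sum(die48_h), 24, 48))
    fate[die_lact] <- "died"
    age[die_lact] <- runif(sum(die_lact), 0, 21 * 24)
    fate[fate == ""] <- "weaned"

    sire_ids <- pool$ids[pig_sire]
    dam_ids <- pool$ids[pig_dam]
    piglets[[g]] <- tibble(litter_id = lit_id[pig_lit], piglet_id = pid,
                           fate = fate, age_hours = age)
    truth[[g + 1L]] <- tibble(animal_id = pid, lethal_dosage = dosage,
                              fate = fate, age_hours = age, generation = g,
                              litter_id = lit_id[pig_lit])
    live <- fate != "stillborn"
    litters[[g]] <- tibble(
      litter_id = lit_id,
      sire_id = pool$ids[litter_sire],
      dam_id = pool$ids[dams],
      total_born = sizes,
      live_born = as.integer(tapply(live, pig_lit, sum)),
      stillborn = as.integer(tapply(fate == "stillborn", pig_lit, sum)),
      mummified = rpois(n_litter, 0.07),
      n_weaned = as.integer(tapply(fate == "weaned", pig_lit, sum)),
      generation = g
    )
    ped[[g + 1L]] <- tibble(animal_id = pid, sire_id = sire_ids,
                            dam_id = dam_ids, sex = sex, generation = g)
    weaned <- which(fate == "weaned")
    rows <- as.vector(rbind(2L * weaned - 1L, 2L * weaned))
    hap_w <- lapply(hap_off, function(hk) hk[rows, , drop = FALSE])
    panel_gens[[g + 1L]] <- list(ids = pid[weaned], hap = hap_w,
                                 a = a_val[weaned])
    pool <- list(ids = pid[weaned], sex = sex[weaned], a = a_val[weaned],
                 hap = hap_w)
  }

  # assemble genotyped panel (founders + weaned survivors), dropping the
  # hidden lethal pseudo-marker
  ids <- unlist(lapply(panel_gens, `[[`, "ids"))
  a_all <- unlist(lapply(panel_gens, `[[`, "a"))
  hap_panel <- lapply(seq_len(K), function(k) {
    h <- do.call(rbind, lapply(panel_gens, function(p) p$hap[[k]]))
    if (k == lethal_k) h[, -lethal_col, drop = FALSE] else h
  })
  lethal_hap_rows <- do.call(rbind, lapply(panel_gens,
                                           function(p) p$hap[[lethal_k]]))[, lethal_col]
  markers <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    tibble(marker_id = sprintf("C%dM%04d", k, seq_len(M)),
           chrom = as.character(k),
           pos = as.integer(round(marker_cM[[k]] * 1e6)))
  }))
  panel <- phased_panel(markers, ids, do.call(cbind, hap_panel), phased = TRUE)

  truth_tb <- dplyr::bind_rows(truth)
  pedigree <- dplyr::bind_rows(ped)
  litters_tb <- dplyr::bind_rows(litters)
  piglets_tb <- dplyr::bind_rows(piglets)

  panel_dosage <- setNames(marker_pair_sum_vec(lethal_hap_rows), ids)
  trait_records <- simulate_trait_records(ids, panel_dosage, a_all, cfg)
  wgs <- simulate_wgs_subset(ids, lethal_hap_rows, panel_dosage, markers, cfg)

  truth_tb <- dplyr::left_join(
    truth_tb,
    tibble(animal_id = ids, genotyped = TRUE), by = "animal_id") |>
    dplyr::mutate(genotyped = !is.na(.data$genotyped))
  attr(truth_tb, "lethal_chrom") <- as.character(lethal_k)
  attr(truth_tb, "lethal_pos_bp") <- as.integer(round(cfg$lethal_pos_cM * 1e6))
  attr(truth_tb, "tag_marker_idx") <-
    which(markers$chrom == as.character(lethal_k))[tag_cols -
                                                     (tag_cols > lethal_col)]
  attr(truth_tb, "tag_template") <- paste(tag_template, collapse = "")

  structure(
    list(panel = panel, pedigree = pedigree, litters = litters_tb,
         piglets = piglets_tb, truth = truth_tb, wgs = wgs,
         trait_records = trait_records, config = cfg),
    class = "synthetic_dataset"
  )
}

# dosage at one column from an animal-major haplotype matrix
marker_pair_sum <- function(h, col) {
  v <- h[, col]
  marker_pair_sum_vec(v)
}

marker_pair_sum_vec <- function(v) {
  odd <- seq(1L, length(v), by = 2L)
  v[odd] + v[odd + 1L]
}

simulate_trait_records <- function(ids, dosage, a, cfg) {
  n <- length(ids)
  reliability <- runif(n, 0.25, 0.95)
  weight <- runif(n, 0.5, 2.5)
  e <- rnorm(n, 0, sqrt((1 - cfg$trait_heritability) / weight))
  tibble(animal_id = ids,
         debv = cfg$carrier_effect_on_trait * dosage + a + e,
         reliability = reliability, weight = weight)
}

simulate_wgs_subset <- function(ids, lethal_hap_rows, dosage, markers, cfg) {
  carriers <- which(dosage >= 1L)
  n_car <- min(cfg$n_wgs_carriers, length(carriers))
  pick_car <- if (n_car > 0) sample(carriers, n_car) else integer(0)
  non <- setdiff(seq_along(ids), pick_car)
  pick_non <- sample(non, min(cfg$n_wgs - n_car, length(non)))
  pick <- sort(c(pick_car, pick_non))
  seq_ids <- ids[pick]
  hap_rows <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  lethal_local <- lethal_hap_rows[hap_rows]  # per sequenced haplotype

  pos0 <- as.integer(round(cfg$lethal_pos_cM * 1e6))
  nv <- cfg$n_wgs_variants
  offs <- as.integer(round(runif(nv - 1L, -1.5e6, 1.5e6)))
  offs[offs == 0L] <- 101L
  offs <- c(0L, sort(offs))
  ord <- order(offs)
  offs <- offs[ord]
  pos <- pmax(1L, pos0 + offs)
  causal_idx <- which(offs == 0L)[1]
  dist <- abs(offs)
  # graded LD: variants further from the lethal sit on extra, non-lethal
  # haplotype copies; nearby ones are in perfect LD
  extra <- rpois(nv, pmax(0, (dist - 2e5) / 1.5e6) * 3)
  extra[causal_idx] <- 0L
  n_hap <- length(lethal_local)
  geno <- matrix(0L, nrow = nv, ncol = length(pick))
  for (v in seq_len(nv)) {
    on_hap <- lethal_local == 1L
    if (extra[v] > 0) {
      off_idx <- which(!on_hap)
      on_hap[sample(off_idx, min(extra[v], length(off_idx)))] <- TRUE
    }
    geno[v, ] <- marker_pair_sum_vec(as.integer(on_hap))
  }
  del_seq <- "GACGGTGTACGCCGGT"
  chrom <- as.character(cfg$lethal_chrom)
  variant_id <- sprintf("v%03d_%s_%d", seq_len(nv), chrom, pos)
  variant_id[causal_idx] <- sprintf("%s:g.%ddel%s", chrom, pos[causal_idx],
                                    del_seq)
  ref <- rep("A", nv); alt <- rep("G", nv)
  ref[causal_idx] <- paste0("A", del_seq); alt[causal_idx] <- "A"
  consequence <- rep("other", nv)
  score <- rep(NA_real_, nv)
  consequence[causal_idx] <- "frameshift"
  coding_pool <- setdiff(order(dist)[seq_len(min(8L, nv))], causal_idx)
  if (length(coding_pool) >= 4) {
    consequence[coding_pool[1:3]] <- "missense"
    score[coding_pool[1:3]] <- c(0.25, 0.41, 0.63)
    consequence[coding_pool[4]] <- "splice_acceptor"
  }
  variants <- tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, consequence = consequence,
                     score = score)
  genotypes <- tidyr::expand_grid(variant_id = variant_id,
                                  animal_id = seq_ids)
  genotypes$dosage <- as.integer(as.vector(t(geno)))
  list(variants = variants, genotypes = genotypes, animals = seq_ids)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat(sprintf("  genotyped panel : %d animals x %d markers\n",
              length(x$panel$animals), nrow(x$panel$markers)))
  cat(sprintf("  pedigree        : %d animals over %d generations\n",
              nrow(x$pedigree), max(x$pedigree$generation)))
  cat(sprintf("  litters         : %d (%d piglets)\n", nrow(x$litters),
              nrow(x$piglets)))
  cat(sprintf("  sequenced subset: %d animals x %d variants\n",
              length(x$wgs$animals), nrow(x$wgs$variants)))
  invisible(x)
}
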