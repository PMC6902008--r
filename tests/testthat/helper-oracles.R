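# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (no log-space tricks, no sparse algebra).

# HWE conditional exact test by direct enumeration with choose() weights.
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  n_minor <- min(2 * nAA + nAB, 2 * nBB + nAB)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  w <- vapply(hs, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    choose(n, h) * choose(n - h, hom_min) * 2^h
  }, 0.0)
  p <- w / sum(w)
  sum(p[p <= p[hs == nAB] * (1 + 1e-9)])
}

# Lower-tail binomial probability by plain summation.
binom_lower_oracle <- function(n, f, k) {
  sum(dbinom(0:k, n, f^2))
}

# Exact multinomial p by recursive enumeration with prod() probabilities.
multinom_oracle <- function(counts, probs) {
  n <- sum(counts)
  k <- length(counts)
  p_of <- function(x) factorial(n) / prod(factorial(x)) * prod(probs^x)
  enum <- function(left, slots) {
    if (slots == 1) return(matrix(left, ncol = 1))
    do.call(rbind, lapply(0:left, function(i) {
      cbind(i, enum(left - i, slots - 1), deparse.level = 0)
    }))
  }
  outcomes <- enum(n, k)
  pr <- apply(outcomes, 1, p_of)
  obs <- p_of(counts)
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Additive relationship by the textbook recursion, memoised.
a_matrix_recursive <- function(pedigree) {
  ped <- lethalscan::sort_pedigree(pedigree)
  ids <- ped$animal_id
  sire <- setNames(ped$sire_id, ids)
  dam <- setNames(ped$dam_id, ids)
  memo <- new.env()
  rel <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    ix <- match(x, ids); iy <- match(y, ids)
    val <- if (ix == iy) {
      1 + 0.5 * rel(sire[[x]], dam[[x]])
    } else {
      # recurse on the younger animal
      if (ix < iy) { tmp <- x; x <- y; y <- tmp }
      0.5 * (rel(sire[[x]], y) + rel(dam[[x]], y))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- rel(ids[i], ids[j])
  A
}

# Random valid pedigree: founders plus offspring of earlier animals.
random_pedigree <- function(n, n_founders = max(4, n %/% 4)) {
  ids <- sprintf("P%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    sire[i] <- ids[sample(i - 1, 1)]
    dam[i] <- ids[sample(i - 1, 1)]
  }
  tibble::tibble(animal_id = ids, sire_id = sire, dam_id = dam)
}

# Generalised least squares by direct dense inversion of the full
# phenotypic covariance, including the scale estimate used for SEs.
gls_oracle <- function(records, pedigree, ratio) {
  A <- lethalscan::build_a_matrix(pedigree)
  idx <- match(records$animal_id, colnames(A))
  w <- if ("weight" %in% names(records)) records$weight else rep(1, nrow(records))
  V <- ratio * A[idx, idx] + diag(1 / w)
  X <- cbind(1, records$dosage)
  y <- records$debv
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  bcov <- solve(XtVi %*% X)
  b <- bcov %*% XtVi %*% y
  P <- Vi - Vi %*% X %*% bcov %*% XtVi
  s2 <- as.numeric(t(y) %*% P %*% y) / (nrow(X) - ncol(X))
  list(estimate = as.vector(b), se = sqrt(diag(bcov) * s2))
}

# Small in-memory phased panel from a list of per-animal haplotype pairs,
# e.g. panel_from(list(c("01","01"), c("01","10"))).
panel_from <- function(pairs, chrom = "1") {
  m <- nchar(pairs[[1]][1])
  hap <- do.call(rbind, lapply(pairs, function(p) {
    rbind(as.integer(strsplit(p[1], "")[[1]]),
          as.integer(strsplit(p[2], "")[[1]]))
  }))
  mk <- tibble::tibble(marker_id = paste0("m", seq_len(m)), chrom = chrom,
                       pos = seq_len(m) * 1000L)
  lethalscan::phased_panel(mk, paste0("a", seq_along(pairs)), hap)
}

revcomp_for_test <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# All genotype-count triples summing to n.
compositions_for_test <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) {
    out[[length(out) + 1L]] <- c(a, b, n - a - b)
  }
  do.call(rbind, out)
}

# Memoised simulations shared across tests (built on first use).
.fixture_cache <- new.env()
cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

sim_small <- function() {
  cached("sim_small", simulate_population(simulation_config(
    n_founders = 300, n_generations = 3, max_litters_per_generation = 150,
    markers_per_chromosome = 300, n_chromosomes = 2, seed = 7)))
}

sim_null <- function() {
  cached("sim_null", simulate_population(simulation_config(
    n_founders = 300, n_generations = 2, max_litters_per_generation = 150,
    markers_per_chromosome = 150, n_chromosomes = 2,
    lethal_allele_freq = 0, seed = 13)))
}

# Study-scale run used by the acceptance checks (25k genotyped animals,
# 2,000 markers over five chromosomes).
sim_study <- function() {
  cached("sim_study", simulate_population(simulation_config(
    markers_per_chromosome = 400, n_chromosomes = 5,
    p_stillborn_given_homozygote = 0, p_death_48h_given_homozygote = 1,
    seed = 101)))
}
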