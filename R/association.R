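#' Topologically sort a pedigree
#'
#' Orders animals so every parent precedes its offspring; errors on cycles
#' or parents missing from the table (unknown parents are `NA`).
#'
#' @param pedigree A data frame with `animal_id`, `sire_id`, `dam_id`.
#' @return The pedigree tibble in topological order.
#' @export
sort_pedigree <- function(pedigree) {
  ped <- as_tibble(pedigree)
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(ped)))
  if (anyDuplicated(ped$animal_id)) abort("animal appears twice in pedigree")
  known <- ped$animal_id
  bad <- setdiff(c(ped$sire_id, ped$dam_id), c(known, NA))
  if (length(bad) > 0) {
    abort(paste0("parents absent from pedigree: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  n <- nrow(ped)
  sidx <- match(ped$sire_id, ped$animal_id)
  didx <- match(ped$dam_id, ped$animal_id)
  placed <- logical(n)
  order_idx <- integer(0)
  remaining <- seq_len(n)
  while (length(remaining) > 0) {
    ready <- remaining[(is.na(sidx[remaining]) | placed[sidx[remaining]]) &
                         (is.na(didx[remaining]) | placed[didx[remaining]])]
    if (length(ready) == 0) abort("pedigree contains a cycle")
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
    remaining <- remaining[!placed[remaining]]
  }
  ped[order_idx, , drop = FALSE]
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: founders have diagonal 1 (unknown parents assumed unrelated and
#' non-inbred), `a(i, j) = (a(j, sire_i) + a(j, dam_i)) / 2` for j preceding
#' i, and `a(i, i) = 1 + a(sire_i, dam_i) / 2`. Dense; intended for
#' pedigrees up to a few thousand animals (the model fit uses the sparse
#' inverse directly, see [a_inverse()]).
#'
#' @param pedigree A data frame with `animal_id`, `sire_id`, `dam_id` (`NA`
#'   for unknown parents); any order, sorted internally.
#' @return A symmetric matrix with animal ids as dimnames, in topological
#'   order.
#' @export
build_a_matrix <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- ifelse(is.na(ped$sire_id), 0L, idx[ped$sire_id])
  di <- ifelse(is.na(ped$dam_id), 0L, idx[ped$dam_id])
  A <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0) A[j, s] else rep(0, i - 1L)
      ad_ <- if (d > 0) A[j, d] else rep(0, i - 1L)
      A[j, i] <- A[i, j] <- (as_ + ad_) / 2
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i = a(sire_i, dam_i) / 2`, zero when either parent is unknown.
#' Computed from a tabular relationship matrix restricted to the ancestor
#' set (animals that appear as a parent), which keeps memory linear in the
#' number of parents rather than the full population.
#'
#' @param pedigree A data frame with `animal_id`, `sire_id`, `dam_id`.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  parents <- unique(stats::na.omit(c(ped$sire_id, ped$dam_id)))
  if (length(parents) == 0) {
    return(setNames(rep(0, nrow(ped)), ped$animal_id))
  }
  anc <- ped[ped$animal_id %in% parents, , drop = FALSE]
  Aanc <- build_a_matrix(anc)
  Fi <- setNames(rep(0, nrow(ped)), ped$animal_id)
  both <- !is.na(ped$sire_id) & !is.na(ped$dam_id)
  Fi[both] <- Aanc[cbind(ped$sire_id[both], ped$dam_id[both])] / 2
  Fi
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of A-inverse by Henderson's rules, accounting for
#' inbreeding through the Mendelian-sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F for one known parent, 1
#' for none).
#'
#' @param pedigree A data frame with `animal_id`, `sire_id`, `dam_id`.
#' @return A sparse symmetric [Matrix::Matrix()] with animal ids as
#'   dimnames, in topological order.
#' @export
a_inverse <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal_id)
  si <- ifelse(is.na(ped$sire_id), 0L, idx[ped$sire_id])
  di <- ifelse(is.na(ped$dam_id), 0L, idx[ped$dam_id])
  Fi <- unname(inbreeding(ped))
  Fs <- Fd <- numeric(n)
  Fs[si > 0] <- Fi[si[si > 0]]
  Fd[di > 0] <- Fi[di[di > 0]]
  d <- ifelse(si > 0 & di > 0, 0.5 - 0.25 * (Fs + Fd),
              ifelse(si > 0 | di > 0, 0.75 - 0.25 * (Fs + Fd), 1))
  alpha <- 1 / d
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  self <- seq_len(n)
  add(self, self, alpha)
  hs <- si > 0
  add(self[hs], si[hs], -alpha[hs] / 2)
  add(si[hs], self[hs], -alpha[hs] / 2)
  hd <- di > 0
  add(self[hd], di[hd], -alpha[hd] / 2)
  add(di[hd], self[hd], -alpha[hd] / 2)
  add(si[hs & hd], si[hs & hd], alpha[hs & hd] / 4)
  add(di[hs & hd], di[hs & hd], alpha[hs & hd] / 4)
  add(si[hs & hd], di[hs & hd], alpha[hs & hd] / 4)
  add(di[hs & hd], si[hs & hd], alpha[hs & hd] / 4)
  hs_only <- hs & !hd
  add(si[hs_only], si[hs_only], alpha[hs_only] / 4)
  hd_only <- hd & !hs
  add(di[hd_only], di[hd_only], alpha[hd_only] / 4)
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal_id, ped$animal_id))
  Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
}

#' Fit the weighted single-trait animal model for a carrier association
#'
#' Fits `y = mu + beta * dosage + a + e` where `y` is a deregressed breeding
#' value, `dosage` counts copies of the focal (detrimental) haplotype or
#' allele, `a ~ N(0, A sigma2_a)` is the additive genetic effect under the
#' pedigree relationship matrix, and the residual of animal `j` has variance
#' `sigma2_e / w_j` with its deregression weight `w_j`. The variance ratio
#' `sigma2_a / sigma2_e` is supplied (from the routine evaluation's
#' heritability), the mixed-model equations are solved sparsely, the
#' residual scale is estimated from the generalized residual sum of squares,
#' and the carrier effect is tested with a Wald z-test.
#'
#' @param records A data frame with `animal_id`, `debv`, `dosage` and
#'   optionally `weight` (default 1).
#' @param pedigree A pedigree covering at least the recorded animals.
#' @param additive_variance_ratio `sigma2_a / sigma2_e`. For heritability
#'   `h2` on a phenotypic scale this is `h2 / (1 - h2)`.
#' @return An object of class `animal_model_fit`; see [tidy.animal_model_fit()]
#'   and [glance.animal_model_fit()].
#' @export
fit_animal_model <- function(records, pedigree, additive_variance_ratio) {
  records <- as_tibble(records)
  stopifnot(all(c("animal_id", "debv", "dosage") %in% names(records)))
  if (additive_variance_ratio <= 0) abort("additive_variance_ratio must be > 0")
  if (anyDuplicated(records$animal_id)) abort("animal recorded twice")
  if (length(unique(records$dosage)) < 2) {
    abort("all animals share one dosage; carrier effect not estimable")
  }
  w <- records[["weight"]] %||% rep(1, nrow(records))
  if (any(w <= 0)) abort("weights must be positive")
  ped <- sort_pedigree(pedigree)
  missing_ped <- setdiff(records$animal_id, ped$animal_id)
  if (length(missing_ped) > 0) {
    abort(paste0("recorded animals absent from pedigree: ",
                 paste(utils::head(missing_ped, 5), collapse = ", ")))
  }
  n <- nrow(records)
  q <- nrow(ped)
  y <- records$debv
  X <- cbind(mu = 1, dosage = records$dosage)
  p <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(n),
                            j = match(records$animal_id, ped$animal_id),
                            x = 1, dims = c(n, q))
  Ainv <- a_inverse(ped)
  lambda <- 1 / additive_variance_ratio
  Wx <- X * w
  WZ <- Matrix::Diagonal(x = w) %*% Z
  C11 <- methods::as(methods::as(crossprod(X, Wx), "generalMatrix"),
                     "CsparseMatrix")
  C12 <- methods::as(methods::as(as.matrix(Matrix::crossprod(Wx, Z)),
                                 "generalMatrix"), "CsparseMatrix")
  C22 <- methods::as(Matrix::crossprod(Z, WZ) + lambda * Ainv,
                     "CsparseMatrix")
  C <- Matrix::forceSymmetric(rbind(cbind(C11, C12),
                                    cbind(Matrix::t(C12), C22)))
  rhs <- c(crossprod(X, w * y), as.vector(Matrix::crossprod(Z, w * y)))
  chol_C <- Matrix::Cholesky(C, LDL = FALSE, super = NA)
  sol <- as.vector(Matrix::solve(chol_C, rhs, system = "A"))
  b <- sol[seq_len(p)]
  a <- sol[-seq_len(p)]
  resid <- y - as.vector(X %*% b) - as.vector(Z %*% a)
  # generalized residual sum of squares with a known variance ratio
  rss <- sum(w * resid^2) + lambda * as.vector(a %*% (Ainv %*% a))
  sigma2_e <- rss / (n - p)
  E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                            dims = c(nrow(C), p))
  Cinv_fix <- Matrix::solve(chol_C, E, system = "A")
  vcov_b <- as.matrix(Cinv_fix[seq_len(p), , drop = FALSE]) * sigma2_e
  se <- sqrt(diag(vcov_b))
  z <- b / se
  logp <- (pnorm(-abs(z), log.p = TRUE) + log(2)) / log(10)
  coefs <- tibble(term = colnames(X), estimate = b, std.error = se,
                  statistic = z, p.value = 10^logp,
                  minus_log10_p = -logp)
  structure(
    list(coefficients = coefs, n = n, n_pedigree = q,
         additive_variance_ratio = additive_variance_ratio,
         sigma2_e = sigma2_e,
         n_carriers = sum(records$dosage >= 1),
         n_noncarriers = sum(records$dosage == 0),
         random_effects = tibble(animal_id = ped$animal_id, blup = a)),
    class = "animal_model_fit"
  )
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat(sprintf("Weighted animal model: %d records, %d pedigree animals, ratio %.3g\n",
              x$n, x$n_pedigree, x$additive_variance_ratio))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Tidy an animal-model fit
#'
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @return One row per fixed effect: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald z), `p.value`, `minus_log10_p`.
#' @export
tidy.animal_model_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of an animal-model fit
#'
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @return A tibble with the carrier-dosage effect, its test, sample sizes
#'   and the variance ratio used.
#' @export
glance.animal_model_fit <- function(x, ...) {
  d <- x$coefficients[x$coefficients$term == "dosage", ]
  tibble(effect = d$estimate, se = d$std.error,
         minus_log10_p = d$minus_log10_p,
         significant = d$minus_log10_p > 5,
         n = x$n, n_carriers = x$n_carriers,
         n_noncarriers = x$n_noncarriers,
         additive_variance_ratio = x$additive_variance_ratio,
         sigma2_e = x$sigma2_e)
}

#' Carrier association across traits
#'
#' Applies the input filters (deregression weight > 0, reliability > 0.20),
#' joins carrier dosages, and fits the weighted animal model per trait,
#' declaring significance at `-log10(p) > 5`.
#'
#' @param traits A data frame with `trait`, `animal_id`, `debv`,
#'   `reliability`, `weight` (a single-trait table without a `trait` column
#'   is accepted).
#' @param carriers A tibble with `animal_id`, `dosage`.
#' @param pedigree Pedigree covering the recorded animals.
#' @param heritability Named vector of per-trait heritabilities (a single
#'   unnamed value is recycled); converted to the variance ratio
#'   `h2 / (1 - h2)`.
#' @param min_reliability Reliability floor, exclusive (default 0.20).
#' @param min_animals Traits with fewer retained animals are skipped with a
#'   warning (default 100).
#' @return A tibble, one row per fitted trait, in the reporting layout:
#'   `trait`, `n_noncarriers`, `n_carriers`, `effect`, `se`,
#'   `minus_log10_p`, `significant`.
#' @export
run_association <- function(traits, carriers, pedigree, heritability,
                            min_reliability = 0.20, min_animals = 100) {
  traits <- as_tibble(traits)
  if (!"trait" %in% names(traits)) traits$trait <- "trait"
  if (!"weight" %in% names(traits)) traits$weight <- 1
  if (!"reliability" %in% names(traits)) traits$reliability <- 1
  keep <- traits |>
    dplyr::filter(.data$weight > 0, .data$reliability > min_reliability) |>
    dplyr::inner_join(dplyr::select(as_tibble(carriers), "animal_id",
                                    "dosage"),
                      by = "animal_id")
  trait_names <- unique(traits$trait)
  h2 <- if (is.null(names(heritability))) {
    setNames(rep_len(heritability, length(trait_names)), trait_names)
  } else {
    heritability
  }
  purrr::map_dfr(trait_names, function(tr) {
    df <- keep[keep$trait == tr, , drop = FALSE]
    if (nrow(df) < min_animals) {
      warn(sprintf("trait %s: %d retained animals (< %d); skipped", tr,
                   nrow(df), min_animals))
      return(NULL)
    }
    if (length(unique(df$dosage)) < 2) {
      warn(sprintf("trait %s: no dosage contrast among retained animals; skipped",
                   tr))
      return(NULL)
    }
    if (is.na(h2[tr])) abort(paste0("no heritability supplied for trait ", tr))
    fit <- fit_animal_model(df, pedigree, h2[[tr]] / (1 - h2[[tr]]))
    g <- glance(fit)
    tibble(trait = tr, n_noncarriers = g$n_noncarriers,
           n_carriers = g$n_carriers, effect = g$effect, se = g$se,
           minus_log10_p = g$minus_log10_p,
           significant = g$significant)
  })
}
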