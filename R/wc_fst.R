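# Weir & Cockerham (1984) per-locus Fst (theta) from the three variance
# components: a (among populations), b (among individuals within
# populations), c (within individuals).

# Core component computation for one locus, given per-population alternate
# frequencies p, non-missing genotype counts n, and observed heterozygote
# proportions h (populations with n == 0 already removed).
wc_components <- function(p, n, h) {
  r <- length(p)
  out <- c(a = NA_real_, b = NA_real_, c = NA_real_, theta = NA_real_)
  if (r < 2L || any(n < 1)) {
    return(list(components = out, r_used = r, reason = "fewer_than_2_populations"))
  }
  n_bar <- mean(n)
  if (n_bar <= 1) {
    return(list(components = out, r_used = r, reason = "mean_sample_size_le_1"))
  }
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- if (denom == 0) NA_real_ else a / denom
  reason <- if (denom == 0) "monomorphic" else NA_character_
  list(components = c(a = a, b = b, c = cc, theta = theta),
       r_used = r, reason = reason)
}

wc_one_locus <- function(freqs, locus, pops = NULL) {
  j <- match(locus, freqs$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  if (is.null(pops)) pops <- freqs$populations
  i <- match(pops, freqs$populations)
  if (anyNA(i)) stop("unknown population: ", paste(pops[is.na(i)], collapse = ", "))
  n <- freqs$n_geno[i, j]
  use <- n > 0  # populations with no calls are dropped, not imputed
  res <- wc_components(freqs$p[i, j][use], n[use], freqs$h_obs[i, j][use])
  data.frame(locus_id = locus,
             a = res$components[["a"]], b = res$components[["b"]],
             c = res$components[["c"]], theta = res$components[["theta"]],
             r_used = res$r_used, reason = res$reason,
             stringsAsFactors = FALSE)
}

#' Weir & Cockerham variance components and theta for one locus
#'
#' Computes the 1984 moment estimator from per-population allele frequencies,
#' sample sizes and observed heterozygote proportions. Populations with no
#' non-missing genotypes at the locus are dropped from the computation
#' (`r_used` is reduced accordingly). Theta is undefined (`NA`, with a
#' reason) for loci monomorphic across all contributing populations or when
#' fewer than two populations contribute.
#'
#' @param freqs A `pop_freqs` object from [allele_frequencies()].
#' @param locus A locus id present in `freqs`.
#' @return A one-row data frame with columns locus_id, a, b, c, theta,
#'   r_used, reason.
#' @export
wc_fst <- function(freqs, locus) {
  stopifnot(inherits(freqs, "pop_freqs"))
  wc_one_locus(freqs, locus)
}

#' Weir & Cockerham theta for every locus
#'
#' @param freqs A `pop_freqs` object.
#' @param loci Locus ids to compute (default: all loci in `freqs`).
#' @return A data frame with one row per locus (columns as in [wc_fst()]).
#' @export
wc_fst_all <- function(freqs, loci = NULL) {
  stopifnot(inherits(freqs, "pop_freqs"))
  if (is.null(loci)) loci <- freqs$loci
  out <- lapply(loci, function(l) wc_one_locus(freqs, l))
  do.call(rbind, out)
}

#' Pairwise Weir & Cockerham theta between two populations
#'
#' The same estimator restricted to two populations; a diagnostic for
#' population-pair differentiation at a locus.
#'
#' @param freqs A `pop_freqs` object.
#' @param locus A locus id.
#' @param pop_a,pop_b Population labels present in `freqs`.
#' @return A one-row data frame as in [wc_fst()].
#' @export
pairwise_wc_fst <- function(freqs, locus, pop_a, pop_b) {
  stopifnot(inherits(freqs, "pop_freqs"))
  if (pop_a == pop_b) stop("pop_a and pop_b must differ")
  wc_one_locus(freqs, locus, pops = c(pop_a, pop_b))
}
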