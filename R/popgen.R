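# Per-population allele frequencies, heterozygosity, QC filters and the
# within-population MAF spectrum.

#' Per-population allele frequencies
#'
#' For every (population, locus) cell, computes the alternate-allele
#' frequency `p = sum(calls) / (2 * n_geno)`, the number of non-missing
#' genotypes `n_geno`, and the observed heterozygote proportion
#' `h_obs = #(calls == 1) / n_geno`, all over non-missing genotypes only.
#' Cells with `n_geno == 0` carry `NA` frequencies (undefined, never 0).
#'
#' @param genotypes A [genotype_matrix()].
#' @param popmap A [pop_map()] covering exactly the genotyped individuals
#'   (see [join_genotypes()]).
#' @return An object of class `pop_freqs`: a list with `populations` (sorted
#'   labels), `loci`, and populations x loci matrices `p`, `n_geno`, `h_obs`.
#' @export
allele_frequencies <- function(genotypes, popmap) {
  stopifnot(is_genotype_matrix(genotypes), inherits(popmap, "pop_map"))
  ids <- rownames(genotypes)
  if (!setequal(ids, names(popmap))) {
    stop("genotypes and population map cover different individuals; ",
         "join them first (join_genotypes)")
  }
  labels <- unclass(popmap)[ids]
  pops <- sort(unique(labels))
  if (length(pops) < 2L) stop("per-population statistics need at least 2 populations")
  loci <- colnames(genotypes)
  m <- unclass(genotypes)
  p <- n_geno <- h_obs <- matrix(
    NA_real_, nrow = length(pops), ncol = length(loci),
    dimnames = list(pops, loci)
  )
  for (s in pops) {
    rows <- which(labels == s)
    if (length(rows) == 0L) stop("population with zero individuals: ", s)
    sub <- m[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    n_geno[s, ] <- n
    p[s, ] <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    h_obs[s, ] <- ifelse(n > 0, colSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
  }
  structure(list(populations = pops, loci = loci, p = p,
                 n_geno = n_geno, h_obs = h_obs),
            class = "pop_freqs")
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat(sprintf("pop_freqs: %d populations x %d loci\n",
              length(x$populations), length(x$loci)))
  invisible(x)
}

#' Expected heterozygosity (gene diversity)
#'
#' Gene diversity `1 - p^2 - (1-p)^2 = 2p(1-p)` per (population, locus),
#' optionally with the small-sample correction `2n/(2n-1)` so estimates match
#' the unbiased gene-diversity convention. With the correction, cells with
#' fewer than two genotypes are undefined (`NA`).
#'
#' @param freqs A `pop_freqs` object from [allele_frequencies()].
#' @param unbiased Apply the `2n/(2n-1)` correction (default `TRUE`).
#' @return A populations x loci matrix of expected heterozygosities.
#' @export
expected_heterozygosity <- function(freqs, unbiased = TRUE) {
  stopifnot(inherits(freqs, "pop_freqs"))
  he <- 2 * freqs$p * (1 - freqs$p)
  if (unbiased) {
    n <- freqs$n_geno
    he <- ifelse(n >= 2, he * (2 * n) / (2 * n - 1), NA_real_)
  }
  he
}

#' Locus quality control: call rate and pooled MAF
#'
#' Keeps loci whose overall (population-agnostic) call rate is strictly above
#' `call_rate_min` and whose pooled minor-allele frequency is strictly above
#' `maf_min`. Call rate is tested first, so each removed locus is attributed
#' to exactly one filter.
#'
#' @param genotypes A [genotype_matrix()].
#' @param call_rate_min Minimum call rate, exclusive (default 0.8).
#' @param maf_min Minimum pooled MAF, exclusive (default 0.05).
#' @return A list with `genotypes` (the filtered matrix) and `report`, a
#'   `qc_report` recording `n_loci_in`, `n_loci_out`,
#'   `removed_for_call_rate`, `removed_for_maf`, the thresholds, and a data
#'   frame `removed` of (locus_id, reason).
#' @export
qc_filter <- function(genotypes, call_rate_min = 0.8, maf_min = 0.05) {
  stopifnot(is_genotype_matrix(genotypes))
  m <- unclass(genotypes)
  n <- nrow(m)
  n_called <- colSums(!is.na(m))
  call_rate <- n_called / n
  fail_cr <- !(call_rate > call_rate_min)
  p <- ifelse(n_called > 0, colSums(m, na.rm = TRUE) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  fail_maf <- !fail_cr & !(!is.na(maf) & maf > maf_min)
  keep <- !fail_cr & !fail_maf
  removed <- data.frame(
    locus_id = colnames(m)[!keep],
    reason = ifelse(fail_cr[!keep], "call_rate", "maf"),
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_loci_in = ncol(m),
    n_loci_out = sum(keep),
    removed_for_call_rate = sum(fail_cr),
    removed_for_maf = sum(fail_maf),
    call_rate_min = call_rate_min,
    maf_min = maf_min,
    removed = removed
  ), class = "qc_report")
  if (!any(keep)) warning("QC removed every locus")
  list(genotypes = genotype_matrix(m[, keep, drop = FALSE]), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "QC: %d loci in, %d retained (call rate > %.2f, pooled MAF > %.2f)\n",
    "    removed: %d for call rate, %d for MAF\n"),
    x$n_loci_in, x$n_loci_out, x$call_rate_min, x$maf_min,
    x$removed_for_call_rate, x$removed_for_maf))
  invisible(x)
}

#' Within-population minor-allele-frequency spectrum
#'
#' Bins within-population MAF `min(p, 1-p)` into the fixed intervals
#' `[0,0.05), [0.05,0.1), ..., [0.45,0.5]` and counts loci with MAF strictly
#' above `breakpoint`. Loci with undefined frequency (no genotypes in that
#' population) are excluded from the histogram and counted separately.
#'
#' @param freqs A `pop_freqs` object.
#' @param breakpoint Strict MAF threshold for the high-MAF count (default 0.1).
#' @return An object of class `maf_spectrum`: list with `breaks`, a
#'   populations x bins `counts` matrix, and per-population vectors
#'   `n_above_breakpoint` and `n_undefined`.
#' @export
maf_spectrum <- function(freqs, breakpoint = 0.1) {
  stopifnot(inherits(freqs, "pop_freqs"))
  breaks <- seq(0, 0.5, by = 0.05)
  pops <- freqs$populations
  counts <- matrix(0L, nrow = length(pops), ncol = length(breaks) - 1L,
                   dimnames = list(pops, sprintf("[%.2f,%.2f)",
                                                 breaks[-length(breaks)], breaks[-1L])))
  n_above <- n_undef <- stats::setNames(integer(length(pops)), pops)
  for (s in pops) {
    maf <- pmin(freqs$p[s, ], 1 - freqs$p[s, ])
    n_undef[s] <- sum(is.na(maf))
    maf <- maf[!is.na(maf)]
    if (length(maf)) {
      counts[s, ] <- graphics::hist(maf, breaks = breaks, right = FALSE,
                                    include.lowest = TRUE, plot = FALSE)$counts
      n_above[s] <- sum(maf > breakpoint)
    }
  }
  structure(list(breaks = breaks, counts = counts, breakpoint = breakpoint,
                 n_above_breakpoint = n_above, n_undefined = n_undef),
            class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  cat(sprintf("maf_spectrum: %d populations; loci with MAF > %.2f:\n",
              nrow(x$counts), x$breakpoint))
  print(x$n_above_breakpoint)
  invisible(x)
}

#' Export per-(population, locus) statistics as a tidy data frame
#'
#' One row per (population, locus) with frequency, genotype count, observed
#' and expected heterozygosity; suitable for TSV export.
#'
#' @param freqs A `pop_freqs` object.
#' @param unbiased Passed to [expected_heterozygosity()].
#' @return A data frame with columns population, locus_id, p, n_geno, h_obs,
#'   h_exp.
#' @export
freqs_to_table <- function(freqs, unbiased = TRUE) {
  he <- expected_heterozygosity(freqs, unbiased = unbiased)
  data.frame(
    population = rep(freqs$populations, times = length(freqs$loci)),
    locus_id = rep(freqs$loci, each = length(freqs$populations)),
    p = as.vector(freqs$p),
    n_geno = as.vector(freqs$n_geno),
    h_obs = as.vector(freqs$h_obs),
    h_exp = as.vector(he),
    stringsAsFactors = FALSE
  )
}
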