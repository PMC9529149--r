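# Private-locus detection and resampling stability selection: the core of
# the panel-reduction procedure, plus the Fst filter and Table-1-style
# summaries.

#' Configuration for private-SNP panel selection
#'
#' @param seg_min Minimum frequency of the segregating allele in the host
#'   population (default 0.03); the host frequency must lie in
#'   `[seg_min, 1 - seg_min]` so near-fixed loci are not called private.
#' @param fixed_tol Maximum deviation from 0 or 1 for a non-host population
#'   to count as fixed (default 0, i.e. exactly fixed).
#' @param n_runs Number of resampling runs (default 100).
#' @param resample_fraction Fraction of each population drawn per run,
#'   without replacement, rounded up (default 0.8).
#' @param panel50_min_runs Strict lower bound on the stability count for the
#'   relaxed panel (default 50, i.e. detected in more than 50 runs).
#' @param panel80_min_runs Strict lower bound for the core panel (default 80).
#' @param fst_min Strict lower bound on per-locus theta for the Fst filter
#'   (default 0.7).
#' @param seed Integer seed driving the resampling (optional).
#' @return A validated list of class `selection_config`.
#' @export
selection_config <- function(seg_min = 0.03, fixed_tol = 0, n_runs = 100L,
                             resample_fraction = 0.8, panel50_min_runs = 50L,
                             panel80_min_runs = 80L, fst_min = 0.7,
                             seed = NULL) {
  stopifnot(seg_min > 0, seg_min < 0.5,
            fixed_tol >= 0, fixed_tol < 0.5,
            n_runs >= 1,
            resample_fraction > 0, resample_fraction <= 1,
            panel80_min_runs >= panel50_min_runs)
  structure(list(seg_min = seg_min, fixed_tol = fixed_tol,
                 n_runs = as.integer(n_runs),
                 resample_fraction = resample_fraction,
                 panel50_min_runs = as.integer(panel50_min_runs),
                 panel80_min_runs = as.integer(panel80_min_runs),
                 fst_min = fst_min, seed = seed),
            class = "selection_config")
}

#' Detect loci private to a single population
#'
#' A locus is private to population `s` iff (i) in `s` it is polymorphic
#' with segregating-allele frequency in `[seg_min, 1 - seg_min]`; (ii) every
#' other population with data is fixed (within `fixed_tol` of 0 or 1) for
#' the same allele; (iii) every population has at least one non-missing
#' genotype at the locus (missingness must not manufacture privacy). The
#' segregating allele is the one absent from the non-host populations, so
#' the reported `host_freq` is the alternate-allele frequency when non-host
#' populations are fixed for the reference allele, and `1 - p` otherwise.
#'
#' @param freqs A `pop_freqs` object over at least two populations.
#' @param config A [selection_config()].
#' @return A data frame with columns locus_id, host_population, host_freq
#'   (possibly zero rows).
#' @export
detect_private_loci <- function(freqs, config = selection_config()) {
  stopifnot(inherits(freqs, "pop_freqs"), inherits(config, "selection_config"))
  p <- freqs$p
  n <- freqs$n_geno
  tol <- config$fixed_tol
  eligible <- colSums(n == 0) == 0L
  fixed_ref <- !is.na(p) & p <= tol
  fixed_alt <- !is.na(p) & p >= 1 - tol
  seg <- !is.na(p) & !fixed_ref & !fixed_alt
  candidates <- which(eligible & colSums(seg) == 1L)
  rows <- lapply(candidates, function(j) {
    host <- which(seg[, j])
    others <- setdiff(seq_len(nrow(p)), host)
    if (all(fixed_ref[others, j])) {
      host_freq <- p[host, j]           # segregating allele = alternate
    } else if (all(fixed_alt[others, j])) {
      host_freq <- 1 - p[host, j]       # segregating allele = reference
    } else {
      return(NULL)                      # non-hosts fixed for different alleles
    }
    if (host_freq < config$seg_min || host_freq > 1 - config$seg_min) return(NULL)
    data.frame(locus_id = freqs$loci[j],
               host_population = freqs$populations[host],
               host_freq = host_freq, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(), host_population = character(),
                      host_freq = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Draw a per-population resample of individuals
#'
#' Draws `ceiling(fraction * n_s)` individuals without replacement from each
#' population (so a population of 5 keeps 4 at the default 0.8) and returns
#' the union.
#'
#' @param popmap A [pop_map()].
#' @param fraction Fraction of each population to keep (0 < fraction <= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [stability_select()]).
#' @return Character vector of sampled individual ids.
#' @export
resample_indices <- function(popmap, fraction, seed = NULL) {
  stopifnot(inherits(popmap, "pop_map"), fraction > 0, fraction <= 1)
  draw <- function() {
    by_pop <- split(names(popmap), unclass(popmap))
    too_small <- names(by_pop)[lengths(by_pop) < 2L]
    if (length(too_small)) {
      stop("population too small to resample (need >= 2): ",
           paste(too_small, collapse = ", "))
    }
    unlist(lapply(by_pop, function(ids) {
      ids[sample.int(length(ids), ceiling(fraction * length(ids)))]
    }), use.names = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Resampling stability selection of private loci
#'
#' Runs [detect_private_loci()] on the full data, then on `n_runs` random
#' per-population resamples, counting for each full-data private locus the
#' number of runs in which it is re-detected as private to the *same* host
#' population (a run calling a different host contributes nothing and is
#' logged). The relaxed and core panels keep loci detected in strictly more
#' than `panel50_min_runs` and `panel80_min_runs` runs respectively, so
#' `panel80` is always nested in `panel50`, which is nested in the full-data
#' panel.
#'
#' @param genotypes A quality-controlled [genotype_matrix()].
#' @param popmap A [pop_map()] joined to `genotypes`.
#' @param config A [selection_config()]; its `seed` drives the resampling.
#' @return An object of class `stability_panels`: list with `full_panel`
#'   (data frame from the full data), `counts` (named integer vector of
#'   stability counts), `detections` (loci x runs 0/1 matrix),
#'   `host_mismatches` (named count of runs detecting a different host),
#'   `panel50`, `panel80` (character vectors of locus ids) and `config`.
#' @export
stability_select <- function(genotypes, popmap, config = selection_config()) {
  stopifnot(is_genotype_matrix(genotypes), inherits(popmap, "pop_map"),
            inherits(config, "selection_config"))
  freqs_full <- allele_frequencies(genotypes, popmap)
  full_panel <- detect_private_loci(freqs_full, config)
  loci <- full_panel$locus_id
  host_of <- stats::setNames(full_panel$host_population, loci)
  detections <- matrix(0L, nrow = length(loci), ncol = config$n_runs,
                       dimnames = list(loci, NULL))
  mismatches <- stats::setNames(integer(length(loci)), loci)
  run_once <- function(run) {
    ids <- resample_indices(popmap, config$resample_fraction)
    sub <- subset_genotypes(genotypes, individuals = ids)
    calls <- detect_private_loci(allele_frequencies(sub, popmap[ids]), config)
    hit <- calls$locus_id %in% loci
    for (k in which(hit)) {
      l <- calls$locus_id[k]
      if (calls$host_population[k] == host_of[[l]]) {
        detections[l, run] <<- 1L
      } else {
        mismatches[[l]] <<- mismatches[[l]] + 1L
      }
    }
  }
  runs <- function() for (run in seq_len(config$n_runs)) run_once(run)
  if (is.null(config$seed)) runs() else withr::with_seed(config$seed, runs())
  counts <- stats::setNames(as.integer(rowSums(detections)), loci)
  structure(list(
    full_panel = full_panel,
    counts = counts,
    detections = detections,
    host_mismatches = mismatches,
    panel50 = loci[counts > config$panel50_min_runs],
    panel80 = loci[counts > config$panel80_min_runs],
    config = config
  ), class = "stability_panels")
}

#' @export
print.stability_panels <- function(x, ...) {
  cat(sprintf(paste0(
    "stability_panels: %d full-data private loci over %d runs\n",
    "  panel-50 (> %d runs): %d loci; panel-80 (> %d runs): %d loci\n"),
    nrow(x$full_panel), x$config$n_runs,
    x$config$panel50_min_runs, length(x$panel50),
    x$config$panel80_min_runs, length(x$panel80)))
  invisible(x)
}

#' Assemble panel entries with per-locus statistics
#'
#' Joins a stability-selection result with full-data frequencies and theta
#' values into the per-SNP panel table: within-host MAF, observed and
#' unbiased expected heterozygosity in the host, stability count and theta.
#'
#' @param stability A `stability_panels` object.
#' @param freqs Full-data `pop_freqs` (the same data the selection ran on).
#' @param fst Data frame from [wc_fst_all()] on the full data.
#' @param which Which panel to materialise: `"panel80"`, `"panel50"` or
#'   `"full"`.
#' @return A data frame with columns locus_id, host_population,
#'   stability_count, maf_within_host, theta, hobs_within_host,
#'   hexp_within_host.
#' @export
panel_entries <- function(stability, freqs, fst,
                          which = c("panel80", "panel50", "full")) {
  which <- match.arg(which)
  stopifnot(inherits(stability, "stability_panels"), inherits(freqs, "pop_freqs"))
  ids <- switch(which,
                panel80 = stability$panel80,
                panel50 = stability$panel50,
                full = stability$full_panel$locus_id)
  fp <- stability$full_panel
  rows <- fp[match(ids, fp$locus_id), , drop = FALSE]
  he <- expected_heterozygosity(freqs, unbiased = TRUE)
  pick <- function(mat) {
    vapply(seq_len(nrow(rows)), function(k) {
      mat[rows$host_population[k], rows$locus_id[k]]
    }, numeric(1L))
  }
  if (nrow(rows) == 0L) {
    return(data.frame(locus_id = character(), host_population = character(),
                      stability_count = integer(), maf_within_host = numeric(),
                      theta = numeric(), hobs_within_host = numeric(),
                      hexp_within_host = numeric(), stringsAsFactors = FALSE))
  }
  p_host <- pick(freqs$p)
  data.frame(
    locus_id = rows$locus_id,
    host_population = rows$host_population,
    stability_count = unname(stability$counts[rows$locus_id]),
    maf_within_host = pmin(p_host, 1 - p_host),
    theta = fst$theta[match(rows$locus_id, fst$locus_id)],
    hobs_within_host = pick(freqs$h_obs),
    hexp_within_host = pick(he),
    stringsAsFactors = FALSE
  )
}

#' Filter a panel by per-locus Weir & Cockerham theta
#'
#' Keeps entries with theta strictly above `fst_min`; entries with smaller or
#' undefined theta are returned in the exclusion list with a reason, mirroring
#' the removal of low-Fst private SNPs from the core panel.
#'
#' @param panel A panel data frame from [panel_entries()].
#' @param fst Data frame from [wc_fst_all()] on the full data over all
#'   populations.
#' @param fst_min Strict theta threshold (default 0.7).
#' @return List with `kept` and `excluded` data frames; `excluded` carries
#'   an extra `reason` column (`"low_theta"` or `"theta_undefined"`).
#' @export
apply_fst_filter <- function(panel, fst, fst_min = 0.7) {
  theta <- fst$theta[match(panel$locus_id, fst$locus_id)]
  panel$theta <- theta
  keep <- !is.na(theta) & theta > fst_min
  excluded <- panel[!keep, , drop = FALSE]
  excluded$reason <- ifelse(is.na(excluded$theta), "theta_undefined", "low_theta")
  list(kept = panel[keep, , drop = FALSE], excluded = excluded)
}

#' Per-population summary of a private-SNP panel
#'
#' One row per population: the number of private loci, the range and mean of
#' within-host MAF, mean observed and mean unbiased expected heterozygosity
#' (over that population's own private loci), and the theta range. A
#' population with no private loci gets `n_private = 0` and undefined
#' ranges.
#'
#' @param panel A panel data frame from [panel_entries()].
#' @param freqs Full-data `pop_freqs` (defines the set of populations).
#' @param loci Compute heterozygosity means over each population's `"own"`
#'   private loci (default) or over `"all"` panel loci.
#' @return A data frame with one row per population.
#' @export
summarize_panel <- function(panel, freqs, loci = c("own", "all")) {
  loci <- match.arg(loci)
  stopifnot(inherits(freqs, "pop_freqs"))
  he <- expected_heterozygosity(freqs, unbiased = TRUE)
  rows <- lapply(freqs$populations, function(s) {
    own <- panel[panel$host_population == s, , drop = FALSE]
    n_private <- nrow(own)
    if (loci == "own") {
      hobs <- own$hobs_within_host
      hexp <- own$hexp_within_host
    } else {
      hobs <- freqs$h_obs[s, panel$locus_id]
      hexp <- he[s, panel$locus_id]
    }
    rng <- function(x) if (length(x) == 0L || all(is.na(x))) c(NA_real_, NA_real_) else range(x, na.rm = TRUE)
    mn <- function(x) if (length(x) == 0L || all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    maf_r <- rng(own$maf_within_host)
    th_r <- rng(own$theta)
    data.frame(population = s, n_private = n_private,
               maf_min = maf_r[1L], maf_max = maf_r[2L],
               maf_mean = mn(own$maf_within_host),
               hobs_mean = mn(hobs), hexp_mean = mn(hexp),
               theta_min = th_r[1L], theta_max = th_r[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
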