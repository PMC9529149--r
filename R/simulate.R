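# Synthetic genotype generator: several populations with species-private
# segregating loci on top of a shared Balding-Nichols background, with a
# heterozygote-deficit (inbreeding-style) genotype draw, uneven sample
# sizes, missing calls, and optional conspecific label pairs drawn from one
# underlying population.

#' Configuration for the genotype simulator
#'
#' @param populations Data frame with columns `label` (sample label, e.g. a
#'   morphological species name), `size` (number of individuals, >= 2) and
#'   optionally `underlying` (underlying-population id; distinct labels may
#'   share an id to emulate conspecific label pairs; defaults to `label`).
#' @param n_shared_loci Number of shared loci segregating across populations.
#' @param shared_beta Shape parameters `c(alpha, beta)` of the Beta
#'   distribution of ancestral (base) allele frequencies for shared loci.
#' @param shared_freq_bounds Truncation interval for the base frequencies.
#' @param shared_divergence_theta Balding-Nichols drift parameter in (0,1):
#'   each underlying population's frequency at a shared locus is drawn from
#'   `Beta(p(1-t)/t, (1-p)(1-t)/t)` around the base frequency `p`.
#' @param n_private_per_pop Number of private loci planted per underlying
#'   population: host frequency uniform on `private_freq_range`, exactly 0
#'   in every other underlying population.
#' @param private_freq_range Interval for the host-population
#'   segregating-allele frequency of planted private loci.
#' @param inbreeding_f Heterozygote-deficit parameter F in `[0,1]`:
#'   genotypes are drawn with `P(het) = 2p(1-p)(1-F)`,
#'   `P(hom alt) = p^2 + p(1-p)F`, `P(hom ref) = (1-p)^2 + p(1-p)F`.
#' @param missing_rate Probability that any single call is missing
#'   (missing-completely-at-random), in `[0, 1)`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(populations,
                              n_shared_loci = 1740L,
                              shared_beta = c(0.5, 0.5),
                              shared_freq_bounds = c(0.05, 0.95),
                              shared_divergence_theta = 0.05,
                              n_private_per_pop = 15L,
                              private_freq_range = c(0.05, 0.48),
                              inbreeding_f = 0.95,
                              missing_rate = 0.05,
                              seed = NULL) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  if (!all(c("label", "size") %in% names(populations))) {
    stop("populations needs columns 'label' and 'size'")
  }
  if (is.null(populations$underlying)) populations$underlying <- populations$label
  if (anyDuplicated(populations$label)) stop("duplicate population label")
  if (any(populations$size < 2)) stop("every population needs size >= 2")
  stopifnot(n_shared_loci >= 0, n_private_per_pop >= 0,
            length(shared_beta) == 2L, all(shared_beta > 0),
            length(shared_freq_bounds) == 2L,
            shared_freq_bounds[1L] > 0, shared_freq_bounds[2L] < 1,
            shared_freq_bounds[1L] <= shared_freq_bounds[2L],
            shared_divergence_theta > 0, shared_divergence_theta < 1,
            length(private_freq_range) == 2L,
            private_freq_range[1L] > 0, private_freq_range[2L] < 1,
            private_freq_range[1L] <= private_freq_range[2L])
  if (inbreeding_f < 0 || inbreeding_f > 1) {
    stop("inbreeding_f must be in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  structure(list(populations = populations,
                 n_shared_loci = as.integer(n_shared_loci),
                 shared_beta = shared_beta,
                 shared_freq_bounds = shared_freq_bounds,
                 shared_divergence_theta = shared_divergence_theta,
                 n_private_per_pop = as.integer(n_private_per_pop),
                 private_freq_range = private_freq_range,
                 inbreeding_f = inbreeding_f,
                 missing_rate = missing_rate,
                 seed = seed),
            class = "simulation_config")
}

#' Demonstration configuration: seven labels, five underlying populations
#'
#' Mirrors the structure of a seven-species freshwater-prawn survey: labels
#' with sizes 18, 18, 18, 17, 12, 5 and 5 individuals, where two pairs of
#' morphological labels are conspecific (drawn from one underlying
#' population each), giving five underlying populations. Defaults elsewhere
#' reproduce the regime of that survey's panel: within-host MAF between 0.05
#' and about 0.48, strong heterozygote deficit (F = 0.95, observed
#' heterozygosity well below Hardy-Weinberg expectation), a low-MAF-dominated
#' shared-locus spectrum, and roughly 1,800 loci in total.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
demo_simulation_config <- function(seed = NULL, ...) {
  pops <- data.frame(
    label = c("sp_A", "sp_B", "sp_C", "sp_D", "sp_E", "sp_F", "sp_G"),
    size = c(18L, 18L, 18L, 17L, 12L, 5L, 5L),
    underlying = c("U1", "U2", "U1", "U2", "U3", "U4", "U5"),
    stringsAsFactors = FALSE
  )
  simulation_config(populations = pops, seed = seed, ...)
}

# Truncated Beta draws by inverse-CDF so truncation costs no rejection loop.
rbeta_trunc <- function(n, shape1, shape2, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape1, shape2),
                    stats::pbeta(hi, shape1, shape2))
  stats::qbeta(u, shape1, shape2)
}

#' Simulate a genotype dataset with planted private loci
#'
#' Shared loci: a base frequency is drawn from the truncated Beta, then each
#' underlying population's frequency from the Balding-Nichols distribution
#' around it. Private loci: the host underlying population's frequency is
#' uniform on `private_freq_range` and exactly 0 elsewhere. Genotypes are
#' drawn per individual with the inbreeding-style probabilities (see
#' [simulation_config()]); labels sharing an underlying id draw from
#' identical frequencies. Missing calls are applied uniformly at random.
#'
#' @param config A [simulation_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]), `popmap` (a
#'   [pop_map()]) and `truth` (a data frame with locus_id, kind,
#'   host_underlying_population and one `freq_<id>` column per underlying
#'   population holding the nominal frequencies).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  gen <- function() {
    pops <- config$populations
    upops <- unique(pops$underlying)
    nu <- length(upops)

    n_priv_total <- config$n_private_per_pop * nu
    freq <- matrix(0, nrow = nu, ncol = config$n_shared_loci + n_priv_total,
                   dimnames = list(upops, NULL))
    kind <- character(ncol(freq))
    host <- rep(NA_character_, ncol(freq))
    ids <- character(ncol(freq))

    if (config$n_shared_loci > 0L) {
      base <- rbeta_trunc(config$n_shared_loci,
                          config$shared_beta[1L], config$shared_beta[2L],
                          config$shared_freq_bounds[1L], config$shared_freq_bounds[2L])
      t <- config$shared_divergence_theta
      for (u in seq_len(nu)) {
        freq[u, seq_len(config$n_shared_loci)] <-
          stats::rbeta(config$n_shared_loci,
                       base * (1 - t) / t, (1 - base) * (1 - t) / t)
      }
      kind[seq_len(config$n_shared_loci)] <- "shared"
      ids[seq_len(config$n_shared_loci)] <-
        sprintf("shared_%04d", seq_len(config$n_shared_loci))
    }
    if (config$n_private_per_pop > 0L) {
      j <- config$n_shared_loci
      for (u in seq_len(nu)) {
        cols <- j + seq_len(config$n_private_per_pop)
        freq[u, cols] <- stats::runif(config$n_private_per_pop,
                                      config$private_freq_range[1L],
                                      config$private_freq_range[2L])
        kind[cols] <- "private"
        host[cols] <- upops[u]
        ids[cols] <- sprintf("priv_%s_%02d", upops[u],
                             seq_len(config$n_private_per_pop))
        j <- j + config$n_private_per_pop
      }
    }
    colnames(freq) <- ids
    if (ncol(freq) == 0L) stop("configuration yields zero loci")

    ind_pop <- rep(pops$label, pops$size)
    ind_under <- rep(pops$underlying, pops$size)
    ind_ids <- unlist(lapply(seq_len(nrow(pops)), function(i) {
      sprintf("%s_%02d", pops$label[i], seq_len(pops$size[i]))
    }), use.names = FALSE)
    n_ind <- length(ind_ids)

    pmat <- freq[match(ind_under, upops), , drop = FALSE]  # n_ind x L
    f <- config$inbreeding_f
    pq <- pmat * (1 - pmat)
    p0 <- (1 - pmat)^2 + pq * f
    p1 <- 2 * pq * (1 - f)
    u <- matrix(stats::runif(length(pmat)), nrow = n_ind)
    calls <- matrix(0L, nrow = n_ind, ncol = ncol(pmat))
    calls[u >= p0] <- 1L
    calls[u >= p0 + p1] <- 2L
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(calls)) < config$missing_rate,
                     nrow = n_ind)
      calls[miss] <- NA_integer_
    }

    truth <- data.frame(locus_id = ids, kind = kind,
                        host_underlying_population = host,
                        stringsAsFactors = FALSE)
    for (u_id in upops) truth[[paste0("freq_", u_id)]] <- freq[u_id, ]

    list(
      genotypes = genotype_matrix(calls, individual_ids = ind_ids, locus_ids = ids),
      popmap = pop_map(ind_pop, individual_ids = ind_ids),
      truth = truth
    )
  }
  if (is.null(config$seed)) gen() else withr::with_seed(config$seed, gen())
}

#' Write a simulated dataset as a set of fixture files
#'
#' Emits `genotypes.vcf` (synthetic chrom/pos metadata), `genotypes.tsv`,
#' `popmap.tsv` and `truth.tsv` into `out_dir`, overwriting deterministically.
#' All files are readable back without loss by the package's readers.
#'
#' @param config A [simulation_config()], or an already simulated dataset
#'   from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly; the
#'   simulated dataset is attached as attribute `"dataset"`.
#' @export
write_fixture <- function(config, out_dir) {
  sim <- if (inherits(config, "simulation_config")) simulate_dataset(config) else config
  stopifnot(is.list(sim), is_genotype_matrix(sim$genotypes))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    popmap = file.path(out_dir, "popmap.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_vcf(sim$genotypes, paths[["vcf"]])
  write_genotype_table(sim$genotypes, paths[["genotypes"]])
  write_population_map(sim$popmap, paths[["popmap"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(paths, "dataset") <- sim
  invisible(paths)
}
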