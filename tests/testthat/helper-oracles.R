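# Independent oracles and small fixture builders, kept deliberately naive:
# explicit loops and literal transcriptions of the defining formulas, so
# they share no code path with the package implementation.

# Build a genotype_matrix + pop_map from a list of per-population call
# matrices (rows = individuals, columns = loci).
make_dataset <- function(pop_calls, locus_ids = NULL) {
  mats <- lapply(pop_calls, as.matrix)
  n_loci <- ncol(mats[[1L]])
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(n_loci))
  calls <- do.call(rbind, mats)
  ind <- unlist(lapply(names(mats), function(s) {
    paste0(s, "_", seq_len(nrow(mats[[s]])))
  }))
  labels <- rep(names(mats), vapply(mats, nrow, integer(1L)))
  list(
    genotypes = genotype_matrix(calls, individual_ids = ind, locus_ids = locus_ids),
    popmap = pop_map(labels, individual_ids = ind)
  )
}

# Naive per-population frequency computation by explicit counting.
oracle_freqs <- function(genotypes, popmap) {
  pops <- sort(unique(unclass(popmap)))
  loci <- colnames(genotypes)
  out <- list()
  for (s in pops) {
    ids <- names(popmap)[unclass(popmap) == s]
    for (l in loci) {
      calls <- unclass(genotypes)[ids, l]
      calls <- calls[!is.na(calls)]
      n <- length(calls)
      out[[paste(s, l)]] <- data.frame(
        population = s, locus_id = l, n_geno = n,
        p = if (n > 0) sum(calls) / (2 * n) else NA_real_,
        h_obs = if (n > 0) sum(calls == 1) / n else NA_real_
      )
    }
  }
  do.call(rbind, out)
}

# Exhaustive enumeration of the private-locus rule, straight from its
# definition, one (locus, candidate host) pair at a time.
oracle_private_calls <- function(genotypes, popmap, seg_min = 0.03, fixed_tol = 0) {
  of <- oracle_freqs(genotypes, popmap)
  pops <- sort(unique(of$population))
  rows <- list()
  for (l in unique(of$locus_id)) {
    sub <- of[of$locus_id == l, ]
    if (any(sub$n_geno == 0)) next
    for (host in pops) {
      others <- sub[sub$population != host, ]
      p_host <- sub$p[sub$population == host]
      host_is_seg <- p_host > fixed_tol && p_host < 1 - fixed_tol
      if (!host_is_seg) next
      others_seg <- others$p > fixed_tol & others$p < 1 - fixed_tol
      if (any(others_seg)) next
      if (all(others$p <= fixed_tol)) {
        host_freq <- p_host
      } else if (all(others$p >= 1 - fixed_tol)) {
        host_freq <- 1 - p_host
      } else {
        next
      }
      if (host_freq >= seg_min && host_freq <= 1 - seg_min) {
        rows[[paste(l, host)]] <- data.frame(
          locus_id = l, host_population = host, host_freq = host_freq,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(), host_population = character(),
                      host_freq = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

# Literal transcription of the Weir & Cockerham (1984) component formulas,
# structured differently from the package implementation.
oracle_wc <- function(p, n, h) {
  r <- length(p)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n * n) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Assemble a pop_freqs object directly from p / n / h matrices, for analytic
# cases whose frequencies cannot arise from an integer genotype table.
make_pop_freqs <- function(p, n_geno, h_obs) {
  structure(list(populations = rownames(p), loci = colnames(p),
                 p = p, n_geno = n_geno, h_obs = h_obs),
            class = "pop_freqs")
}

random_genotype_matrix <- function(n_ind, n_loci, miss_rate = 0.1) {
  vals <- sample(c(0L, 0L, 0L, 1L, 2L, 2L), n_ind * n_loci, replace = TRUE)
  vals[stats::runif(length(vals)) < miss_rate] <- NA_integer_
  genotype_matrix(matrix(vals, nrow = n_ind),
                  individual_ids = paste0("i", seq_len(n_ind)),
                  locus_ids = paste0("L", seq_len(n_loci)))
}
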