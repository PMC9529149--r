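test_that("private-locus rule handles the canonical frequency patterns", {
  dn <- list(c("a", "b", "c"), paste0("L", 1:5))
  #         private  below-min two-seg no-seg  alt-fixed-elsewhere
  p <- cbind(c(0.4, 0, 0), c(0.02, 0, 0), c(0.4, 0.1, 0), c(1, 1, 0),
             c(0.6, 1, 1))
  dimnames(p) <- dn
  n <- matrix(10, 3, 5, dimnames = dn)
  h <- matrix(0, 3, 5, dimnames = dn)
  f <- make_pop_freqs(p, n, h)
  calls <- detect_private_loci(f, selection_config())
  expect_identical(calls$locus_id, c("L1", "L5"))
  expect_identical(calls$host_population, c("a", "a"))
  expect_equal(calls$host_freq, c(0.4, 1 - 0.6))  # segregating allele = reference at L5

  # a population with no data makes the locus ineligible
  n["c", 1L] <- 0
  p["c", 1L] <- NA
  f <- make_pop_freqs(p, n, h)
  expect_false("L1" %in% detect_private_loci(f)$locus_id)
})

test_that("host frequency near fixation is rejected symmetrically", {
  dn <- list(c("a", "b"), c("L1", "L2"))
  p <- cbind(c(0.98, 0), c(0.97, 0))
  dimnames(p) <- dn
  f <- make_pop_freqs(p, matrix(50, 2, 2, dimnames = dn),
                      matrix(0, 2, 2, dimnames = dn))
  calls <- detect_private_loci(f)
  expect_identical(calls$locus_id, "L2")   # 0.97 = 1 - seg_min allowed, 0.98 not
})

test_that("detection matches exhaustive enumeration on random small matrices", {
  withr::local_seed(2024L)
  for (rep in 1:60) {
    sizes <- sample(2:3, 3L, replace = TRUE)
    n_loci <- sample(1:10, 1L)
    g <- random_genotype_matrix(sum(sizes), n_loci, miss_rate = 0.15)
    pm <- pop_map(rep(c("pa", "pb", "pc"), sizes), individual_ids = rownames(g))
    f <- allele_frequencies(g, pm)
    got <- detect_private_loci(f, selection_config())
    got <- got[order(got$locus_id), , drop = FALSE]
    rownames(got) <- NULL
    want <- oracle_private_calls(g, pm)
    expect_identical(got$locus_id, want$locus_id)
    expect_identical(got$host_population, want$host_population)
    expect_equal(got$host_freq, want$host_freq)
  }
})

test_that("resampling draws ceil(fraction * n) per population, reproducibly", {
  pm <- pop_map(rep(c("A", "B", "C"), c(18L, 5L, 3L)),
                individual_ids = paste0("i", 1:26))
  ids <- resample_indices(pm, 0.8, seed = 9L)
  drawn <- table(unclass(pm)[ids])
  expect_identical(as.integer(drawn[c("A", "B", "C")]), c(15L, 4L, 3L))  # ceil(14.4), ceil(4), ceil(2.4)
  expect_identical(resample_indices(pm, 0.8, seed = 9L), ids)
  # fraction 1 returns everyone regardless of seed
  expect_setequal(resample_indices(pm, 1, seed = 1L), names(pm))
  # population below the minimum size errors with its name
  pm_small <- pop_map(c(x = "A", y = "A", z = "B"))
  expect_error(resample_indices(pm_small, 0.8, seed = 1L), "B")
})

test_that("a robust private locus is detected in every resampling run", {
  # host frequency 0.5 in a host of 20 with no missing data: every 16-subset
  # keeps the allele frequency far above the 0.03 floor
  host <- matrix(0L, 20, 1)
  host[1:10, 1] <- 2L
  ds <- make_dataset(list(hostpop = host, other1 = matrix(0L, 10, 1),
                          other2 = matrix(0L, 10, 1)))
  stab <- stability_select(ds$genotypes, ds$popmap,
                           selection_config(seed = 3L))
  expect_identical(unname(stab$counts["L1"]), 100L)
  expect_identical(stab$panel80, "L1")
})

test_that("panel membership uses strict count thresholds and panels nest across seeds", {
  # a locus detected in every run (count 100) is excluded by a strict
  # threshold equal to its count, included one below
  host <- matrix(0L, 20, 1)
  host[1:10, 1] <- 2L
  ds <- make_dataset(list(hostpop = host, other = matrix(0L, 10, 1)))
  st_strict <- stability_select(ds$genotypes, ds$popmap,
                                selection_config(seed = 4L,
                                                 panel50_min_runs = 99L,
                                                 panel80_min_runs = 100L))
  expect_identical(st_strict$panel50, "L1")       # 100 > 99
  expect_identical(st_strict$panel80, character())  # 100 > 100 is FALSE

  withr::local_seed(55L)
  for (seed in sample.int(1000L, 5L)) {
    cfg2 <- simulation_config(
      populations = data.frame(label = c("A", "B", "C"), size = c(8L, 6L, 6L)),
      n_shared_loci = 20L, n_private_per_pop = 3L,
      private_freq_range = c(0.1, 0.4), inbreeding_f = 0.5,
      missing_rate = 0.05, seed = seed)
    sim <- simulate_dataset(cfg2)
    st <- stability_select(sim$genotypes, sim$popmap,
                           selection_config(seed = seed + 1L))
    expect_true(all(st$panel80 %in% st$panel50))
    expect_true(all(st$panel50 %in% st$full_panel$locus_id))
    # determinism: same config and seed give identical counts
    st2 <- stability_select(sim$genotypes, sim$popmap,
                            selection_config(seed = seed + 1L))
    expect_identical(st2$counts, st$counts)
  }
})

test_that("the Fst filter is strict, keeps excluded loci with reasons", {
  panel <- data.frame(locus_id = c("L1", "L2", "L3"),
                      host_population = "a", stability_count = 90L,
                      maf_within_host = 0.3, theta = NA_real_,
                      hobs_within_host = 0, hexp_within_host = 0.4,
                      stringsAsFactors = FALSE)
  fst <- data.frame(locus_id = c("L1", "L2", "L3"),
                    theta = c(0.71, 0.70, NA))
  res <- apply_fst_filter(panel, fst, fst_min = 0.7)
  expect_identical(res$kept$locus_id, "L1")
  expect_identical(res$excluded$reason, c("low_theta", "theta_undefined"))
  # empty panel passes through
  res0 <- apply_fst_filter(panel[0L, ], fst, 0.7)
  expect_identical(nrow(res0$kept), 0L)
  expect_identical(nrow(res0$excluded), 0L)
})

test_that("panel summaries report per-population counts and ranges", {
  panel <- data.frame(
    locus_id = c("L1", "L2", "L3"),
    host_population = c("a", "a", "b"),
    stability_count = c(100L, 95L, 99L),
    maf_within_host = c(0.38, 0.2, 0.1),
    theta = c(0.85, 0.98, 0.9),
    hobs_within_host = c(0, 0.1, 0.05),
    hexp_within_host = c(0.47, 0.32, 0.18),
    stringsAsFactors = FALSE
  )
  dn <- list(c("a", "b", "c"), c("L1", "L2", "L3"))
  f <- make_pop_freqs(matrix(0.2, 3, 3, dimnames = dn),
                      matrix(10, 3, 3, dimnames = dn),
                      matrix(0.1, 3, 3, dimnames = dn))
  s <- summarize_panel(panel, f)
  expect_identical(s$n_private, c(2L, 1L, 0L))
  expect_equal(s$maf_min[1L], 0.2)
  expect_equal(s$maf_max[1L], 0.38)
  expect_equal(s$theta_min[1L], 0.85)
  expect_equal(s$theta_max[1L], 0.98)
  expect_equal(s$hobs_mean[1L], 0.05)
  expect_true(is.na(s$maf_min[3L]))  # population with no private loci
})
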