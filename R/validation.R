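# Panel validation: PCA, K-means/BIC cluster-number inference, DAPC
# (PCA dimension reduction followed by linear discriminant analysis with
# posterior membership probabilities), and assignment accuracy.

#' Mean-impute missing calls and center each locus
#'
#' Missing entries are replaced by the locus mean and every locus is then
#' centered to mean zero; constant loci become all-zero columns. This is the
#' standard preprocessing that lets PCA and DAPC run on genotype matrices
#' with missing data.
#'
#' @param genotypes A [genotype_matrix()]; every locus must have at least one
#'   non-missing call.
#' @return A list with `x` (the centered numeric matrix) and `locus_means`
#'   (the per-locus imputation/centering vector).
#' @export
impute_center <- function(genotypes) {
  stopifnot(is_genotype_matrix(genotypes))
  x <- unclass(genotypes)
  storage.mode(x) <- "double"
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    stop("locus with no non-missing calls: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  means <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- means[idx[, 2L]]
  x <- sweep(x, 2L, means)
  list(x = x, locus_means = means)
}

#' Principal component analysis of a centered genotype matrix
#'
#' Eigen-decomposition of the covariance of the centered matrix via SVD.
#' Axes are deterministic up to sign; the sign is fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param x Centered numeric matrix (individuals x loci), e.g. from
#'   [impute_center()].
#' @param n_components Number of axes to retain; at most
#'   `min(nrow(x) - 1, ncol(x))` (the default).
#' @return An object of class `pca_model`: list with `components` (loci x
#'   n_components orthonormal axes), `explained_variance` (all
#'   `min(n-1, L)` eigenvalues, non-increasing), `scores` (individuals x
#'   n_components) and `n_components`.
#' @export
pca_fit <- function(x, n_components = NULL) {
  n <- nrow(x)
  max_c <- min(n - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_c
  if (n_components > max_c) {
    stop("n_components must be <= min(n_individuals - 1, n_loci) = ", max_c)
  }
  sv <- svd(x)
  ev <- sv$d^2 / (n - 1)
  comps <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(comps))) {
    i0 <- which.max(abs(comps[, j]))
    if (comps[i0, j] < 0) comps[, j] <- -comps[, j]
  }
  scores <- x %*% comps
  rownames(comps) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(comps) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(components = comps,
                 explained_variance = ev[seq_len(max_c)],
                 scores = scores, n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$explained_variance)
  k <- min(3L, x$n_components)
  cat(sprintf("pca_model: %d components retained; PC1..PC%d explain %.1f%% of variance\n",
              x$n_components, k,
              100 * sum(x$explained_variance[seq_len(k)]) / tot))
  invisible(x)
}

# Best-of-restarts K-means; retries on the rare empty-cluster failure of the
# Hartigan-Wong algorithm.
kmeans_best <- function(scores, k, restarts, iter_max) {
  if (k == 1L) {
    centered <- sweep(scores, 2L, colMeans(scores))
    return(list(cluster = rep(1L, nrow(scores)), tot.withinss = sum(centered^2)))
  }
  for (attempt in seq_len(5L)) {
    fit <- tryCatch(
      stats::kmeans(scores, centers = k, nstart = restarts, iter.max = iter_max),
      error = function(e) e
    )
    if (!inherits(fit, "error")) return(fit)
  }
  stop("K-means degenerate for K = ", k, ": ", conditionMessage(fit))
}

#' K-means BIC scan over the number of clusters
#'
#' For each `K` in `1..k_max`, runs best-of-`restarts` K-means on the
#' retained principal-component scores and evaluates
#' `BIC(K) = n * log(W_K / n) + K * log(n)`, with `W_K` the total
#' within-cluster sum of squares. `chosen_k` is the argmin (ties broken
#' towards the smallest K); the full curve is returned so an elbow rule can
#' be applied externally.
#'
#' @param scores Individuals x components score matrix.
#' @param k_max Largest number of clusters to try; must be `< nrow(scores)`.
#' @param restarts Random restarts per K (default 50; K-means on many
#'   retained components is sensitive to its random start).
#' @param seed Optional integer seed.
#' @param iter_max K-means iteration cap (default 300).
#' @return An object of class `bic_curve`: list with `k_values`, `bic`,
#'   `withinss` and `chosen_k`.
#' @export
kmeans_bic_scan <- function(scores, k_max, restarts = 50L, seed = NULL,
                            iter_max = 300L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k_max >= n) stop("k_max must be smaller than the number of individuals")
  scan <- function() {
    w <- vapply(seq_len(k_max), function(k) {
      # with K >= the number of distinct points a zero-withinss clustering
      # exists; record W = 0 rather than failing the whole scan
      tryCatch(kmeans_best(scores, k, restarts, iter_max)$tot.withinss,
               error = function(e) {
                 if (grepl("distinct", conditionMessage(e))) 0 else stop(e)
               })
    }, numeric(1L))
    bic <- n * log(w / n) + seq_len(k_max) * log(n)
    structure(list(k_values = seq_len(k_max), bic = bic, withinss = w,
                   chosen_k = which.min(bic)),
              class = "bic_curve")
  }
  if (is.null(seed)) scan() else withr::with_seed(seed, scan())
}

#' @export
print.bic_curve <- function(x, ...) {
  cat("bic_curve: K =", paste(x$k_values, collapse = " "),
      "\n  BIC:", paste(sprintf("%.1f", x$bic), collapse = " "),
      "\n  chosen K =", x$chosen_k, "\n")
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA dimension reduction followed by linear discriminant analysis on the
#' retained scores, yielding posterior membership probabilities under equal
#' cluster priors (so sample-size imbalance between species does not bias
#' the posterior). Cluster labels may be supplied, or inferred by K-means on
#' the retained scores when only `k` is given.
#'
#' @param x Centered numeric matrix from [impute_center()].
#' @param grouping Optional factor/vector of cluster labels per individual.
#' @param k Number of clusters, required when `grouping` is `NULL`.
#' @param n_pca Number of principal components retained for the discriminant
#'   step; default: the smallest number explaining at least 90% of variance,
#'   capped at `n - k - 1`.
#' @param n_da Number of discriminant axes (default `k - 1`).
#' @param restarts K-means restarts when clusters are inferred (default 50).
#' @param seed Optional integer seed for the K-means step.
#' @param lda_tol Tolerance passed to [MASS::lda()] (default 1e-9; the
#'   leading PCs of well-separated panels have very small within-group
#'   variance, which the default tolerance would reject as constant).
#' @return An object of class `dapc_model`: list with `k`,
#'   `n_pca_retained`, `n_da`, `cluster_labels` (integers in 1..k),
#'   `cluster_levels`, `discriminant_axes` (retained-PC space x n_da),
#'   `memberships` (individuals x k posterior matrix, rows summing to 1),
#'   `pca` (the underlying `pca_model`) and `grouping_given`.
#' @export
dapc_fit <- function(x, grouping = NULL, k = NULL, n_pca = NULL, n_da = NULL,
                     restarts = 50L, seed = NULL, lda_tol = 1e-9) {
  n <- nrow(x)
  pca <- pca_fit(x)
  ev <- pca$explained_variance
  pick_n_pca <- function(k) {
    m <- if (is.null(n_pca)) {
      cum <- cumsum(ev) / sum(ev)
      which(cum >= 0.9)[1L]
    } else n_pca
    max(1L, min(m, n - k - 1L, pca$n_components))
  }
  grouping_given <- !is.null(grouping)
  if (grouping_given) {
    grouping <- factor(grouping)
    if (length(grouping) != n) stop("grouping length does not match individuals")
    k <- nlevels(grouping)
  } else {
    if (is.null(k)) stop("either grouping or k must be given")
    m_clust <- pick_n_pca(k)
    run_km <- function() kmeans_best(pca$scores[, seq_len(m_clust), drop = FALSE],
                                     k, restarts, 300L)$cluster
    cl <- if (is.null(seed)) run_km() else withr::with_seed(seed, run_km())
    grouping <- factor(cl, levels = sort(unique(cl)))
  }
  if (k < 2L) stop("DAPC needs at least 2 clusters")
  m <- pick_n_pca(k)
  if (is.null(n_da)) n_da <- k - 1L
  n_da <- min(n_da, k - 1L, m)
  scores <- pca$scores[, seq_len(m), drop = FALSE]
  fit <- tryCatch(
    MASS::lda(scores, grouping = grouping, prior = rep(1 / k, k), tol = lda_tol),
    error = function(e) {
      stop("discriminant fit failed (", conditionMessage(e),
           "); try a smaller n_pca", call. = FALSE)
    }
  )
  pred <- stats::predict(fit, scores)
  memberships <- pred$posterior
  rownames(memberships) <- rownames(x)
  structure(list(
    k = k,
    n_pca_retained = m,
    n_da = n_da,
    cluster_labels = as.integer(grouping),
    cluster_levels = levels(grouping),
    discriminant_axes = fit$scaling[, seq_len(min(n_da, ncol(fit$scaling))), drop = FALSE],
    memberships = memberships,
    pca = pca,
    grouping_given = grouping_given
  ), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("dapc_model: %d clusters, %d PCs retained, %d discriminant axes\n",
              x$k, x$n_pca_retained, ncol(x$discriminant_axes)))
  cat(sprintf("  mean max posterior membership: %.3f\n",
              mean(apply(x$memberships, 1L, max))))
  invisible(x)
}

# All injective maps from k clusters to labels, maximizing the confusion
# trace; exact enumeration for small k, greedy otherwise.
best_cluster_mapping <- function(confusion) {
  labels <- rownames(confusion)
  k <- ncol(confusion)
  if (k <= 8L && length(labels) <= 8L) {
    best <- NULL
    best_score <- -1
    assign_rec <- function(col, used, map, score) {
      if (col > k) {
        if (score > best_score) {
          best_score <<- score
          best <<- map
        }
        return()
      }
      # leaving a cluster unmatched is allowed (counts as all errors)
      assign_rec(col + 1L, used, c(map, NA_character_), score)
      for (l in setdiff(labels, used)) {
        assign_rec(col + 1L, c(used, l), c(map, l), score + confusion[l, col])
      }
    }
    assign_rec(1L, character(), character(), 0)
    return(stats::setNames(best, colnames(confusion)))
  }
  # greedy fallback: repeatedly take the largest remaining cell
  map <- stats::setNames(rep(NA_character_, k), colnames(confusion))
  cf <- confusion
  while (any(cf > -1)) {
    ij <- which(cf == max(cf), arr.ind = TRUE)[1L, ]
    map[colnames(cf)[ij[2L]]] <- rownames(cf)[ij[1L]]
    cf[ij[1L], ] <- -1
    cf[, ij[2L]] <- -1
    if (all(cf < 0)) break
  }
  map
}

#' Assignment accuracy of a DAPC clustering against true labels
#'
#' Maps inferred clusters to true population labels (majority vote per
#' cluster, or optimal one-to-one matching maximizing the confusion-matrix
#' trace) and reports the fraction of individuals whose mapped cluster
#' equals their true label. Under the one-to-one policy, clusters left
#' unmatched (more clusters than labels) count all their individuals as
#' errors; under majority vote, two clusters may map to the same label, in
#' which case the minority-label individuals are errors.
#'
#' @param model A `dapc_model`.
#' @param truth A [pop_map()] covering the same individuals.
#' @param label_policy `"optimal"` (default) or `"majority"`.
#' @return An object of class `assignment_result`: list with `confusion`
#'   (true label x cluster counts), `mapping` (cluster -> label), `accuracy`
#'   and `mean_max_membership`.
#' @export
assignment_accuracy <- function(model, truth,
                                label_policy = c("optimal", "majority")) {
  label_policy <- match.arg(label_policy)
  stopifnot(inherits(model, "dapc_model"), inherits(truth, "pop_map"))
  ids <- rownames(model$memberships)
  if (!all(ids %in% names(truth))) {
    stop("truth labels missing for: ",
         paste(utils::head(setdiff(ids, names(truth)), 3L), collapse = ", "))
  }
  true_labels <- unclass(truth)[ids]
  clusters <- factor(model$cluster_labels, levels = seq_len(model$k))
  confusion <- table(truth = true_labels, cluster = clusters)
  mapping <- if (label_policy == "optimal") {
    best_cluster_mapping(confusion)
  } else {
    stats::setNames(rownames(confusion)[apply(confusion, 2L, which.max)],
                    colnames(confusion))
  }
  mapped <- mapping[as.character(model$cluster_labels)]
  accuracy <- mean(!is.na(mapped) & mapped == true_labels)
  structure(list(confusion = confusion, mapping = mapping,
                 accuracy = accuracy,
                 mean_max_membership = mean(apply(model$memberships, 1L, max))),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment_result: accuracy %.3f, mean max membership %.3f\n",
              x$accuracy, x$mean_max_membership))
  print(x$confusion)
  invisible(x)
}
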