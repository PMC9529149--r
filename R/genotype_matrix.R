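#' Construct a genotype matrix
#'
#' The single substrate of the whole pipeline: an individuals x loci matrix of
#' alternate-allele counts. Each entry is 0 (homozygous reference), 1
#' (heterozygous), 2 (homozygous alternate) or `NA` (missing call).
#'
#' @param calls A matrix with one row per individual and one column per locus;
#'   entries must be in `{0, 1, 2, NA}`.
#' @param individual_ids Character vector of unique individual identifiers
#'   (defaults to `rownames(calls)`).
#' @param locus_ids Character vector of unique locus identifiers (defaults to
#'   `colnames(calls)`).
#' @return An integer matrix of class `genotype_matrix` with individuals as
#'   row names and loci as column names.
#' @examples
#' g <- genotype_matrix(rbind(ind1 = c(L1 = 0, L2 = 2), ind2 = c(1, NA)))
#' @export
genotype_matrix <- function(calls, individual_ids = rownames(calls),
                            locus_ids = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (is.null(individual_ids) && nrow(calls) == 0L) individual_ids <- character()
  if (is.null(locus_ids) && ncol(calls) == 0L) locus_ids <- character()
  if (is.null(individual_ids) || is.null(locus_ids)) {
    stop("genotype matrix needs individual and locus identifiers")
  }
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (length(individual_ids) != nrow(calls)) {
    stop("length of individual_ids does not match the number of rows")
  }
  if (length(locus_ids) != ncol(calls)) {
    stop("length of locus_ids does not match the number of columns")
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual id: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus id: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  }
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    bad <- utils::head(unique(vals[!vals %in% c(0L, 1L, 2L)]), 3L)
    stop("genotype calls must be 0, 1, 2 or NA; found: ",
         paste(bad, collapse = ", "))
  }
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(individual_ids, locus_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' Subset a genotype matrix by locus or individual ids
#'
#' @param genotypes A [genotype_matrix()].
#' @param loci,individuals Character vectors of ids to keep (either may be
#'   `NULL` to keep all). Unknown ids are an error listing the missing ids.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(genotypes, loci = NULL, individuals = NULL) {
  stopifnot(is_genotype_matrix(genotypes))
  m <- unclass(genotypes)
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, rownames(m))
    if (length(missing_ids)) {
      stop("unknown individual ids: ", paste(missing_ids, collapse = ", "))
    }
    m <- m[individuals, , drop = FALSE]
  }
  if (!is.null(loci)) {
    missing_ids <- setdiff(loci, colnames(m))
    if (length(missing_ids)) {
      stop("loci absent from the genotype matrix: ",
           paste(missing_ids, collapse = ", "))
    }
    m <- m[, loci, drop = FALSE]
  }
  genotype_matrix(m)
}

#' Construct a population map
#'
#' Assigns every individual to exactly one population (species) label; the
#' grouping used by all per-population statistics.
#'
#' @param labels Character vector of population labels, named by individual id
#'   (or unnamed, with `individual_ids` supplied). Labels are stripped of
#'   surrounding whitespace.
#' @param individual_ids Optional character vector of individual ids.
#' @return A named character vector of class `pop_map`.
#' @export
pop_map <- function(labels, individual_ids = names(labels)) {
  if (is.null(individual_ids)) stop("population map needs individual ids")
  individual_ids <- trimws(as.character(individual_ids))
  labels <- trimws(as.character(labels))
  if (length(labels) != length(individual_ids)) {
    stop("labels and individual_ids differ in length")
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("empty or missing population label")
  }
  dup <- duplicated(individual_ids)
  if (any(dup)) {
    first <- labels[match(individual_ids[dup], individual_ids)]
    if (any(first != labels[dup])) {
      bad <- individual_ids[dup][first != labels[dup]]
      stop("conflicting population labels for individual(s): ",
           paste(unique(bad), collapse = ", "))
    }
    labels <- labels[!dup]
    individual_ids <- individual_ids[!dup]
  }
  structure(stats::setNames(labels, individual_ids), class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  tab <- table(unclass(x))
  cat(sprintf("pop_map: %d individuals in %d populations\n", length(x), length(tab)))
  print(tab)
  invisible(x)
}

#' @export
`[.pop_map` <- function(x, i, ...) {
  y <- NextMethod()
  class(y) <- "pop_map"
  y
}

#' Align a genotype matrix with a population map
#'
#' @param genotypes A [genotype_matrix()].
#' @param popmap A [pop_map()].
#' @param policy `"strict"` errors unless the two id sets are identical;
#'   `"intersect"` restricts both objects to the common ids, preserving the
#'   genotype-matrix order.
#' @return A list with elements `genotypes`, `popmap`,
#'   `dropped_individuals` (ids present only in the genotypes) and
#'   `dropped_from_popmap` (ids present only in the map).
#' @export
join_genotypes <- function(genotypes, popmap, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(is_genotype_matrix(genotypes), inherits(popmap, "pop_map"))
  gid <- rownames(genotypes)
  pid <- names(popmap)
  common <- intersect(gid, pid)
  if (length(common) == 0L) stop("genotypes and population map share no individuals")
  if (policy == "strict" && (length(common) != length(gid) || length(common) != length(pid))) {
    stop("id sets differ (", length(setdiff(gid, pid)), " only in genotypes, ",
         length(setdiff(pid, gid)), " only in popmap); use policy = 'intersect'")
  }
  keep <- gid[gid %in% common]
  out <- list(
    genotypes = subset_genotypes(genotypes, individuals = keep),
    popmap = popmap[keep],
    dropped_individuals = setdiff(gid, common),
    dropped_from_popmap = setdiff(pid, common)
  )
  if (length(out$dropped_individuals) || length(out$dropped_from_popmap)) {
    message(sprintf("join: dropped %d genotyped individual(s) and %d map entrie(s)",
                    length(out$dropped_individuals), length(out$dropped_from_popmap)))
  }
  out
}
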