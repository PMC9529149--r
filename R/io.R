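# File input/output: VCF and TSV genotype matrices, population maps,
# panel tables. All tabular outputs are plain TSV so every stage can be
# re-read without loss.

gt_codes <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Read genotypes from a VCF file
#'
#' Parses GT fields of biallelic SNP records into alternate-allele counts.
#' Missing and half-missing calls (`./.`, `./1`, ...) become `NA`; phased and
#' unphased separators are treated identically. When a record has no ID the
#' locus id is `chrom:pos:ref:alt`.
#'
#' @param path Path to a VCF (v4.x) file with GT in FORMAT.
#' @param multiallelic Policy for records with more than one ALT allele:
#'   `"skip"` (default) drops them with a warning, `"error"` aborts.
#' @return A list with `genotypes` (a [genotype_matrix()]), `metadata` (a
#'   data frame with locus_id, chrom, pos, ref, alt) and `n_skipped` (count
#'   of non-biallelic records dropped).
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path)
  # vcfR is lenient about ragged records; pre-scan so a malformed line is
  # reported with its line number.
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) stop("malformed VCF: no #CHROM header line")
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  if (nfield < 10L) stop("VCF has no sample columns")
  body <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
  if (length(body)) {
    counts <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    bad <- body[counts != nfield & nzchar(lines[body])]
    if (length(bad)) {
      stop(sprintf("malformed VCF line %d: expected %d fields, found %d",
                   bad[1L], nfield, counts[match(bad[1L], body)]))
    }
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("empty input: VCF contains no variant records")

  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & alt != "." & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0L) {
    if (multiallelic == "error") {
      stop(n_skipped, " non-biallelic record(s) present")
    }
    warning("skipped ", n_skipped, " non-biallelic record(s)")
  }
  if (!any(biallelic)) stop("empty input: no biallelic SNP records")

  fix <- fix[biallelic, , drop = FALSE]
  gt <- vcf@gt[biallelic, , drop = FALSE]
  fmt <- gt[, 1L]
  samples <- colnames(gt)[-1L]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1L))
  if (anyNA(gt_idx)) stop("record without GT in FORMAT")

  raw <- gt[, -1L, drop = FALSE]
  calls <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw))
  for (i in seq_len(nrow(raw))) {
    g <- vapply(strsplit(raw[i, ], ":", fixed = TRUE), function(f) {
      if (length(f) >= gt_idx[i]) f[gt_idx[i]] else NA_character_
    }, character(1L))
    code <- gt_codes[g]
    unknown <- !is.na(g) & is.na(code) & !grepl(".", g, fixed = TRUE)
    if (any(unknown)) {
      stop("unparseable GT value '", g[unknown][1L], "' in biallelic record ",
           fix[i, "CHROM"], ":", fix[i, "POS"])
    }
    calls[i, ] <- unname(code)  # anything containing '.' stays NA
  }

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste(fix[no_id, "CHROM"], fix[no_id, "POS"],
                      fix[no_id, "REF"], fix[no_id, "ALT"], sep = ":")
  metadata <- data.frame(
    locus_id = ids, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  list(
    genotypes = genotype_matrix(t(calls), individual_ids = samples, locus_ids = ids),
    metadata = metadata,
    n_skipped = n_skipped
  )
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 file with GT-only records. When no locus metadata is
#' given, synthetic coordinates are used (chrom `"1"`, pos = column index,
#' REF `A`, ALT `G`); these carry no biological meaning.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param metadata Optional data frame as returned by [read_vcf()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path, metadata = NULL) {
  stopifnot(is_genotype_matrix(genotypes))
  loci <- colnames(genotypes)
  if (is.null(metadata)) {
    metadata <- data.frame(locus_id = loci, chrom = "1", pos = seq_along(loci),
                           ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  metadata <- metadata[match(loci, metadata$locus_id), ]
  gt_str <- c("0/0", "0/1", "1/1")
  m <- unclass(genotypes)
  body <- vapply(seq_along(loci), function(j) {
    g <- m[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(metadata$chrom[j], metadata$pos[j], loci[j], metadata$ref[j],
            metadata$alt[j], ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1L))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=privsnp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype matrix from a TSV table
#'
#' Expects a header row of locus ids, a first column of individual ids, and
#' cells in `{0, 1, 2, <missing_token>}`.
#'
#' @param path Path to the TSV file.
#' @param missing_token Cell value encoding a missing call (default `"NA"`).
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  widths <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(widths) == 0L) stop("empty input: no data in ", path)
  if (length(unique(widths)) != 1L) {
    stop("ragged table: line ", which(widths != widths[1L])[1L],
         " has ", widths[widths != widths[1L]][1L], " fields, expected ", widths[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = character())
  if (nrow(df) == 0L) stop("empty input: table has a header but no data rows")
  ids <- trimws(df[[1L]])
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- cells %in% c("0", "1", "2", missing_token)
  if (!all(ok)) {
    stop("invalid genotype cell value(s): ",
         paste(utils::head(unique(cells[!ok]), 3L), collapse = ", "))
  }
  cells[cells == missing_token] <- NA_character_
  calls <- matrix(as.integer(cells), nrow = nrow(cells),
                  dimnames = list(ids, colnames(df)[-1L]))
  genotype_matrix(calls)
}

#' Write a genotype matrix as a TSV table
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @param missing_token Token written for missing calls (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path, missing_token = "NA") {
  stopifnot(is_genotype_matrix(genotypes))
  m <- unclass(genotypes)
  df <- data.frame(individual_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = missing_token)
  invisible(path)
}

#' Read a population map from a two-column TSV
#'
#' @param path Path to a TSV with columns individual id and population label.
#' @param has_header Set `TRUE` when the first line is a header to skip.
#' @return A [pop_map()].
#' @export
read_population_map <- function(path, has_header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("population map needs two tab-separated columns")
  if (nrow(df) == 0L) stop("empty input: population map has no entries")
  pop_map(df[[2L]], individual_ids = df[[1L]])
}

#' Write a population map as a two-column TSV
#'
#' @param popmap A [pop_map()].
#' @param path Output path.
#' @param header Write a `individual_id<TAB>population` header line.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(popmap, path, header = TRUE) {
  df <- data.frame(individual_id = names(popmap),
                   population = unclass(popmap), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

panel_columns <- c("locus_id", "host_population", "stability_count",
                   "maf_within_host", "theta", "hobs_within_host",
                   "hexp_within_host")

#' Write a panel of selected private SNPs as TSV
#'
#' Rows are ordered deterministically by host population, then locus id.
#'
#' @param panel A panel data frame as built by [panel_entries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(panel, path) {
  if (nrow(panel) > 0L) {
    panel <- panel[order(panel$host_population, panel$locus_id), , drop = FALSE]
  }
  missing_cols <- setdiff(panel_columns, names(panel))
  for (cn in missing_cols) panel[[cn]] <- rep(NA_real_, nrow(panel))
  utils::write.table(panel[, panel_columns, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel table written by [write_panel_table()]
#'
#' @param path Path to the panel TSV.
#' @return A data frame with the panel columns.
#' @export
read_panel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel_columns, names(df))
  if (length(missing_cols)) {
    stop("panel table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df
}
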