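#' Construct a count matrix object
#'
#' The central count container: a non-negative integer gene x sample matrix
#' with unique row (gene) and column (sample) names, plus per-sample library
#' sizes (column sums unless overridden).
#'
#' @param counts integer matrix, genes as rows, samples as columns, with
#'   dimnames.
#' @param lib_sizes optional positive numeric vector of library sizes, one per
#'   sample; defaults to column sums.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_ids`, `sample_ids` and `lib_sizes`.
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) {
    abort("count matrix is empty")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("count matrix must carry gene (row) and sample (column) names")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) {
    abort(paste0("duplicate gene ids: ", paste(dup_g, collapse = ", ")))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    abort(paste0("duplicate sample ids: ", paste(dup_s, collapse = ", ")))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    loc <- paste0("(", rownames(counts)[bad[1, 1]], ", ",
                  colnames(counts)[bad[1, 2]], ")")
    abort(paste0("counts must be non-negative integers; first offending entry at ",
                 loc))
  }
  storage.mode(counts) <- "double"
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  }
  lib_sizes <- as.numeric(lib_sizes)
  if (length(lib_sizes) != ncol(counts)) {
    abort("lib_sizes length must equal the number of samples")
  }
  if (any(lib_sizes <= 0)) {
    abort(paste0("non-positive library size for sample(s): ",
                 paste(colnames(counts)[lib_sizes <= 0], collapse = ", ")))
  }
  names(lib_sizes) <- colnames(counts)
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         sample_ids = colnames(counts), lib_sizes = lib_sizes),
    class = "count_matrix"
  )
}

#' @exportS3Method base::print
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ", format(min(x$lib_sizes), big.mark = ","), " - ",
      format(max(x$lib_sizes), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or samples
#'
#' @param x a [count_matrix()].
#' @param genes,samples logical, integer or character index vectors.
#' @return A `count_matrix` restricted to the requested rows/columns; library
#'   sizes of retained samples are carried over unchanged.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  lib <- x$lib_sizes
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) {
    counts <- counts[, samples, drop = FALSE]
    lib <- lib[colnames(counts)]
  }
  count_matrix(counts, lib_sizes = lib)
}

#' Read a gene x sample count matrix
#'
#' TSV files follow the HTSeq-count convention: genes as rows (first column of
#' gene ids), samples as columns (header row of sample ids). MatrixMarket
#' input expects `<path>` plus row and column label files `<path>.rownames` /
#' `<path>.colnames` (one id per line).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param transpose set when the file stores samples as rows.
#' @param drop_prefixes character vector of row-id prefixes to drop (e.g.
#'   `"__"` for HTSeq special counters); default drops nothing.
#' @return A [count_matrix()]. Library sizes are the column sums.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              transpose = FALSE, drop_prefixes = character()) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character")
    ids <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                   dimnames = list(ids, colnames(m))))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      abort(paste0("non-numeric count at gene ", ids[bad[1]], ", sample ",
                   colnames(num)[bad[2]]))
    }
    counts <- num
  } else {
    m <- Matrix::readMM(path)
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    counts <- as.matrix(m)
    if (nrow(counts) != length(rn) || ncol(counts) != length(cn)) {
      abort("mtx dimensions disagree with the rownames/colnames label files")
    }
    dimnames(counts) <- list(rn, cn)
  }
  if (transpose) counts <- t(counts)
  if (length(drop_prefixes)) {
    pat <- paste0("^(", paste(drop_prefixes, collapse = "|"), ")")
    counts <- counts[!grepl(pat, rownames(counts)), , drop = FALSE]
  }
  count_matrix(counts)
}

#' Write a count matrix as TSV
#'
#' @param x a [count_matrix()].
#' @param path output file path.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate or read the per-sample design table
#'
#' The sample table records the clustered design: each sample belongs to one
#' individual, each individual to exactly one species, and each sample to one
#' brain part. Factor levels are recorded in first-appearance order.
#'
#' @param x a data frame with columns `sample_id`, `individual`, `species`,
#'   `brain_part`.
#' @return A tibble of class `sample_table` with the four columns as factors
#'   (`sample_id` as character).
#' @export
sample_table <- function(x) {
  req <- c("sample_id", "individual", "species", "brain_part")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    abort(paste0("sample table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(x), req)
  if (length(extra)) {
    abort(paste0("unknown sample table column(s): ",
                 paste(extra, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(x$sample_id[duplicated(x$sample_id)]),
                       collapse = ", ")))
  }
  for (col in c("individual", "species", "brain_part")) {
    x[[col]] <- factor(as.character(x[[col]]),
                       levels = unique(as.character(x[[col]])))
  }
  # individuals must be nested in species
  tab <- unique(x[, c("individual", "species")])
  dup <- tab$individual[duplicated(tab$individual)]
  if (length(dup)) {
    abort(paste0("individual(s) observed under more than one species: ",
                 paste(unique(as.character(dup)), collapse = ", "),
                 " (individuals must be nested in species)"))
  }
  class(x) <- c("sample_table", class(x))
  x
}

#' @rdname sample_table
#' @param path TSV file with a header row naming the four columns.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  sample_table(read.delim(path, sep = "\t", colClasses = "character"))
}

#' @rdname sample_table
#' @export
write_sample_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection
#'
#' Two formats: a two-column TSV of `(gene_id, set_id)` pairs, or GMT
#' (set id, description, then member genes, tab-separated). Duplicate
#' (gene, set) pairs are stored once; empty sets are dropped with a warning.
#' Genes absent from a downstream universe are dropped at use time, not here.
#'
#' @param path file path.
#' @param format `"two_column_tsv"` or `"gmt"`.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of gene ids, with an optional `description` attribute
#'   per set stored in `attr(, "descriptions")`.
#' @export
read_gene_sets <- function(path, format = c("two_column_tsv", "gmt")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  descriptions <- character()
  if (format == "two_column_tsv") {
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield != 2L)) {
      abort(paste0("malformed gene-set line ", which(nfield != 2L)[1],
                   ": expected 2 tab-separated fields"))
    }
    gene <- vapply(parts, `[`, "", 1L)
    set <- vapply(parts, `[`, "", 2L)
    keep <- !duplicated(paste0(gene, "\r", set))
    sets <- split(gene[keep], set[keep])
  } else {
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2L)
    if (length(short)) {
      abort(paste0("malformed GMT line ", short[1],
                   ": expected at least id and description fields"))
    }
    ids <- vapply(parts, `[`, "", 1L)
    descriptions <- setNames(vapply(parts, `[`, "", 2L), ids)
    sets <- setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn(paste0("dropping ", sum(empty), " empty gene set(s): ",
                paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), fixed floating precision, and the
#' single sentinel `NA` for untested/undefined statistics.
#'
#' @param rows a data frame of result records.
#' @param path output file path.
#' @param digits significant digits for numeric columns (default 10, ample for
#'   round-tripping at 1e-6).
#' @export
write_results_table <- function(rows, path, digits = 10) {
  rows <- as.data.frame(rows)
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write results table to ", path))
  invisible(path)
}

#' Read back a result table written by [write_results_table()]
#'
#' @param path TSV file path.
#' @return A tibble; `NA` strings become missing values.
#' @export
read_results_table <- function(path) {
  as_tibble(read.delim(path, sep = "\t", na.strings = "NA",
                       check.names = FALSE))
}
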