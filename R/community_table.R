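#' Construct a validated community table
#'
#' A community table is a taxa x samples matrix of non-negative abundances
#' (counts or relative abundances) with unique taxon and sample IDs. It is
#' the basic container for all downstream analyses.
#'
#' @param abundance Numeric matrix, taxa in rows, samples in columns, with
#'   dimnames giving taxon and sample IDs.
#' @param is_relative Logical; if `TRUE` each sample column must sum to 1
#'   (within 1e-9).
#' @return An object of class `comm_table`: the matrix with attributes.
#' @export
community_table <- function(abundance, is_relative = FALSE) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("abundance must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance must have taxon row names and sample column names")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate taxon IDs")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate sample IDs")
  if (anyNA(abundance) || any(abundance < 0))
    stop("negative abundance or missing values not allowed")
  cs <- colSums(abundance)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(colnames(abundance)[cs == 0], collapse = ", "))
  if (is_relative && any(abs(cs - 1) > 1e-9))
    stop("is_relative = TRUE but sample sums deviate from 1")
  structure(abundance, class = c("comm_table", "matrix", "array"),
            is_relative = is_relative)
}

#' @export
print.comm_table <- function(x, ...) {
  cat(sprintf("Community table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_relative"))) "relative abundances" else "counts/raw"))
  invisible(x)
}

#' Read a taxa-by-sample abundance table from TSV
#'
#' @param path Path to a tab-separated file with a header row and row IDs in
#'   the first column.
#' @param orientation `"taxa_rows"` (default) if rows are taxa, or
#'   `"samples_rows"` if rows are samples (the matrix is transposed on read).
#' @param is_relative Logical; declare the table to hold relative abundances.
#' @return A [community_table()].
#' @export
read_community_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                                 is_relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in abundance table")
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance in ", path)
  if (orientation == "samples_rows") m <- t(m)
  community_table(m, is_relative = is_relative)
}

#' Write a community table to TSV
#'
#' @param table A `comm_table`.
#' @param path Output path; taxa are written as rows.
#' @export
write_community_table <- function(table, path) {
  df <- data.frame(taxon = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a community table to relative abundances
#'
#' Divides every sample column by its sum, so each column sums to 1.
#' Relative abundances are the f_iu quantities entering the bin-level
#' beta-diversity metrics.
#'
#' @param table A `comm_table`.
#' @return A relative `comm_table`; idempotent on relative input.
#' @export
to_relative <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0)) stop("cannot normalise all-zero sample column")
  community_table(sweep(unclass(table), 2, cs, "/"), is_relative = TRUE)
}

#' Rarefy counts to a fixed depth per sample
#'
#' Randomly draws, without replacement, the same number of individuals from
#' every sample, the standard way to equalise sequencing effort before
#' null-model analysis.
#'
#' @param table A `comm_table` of counts (integers).
#' @param depth Number of individuals to draw per sample; must not exceed the
#'   smallest sample total.
#' @param seed Integer seed.
#' @return A rarefied `comm_table` whose columns each sum to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  m <- unclass(table)
  if (any(m != round(m))) stop("rarefy requires integer counts")
  if (depth != round(depth) || depth < 1) stop("depth must be a positive integer")
  cs <- colSums(m)
  if (depth > min(cs)) stop("depth exceeds the smallest sample total")
  set.seed(as.integer(seed))
  out <- m
  for (j in seq_len(ncol(m))) {
    pool <- rep.int(seq_len(nrow(m)), m[, j])
    drawn <- sample(pool, depth, replace = FALSE)
    out[, j] <- tabulate(drawn, nbins = nrow(m))
  }
  dimnames(out) <- dimnames(m)
  community_table(out, is_relative = FALSE)
}

# mean relative abundance per taxon across samples (column-normalised first)
mean_relative_abundance <- function(table) {
  rel <- sweep(unclass(table), 2, colSums(table), "/")
  rowMeans(rel)
}

#' Keep only the most abundant taxa by average relative abundance
#'
#' Ranks taxa from abundant to rare by their mean relative abundance across
#' samples and keeps the top `keep_rank` taxa. Ties are broken by taxon ID
#' (lexicographic) for determinism.
#'
#' @param table A `comm_table`.
#' @param keep_rank Number of taxa to keep.
#' @return A `comm_table` restricted to the kept taxa; abundances unchanged.
#' @export
trim_by_average_abundance <- function(table, keep_rank) {
  if (keep_rank < 1 || keep_rank > nrow(table))
    stop("keep_rank out of range")
  mra <- mean_relative_abundance(table)
  ord <- order(-mra, rownames(table))
  keep <- sort(ord[seq_len(keep_rank)])
  community_table(unclass(table)[keep, , drop = FALSE],
                  is_relative = isTRUE(attr(table, "is_relative")))
}

#' Keep taxa reaching a cumulative abundance fraction in every sample
#'
#' In each sample, taxa are ranked from abundant to rare and the minimal
#' prefix whose cumulative abundance reaches at least `fraction` of the
#' sample total is marked. The union of marked taxa across samples is kept,
#' so every sample retains at least that cumulative share.
#'
#' @param table A `comm_table`.
#' @param fraction Target cumulative fraction in (0, 1].
#' @return A `comm_table` restricted to the kept taxa.
#' @export
trim_by_cumulative_abundance <- function(table, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- unclass(table)
  keep <- logical(nrow(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ord <- order(-x, rownames(m))
    cum <- cumsum(x[ord]) / sum(x)
    n_mark <- which(cum >= fraction - 1e-12)[1]
    keep[ord[seq_len(n_mark)]] <- TRUE
  }
  community_table(m[keep, , drop = FALSE],
                  is_relative = isTRUE(attr(table, "is_relative")))
}

#' Read an environmental factor table from TSV
#'
#' @param path TSV with samples as rows (row IDs in first column) and
#'   factors as columns; values numeric.
#' @return A numeric matrix, samples x factors.
#' @export
read_env_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in environment table")
  if (anyDuplicated(rownames(m))) stop("duplicate sample IDs")
  m
}
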