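#' Construct a genus abundance table
#'
#' The canonical container used throughout the package: a non-negative
#' numeric matrix with taxa as rows and samples as columns, carrying a unit
#' flag that records whether entries are raw counts or per-sample relative
#' abundances (each column summing to one).
#'
#' @param values Numeric matrix, taxa in rows, samples in columns. Must have
#'   unique, non-empty dimnames.
#' @param unit `"counts"` or `"relative"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, unit = c("counts", "relative")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("abundance matrix contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at taxon '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  if (unit == "relative") {
    cs <- colSums(values)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad) > 0)
      stop(sprintf("relative-abundance column '%s' sums to %.6f, not 1",
                   colnames(values)[bad[1]], cs[bad[1]]))
  }
  structure(list(values = values, unit = unit), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa x %d samples, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

taxa_ids <- function(t) rownames(t$values)
sample_ids <- function(t) colnames(t$values)

.table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance table from TSV/CSV
#'
#' Expects a header row of labels and a first column of labels with a
#' numeric body. Canonical orientation is taxa rows x sample columns;
#' transposed input is accepted via `orientation`, or auto-detected when a
#' metadata table listing the sample ids is supplied.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma-separated).
#' @param orientation `"taxa_rows"` (default), `"samples_rows"`, or `"auto"`
#'   (requires `metadata`).
#' @param metadata Optional `sample_metadata` data frame used to auto-detect
#'   orientation by matching its sample ids against the file's labels.
#' @param unit `"auto"` (relative if every column sums to 1 within 1e-6,
#'   counts otherwise), `"counts"`, or `"relative"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("taxa_rows", "samples_rows", "auto"),
                                 metadata = NULL,
                                 unit = "auto") {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rownames(raw)[bad], colnames(raw)[j]))
    }
  }
  m <- as.matrix(raw)
  if (orientation == "auto") {
    if (is.null(metadata))
      stop("orientation = 'auto' requires a metadata table")
    ids <- metadata$sample_id
    in_cols <- mean(colnames(m) %in% ids)
    in_rows <- mean(rownames(m) %in% ids)
    orientation <- if (in_rows > in_cols) "samples_rows" else "taxa_rows"
  }
  if (orientation == "samples_rows") m <- t(m)
  if (identical(unit, "auto")) {
    unit <- if (all(abs(colSums(m) - 1) < 1e-6)) "relative" else "counts"
  }
  abundance_table(m, unit = unit)
}

#' Write an abundance table to TSV/CSV
#'
#' @param t An [abundance_table()].
#' @param path Output path; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  df <- data.frame(taxon_id = taxa_ids(t), t$values, check.names = FALSE)
  utils::write.table(df, path, sep = .table_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total so that columns sum to one.
#' Already-relative tables pass through unchanged (idempotent).
#'
#' @param t An [abundance_table()].
#' @return An [abundance_table()] with `unit = "relative"`.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$unit == "relative") return(t)
  cs <- colSums(t$values)
  zero <- which(cs == 0)
  if (length(zero) > 0)
    stop(sprintf("sample '%s' has zero total abundance", sample_ids(t)[zero[1]]))
  abundance_table(sweep(t$values, 2, cs, "/"), unit = "relative")
}

#' Dominant taxa by mean relative abundance
#'
#' Returns the taxa whose mean relative abundance across samples strictly
#' exceeds `threshold`, most abundant first. Count tables are converted to
#' relative abundances internally so unequal sequencing depths do not bias
#' the ranking.
#'
#' @param t An [abundance_table()].
#' @param threshold Fraction in (0, 1); e.g. 0.01 for the conventional 1 percent
#'   dominance cut.
#' @return Character vector of taxon ids, sorted by descending mean relative
#'   abundance.
#' @export
dominant_taxa <- function(t, threshold = 0.01) {
  stopifnot(inherits(t, "abundance_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  rel <- to_relative_abundance(t)
  mu <- rowMeans(rel$values)
  keep <- mu > threshold
  ids <- taxa_ids(t)[keep]
  ids[order(mu[keep], decreasing = TRUE)]
}

#' Construct or read a sample metadata table
#'
#' Per-sample records: optional group label and non-negative soil available
#' nutrient (N/P/K, mg/kg) and leaf quality (polyphenols, theanine, caffeine,
#' mg/kg) measurements. Missing fields are allowed; operations that need a
#' field fail fast naming it.
#'
#' @param df Data frame with at least a `sample_id` column.
#' @return A validated data frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df)) stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  num_fields <- intersect(
    c("available_N", "available_P", "available_K",
      "polyphenols", "theanine", "caffeine"), names(df))
  for (f in num_fields) {
    v <- df[[f]]
    if (any(!is.na(v) & v < 0)) stop(sprintf("negative value in metadata field '%s'", f))
  }
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path TSV file keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' @rdname sample_metadata
#' @param md A `sample_metadata` data frame to write.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fetch a metadata field, failing fast with its name
metadata_field <- function(md, field) {
  if (!field %in% names(md) || all(is.na(md[[field]])))
    stop(sprintf("metadata field '%s' is required but absent", field))
  md[[field]]
}
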