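#' Construct a sample design
#'
#' A sample design maps each sample to a plant line and a biological
#' replicate index. Between-line statistics require at least two lines;
#' residency classification works with any number of replicates per line
#' (replicate numbers may be unequal across lines).
#'
#' @param df Data frame with columns `sample_id`, `line`, `replicate`.
#' @return Object of class `sample_design` (a validated data frame).
#' @export
sample_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "replicate")
  if (!all(need %in% names(df)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$line <- as.character(df$line)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate indices must be integers >= 1")
  key <- paste(df$line, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, replicate) pair in design")
  rownames(df) <- NULL
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Construct an OTU count table
#'
#' Counts are OTUs (rows) by samples (columns), non-negative integers.
#' Every sample column must appear in the design. An optional taxonomy
#' maps OTU ids to lineage strings.
#'
#' @param counts Integer matrix with OTU ids as rownames and sample ids
#'   as colnames.
#' @param design A [sample_design()] covering every sample column.
#' @param taxonomy Optional named character vector (names = OTU ids).
#' @return Object of class `otu_table`.
#' @export
otu_table <- function(counts, design, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate otu_ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample_ids")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing) > 0)
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[rownames(counts)]
    names(taxonomy) <- rownames(counts)
    taxonomy[is.na(taxonomy)] <- ""
  }
  structure(list(counts = counts, taxonomy = taxonomy, design = design),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples (%d plant lines)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$design$line))))
  cat(sprintf("  total reads: %d; column sums %d-%d\n",
              sum(x$counts), min(colSums(x$counts)), max(colSums(x$counts))))
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Construct a binary presence/absence matrix
#'
#' Rows are features (OTUs or DGGE band types), columns are samples;
#' values are strictly 0/1.
#'
#' @param values 0/1 matrix with feature rownames and sample colnames.
#' @param design A [sample_design()] covering every sample column.
#' @return Object of class `binary_matrix`.
#' @export
binary_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("binary matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample_ids")
  if (!all(values %in% c(0, 1)))
    stop("binary matrix values must be 0 or 1")
  storage.mode(values) <- "integer"
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing) > 0)
    stop("samples missing from design: ", paste(missing, collapse = ", "))
  structure(list(values = values, design = design), class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary matrix: %d features x %d samples; fill %.1f%%\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$values)))
  invisible(x)
}

#' Construct a chemical profile table
#'
#' Units (plant lines or samples) by features (wax compound classes),
#' non-negative real values in ug cm^-2.
#'
#' @param values Numeric matrix, unit rownames, feature colnames.
#' @return Object of class `profile_table`.
#' @export
profile_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("profile table must have unit rownames and feature colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate unit ids")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("profile table contains missing or non-finite values")
  if (any(values < 0)) stop("profile values must be non-negative")
  structure(list(values = values), class = "profile_table")
}

# ---- TSV I/O -------------------------------------------------------------
# Dialect: tab-separated, UTF-8, lines starting '#' ignored, first header
# cell names the row-id column (classic QIIME-era OTU table exports).

read_tsv_matrix <- function(path, id_col) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expected '", id_col, "' column plus data columns in ", path)
  ids <- df[[1]]
  df[[1]] <- NULL
  list(ids = ids, df = df)
}

parse_count_cells <- function(df, ids, path) {
  m <- matrix(0L, nrow = length(ids), ncol = ncol(df),
              dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop(sprintf("invalid count '%s' at OTU '%s', sample '%s' in %s",
                   df[[j]][bad[1]], ids[bad[1]], names(df)[j], path))
    m[, j] <- as.integer(v)
  }
  m
}

#' Read a sample design TSV
#'
#' Columns: `sample_id`, `line`, `replicate`.
#'
#' @param path Path to a tab-separated design file.
#' @return A [sample_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_design(df)
}

#' @rdname read_design
#' @param design A [sample_design()] to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(unclass(design)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU count table from TSV
#'
#' First column `otu_id`, one column per sample, optional trailing
#' `taxonomy` column with lineage strings.
#'
#' @param path OTU table TSV.
#' @param design_path Sample design TSV (see [read_design()]).
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, design_path) {
  design <- read_design(design_path)
  parts <- read_tsv_matrix(path, "otu_id")
  df <- parts$df
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- stats::setNames(df[[ncol(df)]], parts$ids)
    df[[ncol(df)]] <- NULL
  }
  counts <- parse_count_cells(df, parts$ids, path)
  otu_table(counts, design, taxonomy)
}

#' Write an OTU table to TSV
#'
#' @param t An [otu_table()].
#' @param path Output path.
#' @param header Optional character vector of '#'-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path, header = NULL) {
  df <- data.frame(otu_id = rownames(t$counts), t$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(t$taxonomy)) df$taxonomy <- unname(t$taxonomy)
  write_with_header(df, path, header)
}

#' Read/write a binary feature-by-sample matrix
#'
#' First column `feature_id`, one 0/1 column per sample.
#'
#' @param path Matrix TSV.
#' @param design_path Sample design TSV.
#' @return A [binary_matrix()].
#' @export
read_binary_matrix <- function(path, design_path) {
  design <- read_design(design_path)
  parts <- read_tsv_matrix(path, "feature_id")
  m <- parse_count_cells(parts$df, parts$ids, path)
  if (!all(m %in% c(0L, 1L)))
    stop("non-binary value in ", path)
  binary_matrix(m, design)
}

#' @rdname read_binary_matrix
#' @param m A [binary_matrix()].
#' @param header Optional '#' comment lines.
#' @export
write_binary_matrix <- function(m, path, header = NULL) {
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(df, path, header)
}

#' Read/write a chemical profile table
#'
#' First column `unit_id` (plant line or sample), one numeric column per
#' compound class.
#'
#' @param path Profile TSV.
#' @return A [profile_table()].
#' @export
read_profile_table <- function(path) {
  parts <- read_tsv_matrix(path, "unit_id")
  df <- parts$df
  m <- matrix(0, nrow = length(parts$ids), ncol = ncol(df),
              dimnames = list(parts$ids, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      stop(sprintf("invalid value '%s' at unit '%s', feature '%s' in %s",
                   df[[j]][bad[1]], parts$ids[bad[1]], names(df)[j], path))
    m[, j] <- v
  }
  profile_table(m)
}

#' @rdname read_profile_table
#' @param p A [profile_table()].
#' @param header Optional '#' comment lines.
#' @export
write_profile_table <- function(p, path, header = NULL) {
  df <- data.frame(unit_id = rownames(p$values), p$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(df, path, header)
}

write_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- filters -------------------------------------------------------------

#' Filter an OTU table by taxonomy and minimum total count
#'
#' Drops OTUs whose taxonomy contains any of the given substrings
#' (case-insensitive; e.g. `"chloroplast"` removes host plastid reads),
#' then OTUs whose table-wide total count is below `min_total_count`
#' (default 2, removing dataset-wide singletons). OTU order is preserved.
#' Idempotent.
#'
#' @param t An [otu_table()].
#' @param drop_taxon_substrings Character vector of substrings.
#' @param min_total_count Minimum table-wide total (default 2).
#' @return Filtered [otu_table()].
#' @export
filter_table <- function(t, drop_taxon_substrings = character(),
                         min_total_count = 2L) {
  stopifnot(inherits(t, "otu_table"), min_total_count >= 0)
  keep <- rep(TRUE, nrow(t$counts))
  if (length(drop_taxon_substrings) > 0 && !is.null(t$taxonomy)) {
    tax <- tolower(t$taxonomy)
    for (s in tolower(drop_taxon_substrings))
      keep <- keep & !grepl(s, tax, fixed = TRUE)
  }
  keep <- keep & rowSums(t$counts) >= min_total_count
  if (!any(keep)) stop("all OTUs removed by filtering")
  out <- otu_table(t$counts[keep, , drop = FALSE], t$design,
                   if (is.null(t$taxonomy)) NULL else t$taxonomy[keep])
  zero <- rowSums(out$counts) == 0
  if (any(zero))
    message(sum(zero), " OTU(s) retained with zero total count")
  out
}

#' Convert counts to presence/absence
#'
#' A feature is present (1) in a sample iff its count is positive.
#' All-zero rows (possible after rarefaction) are retained and reported.
#'
#' @param t An [otu_table()].
#' @return A [binary_matrix()] with the same dimensions and design.
#' @export
to_presence <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  m <- (t$counts > 0) * 1L
  zero <- rowSums(m) == 0
  if (any(zero))
    message(sum(zero), " OTU(s) absent from every sample")
  binary_matrix(m, t$design)
}
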