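#' Per-line residency status of each OTU
#'
#' For every (OTU, plant line) pair: `RESIDENT` if the OTU is present in
#' all of that line's replicates, `ABSENT` if present in none, and
#' `VARIABLE` otherwise. With a single replicate per line, `VARIABLE`
#' cannot occur.
#'
#' @param m A [binary_matrix()] with its sample design.
#' @return Character matrix (OTU x line) of statuses, with the number of
#'   replicates per line in attribute `n_reps`.
#' @export
residency <- function(m) {
  stopifnot(inherits(m, "binary_matrix"))
  lines <- unique(m$design$line)
  v <- m$values
  status <- matrix(NA_character_, nrow(v), length(lines),
                   dimnames = list(rownames(v), lines))
  n_reps <- integer(length(lines))
  for (k in seq_along(lines)) {
    cols <- m$design$sample_id[m$design$line == lines[k]]
    cols <- intersect(cols, colnames(v))
    n_reps[k] <- length(cols)
    hits <- rowSums(v[, cols, drop = FALSE])
    status[, k] <- ifelse(hits == length(cols), "RESIDENT",
                          ifelse(hits == 0L, "ABSENT", "VARIABLE"))
  }
  names(n_reps) <- lines
  attr(status, "n_reps") <- n_reps
  status
}

#' Collapse a presence matrix to per-line resident communities
#'
#' One binary column per plant line: 1 iff the OTU is resident in that
#' line (present in all of its replicates). This is the line-level view
#' of the community used for line-versus-chemistry comparisons.
#'
#' @param m A [binary_matrix()].
#' @return Integer 0/1 matrix, OTUs x lines.
#' @export
line_residency_matrix <- function(m) {
  (residency(m) == "RESIDENT") * 1L
}

#' Partition OTUs into transient, resident, core and line-specific sets
#'
#' The central classifier. From replicate presence/absence, each OTU is:
#' * `RESIDENT` if present in all replicates of at least one plant line,
#'   `TRANSIENT` otherwise (complement; the two categories partition the
#'   OTU set);
#' * *core* if resident and present in at least `n_samples - core_slack`
#'   of all samples (default slack 1, i.e. present in all or all but one
#'   sample);
#' * *plant line-specific* if resident in some line but absent from all
#'   replicates of at least one other line;
#' * *uniquely present* in line L if resident in L and absent from every
#'   other line; *uniquely absent* in L if absent from L and resident in
#'   every other line.
#'
#' When a count table is supplied, the summary reports the percentage of
#' total sequence count carried by each category.
#'
#' @param m A [binary_matrix()] of OTU presence/absence.
#' @param counts Optional [otu_table()] whose rows cover the OTUs of
#'   `m`, used for the percent-of-reads summary.
#' @param core_slack Number of samples a core OTU may miss (default 1).
#' @return Object of class `community_partition` with elements `otu`
#'   (per-OTU data frame), `residency` (status matrix), `summary`
#'   (per-category counts and percentages), `lines`, `n_samples`,
#'   `core_slack`.
#' @export
partition_communities <- function(m, counts = NULL, core_slack = 1L) {
  stopifnot(inherits(m, "binary_matrix"), core_slack >= 0)
  status <- residency(m)
  lines <- colnames(status)
  n_samples <- ncol(m$values)
  res_any <- rowSums(status == "RESIDENT") > 0
  abs_any <- rowSums(status == "ABSENT") > 0
  occupancy <- rowSums(m$values)

  category <- ifelse(res_any, "RESIDENT", "TRANSIENT")
  is_core <- res_any & occupancy >= (n_samples - core_slack)
  is_specific <- res_any & abs_any

  n_res_lines <- rowSums(status == "RESIDENT")
  n_abs_lines <- rowSums(status == "ABSENT")
  uniq_present <- ifelse(n_res_lines == 1L & n_abs_lines == (length(lines) - 1L),
                         lines[apply(status == "RESIDENT", 1, which.max)],
                         NA_character_)
  uniq_absent <- ifelse(n_abs_lines == 1L & n_res_lines == (length(lines) - 1L),
                        lines[apply(status == "ABSENT", 1, which.max)],
                        NA_character_)

  otu <- data.frame(otu_id = rownames(m$values),
                    category = category,
                    is_core = unname(is_core),
                    is_line_specific = unname(is_specific),
                    unique_present_line = unname(uniq_present),
                    unique_absent_line = unname(uniq_absent),
                    occupancy = as.integer(unname(occupancy)),
                    stringsAsFactors = FALSE)
  rownames(otu) <- NULL

  smry <- data.frame(
    category = c("transient", "resident", "core", "line_specific",
                 "unique_present", "unique_absent"),
    n_otus = c(sum(category == "TRANSIENT"), sum(category == "RESIDENT"),
               sum(is_core), sum(is_specific),
               sum(!is.na(uniq_present)), sum(!is.na(uniq_absent))),
    stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "otu_table"))
    cc <- counts$counts[rownames(m$values), , drop = FALSE]
    tot <- sum(cc)
    reads_of <- function(sel) if (tot == 0) NA_real_ else 100 * sum(cc[sel, , drop = FALSE]) / tot
    smry$pct_reads <- c(reads_of(category == "TRANSIENT"),
                        reads_of(category == "RESIDENT"),
                        reads_of(is_core),
                        reads_of(is_specific),
                        reads_of(!is.na(uniq_present)),
                        reads_of(!is.na(uniq_absent)))
  }

  structure(list(otu = otu, residency = status, summary = smry,
                 lines = lines, n_samples = n_samples,
                 core_slack = as.integer(core_slack)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d OTUs, %d samples, %d plant lines (core slack %d)\n",
              nrow(x$otu), x$n_samples, length(x$lines), x$core_slack))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s %4d OTUs", s$category[i], s$n_otus[i]))
    if (!is.null(s$pct_reads) && !is.na(s$pct_reads[i]))
      cat(sprintf("  (%5.1f%% of reads)", s$pct_reads[i]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.community_partition <- function(object, ...) object$summary

#' @export
plot.community_partition <- function(x, ...) {
  s <- x$summary
  graphics::barplot(s$n_otus, names.arg = s$category, las = 2,
                    ylab = "OTUs", main = "Community partition", ...)
  invisible(x)
}

#' Venn counts of plant line-specific residency
#'
#' Per line, the number of uniquely present and uniquely absent OTUs,
#' plus the number of line-specific OTUs resident in each subset of
#' lines (the Venn regions). Subset counts sum to the number of
#' line-specific OTUs.
#'
#' @param p A [partition_communities()] result.
#' @return List with `per_line` (data frame: line, unique_present,
#'   unique_absent) and `subsets` (data frame: comma-joined resident
#'   line set, n).
#' @export
venn_counts <- function(p) {
  stopifnot(inherits(p, "community_partition"))
  lines <- p$lines
  per_line <- data.frame(
    line = lines,
    unique_present = vapply(lines, function(L)
      sum(p$otu$unique_present_line == L, na.rm = TRUE), integer(1)),
    unique_absent = vapply(lines, function(L)
      sum(p$otu$unique_absent_line == L, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_line) <- NULL

  spec <- p$otu$otu_id[p$otu$is_line_specific]
  if (length(spec) > 0) {
    sets <- vapply(spec, function(o)
      paste(lines[p$residency[o, ] == "RESIDENT"], collapse = ","),
      character(1))
    tab <- table(sets)
    subsets <- data.frame(lines = names(tab), n = as.integer(tab),
                          stringsAsFactors = FALSE)
  } else {
    subsets <- data.frame(lines = character(0), n = integer(0),
                          stringsAsFactors = FALSE)
  }
  rownames(subsets) <- NULL
  list(per_line = per_line, subsets = subsets)
}

#' Extract the resident-community submatrix
#'
#' Restricts a presence/absence matrix to the OTUs classified RESIDENT,
#' preserving row order. Downstream beta-diversity statistics operate on
#' this matrix.
#'
#' @param m The [binary_matrix()] that was classified.
#' @param p The corresponding [partition_communities()] result.
#' @return A [binary_matrix()] of resident OTUs.
#' @export
resident_submatrix <- function(m, p) {
  stopifnot(inherits(m, "binary_matrix"), inherits(p, "community_partition"))
  keep <- p$otu$otu_id[p$otu$category == "RESIDENT"]
  if (length(keep) == 0) stop("no resident OTUs")
  binary_matrix(m$values[rownames(m$values) %in% keep, , drop = FALSE],
                m$design)
}
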