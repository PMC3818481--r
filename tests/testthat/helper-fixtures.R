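# Small builders and independent oracles used across the suite.

make_design <- function(n_lines = 3, reps = 3,
                        lines = LETTERS[seq_len(n_lines)]) {
  sample_design(data.frame(
    sample_id = paste0(rep(lines, each = reps), rep(seq_len(reps), n_lines)),
    line = rep(lines, each = reps),
    replicate = rep(seq_len(reps), n_lines)))
}

random_presence <- function(n_otu, design, p = 0.5) {
  m <- matrix(rbinom(n_otu * nrow(design), 1, p), n_otu,
              dimnames = list(sprintf("otu%03d", seq_len(n_otu)),
                              design$sample_id))
  binary_matrix(m, design)
}

small_table <- function(counts, design, taxonomy = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("otu%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- design$sample_id
  otu_table(counts, design, taxonomy)
}

# Independent brute-force classifier: literally re-evaluates the
# category definitions per OTU with explicit loops, sharing no code with
# partition_communities().
oracle_classify <- function(values, design, core_slack = 1) {
  lines <- unique(design$line)
  n_samples <- ncol(values)
  out <- data.frame(otu_id = rownames(values), category = NA_character_,
                    is_core = NA, is_line_specific = NA,
                    unique_present_line = NA_character_,
                    unique_absent_line = NA_character_,
                    occupancy = NA_integer_, stringsAsFactors = FALSE)
  for (o in seq_len(nrow(values))) {
    res_in <- character(0); abs_in <- character(0)
    for (L in lines) {
      reps <- design$sample_id[design$line == L]
      present <- 0
      for (s in reps) if (values[o, s] == 1) present <- present + 1
      if (present == length(reps)) res_in <- c(res_in, L)
      if (present == 0) abs_in <- c(abs_in, L)
    }
    occ <- sum(values[o, ])
    resident <- length(res_in) > 0
    out$category[o] <- if (resident) "RESIDENT" else "TRANSIENT"
    out$is_core[o] <- resident && occ >= n_samples - core_slack
    out$is_line_specific[o] <- resident && length(abs_in) > 0
    out$unique_present_line[o] <-
      if (length(res_in) == 1 && length(abs_in) == length(lines) - 1)
        res_in else NA_character_
    out$unique_absent_line[o] <-
      if (length(abs_in) == 1 && length(res_in) == length(lines) - 1)
        abs_in else NA_character_
    out$occupancy[o] <- occ
  }
  out
}

# Procrustes correlation between a target and a fitted configuration
# (via vegan's symmetric Procrustes rotation).
procrustes_cor <- function(truth, fitted) {
  pr <- vegan::procrustes(truth, fitted, symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}
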