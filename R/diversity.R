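#' Rarefy an OTU table to even depth
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric) to exactly `depth` reads, equalising
#' sampling effort across samples before presence/absence analysis.
#' The OTU set is unchanged; rows may become all-zero. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param t An [otu_table()].
#' @param depth Target depth; must not exceed any sample's total.
#' @param seed Integer seed (or `NULL` for the current RNG stream).
#' @return A rarefied [otu_table()].
#' @export
rarefy <- function(t, depth, seed = NULL) {
  stopifnot(inherits(t, "otu_table"), depth >= 1)
  depth <- as.integer(depth)
  tot <- colSums(t$counts)
  low <- which(tot < depth)
  if (length(low) > 0)
    stop(sprintf("depth %d exceeds total count (%d) of sample '%s'",
                 depth, tot[low[1]], colnames(t$counts)[low[1]]))
  out <- t$counts
  n_otu <- nrow(out)
  with_seed(seed, {
    for (j in seq_len(ncol(out))) {
      reads <- rep.int(seq_len(n_otu), out[, j])
      picked <- reads[sample.int(length(reads), depth)]
      out[, j] <- tabulate(picked, nbins = n_otu)
    }
  })
  otu_table(out, t$design, t$taxonomy)
}

#' Expected rarefaction curve for one sample
#'
#' Expected OTU richness at each subsampling depth under hypergeometric
#' subsampling without replacement:
#' `E[S(d)] = S_obs - sum_i P(OTU i absent from a subsample of d reads)`,
#' computed analytically (via vegan). An optional Monte-Carlo mode
#' repeats the subsampling and reports the mean and standard deviation
#' of observed richness; it agrees with the analytic curve to within
#' sampling error.
#'
#' @param counts Non-negative integer count vector for one sample.
#' @param depths Increasing integer depths, each `<= sum(counts)`.
#' @param method `"analytic"` (default) or `"montecarlo"`.
#' @param n_rep Monte-Carlo replicates (default 1000).
#' @param seed Seed for Monte-Carlo mode.
#' @return Data frame with `depth`, `expected_richness` and, in
#'   Monte-Carlo mode, `sd`.
#' @export
rarefaction_curve <- function(counts, depths,
                              method = c("analytic", "montecarlo"),
                              n_rep = 1000L, seed = NULL) {
  method <- match.arg(method)
  counts <- as.integer(counts)
  if (sum(counts) < 1) stop("empty sample")
  if (any(depths < 1) || any(depths > sum(counts)))
    stop("depths must lie in [1, total count]")
  depths <- as.integer(depths)
  if (method == "analytic") {
    # vegan warns when the smallest count exceeds 1 (heuristic check for
    # non-count data); irrelevant for validated integer counts
    er <- as.numeric(suppressWarnings(
      vegan::rarefy(matrix(counts, nrow = 1), sample = depths)))
    return(data.frame(depth = depths, expected_richness = er))
  }
  n_otu <- length(counts)
  reads <- rep.int(seq_len(n_otu), counts)
  res <- with_seed(seed, {
    vapply(depths, function(d) {
      s <- vapply(seq_len(n_rep), function(r) {
        picked <- reads[sample.int(length(reads), d)]
        sum(tabulate(picked, nbins = n_otu) > 0)
      }, numeric(1))
      c(mean(s), stats::sd(s))
    }, numeric(2))
  })
  data.frame(depth = depths, expected_richness = res[1, ], sd = res[2, ])
}

#' Alpha diversity, evenness and richness estimators
#'
#' Per sample: observed richness, Shannon H (natural log), Simpson
#' (reported as 1 - D), Pielou evenness J = H / ln(S_obs) (NA when
#' S_obs <= 1), bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (finite when doubletons are
#' absent) and ACE with the classical rare/abundant threshold of 10.
#' Chao1 and ACE are taken from vegan's `estimateR`.
#'
#' @param t An [otu_table()].
#' @return Data frame, one row per sample: `sample_id`, `s_obs`,
#'   `shannon`, `simpson`, `pielou`, `chao1`, `ace`.
#' @export
alpha_diversity <- function(t) {
  stopifnot(inherits(t, "otu_table"))
  x <- t(t$counts)                      # samples x OTUs for vegan
  if (any(rowSums(x) == 0)) stop("sample with zero total count")
  s_obs <- rowSums(x > 0)
  h <- vegan::diversity(x, index = "shannon")
  simp <- vegan::diversity(x, index = "simpson")
  est <- vegan::estimateR(x)
  j <- ifelse(s_obs > 1, h / log(s_obs), NA_real_)
  # ACE is undefined when a sample has no rare (count <= 10) OTUs; all
  # species are then abundant and the estimator reduces to S_obs
  ace <- est["S.ACE", ]
  ace <- ifelse(is.finite(ace), ace, s_obs)
  data.frame(sample_id = rownames(x),
             s_obs = unname(s_obs),
             shannon = unname(h),
             simpson = unname(simp),
             pielou = unname(j),
             chao1 = unname(est["S.chao1", ]),
             ace = unname(ace),
             stringsAsFactors = FALSE)
}
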