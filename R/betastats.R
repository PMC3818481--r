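#' Jaccard distances between samples
#'
#' d(a,b) = 1 - |a intersect b| / |a union b| over the feature sets of
#' the two samples; two empty samples are at distance 0.
#'
#' @param m A [binary_matrix()] (features x samples) or plain 0/1 matrix.
#' @return A `dist` object labelled by sample id.
#' @export
jaccard_distances <- function(m) {
  v <- if (inherits(m, "binary_matrix")) m$values else as.matrix(m)
  if (ncol(v) < 2) stop("need at least 2 samples")
  storage.mode(v) <- "double"
  inter <- crossprod(v)
  sums <- colSums(v)
  union <- outer(sums, sums, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Euclidean distances between profile units
#'
#' Standard Euclidean distance between the rows of a chemical profile
#' table (or any numeric matrix).
#'
#' @param p A [profile_table()] or numeric matrix (units x features).
#' @return A `dist` object labelled by unit id.
#' @export
euclidean_distances <- function(p) {
  v <- if (inherits(p, "profile_table")) p$values else as.matrix(p)
  if (nrow(v) < 2) stop("need at least 2 units")
  stats::dist(v, method = "euclidean")
}

#' Expand a per-line profile table to samples
#'
#' Each sample inherits the profile of its plant line, yielding a
#' profile table conformable with per-sample community distances (used
#' by the Mantel test when wax chemistry is measured per line).
#'
#' @param p A [profile_table()] whose units are line labels.
#' @param design A [sample_design()].
#' @return A [profile_table()] with one unit per sample.
#' @export
expand_profile <- function(p, design) {
  stopifnot(inherits(p, "profile_table"))
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  missing <- setdiff(unique(design$line), rownames(p$values))
  if (length(missing) > 0)
    stop("lines missing from profile table: ", paste(missing, collapse = ", "))
  v <- p$values[design$line, , drop = FALSE]
  rownames(v) <- design$sample_id
  profile_table(v)
}

# ANOSIM R for a fixed rank vector and grouping.
# r: average ranks of the dist vector; pairs: lower_pairs(n); g: labels.
anosim_R <- function(r, pairs, g) {
  within <- g[pairs[, "i"]] == g[pairs[, "j"]]
  M <- length(r)
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

# all n! permutations of 1..n as a matrix (n! rows); guard small n
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# all distinct assignments of the label multiset g to positions
multiset_assignments <- function(g) {
  counts <- table(g)
  labels <- names(counts)
  n <- length(g)
  out <- list()
  recurse <- function(pos, counts, cur) {
    if (pos > n) {
      out[[length(out) + 1L]] <<- cur
      return(invisible())
    }
    for (k in seq_along(labels)) {
      if (counts[k] > 0L) {
        counts[k] <- counts[k] - 1L
        cur[pos] <- labels[k]
        recurse(pos + 1L, counts, cur)
        counts[k] <- counts[k] + 1L
      }
    }
  }
  recurse(1L, as.integer(counts), character(n))
  out
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of between-group vs within-group
#' dissimilarities (Clarke's R). All n(n-1)/2 distances are ranked with
#' average ranks for ties; `R = (rB - rW) / (M/2)` with `M = n(n-1)/2`,
#' so R = 1 when every between-group distance exceeds every within-group
#' distance. Significance by random relabelling of samples, with the
#' never-zero estimator `p = (exceedances + 1) / (n_perm + 1)`. Pairwise
#' group comparisons restrict the distance matrix to each pair of
#' groups; pairs in which a group has fewer than 2 members are flagged
#' untestable.
#'
#' @param d A `dist` object.
#' @param grouping Group label per sample: either a named vector (names
#'   matching the dist labels) or a vector in dist label order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param pairwise Compute pairwise group comparisons (default TRUE).
#' @param exact Enumerate all distinct label assignments instead of
#'   sampling (feasible up to 5000 assignments); p is then the exact
#'   proportion of assignments with R at least the observed value
#'   (identity included, so p is never zero).
#' @return Object of class `anosim_test`: `R`, `p`, `n_perm`,
#'   `pairwise` (data frame), `seed`.
#' @export
anosim_test <- function(d, grouping, n_perm = 999L, seed = NULL,
                        pairwise = TRUE, exact = FALSE) {
  stopifnot(inherits(d, "dist"), n_perm >= 1)
  labs <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  g <- if (!is.null(names(grouping))) {
    missing <- setdiff(labs, names(grouping))
    if (length(missing) > 0)
      stop("samples missing from grouping: ", paste(missing, collapse = ", "))
    as.character(grouping[labs])
  } else {
    if (length(grouping) != length(labs))
      stop("grouping length does not match distance matrix")
    as.character(grouping)
  }
  if (length(unique(g)) < 2) stop("need at least 2 groups")

  n <- attr(d, "Size")
  r <- rank(as.vector(d))
  pairs <- lower_pairs(n)
  R_obs <- anosim_R(r, pairs, g)
  if (exact) {
    assigns <- multiset_assignments(g)
    if (length(assigns) > 5000)
      stop("too many label assignments for exact enumeration")
    Rs <- vapply(assigns, function(gp) anosim_R(r, pairs, gp), numeric(1))
    p <- mean(Rs >= R_obs - 1e-12)
    n_perm <- length(assigns)
  } else {
    p <- with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        Rp <- anosim_R(r, pairs, sample(g))
        if (Rp >= R_obs - 1e-12) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  }

  pw <- NULL
  if (pairwise) {
    groups <- sort(unique(g))
    combos <- utils::combn(groups, 2)
    dm <- dist_matrix(d)
    rows <- lapply(seq_len(ncol(combos)), function(k) {
      ga <- combos[1, k]; gb <- combos[2, k]
      sel <- labs[g %in% c(ga, gb)]
      testable <- sum(g == ga) >= 2 && sum(g == gb) >= 2
      if (!testable)
        return(data.frame(group_a = ga, group_b = gb, R = NA_real_,
                          p = NA_real_, testable = FALSE,
                          stringsAsFactors = FALSE))
      sub <- stats::as.dist(dm[sel, sel])
      fit <- anosim_test(sub, stats::setNames(g[match(sel, labs)], sel),
                         n_perm = n_perm, seed = derive_seed(seed, k),
                         pairwise = FALSE)
      data.frame(group_a = ga, group_b = gb, R = fit$R, p = fit$p,
                 testable = TRUE, stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
  }

  structure(list(R = R_obs, p = p, n_perm = as.integer(n_perm),
                 pairwise = pw, grouping = stats::setNames(g, labs),
                 seed = seed),
            class = "anosim_test")
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf("ANOSIM: global R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the strictly lower triangles of two distance
#' matrices with identical labels; significance by simultaneous
#' row/column permutation of the second matrix, two-sided on |r|, with
#' the +1 correction. The test is carried out on distances; with
#' similarity = 1 - distance (Jaccard) or any decreasing affine map
#' (Euclidean), |r| and the permutation p are unchanged and only the
#' sign of r flips.
#'
#' @param d1,d2 `dist` objects with the same labels in the same order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param exact Enumerate all n! row/column permutations (feasible for
#'   n <= 7); p is then the exact proportion of permutations with |r| at
#'   least the observed |r| (identity included).
#' @return Object of class `mantel_test`: `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL, exact = FALSE) {
  stopifnot(inherits(d1, "dist"), inherits(d2, "dist"), n_perm >= 1)
  n <- attr(d1, "Size")
  if (n != attr(d2, "Size")) stop("distance matrices differ in size")
  if (n < 3) stop("need at least 3 units")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrix labels differ")
  x <- as.vector(d1)
  y <- as.vector(d2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a distance matrix; r undefined")
  r_obs <- stats::cor(x, y)

  ys_m <- dist_matrix(d2)
  lt <- lower.tri(ys_m)
  if (exact) {
    if (n > 7) stop("too many permutations for exact enumeration")
    perms <- all_perms(n)
    rs <- vapply(seq_len(nrow(perms)), function(b) {
      perm <- perms[b, ]
      stats::cor(x, ys_m[perm, perm][lt])
    }, numeric(1))
    p <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    p <- with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        yp <- ys_m[perm, perm][lt]
        rp <- stats::cor(x, yp)
        if (abs(rp) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  }
  structure(list(r = r_obs, p = p, n_perm = as.integer(n_perm), seed = seed),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
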