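# Agglomerative clustering with deterministic tie-breaking.
#
# At each step the pair of clusters at minimal distance is merged; among
# tied pairs the one whose (lexicographically smallest member label of
# each cluster, sorted) pair is smallest wins, so results do not depend
# on input order. Update rules: arithmetic mean (UPGMA) or maximum
# (complete linkage).
agglomerate <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  dm <- dist_matrix(d)
  labs <- rownames(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 units")

  # active cluster bookkeeping
  size <- rep(1L, n)
  rep_lab <- labs                       # smallest member label per cluster
  node <- -seq_len(n)                   # hclust coding: leaves negative
  active <- rep(TRUE, n)
  D <- dm
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    hits <- which(sub <= dmin + 0, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographic smallest sorted label pair
    keys <- apply(hits, 1, function(h) {
      pair <- sort(c(rep_lab[idx[h[1]]], rep_lab[idx[h[2]]]))
      paste(pair, collapse = "\r")
    })
    pick <- hits[order(keys)[1], ]
    a <- idx[pick[1]]; b <- idx[pick[2]]

    # hclust convention: singletons (negative) first, by leaf index
    pair <- c(node[a], node[b])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- if (method == "average") dmin / 2 else dmin

    # merge b into a
    others <- setdiff(idx, c(a, b))
    if (length(others) > 0) {
      D[a, others] <- if (method == "average")
        (size[a] * D[a, others] + size[b] * D[b, others]) / (size[a] + size[b])
      else
        pmax(D[a, others], D[b, others])
      D[others, a] <- D[a, others]
    }
    size[a] <- size[a] + size[b]
    rep_lab[a] <- min(rep_lab[a], rep_lab[b])
    node[a] <- step
    active[b] <- FALSE
  }

  hc <- list(merge = merge, height = height, order = hclust_order(merge),
             labels = labs, method = if (method == "average") "average" else "complete",
             call = match.call(), dist.method = "user")
  class(hc) <- "hclust"
  hc
}

# leaf order by traversal of the merge matrix (left subtree first)
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' UPGMA (average linkage) clustering
#'
#' Agglomerative clustering with the arithmetic-mean update rule,
#' producing an ultrametric dendrogram: merge height is half the
#' inter-cluster distance, so the cophenetic distance between two leaves
#' equals the (averaged) distance at which their clusters merged. Ties
#' are broken by the lexicographically smallest label pair, so the tree
#' is invariant to input order.
#'
#' @param d A `dist` object.
#' @return Object of class `dendrogram_fit`: `hclust` (base-R hclust
#'   structure), `newick` (string with branch lengths), `leaf_order`
#'   (labels in dendrogram order), `method`.
#' @export
upgma <- function(d) dendrogram_fit(agglomerate(d, "average"))

#' Complete-linkage clustering
#'
#' Agglomerative clustering with the maximum update rule; merge height
#' is the inter-cluster distance. Used to order heatmap rows/columns of
#' resident-community presence/absence matrices ("binary" distances).
#'
#' @param d A `dist` object.
#' @return A `dendrogram_fit` (see [upgma()]).
#' @export
complete_linkage <- function(d) dendrogram_fit(agglomerate(d, "complete"))

dendrogram_fit <- function(hc) {
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc,
                 newick = ape::write.tree(phy),
                 leaf_order = hc$labels[hc$order],
                 method = hc$method),
            class = "dendrogram_fit")
}

#' @export
print.dendrogram_fit <- function(x, ...) {
  cat(sprintf("%s dendrogram over %d leaves\n",
              if (x$method == "average") "UPGMA" else "complete-linkage",
              length(x$leaf_order)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' @export
plot.dendrogram_fit <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}
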