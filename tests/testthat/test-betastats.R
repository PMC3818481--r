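test_that("Jaccard distances match set-based hand calculations", {
  des <- make_design(2, 2)
  m <- matrix(0L, 4, 4, dimnames = list(paste0("f", 1:4), des$sample_id))
  m[c(1, 2, 3), 1] <- 1L                # {1,2,3}
  m[c(2, 3, 4), 2] <- 1L                # {2,3,4}
  m[c(1, 2, 3), 3] <- 1L                # identical to sample 1
  d <- as.matrix(jaccard_distances(binary_matrix(m, des)))
  expect_equal(d["A1", "A2"], 1 - 2 / 4)
  expect_equal(d["A1", "B1"], 0)        # identical feature sets
  expect_equal(d["A1", "B2"], 1)        # non-empty vs empty sample
  # disjoint non-empty samples are at distance 1
  m2 <- rbind(c(1L, 0L), c(0L, 1L))
  dimnames(m2) <- list(c("f1", "f2"), c("s1", "s2"))
  expect_equal(as.vector(jaccard_distances(m2)), 1)
  # two empty samples are at distance 0
  m3 <- matrix(0L, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(as.vector(jaccard_distances(m3)), 0)
})

test_that("Euclidean profile distances are translation invariant", {
  pv <- rbind(u1 = c(0, 0), u2 = c(3, 4))
  colnames(pv) <- c("x", "y")
  p <- profile_table(pv)
  expect_equal(as.vector(euclidean_distances(p)), 5)
  set.seed(1)
  v <- matrix(runif(20), 4, 5,
              dimnames = list(paste0("u", 1:4), paste0("c", 1:5)))
  d1 <- euclidean_distances(profile_table(v))
  d2 <- euclidean_distances(profile_table(v + 7))
  expect_equal(as.vector(d1), as.vector(d2))
})

test_that("ANOSIM gives R = 1 for fully separated groups and matches vegan", {
  # two groups of 3: every between distance larger than every within
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("s", 1:6)
  g <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  fit <- anosim_test(d, g, n_perm = 99, seed = 1, pairwise = FALSE)
  expect_equal(fit$R, 1)
  # R agrees with vegan on random data
  set.seed(2)
  for (rep in 1:10) {
    x <- matrix(rnorm(12 * 3), 12)
    dd <- dist(x)
    gg <- sample(rep(c("A", "B", "C"), 4))
    ours <- anosim_test(dd, gg, n_perm = 9, seed = 1, pairwise = FALSE)$R
    theirs <- vegan::anosim(dd, gg, permutations = 0)$statistic
    expect_equal(ours, unname(theirs), tolerance = 1e-12)
  }
})

test_that("ANOSIM R is invariant to strictly monotone transforms of the distances", {
  set.seed(3)
  x <- matrix(rnorm(10 * 2), 10)
  d <- dist(x)
  g <- rep(c("A", "B"), 5)
  r0 <- anosim_test(d, g, n_perm = 9, seed = 1, pairwise = FALSE)$R
  for (f in list(function(z) z^2, function(z) log1p(z), function(z) 3 * z + 1)) {
    dt <- d; dt[] <- f(as.vector(d))
    expect_equal(anosim_test(dt, g, n_perm = 9, seed = 1,
                             pairwise = FALSE)$R, r0, tolerance = 1e-12)
  }
})

test_that("exact ANOSIM p equals exhaustive enumeration by a brute-force oracle", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(6 * 2), 6)
    d <- dist(x)
    g <- rep(c("A", "B"), each = 3)
    fit <- anosim_test(d, g, exact = TRUE, pairwise = FALSE)
    # oracle: every assignment of 3 A's to 6 positions, R recomputed from scratch
    dm <- as.matrix(d)
    R_of <- function(lab) {
      v <- numeric(0); w <- logical(0)
      for (i in 2:6) for (j in 1:(i - 1)) {
        v <- c(v, dm[i, j]); w <- c(w, lab[i] == lab[j])
      }
      r <- rank(v)
      (mean(r[!w]) - mean(r[w])) / (length(v) / 2)
    }
    combos <- combn(6, 3)
    Rs <- apply(combos, 2, function(idx) {
      lab <- rep("B", 6); lab[idx] <- "A"; R_of(lab)
    })
    expect_equal(fit$n_perm, 20L)
    expect_equal(fit$p, mean(Rs >= R_of(rep(c("A", "B"), each = 3)) - 1e-12))
  }
})

test_that("pairwise ANOSIM restricts to each group pair and flags untestable ones", {
  set.seed(5)
  des <- make_design(3, 3)
  m <- random_presence(25, des, p = 0.5)
  d <- jaccard_distances(m)
  g <- setNames(des$line, des$sample_id)
  fit <- anosim_test(d, g, n_perm = 99, seed = 9)
  expect_equal(nrow(fit$pairwise), 3)
  expect_true(all(fit$pairwise$testable))
  expect_true(all(abs(fit$pairwise$R) <= 1))
  # singleton group
  g2 <- g; g2[des$line == "C"] <- c("C", "D", "C")[seq_len(sum(des$line == "C"))]
  fit2 <- anosim_test(d, g2, n_perm = 19, seed = 9)
  bad <- fit2$pairwise[fit2$pairwise$group_a == "D" | fit2$pairwise$group_b == "D", ]
  expect_true(all(!bad$testable))
})

test_that("Mantel r hits its closed-form identities and matches vegan", {
  set.seed(6)
  x <- matrix(rnorm(8 * 3), 8)
  d1 <- dist(x)
  expect_equal(mantel_test(d1, d1, n_perm = 9, seed = 1)$r, 1)
  d2 <- d1; d2[] <- 2.5 * as.vector(d1) + 1
  expect_equal(mantel_test(d1, d2, n_perm = 9, seed = 1)$r, 1)
  y <- matrix(rnorm(8 * 3), 8)
  d3 <- dist(y)
  ours <- mantel_test(d1, d3, n_perm = 9, seed = 1)$r
  theirs <- vegan::mantel(d1, d3, permutations = 0)$statistic
  expect_equal(ours, unname(theirs), tolerance = 1e-12)
  # degenerate matrix
  d0 <- d1; d0[] <- 1
  expect_error(mantel_test(d1, d0, n_perm = 9), "zero variance")
})

test_that("exact Mantel p equals exhaustive enumeration at n = 4", {
  set.seed(7)
  for (rep in 1:5) {
    d1 <- dist(matrix(rnorm(8), 4))
    d2 <- dist(matrix(rnorm(8), 4))
    fit <- mantel_test(d1, d2, exact = TRUE)
    # oracle: loop over all 24 permutations written out directly
    m1 <- as.matrix(d1); m2 <- as.matrix(d2)
    lt <- function(m) m[lower.tri(m)]
    perms <- list()
    for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (e in 1:4)
      if (length(unique(c(a, b, cc, e))) == 4)
        perms[[length(perms) + 1]] <- c(a, b, cc, e)
    r_obs <- cor(lt(m1), lt(m2))
    rs <- vapply(perms, function(p) cor(lt(m1), lt(m2[p, p])), numeric(1))
    expect_equal(fit$n_perm, 24L)
    expect_equal(fit$p, mean(abs(rs) >= abs(r_obs) - 1e-12))
  }
})

test_that("permutation p agrees with exact p within Monte-Carlo error", {
  set.seed(8)
  d1 <- dist(matrix(rnorm(12), 6))
  d2 <- dist(matrix(rnorm(12), 6))
  pe <- mantel_test(d1, d2, exact = TRUE)$p
  pm <- mantel_test(d1, d2, n_perm = 9999, seed = 3)$p
  expect_lt(abs(pm - pe), 4 * sqrt(pe * (1 - pe) / 9999) + 2e-4)
})
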