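test_that("generation is deterministic given a seed and honours the depth range", {
  spec <- synthetic_spec(n_core = 5, n_specific = 8, n_transient = 40,
                         seed = 9)
  g1 <- generate_community(spec)
  g2 <- generate_community(spec)
  expect_identical(g1$table$counts, g2$table$counts)
  expect_identical(g1$profile$values, g2$profile$values)
  expect_identical(g1$truth, g2$truth)
  cs <- colSums(g1$table$counts)
  expect_true(all(cs >= spec$depth_range[1] & cs <= spec$depth_range[2]))
  expect_identical(nrow(g1$table$counts), 53L)
  expect_identical(ncol(g1$table$counts), 15L)
  g3 <- generate_community(spec, seed = 10)
  expect_false(identical(g1$table$counts, g3$table$counts))
})

test_that("counts realise the planted occupancy mask exactly", {
  spec <- synthetic_spec(n_core = 4, n_specific = 6, n_transient = 30,
                         depth_range = c(500, 800), seed = 3)
  g <- generate_community(spec)
  pres <- suppressMessages(to_presence(g$table))
  # every planted-resident (otu, line) cell of a SPECIFIC OTU is present
  # unless dropout removed it; absent lines are strictly absent
  tr <- g$truth
  for (i in which(tr$class == "SPECIFIC")) {
    absent <- strsplit(tr$absent_lines[i], ",")[[1]]
    cols <- g$design$sample_id[g$design$line %in% absent]
    expect_true(all(pres$values[tr$otu_id[i], cols] == 0))
  }
})

test_that("the noiseless generator is exactly recovered by classification", {
  spec <- synthetic_spec(n_core = 6, n_specific = 10, n_transient = 50,
                         p_transient = 0, p_dropout = 0, coupling = 0,
                         depth_range = c(300, 500), seed = 17)
  g <- generate_community(spec)
  pres <- suppressMessages(to_presence(g$table))
  p <- partition_communities(pres)
  got_core <- p$otu$otu_id[p$otu$is_core]
  got_spec <- p$otu$otu_id[p$otu$is_line_specific]
  got_trans <- p$otu$otu_id[p$otu$category == "TRANSIENT"]
  expect_setequal(got_core, g$truth$otu_id[g$truth$class == "CORE"])
  expect_setequal(got_spec, g$truth$otu_id[g$truth$class == "SPECIFIC"])
  expect_setequal(got_trans, g$truth$otu_id[g$truth$class == "TRANSIENT"])
  # recovered resident line sets equal the planted ones
  for (i in which(g$truth$class == "SPECIFIC")) {
    planted <- sort(strsplit(g$truth$resident_lines[i], ",")[[1]])
    found <- sort(names(which(residency(pres)[g$truth$otu_id[i], ] == "RESIDENT")))
    expect_identical(found, planted)
  }
})

test_that("planted line-specific OTUs are recovered with high recall under mild noise", {
  spec <- synthetic_spec(n_core = 10, n_specific = 20, n_transient = 200,
                         p_transient = 0.1, p_dropout = 0.02,
                         depth_range = c(1000, 2000))
  recalls <- vapply(1:100, function(s) {
    g <- generate_community(spec, seed = s)
    pres <- suppressMessages(to_presence(g$table))
    p <- partition_communities(pres)
    planted <- g$truth$otu_id[g$truth$class == "SPECIFIC"]
    mean(planted %in% p$otu$otu_id[p$otu$is_line_specific])
  }, numeric(1))
  expect_gt(mean(recalls), 0.8)
})

test_that("fingerprint reduction keeps the dominant OTUs and nests monotonically", {
  spec <- synthetic_spec(n_core = 5, n_specific = 5, n_transient = 30,
                         depth_range = c(500, 700), seed = 23)
  g <- generate_community(spec)
  all_bands <- to_fingerprint(g$table, nrow(g$table$counts))
  pres <- suppressMessages(to_presence(g$table))
  expect_identical(all_bands$values, pres$values)
  one <- to_fingerprint(g$table, 1)
  expect_identical(nrow(one$values), 1L)
  for (k in c(5, 10, 20)) {
    a <- rownames(to_fingerprint(g$table, k)$values)
    b <- rownames(to_fingerprint(g$table, k + 1)$values)
    expect_true(all(a %in% b))
  }
})

test_that("wax coupling induces a community-chemistry correlation; lambda = 0 does not", {
  # with coupling the Mantel r between resident-community Jaccard and
  # wax Euclidean distances is positive for most seeds
  spec1 <- synthetic_spec(coupling = 1, p_dropout = 0, n_core = 10,
                          n_specific = 25, n_transient = 100,
                          depth_range = c(1000, 1500))
  rs <- vapply(1:30, function(s) {
    g <- generate_community(spec1, seed = s)
    pres <- suppressMessages(to_presence(g$table))
    res <- resident_submatrix(pres, partition_communities(pres))
    pv <- g$profile$values[res$design$sample_id, , drop = FALSE]
    mantel_test(jaccard_distances(res), euclidean_distances(profile_table(pv)),
                n_perm = 99, seed = s)$r
  }, numeric(1))
  expect_gt(mean(rs > 0), 0.9)
  # null calibration at line level: with lambda = 0 the assignment of
  # specific OTUs to lines is independent of wax chemistry, so the
  # Mantel p between line resident communities and line wax means is
  # uniform (sample-level matrices still share line-block structure, so
  # the null must be tested on the line-collapsed community)
  spec0 <- synthetic_spec(coupling = 0, p_dropout = 0, n_core = 10,
                          n_specific = 25, n_transient = 100,
                          depth_range = c(1000, 1500))
  ps <- vapply(1:80, function(s) {
    g <- generate_community(spec0, seed = s)
    pres <- suppressMessages(to_presence(g$table))
    lines <- line_residency_matrix(pres)
    mantel_test(jaccard_distances(lines),
                euclidean_distances(profile_table(g$wax_means)),
                exact = TRUE)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps <= 0.05), 0.15)
})
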