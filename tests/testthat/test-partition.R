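test_that("residency statuses follow the replicate definitions", {
  des <- make_design(2, 3)
  v <- rbind(
    all_A = c(1L, 1L, 1L, 0L, 1L, 0L),
    none_A = c(0L, 0L, 0L, 1L, 1L, 1L),
    one_A = c(1L, 0L, 0L, 0L, 0L, 0L))
  colnames(v) <- des$sample_id
  m <- binary_matrix(v, des)
  s <- residency(m)
  expect_identical(s["all_A", "A"], "RESIDENT")
  expect_identical(s["none_A", "A"], "ABSENT")
  expect_identical(s["one_A", "A"], "VARIABLE")
  # single replicate per line cannot be VARIABLE
  des1 <- make_design(3, 1)
  m1 <- random_presence(20, des1, p = 0.5)
  expect_false(any(residency(m1) == "VARIABLE"))
})

test_that("classification reproduces the category definitions on toy cases", {
  des <- make_design(2, 2)
  v <- rbind(
    everywhere = c(1L, 1L, 1L, 1L),
    only_A = c(1L, 1L, 0L, 0L),
    scattered = c(1L, 0L, 0L, 1L))
  colnames(v) <- des$sample_id
  m <- binary_matrix(v, des)
  p <- partition_communities(m)
  otu <- p$otu
  expect_identical(otu$category, c("RESIDENT", "RESIDENT", "TRANSIENT"))
  expect_identical(otu$is_core, c(TRUE, FALSE, FALSE))
  expect_identical(otu$is_line_specific, c(FALSE, TRUE, FALSE))
  expect_identical(otu$unique_present_line, c(NA, "A", NA))
  expect_identical(otu$unique_absent_line, c(NA, "B", NA))
})

test_that("classification agrees with an independent brute-force oracle", {
  des <- make_design(3, 3)
  set.seed(101)
  for (rep in seq_len(200)) {
    m <- random_presence(8, des, p = runif(1, 0.2, 0.8))
    p <- partition_communities(m)
    o <- oracle_classify(m$values, des)
    expect_identical(p$otu$category, o$category)
    expect_identical(p$otu$is_core, o$is_core)
    expect_identical(p$otu$is_line_specific, o$is_line_specific)
    expect_identical(p$otu$unique_present_line, o$unique_present_line)
    expect_identical(p$otu$unique_absent_line, o$unique_absent_line)
    expect_identical(p$otu$occupancy, as.integer(o$occupancy))
  }
})

test_that("partition algebra holds over random matrices", {
  set.seed(202)
  for (rep in seq_len(300)) {
    n_lines <- sample(2:5, 1); reps <- sample(2:4, 1)
    des <- make_design(n_lines, reps)
    m <- random_presence(sample(5:20, 1), des, p = runif(1, 0.1, 0.9))
    p <- partition_communities(m)
    otu <- p$otu
    # transient/resident: disjoint and exhaustive
    expect_true(all(otu$category %in% c("TRANSIENT", "RESIDENT")))
    # core and line-specific imply resident
    expect_true(all(otu$category[otu$is_core] == "RESIDENT"))
    expect_true(all(otu$category[otu$is_line_specific] == "RESIDENT"))
    # core and line-specific are mutually exclusive at slack 1 with >= 2 reps
    expect_false(any(otu$is_core & otu$is_line_specific))
    # unique present implies line-specific
    expect_true(all(otu$is_line_specific[!is.na(otu$unique_present_line)]))
    # Venn subset counts recount the line-specific set
    v <- venn_counts(p)
    expect_identical(sum(v$subsets$n), sum(otu$is_line_specific))
    expect_identical(v$per_line$unique_present,
                     vapply(p$lines, function(L)
                       sum(otu$unique_present_line == L, na.rm = TRUE),
                       integer(1), USE.NAMES = FALSE))
  }
})

test_that("classification is invariant to row and column permutations", {
  set.seed(303)
  des <- make_design(3, 3)
  m <- random_presence(12, des, p = 0.5)
  p0 <- partition_communities(m)
  perm_rows <- sample(nrow(m$values))
  perm_cols <- sample(ncol(m$values))
  m2 <- binary_matrix(m$values[perm_rows, perm_cols], des)
  p2 <- partition_communities(m2)
  o0 <- p0$otu[order(p0$otu$otu_id), ]
  o2 <- p2$otu[order(p2$otu$otu_id), ]
  rownames(o0) <- rownames(o2) <- NULL
  expect_identical(o0, o2)
})

test_that("summary percentages for transient + resident account for all reads", {
  set.seed(404)
  des <- make_design(3, 3)
  tab <- small_table(matrix(rpois(9 * 15, 4) + 0L, 15, 9), des)
  pres <- suppressMessages(to_presence(tab))
  p <- partition_communities(pres, counts = tab)
  s <- p$summary
  expect_equal(s$pct_reads[s$category == "transient"] +
               s$pct_reads[s$category == "resident"], 100)
  expect_true(s$pct_reads[s$category == "core"] <=
              s$pct_reads[s$category == "resident"] + 1e-9)
})

test_that("resident submatrix keeps exactly the resident OTUs, stably", {
  set.seed(505)
  des <- make_design(3, 3)
  m <- random_presence(30, des, p = 0.4)
  p <- partition_communities(m)
  sub <- resident_submatrix(m, p)
  expect_identical(nrow(sub$values), sum(p$otu$category == "RESIDENT"))
  # re-classifying the submatrix leaves every retained OTU resident
  p2 <- partition_communities(sub)
  expect_true(all(p2$otu$category == "RESIDENT"))
  # all-resident input is returned unchanged
  allres <- binary_matrix(matrix(1L, 3, 9,
                                 dimnames = list(paste0("o", 1:3),
                                                 des$sample_id)), des)
  pa <- partition_communities(allres)
  expect_identical(resident_submatrix(allres, pa)$values, allres$values)
  # no residents is an error
  none <- binary_matrix(matrix(c(1L, rep(0L, 8)), 1, 9, byrow = TRUE,
                               dimnames = list("o1", des$sample_id)), des)
  pn <- partition_communities(none)
  expect_error(resident_submatrix(none, pn), "no resident")
})

test_that("core slack controls the occupancy threshold", {
  des <- make_design(5, 3)
  v <- matrix(1L, 1, 15, dimnames = list("o1", des$sample_id))
  v[1, 1:2] <- 0L                       # present in 13 of 15 samples
  m <- binary_matrix(v, des)
  expect_false(partition_communities(m, core_slack = 1)$otu$is_core)
  expect_true(partition_communities(m, core_slack = 2)$otu$is_core)
})
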