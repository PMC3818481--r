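#' Build a pipeline configuration
#'
#' Collects the inputs and settings for [run_pipeline()]. Inputs may be
#' in-memory objects or TSV paths (loaded with the tables_io readers).
#'
#' @param otu_table An [otu_table()] or path to an OTU table TSV.
#' @param design A [sample_design()] or path (required when
#'   `otu_table` is a path).
#' @param profile Optional [profile_table()] or path; per-line profiles
#'   are expanded to samples for the Mantel test.
#' @param out_dir Output directory (created if missing).
#' @param depth Rarefaction depth, or `"auto"` for the minimum sample
#'   total.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param core_slack Core occupancy slack (default 1).
#' @param n_permutations ANOSIM/Mantel permutations (default 999).
#' @param drop_taxa Taxonomy substrings to filter (default
#'   `"chloroplast"`).
#' @param min_total_count Singleton filter threshold (default 2).
#' @param nmds_k,nmds_restarts NMDS dimension and restarts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(otu_table, design = NULL, profile = NULL,
                            out_dir, depth = "auto", seed = 1L,
                            core_slack = 1L, n_permutations = 999L,
                            drop_taxa = "chloroplast",
                            min_total_count = 2L,
                            nmds_k = 2L, nmds_restarts = 8L) {
  if (is.character(otu_table)) {
    if (is.null(design)) stop("design path required with an OTU table path")
    otu_table <- read_otu_table(otu_table, design)
  }
  if (is.character(profile)) profile <- read_profile_table(profile)
  stopifnot(inherits(otu_table, "otu_table"))
  structure(list(otu_table = otu_table, profile = profile,
                 out_dir = out_dir, depth = depth, seed = as.integer(seed),
                 core_slack = as.integer(core_slack),
                 n_permutations = as.integer(n_permutations),
                 drop_taxa = drop_taxa,
                 min_total_count = as.integer(min_total_count),
                 nmds_k = as.integer(nmds_k),
                 nmds_restarts = as.integer(nmds_restarts)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full partition-and-statistics pipeline
#'
#' Stage order mirrors the analysis workflow: filter, rarefy to even
#' depth, classify OTUs from replicate presence/absence, extract the
#' resident community, then compute the beta-diversity statistics on the
#' resident matrix (Jaccard distances, ANOSIM by plant line with
#' pairwise comparisons, NMDS, UPGMA dendrogram, complete-linkage
#' heatmap ordering, and — when a wax profile is supplied — a Mantel
#' test against Euclidean profile distances). Each artifact is written
#' as TSV/Newick with the seed recorded in its header, plus a JSON run
#' manifest; with a fixed seed two runs produce byte-identical bundles.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of all in-memory stage results (including
#'   `depth_used` and `files`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  hdr <- function(what) c(sprintf("phyllopart %s", what),
                          sprintf("seed: %d", cfg$seed))
  files <- character(0)
  note <- function(f) files <<- c(files, f)

  filtered <- stage("filter", filter_table(cfg$otu_table, cfg$drop_taxa,
                                           cfg$min_total_count))
  note(write_otu_table(filtered, out("01_filtered_otu_table.tsv"),
                       hdr("filtered OTU table")))

  depth_used <- if (identical(cfg$depth, "auto"))
    min(colSums(filtered$counts)) else as.integer(cfg$depth)
  rarefied <- stage("rarefy", rarefy(filtered, depth_used,
                                     seed = derive_seed(cfg$seed, 1L)))
  note(write_otu_table(rarefied, out("02_rarefied_otu_table.tsv"),
                       c(hdr("rarefied OTU table"),
                         sprintf("depth: %d", depth_used))))

  pres <- stage("presence", suppressMessages(to_presence(rarefied)))
  part <- stage("partition",
                partition_communities(pres, counts = rarefied,
                                      core_slack = cfg$core_slack))
  note(write_with_header(part$otu, out("03_otu_categories.tsv"),
                         hdr("per-OTU categories")))
  note(write_with_header(part$summary, out("04_partition_summary.tsv"),
                         hdr("partition summary")))

  resident <- stage("resident", resident_submatrix(pres, part))
  note(write_binary_matrix(resident, out("05_resident_matrix.tsv"),
                           hdr("resident community matrix")))

  heat <- stage("heatmap_order", {
    ord_rows <- if (nrow(resident$values) >= 2)
      complete_linkage(jaccard_distances(t(resident$values)))$leaf_order
    else rownames(resident$values)
    ord_cols <- if (ncol(resident$values) >= 2)
      complete_linkage(jaccard_distances(resident$values))$leaf_order
    else colnames(resident$values)
    resident$values[ord_rows, ord_cols, drop = FALSE]
  })
  note(write_with_header(
    data.frame(feature_id = rownames(heat), heat, check.names = FALSE),
    out("06_heatmap_matrix.tsv"), hdr("heatmap-ordered resident matrix")))

  jd <- stage("jaccard", jaccard_distances(resident))
  jm <- dist_matrix(jd)
  note(write_with_header(
    data.frame(sample_id = rownames(jm), jm, check.names = FALSE),
    out("07_jaccard_distances.tsv"), hdr("Jaccard distance matrix")))

  grouping <- stats::setNames(resident$design$line, resident$design$sample_id)
  ano <- stage("anosim", anosim_test(jd, grouping,
                                     n_perm = cfg$n_permutations,
                                     seed = derive_seed(cfg$seed, 2L)))
  ano_df <- rbind(
    data.frame(group_a = "(global)", group_b = "(global)",
               R = ano$R, p = ano$p, testable = TRUE,
               stringsAsFactors = FALSE),
    ano$pairwise)
  note(write_with_header(ano_df, out("08_anosim.tsv"), hdr("ANOSIM results")))
  writeLines(c(paste0("# ", hdr("ANOSIM pairwise R (asterisk: p < 0.05)")),
               pairwise_table(ano, 0.05)),
             out("08_anosim_pairwise.txt"))
  note(out("08_anosim_pairwise.txt"))

  ord <- stage("nmds", nmds(jd, k = cfg$nmds_k,
                            n_restarts = cfg$nmds_restarts,
                            seed = derive_seed(cfg$seed, 3L)))
  note(write_with_header(
    data.frame(sample_id = rownames(ord$points), ord$points,
               check.names = FALSE),
    out("09_nmds_coordinates.tsv"),
    c(hdr("NMDS coordinates"), sprintf("stress: %.6f", ord$stress))))

  tree <- stage("upgma", upgma(jd))
  writeLines(tree$newick, out("10_upgma.nwk"))
  note(out("10_upgma.nwk"))

  man <- NULL
  if (!is.null(cfg$profile)) {
    man <- stage("mantel", {
      p <- cfg$profile
      expanded <- FALSE
      if (!all(resident$design$sample_id %in% rownames(p$values))) {
        p <- expand_profile(p, resident$design)
        expanded <- TRUE
      }
      pv <- p$values[resident$design$sample_id, , drop = FALSE]
      fit <- mantel_test(jd, euclidean_distances(profile_table(pv)),
                         n_perm = cfg$n_permutations,
                         seed = derive_seed(cfg$seed, 4L))
      fit$profile_expanded_from_lines <- expanded
      fit
    })
    note(write_with_header(
      data.frame(r = man$r, p = man$p, n_perm = man$n_perm,
                 profile_expanded_from_lines = man$profile_expanded_from_lines),
      out("11_mantel.tsv"), hdr("Mantel test")))
  }

  venn <- stage("venn", venn_counts(part))
  note(write_with_header(venn$per_line, out("12_venn_per_line.tsv"),
                         hdr("uniquely present/absent OTUs per line")))
  note(write_with_header(venn$subsets, out("12_venn_subsets.tsv"),
                         hdr("line-specific OTUs per resident line set")))

  manifest <- list(
    package = "phyllopart",
    version = as.character(utils::packageVersion("phyllopart")),
    seed = cfg$seed, depth = depth_used,
    core_slack = cfg$core_slack, n_permutations = cfg$n_permutations,
    drop_taxa = cfg$drop_taxa, min_total_count = cfg$min_total_count,
    nmds = list(k = cfg$nmds_k, restarts = cfg$nmds_restarts),
    stages = c("filter", "rarefy", "presence", "partition", "resident",
               "heatmap_order", "jaccard", "anosim", "nmds", "upgma",
               if (!is.null(cfg$profile)) "mantel", "venn"),
    n_otus_in = nrow(cfg$otu_table$counts),
    n_otus_filtered = nrow(filtered$counts),
    n_samples = ncol(filtered$counts),
    files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  note(out("manifest.json"))

  invisible(list(filtered = filtered, rarefied = rarefied,
                 presence = pres, partition = part, resident = resident,
                 heatmap = heat, jaccard = jd, anosim = ano, nmds = ord,
                 upgma = tree, mantel = man, venn = venn,
                 depth_used = depth_used, files = files))
}

#' Render pairwise ANOSIM results as a lower-triangle table
#'
#' One row/column per group; each cell shows the pairwise R, with an
#' asterisk iff its permutation p is below `threshold`; untestable pairs
#' show `NA`.
#'
#' @param a An [anosim_test()] result with pairwise comparisons.
#' @param threshold Significance threshold for the asterisk.
#' @return Character vector of table lines.
#' @export
pairwise_table <- function(a, threshold) {
  stopifnot(inherits(a, "anosim_test"))
  if (is.null(a$pairwise)) stop("no pairwise results")
  groups <- sort(unique(a$grouping))
  cellw <- max(nchar(groups), 8L)
  fmt <- function(s) formatC(s, width = cellw)
  lines <- paste0(fmt(""), "")
  for (i in seq_along(groups)[-1]) {
    row <- fmt(groups[i])
    for (j in seq_len(i - 1)) {
      hit <- a$pairwise[(a$pairwise$group_a == groups[i] & a$pairwise$group_b == groups[j]) |
                        (a$pairwise$group_a == groups[j] & a$pairwise$group_b == groups[i]), ]
      cell <- if (nrow(hit) == 0 || !hit$testable[1]) "NA"
      else sprintf("%.3f%s", hit$R[1],
                   if (!is.na(hit$p[1]) && hit$p[1] < threshold) "*" else "")
      row <- paste0(row, fmt(cell))
    }
    lines <- c(lines, row)
  }
  header <- paste0(fmt(""), paste0(vapply(groups[-length(groups)], fmt,
                                          character(1)), collapse = ""))
  c(header, lines[-1])
}
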