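# Per-line cuticular wax compound-class baselines (ug cm^-2) for a
# 5-line Arabidopsis design: Landsberg erecta wild type and four
# eceriferum wax mutants. Alkane, fatty-acid and aldehyde totals follow
# the measured per-line amounts; ester and alkanol values sit inside the
# measured ranges; "additional" is the measured total wax load minus the
# other classes.
wax_baselines <- function() {
  m <- rbind(
    Ler   = c(2.30, 1.25, 0.01, 0.30, 0.33, 0.30),
    cer1  = c(0.48, 1.08, 0.01, 0.30, 0.33, 0.08),
    cer6  = c(0.97, 0.62, 0.01, 0.44, 0.33, 0.18),
    cer9  = c(0.45, 1.61, 0.01, 0.43, 0.07, 0.77),
    cer16 = c(1.71, 0.91, 0.03, 0.30, 0.33, 0.10))
  colnames(m) <- c("alkanes", "fatty_acids", "aldehydes", "alkyl_esters",
                   "prim_alkanols", "additional")
  m
}

#' Specification of a synthetic phyllosphere community
#'
#' Parameters of the generator, defaulting to the study conditions: a
#' 5-line x 3-replicate design, 507 OTUs split into 13 core, 35
#' line-specific and 459 transient, per-sample depths uniform on
#' 2340-10010 reads, lognormal rank-abundance, per-line wax profiles
#' from measured compound-class baselines, and full coupling between wax
#' chemistry and which lines share the line-specific OTUs.
#'
#' @param n_lines Number of plant lines (default 5).
#' @param reps_per_line Biological replicates per line (default 3).
#' @param n_core Planted core OTUs (default 13).
#' @param n_specific Planted line-specific OTUs (default 35).
#' @param n_transient Planted transient OTUs (default 459).
#' @param p_transient Per-sample occupancy probability of a transient
#'   OTU (default 0.1).
#' @param p_dropout Probability a core/resident OTU is missed in one
#'   sample (observation noise; default 0.02).
#' @param depth_range Reads per sample, uniform integer range (default
#'   c(2340, 10010)).
#' @param abundance_shape Lognormal sigma of the rank-abundance
#'   distribution (default 1.5).
#' @param wax_features Number of wax compound classes (default 6; with 5
#'   lines and 6 features the measured baselines are used, otherwise
#'   baselines are drawn lognormally).
#' @param wax_noise_sd SD of Gaussian replicate noise around the line
#'   wax means, ug cm^-2 (default 0.15).
#' @param coupling Strength lambda in \[0,1\] with which wax-space
#'   distance between lines determines sharing of line-specific OTUs
#'   (default 1; 0 decouples community from chemistry).
#' @param seed Integer seed (default 1).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lines = 5L, reps_per_line = 3L,
                           n_core = 13L, n_specific = 35L,
                           n_transient = 459L,
                           p_transient = 0.1, p_dropout = 0.02,
                           depth_range = c(2340L, 10010L),
                           abundance_shape = 1.5,
                           wax_features = 6L, wax_noise_sd = 0.15,
                           coupling = 1, seed = 1L) {
  stopifnot(n_lines >= 1, reps_per_line >= 1,
            n_core >= 0, n_specific >= 0, n_transient >= 0,
            n_core + n_specific + n_transient >= 1,
            p_transient >= 0, p_transient <= 1,
            p_dropout >= 0, p_dropout <= 1,
            length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[1] <= depth_range[2],
            abundance_shape >= 0, wax_features >= 1, wax_noise_sd >= 0,
            coupling >= 0, coupling <= 1)
  if (n_specific > 0 && n_lines < 2)
    stop("line-specific OTUs require at least 2 lines")
  structure(list(n_lines = as.integer(n_lines),
                 reps_per_line = as.integer(reps_per_line),
                 n_core = as.integer(n_core),
                 n_specific = as.integer(n_specific),
                 n_transient = as.integer(n_transient),
                 p_transient = p_transient, p_dropout = p_dropout,
                 depth_range = as.integer(depth_range),
                 abundance_shape = abundance_shape,
                 wax_features = as.integer(wax_features),
                 wax_noise_sd = wax_noise_sd,
                 coupling = coupling, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic community with planted ground truth
#'
#' Emulates the data structure the partition analysis assumes:
#' * per-line wax mean vectors (measured baselines for the default
#'   5-line/6-class setting) plus Gaussian replicate noise give a
#'   per-sample chemical profile table;
#' * an occupancy mask plants the categories: core OTUs are present in
#'   every sample apart from independent dropouts; line-specific OTUs
#'   are present in all replicates of their resident lines (minus
#'   dropouts), strictly absent from their absent lines, and Bernoulli
#'   elsewhere; transient OTUs are i.i.d. Bernoulli per sample. With
#'   coupling > 0 a line joins a specific OTU's resident set with
#'   probability decreasing in its wax-space distance from the anchor
#'   line, inducing a true wax-community correlation;
#' * per-OTU lognormal relative abundances, renormalized over the OTUs
#'   present in each sample, and a uniform random depth per sample turn
#'   the mask into multinomial read counts. Every present OTU receives
#'   at least one read, so the counts realise the planted mask exactly.
#'
#' Deterministic given `spec$seed` (overridable with `seed`).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return List with `table` ([otu_table()]), `design`
#'   ([sample_design()]), `profile` (per-sample [profile_table()]),
#'   `truth` (data frame: otu_id, class, resident_lines, absent_lines)
#'   and `wax_means` (line x class matrix).
#' @export
generate_community <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, generate_community_impl(spec))
}

generate_community_impl <- function(spec) {
  lines <- if (spec$n_lines == 5L) rownames(wax_baselines())
           else paste0("line", seq_len(spec$n_lines))
  design <- sample_design(data.frame(
    sample_id = paste(rep(lines, each = spec$reps_per_line),
                      rep(seq_len(spec$reps_per_line), spec$n_lines),
                      sep = "_"),
    line = rep(lines, each = spec$reps_per_line),
    replicate = rep(seq_len(spec$reps_per_line), spec$n_lines)))
  n_samples <- nrow(design)

  # wax means and per-sample profiles
  if (spec$n_lines == 5L && spec$wax_features == 6L) {
    wax_means <- wax_baselines()
  } else {
    wax_means <- matrix(stats::rlnorm(spec$n_lines * spec$wax_features,
                                      meanlog = -0.7, sdlog = 0.8),
                        spec$n_lines, spec$wax_features,
                        dimnames = list(lines,
                                        paste0("class", seq_len(spec$wax_features))))
  }
  prof <- wax_means[design$line, , drop = FALSE] +
    matrix(stats::rnorm(n_samples * ncol(wax_means), sd = spec$wax_noise_sd),
           n_samples, ncol(wax_means))
  prof[prof < 0] <- 0
  rownames(prof) <- design$sample_id
  profile <- profile_table(prof)

  n_otu <- spec$n_core + spec$n_specific + spec$n_transient
  otu_ids <- sprintf("OTU%04d", seq_len(n_otu))
  classes <- rep(c("CORE", "SPECIFIC", "TRANSIENT"),
                 c(spec$n_core, spec$n_specific, spec$n_transient))

  wax_dist <- as.matrix(stats::dist(wax_means))
  d_scale <- if (spec$n_lines > 1) stats::median(wax_dist[lower.tri(wax_dist)]) else 1
  if (!is.finite(d_scale) || d_scale <= 0) d_scale <- 1

  mask <- matrix(0L, n_otu, n_samples, dimnames = list(otu_ids, design$sample_id))
  res_lines <- rep(NA_character_, n_otu)
  abs_lines <- rep(NA_character_, n_otu)
  line_cols <- lapply(lines, function(L) which(design$line == L))
  names(line_cols) <- lines

  for (i in seq_len(n_otu)) {
    cls <- classes[i]
    if (cls == "CORE") {
      mask[i, ] <- 1L
      res_lines[i] <- paste(lines, collapse = ",")
      abs_lines[i] <- ""
    } else if (cls == "SPECIFIC") {
      anchor <- sample(lines, 1)
      others <- setdiff(lines, anchor)
      w <- (1 - spec$coupling) * 0.5 +
        spec$coupling * exp(-wax_dist[anchor, others] / d_scale)
      joins <- stats::runif(length(others)) < w
      members <- c(anchor, others[joins])
      non <- setdiff(lines, members)
      if (length(non) == 0) {            # keep the resident set proper
        drop <- others[which.min(w)]
        members <- setdiff(members, drop)
        non <- drop
      }
      # non-member lines: mostly strictly absent, occasionally variable
      absent <- non[stats::runif(length(non)) < 0.7]
      variable <- setdiff(non, absent)
      if (length(absent) == 0) {         # specific OTUs need an absent line
        pick <- if (length(variable) > 0) variable[1] else non[1]
        absent <- pick
        variable <- setdiff(variable, pick)
      }
      for (L in members) mask[i, line_cols[[L]]] <- 1L
      for (L in variable)
        mask[i, line_cols[[L]]] <-
          as.integer(stats::runif(length(line_cols[[L]])) < spec$p_transient)
      res_lines[i] <- paste(members, collapse = ",")
      abs_lines[i] <- paste(absent, collapse = ",")
    } else {
      mask[i, ] <- as.integer(stats::runif(n_samples) < spec$p_transient)
    }
  }

  # observation noise: core/specific resident presences can drop out
  if (spec$p_dropout > 0) {
    solid <- classes != "TRANSIENT"
    drop <- matrix(stats::runif(sum(solid) * n_samples) < spec$p_dropout,
                   sum(solid), n_samples)
    mask[solid, ][drop] <- 0L
  }

  # abundances and counts
  abund <- stats::rlnorm(n_otu, meanlog = 0, sdlog = spec$abundance_shape)
  depths <- spec$depth_range[1] +
    floor(stats::runif(n_samples) * (spec$depth_range[2] - spec$depth_range[1] + 1L))
  counts <- matrix(0L, n_otu, n_samples, dimnames = dimnames(mask))
  for (j in seq_len(n_samples)) {
    present <- which(mask[, j] == 1L)
    if (length(present) == 0)
      stop("sample '", design$sample_id[j], "' has no present OTUs; ",
           "increase n_core or p_transient")
    if (depths[j] < length(present))
      stop("depth ", depths[j], " smaller than number of present OTUs")
    extra <- stats::rmultinom(1, depths[j] - length(present),
                              abund[present] / sum(abund[present]))
    counts[present, j] <- 1L + extra[, 1]
  }

  truth <- data.frame(otu_id = otu_ids, class = classes,
                      resident_lines = res_lines, absent_lines = abs_lines,
                      stringsAsFactors = FALSE)
  list(table = otu_table(counts, design), design = design,
       profile = profile, truth = truth, wax_means = wax_means)
}

#' Reduce a community to a fingerprint-style binary matrix
#'
#' Presence/absence of the `top_k` highest-total-count OTUs: a band-like
#' reduction emulating a DGGE fingerprint, where only the dominant
#' community members produce visible bands. Ties in total count are
#' broken by OTU id.
#'
#' @param t An [otu_table()].
#' @param top_k Number of dominant OTUs to keep.
#' @return A [binary_matrix()] with `top_k` rows.
#' @export
to_fingerprint <- function(t, top_k) {
  stopifnot(inherits(t, "otu_table"), top_k >= 1,
            top_k <= nrow(t$counts))
  tot <- rowSums(t$counts)
  ord <- order(-tot, rownames(t$counts))
  keep <- sort(ord[seq_len(top_k)])
  binary_matrix((t$counts[keep, , drop = FALSE] > 0) * 1L, t$design)
}
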