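#' Configuration for a simulated multiplexed perturbation screen
#'
#' The generator emulates a TMT-multiplexed cytotoxic-compound screen at a
#' normalized biological endpoint: each compound carries a few strongly and
#' specifically regulated target proteins, a death/stress response shared
#' (with compound-specific intensity) across almost all compounds,
#' co-regulated protein clusters, replicate noise, per-channel loading
#' differences, per-plex batch effects and per-plex missing values.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_compounds number of library compounds (3 replicates each by
#'   default).
#' @param n_replicates biological replicates per compound.
#' @param n_controls_per_plex vehicle-control channels per plex.
#' @param plex_size channels per multiplexed experiment (default 10,
#'   TMT-10).
#' @param targets_per_compound planted specifically regulated proteins per
#'   compound.
#' @param target_effect |log2 fold change| of a planted target.
#' @param target_direction `"up"`, `"down"` or `"mixed"` (random sign per
#'   target).
#' @param death_frac fraction of proteins in the shared death/stress
#'   response.
#' @param death_magnitude_mean,death_magnitude_sd per-protein death-response
#'   magnitude, drawn once (log2 scale); 75% of the response proteins go
#'   up, the rest down.
#' @param death_scale_sdlog per-compound death-response scale is drawn
#'   log-normal(0, `death_scale_sdlog`), so generic response proteins are
#'   regulated under (almost) all compounds.
#' @param n_protein_clusters co-regulation modules covering all proteins.
#' @param cluster_sd standard deviation (log2) of the per-compound cluster
#'   background.
#' @param within_cluster_cor correlation of the cluster background between
#'   proteins of the same module.
#' @param noise_sd replicate noise standard deviation (log2 scale).
#' @param plex_batch_sd per-protein, per-plex batch offset SD (log2).
#' @param channel_scale_sd per-channel loading offset SD (log2); removed by
#'   [median_normalize()].
#' @param dropout_prob probability that a protein is missing (zero) in an
#'   entire plex.
#' @param frac_single_peptide fraction of (non-planted) proteins given a
#'   single unique peptide, to exercise the peptide filter.
#' @param frac_contaminant fraction flagged as contaminants.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution
#'   (log-normal intensities, the standard assumption for proteomics).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200L, n_compounds = 9L,
                       n_replicates = 3L, n_controls_per_plex = 1L,
                       plex_size = 10L, targets_per_compound = 1L,
                       target_effect = 2, target_direction = "up",
                       death_frac = 0.10, death_magnitude_mean = 0.8,
                       death_magnitude_sd = 0.3, death_scale_sdlog = 0.4,
                       n_protein_clusters = 10L, cluster_sd = 0.25,
                       within_cluster_cor = 0.5, noise_sd = 0.25,
                       plex_batch_sd = 0.1, channel_scale_sd = 0.1,
                       dropout_prob = 0, frac_single_peptide = 0.05,
                       frac_contaminant = 0.02, baseline_mean = 20,
                       baseline_sd = 2, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$plex_size > cfg$n_controls_per_plex,
            cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
            cfg$within_cluster_cor >= 0, cfg$within_cluster_cor <= 1,
            target_direction %in% c("up", "down", "mixed"),
            cfg$targets_per_compound * cfg$n_compounds +
              ceiling(cfg$death_frac * cfg$n_proteins) < cfg$n_proteins)
  structure(cfg, class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"tiny"`: 200 proteins, 9 compounds, 3 plexes — fast enough for unit
#' tests. `"screen"`: 5000 proteins, 27 compounds, 9 plexes — the scale of
#' a full signature-library screen.
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("tiny", "screen"), ...) {
  name <- match.arg(name)
  args <- switch(name,
                 tiny = list(n_proteins = 200L, n_compounds = 9L),
                 screen = list(n_proteins = 5000L, n_compounds = 27L))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Simulate a multiplexed perturbation-proteomics screen
#'
#' Draws one log2 baseline per protein, adds compound-specific target
#' effects, the shared death response, cluster-correlated per-compound
#' background, per-plex batch offsets, per-channel loading offsets and
#' replicate noise, exponentiates to reporter intensities, and applies
#' per-plex dropout. Treated samples are laid out replicate-major so a
#' compound's replicates fall into different plexes, as in a real screen.
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_screen`: `tables` (one [abundance_table()]
#'   per plex), `design` (a `sample_design`), and `truth` — the planted
#'   ground truth (targets and effects, death-response membership and
#'   per-compound scales, cluster memberships, plex map, filter-survivor
#'   count, and the config).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  p <- cfg$n_proteins
  acc <- sprintf("P%05d", seq_len(p))
  gene <- sprintf("G%05d", seq_len(p))

  compounds <- sprintf("C%02d", seq_len(cfg$n_compounds))
  # planted structure ----------------------------------------------------
  n_death <- ceiling(cfg$death_frac * p)
  special <- sample(p, cfg$targets_per_compound * cfg$n_compounds + n_death)
  target_idx <- special[seq_len(cfg$targets_per_compound * cfg$n_compounds)]
  death_idx <- special[-seq_len(cfg$targets_per_compound * cfg$n_compounds)]
  target_map <- data.frame(
    compound = rep(compounds, each = cfg$targets_per_compound),
    accession = acc[target_idx],
    row = target_idx,
    effect = cfg$target_effect *
      switch(cfg$target_direction,
             up = 1,
             down = -1,
             mixed = sample(c(-1, 1), length(target_idx), replace = TRUE)),
    stringsAsFactors = FALSE)
  death_sign <- ifelse(stats::runif(n_death) < 0.75, 1, -1)
  death_mag <- abs(stats::rnorm(n_death, cfg$death_magnitude_mean,
                                cfg$death_magnitude_sd))
  death_vec <- numeric(p)
  death_vec[death_idx] <- death_sign * death_mag
  death_scale <- stats::setNames(
    stats::rlnorm(cfg$n_compounds, 0, cfg$death_scale_sdlog), compounds)
  clusters <- stats::setNames(
    sample(rep_len(seq_len(cfg$n_protein_clusters), p)), acc)

  # flags (kept off the planted proteins so truth counts stay clean) -----
  plain <- setdiff(seq_len(p), special)
  n_single <- round(cfg$frac_single_peptide * p)
  n_contam <- round(cfg$frac_contaminant * p)
  flagged <- sample(plain, min(n_single + n_contam, length(plain)))
  single_idx <- flagged[seq_len(min(n_single, length(flagged)))]
  contam_idx <- setdiff(flagged, single_idx)
  unique_peptides <- sample(2:30, p, replace = TRUE)
  unique_peptides[single_idx] <- 1L
  is_contaminant <- seq_len(p) %in% contam_idx

  # sample layout: replicate-major so replicates spread across plexes ----
  treated <- data.frame(
    compound = rep(compounds, times = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), each = cfg$n_compounds),
    stringsAsFactors = FALSE)
  cap <- cfg$plex_size - cfg$n_controls_per_plex
  n_plex <- ceiling(nrow(treated) / cap)
  treated$experiment_id <- sprintf("plex%02d", rep(seq_len(n_plex),
                                                   each = cap)[seq_len(nrow(treated))])
  treated$sample_id <- sprintf("%s_r%d", treated$compound, treated$replicate)

  # per-compound biological signal (shared by its replicates) ------------
  rho <- cfg$within_cluster_cor
  u <- matrix(stats::rnorm(cfg$n_protein_clusters * cfg$n_compounds),
              cfg$n_protein_clusters, cfg$n_compounds)
  v <- matrix(stats::rnorm(p * cfg$n_compounds), p, cfg$n_compounds)
  bg <- cfg$cluster_sd * (sqrt(rho) * u[clusters, , drop = FALSE] +
                            sqrt(1 - rho) * v)
  colnames(bg) <- compounds
  signal <- bg + outer(death_vec, death_scale[compounds])
  for (i in seq_len(nrow(target_map))) {
    signal[target_map$row[i], target_map$compound[i]] <-
      signal[target_map$row[i], target_map$compound[i]] + target_map$effect[i]
  }

  baseline <- stats::rnorm(p, cfg$baseline_mean, cfg$baseline_sd)

  tables <- list()
  design_rows <- list()
  for (e in sprintf("plex%02d", seq_len(n_plex))) {
    te <- treated[treated$experiment_id == e, , drop = FALSE]
    ctrl_ids <- sprintf("ctrl_%s_%d", e, seq_len(cfg$n_controls_per_plex))
    ids <- c(ctrl_ids, te$sample_id)
    batch <- stats::rnorm(p, 0, cfg$plex_batch_sd)
    L <- matrix(baseline + batch, p, length(ids))
    for (j in seq_along(te$sample_id)) {
      L[, cfg$n_controls_per_plex + j] <-
        L[, cfg$n_controls_per_plex + j] + signal[, te$compound[j]]
    }
    L <- L + matrix(stats::rnorm(p * length(ids), 0, cfg$noise_sd),
                    p, length(ids))
    L <- sweep(L, 2, stats::rnorm(length(ids), 0, cfg$channel_scale_sd), `+`)
    inten <- 2^L
    if (cfg$dropout_prob > 0) {
      drop_rows <- stats::runif(p) < cfg$dropout_prob
      inten[drop_rows, ] <- 0
    }
    tables[[e]] <- abundance_table(acc, gene, unique_peptides,
                                   is_contaminant, rep(FALSE, p),
                                   inten, ids, e)
    design_rows[[e]] <- data.frame(
      sample_id = ids,
      compound = c(rep("vehicle", length(ctrl_ids)), te$compound),
      cell_line = "SIM1",
      replicate = c(seq_along(ctrl_ids), te$replicate),
      experiment_id = e,
      is_control = c(rep(TRUE, length(ctrl_ids)),
                     rep(FALSE, nrow(te))),
      stringsAsFactors = FALSE)
  }
  design <- as_sample_design(do.call(rbind, design_rows))
  truth <- list(
    targets = target_map[, c("compound", "accession", "effect")],
    death_proteins = acc[death_idx],
    death_effect = stats::setNames(death_vec[death_idx], acc[death_idx]),
    death_scale = death_scale,
    clusters = clusters,
    plex_map = stats::setNames(design$experiment_id, design$sample_id),
    n_pass_filter = sum(unique_peptides >= 2 & !is_contaminant),
    config = unclass(cfg))
  structure(list(tables = tables, design = design, truth = truth),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cfg <- x$truth$config
  cat("sim_screen:", cfg$n_proteins, "proteins,", cfg$n_compounds,
      "compounds x", cfg$n_replicates, "replicates in",
      length(x$tables), "plex(es), seed", cfg$seed, "\n")
  invisible(x)
}

#' Run the full normalization chain on a simulated screen
#'
#' Convenience wrapper: peptide/QC filter, per-channel median
#' normalization, log2 fold change versus control mean, per-column median
#' centering, and a complete-case merge across plexes.
#'
#' @param sim a `sim_screen` from [simulate_screen()].
#' @param min_unique_peptides passed to [filter_proteins()].
#' @param center_mode passed to [global_median_center()].
#' @param policy merge policy (default `"complete"`).
#' @return An [expression_matrix()].
#' @export
sim_expression <- function(sim, min_unique_peptides = 2L,
                           center_mode = "per_sample",
                           policy = "complete") {
  stopifnot(inherits(sim, "sim_screen"))
  ms <- lapply(sim$tables, function(tbl) {
    tbl <- filter_proteins(tbl, min_unique_peptides)
    tbl <- median_normalize(tbl)
    global_median_center(compute_log2fc(tbl, sim$design), mode = center_mode)
  })
  merge_experiments(ms, policy = policy)
}

#' Write a simulated screen to disk
#'
#' Produces the protein-group dialect consumed by [read_protein_groups()]
#' (one tab-delimited table whose intensity columns are named by sample
#' id), the design CSV, and a JSON ground-truth sidecar.
#'
#' @param sim a `sim_screen`.
#' @param dir output directory (created if needed).
#' @return Named list of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t1 <- sim$tables[[1]]
  inten <- do.call(cbind, lapply(sim$tables, function(tb) tb$intensities))
  # full-precision text so a write -> read round trip is bit-exact
  inten <- apply(inten, 2, function(v) sprintf("%.17g", v))
  df <- data.frame(
    "Protein IDs" = t1$protein_id,
    "Gene names" = t1$gene_name,
    "Unique peptides" = t1$unique_peptides,
    "Potential contaminant" = ifelse(t1$is_contaminant, "+", ""),
    "Reverse" = ifelse(t1$is_reverse, "+", ""),
    inten, check.names = FALSE, stringsAsFactors = FALSE)
  pg <- file.path(dir, "proteinGroups.txt")
  utils::write.table(df, pg, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- file.path(dir, "design.csv")
  utils::write.csv(as.data.frame(sim$design), ds, row.names = FALSE)
  tr <- file.path(dir, "truth.json")
  truth <- sim$truth
  truth$clusters <- as.list(truth$clusters)
  jsonlite::write_json(truth, tr, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(protein_groups = pg, design = ds, truth = tr))
}
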