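#' Specification of a one-vs-rest compound contrast
#'
#' @param compound compound to contrast against the rest of the panel.
#' @param cell_lines optional subset of cell lines (default: all present).
#' @param excluded_compounds compounds dropped from the contrasting panel
#'   (gross outliers are excluded manually after inspection, not
#'   automatically).
#' @param scaling preprocessing mode for [scale_matrix()].
#' @param n_ortho orthogonal components for [fit_oplsda()] (or `"auto"`).
#' @param seed seed for the cross-validation fold assignment.
#' @param compute_q2 fill the model's Q2 by seven-fold cross-validation
#'   (default `TRUE`; disable in large screening loops where only the
#'   ranking is needed).
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(compound, cell_lines = NULL,
                          excluded_compounds = character(0),
                          scaling = "uv", n_ortho = 1L, seed = 1L,
                          compute_q2 = TRUE) {
  if (compound %in% excluded_compounds) {
    stop("the contrasted compound cannot be in excluded_compounds")
  }
  structure(list(compound = compound, cell_lines = cell_lines,
                 excluded_compounds = excluded_compounds,
                 scaling = scaling, n_ortho = n_ortho,
                 seed = as.integer(seed), compute_q2 = isTRUE(compute_q2)),
            class = "contrast_spec")
}

.contrast_samples <- function(m, spec) {
  d <- m$design
  keep <- !d$is_control & !(d$compound %in% spec$excluded_compounds)
  if (!is.null(spec$cell_lines)) keep <- keep & d$cell_line %in% spec$cell_lines
  avail <- sort(unique(d$compound[keep]))
  if (!spec$compound %in% avail) {
    stop("compound '", spec$compound, "' not in the matrix; available: ",
         paste(avail, collapse = ", "))
  }
  if (sum(keep & d$compound == spec$compound) < 2L) {
    stop("compound '", spec$compound, "' has fewer than 2 replicates")
  }
  keep
}

#' Build a one-vs-rest OPLS-DA contrast and target ranking
#'
#' Fits an OPLS-DA model of the given compound's samples against all other
#' compounds' samples (vehicle controls are excluded from both classes) and
#' derives a per-protein ranking table: predictive loading (signed
#' specificity coordinate), orthogonal coordinate, VIP, specificity versus
#' the median of the other compounds, and dense up/down ranks. Proteins
#' near the positive end of the predictive axis with a small orthogonal
#' coordinate are the specifically up-regulated target candidates.
#'
#' @param m a complete (no missing values) [expression_matrix()].
#' @param spec a [contrast_spec()].
#' @return List of class `contrast_result` with elements `model`
#'   (`opls_model`) and `ranking` (data.frame sorted by `rank_up`, then the
#'   down side by `rank_down`). Ties in any ranking are broken by
#'   accession order.
#' @export
build_contrast <- function(m, spec) {
  stopifnot(inherits(m, "expression_matrix"), inherits(spec, "contrast_spec"))
  keep <- .contrast_samples(m, spec)
  d <- m$design
  vals <- m$values[, keep, drop = FALSE]
  if (anyNA(vals)) {
    stop("matrix contains missing values; merge with policy = \"complete\"")
  }
  X <- t(vals)
  y <- as.integer(d$compound[keep] == spec$compound)
  model <- fit_oplsda(X, y, n_ortho = spec$n_ortho, scaling = spec$scaling,
                      seed = spec$seed, compute_q2 = spec$compute_q2)
  ranking <- .ranking_table(m, model, spec)
  structure(list(model = model, ranking = ranking, spec = spec),
            class = "contrast_result")
}

.ranking_table <- function(m, model, spec) {
  acc <- rownames(model$W)
  p_pred <- stats::setNames(drop(model$P[, 1]), acc)
  orth <- if (model$n_ortho > 0) {
    sqrt(rowSums(model$P_ortho^2))
  } else rep(0, length(acc))
  vip <- model$vip[acc]
  gene <- stats::setNames(m$genes, rownames(m$values))[acc]
  comp_cols <- !m$design$is_control & m$design$compound == spec$compound
  if (!is.null(spec$cell_lines)) {
    comp_cols <- comp_cols & m$design$cell_line %in% spec$cell_lines
  }
  mean_fc <- rowMeans(m$values[acc, comp_cols, drop = FALSE], na.rm = TRUE)
  specificity <- fitexp_specificity(
    m, spec$compound, excluded_compounds = spec$excluded_compounds)[acc]
  df <- data.frame(accession = acc, gene = unname(gene),
                   p_pred = unname(p_pred), orth_coord = unname(orth),
                   vip = unname(vip),
                   fitexp_specificity = unname(specificity),
                   mean_log2fc_vs_control = unname(mean_fc),
                   stringsAsFactors = FALSE)
  # dense ranks, ties broken by accession (lexicographic) for determinism
  up <- df$p_pred > 0
  df$rank_up <- NA_integer_
  df$rank_up[up] <- order(order(-df$p_pred[up], df$accession[up]))
  dn <- df$p_pred < 0
  df$rank_down <- NA_integer_
  df$rank_down[dn] <- order(order(df$p_pred[dn], df$accession[dn]))
  df$rank_vip <- order(order(-df$vip, df$accession))
  df[order(-df$p_pred, df$accession), ]
}

#' Specificity of protein regulation for one compound
#'
#' The specificity statistic compares a protein's regulation under one
#' compound with the median regulation under all other compounds. In the
#' default log mode it is the difference, per protein, between the mean
#' log2 fold change over the compound's replicates and the median across
#' other compounds of their per-compound mean log2 fold changes (a
#' log-space ratio). `mode = "linear"` returns the equivalent ratio of
#' linear fold changes.
#'
#' @param m an [expression_matrix()].
#' @param compound compound of interest.
#' @param mode `"log"` (difference of log2 fold changes) or `"linear"`.
#' @param excluded_compounds compounds left out of the reference panel.
#' @return Named numeric vector, one specificity per protein.
#' @export
fitexp_specificity <- function(m, compound, mode = c("log", "linear"),
                               excluded_compounds = character(0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expression_matrix"))
  d <- m$design
  treated <- !d$is_control & !(d$compound %in% excluded_compounds)
  others <- setdiff(unique(d$compound[treated]), compound)
  if (length(others) < 2L) stop("need at least 2 other compounds")
  per_compound <- vapply(c(compound, others), function(cc) {
    rowMeans(m$values[, treated & d$compound == cc, drop = FALSE],
             na.rm = TRUE)
  }, numeric(nrow(m$values)))
  own <- per_compound[, 1]
  med <- apply(per_compound[, -1, drop = FALSE], 1, stats::median,
               na.rm = TRUE)
  out <- own - med
  if (mode == "linear") out <- 2^out
  stats::setNames(out, rownames(m$values))
}

#' Merge expression matrices from several cell lines
#'
#' Keeps the proteins quantified without missing values in every cell
#' line's matrix and stacks the sample columns, so a downstream contrast
#' treats all cell lines' replicates of a compound as one class. Merging
#' cell lines emphasizes targets shared across cellular contexts over
#' cell-line-private responses.
#'
#' @param ms list of [expression_matrix()] objects, jointly covering at
#'   least 2 cell lines.
#' @return The merged `expression_matrix`.
#' @export
merge_cell_lines <- function(ms) {
  stopifnot(length(ms) >= 2L)
  lines <- unique(unlist(lapply(ms, function(m) m$design$cell_line)))
  if (length(lines) < 2L) stop("need matrices from at least 2 cell lines")
  complete_rows <- lapply(ms, function(m) {
    rownames(m$values)[stats::complete.cases(m$values)]
  })
  common <- Reduce(intersect, complete_rows)
  if (length(common) == 0L) {
    n <- length(ms)
    pairs <- utils::combn(n, 2)
    ov <- apply(pairs, 2, function(ij) {
      length(intersect(complete_rows[[ij[1]]], complete_rows[[ij[2]]]))
    })
    stop("no protein is complete in every cell line; pairwise overlaps: ",
         paste(sprintf("(%d,%d)=%d", pairs[1, ], pairs[2, ], ov),
               collapse = ", "))
  }
  trimmed <- lapply(ms, function(m) {
    expression_matrix(m$values[common, , drop = FALSE],
                      stats::setNames(m$genes, rownames(m$values))[common],
                      m$design)
  })
  merge_experiments(trimmed, policy = "complete")
}

#' Count up- and down-regulated proteins for a compound
#'
#' Counts proteins whose mean fold change versus control (averaged over the
#' compound's replicates in log2 space, then transformed to the linear
#' scale) is at least `fc_cutoff` (up) or at most `1/fc_cutoff` (down).
#'
#' @param m an [expression_matrix()].
#' @param compound compound of interest.
#' @param fc_cutoff minimum linear fold change (> 1), e.g. 1.5.
#' @return List with `n_up`, `n_down`, `up_down_ratio` (`Inf` when nothing
#'   is down-regulated).
#' @export
regulation_summary <- function(m, compound, fc_cutoff = 1.5) {
  stopifnot(inherits(m, "expression_matrix"), fc_cutoff > 1)
  d <- m$design
  cols <- !d$is_control & d$compound == compound
  if (!any(cols)) stop("compound '", compound, "' not in the matrix")
  fc <- 2^rowMeans(m$values[, cols, drop = FALSE], na.rm = TRUE)
  n_up <- sum(fc >= fc_cutoff, na.rm = TRUE)
  n_down <- sum(fc <= 1 / fc_cutoff, na.rm = TRUE)
  list(n_up = n_up, n_down = n_down,
       up_down_ratio = if (n_down == 0) Inf else n_up / n_down)
}

#' Export a contrast ranking as TSV
#'
#' Writes the per-protein ranking table with a small header of model
#' statistics (R2X/R2Y/Q2, orthogonal-component count, scaling mode, seed)
#' as `#`-prefixed lines, so the output is bit-stable given identical
#' input and seed.
#'
#' @param result a `contrast_result` from [build_contrast()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path) {
  stopifnot(inherits(result, "contrast_result"))
  mod <- result$model
  hdr <- sprintf(
    "# compound=%s r2x=%.6f r2y=%.6f q2=%s n_ortho=%d scaling=%s seed=%d",
    result$spec$compound, mod$r2x, mod$r2y,
    ifelse(is.na(mod$q2), "NA", sprintf("%.6f", mod$q2)),
    mod$n_ortho, mod$scaling_mode, result$spec$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(result$ranking, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Top specifically regulated proteins of a contrast
#'
#' @param result a `contrast_result`.
#' @param n proteins per side (the cut is empirical; default 30).
#' @param side `"up"`, `"down"` or `"both"`.
#' @return Character vector of accessions.
#' @export
top_proteins <- function(result, n = 30L, side = c("up", "down", "both")) {
  side <- match.arg(side)
  r <- result$ranking
  up <- r$accession[!is.na(r$rank_up)][order(r$rank_up[!is.na(r$rank_up)])]
  dn <- r$accession[!is.na(r$rank_down)][order(r$rank_down[!is.na(r$rank_down)])]
  switch(side,
         up = utils::head(up, n),
         down = utils::head(dn, n),
         both = c(utils::head(up, n), utils::head(dn, n)))
}
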