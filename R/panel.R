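#' Target rank as a function of contrasting-panel size
#'
#' Characterizes how many contrasting compounds a signature library needs
#' before a known target surfaces: for each panel size `n`, draws
#' `n_combinations` random subsets of `n` contrasting compounds (without
#' replacement within a draw), fits a PLS-DA model of the compound against
#' the subset, and records the target's rank by absolute loading on the
#' first (predictive) component among proteins regulated in the target's
#' known direction. Ranks among all proteins (ignoring direction) are
#' recorded as well.
#'
#' @param m a complete [expression_matrix()].
#' @param compound contrasted compound.
#' @param target accession of the known target protein.
#' @param direction `"up"` or `"down"`: the target's known regulation
#'   direction under the compound.
#' @param n_range integer panel sizes (default 1 to all available
#'   contrasting compounds); values beyond availability are truncated with
#'   a warning.
#' @param n_combinations random panels per size (default 50). When `n`
#'   equals the number of available compounds every draw is identical and
#'   only one model is fitted.
#' @param seed integer seed for panel sampling.
#' @param n_components PLS components (default 2).
#' @param excluded_compounds compounds never drawn into panels.
#' @return Object of class `panel_curve`: `n_values`, `mean_rank`,
#'   `sd_rank`, `mean_rank_all`, and `draws`, a long data.frame with one
#'   row per (n, combination).
#' @export
panel_size_curve <- function(m, compound, target,
                             direction = c("up", "down"),
                             n_range = NULL, n_combinations = 50L,
                             seed = 1L, n_components = 2L,
                             excluded_compounds = character(0)) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "expression_matrix"))
  if (!target %in% rownames(m$values)) {
    stop("target '", target, "' not in the matrix")
  }
  d <- m$design
  treated <- !d$is_control & !(d$compound %in% excluded_compounds)
  pool <- sort(setdiff(unique(d$compound[treated]), compound))
  if (length(pool) == 0L) stop("no contrasting compounds available")
  if (is.null(n_range)) n_range <- seq_along(pool)
  if (any(n_range > length(pool))) {
    warning("n_range truncated to the ", length(pool),
            " available contrasting compounds")
    n_range <- n_range[n_range <= length(pool)]
  }
  comp_cols <- which(treated & d$compound == compound)
  set.seed(as.integer(seed))
  draws <- vector("list", length(n_range) * n_combinations)
  di <- 0L
  for (n in n_range) {
    for (b in seq_len(n_combinations)) {
      panel <- if (n == length(pool)) pool else sample(pool, n)
      cols <- c(comp_cols, which(treated & d$compound %in% panel))
      X <- t(m$values[, cols, drop = FALSE])
      if (anyNA(X)) {
        stop("matrix contains missing values; merge with policy = \"complete\"")
      }
      y <- as.integer(d$compound[cols] == compound)
      ncomp <- min(n_components, nrow(X) - 1L)
      fit <- fit_pls(X, y, n_components = ncomp)
      rk <- .panel_rank(fit, target, direction)
      di <- di + 1L
      draws[[di]] <- data.frame(compound = compound, target = target,
                                n = n, combination_index = b,
                                rank = rk["directional"],
                                rank_all = rk["all"])
    }
  }
  draws <- do.call(rbind, draws)
  rownames(draws) <- NULL
  agg <- function(f) vapply(n_range, function(n) {
    f(draws$rank[draws$n == n])
  }, numeric(1))
  structure(list(compound = compound, target = target,
                 direction = direction, n_values = n_range,
                 mean_rank = agg(mean), sd_rank = agg(stats::sd),
                 mean_rank_all = vapply(n_range, function(n) {
                   mean(draws$rank_all[draws$n == n])
                 }, numeric(1)),
                 n_combinations = n_combinations, seed = as.integer(seed),
                 draws = draws),
            class = "panel_curve")
}

# Rank of `target` by |first-component loading|, among proteins whose
# loading sign matches the contrasted compound's side for `direction`
# ("directional") and among all proteins ("all"). Positive score side is
# oriented to the contrasted class first.
.panel_rank <- function(fit, target, direction) {
  p1 <- drop(fit$P[, 1])
  # orient: contrasted class (y = 1) on the positive side of t1
  if (mean(fit$T[fit$y == 1, 1]) < 0) p1 <- -p1
  acc <- rownames(fit$P)
  want_pos <- direction == "up"
  side <- if (want_pos) p1 > 0 else p1 < 0
  ord <- order(-abs(p1), acc)
  rank_all <- match(target, acc[ord])
  side_acc <- acc[side][order(-abs(p1[side]), acc[side])]
  rank_dir <- match(target, side_acc)
  if (is.na(rank_dir)) rank_dir <- sum(side) + rank_all  # wrong side: past the end
  c(directional = rank_dir, all = rank_all)
}

#' @export
print.panel_curve <- function(x, ...) {
  cat("panel_curve:", x$compound, "/ target", x$target,
      sprintf("(%s), %d panel sizes x %d combinations, seed %d\n",
              x$direction, length(x$n_values), x$n_combinations, x$seed))
  invisible(x)
}

#' Write a panel curve (long draws + summary) as CSV
#'
#' @param curve a `panel_curve`.
#' @param path path of the long-format CSV (one row per draw); the
#'   summarized curve is written to `<path>.summary.csv`.
#' @return `path`, invisibly.
#' @export
write_panel_curve <- function(curve, path) {
  stopifnot(inherits(curve, "panel_curve"))
  utils::write.csv(curve$draws, path, row.names = FALSE)
  utils::write.csv(
    data.frame(compound = curve$compound, target = curve$target,
               n = curve$n_values, mean_rank = curve$mean_rank,
               sd_rank = curve$sd_rank,
               mean_rank_all = curve$mean_rank_all),
    paste0(path, ".summary.csv"), row.names = FALSE)
  invisible(path)
}
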