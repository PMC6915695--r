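#' Read a sample design table
#'
#' The design maps quantification columns (TMT channels) to experimental
#' conditions. One row per sample; within a multiplexed experiment the row
#' order is the channel order of the corresponding reporter-intensity
#' columns.
#'
#' @param path CSV file with columns `sample_id`, `compound`, `cell_line`,
#'   `replicate`, `experiment_id`, `is_control`.
#' @return A validated `data.frame` of class `sample_design`.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_sample_design(d)
}

#' Validate a sample design data frame
#'
#' @param d data.frame with the columns listed in [read_sample_design()].
#' @return `d` with canonical column types and class `sample_design`.
#' @export
as_sample_design <- function(d) {
  req <- c("sample_id", "compound", "cell_line", "replicate",
           "experiment_id", "is_control")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0L) {
    stop("sample design is missing column(s): ", paste(miss, collapse = ", "))
  }
  d$sample_id <- as.character(d$sample_id)
  d$compound <- as.character(d$compound)
  d$cell_line <- as.character(d$cell_line)
  d$replicate <- as.integer(d$replicate)
  d$experiment_id <- as.character(d$experiment_id)
  d$is_control <- parse_flag(d$is_control)
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  }
  key <- paste(d$compound, d$cell_line, d$replicate, sep = "\r")
  dup <- duplicated(key) & !d$is_control
  if (any(dup)) {
    stop("duplicate (compound, cell_line, replicate) in design: ",
         paste(unique(d$compound[dup]), collapse = ", "))
  }
  for (e in unique(d$experiment_id)) {
    if (!any(d$is_control[d$experiment_id == e])) {
      stop("experiment ", e, " has no control sample")
    }
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

# Accept "+", TRUE/FALSE, 1/0, "yes"/"no" flag encodings (MaxQuant uses "+").
parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- trimws(tolower(as.character(x)))
  x %in% c("+", "true", "t", "1", "yes", "y")
}

#' Construct an abundance table
#'
#' Container for the raw reporter intensities of one multiplexed experiment,
#' with per-protein peptide counts and QC flags. Zero intensity encodes "not
#' quantified".
#'
#' @param protein_id character accession vector (unique).
#' @param gene_name character vector, same length.
#' @param unique_peptides non-negative integer vector.
#' @param is_contaminant,is_reverse logical QC flags.
#' @param intensities numeric matrix, proteins x channels, finite and >= 0.
#' @param channel_labels column (sample) labels, unique within the experiment.
#' @param experiment_id scalar experiment identifier.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(protein_id, gene_name, unique_peptides,
                            is_contaminant, is_reverse, intensities,
                            channel_labels, experiment_id) {
  protein_id <- as.character(protein_id)
  n <- length(protein_id)
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == n,
            length(gene_name) == n,
            length(unique_peptides) == n,
            length(is_contaminant) == n,
            length(is_reverse) == n,
            length(channel_labels) == ncol(intensities))
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein ids: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels in experiment ", experiment_id)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and >= 0")
  }
  dimnames(intensities) <- list(protein_id, channel_labels)
  structure(
    list(protein_id = protein_id,
         gene_name = as.character(gene_name),
         unique_peptides = as.integer(unique_peptides),
         is_contaminant = as.logical(is_contaminant),
         is_reverse = as.logical(is_reverse),
         intensities = intensities,
         channel_labels = as.character(channel_labels),
         experiment_id = as.character(experiment_id)[1]),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table: experiment", x$experiment_id, "-",
      length(x$protein_id), "proteins x", length(x$channel_labels),
      "channels\n")
  cat("  flagged:", sum(x$is_contaminant), "contaminant,",
      sum(x$is_reverse), "reverse;",
      sum(x$intensities == 0), "zero (missing) entries\n")
  invisible(x)
}

# Column-name dialects accepted in protein-group tables.
.pg_dialects <- list(
  protein_id = c("Protein IDs", "Majority protein IDs", "protein_id",
                 "accession", "Accession"),
  gene_name = c("Gene names", "Gene Names", "gene_name", "gene"),
  unique_peptides = c("Unique peptides", "unique_peptides",
                      "Peptide counts (unique)"),
  is_contaminant = c("Potential contaminant", "Contaminant",
                     "is_contaminant"),
  is_reverse = c("Reverse", "is_reverse")
)

.pg_pick <- function(nms, field, required = TRUE) {
  hit <- intersect(.pg_dialects[[field]], nms)
  if (length(hit) == 0L) {
    if (required) {
      stop("protein-group table is missing a '", field,
           "' column (accepted names: ",
           paste(.pg_dialects[[field]], collapse = ", "), ")")
    }
    return(NA_character_)
  }
  hit[1]
}

#' Read a protein-group quantification table
#'
#' Parses tab-delimited protein-group output (MaxQuant `proteinGroups.txt`
#' style) or a generic protein x sample table. Reporter-intensity columns
#' are located by name: either exactly the design's `sample_id`s, or
#' MaxQuant-style `Reporter intensity corrected <k> <experiment_id>` columns
#' whose channel index `k` (0- or 1-based) maps to the design rows of that
#' experiment in order. Matching is keyed by column name, so column order in
#' the file is irrelevant. Contaminant/reverse status is taken from flag
#' columns when present and additionally from `CON__`/`REV__` accession
#' prefixes.
#'
#' @param path tab-delimited file.
#' @param design a `sample_design` covering the quantified samples.
#' @return A named list with one [abundance_table()] per experiment in
#'   `design` (file row order preserved).
#' @export
read_protein_groups <- function(path, design) {
  design <- as_sample_design(as.data.frame(design))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  nms <- names(tab)
  id_col <- .pg_pick(nms, "protein_id")
  gene_col <- .pg_pick(nms, "gene_name")
  pep_col <- .pg_pick(nms, "unique_peptides")
  con_col <- .pg_pick(nms, "is_contaminant", required = FALSE)
  rev_col <- .pg_pick(nms, "is_reverse", required = FALSE)

  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  is_con <- if (!is.na(con_col)) parse_flag(tab[[con_col]]) else
    rep(FALSE, length(ids))
  is_rev <- if (!is.na(rev_col)) parse_flag(tab[[rev_col]]) else
    rep(FALSE, length(ids))
  is_con <- is_con | startsWith(ids, "CON__")
  is_rev <- is_rev | startsWith(ids, "REV__")

  out <- list()
  for (e in unique(design$experiment_id)) {
    de <- design[design$experiment_id == e, , drop = FALSE]
    cols <- .pg_intensity_cols(nms, de, e)
    m <- as.matrix(tab[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    m[is.na(m)] <- 0
    out[[e]] <- abundance_table(
      protein_id = ids,
      gene_name = as.character(tab[[gene_col]]),
      unique_peptides = suppressWarnings(as.integer(tab[[pep_col]])),
      is_contaminant = is_con,
      is_reverse = is_rev,
      intensities = m,
      channel_labels = de$sample_id,
      experiment_id = e)
  }
  out
}

# Locate one intensity column per design row of experiment `e`.
.pg_intensity_cols <- function(nms, de, e) {
  if (all(de$sample_id %in% nms)) return(match(de$sample_id, nms))
  k <- nrow(de)
  for (base in c(0L, 1L)) {
    cand <- paste("Reporter intensity corrected",
                  seq_len(k) - 1L + base, e)
    if (all(cand %in% nms)) return(match(cand, nms))
    cand <- paste("Reporter intensity", seq_len(k) - 1L + base, e)
    if (all(cand %in% nms)) return(match(cand, nms))
  }
  stop("no reporter-intensity columns found for experiment ", e,
       ": expected columns named after sample ids (",
       paste(utils::head(de$sample_id, 3), collapse = ", "),
       ", ...) or 'Reporter intensity [corrected] <channel> ", e, "'")
}

#' Filter proteins by peptide evidence and QC flags
#'
#' Retains proteins quantified with at least `min_unique_peptides` unique
#' peptides that are neither contaminants nor reverse-database hits. Row
#' order is preserved.
#'
#' @param tbl an [abundance_table()].
#' @param min_unique_peptides minimum unique-peptide count (default 2).
#' @return The filtered `abundance_table`; a warning is issued (and an empty
#'   table returned) if nothing survives.
#' @export
filter_proteins <- function(tbl, min_unique_peptides = 2L) {
  stopifnot(inherits(tbl, "abundance_table"))
  keep <- tbl$unique_peptides >= min_unique_peptides &
    !tbl$is_contaminant & !tbl$is_reverse
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("no proteins pass the filter in experiment ", tbl$experiment_id)
  }
  subset_abundance(tbl, keep)
}

subset_abundance <- function(tbl, keep) {
  abundance_table(
    protein_id = tbl$protein_id[keep],
    gene_name = tbl$gene_name[keep],
    unique_peptides = tbl$unique_peptides[keep],
    is_contaminant = tbl$is_contaminant[keep],
    is_reverse = tbl$is_reverse[keep],
    intensities = tbl$intensities[keep, , drop = FALSE],
    channel_labels = tbl$channel_labels,
    experiment_id = tbl$experiment_id)
}

#' Equalize channel medians within a multiplexed experiment
#'
#' Each channel is scaled multiplicatively so that the median of its
#' positive intensities equals the grand median of the pre-normalization
#' channel medians. Zeros (missing) stay zero.
#'
#' @param tbl an [abundance_table()].
#' @return The normalized `abundance_table`.
#' @export
median_normalize <- function(tbl) {
  stopifnot(inherits(tbl, "abundance_table"))
  m <- tbl$intensities
  meds <- apply(m, 2, function(v) stats::median(v[v > 0]))
  bad <- !is.finite(meds)
  if (any(bad)) {
    stop("channel(s) with no positive intensities: ",
         paste(tbl$channel_labels[bad], collapse = ", "))
  }
  target <- stats::median(meds)
  tbl$intensities <- sweep(m, 2, target / meds, `*`)
  dimnames(tbl$intensities) <- dimnames(m)
  tbl
}

#' Expression matrix of log2 fold changes
#'
#' @param values numeric matrix, proteins x samples; `NA` = missing.
#' @param genes character vector of gene names per row.
#' @param design `sample_design` rows matching the columns of `values`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, design) {
  design <- as_sample_design(as.data.frame(design))
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(design),
            length(genes) == nrow(values))
  if (is.null(rownames(values))) stop("values must have accession rownames")
  colnames(values) <- design$sample_id
  structure(list(values = values, genes = as.character(genes),
                 design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "proteins x",
      ncol(x$values), "samples (",
      length(unique(x$design$compound[!x$design$is_control])), "compounds,",
      length(unique(x$design$cell_line)), "cell line(s) )\n")
  cat("  missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' Log2 fold changes versus the control mean
#'
#' For each protein, every sample's intensity is divided by the arithmetic
#' mean of that experiment's control-channel intensities and log2
#' transformed. Entries whose intensity, or whose control mean, is missing
#' (zero) become `NA`.
#'
#' @param tbl an [abundance_table()] (typically filtered and
#'   median-normalized).
#' @param design `sample_design` covering the experiment's channels.
#' @return An [expression_matrix()] over all channels of the experiment
#'   (control columns included; their values are log2 ratios to the control
#'   mean and hover near zero).
#' @export
compute_log2fc <- function(tbl, design) {
  stopifnot(inherits(tbl, "abundance_table"))
  design <- as_sample_design(as.data.frame(design))
  de <- design[design$experiment_id == tbl$experiment_id, , drop = FALSE]
  de <- de[match(tbl$channel_labels, de$sample_id), , drop = FALSE]
  if (anyNA(de$sample_id)) {
    stop("design does not cover all channels of experiment ",
         tbl$experiment_id)
  }
  ctrl <- which(de$is_control)
  if (length(ctrl) == 0L) {
    stop("no control channel in experiment ", tbl$experiment_id)
  }
  m <- tbl$intensities
  m[m == 0] <- NA
  ctrl_mean <- rowMeans(m[, ctrl, drop = FALSE], na.rm = TRUE)
  ctrl_mean[!is.finite(ctrl_mean) | ctrl_mean == 0] <- NA
  vals <- log2(m / ctrl_mean)
  expression_matrix(vals, tbl$gene_name, de)
}

#' Center log2 fold changes on a zero median
#'
#' Subtracts the median of the non-missing log2 fold changes, either per
#' sample column (default; stabilizes each replicate's median fold change)
#' or as one offset for the whole matrix.
#'
#' @param m an [expression_matrix()].
#' @param mode `"per_sample"` or `"global"`.
#' @return The centered `expression_matrix`.
#' @export
global_median_center <- function(m, mode = c("per_sample", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  if (mode == "per_sample") {
    meds <- apply(v, 2, stats::median, na.rm = TRUE)
    if (any(!is.finite(meds))) {
      stop("sample column(s) with no quantified proteins: ",
           paste(colnames(v)[!is.finite(meds)], collapse = ", "))
    }
    m$values <- sweep(v, 2, meds, `-`)
  } else {
    m$values <- v - stats::median(v, na.rm = TRUE)
  }
  m
}

#' Merge expression matrices from several experiments
#'
#' @param ms list of [expression_matrix()] objects sharing an accession
#'   namespace.
#' @param policy `"complete"` keeps only proteins quantified (non-missing)
#'   in every sample of every matrix; `"union"` keeps all proteins, with
#'   gaps marked missing.
#' @return One merged `expression_matrix`; sample columns are concatenated
#'   and the per-column design (including `experiment_id`) is retained.
#' @export
merge_experiments <- function(ms, policy = c("complete", "union")) {
  policy <- match.arg(policy)
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, TRUE,
                                         "expression_matrix")))
  accs <- lapply(ms, function(m) rownames(m$values))
  all_acc <- if (policy == "union") Reduce(union, accs) else
    Reduce(intersect, accs)
  # gene name per accession; conflicting names -> warn, keep first
  gene_of <- character(0)
  for (m in ms) {
    g <- stats::setNames(m$genes, rownames(m$values))
    new <- setdiff(names(g), names(gene_of))
    clash <- intersect(names(g), names(gene_of))
    clash <- clash[gene_of[clash] != g[clash]]
    if (length(clash) > 0L) {
      warning("conflicting gene names for ", length(clash),
              " accession(s) (e.g. ", clash[1], "); keeping first seen")
    }
    gene_of <- c(gene_of, g[new])
  }
  blocks <- lapply(ms, function(m) {
    out <- matrix(NA_real_, length(all_acc), ncol(m$values),
                  dimnames = list(all_acc, colnames(m$values)))
    hit <- intersect(all_acc, rownames(m$values))
    out[hit, ] <- m$values[hit, , drop = FALSE]
    out
  })
  vals <- do.call(cbind, blocks)
  design <- do.call(rbind, lapply(ms, function(m) as.data.frame(m$design)))
  if (policy == "complete") {
    keep <- stats::complete.cases(vals)
    vals <- vals[keep, , drop = FALSE]
    all_acc <- all_acc[keep]
  }
  expression_matrix(vals, unname(gene_of[all_acc]), design)
}

#' Write / read an expression matrix as TSV
#'
#' The layout is `accession`, `gene`, then one column per sample. The
#' design is written alongside as `<path>.design.csv` and re-read by
#' [read_expression_matrix()].
#'
#' @param m an [expression_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(accession = rownames(m$values), gene = m$genes,
                   m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(m$design), paste0(path, ".design.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @param design_path design CSV; defaults to `<path>.design.csv`.
#' @export
read_expression_matrix <- function(path, design_path = NULL) {
  if (is.null(design_path)) design_path <- paste0(path, ".design.csv")
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  design <- read_sample_design(design_path)
  vals <- as.matrix(df[, design$sample_id, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$accession
  expression_matrix(vals, df$gene, design)
}
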