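# In-code fixture builders used across test files.

# Tiny protein-groups file in the MaxQuant-ish dialect with sample-id
# intensity columns; returns the path.
write_pg_fixture <- function(dir = NULL, shuffle_cols = FALSE) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  df <- data.frame(
    "Protein IDs" = c("P1", "P2", "P3", "P4", "P5"),
    "Gene names" = c("G1", "G2", "G3", "G4", "G5"),
    "Unique peptides" = c(5L, 2L, 1L, 3L, 4L),
    "Potential contaminant" = c("", "", "", "+", ""),
    "Reverse" = c("", "", "", "", ""),
    s1 = c(100, 200, 300, 400, 500),
    s2 = c(110, 210, 310, 410, 510),
    s3 = c(90, 190, 290, 390, 490),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (shuffle_cols) df <- df[, c(1:5, 8, 6, 7)]
  path <- file.path(dir, "pg.txt")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pg_fixture_design <- function() {
  as_sample_design(data.frame(
    sample_id = c("s1", "s2", "s3"),
    compound = c("vehicle", "drugA", "drugB"),
    cell_line = "L1", replicate = 1L, experiment_id = "e1",
    is_control = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE))
}

# Hand-built expression matrix: proteins x samples values, a design with
# `n_rep` replicates per compound (no controls kept).
make_expr <- function(values, compounds, n_rep = 1L, cell_line = "L1",
                      genes = NULL) {
  p <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(p))
  }
  if (is.null(genes)) genes <- paste0("g_", rownames(values))
  design <- data.frame(
    sample_id = paste0("smp", seq_len(ncol(values))),
    compound = rep(compounds, each = n_rep),
    cell_line = cell_line,
    replicate = rep(seq_len(n_rep), times = length(compounds)),
    experiment_id = "e1", is_control = FALSE,
    stringsAsFactors = FALSE)
  # designs must carry a control somewhere; add a phantom control column
  ctrl <- matrix(0, p, 1, dimnames = list(rownames(values), "ctrl1"))
  design <- rbind(design,
                  data.frame(sample_id = "ctrl1", compound = "vehicle",
                             cell_line = cell_line, replicate = 1L,
                             experiment_id = "e1", is_control = TRUE,
                             stringsAsFactors = FALSE))
  expression_matrix(cbind(values, ctrl), genes, design)
}
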