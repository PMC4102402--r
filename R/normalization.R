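# ---- plate-level location normalization ----

#' Preliminary signal/noise clustering within batches
#'
#' Splits plates into experimental batches and runs the empirical-Bayes
#' thresholding machinery within each batch to obtain preliminary per-record
#' cluster labels, without yet modifying any values.
#'
#' @param table a `cell_table` with `lcount`.
#' @param batch_map named character vector mapping plate labels to batch
#'   labels; `NULL` treats all plates as one batch.
#' @param ... passed to [threshold_cell_table()].
#' @return character vector (`"noise"`/`"signal"`) aligned with the rows of
#'   `table`.
#' @export
preliminary_cluster <- function(table, batch_map = NULL, ...) {
  table <- as_cell_table(table)
  if (!"lcount" %in% names(table)) stop("preliminary clustering needs lcount")
  batch <- .batch_of(table, batch_map)
  labels <- character(nrow(table))
  for (b in unique(batch)) {
    idx <- which(batch == b)
    sub <- as_cell_table(as.data.frame(table)[idx, , drop = FALSE])
    thr <- threshold_cell_table(sub, value_col = "lcount", ...)
    labels[idx] <- ifelse(thr$et > 0, "signal", "noise")
  }
  labels
}

.batch_of <- function(table, batch_map) {
  if (is.null(batch_map)) return(rep("batch1", nrow(table)))
  if (!"plate" %in% names(table)) stop("batch mapping requires a plate column")
  plate <- as.character(table$plate)
  missing <- setdiff(unique(plate), names(batch_map))
  if (length(missing))
    stop("plates without a batch assignment: ", paste(missing, collapse = ", "))
  as.character(batch_map[plate])
}

#' Align signal and noise cluster locations across plates
#'
#' Within each batch, fits the additive model
#' `lcount ~ gene + cluster + plate:cluster` by backfitting (Gauss-Seidel on
#' the normal equations, so the converged solution is the least-squares
#' fit), then subtracts from every record the deviation of its
#' plate-by-cluster intercept from that cluster's across-plate mean
#' intercept. Only locations are corrected -- differences between records on
#' the same plate and cluster are preserved exactly; this is a non-pooled
#' location-only analogue of reference-batch correction.
#'
#' @param table a `cell_table` with `lcount` and `plate`.
#' @param labels per-record cluster labels from [preliminary_cluster()].
#' @param batch_map plate-to-batch mapping (see [preliminary_cluster()]).
#' @param tol,max_iter backfitting convergence control.
#' @return numeric vector of normalized values (`ncount`).
#' @export
align_plates <- function(table, labels, batch_map = NULL, tol = 1e-10,
                         max_iter = 200) {
  table <- as_cell_table(table)
  stopifnot(length(labels) == nrow(table))
  if (!"plate" %in% names(table)) {
    # no plate structure: nothing to align
    return(table$lcount)
  }
  batch <- .batch_of(table, batch_map)
  y <- table$lcount
  ncount <- y
  for (b in unique(batch)) {
    idx <- which(batch == b)
    ncount[idx] <- .align_one_batch(y[idx], table$gene_id[idx],
                                    as.character(table$plate[idx]),
                                    labels[idx], tol, max_iter)
  }
  ncount
}

.align_one_batch <- function(y, gene, plate, cluster, tol, max_iter) {
  pc <- interaction(plate, cluster, drop = TRUE, sep = "\r")
  gene <- factor(gene)
  if (length(unique(plate)) < 2) return(y)  # single plate: identity
  g_eff <- rep(0, nlevels(gene)); names(g_eff) <- levels(gene)
  pc_eff <- rep(0, nlevels(pc)); names(pc_eff) <- levels(pc)
  for (i in seq_len(max_iter)) {
    r <- y - pc_eff[as.character(pc)]
    g_new <- tapply(r, gene, mean)
    r2 <- y - g_new[as.character(gene)]
    pc_new <- tapply(r2, pc, mean)
    delta <- max(abs(g_new - g_eff), abs(pc_new - pc_eff))
    g_eff <- g_new; pc_eff <- pc_new
    if (delta < tol) break
  }
  # deviation of each plate:cluster intercept from its cluster's
  # across-plate mean; plates missing a cluster contribute no correction
  key <- do.call(rbind, strsplit(names(pc_eff), "\r", fixed = TRUE))
  clus_of <- key[, 2]
  dev <- pc_eff
  for (cl in unique(clus_of)) {
    sel <- clus_of == cl
    if (sum(sel) < 2) { dev[sel] <- 0; next }
    dev[sel] <- pc_eff[sel] - mean(pc_eff[sel])
  }
  y - as.numeric(dev[as.character(pc)])
}

#' Translate each gene so its minimum normalized value is zero
#'
#' @param values numeric vector of normalized values.
#' @param gene_id gene identifier per value.
#' @return translated values with per-gene minimum exactly 0. Idempotent.
#' @export
translate_min_zero <- function(values, gene_id) {
  mins <- tapply(values, gene_id, min)
  values - as.numeric(mins[as.character(gene_id)])
}

#' Normalize a cell table across plates
#'
#' Full normalization pass: preliminary per-batch clustering, plate-location
#' alignment of the signal and noise clusters, and per-gene min-zero
#' translation. The result carries an `ncount` column; thresholding should
#' then be re-run jointly on the normalized values
#' (see [threshold_cell_table()]).
#'
#' @inheritParams preliminary_cluster
#' @param ... passed to the preliminary thresholding.
#' @return the table with an `ncount` column.
#' @export
normalize_cell_table <- function(table, batch_map = NULL, ...) {
  table <- as_cell_table(table)
  labels <- preliminary_cluster(table, batch_map = batch_map, ...)
  ncount <- align_plates(table, labels, batch_map = batch_map)
  table$ncount <- translate_min_zero(ncount, table$gene_id)
  attr(table, "preliminary_labels") <- labels
  table
}
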