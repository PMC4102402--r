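# ---- per-cell covariates and QC filters ----

#' Cellular detection rate (fraction of panel genes detected per cell)
#'
#' The per-cell proportion of assayed genes with detectable (thresholded)
#' expression. It proxies per-cell amplification/detection efficiency and is
#' used as a nuisance covariate in the hurdle models.
#'
#' @param table a `cell_table` with `et`.
#' @return named numeric vector, one entry per cell, values in `[0, 1]`.
#' @export
compute_ngeneson <- function(table) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("compute_ngeneson requires et")
  out <- tapply(as.numeric(table$et > 0), table$cell_id, mean)
  out[unique(table$cell_id)]
}

#' Per-cell log2 sum of un-thresholded counts
#'
#' `log2(sum_g (2^lcount - 1))` per cell: the analogue of log total read
#' count in sequencing experiments. All-zero cells yield `NA`.
#'
#' @param table a `cell_table` with `lcount`.
#' @return named numeric vector, one entry per cell.
#' @export
compute_logsum <- function(table) {
  table <- as_cell_table(table)
  if (!"lcount" %in% names(table)) stop("compute_logsum requires lcount")
  sums <- tapply(2^table$lcount - 1, table$cell_id, sum)
  out <- ifelse(sums > 0, log2(sums), NA_real_)
  names(out) <- names(sums)
  out[unique(table$cell_id)]
}

.robust_z <- function(x) {
  med <- stats::median(x)
  scale <- stats::mad(x, constant = 1.4826)
  if (scale == 0) {
    warning("MAD is zero; falling back to the standard deviation")
    scale <- stats::sd(x)
  }
  if (!is.finite(scale) || scale == 0) return(rep(0, length(x)))
  abs(x - med) / scale
}

#' Remove empty and outlying cells by robust z-scoring
#'
#' Cells with no expressed gene are removed unconditionally. Among the
#' remaining cells, two outlier criteria are evaluated: the robust z-score
#' (|value - median| / 1.4826 MAD) of (a) the proportion of genes expressed,
#' against `sigma_proportion`, and (b) the mean positive expression (mean of
#' `et` over expressed genes only), against `sigma_continuous`. A cell is
#' removed when it exceeds the cutoff on at least `n_outlier` of the two
#' criteria -- with the default `n_outlier = 2` both must fire.
#'
#' @param table a `cell_table` with `et`.
#' @param n_outlier number of outlier criteria that must fire (default 2).
#' @param sigma_proportion robust-z cutoff on the expression proportion
#'   (default 2).
#' @param sigma_continuous robust-z cutoff on mean positive expression
#'   (default 5).
#' @return list with the filtered `table`, the retained `cells`, and a
#'   `removals` data frame (`cell_id`, `reason`).
#' @export
filter_cells <- function(table, n_outlier = 2, sigma_proportion = 2,
                         sigma_continuous = 5) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("filter_cells requires et")
  cells <- unique(table$cell_id)
  prop <- tapply(as.numeric(table$et > 0), table$cell_id, mean)[cells]
  pos_mean <- tapply(table$et, table$cell_id,
                     function(v) if (any(v > 0)) mean(v[v > 0]) else NA_real_)[cells]
  empty <- prop == 0
  nonempty <- cells[!empty]
  removals <- data.frame(cell_id = cells[empty],
                         reason = rep("no expression", sum(empty)),
                         stringsAsFactors = FALSE)
  if (length(nonempty)) {
    z_prop <- .robust_z(prop[nonempty])
    z_cont <- .robust_z(pos_mean[nonempty])
    fails <- (z_prop > sigma_proportion) + (z_cont > sigma_continuous)
    out <- fails >= n_outlier
    if (any(out)) {
      reason <- ifelse(z_prop[out] > sigma_proportion & z_cont[out] > sigma_continuous,
                       "proportion+continuous outlier",
                       ifelse(z_prop[out] > sigma_proportion,
                              "proportion outlier", "continuous outlier"))
      removals <- rbind(removals,
                        data.frame(cell_id = nonempty[out], reason = reason,
                                   stringsAsFactors = FALSE))
    }
  }
  keep <- setdiff(cells, removals$cell_id)
  filtered <- as.data.frame(table)[table$cell_id %in% keep, , drop = FALSE]
  list(table = as_cell_table(filtered), cells = keep, removals = removals)
}

#' Remove non-variable genes
#'
#' A gene is retained only if its expression frequency (fraction of cells
#' with `et > 0`) is at least `min_freq` in every cell line.
#'
#' @param table a `cell_table` with `et` and `cell_line`.
#' @param min_freq minimum per-line expression frequency (default 0.01).
#' @return list with the filtered `table`, retained `genes`, and the
#'   per-gene-by-line frequency matrix.
#' @export
filter_genes <- function(table, min_freq = 0.01) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("filter_genes requires et")
  if (!"cell_line" %in% names(table)) stop("filter_genes requires cell_line")
  freq <- tapply(as.numeric(table$et > 0),
                 list(table$gene_id, table$cell_line), mean)
  keep_gene <- apply(freq, 1, function(f) all(f[!is.na(f)] >= min_freq) &&
                       any(!is.na(f)))
  genes <- rownames(freq)[keep_gene]
  filtered <- as.data.frame(table)[table$gene_id %in% genes, , drop = FALSE]
  list(table = as_cell_table(filtered), genes = genes, freq = freq)
}

#' Per-gene expression frequency
#'
#' @param table a `cell_table` with `et`.
#' @return named numeric vector of the fraction of cells with `et > 0` per
#'   gene.
#' @export
expression_frequency <- function(table) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("expression_frequency requires et")
  out <- tapply(as.numeric(table$et > 0), table$gene_id, mean)
  out[unique(table$gene_id)]
}
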