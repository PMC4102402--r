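# ---- long-format cell x gene expression tables ----

# canonical internal column names and the external (supplementary-file
# style) header they map from
.S2_ALIASES <- c(
  cell_id = "CellID", cycle = "cycle", cell_line = "cellline",
  plate = "plate", plate_row = "platerow", ngeneson = "ngeneson",
  gene_id = "primerid", et = "et", lcount = "lCount", ncount = "nCount")

.PHASES <- c("G0/G1", "S", "G2/M")

#' Coerce a data frame to a validated cell table
#'
#' A cell table is a long-format data frame with one row per cell x gene
#' record. Required columns: `cell_id`, `gene_id`, and at least one of
#' `lcount` (log2(count + 1)), `ncount` (normalized log2 count), or `et`
#' (thresholded normalized log2 count, 0 = no detectable expression).
#' Optional annotations: `cycle`, `cell_line`, `plate`, `plate_row`,
#' `ngeneson`.
#'
#' @param x a data frame in internal or supplementary-file column naming.
#' @return an object of class `cell_table`.
#' @export
as_cell_table <- function(x) {
  if (inherits(x, "cell_table")) return(x)
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  nm <- names(x)
  for (internal in names(.S2_ALIASES)) {
    ext <- .S2_ALIASES[[internal]]
    hit <- which(tolower(nm) == tolower(ext) | nm == internal)
    if (length(hit)) names(x)[hit[1]] <- internal
  }
  if (!all(c("cell_id", "gene_id") %in% names(x)))
    stop("cell table needs cell and gene identifier columns")
  if ("count" %in% names(x) && !"lcount" %in% names(x))
    x$lcount <- log2(x$count + 1)
  if (!any(c("lcount", "ncount", "et") %in% names(x)))
    stop("cell table needs at least one expression column (lcount/ncount/et)")
  x$cell_id <- as.character(x$cell_id)
  x$gene_id <- as.character(x$gene_id)
  dup <- duplicated(x[c("cell_id", "gene_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (cell, gene) pair: (%s, %s)",
                 x$cell_id[i], x$gene_id[i]))
  }
  if ("cycle" %in% names(x)) {
    unknown <- setdiff(unique(as.character(x$cycle)), .PHASES)
    if (length(unknown))
      warning("unknown cycle phase label(s): ",
              paste(unknown, collapse = ", "),
              " (treated as additional factor levels)")
  }
  class(x) <- c("cell_table", "data.frame")
  x
}

#' Read a long-format cell table from CSV or TSV
#'
#' Accepts the supplementary-file column layout (`CellID, cycle, cellline,
#' plate, platerow, ngeneson, primerid, et, lCount, nCount`) or the internal
#' names. A raw `count` column is converted to `lcount = log2(count + 1)`
#' at ingest. Missing optional columns are simply absent, never fabricated.
#'
#' @param path file path.
#' @param dialect `"auto"` (sniff the delimiter from the header), `"csv"`,
#'   or `"tsv"`.
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- switch(dialect, csv = ",", tsv = "\t",
                auto = {
                  hdr <- readLines(path, n = 1)
                  if (grepl("\t", hdr)) "\t" else ","
                })
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  as_cell_table(df)
}

#' Write a cell table in the supplementary-file layout
#'
#' Numeric columns are rendered at full (17 significant digit) precision so
#' that a read/write round trip is bit-identical.
#'
#' @param table a `cell_table`.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_cell_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  table <- as_cell_table(table)
  out <- as.data.frame(table)
  keep <- intersect(names(.S2_ALIASES), names(out))
  out <- out[keep]
  names(out) <- .S2_ALIASES[keep]
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene metadata (external cell-cycle annotation)
#'
#' Consumes the gene-information layout `primerid, cbRank, cbPeaktime,
#' expPeaktime, pvalue`. `cb_rank` is the periodicity-evidence rank from the
#' Cyclebase database (missing = unranked); `cb_peaktime` is the annotated
#' peak time on a 0-100 scale (0 = G0, 100 = M). Genes with a rank below
#' 1000 form the "ranked" set carrying prior evidence of periodic
#' expression.
#'
#' @param path file path (CSV/TSV, auto-detected).
#' @return a data frame of class `gene_meta` with columns `gene_id`,
#'   `cb_rank`, `cb_peaktime`, and logical `ranked`.
#' @export
read_gene_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_gene_meta(df)
}

#' @rdname read_gene_meta
#' @param x a data frame with gene id and optional rank/peaktime columns.
#' @export
as_gene_meta <- function(x) {
  if (inherits(x, "gene_meta")) return(x)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  aliases <- c(gene_id = "primerid", cb_rank = "cbRank",
               cb_peaktime = "cbPeaktime", exp_peaktime = "expPeaktime",
               pvalue = "pvalue")
  nm <- names(x)
  for (internal in names(aliases)) {
    hit <- which(tolower(nm) == tolower(aliases[[internal]]) | nm == internal)
    if (length(hit)) names(x)[hit[1]] <- internal
  }
  if (nrow(x) == 0) {
    out <- data.frame(gene_id = character(), cb_rank = numeric(),
                      cb_peaktime = numeric(), ranked = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("gene_meta", "data.frame")
    return(out)
  }
  if (!"gene_id" %in% names(x)) stop("gene metadata needs a gene id column")
  x$gene_id <- as.character(x$gene_id)
  if (!"cb_rank" %in% names(x)) x$cb_rank <- NA_real_
  if (!"cb_peaktime" %in% names(x)) x$cb_peaktime <- NA_real_
  x$cb_rank <- suppressWarnings(as.numeric(x$cb_rank))
  x$cb_peaktime <- suppressWarnings(as.numeric(x$cb_peaktime))
  x$ranked <- !is.na(x$cb_rank) & x$cb_rank < 1000
  class(x) <- c("gene_meta", "data.frame")
  x
}

#' Map a 0-100 peak time onto a cell-cycle phase bin
#'
#' Bins the continuous peak-time annotation (0 = G0, 100 = M) into the three
#' assayable phases by thirds. Boundaries are configurable because the
#' annotation scale does not prescribe them.
#'
#' @param peaktime numeric vector on the 0-100 scale.
#' @param breaks two interior cut points; defaults to thirds.
#' @return factor with levels `G0/G1`, `S`, `G2/M` (NA preserved).
#' @export
peaktime_to_phase <- function(peaktime, breaks = c(100 / 3, 200 / 3)) {
  cut(as.numeric(peaktime), breaks = c(-Inf, breaks, Inf), labels = .PHASES)
}

# recompute the per-cell detected-gene fraction from et
recompute_ngeneson <- function(table) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("ngeneson requires an et column")
  on <- as.numeric(table$et > 0)
  frac <- tapply(on, table$cell_id, mean)
  table$ngeneson <- as.numeric(frac[table$cell_id])
  table
}

#' Run the full analysis pipeline on a dataset
#'
#' Drives the stages in their scientific order: `normalize` (per-batch
#' preliminary clustering, plate alignment, min-zero translation),
#' `threshold` (joint empirical-Bayes thresholding of the normalized values),
#' `filter` (cell and gene QC), `test` (per-gene hurdle cycle tests),
#' `deviance` (cycle deviance-ratio partitioning), and `network`
#' (penalized co-expression network). Stages already satisfied by the input
#' (e.g. an existing `et` column) may be skipped by omitting them from
#' `stages`. Each stage's output table is written to `out_dir` (when given)
#' together with a JSON log of the parameters used.
#'
#' @param table a `cell_table` (or path readable by [read_cell_table()]).
#' @param stages character vector of stage names, in any order; executed in
#'   the canonical order above.
#' @param batch_map optional named vector mapping plate labels to batches
#'   (for `normalize`); defaults to one batch.
#' @param out_dir optional directory for per-stage CSV outputs and the
#'   parameter log.
#' @param seed integer seed recorded in the log and used for any stochastic
#'   stage.
#' @param params named list of stage parameter overrides, e.g.
#'   `list(network = list(edges = 60))`.
#' @return a list with the final `table` and one entry per executed stage.
#' @export
run_pipeline <- function(table, stages = c("normalize", "threshold", "filter",
                                           "test", "deviance", "network"),
                         batch_map = NULL, out_dir = NULL, seed = 1,
                         params = list()) {
  if (is.character(table) && length(table) == 1) table <- read_cell_table(table)
  table <- as_cell_table(table)
  canonical <- c("normalize", "threshold", "filter", "test", "deviance",
                 "network")
  unknown <- setdiff(stages, canonical)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  stages <- canonical[canonical %in% stages]
  set.seed(seed)
  results <- list()
  log <- list(seed = seed, stages = stages)

  emit <- function(name, tab) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(tab),
                       file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }

  for (stage in stages) {
    if (stage == "normalize") {
      if (!"lcount" %in% names(table))
        stop("stage 'normalize' requires column lcount")
      p <- params$normalize %||% list()
      table <- do.call(normalize_cell_table,
                       c(list(table = table, batch_map = batch_map), p))
      log$normalize <- c(list(batches = length(unique(batch_map %||% "all"))), p)
      emit("normalized", table)
    } else if (stage == "threshold") {
      p <- params$threshold %||% list()
      table <- do.call(threshold_cell_table, c(list(table = table), p))
      log$threshold <- c(list(value_col = attr(table, "value_col")), p)
      emit("thresholded", table)
    } else if (stage == "filter") {
      if (!"et" %in% names(table))
        stop("stage 'filter' requires column et (run threshold first)")
      p <- params$filter %||% list()
      cf <- do.call(filter_cells, c(list(table = table), p))
      table <- cf$table
      gf <- do.call(filter_genes, c(list(table = table),
                                    p[intersect(names(p), "min_freq")]))
      table <- gf$table
      results$filter <- list(cells = cf, genes = gf)
      log$filter <- p
      emit("filtered", table)
    } else if (stage == "test") {
      if (!"et" %in% names(table))
        stop("stage 'test' requires column et (run threshold first)")
      p <- params$test %||% list()
      results$test <- do.call(test_cycle_genes, c(list(table = table), p))
      log$test <- p
      if (!is.null(out_dir))
        utils::write.csv(results$test, file.path(out_dir, "cycle_tests.csv"),
                         row.names = FALSE)
    } else if (stage == "deviance") {
      if (!"et" %in% names(table))
        stop("stage 'deviance' requires column et (run threshold first)")
      p <- params$deviance %||% list()
      results$deviance <- do.call(deviance_table, c(list(table = table), p))
      log$deviance <- p
      if (!is.null(out_dir))
        utils::write.csv(results$deviance,
                         file.path(out_dir, "deviance_ratios.csv"),
                         row.names = FALSE)
    } else if (stage == "network") {
      if (!"et" %in% names(table))
        stop("stage 'network' requires column et (run threshold first)")
      p <- params$network %||% list()
      results$network <- do.call(estimate_network, c(list(table = table), p))
      log$network <- p
      if (!is.null(out_dir))
        write_network(results$network, file.path(out_dir, "network_edges.tsv"))
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$table <- table
  results$log <- log
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
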