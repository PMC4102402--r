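# ---- penalized neighborhood selection for co-expression networks ----

# wide cells x genes matrix of a long-format column
.wide_matrix <- function(table, col = "et") {
  cells <- unique(table$cell_id)
  genes <- unique(table$gene_id)
  m <- matrix(NA_real_, length(cells), length(genes),
              dimnames = list(cells, genes))
  m[cbind(match(table$cell_id, cells), match(table$gene_id, genes))] <-
    table[[col]]
  if (anyNA(m)) stop("cell table is not complete in cells x genes")
  m
}

# per-cell covariate model matrix (no intercept column; glmnet supplies it)
.covariate_mm <- function(table, adjust_cycle = TRUE, ngeneson = TRUE) {
  cells <- unique(table$cell_id)
  first <- match(cells, table$cell_id)
  df <- as.data.frame(table)[first, , drop = FALSE]
  X <- .hurdle_mm(df, cell_line = TRUE, cycle = adjust_cycle,
                  interactions = adjust_cycle, ngeneson = ngeneson)
  X <- X[, -1, drop = FALSE]  # drop intercept
  rownames(X) <- cells
  X
}

.glmnet_safe <- function(x, y, family, lambda, penalty.factor) {
  tryCatch(
    glmnet::glmnet(x, y, family = family, lambda = lambda,
                   penalty.factor = penalty.factor, standardize = TRUE),
    error = function(e) NULL)
}

# gene coefficients of the neighborhood regression for gene g at each
# lambda of `lambda_seq`; matrix (other genes) x lambda, NULL if unfittable
.neighborhood_coefs <- function(expr, covars, g, family, lambda_seq,
                                response = NULL) {
  others <- setdiff(colnames(expr), g)
  if (family == "binomial") {
    y <- as.numeric(expr[, g] > 0)
    rows <- seq_len(nrow(expr))
  } else {
    resp <- if (is.null(response)) expr[, g] else response[, g]
    rows <- which(expr[, g] > 0)
    if (!is.null(response)) rows <- seq_len(nrow(expr))  # raw model: all cells
    y <- resp[rows]
  }
  if (length(unique(y)) < 2 || length(rows) < 10) return(NULL)
  x <- cbind(expr[rows, others, drop = FALSE], covars[rows, , drop = FALSE])
  pf <- c(rep(1, length(others)), rep(0, ncol(covars)))
  fit <- .glmnet_safe(x, y, family, lambda_seq, pf)
  if (is.null(fit)) return(NULL)
  b <- as.matrix(stats::coef(fit, s = lambda_seq))[-1, , drop = FALSE]
  b[others, , drop = FALSE]
}

#' Fit one gene's penalized hurdle neighborhood regression
#'
#' Discrete part: L1-penalized logistic regression of the gene's expression
#' indicator on all other genes' `et` values; continuous part: L1-penalized
#' linear regression of the gene's positive `et` on all other genes' `et`,
#' over cells where the target gene is expressed. Nuisance covariates
#' (`ngeneson`, cell line, and -- when `adjust_cycle` -- cycle and its
#' interaction with line) are included unpenalized.
#'
#' @param table a `cell_table` with `et`.
#' @param gene target gene.
#' @param lambda_d,lambda_c positive L1 penalties for the two parts.
#' @param adjust_cycle adjust for cell-cycle phase (and line x cycle)?
#' @return a `neighborhood_fit`: named coefficient vectors `coef_discrete`
#'   and `coef_continuous` over the other genes (zero = no edge proposed).
#' @export
fit_neighborhood <- function(table, gene, lambda_d, lambda_c,
                             adjust_cycle = TRUE) {
  table <- as_cell_table(table)
  if (lambda_d <= 0 || lambda_c <= 0) stop("penalties must be positive")
  expr <- .wide_matrix(table, "et")
  if (!gene %in% colnames(expr)) stop("gene not found: ", gene)
  covars <- .covariate_mm(table, adjust_cycle)
  # a short descending path ending at the requested lambda stabilises glmnet
  path_d <- sort(unique(c(lambda_d * c(8, 4, 2), lambda_d)), decreasing = TRUE)
  path_c <- sort(unique(c(lambda_c * c(8, 4, 2), lambda_c)), decreasing = TRUE)
  bd <- .neighborhood_coefs(expr, covars, gene, "binomial", path_d)
  bc <- .neighborhood_coefs(expr, covars, gene, "gaussian", path_c)
  structure(
    list(gene = gene,
         coef_discrete = if (is.null(bd)) NULL else bd[, length(path_d)],
         coef_continuous = if (is.null(bc)) NULL else bc[, length(path_c)],
         lambda_d = lambda_d, lambda_c = lambda_c,
         adjusted = adjust_cycle),
    class = "neighborhood_fit")
}

.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

.edges_at <- function(coef_list, lambda_index) {
  # union-symmetrized edge set with max |coefficient| per edge
  rows <- list()
  for (g in names(coef_list)) {
    b <- coef_list[[g]]
    if (is.null(b)) next
    nz <- which(abs(b[, lambda_index]) > 0)
    if (length(nz))
      rows[[g]] <- data.frame(a = g, b = rownames(b)[nz],
                              weight = abs(b[nz, lambda_index]),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  d <- do.call(rbind, rows)
  key <- .edge_key(d$a, d$b)
  agg <- tapply(d$weight, key, max)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
             weight = as.numeric(agg), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Calibrate a shared L1 penalty to an edge budget
#'
#' Finds a single penalty, shared across all gene-wise neighborhood
#' regressions of one component, such that the union-symmetrized network
#' has `target_edges` edges. The penalty path is scanned from the smallest
#' penalty producing an empty network downward; if the edge count jumps
#' past the budget between grid points, the network at the last penalty
#' not exceeding the budget is topped up with the edges entering at the
#' next grid point, ranked by absolute coefficient magnitude, so the
#' returned network hits the budget exactly whenever attainable.
#'
#' @param table a `cell_table` with `et`.
#' @param component `"discrete"` or `"continuous"`.
#' @param target_edges edge budget (e.g. half the combined budget).
#' @param adjust_cycle adjust for cycle as in [fit_neighborhood()].
#' @param model `"hurdle"` (thresholded `et`) or `"raw"` (ordinary
#'   penalized linear regressions on un-thresholded `lcount`).
#' @param n_lambda,lambda_min_ratio path grid resolution.
#' @return list with `lambda`, the calibrated `edges` data frame
#'   (`gene_a`, `gene_b`, `weight`), the path `edge_counts`, and
#'   `monotone` (whether the count was non-increasing in lambda).
#' @export
calibrate_penalty <- function(table, component = c("discrete", "continuous"),
                              target_edges, adjust_cycle = TRUE,
                              model = c("hurdle", "raw"),
                              n_lambda = 60, lambda_min_ratio = 0.05) {
  component <- match.arg(component)
  model <- match.arg(model)
  table <- as_cell_table(table)
  if (target_edges < 0) stop("target_edges must be nonnegative")
  raw <- model == "raw"
  expr <- .wide_matrix(table, "et")
  response <- if (raw) .wide_matrix(table, "lcount") else NULL
  if (raw) expr <- response
  covars <- .covariate_mm(table, adjust_cycle)
  family <- if (!raw && component == "discrete") "binomial" else "gaussian"
  genes <- colnames(expr)

  # shared descending lambda grid spanning the largest per-gene entry point
  lmax <- 0
  for (g in genes) {
    others <- setdiff(genes, g)
    if (family == "binomial") {
      y <- as.numeric(expr[, g] > 0); rows <- seq_len(nrow(expr))
    } else if (raw) {
      y <- expr[, g]; rows <- seq_len(nrow(expr))
    } else {
      rows <- which(expr[, g] > 0); y <- expr[rows, g]
    }
    if (length(unique(y)) < 2 || length(rows) < 10) next
    x <- scale(expr[rows, others, drop = FALSE])
    x[is.na(x)] <- 0
    if (family == "binomial") {
      mu <- mean(y); r <- y - mu
    } else r <- y - mean(y)
    lmax <- max(lmax, max(abs(crossprod(x, r))) / length(rows))
  }
  if (lmax == 0) stop("no fittable neighborhood regression")
  lambda_seq <- exp(seq(log(lmax * 1.05), log(lmax * lambda_min_ratio),
                        length.out = n_lambda))

  coef_list <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes)
    coef_list[[g]] <- .neighborhood_coefs(expr, covars, g, family, lambda_seq,
                                          response = if (raw) response else NULL)

  counts <- vapply(seq_along(lambda_seq),
                   function(l) nrow(.edges_at(coef_list, l)), integer(1))
  monotone <- all(diff(counts) >= 0)  # counts grow as lambda decreases
  if (!monotone)
    warning("edge count not monotone along the penalty path")

  ok <- which(counts <= target_edges)
  if (!length(ok)) {
    # even the strongest penalty overshoots: take the sparsest network,
    # trimmed to budget by coefficient magnitude
    e <- .edges_at(coef_list, 1L)
    e <- e[order(-e$weight), ][seq_len(min(target_edges, nrow(e))), ,
                               drop = FALSE]
    return(list(lambda = lambda_seq[1], edges = e, edge_counts = counts,
                lambda_seq = lambda_seq, monotone = monotone, exact = FALSE))
  }
  l_at <- max(ok)
  edges <- .edges_at(coef_list, l_at)
  exact <- nrow(edges) == target_edges
  if (!exact && l_at < length(lambda_seq)) {
    # top up with edges entering at the next grid point, by |coefficient|
    nxt <- .edges_at(coef_list, l_at + 1L)
    new <- nxt[!.edge_key(nxt$gene_a, nxt$gene_b) %in%
                 .edge_key(edges$gene_a, edges$gene_b), , drop = FALSE]
    new <- new[order(-new$weight), , drop = FALSE]
    need <- target_edges - nrow(edges)
    edges <- rbind(edges, new[seq_len(min(need, nrow(new))), , drop = FALSE])
    exact <- nrow(edges) == target_edges
  }
  list(lambda = lambda_seq[l_at], edges = edges, edge_counts = counts,
       lambda_seq = lambda_seq, monotone = monotone, exact = exact)
}

new_gene_network <- function(edges, component, lambda_d = NA, lambda_c = NA,
                             adjusted = NA, model = "hurdle") {
  edges <- edges[, intersect(c("gene_a", "gene_b", "weight"), names(edges)),
                 drop = FALSE]
  edges$component <- rep(component, length.out = nrow(edges))
  structure(edges, class = c("gene_network", "data.frame"),
            lambda_d = lambda_d, lambda_c = lambda_c, adjusted = adjusted,
            model = model)
}

#' Combine discrete and continuous networks by union
#'
#' Edges present in both components get provenance `"both"`.
#'
#' @param disc,cont `gene_network` objects over the same gene universe.
#' @return a combined `gene_network`.
#' @export
combine_networks <- function(disc, cont) {
  kd <- .edge_key(disc$gene_a, disc$gene_b)
  kc <- .edge_key(cont$gene_a, cont$gene_b)
  all_keys <- union(kd, kc)
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  comp <- ifelse(all_keys %in% kd & all_keys %in% kc, "both",
                 ifelse(all_keys %in% kd, "discrete", "continuous"))
  out <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    component = comp, stringsAsFactors = FALSE)
  structure(out, class = c("gene_network", "data.frame"),
            lambda_d = attr(disc, "lambda_d"),
            lambda_c = attr(cont, "lambda_c"),
            adjusted = attr(disc, "adjusted"),
            model = attr(disc, "model"))
}

#' Estimate a co-expression network at a fixed edge budget
#'
#' Calibrates per-component penalties so the discrete and continuous
#' neighborhood networks contribute `split[1]` and `split[2]` edges, and
#' returns their union (provenance marks edges found by both). With
#' `model = "raw"` a single penalized linear-regression network on
#' un-thresholded `lcount` is returned at the full `edges` budget.
#'
#' @param table a `cell_table` with `et` (and `lcount` for `model="raw"`).
#' @param edges total edge budget (default 60).
#' @param split per-component budgets (default half each).
#' @param adjust_cycle adjust for cell-cycle phase?
#' @param model `"hurdle"` or `"raw"`.
#' @param ... passed to [calibrate_penalty()].
#' @return a `gene_network` data frame (`gene_a`, `gene_b`, `component`)
#'   with attributes `lambda_d`, `lambda_c`, `adjusted`, `model`.
#' @export
estimate_network <- function(table, edges = 60,
                             split = c(ceiling(edges / 2), floor(edges / 2)),
                             adjust_cycle = TRUE,
                             model = c("hurdle", "raw"), ...) {
  model <- match.arg(model)
  table <- as_cell_table(table)
  if (model == "raw") {
    cal <- calibrate_penalty(table, "continuous", edges,
                             adjust_cycle = adjust_cycle, model = "raw", ...)
    return(new_gene_network(cal$edges, "continuous", lambda_c = cal$lambda,
                            adjusted = adjust_cycle, model = "raw"))
  }
  cal_d <- calibrate_penalty(table, "discrete", split[1],
                             adjust_cycle = adjust_cycle, ...)
  cal_c <- calibrate_penalty(table, "continuous", split[2],
                             adjust_cycle = adjust_cycle, ...)
  disc <- new_gene_network(cal_d$edges, "discrete", lambda_d = cal_d$lambda,
                           adjusted = adjust_cycle)
  cont <- new_gene_network(cal_c$edges, "continuous", lambda_c = cal_c$lambda,
                           adjusted = adjust_cycle)
  combine_networks(disc, cont)
}

#' Write a network as an edge-list TSV
#'
#' @param net a `gene_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(as.data.frame(net)[c("gene_a", "gene_b", "component")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fraction of edges joining genes with the same annotated peak phase
#'
#' @param net a `gene_network`.
#' @param meta a `gene_meta` (peak times binned via [peaktime_to_phase()])
#'   or a named vector/factor of phase labels per gene.
#' @return fraction in `[0, 1]` among edges with both endpoints annotated
#'   (`NaN` if none).
#' @export
peaktime_concordance <- function(net, meta) {
  if (inherits(meta, "gene_meta")) {
    phase <- stats::setNames(as.character(peaktime_to_phase(meta$cb_peaktime)),
                             meta$gene_id)
  } else phase <- stats::setNames(as.character(meta), names(meta))
  pa <- phase[net$gene_a]
  pb <- phase[net$gene_b]
  ok <- !is.na(pa) & !is.na(pb)
  mean(pa[ok] == pb[ok])
}

#' Node and edge agreement between two networks
#'
#' @param a,b `gene_network` objects over the same gene universe.
#' @return list with `node_jaccard` (shared non-isolated nodes over their
#'   union) and `edge_hamming` (symmetric-difference edge count divided by
#'   the per-network edge count).
#' @export
compare_networks <- function(a, b) {
  va <- unique(c(a$gene_a, a$gene_b))
  vb <- unique(c(b$gene_a, b$gene_b))
  ka <- .edge_key(a$gene_a, a$gene_b)
  kb <- .edge_key(b$gene_a, b$gene_b)
  n_edges <- nrow(a)
  if (nrow(a) != nrow(b))
    warning("networks have unequal edge counts; using the first network's")
  list(node_jaccard = length(intersect(va, vb)) / length(union(va, vb)),
       edge_hamming = length(c(setdiff(ka, kb), setdiff(kb, ka))) / n_edges)
}

#' Decompose covariance into within- and between-cluster parts
#'
#' For genes `x`, `y` and clustering factor `f`:
#' `cov(x, y) = E[cov(x, y | f)] + cov(E[x | f], E[y | f])`. All terms use
#' the population (divisor n) convention so the identity is exact in finite
#' samples.
#'
#' @param x,y numeric vectors of equal length.
#' @param f clustering factor.
#' @return list with `total`, `within` (average conditional covariance),
#'   `between` (covariance of cluster means).
#' @export
conditional_covariance_decomposition <- function(x, y, f) {
  stopifnot(length(x) == length(y), length(f) == length(x))
  f <- as.factor(f)
  n <- length(x)
  pop_cov <- function(u, v) mean(u * v) - mean(u) * mean(v)
  total <- pop_cov(x, y)
  w <- tapply(seq_len(n), f, function(i) length(i) / n)
  cov_f <- tapply(seq_len(n), f, function(i) pop_cov(x[i], y[i]))
  mx <- tapply(x, f, mean); my <- tapply(y, f, mean)
  within <- sum(w * cov_f)
  between <- sum(w * (mx - sum(w * mx)) * (my - sum(w * my)))
  list(total = total, within = within, between = between)
}
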