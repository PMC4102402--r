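# ---- two-part (hurdle) GLM: fitting, combined LRT, deviance partition ----

# Build the cell-level model matrix in sum-to-zero parameterization.
# Factors with fewer than 2 observed levels are dropped silently (their
# effect is unidentifiable and absorbed by the intercept).
.hurdle_mm <- function(df, cell_line = TRUE, cycle = TRUE,
                       interactions = FALSE, ngeneson = TRUE) {
  terms <- character(0)
  contr <- list()
  if (cell_line && "cell_line" %in% names(df)) {
    df$cell_line <- factor(df$cell_line)
    if (nlevels(df$cell_line) >= 2) {
      terms <- c(terms, "cell_line")
      contr$cell_line <- "contr.sum"
    }
  }
  if (cycle && "cycle" %in% names(df)) {
    lev <- intersect(.PHASES, unique(as.character(df$cycle)))
    lev <- c(lev, setdiff(unique(as.character(df$cycle)), .PHASES))
    df$cycle <- factor(df$cycle, levels = lev)
    if (nlevels(df$cycle) >= 2) {
      terms <- c(terms, "cycle")
      contr$cycle <- "contr.sum"
    }
  }
  if (interactions && all(c("cell_line", "cycle") %in% terms))
    terms <- c(terms, "cell_line:cycle")
  if (ngeneson && "ngeneson" %in% names(df)) terms <- c(terms, "ngeneson")
  f <- stats::as.formula(paste("~", paste(c("1", terms), collapse = " + ")))
  X <- stats::model.matrix(f, df, contrasts.arg = contr)
  attr(X, "term_labels") <- terms
  X
}

# iteratively reweighted least squares for logistic regression; optional
# ridge on all non-intercept coefficients guards against separation
.logistic_fit <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- c(0, rep(ridge, p - 1))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X, X * w) + diag(pen, p)
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, p), grad)
    })
    beta <- beta + step
    if (sqrt(sum(grad^2)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  converged <- sqrt(sum((drop(crossprod(X, y - mu)) - pen * beta)^2)) < 1e-6
  separated <- any(abs(eta) > 25)
  loglik <- sum(y * stats::plogis(eta, log.p = TRUE) +
                  (1 - y) * stats::plogis(-eta, log.p = TRUE))
  list(coef = stats::setNames(beta, colnames(X)), loglik = loglik,
       fitted = mu, converged = converged, separated = separated)
}

.fit_discrete <- function(X, y) {
  fit <- .logistic_fit(X, y)
  if (!fit$converged || fit$separated) {
    # (quasi-)separation: a small fixed ridge keeps the optimum finite
    fit <- .logistic_fit(X, y, ridge = 1e-6)
    fit$ridged <- TRUE
  } else fit$ridged <- FALSE
  fit
}

# Gaussian ML fit on the positive part; ML (n-denominator) variance so that
# deviances are comparable across nested models
.fit_continuous <- function(X, y) {
  qr_ <- qr(X)
  beta <- qr.coef(qr_, y)
  beta[is.na(beta)] <- 0
  res <- y - drop(X %*% beta)
  n <- length(y)
  rss <- sum(res^2)
  sigma2 <- max(rss / n, 1e-12)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(coef = stats::setNames(beta, colnames(X)), sigma2 = sigma2,
       loglik = loglik, rss = rss, rank = qr_$rank)
}

#' Fit the two-part hurdle model for one gene
#'
#' The discrete part is a logistic regression of the expression indicator
#' `et > 0`; the continuous part a Gaussian linear model of `et` restricted
#' to cells with positive expression. Both parts share a design built from
#' cell line, cell-cycle phase, their interaction (optional), and the
#' cellular detection rate `ngeneson`, with sum-to-zero factor coding so
#' that effects are interpretable as deviations from the grand mean and
#' tests are invariant to the choice of reference level. The total
#' log-likelihood is the sum of the two parts.
#'
#' @param table a `cell_table` with `et` (plus `cycle`, `cell_line`,
#'   `ngeneson` as required by the design).
#' @param gene gene identifier to fit.
#' @param cell_line,cycle include the factor? (logical)
#' @param interactions include the cell line x cycle interaction?
#' @param ngeneson adjust for the cellular detection rate?
#' @return a `hurdle_fit`: coefficients, per-part log-likelihoods,
#'   `loglik = loglik_discrete + loglik_continuous`,
#'   `deviance = -2 * loglik`, per-part parameter counts, and flags
#'   (`discrete_degenerate`, `ridged`).
#' @export
fit_hurdle <- function(table, gene, cell_line = TRUE, cycle = TRUE,
                       interactions = FALSE, ngeneson = TRUE) {
  table <- as_cell_table(table)
  if (!"et" %in% names(table)) stop("fit_hurdle requires et")
  df <- as.data.frame(table)[table$gene_id == gene, , drop = FALSE]
  if (!nrow(df)) stop("gene not found: ", gene)
  X <- .hurdle_mm(df, cell_line, cycle, interactions, ngeneson)
  y_d <- as.numeric(df$et > 0)
  pos <- df$et > 0
  degenerate <- all(pos) || !any(pos)
  if (sum(pos) < ncol(X) + 1)
    stop(sprintf("gene %s: too few positive cells (%d) for the continuous part",
                 gene, sum(pos)))
  disc <- NULL
  if (!degenerate) disc <- .fit_discrete(X, y_d)
  cont <- .fit_continuous(X[pos, , drop = FALSE], df$et[pos])
  ll_d <- if (degenerate) 0 else disc$loglik
  structure(
    list(gene = gene,
         coef_discrete = if (degenerate) NULL else disc$coef,
         coef_continuous = cont$coef,
         sigma2 = cont$sigma2,
         loglik_discrete = ll_d,
         loglik_continuous = cont$loglik,
         loglik = ll_d + cont$loglik,
         deviance = -2 * (ll_d + cont$loglik),
         # GLM-scale deviances: binomial deviance (saturated loglik 0) plus
         # the continuous part's residual sum of squares; used by the
         # deviance-ratio partition so it reduces to R^2 for continuous data
         deviance_glm = -2 * ll_d + cont$rss,
         df_discrete = if (degenerate) 0L else ncol(X),
         df_continuous = ncol(X),
         n = nrow(df), n_pos = sum(pos),
         terms = attr(X, "term_labels"),
         discrete_degenerate = degenerate,
         ridged = if (degenerate) FALSE else disc$ridged),
    class = "hurdle_fit")
}

#' @method print hurdle_fit
#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("Hurdle fit for %s: n = %d (%d positive)\n",
              x$gene, x$n, x$n_pos))
  cat(sprintf("  loglik = %.4f (discrete %.4f + continuous %.4f)\n",
              x$loglik, x$loglik_discrete, x$loglik_continuous))
  if (x$discrete_degenerate)
    cat("  discrete part degenerate (gene always/never expressed)\n")
  invisible(x)
}

#' Combined likelihood-ratio test between nested hurdle fits
#'
#' Computes the per-part likelihood-ratio statistics and adds them:
#' `lambda = lambda_d + lambda_c`, referred to a chi-square whose degrees
#' of freedom are the summed per-part parameter differences (for the
#' default three-phase cycle test: 2 discrete + 2 continuous = 4). The
#' per-part statistics are also referred to their own chi-square for the
#' component and union tests. When the discrete part is degenerate in both
#' fits its statistic is 0 and contributes no degrees of freedom.
#'
#' @param full,reduced `hurdle_fit` objects on the same data, with the
#'   reduced design a strict subset of the full design's terms.
#' @return a `test_result`: `lambda_d`, `lambda_c`, `lambda`, `df`,
#'   `p_combined`, `p_discrete`, `p_continuous`.
#' @export
lrt_cycle <- function(full, reduced) {
  stopifnot(inherits(full, "hurdle_fit"), inherits(reduced, "hurdle_fit"))
  if (!all(reduced$terms %in% full$terms))
    stop("models are not nested: reduced terms ",
         paste(setdiff(reduced$terms, full$terms), collapse = ", "),
         " absent from the full model")
  if (full$n != reduced$n || full$n_pos != reduced$n_pos)
    stop("models are not fitted to the same data")
  lambda_d <- 2 * (full$loglik_discrete - reduced$loglik_discrete)
  lambda_c <- 2 * (full$loglik_continuous - reduced$loglik_continuous)
  clamped <- FALSE
  if (lambda_d < 0) {
    if (lambda_d < -1e-6) { warning("negative discrete LRT clamped to 0"); clamped <- TRUE }
    lambda_d <- 0
  }
  if (lambda_c < 0) {
    if (lambda_c < -1e-6) { warning("negative continuous LRT clamped to 0"); clamped <- TRUE }
    lambda_c <- 0
  }
  df_d <- full$df_discrete - reduced$df_discrete
  df_c <- full$df_continuous - reduced$df_continuous
  df <- df_d + df_c
  structure(
    list(lambda_d = lambda_d, lambda_c = lambda_c,
         lambda = lambda_d + lambda_c,
         df = df, df_discrete = df_d, df_continuous = df_c,
         p_combined = if (df > 0) stats::pchisq(lambda_d + lambda_c, df,
                                               lower.tail = FALSE) else 1,
         p_discrete = if (df_d > 0) stats::pchisq(lambda_d, df_d,
                                                  lower.tail = FALSE) else 1,
         p_continuous = if (df_c > 0) stats::pchisq(lambda_c, df_c,
                                                    lower.tail = FALSE) else 1,
         clamped = clamped),
    class = "test_result")
}

#' @method print test_result
#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Combined LRT: lambda = %.4f (d %.4f + c %.4f), df = %d, p = %.3g\n",
              x$lambda, x$lambda_d, x$lambda_c, x$df, x$p_combined))
  invisible(x)
}

#' Hurdle likelihood-ratio test of cell-cycle effects for one gene
#'
#' Fits the full and cycle-free hurdle models and runs the combined test.
#' With `interactions = FALSE` (the differential-expression default) only
#' cycle main effects are tested, with cell line and `ngeneson` adjusted
#' for in both models; with `interactions = TRUE` (the deviance-analysis
#' model) the reduced model drops both cycle main effects and the cell
#' line x cycle interaction.
#'
#' @inheritParams fit_hurdle
#' @return a `test_result` (see [lrt_cycle()]).
#' @export
hurdle_cycle_test <- function(table, gene, interactions = FALSE,
                              ngeneson = TRUE) {
  full <- fit_hurdle(table, gene, cycle = TRUE, interactions = interactions,
                     ngeneson = ngeneson)
  reduced <- fit_hurdle(table, gene, cycle = FALSE, interactions = FALSE,
                        ngeneson = ngeneson)
  lrt_cycle(full, reduced)
}

#' Union-intersection test from per-part p-values
#'
#' Rejects the joint null when either component test rejects at the
#' allocated level (Bonferroni split `alpha / 2` by default, which
#' guarantees size at most `alpha`).
#'
#' @param p_discrete,p_continuous component p-values in `[0, 1]`.
#' @param alpha overall level.
#' @param component_level level allocated to each component (default
#'   `alpha / 2`).
#' @return logical: reject?
#' @export
union_test <- function(p_discrete, p_continuous, alpha = 0.05,
                       component_level = alpha / 2) {
  stopifnot(all(p_discrete >= 0 & p_discrete <= 1),
            all(p_continuous >= 0 & p_continuous <= 1))
  pmin(p_discrete, p_continuous) <= component_level
}

#' Bonferroni adjustment
#'
#' @param pvals vector of p-values.
#' @param m number of tests (defaults to `length(pvals)`).
#' @return `pmin(1, pvals * m)`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  pmin(1, pvals * m)
}

#' Proportion of hurdle deviance explained by the cell cycle
#'
#' Compares the full hurdle model (cell line + cycle + interaction +
#' `ngeneson`) against the same model with every cycle term removed. With
#' `D1` and `D0` the hurdle GLM deviances (binomial deviance of the
#' discrete part plus residual sum of squares of the continuous part) of
#' the full and cycle-free models, the cycle deviance ratio is
#' `(D0 - D1) / D0`, the hurdle analogue of the coefficient of
#' determination for the cycle terms: for fully continuous data it is
#' exactly the OLS R-squared of the cycle terms. The deflated ratio
#' divides by `max_ratio`, the largest ratio observed across genes,
#' interpreting it as the ratio a fully cycle-regulated gene would attain.
#'
#' @inheritParams fit_hurdle
#' @param max_ratio reference maximum for the deflated ratio; `NA` leaves
#'   the deflated ratio unset (it is usually supplied by [deviance_table()]
#'   which estimates it as the within-panel maximum).
#' @return a `deviance_decomposition` list: `dev_full`, `dev_nocycle`,
#'   `cycle_deviance`, `ratio`, `deflated_ratio`.
#' @export
deviance_ratio <- function(table, gene, interactions = TRUE, ngeneson = TRUE,
                           max_ratio = NA_real_) {
  full <- fit_hurdle(table, gene, cycle = TRUE, interactions = interactions,
                     ngeneson = ngeneson)
  reduced <- fit_hurdle(table, gene, cycle = FALSE, interactions = FALSE,
                        ngeneson = ngeneson)
  d1 <- full$deviance_glm; d0 <- reduced$deviance_glm
  cycle_dev <- d0 - d1
  clamped <- FALSE
  if (cycle_dev < 0) { cycle_dev <- 0; clamped <- TRUE }
  ratio <- cycle_dev / d0
  structure(
    list(gene = gene, dev_full = d1, dev_nocycle = d0,
         cycle_deviance = cycle_dev, residual_deviance = d1,
         ratio = ratio, deflated_ratio = ratio / max_ratio,
         clamped = clamped),
    class = "deviance_decomposition")
}

#' Phase of peak expression
#'
#' For each gene, the cell-cycle phase with the maximum average `et`
#' (zeros included) across all cells of all lines. Ties are broken by phase
#' order G0/G1 < S < G2/M and flagged.
#'
#' @param table a `cell_table` with `et` and `cycle`.
#' @param gene optional single gene; default computes all genes.
#' @return data frame with `gene_id`, `peaktime` (phase label), `tie`.
#' @export
estimate_peaktime <- function(table, gene = NULL) {
  table <- as_cell_table(table)
  if (!all(c("et", "cycle") %in% names(table)))
    stop("estimate_peaktime requires et and cycle")
  df <- as.data.frame(table)
  if (!is.null(gene)) df <- df[df$gene_id == gene, , drop = FALSE]
  phases <- intersect(.PHASES, unique(as.character(df$cycle)))
  m <- tapply(df$et, list(df$gene_id, as.character(df$cycle)), mean)
  m <- m[, phases, drop = FALSE]
  pick <- apply(m, 1, function(v) {
    v[is.na(v)] <- -Inf
    which(v == max(v))
  }, simplify = FALSE)
  data.frame(
    gene_id = rownames(m),
    peaktime = phases[vapply(pick, `[`, integer(1), 1L)],
    tie = vapply(pick, length, integer(1)) > 1,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene cycle differential-expression table
#'
#' Runs the combined hurdle cycle test for every gene, Bonferroni-adjusts
#' across genes, and annotates each gene with its expression frequency and
#' estimated phase of peak expression. p-values are also reported as
#' `-log10(p)`.
#'
#' @inheritParams fit_hurdle
#' @param alpha significance level after adjustment.
#' @return data frame with one row per gene: `gene_id`, `freq`, `lambda_d`,
#'   `lambda_c`, `lambda`, `df`, `p`, `neglog10_p`, `p_adj`, `significant`,
#'   `union_reject`, `peaktime`.
#' @export
test_cycle_genes <- function(table, interactions = FALSE, ngeneson = TRUE,
                             alpha = 0.05) {
  table <- as_cell_table(table)
  genes <- unique(table$gene_id)
  freq <- expression_frequency(table)
  peaks <- estimate_peaktime(table)
  rows <- lapply(genes, function(g) {
    tr <- tryCatch(hurdle_cycle_test(table, g, interactions = interactions,
                                     ngeneson = ngeneson),
                   error = function(e) NULL)
    if (is.null(tr))
      return(data.frame(gene_id = g, lambda_d = NA_real_, lambda_c = NA_real_,
                        lambda = NA_real_, df = NA_integer_, p = NA_real_,
                        p_discrete = NA_real_, p_continuous = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, lambda_d = tr$lambda_d, lambda_c = tr$lambda_c,
               lambda = tr$lambda, df = tr$df, p = tr$p_combined,
               p_discrete = tr$p_discrete, p_continuous = tr$p_continuous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$freq <- as.numeric(freq[out$gene_id])
  out$neglog10_p <- -log10(out$p)
  out$p_adj <- bonferroni_adjust(out$p, m = sum(!is.na(out$p)))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$union_reject <- union_test(ifelse(is.na(out$p_discrete), 1, out$p_discrete),
                                 ifelse(is.na(out$p_continuous), 1, out$p_continuous),
                                 alpha = alpha / sum(!is.na(out$p)))
  out <- merge(out, peaks, by = "gene_id", sort = FALSE)
  out[match(genes, out$gene_id),
      c("gene_id", "freq", "lambda_d", "lambda_c", "lambda", "df", "p",
        "p_discrete", "p_continuous", "neglog10_p", "p_adj", "significant",
        "union_reject", "peaktime", "tie")]
}

#' Per-gene cycle deviance-ratio table
#'
#' Computes the cycle deviance decomposition for every gene and the
#' deflated ratio against the panel maximum (or a supplied reference).
#'
#' @inheritParams deviance_ratio
#' @return data frame with `gene_id`, `dev_full`, `dev_nocycle`, `ratio`,
#'   `deflated_ratio`, plus attribute `"max_ratio"`.
#' @export
deviance_table <- function(table, interactions = TRUE, ngeneson = TRUE,
                           max_ratio = NULL) {
  table <- as_cell_table(table)
  genes <- unique(table$gene_id)
  rows <- lapply(genes, function(g) {
    d <- tryCatch(deviance_ratio(table, g, interactions = interactions,
                                 ngeneson = ngeneson),
                  error = function(e) NULL)
    if (is.null(d))
      return(data.frame(gene_id = g, dev_full = NA_real_,
                        dev_nocycle = NA_real_, ratio = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(gene_id = g, dev_full = d$dev_full, dev_nocycle = d$dev_nocycle,
               ratio = d$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(max_ratio)) max_ratio <- max(out$ratio, na.rm = TRUE)
  out$deflated_ratio <- out$ratio / max_ratio
  attr(out, "max_ratio") <- max_ratio
  out
}
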