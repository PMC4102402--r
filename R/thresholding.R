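# ---- two-component Gaussian mixtures: MLE (omnibus) and MAP (per gene) ----

new_mixture_fit <- function(mu, var, pi_signal, loglik, n_obs, converged,
                            iterations) {
  # relabel so the noise cluster has the smaller mean
  o <- order(mu)
  structure(
    list(mu_noise = mu[o[1]], mu_signal = mu[o[2]],
         var_noise = var[o[1]], var_signal = var[o[2]],
         pi_signal = if (o[1] == 1L) pi_signal else 1 - pi_signal,
         loglik = loglik, n_obs = n_obs, converged = converged,
         iterations = iterations),
    class = "mixture_fit")
}

#' @method print mixture_fit
#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit (n =", x$n_obs, ")\n")
  cat(sprintf("  noise : mu = %.4f, var = %.4f\n", x$mu_noise, x$var_noise))
  cat(sprintf("  signal: mu = %.4f, var = %.4f (pi = %.4f)\n",
              x$mu_signal, x$var_signal, x$pi_signal))
  cat(sprintf("  loglik = %.4f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

# deterministic 2-means initialisation: Lloyd's algorithm started from the
# extremes of the data, ties broken toward the lower cluster
.init_two_means <- function(x) {
  centers <- range(x)
  for (i in 1:50) {
    assign <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    new_centers <- c(mean(x[assign == 1L]), mean(x[assign == 2L]))
    if (anyNA(new_centers)) break
    if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
    centers <- new_centers
  }
  assign <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
  list(centers = centers, assign = assign)
}

.mix_loglik <- function(x, mu, var, pi1) {
  # pi1 is the weight of component 1 (the first entry of mu/var)
  d1 <- stats::dnorm(x, mu[1], sqrt(var[1]))
  d2 <- stats::dnorm(x, mu[2], sqrt(var[2]))
  sum(log(pmax((1 - pi1) * d1, 0) + pi1 * d2 + 1e-300))
}

#' Fit the omnibus two-component Gaussian mixture by maximum likelihood
#'
#' Pools positive log2 expression values across all genes and fits a
#' two-component Gaussian mixture by EM. The lower-mean component is the
#' background-noise cluster, the higher-mean component the signal cluster.
#' The fit seeds the empirical-Bayes prior used for the per-gene MAP fits
#' (see [build_prior()] and [fit_gene_map()]).
#'
#' @param values numeric vector of pooled positive-support log2 expression.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations; non-convergence is flagged, not an
#'   error.
#' @param min_var variance floor guarding against cluster collapse.
#' @return a `mixture_fit` with fields `mu_noise`, `mu_signal`, `var_noise`,
#'   `var_signal`, `pi_signal`, `loglik`, `n_obs`, `converged`.
#' @export
fit_omnibus_mixture <- function(values, tol = 1e-8, max_iter = 500,
                                min_var = 1e-6) {
  x <- values[is.finite(values)]
  if (length(x) < 10)
    stop("need at least 10 finite observations for the omnibus fit")
  if (stats::sd(x) < 1e-12)
    stop("degenerate data: all omnibus observations are (nearly) equal")
  init <- .init_two_means(x)
  mu <- sort(init$centers)
  var <- vapply(1:2, function(j) {
    v <- stats::var(x[init$assign == order(init$centers)[j]])
    if (!is.finite(v) || v < min_var) stats::var(x) / 4 else v
  }, numeric(1))
  pi2 <- mean(init$assign == order(init$centers)[2])
  pi2 <- min(max(pi2, 0.01), 0.99)

  ll <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: responsibility of the signal (second) component
    r <- .posterior_component2(x, mu, var, pi2)
    n2 <- sum(r); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    # M-step
    mu_new <- c(sum((1 - r) * x) / n1, sum(r * x) / n2)
    var_new <- c(max(sum((1 - r) * (x - mu_new[1])^2) / n1, min_var),
                 max(sum(r * (x - mu_new[2])^2) / n2, min_var))
    pi2_new <- n2 / length(x)
    mu <- mu_new; var <- var_new; pi2 <- pi2_new
    ll_new <- .mix_loglik(x, mu, var, pi2)
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  new_mixture_fit(mu, var, pi2, ll, length(x), converged, it)
}

.posterior_component2 <- function(x, mu, var, pi2) {
  l1 <- log1p(-pi2) + stats::dnorm(x, mu[1], sqrt(var[1]), log = TRUE)
  l2 <- log(pi2) + stats::dnorm(x, mu[2], sqrt(var[2]), log = TRUE)
  m <- pmax(l1, l2)
  exp(l2 - m) / (exp(l1 - m) + exp(l2 - m))
}

#' Build the empirical-Bayes prior from the omnibus mixture fit
#'
#' Constructs a conjugate Normal-Inverse-Gamma + Beta prior centred at the
#' omnibus maximum-likelihood estimates. Each cluster mean gets a Gaussian
#' prior with pseudo-observation weight `kappa * nt`; each cluster variance
#' an inverse-gamma prior whose mode equals the omnibus variance with the
#' same effective weight; the signal mixing proportion a
#' Beta(`mix_weight`, `mix_weight`) prior (the default corresponds to prior
#' mass worth 10 observations).
#'
#' @param omnibus a converged `mixture_fit` from [fit_omnibus_mixture()].
#' @param kappa pseudo-count multiplier (default 3).
#' @param nt prior scale (default 5); the per-cluster pseudo-count is
#'   `kappa * nt`.
#' @param mix_weight symmetric Beta hyperparameter for the mixing
#'   proportion (default 5).
#' @return a `mixture_prior` list.
#' @export
build_prior <- function(omnibus, kappa = 3, nt = 5, mix_weight = 5) {
  stopifnot(inherits(omnibus, "mixture_fit"))
  if (kappa <= 0 || nt <= 0) stop("kappa and nt must be positive")
  if (!isTRUE(omnibus$converged))
    warning("omnibus fit did not converge; prior may be unreliable")
  w <- kappa * nt
  vars <- c(omnibus$var_noise, omnibus$var_signal)
  shape <- rep(w / 2, 2)
  # inverse-gamma mode b/(a+1) matched to the omnibus variance
  scale <- (shape + 1) * vars
  structure(
    list(mean_locations = c(omnibus$mu_noise, omnibus$mu_signal),
         mean_strength = w,
         var_shape = shape, var_scale = scale,
         mix_a = mix_weight, mix_b = mix_weight),
    class = "mixture_prior")
}

#' Fit a per-gene mixture by MAP estimation under the empirical-Bayes prior
#'
#' Runs Expectation Conditional Maximization for a two-component Gaussian
#' mixture under the conjugate prior from [build_prior()]: conditional on the
#' E-step responsibilities, the cluster means, then variances, then the
#' mixing proportion are maximised in turn against their priors. The prior
#' prevents cluster collapse when a gene shows only one mode.
#'
#' @param values one gene's positive log2 expression values (length >= 3).
#' @param prior a `mixture_prior`.
#' @inheritParams fit_omnibus_mixture
#' @return a `mixture_fit`; `loglik` holds the log posterior objective.
#' @export
fit_gene_map <- function(values, prior, tol = 1e-8, max_iter = 500,
                         min_var = 1e-8) {
  stopifnot(inherits(prior, "mixture_prior"))
  x <- values[is.finite(values)]
  if (length(x) < 3) stop("need at least 3 observations for a per-gene fit")
  m <- prior$mean_locations
  w <- prior$mean_strength
  a <- prior$var_shape; b <- prior$var_scale
  # initialise at the prior centres: guarantees both clusters present
  mu <- m
  var <- b / (a + 1)
  pi2 <- 0.5
  obj <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    r <- .posterior_component2(x, mu, var, pi2)
    n_resp <- c(length(x) - sum(r), sum(r))
    # CM-step 1: means (Gaussian prior with pseudo-count w)
    sx <- c(sum((1 - r) * x), sum(r * x))
    mu <- (w * m + sx) / (w + n_resp)
    # CM-step 2: variances (inverse-gamma prior + mean-prior quadratic term)
    ss <- c(sum((1 - r) * (x - mu[1])^2), sum(r * (x - mu[2])^2))
    var <- pmax((2 * b + w * (mu - m)^2 + ss) / (n_resp + 2 * a + 3), min_var)
    # CM-step 3: mixing proportion (Beta prior MAP update)
    pi2 <- (n_resp[2] + prior$mix_a - 1) /
      (length(x) + prior$mix_a + prior$mix_b - 2)
    obj_new <- .map_objective(x, mu, var, pi2, prior)
    if (is.finite(obj) && abs(obj_new - obj) < tol * (abs(obj) + 1)) {
      obj <- obj_new; converged <- TRUE; break
    }
    obj <- obj_new
  }
  new_mixture_fit(mu, var, pi2, obj, length(x), converged, it)
}

.map_objective <- function(x, mu, var, pi2, prior) {
  lp <- sum(stats::dnorm(mu, prior$mean_locations,
                         sqrt(var / prior$mean_strength), log = TRUE)) +
    sum(prior$var_shape * log(prior$var_scale) - lgamma(prior$var_shape) -
          (prior$var_shape + 1) * log(var) - prior$var_scale / var) +
    stats::dbeta(pi2, prior$mix_a, prior$mix_b, log = TRUE)
  .mix_loglik(x, mu, var, pi2) + lp
}

#' Posterior probability that an observation is signal
#'
#' Evaluates `pi * N(x; mu_s, var_s) / [pi * N(x; mu_s, var_s) +
#' (1 - pi) * N(x; mu_n, var_n)]` under a fitted mixture.
#'
#' @param x numeric vector of log2 expression values.
#' @param fit a `mixture_fit`.
#' @return probabilities in `[0, 1]`, same length as `x`.
#' @export
posterior_signal_prob <- function(x, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  .posterior_component2(x, c(fit$mu_noise, fit$mu_signal),
                        c(fit$var_noise, fit$var_signal), fit$pi_signal)
}

#' Truncate noise-classified observations to zero
#'
#' Observations whose posterior probability of belonging to the noise
#' cluster strictly exceeds 0.5 are set to zero; all others are returned
#' unchanged. Zero inputs are always zero on output.
#'
#' @param values one gene's (normalized) log2 expression values.
#' @param fit a `mixture_fit` for that gene.
#' @return the thresholded values (`et`).
#' @export
threshold_gene <- function(values, fit) {
  p_signal <- posterior_signal_prob(values, fit)
  out <- ifelse(1 - p_signal > 0.5, 0, values)
  out[values <= 0] <- 0
  out
}

#' Scalar expression threshold implied by a mixture fit
#'
#' The smallest value at which the posterior signal probability reaches 0.5
#' (the dashed-line threshold in per-gene violin plots), located by root
#' finding on the posterior.
#'
#' @param fit a `mixture_fit`.
#' @return a single numeric threshold (may be `-Inf` if everything is
#'   classified signal).
#' @export
threshold_point <- function(fit) {
  f <- function(x) posterior_signal_prob(x, fit) - 0.5
  lo <- fit$mu_noise - 10 * sqrt(fit$var_noise)
  hi <- fit$mu_signal
  if (f(hi) <= 0) return(Inf)
  if (f(lo) >= 0) return(-Inf)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Threshold every gene in a cell table
#'
#' Full thresholding pass: pools all positive values for the omnibus
#' maximum-likelihood mixture, builds the empirical-Bayes prior, fits each
#' gene by MAP-ECM, and truncates noise-classified observations to zero.
#' Zeros in the input are treated as background unconditionally and never
#' enter the mixture fits. Genes whose MAP fit is effectively unimodal
#' (cluster means closer than `unimodal_sd` pooled standard deviations) fall
#' back to the omnibus-derived threshold.
#'
#' @param table a `cell_table` (see [read_cell_table()]).
#' @param value_col column to threshold: `"ncount"` if present (normalized),
#'   else `"lcount"`.
#' @param kappa,nt,mix_weight prior hyperparameters, see [build_prior()].
#' @param tol,max_iter ECM control.
#' @param unimodal_sd separation (in pooled sd units) under which a per-gene
#'   fit is declared unimodal.
#' @return the table with an `et` column and recomputed `ngeneson`;
#'   per-gene fits are attached as attribute `"gene_fits"`, the omnibus fit
#'   as `"omnibus_fit"`.
#' @export
threshold_cell_table <- function(table, value_col = NULL, kappa = 3, nt = 5,
                                 mix_weight = 5, tol = 1e-8, max_iter = 500,
                                 unimodal_sd = 0.5) {
  table <- as_cell_table(table)
  if (is.null(value_col))
    value_col <- if ("ncount" %in% names(table)) "ncount" else "lcount"
  v <- table[[value_col]]
  pos <- v > 0
  omni <- fit_omnibus_mixture(v[pos], tol = tol, max_iter = max_iter)
  prior <- build_prior(omni, kappa = kappa, nt = nt, mix_weight = mix_weight)
  pooled_sd <- stats::sd(v[pos])
  et <- numeric(nrow(table))
  genes <- unique(table$gene_id)
  fits <- vector("list", length(genes)); names(fits) <- genes
  for (g in genes) {
    idx <- which(table$gene_id == g)
    xg <- v[idx]
    fit_idx <- idx[xg > 0]
    if (length(fit_idx) < 3) {
      # too few positive values to fit: classify against the omnibus
      fits[[g]] <- omni
      et[idx] <- threshold_gene(xg, omni)
      next
    }
    fit <- fit_gene_map(v[fit_idx], prior, tol = tol, max_iter = max_iter)
    if (fit$mu_signal - fit$mu_noise < unimodal_sd * pooled_sd) {
      # effectively unimodal gene: use the omnibus-derived threshold
      fits[[g]] <- omni
      et[idx] <- threshold_gene(xg, omni)
    } else {
      fits[[g]] <- fit
      et[idx] <- threshold_gene(xg, fit)
    }
  }
  table$et <- et
  table <- recompute_ngeneson(table)
  attr(table, "gene_fits") <- fits
  attr(table, "omnibus_fit") <- omni
  attr(table, "value_col") <- value_col
  table
}
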