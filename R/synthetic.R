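# ---- synthetic data with known ground truth ----

# normal draw truncated below at `lower` by inverse-CDF sampling
.rtnorm <- function(n, mean, sd, lower = 0) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

# center a vector/matrix of effects so each row sums to zero
.sum_to_zero <- function(m) {
  if (is.null(dim(m))) return(m - mean(m))
  sweep(m, 1, rowMeans(m))
}

#' Describe a synthetic single-cell expression experiment
#'
#' Collects the generative parameters for [simulate_dataset()]. The
#' generator mirrors the hurdle data-generating process: per gene, a
#' logistic model decides whether the gene is on in a cell, and a Gaussian
#' model generates the positive log2 expression given "on"; off records
#' draw from a near-zero background cluster. Cell line and cycle effects
#' (sum-to-zero) act on both the on/off log-odds and the positive mean, a
#' per-cell efficiency shift acts on both parts (inducing the
#' detection-rate / log-sum correlation seen in real panels), and plates
#' shift all measurements additively.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_group cells per cell line x phase combination.
#' @param lines,phases factor level labels.
#' @param n_plates plates, assigned to cells cyclically across the design.
#' @param freq_range baseline expression-frequency range; per-gene
#'   frequencies are drawn uniformly in it (default `[0.56, 0.9]`, matching
#'   typical panel interquartile ranges).
#' @param signal_mean_range per-gene signal-cluster mean range (log2 scale).
#' @param signal_sd signal-cluster standard deviation.
#' @param noise_mean,noise_sd background cluster location/scale; draws are
#'   truncated at zero.
#' @param line_sd_disc,line_sd_cont sd of random per-gene cell-line effects
#'   on the log-odds and positive mean (centered to sum to zero).
#' @param cycle_disc,cycle_cont optional `n_genes x length(phases)` effect
#'   matrices (rows centered); default all zero. See
#'   [plant_cycle_effect()].
#' @param interaction_disc,interaction_cont optional
#'   `n_genes x lines x phases` arrays (doubly centered); default zero.
#' @param efficiency_sd sd of the per-cell efficiency shift.
#' @param eff_coef_disc,eff_coef_cont loadings of the efficiency shift on
#'   the log-odds and the positive mean.
#' @param plate_sd sd of additive plate intercept shifts.
#' @param edges optional data frame (`a`, `b`, `disc`, `cont`) of planted
#'   conditional dependencies: gene `a`'s log-odds gains
#'   `disc * (et_b - mean(et_b))` and its positive mean
#'   `cont * (et_b - mean(et_b))`.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 50, n_cells_per_group = 12,
                            lines = c("H9", "MB231", "PC3"),
                            phases = c("G0/G1", "S", "G2/M"),
                            n_plates = 3,
                            freq_range = c(0.56, 0.9),
                            signal_mean_range = c(6, 11),
                            signal_sd = 1,
                            noise_mean = 0.5, noise_sd = 0.5,
                            line_sd_disc = 0.5, line_sd_cont = 0.5,
                            cycle_disc = NULL, cycle_cont = NULL,
                            interaction_disc = NULL, interaction_cont = NULL,
                            efficiency_sd = 1,
                            eff_coef_disc = 1, eff_coef_cont = 0.75,
                            plate_sd = 0.5,
                            edges = NULL) {
  if (signal_sd <= 0 || noise_sd <= 0 || efficiency_sd < 0 || plate_sd < 0)
    stop("scale parameters must be positive (efficiency/plate sd nonnegative)")
  if (!is.null(cycle_disc)) cycle_disc <- .sum_to_zero(cycle_disc)
  if (!is.null(cycle_cont)) cycle_cont <- .sum_to_zero(cycle_cont)
  structure(as.list(environment()), class = "simulation_spec")
}

#' Plant a cell-cycle effect on selected genes
#'
#' Adds a sum-to-zero cycle effect to the spec's effect matrices for the
#' given genes: `pattern` gives the raw per-phase effect (it is centered),
#' scaled by `size_disc` on the log-odds scale and `size_cont` on the
#' positive-mean scale.
#'
#' @param spec a `simulation_spec`.
#' @param genes integer indices of affected genes.
#' @param size_disc,size_cont effect sizes.
#' @param pattern per-phase pattern, recycled/centered; default peaks in the
#'   last phase.
#' @return the modified spec.
#' @export
plant_cycle_effect <- function(spec, genes, size_disc = 1, size_cont = 1,
                               pattern = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  n_ph <- length(spec$phases)
  if (is.null(pattern)) pattern <- c(rep(0, n_ph - 1), 1)
  pattern <- pattern - mean(pattern)
  if (is.null(spec$cycle_disc))
    spec$cycle_disc <- matrix(0, spec$n_genes, n_ph)
  if (is.null(spec$cycle_cont))
    spec$cycle_cont <- matrix(0, spec$n_genes, n_ph)
  for (g in genes) {
    spec$cycle_disc[g, ] <- spec$cycle_disc[g, ] + size_disc * pattern
    spec$cycle_cont[g, ] <- spec$cycle_cont[g, ] + size_cont * pattern
  }
  spec
}

#' Simulate a single-cell expression dataset with known ground truth
#'
#' Draws a long-format cell table from the generative model described in
#' [simulation_spec()]. Counts are emitted as `round(2^value - 1)` and
#' re-logged so the table carries `lcount = log2(count + 1)`; `et` holds
#' the oracle-thresholded value (the generated value where the gene is
#' truly on, 0 elsewhere) and `ngeneson` is recomputed from it.
#'
#' @param spec a `simulation_spec`.
#' @param seed integer seed; the draw is fully reproducible given
#'   `(spec, seed)`.
#' @return list with `table` (a `cell_table`) and `truth` (per-gene
#'   parameters, effect matrices, the on/off indicator matrix, per-cell
#'   efficiency shifts, plate shifts, planted edges, and per-gene phase of
#'   peak expression).
#' @export
simulate_dataset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  G <- spec$n_genes
  lines <- spec$lines; phases <- spec$phases
  n_group <- spec$n_cells_per_group
  cells <- expand.grid(rep_idx = seq_len(n_group), cycle = phases,
                       cell_line = lines, stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("C%04d", seq_len(n_cells))
  cells$plate <- paste0("P", (seq_len(n_cells) - 1L) %% spec$n_plates + 1L)
  cells$plate_row <- LETTERS[(seq_len(n_cells) - 1L) %/% 12L %% 8L + 1L]

  freq0 <- stats::runif(G, spec$freq_range[1], spec$freq_range[2])
  mu_sig <- stats::runif(G, spec$signal_mean_range[1], spec$signal_mean_range[2])
  line_disc <- .sum_to_zero(matrix(stats::rnorm(G * length(lines), 0,
                                                spec$line_sd_disc), G))
  line_cont <- .sum_to_zero(matrix(stats::rnorm(G * length(lines), 0,
                                                spec$line_sd_cont), G))
  cyc_d <- spec$cycle_disc %||% matrix(0, G, length(phases))
  cyc_c <- spec$cycle_cont %||% matrix(0, G, length(phases))
  e_cell <- stats::rnorm(n_cells, 0, spec$efficiency_sd)
  plate_shift <- stats::setNames(stats::rnorm(spec$n_plates, 0, spec$plate_sd),
                                 paste0("P", seq_len(spec$n_plates)))

  li <- match(cells$cell_line, lines)
  ph <- match(cells$cycle, phases)
  pl <- cells$plate

  edges <- spec$edges
  order_g <- seq_len(G)
  if (!is.null(edges) && nrow(edges)) {
    # generate parents before children (no cycles allowed in the plan)
    deps <- edges
    ordered <- integer(0); remaining <- seq_len(G)
    while (length(remaining)) {
      free <- remaining[!remaining %in% deps$a[deps$b %in% remaining]]
      if (!length(free)) stop("planted edge list is cyclic")
      ordered <- c(ordered, free)
      remaining <- setdiff(remaining, free)
    }
    order_g <- ordered
  }

  on <- matrix(NA, n_cells, G)
  val <- matrix(0, n_cells, G)        # true (pre-measurement) log2 value
  for (g in order_g) {
    logit <- stats::qlogis(freq0[g]) + line_disc[g, li] + cyc_d[g, ph] +
      spec$eff_coef_disc * e_cell
    mean_g <- mu_sig[g] + line_cont[g, li] + cyc_c[g, ph] +
      spec$eff_coef_cont * e_cell
    if (!is.null(spec$interaction_disc))
      logit <- logit + spec$interaction_disc[cbind(g, li, ph)]
    if (!is.null(spec$interaction_cont))
      mean_g <- mean_g + spec$interaction_cont[cbind(g, li, ph)]
    if (!is.null(edges) && nrow(edges)) {
      for (e in which(edges$a == g)) {
        xb <- val[, edges$b[e]] * on[, edges$b[e]]
        xb <- xb - mean(xb)
        logit <- logit + edges$disc[e] * xb
        mean_g <- mean_g + edges$cont[e] * xb
      }
    }
    on[, g] <- stats::rbinom(n_cells, 1, stats::plogis(logit))
    y_on <- stats::rnorm(n_cells, mean_g, spec$signal_sd)
    y_off <- .rtnorm(n_cells, spec$noise_mean, spec$noise_sd)
    val[, g] <- ifelse(on[, g] == 1, pmax(y_on, 0), y_off)
  }
  # plate-level intercept shift applies to the measured value
  measured <- val + plate_shift[pl]
  counts <- pmax(round(2^measured - 1), 0)
  lcount <- log2(counts + 1)

  table <- data.frame(
    cell_id = rep(cells$cell_id, G),
    cycle = rep(cells$cycle, G),
    cell_line = rep(cells$cell_line, G),
    plate = rep(cells$plate, G),
    plate_row = rep(cells$plate_row, G),
    gene_id = rep(sprintf("G%03d", seq_len(G)), each = n_cells),
    lcount = as.vector(lcount),
    et = as.vector(lcount * on),
    stringsAsFactors = FALSE)
  table <- recompute_ngeneson(as_cell_table(table))

  peak <- phases[apply(cyc_c + cyc_d, 1, which.max)]
  peak[rowSums(abs(cyc_c) + abs(cyc_d)) == 0] <- NA
  truth <- list(freq0 = freq0, mu_signal = mu_sig,
                line_disc = line_disc, line_cont = line_cont,
                cycle_disc = cyc_d, cycle_cont = cyc_c,
                efficiency = e_cell, plate_shift = plate_shift,
                on = on, edges = edges, peak_phase = peak,
                gene_id = sprintf("G%03d", seq_len(G)),
                cells = cells, seed = seed)
  list(table = table, truth = truth)
}

#' Simulate datasets under the cycle-free null
#'
#' Zeroes every cycle main effect and interaction in the spec and draws
#' `n_reps` independent datasets; rep `i` uses seed `seed + i - 1`, so each
#' rep is individually reproducible.
#'
#' @param spec a `simulation_spec`.
#' @param n_reps number of replicate datasets.
#' @param seed base seed.
#' @return list of [simulate_dataset()] results.
#' @export
simulate_null <- function(spec, n_reps = 1, seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec$cycle_disc <- NULL
  spec$cycle_cont <- NULL
  spec$interaction_disc <- NULL
  spec$interaction_cont <- NULL
  lapply(seq_len(n_reps), function(i) simulate_dataset(spec, seed = seed + i - 1))
}
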