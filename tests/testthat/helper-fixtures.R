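# small deterministic fixtures built in code

# long-format table from a cells x genes value matrix plus cell annotations
long_table <- function(values, cycle = NULL, cell_line = NULL, plate = NULL,
                       et = NULL) {
  n <- nrow(values); G <- ncol(values)
  cells <- sprintf("c%03d", seq_len(n))
  genes <- if (is.null(colnames(values))) sprintf("g%02d", seq_len(G))
           else colnames(values)
  df <- data.frame(
    cell_id = rep(cells, G),
    gene_id = rep(genes, each = n),
    lcount = as.vector(values),
    stringsAsFactors = FALSE)
  if (!is.null(cycle)) df$cycle <- rep(cycle, G)
  if (!is.null(cell_line)) df$cell_line <- rep(cell_line, G)
  if (!is.null(plate)) df$plate <- rep(plate, G)
  if (!is.null(et)) df$et <- as.vector(et)
  as_cell_table(df)
}

# a well-separated mixture fit for classification tests
toy_fit <- function(mu_noise = 1, mu_signal = 8, var_noise = 0.25,
                    var_signal = 1, pi_signal = 0.6) {
  scHurdle:::new_mixture_fit(c(mu_noise, mu_signal), c(var_noise, var_signal),
                             pi_signal, loglik = NA_real_, n_obs = 0L,
                             converged = TRUE, iterations = 0L)
}

# network edge-list constructor for combine/compare tests
toy_network <- function(pairs, component = "discrete") {
  scHurdle:::new_gene_network(
    data.frame(gene_a = vapply(pairs, `[`, "", 1),
               gene_b = vapply(pairs, `[`, "", 2),
               stringsAsFactors = FALSE),
    component)
}
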