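# Small builders used across the suite.

# Expression matrix from a bare numeric matrix (auto ids when unnamed).
make_em <- function(values, below = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  if (is.null(below)) below <- matrix(FALSE, nrow(values), ncol(values))
  expr_matrix(values, below)
}

# LVSI label vector for the first n_pos of n samples positive.
make_labels <- function(n_pos, n_neg, ids = NULL) {
  lab <- rep(c("positive", "negative"), c(n_pos, n_neg))
  if (!is.null(ids)) names(lab) <- ids
  lab
}

# Random matrix at the reference design with planted signal, for quick runs.
quick_dataset <- function(seed = 1, ...) {
  simulate_expression(sim_config(n_genes = 300, n_signature = 20,
                                 seed = seed, ...))
}
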