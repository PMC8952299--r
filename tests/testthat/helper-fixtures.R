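# Small fixtures shared across test files.

# Expression object with one sample per condition per experiment; `values`
# is a genes x 8 matrix (or vector for one gene) in the column order
# E1_NODHT, E1_DHT, E1_VEH, E1_ENZA, E2_NODHT, E2_DHT, E2_VEH, E2_ENZA.
make_expr <- function(values, gene_ids = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(values)))
  conds <- c("NODHT", "DHT", "VEH", "ENZA")
  ids <- as.vector(outer(conds, 1:2, function(co, e) sprintf("E%d_%s", e, co)))
  dimnames(values) <- list(gene_ids, ids)
  md <- data.frame(sample_id = ids,
                   experiment = rep(1:2, each = 4L),
                   condition = rep(conds, 2L),
                   stringsAsFactors = FALSE)
  apdt_expression(values, md)
}

# One gene with explicit per-condition RPKM, identical in both experiments.
make_expr_conditions <- function(nodht, dht, veh, enza, gene_id = "g001") {
  make_expr(matrix(rep(c(nodht, dht, veh, enza), 2L), nrow = 1L), gene_id)
}

# Independent exact Fisher oracle: full enumeration of the hypergeometric
# family via log-binomial coefficients (no dhyper), minimum-likelihood
# two-sided rule with the same 1e-7 tie tolerance.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0L, k - n2); hi <- min(m, k)
  support <- lo:hi
  probs <- exp(lchoose(m, support) + lchoose(n2, k - support) -
               lchoose(m + n2, k))
  min(sum(probs[probs <= probs[a - lo + 1L] * (1 + 1e-7)]), 1)
}
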