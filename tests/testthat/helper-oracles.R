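# Independent oracles used across the suite. These deliberately avoid the
# package's decoding/metric code paths: the tree oracle re-derives Karva
# semantics recursively, the confusion oracle enumerates pairs.

oracle_arity <- function(sym) {
  vapply(sym, function(s) {
    if (grepl("^\\*", s)) as.integer(sub("^\\*", "", s)) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

oracle_delays <- function(gene) {
  w <- gene$bit_width
  bits <- matrix(gene$delay_bits, nrow = w)
  as.integer(colSums(bits * 2 ^ ((w - 1):0)))
}

# recursive expression-tree evaluation of one gene's decoded product, given
# an assignment matrix A[j, tau + 1] of delayed expression levels
oracle_gene_value <- function(gene, A) {
  syms <- c(gene$head, gene$tail)
  ar <- oracle_arity(syms)
  children <- vector("list", length(syms))
  queue <- 1L
  nxt <- 2L
  qi <- 1L
  while (qi <= length(queue)) {
    node <- queue[qi]
    qi <- qi + 1L
    if (ar[node] > 0) {
      kids <- nxt:(nxt + ar[node] - 1L)
      nxt <- nxt + ar[node]
      children[[node]] <- kids
      queue <- c(queue, kids)
    }
  }
  delays <- oracle_delays(gene)
  eval_node <- function(p) {
    if (ar[p] > 0) return(prod(vapply(children[[p]], eval_node, numeric(1))))
    if (syms[p] == "R") return(exp(gene$korders[p]))
    j <- as.integer(sub("^x", "", syms[p]))
    A[j, delays[p] + 1] ^ gene$korders[p]
  }
  gene$rate * eval_node(1L)
}

# package-path value of a decoded term under the same assignment matrix
decoded_term_value <- function(term, A) {
  f <- term$factors
  v <- term$rate * term$constant
  if (nrow(f)) v <- v * prod(A[cbind(f[, "gene"], f[, "delay"] + 1)] ^ f[, "exponent"])
  v
}

# brute-force confusion counts: explicit double loop over ordered pairs
oracle_confusion <- function(predicted, truth, n, include_self = FALSE) {
  has <- function(df, j, i) any(df$regulator == j & df$target == i)
  TP <- FN <- FP <- TN <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (!include_self && i == j) next
    p <- has(predicted, j, i)
    g <- has(truth, j, i)
    if (p && g) TP <- TP + 1L
    else if (!p && g) FN <- FN + 1L
    else if (p && !g) FP <- FP + 1L
    else TN <- TN + 1L
  }
  list(TP = TP, FN = FN, FP = FP, TN = TN)
}

# plain R fixed-step RK4 for a *non-delayed* S-system: the reference solver
# for the delays-all-zero equivalence check
oracle_rk4_ssystem <- function(equations, x0, times, substeps) {
  N <- length(x0)
  term_v <- function(tm, x) {
    v <- tm$rate * tm$constant
    f <- tm$factors
    if (nrow(f)) v <- v * prod(x[f[, "gene"]] ^ f[, "exponent"])
    v
  }
  deriv <- function(x) {
    vapply(seq_len(N), function(i) {
      term_v(equations[[i]]$production, x) - term_v(equations[[i]]$consumption, x)
    }, numeric(1))
  }
  out <- matrix(NA_real_, N, length(times))
  out[, 1] <- x <- x0
  h <- (times[2] - times[1]) / substeps
  for (k in 2:length(times)) {
    for (s in seq_len(substeps)) {
      k1 <- deriv(x)
      k2 <- deriv(x + h / 2 * k1)
      k3 <- deriv(x + h / 2 * k2)
      k4 <- deriv(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[, k] <- x
  }
  out
}

# random edge set over non-self ordered pairs
rand_edges <- function(n_genes, m) {
  pairs <- expand.grid(regulator = seq_len(n_genes), target = seq_len(n_genes))
  pairs <- pairs[pairs$regulator != pairs$target, ]
  pick <- pairs[sample.int(nrow(pairs), m), ]
  edge_set(pick$regulator, pick$target,
           rep("production", m), runif(m, 0.1, 1),
           sample(0:3, m, replace = TRUE))
}

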