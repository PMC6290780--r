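# Karva (level-order) decoding of RGEP genes into evaluable TDSS terms.
#
# A gene string is read breadth-first from position 1: the root consumes its
# arity of subsequent positions, those consume theirs, and so on; only this
# expressed prefix (the open reading frame) contributes. Each expressed gene
# terminal x_j contributes a power-law factor using that position's kinetic
# order and delay slots; each expressed constant terminal R multiplies
# exp(kinetic order slot) into the term's constant factor. The chromosome's
# two decoded terms joined by subtraction give the TDSS right-hand side
#   dX_i/dt = alpha_i prod_j X_{j,t-tau_gij}^{g_ij}
#           - beta_i  prod_j X_{j,t-tau_hij}^{h_ij}.

# number of expressed symbols under level-order filling
expressed_length <- function(symbols, alphabet) {
  ar <- symbol_arity(alphabet, symbols)
  need <- 1L
  pos <- 0L
  while (pos < need) {
    pos <- pos + 1L
    need <- need + ar[pos]
  }
  need
}

new_tdss_term <- function(rate, factors, constant = 1) {
  structure(list(rate = rate, factors = factors, constant = constant),
            class = "tdss_term")
}

empty_factors <- function() {
  matrix(numeric(0), ncol = 3,
         dimnames = list(NULL, c("gene", "exponent", "delay")))
}

#' Decode an RGEP gene into a TDSS term
#'
#' @param gene an `rgep_gene`.
#' @param alphabet the [symbol_alphabet()] the gene was built over.
#' @return a `tdss_term`: list with `rate`, `constant` (product of expressed
#'   R terminals, 1 if none) and `factors`, a matrix with columns
#'   `gene` (regulator index), `exponent`, `delay` in expressed level-order.
#' @export
decode_gene <- function(gene, alphabet) {
  symbols <- gene_symbols(gene)
  k <- expressed_length(symbols, alphabet)
  expr <- symbols[seq_len(k)]
  idx <- symbol_gene_index(expr)
  delays <- gene_delays(gene)
  term_pos <- which(!is.na(idx))              # expressed gene terminals
  factors <- cbind(gene = idx[term_pos],
                   exponent = gene$korders[term_pos],
                   delay = delays[term_pos])
  if (length(term_pos) == 0) factors <- empty_factors()
  r_pos <- which(expr == "R")
  constant <- if (length(r_pos)) exp(sum(gene$korders[r_pos])) else 1
  new_tdss_term(gene$rate, factors, constant)
}

#' Decode a chromosome into a TDSS equation
#'
#' @param chrom a `chromosome`.
#' @param alphabet the shared [symbol_alphabet()].
#' @param target_index 1-based index of the target gene the equation models.
#' @return a `tdss_equation`: list with `target`, `production`, `consumption`.
#' @export
decode_chromosome <- function(chrom, alphabet, target_index = NA_integer_) {
  structure(list(target = as.integer(target_index),
                 production = decode_gene(chrom$gene1, alphabet),
                 consumption = decode_gene(chrom$gene2, alphabet)),
            class = "tdss_equation")
}

# numeric value of one term given a lookup function (j, tau) -> level
term_value <- function(term, lookup) {
  v <- term$rate * term$constant
  f <- term$factors
  for (r in seq_len(nrow(f))) {
    x <- lookup(f[r, "gene"], f[r, "delay"])
    g <- f[r, "exponent"]
    if (x <= 0 && g != round(g))
      stop("domain error: nonpositive expression level with noninteger exponent")
    v <- v * x ^ g
  }
  unname(v)
}

#' Evaluate the TDSS derivative at one time point
#'
#' @param eq a `tdss_equation`.
#' @param history function `(gene j, lag tau) -> expression level` resolving
#'   delayed lookups at the evaluation time.
#' @return the instantaneous rate of change of the target gene.
#' @export
evaluate_derivative <- function(eq, history) {
  term_value(eq$production, history) - term_value(eq$consumption, history)
}

#' @export
print.tdss_equation <- function(x, ...) {
  fmt_term <- function(tm, sym) {
    f <- tm$factors
    parts <- vapply(seq_len(nrow(f)), function(r) {
      sprintf("x%d[t-%d]^%.3g", as.integer(f[r, "gene"]),
              as.integer(f[r, "delay"]), f[r, "exponent"])
    }, character(1))
    cst <- if (tm$constant != 1) sprintf(" * %.3g", tm$constant) else ""
    paste0(sprintf("%.3g", tm$rate), cst,
           if (length(parts)) paste0(" * ", paste(parts, collapse = " * ")) else "")
  }
  cat(sprintf("dX_%s/dt = %s  -  %s\n",
              ifelse(is.na(x$target), "i", x$target),
              fmt_term(x$production), fmt_term(x$consumption)))
  invisible(x)
}
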