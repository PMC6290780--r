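# Symbol alphabet for restricted gene expression programming (RGEP).
#
# The function set holds only multiplication operators "*m" (product of m
# operands); the terminal set holds gene variables x1..xN plus (optionally)
# the constant terminal R. Power-law S-system terms are products, so no
# other operators are needed.

#' Construct an RGEP symbol alphabet
#'
#' @param arities integer vector of multiplication arities (each `m` yields a
#'   function symbol `*m` multiplying `m` operands); all must be >= 2.
#' @param n_genes number of gene variables `x1..xN`.
#' @param use_constant include the constant terminal `R`?
#' @return an object of class `symbol_alphabet` with elements `functions`,
#'   `terminals`, `max_arity`, `arity` (named lookup), `n_genes`.
#' @export
symbol_alphabet <- function(arities = 2:5, n_genes, use_constant = TRUE) {
  arities <- as.integer(arities)
  if (length(arities) == 0 || any(arities < 2))
    stop("invalid configuration: every function symbol needs arity >= 2")
  if (n_genes < 1)
    stop("invalid configuration: need at least one gene variable")
  funs <- paste0("*", arities)
  terms <- c(paste0("x", seq_len(n_genes)), if (use_constant) "R")
  arity <- c(stats::setNames(arities, funs),
             stats::setNames(integer(length(terms)), terms))
  structure(list(functions = funs, terminals = terms,
                 max_arity = max(arities), arity = arity,
                 n_genes = as.integer(n_genes)),
            class = "symbol_alphabet")
}

#' @export
print.symbol_alphabet <- function(x, ...) {
  cat("RGEP alphabet: F = {", paste(x$functions, collapse = ", "),
      "}, T = {", paste(x$terminals, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# arity of each symbol (0 for terminals)
symbol_arity <- function(alphabet, symbols) {
  unname(alphabet$arity[symbols])
}

# gene index of terminal symbols ("x7" -> 7L), NA for functions and R
symbol_gene_index <- function(symbols) {
  idx <- rep(NA_integer_, length(symbols))
  is_x <- grepl("^x[0-9]+$", symbols)
  idx[is_x] <- as.integer(sub("^x", "", symbols[is_x]))
  idx
}
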