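# RGEP genes, Karva decoding, TDSS equation evaluation.

test_that("tail_length follows (n-1)h+1 and rejects bad configurations", {
  expect_equal(tail_length(5, 2), 9L)
  expect_equal(tail_length(2, 3), 4L)
  expect_equal(tail_length(3, 1), 3L)
  expect_error(tail_length(1, 2), "invalid configuration")
  expect_error(tail_length(3, 0), "invalid configuration")
})

test_that("random genes satisfy all invariants and are seed-deterministic", {
  al <- symbol_alphabet(2:3, 5)
  iv <- param_intervals()
  g <- with_seed(1, random_gene(al, 2, iv))
  expect_length(g$tail, 5)                       # (3-1)*2 + 1
  expect_silent(validate_gene(g, al, 2, iv))
  g2 <- with_seed(1, random_gene(al, 2, iv))
  expect_identical(g, g2)
  # empty sets rejected
  expect_error(symbol_alphabet(integer(), 5), "invalid configuration")
})

test_that("random gene symbol frequencies are uniform over their sets", {
  al <- symbol_alphabet(2:3, 5)
  iv <- param_intervals()
  genes <- with_seed(99, replicate(2000, random_gene(al, 2, iv),
                                   simplify = FALSE))
  heads <- unlist(lapply(genes, `[[`, "head"))      # 4000 head draws
  tails <- unlist(lapply(genes, `[[`, "tail"))      # 10000 tail draws
  pool_h <- c(al$functions, al$terminals)
  ph <- chisq.test(table(factor(heads, levels = pool_h)))$p.value
  pt <- chisq.test(table(factor(tails, levels = al$terminals)))$p.value
  expect_gt(ph, 0.01)
  expect_gt(pt, 0.01)
  # parameters inside intervals
  ko <- unlist(lapply(genes, `[[`, "korders"))
  expect_true(all(ko >= 0 & ko <= 1))
})

test_that("decoding reproduces the worked two-gene example", {
  ch <- fig_chromosome()
  eq <- decode_chromosome(ch, fig_alphabet(), 1)
  expect_equal(unname(eq$production$factors[, "gene"]), c(3, 1, 2))
  expect_equal(unname(eq$consumption$factors[, "gene"]), c(2, 4, 1, 3))
  expect_equal(nrow(eq$production$factors), 3)
  expect_equal(nrow(eq$consumption$factors), 4)
  # factor parameters come from the expressed positions' slots
  expect_equal(unname(eq$production$factors[1, "exponent"]),
               ch$gene1$korders[2])
})

test_that("a terminal root expresses a single-factor term", {
  al <- symbol_alphabet(2:3, 5)
  g <- with_seed(3, random_gene(al, 2, param_intervals()))
  g$head[1] <- "x2"
  term <- decode_gene(g, al)
  expect_equal(nrow(term$factors), 1)
  expect_equal(unname(term$factors[1, "gene"]), 2)
})

test_that("level-order decoding equals recursive tree-walk evaluation", {
  al <- symbol_alphabet(2:4, 6)
  iv <- param_intervals()
  with_seed(11, {
    for (rep in 1:100) {
      g <- random_gene(al, 3, iv)
      A <- matrix(runif(6 * 4, 0.2, 3), 6, 4)
      expect_equal(decoded_term_value(decode_gene(g, al), A),
                   oracle_gene_value(g, A), tolerance = 1e-12)
    }
  })
})

test_that("chromosome decode-then-evaluate matches tree evaluation", {
  al <- symbol_alphabet(2:3, 5)
  iv <- param_intervals()
  with_seed(12, {
    for (rep in 1:50) {
      ch <- random_chromosome(al, 2, iv)
      eq <- decode_chromosome(ch, al, 1)
      A <- matrix(runif(5 * 4, 0.2, 3), 5, 4)
      expect_equal(
        decoded_term_value(eq$production, A) - decoded_term_value(eq$consumption, A),
        oracle_gene_value(ch$gene1, A) - oracle_gene_value(ch$gene2, A),
        tolerance = 1e-12)
    }
  })
})

test_that("identical genes with equal rates give a zero derivative", {
  al <- symbol_alphabet(2:3, 5)
  ch <- with_seed(4, random_chromosome(al, 2, param_intervals()))
  ch$gene2 <- ch$gene1
  eq <- decode_chromosome(ch, al, 1)
  hist <- function(j, tau) 0.7 + 0.1 * j + 0.05 * tau
  expect_equal(evaluate_derivative(eq, hist), 0)
})

test_that("evaluate_derivative matches the hand-composed formula", {
  # zero exponents: alpha - beta regardless of state
  eq0 <- make_eq(1, 2.0, cbind(1, 0, 0), 0.5, cbind(2, 0, 1))
  expect_equal(evaluate_derivative(eq0, function(j, tau) runif(1, 1, 9)), 1.5)
  # random instance vs direct product formula
  with_seed(21, {
    for (rep in 1:20) {
      eq <- random_eq(1, 4)
      A <- matrix(runif(4 * 4, 0.3, 2.5), 4, 4)
      hist <- function(j, tau) A[j, tau + 1]
      f <- eq$production$factors
      g <- eq$consumption$factors
      direct <- eq$production$rate * prod(A[cbind(f[, 1], f[, 3] + 1)] ^ f[, 2]) -
        eq$consumption$rate * prod(A[cbind(g[, 1], g[, 3] + 1)] ^ g[, 2])
      expect_equal(evaluate_derivative(eq, hist), direct, tolerance = 1e-12)
    }
  })
  # delays all zero equal a current-value lookup
  eqz <- make_eq(1, 1.2, cbind(c(1, 2), c(0.5, 0.7), c(0, 0)),
                 0.8, cbind(1, 0.9, 0))
  x <- c(1.4, 0.6)
  expect_equal(evaluate_derivative(eqz, function(j, tau) x[j]),
               evaluate_derivative(eqz, function(j, tau) {
                 stopifnot(tau == 0); x[j]
               }))
  # domain error on nonpositive level with noninteger exponent
  eqd <- make_eq(1, 1, cbind(1, 0.5, 0), 1, NULL)
  expect_error(evaluate_derivative(eqd, function(j, tau) -1), "domain error")
})

test_that("chromosome serialization round-trips exactly", {
  al <- symbol_alphabet(2:5, 8)
  with_seed(31, {
    for (rep in 1:20) {
      ch <- random_chromosome(al, 2, param_intervals())
      ch2 <- deserialize_chromosome(serialize_chromosome(ch))
      expect_identical(ch2$gene1$head, ch$gene1$head)
      expect_identical(ch2$gene2$tail, ch$gene2$tail)
      expect_identical(ch2$gene1$delay_bits, ch$gene1$delay_bits)
      expect_equal(ch2$gene1$rate, ch$gene1$rate, tolerance = 0)
      expect_equal(ch2$gene2$korders, ch$gene2$korders, tolerance = 0)
    }
  })
})
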