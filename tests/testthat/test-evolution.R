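# Fitness and the hybrid variation/selection operators.

cfg5 <- evolution_config(population_size = 20, max_iterations = 2,
                         partitions = 2, seed = 1)
al5 <- symbol_alphabet(2:5, 5)
iv <- param_intervals()

test_that("fitness is 1/(1+SSE) and matches a hand summation", {
  # two-point, one-gene toy series under a flat (zero-exponent) model
  al1 <- symbol_alphabet(2:3, 1, use_constant = FALSE)
  ds <- time_series_dataset(0:1, matrix(c(1, 1.2), 1))
  ch <- with_seed(2, flat_chromosome(al1, 2, alpha = 2, beta = 0.5))
  cfg <- evolution_config(population_size = 10, seed = 1)
  # prediction: x(1) = 1 + (2 - 0.5); SSE = (2.5 - 1.2)^2 (t0 term is 0)
  expect_equal(fitness(ch, 1, list(ds), cfg, al1),
               1 / (1 + (2.5 - 1.2)^2), tolerance = 1e-12)
})

test_that("the generating equation of a noise-free dataset scores ~1", {
  w <- toy_world()
  al <- symbol_alphabet(2:5, 5)
  sse <- sum(vapply(w$datasets, function(d) {
    p <- simulate_gene_decoupled(w$net$equations[[3]], d)
    sum((p$values - d$values[3, ])^2)
  }, numeric(1)))
  expect_lt(sse, 1e-3)   # limited by decoupled-vs-network interpolation error
  expect_gt(1 / (1 + sse), 0.999)
})

test_that("divergent models get fitness zero", {
  ds <- time_series_dataset(0:20, matrix(runif(105, 1, 2), 5))
  ch <- with_seed(3, flat_chromosome(al5, 2, alpha = 3, beta = 0))
  ch$gene1$head <- c("x1", "x1")
  ch$gene1$korders[] <- 60          # x^60 positive feedback: overflows
  expect_identical(fitness(ch, 1, list(ds),
                           evolution_config(population_size = 10, seed = 1),
                           al5), 0)
})

test_that("structure mutation strategies preserve legality", {
  with_seed(7, {
    g <- random_gene(al5, 2, iv)
    for (rep in 1:1000) {
      m <- mutate_structure(g, "single_point", al5, 2, iv)
      expect_silent(validate_gene(m, al5, 2, iv))
    }
    # tail positions never receive a function symbol
    tails <- replicate(500, mutate_structure(g, "single_point", al5, 2, iv)$tail)
    expect_false(any(grepl("^\\*", tails)))
  })
})

test_that("all_variables keeps the tree shape and changes terminals", {
  ch <- fig_chromosome()
  al <- fig_alphabet()
  with_seed(8, {
    m <- mutate_structure(ch$gene1, "all_variables", al, 2, iv)
    syms0 <- c(ch$gene1$head, ch$gene1$tail)
    syms1 <- c(m$head, m$tail)
    is_fun <- grepl("^\\*", syms0)
    expect_identical(syms1[is_fun], syms0[is_fun])     # functions untouched
    expect_false(any(syms1[!is_fun] == syms0[!is_fun]))  # every terminal changed
  })
})

test_that("single_gene mutation is reproducible under a fixed seed", {
  g <- with_seed(9, random_gene(al5, 2, iv))
  m1 <- with_seed(10, mutate_structure(g, "single_gene", al5, 2, iv))
  m2 <- with_seed(10, mutate_structure(g, "single_gene", al5, 2, iv))
  expect_identical(m1, m2)
  expect_error(mutate_structure(g, "bogus", al5, 2, iv), "unknown mutation")
})

test_that("real mutation: identity, degenerate sigma, and moments", {
  v <- with_seed(1, runif(100))
  expect_equal(mutate_real(v, c(0, 1), 0, 0.1), v, tolerance = 0)
  expect_equal(with_seed(1, mutate_real(v, c(0, 1), 1, 1e-12)), v,
               tolerance = 1e-9)
  # wide interval so clipping never engages: displacements are N(0, 0.1^2)
  d <- with_seed(2, mutate_real(rep(0.5, 1e5), c(-10, 10), 1, 0.1)) - 0.5
  expect_lt(abs(mean(d)), 3 * 0.1 / sqrt(1e5))
  se_var <- sqrt(2 / (1e5 - 1)) * 0.01
  expect_lt(abs(stats::var(d) - 0.01), 3 * se_var)
})

test_that("binary mutation: identity, inversion, flip frequency", {
  bits <- c(0L, 1L)
  expect_identical(mutate_binary(bits, 0), bits)
  expect_identical(with_seed(1, mutate_binary(c(0L, 1L), 1)), c(1L, 0L))
  b <- with_seed(3, mutate_binary(integer(1e5), 0.3))
  p_hat <- mean(b)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("structure crossover: identity, conservation, legality", {
  x <- with_seed(11, random_chromosome(al5, 2, iv))
  y <- with_seed(12, random_chromosome(al5, 2, iv))
  # crossing a chromosome with itself yields two copies of itself
  off <- with_seed(13, crossover_structure(x, x, "single_point"))
  expect_identical(off[[1]]$gene1$head, x$gene1$head)
  expect_identical(off[[2]]$gene2$tail, x$gene2$tail)
  # single_gene swap conserves the multiset of the four genes
  off <- with_seed(14, crossover_structure(x, y, "single_gene"))
  strip <- function(g) serialize_chromosome(
    structure(list(gene1 = g, gene2 = g, fitness = NA_real_,
                   partition_id = NA_integer_), class = "chromosome"))
  before <- sort(c(strip(x$gene1), strip(x$gene2), strip(y$gene1), strip(y$gene2)))
  after <- sort(c(strip(off[[1]]$gene1), strip(off[[1]]$gene2),
                  strip(off[[2]]$gene1), strip(off[[2]]$gene2)))
  expect_identical(after, before)
  with_seed(15, {
    for (rep in 1:500) {
      off <- crossover_structure(x, y, "single_point")
      expect_silent(validate_chromosome(off[[1]], al5, 2, iv))
      expect_silent(validate_chromosome(off[[2]], al5, 2, iv))
    }
  })
})

test_that("real crossover conserves the sum before clipping", {
  expect_equal(crossover_real(1, 3, 0.5), list(0, 4))
  expect_equal(crossover_real(c(1, 2), c(3, 1), 0), list(c(1, 2), c(3, 1)))
  # conservation is algebraically exact; in floating point the recovered sum
  # can differ by at most one unit in the last place (pure final rounding)
  with_seed(16, {
    ok <- TRUE
    for (rep in 1:200) {
      x <- runif(5); y <- runif(5); g <- runif(1)
      off <- crossover_real(x, y, g)
      d <- abs((off[[1]] + off[[2]]) - (x + y))
      ok <- ok && all(d <= 2 * .Machine$double.eps * pmax(1, abs(x + y)))
    }
    expect_true(ok)
  })
})

test_that("gamma schedule decays geometrically", {
  expect_equal(gamma_schedule(0, 1), 1.0)
  expect_equal(gamma_schedule(1, 1), 0.99)
  expect_equal(gamma_schedule(2, 1), 0.9801)
})

test_that("binary crossover conserves per-position bits", {
  x <- c(1L, 1L, 0L, 0L, 1L, 0L)
  expect_identical(with_seed(1, crossover_binary(x, x, "single_point")),
                   list(x, x))
  with_seed(17, {
    for (strategy in c("single_point", "two_point")) {
      for (rep in 1:200) {
        a <- as.integer(runif(8) < 0.5)
        b <- as.integer(runif(8) < 0.5)
        off <- crossover_binary(a, b, strategy)
        expect_identical(off[[1]] + off[[2]], a + b)
      }
    }
  })
  expect_error(crossover_binary(c(0L, 1L), c(0L, 1L, 1L)), "incompatible")
})

test_that("roulette selection is fitness-proportional", {
  pop <- list("a", "b")
  with_seed(18, {
    picks <- unlist(roulette_select(pop, c(3, 1), 4, 1e4))
    p_hat <- mean(picks == "a")
    expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / 1e4))
  })
  expect_identical(roulette_select(list("z"), 1, 1, 3), list("z", "z", "z"))
  expect_message(with_seed(19, roulette_select(pop, c(0, 0), 0, 5)),
                 "uniform")
})

test_that("reproduce_group preserves size and chromosome invariants", {
  with_seed(20, {
    pop <- lapply(1:10, function(i) random_chromosome(al5, 2, iv))
    fits <- runif(10)
    off <- reproduce_group(pop, fits, sum(fits), cfg5, 0.5, al5)
    expect_length(off, 10)
    for (ch in off) expect_silent(validate_chromosome(ch, al5, 2, iv))
  })
})
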