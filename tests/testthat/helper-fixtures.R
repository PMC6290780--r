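# Shared fixtures, built in code at test time.

# the worked decoding example: two genes over F = {*2, *3}, T = {x1..x5, R},
# head length 2; production decodes to factors on x3, x1, x2 and consumption
# to factors on x2, x4, x1, x3
fig_alphabet <- function() symbol_alphabet(2:3, 5)

fig_chromosome <- function(seed = 42) {
  al <- fig_alphabet()
  iv <- param_intervals()
  with_seed(seed, {
    g1 <- random_gene(al, 2, iv)
    g2 <- random_gene(al, 2, iv)
    g1$head <- c("*3", "x3"); g1$tail <- c("x1", "x2", "x2", "x1", "x1")
    g2$head <- c("*2", "*3"); g2$tail <- c("x2", "x4", "x1", "x3", "x2")
    structure(list(gene1 = g1, gene2 = g2, fitness = NA_real_,
                   partition_id = NA_integer_), class = "chromosome")
  })
}

# a chromosome whose korders/exponents are all zero: decodes to dX = alpha - beta
flat_chromosome <- function(alphabet, h, alpha, beta, intervals = param_intervals()) {
  ch <- random_chromosome(alphabet, h, intervals)
  ch$gene1$rate <- alpha
  ch$gene2$rate <- beta
  ch$gene1$korders[] <- 0
  ch$gene2$korders[] <- 0
  # R terminals decode through exp(), so keep them out of the strings
  strip_R <- function(g) {
    g$head[g$head == "R"] <- "x1"
    g$tail[g$tail == "R"] <- "x1"
    g
  }
  ch$gene1 <- strip_R(ch$gene1)
  ch$gene2 <- strip_R(ch$gene2)
  ch
}

# hand-built TDSS equation
make_eq <- function(target, prod_rate, prod_f, cons_rate, cons_f,
                    prod_cst = 1, cons_cst = 1) {
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("gene", "exponent", "delay")))
  fix <- function(f) {
    if (is.null(f)) return(empty)
    colnames(f) <- c("gene", "exponent", "delay")
    f
  }
  structure(list(
    target = as.integer(target),
    production = structure(list(rate = prod_rate, factors = fix(prod_f),
                                constant = prod_cst), class = "tdss_term"),
    consumption = structure(list(rate = cons_rate, factors = fix(cons_f),
                                 constant = cons_cst), class = "tdss_term")),
    class = "tdss_equation")
}

# gentle 5-gene delayed test network: near-equilibrium relaxation dynamics,
# smooth enough for refinement studies
gentle_net5 <- function() {
  lapply(1:5, function(i) {
    reg <- if (i == 1) 5 else i - 1
    make_eq(i,
            prod_rate = 1.0,
            prod_f = cbind(reg, 0.4, (i %% 4)),
            cons_rate = 1.0,
            cons_f = cbind(i, 0.8, 0))
  })
}

# small random equation within the default intervals (for refinement and
# decode/evaluate property tests)
random_eq <- function(target, n_genes, tau_max = 3) {
  m1 <- 1 + stats::rpois(1, 1.5)
  m2 <- 1 + stats::rpois(1, 1.5)
  f <- function(m) cbind(sample.int(n_genes, m, replace = TRUE),
                         stats::runif(m, 0, 1),
                         sample(0:tau_max, m, replace = TRUE))
  make_eq(target, stats::runif(1, 0.2, 2), f(m1), stats::runif(1, 0.2, 2), f(m2))
}

# tiny noise-free benchmark world shared by several tests
toy_world <- function(seed = 7, n_genes = 5, n_edges = 8, n_delayed = 2,
                      n_replicates = 2, n_timepoints = 21) {
  net <- with_seed(seed, generate_network(network_spec(n_genes, n_edges, n_delayed)))
  datasets <- with_seed(seed + 1,
                        generate_datasets(net, n_replicates = n_replicates,
                                          n_timepoints = n_timepoints))
  list(net = net, datasets = datasets)
}

# fresh scratch directory per call (under the session tempdir)
local_tmpdir <- function() {
  d <- tempfile("tdssnet-test-")
  dir.create(d, recursive = TRUE)
  d
}
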