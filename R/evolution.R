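# Fitness and the hybrid GA/GEP variation and selection operators.
#
# A chromosome carries three coding regions that evolve under different
# operator families:
#   structure region - the two genes' symbol strings (GEP operators)
#   real region      - rate constants and kinetic orders (real-coded GA)
#   binary region    - the delay bit strings (binary-coded GA)

#' Evolution run configuration
#'
#' Defaults follow the benchmark settings: population 2000, 200 iterations,
#' crossover probability 0.7, mutation probability 0.3, rate constants in
#' [0, 3], kinetic orders in [0, 1], delays in [0, 3] sampling intervals,
#' 200 partitions, function set `{*2, *3, *4, *5}`.
#'
#' @param population_size number of chromosomes.
#' @param max_iterations generations to run.
#' @param p_c per-pair crossover probability.
#' @param p_m mutation probability (per chromosome for the structure region,
#'   per slot for real and binary regions).
#' @param rate_interval,kinetic_interval,delay_interval parameter intervals.
#' @param partitions number of random partitions k in the map/reduce loop.
#' @param head_length GEP head length h.
#' @param arities multiplication arities of the function set.
#' @param use_constant include the constant terminal `R`?
#' @param sigma_frac Gaussian mutation s.d. as a fraction of interval width.
#' @param gamma0 initial value of the real-crossover schedule [gamma_schedule()].
#' @param seed master seed; every stochastic stage derives substreams from it.
#' @param substeps,eps_pos integrator settings used inside fitness.
#' @return list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 2000L, max_iterations = 200L,
                             p_c = 0.7, p_m = 0.3,
                             rate_interval = c(0, 3),
                             kinetic_interval = c(0, 1),
                             delay_interval = c(0, 3),
                             partitions = 200L, head_length = 2L,
                             arities = 2:5, use_constant = TRUE,
                             sigma_frac = 0.1, gamma0 = 1,
                             seed = 1L, substeps = 10L, eps_pos = 1e-6) {
  if (p_c < 0 || p_c > 1 || p_m < 0 || p_m > 1)
    stop("invalid configuration: probabilities must lie in [0, 1]")
  if (partitions < 1) stop("invalid configuration: partitions >= 1 required")
  if (population_size < 2) stop("invalid configuration: population too small")
  cfg <- list(population_size = as.integer(population_size),
              max_iterations = as.integer(max_iterations),
              p_c = p_c, p_m = p_m,
              intervals = param_intervals(rate_interval, kinetic_interval,
                                          delay_interval),
              partitions = as.integer(partitions),
              head_length = as.integer(head_length),
              arities = as.integer(arities), use_constant = use_constant,
              sigma_frac = sigma_frac, gamma0 = gamma0,
              seed = as.integer(seed),
              integrator = integrator_config(substeps, eps_pos))
  class(cfg) <- "evolution_config"
  cfg
}

cfg_alphabet <- function(cfg, n_genes) {
  symbol_alphabet(cfg$arities, n_genes, cfg$use_constant)
}

# --- fitness ---------------------------------------------------------------

#' Fitness of chromosomes for one target gene
#'
#' Decodes each chromosome, integrates the decoupled model against every
#' replicate and scores `1 / (1 + SSE)` where SSE sums squared differences
#' between predicted and observed target trajectories over all replicates
#' and time points. Divergent integrations score 0.
#'
#' @param pop list of chromosomes.
#' @param target 1-based target gene index.
#' @param datasets list of [time_series_dataset()] replicates.
#' @param cfg an [evolution_config()].
#' @param alphabet the shared [symbol_alphabet()] (derived from `cfg` and the
#'   dataset when omitted).
#' @return numeric vector of fitness values in `[0, 1]`.
#' @export
fitness_population <- function(pop, target, datasets, cfg, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- cfg_alphabet(cfg, nrow(datasets[[1]]$values))
  N <- nrow(datasets[[1]]$values)
  if (alphabet$n_genes > N)
    stop("index error: alphabet references gene x", alphabet$n_genes,
         " but the datasets hold only ", N, " genes")
  eqs <- lapply(pop, function(ch) {
    eq <- decode_chromosome(ch, alphabet, target)
    eq_components(eq)
  })
  sse <- sse_batch_cpp(eqs,
                       lapply(datasets, `[[`, "times"),
                       lapply(datasets, `[[`, "values"),
                       target - 1L, cfg$integrator$substeps,
                       cfg$integrator$eps_pos)
  ifelse(sse < 0, 0, 1 / (1 + sse))
}

#' @rdname fitness_population
#' @param chrom a single chromosome.
#' @export
fitness <- function(chrom, target, datasets, cfg, alphabet = NULL) {
  fitness_population(list(chrom), target, datasets, cfg, alphabet)[1]
}

# --- mutation --------------------------------------------------------------

#' Structure-region mutation of one gene
#'
#' Strategies: `single_point` changes one position (head positions may take
#' any symbol, tail positions only terminals, so offspring stay legal);
#' `single_gene` replaces the whole gene with a fresh random gene;
#' `all_variables` replaces every terminal symbol in the structure region
#' with a different terminal (tree shape is untouched).
#'
#' @param gene an `rgep_gene`.
#' @param strategy one of `"single_point"`, `"single_gene"`, `"all_variables"`.
#' @inheritParams random_gene
#' @return the mutated gene.
#' @export
mutate_structure <- function(gene, strategy, alphabet, h, intervals) {
  switch(strategy,
    single_point = {
      L <- length(gene$head) + length(gene$tail)
      pos <- sample.int(L, 1)
      if (pos <= length(gene$head)) {
        gene$head[pos] <- sample(c(alphabet$functions, alphabet$terminals), 1)
      } else {
        gene$tail[pos - length(gene$head)] <- sample(alphabet$terminals, 1)
      }
      gene
    },
    single_gene = random_gene(alphabet, h, intervals),
    all_variables = {
      swap <- function(syms) {
        is_term <- symbol_arity(alphabet, syms) == 0
        for (p in which(is_term)) {
          others <- setdiff(alphabet$terminals, syms[p])
          if (length(others)) syms[p] <- sample(others, 1)
        }
        syms
      }
      gene$head <- swap(gene$head)
      gene$tail <- swap(gene$tail)
      gene
    },
    stop("invalid configuration: unknown mutation strategy '", strategy, "'")
  )
}

#' Gaussian mutation of a real-coded vector
#'
#' Each slot independently, with probability `p_m`, receives additive
#' Gaussian noise `X' = X + delta`, `delta ~ N(0, sigma^2)`, then is clipped
#' back to the interval.
#'
#' @param values numeric vector.
#' @param interval length-2 bounds.
#' @param p_m per-slot mutation probability.
#' @param sigma Gaussian standard deviation.
#' @return mutated vector.
#' @export
mutate_real <- function(values, interval, p_m, sigma) {
  hit <- stats::runif(length(values)) < p_m
  if (any(hit))
    values[hit] <- values[hit] + stats::rnorm(sum(hit), 0, sigma)
  pmin(pmax(values, interval[1]), interval[2])
}

#' Bit-flip mutation of a binary-coded vector
#'
#' @param bits integer vector of 0/1.
#' @param p_m per-bit inversion probability.
#' @return mutated bits.
#' @export
mutate_binary <- function(bits, p_m) {
  hit <- stats::runif(length(bits)) < p_m
  bits[hit] <- 1L - bits[hit]
  bits
}

# full hybrid mutation of one chromosome. p_m is read as the mutation
# budget of each chromosome-region application, split over the three coding
# regions: the structure region is mutated with probability p_m (one
# strategy drawn uniformly), and every real/binary slot sees the per-value
# rule at rate p_m/3. Applying the per-value rules at the full p_m to every
# offspring makes the search non-convergent at benchmark settings (best
# fitness flatlines: offspring scramble ~30% of their parameters every
# generation); see the methods vignette.
mutate_chromosome <- function(chrom, cfg, alphabet) {
  iv <- cfg$intervals
  h <- cfg$head_length
  if (stats::runif(1) < cfg$p_m) {
    strategy <- sample(c("single_point", "single_gene", "all_variables"), 1)
    if (strategy == "all_variables") {
      chrom$gene1 <- mutate_structure(chrom$gene1, strategy, alphabet, h, iv)
      chrom$gene2 <- mutate_structure(chrom$gene2, strategy, alphabet, h, iv)
    } else {
      slot <- paste0("gene", sample(1:2, 1))
      chrom[[slot]] <- mutate_structure(chrom[[slot]], strategy, alphabet, h, iv)
    }
  }
  p_slot <- cfg$p_m / 3
  sig_r <- cfg$sigma_frac * diff(iv$rate)
  sig_k <- cfg$sigma_frac * diff(iv$kinetic)
  for (slot in c("gene1", "gene2")) {
    g <- chrom[[slot]]
    g$rate <- mutate_real(g$rate, iv$rate, p_slot, sig_r)
    g$korders <- mutate_real(g$korders, iv$kinetic, p_slot, sig_k)
    g$delay_bits <- mutate_binary(g$delay_bits, p_slot)
    chrom[[slot]] <- g
  }
  chrom$fitness <- NA_real_
  chrom$partition_id <- NA_integer_
  chrom
}

# --- crossover -------------------------------------------------------------

#' Structure-region crossover
#'
#' `single_point`: a point is drawn in the concatenated structure region
#' (gene1 then gene2 symbols) and all symbols after it are exchanged;
#' because both parents share head length, head positions exchange with head
#' positions and tail with tail, so legality is preserved. `single_gene`:
#' one randomly chosen gene of each parent (with its parameter slots) is
#' swapped.
#'
#' @param x,y parent chromosomes sharing alphabet and head length.
#' @param strategy `"single_point"` or `"single_gene"`.
#' @return list of two offspring chromosomes.
#' @export
crossover_structure <- function(x, y, strategy = c("single_point", "single_gene")) {
  strategy <- match.arg(strategy)
  if (length(x$gene1$head) != length(y$gene1$head) ||
      length(x$gene1$tail) != length(y$gene1$tail))
    stop("incompatible parents: head/tail lengths differ")
  if (strategy == "single_point") {
    sx <- c(gene_symbols(x$gene1), gene_symbols(x$gene2))
    sy <- c(gene_symbols(y$gene1), gene_symbols(y$gene2))
    L <- length(sx)
    p <- sample.int(L, 1)
    if (p < L) {
      idx <- (p + 1):L
      tmp <- sx[idx]; sx[idx] <- sy[idx]; sy[idx] <- tmp
    }
    hl <- length(x$gene1$head); tl <- length(x$gene1$tail)
    put <- function(ch, s) {
      ch$gene1$head <- s[seq_len(hl)]
      ch$gene1$tail <- s[hl + seq_len(tl)]
      ch$gene2$head <- s[hl + tl + seq_len(hl)]
      ch$gene2$tail <- s[2 * hl + tl + seq_len(tl)]
      ch
    }
    x <- put(x, sx); y <- put(y, sy)
  } else {
    a <- sample(1:2, 1); b <- sample(1:2, 1)
    sa <- paste0("gene", a); sb <- paste0("gene", b)
    tmp <- x[[sa]]; x[[sa]] <- y[[sb]]; y[[sb]] <- tmp
  }
  x$fitness <- y$fitness <- NA_real_
  list(x, y)
}

#' Arithmetic crossover of real-coded vectors
#'
#' `X' = X + gamma (X - Y)`, `Y' = Y - gamma (X - Y)`; the sum `X + Y` is
#' conserved exactly before clipping to the interval.
#'
#' @param x,y numeric parent vectors of equal length.
#' @param gamma extrapolation weight, see [gamma_schedule()].
#' @param interval clipping bounds (`NULL` to skip clipping).
#' @return list of the two offspring vectors.
#' @export
crossover_real <- function(x, y, gamma, interval = NULL) {
  if (length(x) != length(y)) stop("incompatible parents: length mismatch")
  d <- x - y
  xo <- x + gamma * d
  yo <- (x + y) - xo        # algebraically y - gamma*d; exact sum conservation
  if (!is.null(interval)) {
    xo <- pmin(pmax(xo, interval[1]), interval[2])
    yo <- pmin(pmax(yo, interval[1]), interval[2])
  }
  list(xo, yo)
}

#' Real-crossover weight schedule
#'
#' Geometric decay `gamma = gamma0 * 0.99^t`: early generations take wide
#' extrapolating steps; late generations protect good individuals.
#'
#' @param t iteration number (0-based).
#' @param gamma0 initial weight in (0, 1].
#' @return gamma.
#' @export
gamma_schedule <- function(t, gamma0 = 1) {
  stopifnot(t >= 0, gamma0 > 0, gamma0 <= 1)
  gamma0 * 0.99 ^ t
}

#' Binary-region crossover
#'
#' `single_point`: a point `p` is drawn in `0..L-1` and bits before it
#' (positions `< p`, 0-based) are exchanged. `two_point`: two distinct
#' points are drawn and the bits strictly between them are exchanged. Both
#' conserve the per-position multiset of bits across the pair.
#'
#' @param x,y equal-length integer 0/1 vectors.
#' @param strategy `"single_point"` or `"two_point"`.
#' @return list of two offspring bit vectors.
#' @export
crossover_binary <- function(x, y, strategy = c("single_point", "two_point")) {
  strategy <- match.arg(strategy)
  L <- length(x)
  if (length(y) != L) stop("incompatible parents: bit string length mismatch")
  if (strategy == "single_point") {
    p <- sample.int(L, 1) - 1L            # 0..L-1; p = 0 leaves both unchanged
    idx <- seq_len(p)
  } else {
    pts <- sort(sample.int(L, 2))
    idx <- if (pts[2] - pts[1] > 1) (pts[1] + 1):(pts[2] - 1) else integer(0)
  }
  if (length(idx)) {
    tmp <- x[idx]; x[idx] <- y[idx]; y[idx] <- tmp
  }
  list(x, y)
}

# full hybrid crossover of a chromosome pair: one coding region is selected
# uniformly per pair and that region's crossover applied — structure
# (strategy uniform), arithmetic on rates and kinetic orders, or binary
# (strategy uniform) on the concatenated delay region
crossover_chromosomes <- function(x, y, cfg, gamma) {
  region <- sample(c("structure", "real", "binary"), 1)
  if (region == "structure") {
    off <- crossover_structure(x, y, sample(c("single_point", "single_gene"), 1))
    x <- off[[1]]; y <- off[[2]]
  } else if (region == "real") {
    iv <- cfg$intervals
    rr <- crossover_real(c(x$gene1$rate, x$gene2$rate),
                         c(y$gene1$rate, y$gene2$rate), gamma, iv$rate)
    kk <- crossover_real(c(x$gene1$korders, x$gene2$korders),
                         c(y$gene1$korders, y$gene2$korders), gamma, iv$kinetic)
    nk <- length(x$gene1$korders)
    put <- function(ch, r, k) {
      ch$gene1$rate <- r[1]; ch$gene2$rate <- r[2]
      ch$gene1$korders <- k[seq_len(nk)]; ch$gene2$korders <- k[nk + seq_len(nk)]
      ch
    }
    x <- put(x, rr[[1]], kk[[1]]); y <- put(y, rr[[2]], kk[[2]])
  } else {
    bb <- crossover_binary(c(x$gene1$delay_bits, x$gene2$delay_bits),
                           c(y$gene1$delay_bits, y$gene2$delay_bits),
                           sample(c("single_point", "two_point"), 1))
    nb <- length(x$gene1$delay_bits)
    x$gene1$delay_bits <- bb[[1]][seq_len(nb)]
    x$gene2$delay_bits <- bb[[1]][nb + seq_len(nb)]
    y$gene1$delay_bits <- bb[[2]][seq_len(nb)]
    y$gene2$delay_bits <- bb[[2]][nb + seq_len(nb)]
  }
  x$fitness <- y$fitness <- NA_real_
  list(x, y)
}

# --- selection -------------------------------------------------------------

#' Roulette (fitness-proportional) selection
#'
#' Samples `count` chromosomes with replacement, each with probability
#' `f_i / sum_f`. A zero total fitness falls back to uniform selection.
#'
#' @param pop list of chromosomes.
#' @param fits nonnegative fitness vector.
#' @param sum_f total fitness (passed explicitly to honour the map/reduce
#'   record contract).
#' @param count number of selections.
#' @return list of selected chromosomes.
#' @export
roulette_select <- function(pop, fits, sum_f, count) {
  n <- length(pop)
  if (any(fits < 0)) stop("negative fitness")
  idx <- if (sum_f <= 0) {
    message("roulette_select: zero total fitness, falling back to uniform")
    sample.int(n, count, replace = TRUE)
  } else {
    sample.int(n, count, replace = TRUE, prob = fits / sum_f)
  }
  pop[idx]
}

# --- one generation over one (sub)population -------------------------------

#' Reproduce one (sub)population for one generation
#'
#' Roulette-selects as many parents as the group holds, pairs them, applies
#' the hybrid crossover to each pair with probability `p_c`, and mutates
#' every offspring. This routine *is* the serial algorithm; the map/reduce
#' engine applies it per partition.
#'
#' @param group list of chromosomes (one partition, or the whole population).
#' @param fits fitness of each group member.
#' @param sum_f global fitness total of the full population.
#' @param cfg an [evolution_config()].
#' @param gamma current real-crossover weight.
#' @param alphabet shared [symbol_alphabet()].
#' @return list of `length(group)` offspring chromosomes.
#' @export
reproduce_group <- function(group, fits, sum_f, cfg, gamma, alphabet) {
  s <- length(group)
  off <- roulette_select(group, fits, sum_f, s)
  if (s >= 2) {
    n_pairs <- s %/% 2
    for (p in seq_len(n_pairs)) {
      i <- 2 * p - 1
      if (stats::runif(1) < cfg$p_c) {
        pair <- crossover_chromosomes(off[[i]], off[[i + 1]], cfg, gamma)
        off[[i]] <- pair[[1]]; off[[i + 1]] <- pair[[2]]
      }
    }
  }
  off <- lapply(off, mutate_chromosome, cfg = cfg, alphabet = alphabet)
  # island-style local elitism: every subpopulation retains its own best,
  # so the partitions act as parallel hill climbers
  off[[1]] <- group[[which.max(fits)]]
  off
}
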