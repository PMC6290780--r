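# Partition-based map/reduce-style generation loop (in-process emulation of
# a Hadoop cluster): map = parallel per-chromosome fitness + random partition
# id + global fitness total; reduce = per-partition reproduction; merge.

#' Map phase: fitness, partition ids, global fitness total
#'
#' Computes every chromosome's fitness (a pure computation, parallelizable
#' across workers with identical results), draws each chromosome's partition
#' id uniformly from `0..k-1`, and attaches the global total `sum_f` to
#' every record.
#'
#' @inheritParams fitness_population
#' @param k number of partitions.
#' @param workers worker processes for fitness evaluation (forked; results
#'   are independent of the worker count).
#' @return object of class `map_records`: list with `chroms`, `fits`,
#'   `sum_f`, `keys` (partition ids), plus `records()`-style access via
#'   [as.list.map_records()].
#' @export
map_phase <- function(pop, target, datasets, cfg, k = cfg$partitions,
                      workers = 1L, alphabet = NULL) {
  if (k < 1) stop("invalid configuration: k >= 1 required")
  if (is.null(alphabet)) alphabet <- cfg_alphabet(cfg, nrow(datasets[[1]]$values))
  n <- length(pop)
  if (workers > 1L && n > 1L) {
    chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
    fits_l <- parallel::mclapply(chunks, function(ix) {
      fitness_population(pop[ix], target, datasets, cfg, alphabet)
    }, mc.cores = workers)
    fits <- unlist(fits_l, use.names = FALSE)[order(unlist(chunks))]
  } else {
    fits <- fitness_population(pop, target, datasets, cfg, alphabet)
  }
  keys <- sample.int(k, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {
    pop[[i]]$fitness <- fits[i]
    pop[[i]]$partition_id <- keys[i]
  }
  structure(list(chroms = pop, fits = fits, sum_f = sum(fits), keys = keys,
                 k = as.integer(k)),
            class = "map_records")
}

#' @export
as.list.map_records <- function(x, ...) {
  lapply(seq_along(x$chroms), function(i) {
    list(key = x$keys[i],
         value = list(chromosome = x$chroms[[i]], f = x$fits[i],
                      sum_f = x$sum_f))
  })
}

#' Reduce phase: per-partition reproduction
#'
#' Groups records by partition id and reproduces each group independently
#' with [reproduce_group()] (roulette selection against the global `sum_f`,
#' crossover restricted to partition members, mutation). Each partition's
#' random substream is derived from `(seed, generation, partition)`, so the
#' result does not depend on scheduling. Empty partitions contribute no
#' offspring; each group's offspring quota equals its size, so the merged
#' offspring population has exactly the parent population's size.
#'
#' @param records a `map_records` object from [map_phase()].
#' @param cfg an [evolution_config()].
#' @param gamma current real-crossover weight.
#' @param alphabet shared [symbol_alphabet()].
#' @param seed_base seed the per-partition substreams are derived from.
#' @param generation generation counter folded into the substreams.
#' @return list of offspring chromosomes (same length as the parents).
#' @export
reduce_phase <- function(records, cfg, gamma, alphabet, seed_base,
                         generation = 0L) {
  groups <- split(seq_along(records$chroms), records$keys)
  offspring <- vector("list", length(records$chroms))
  pos <- 1L
  for (key in names(groups)) {
    ix <- groups[[key]]
    sub <- with_seed(derive_seed(seed_base, generation, as.integer(key)),
                     reproduce_group(records$chroms[ix], records$fits[ix],
                                     records$sum_f, cfg, gamma, alphabet))
    offspring[pos:(pos + length(ix) - 1L)] <- sub
    pos <- pos + length(ix)
  }
  offspring
}

#' Evolve a TDSS model for one target gene
#'
#' Alternates the map and reduce phases for `cfg$max_iterations` generations
#' (or stops early once a fitness of `1 - 1e-9` is reached). The best
#' chromosome ever seen is copied unmodified into every offspring population
#' (elitism), so the best fitness trace is non-decreasing.
#'
#' @inheritParams map_phase
#' @param verbose print one log line per generation (generation, best
#'   fitness, mean fitness, serialized best chromosome)?
#' @param checkpoint_dir if non-`NULL`, a directory receiving one text file
#'   per generation (`gen-<t>.txt`: fitness and serialization of every
#'   chromosome) for inspection and restart.
#' @return list with `best` (chromosome), `fitness`, `equation` (decoded
#'   best), and `trace` (data.frame: generation, best, mean, best_chromosome).
#' @export
evolve <- function(target, datasets, cfg, workers = 1L, verbose = FALSE,
                   checkpoint_dir = NULL) {
  alphabet <- cfg_alphabet(cfg, nrow(datasets[[1]]$values))
  seed <- cfg$seed
  pop <- with_seed(derive_seed(seed, 0L, -1L), {
    lapply(seq_len(cfg$population_size), function(i)
      random_chromosome(alphabet, cfg$head_length, cfg$intervals))
  })
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  elite <- NULL
  elite_fit <- -Inf
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric(), best_chromosome = character())
  for (t in 0:cfg$max_iterations) {
    records <- with_seed(derive_seed(seed, t, -2L),
                         map_phase(pop, target, datasets, cfg,
                                   k = cfg$partitions, workers = workers,
                                   alphabet = alphabet))
    b <- which.max(records$fits)
    if (records$fits[b] > elite_fit) {
      elite_fit <- records$fits[b]
      elite <- records$chroms[[b]]
    }
    trace <- rbind(trace, data.frame(generation = t, best = elite_fit,
                                     mean = mean(records$fits),
                                     best_chromosome = serialize_chromosome(elite)))
    if (verbose)
      message(sprintf("gen %d  best %.6f  mean %.6f  %s", t, elite_fit,
                      mean(records$fits), serialize_chromosome(elite)))
    if (!is.null(checkpoint_dir))
      writeLines(vapply(seq_along(records$chroms), function(i)
        paste0(fmt_num(records$fits[i]), "\t",
               serialize_chromosome(records$chroms[[i]])), character(1)),
        file.path(checkpoint_dir, sprintf("gen-%03d.txt", t)))
    if (t == cfg$max_iterations || elite_fit >= 1 - 1e-9) break
    gamma <- gamma_schedule(t, cfg$gamma0)
    pop <- reduce_phase(records, cfg, gamma, alphabet, seed_base = seed,
                        generation = t)
    pop[[1]] <- elite                      # elitist safeguard
  }
  list(best = elite, fitness = elite_fit,
       equation = decode_chromosome(elite, alphabet, target),
       trace = trace)
}
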