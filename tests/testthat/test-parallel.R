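# Map/reduce generation loop: record contracts, determinism, k=1 serial
# equivalence, population conservation.

make_world <- function(seed = 7) {
  w <- toy_world(seed = seed)
  cfg <- evolution_config(population_size = 24, max_iterations = 3,
                          partitions = 4, seed = 5)
  al <- symbol_alphabet(2:5, 5)
  pop <- with_seed(100, lapply(seq_len(cfg$population_size), function(i)
    random_chromosome(al, cfg$head_length, cfg$intervals)))
  list(w = w, cfg = cfg, al = al, pop = pop)
}

test_that("map phase: keys, sum_f contract, record view", {
  ww <- make_world()
  rec <- with_seed(1, map_phase(ww$pop, 1, ww$w$datasets, ww$cfg, k = 1,
                                alphabet = ww$al))
  expect_true(all(rec$keys == 0L))
  rec4 <- with_seed(1, map_phase(ww$pop, 1, ww$w$datasets, ww$cfg, k = 4,
                                 alphabet = ww$al))
  expect_true(all(rec4$keys %in% 0:3))
  # sum_f equals an independent recomputation and is attached to every record
  f_indep <- vapply(ww$pop, fitness, numeric(1), target = 1,
                    datasets = ww$w$datasets, cfg = ww$cfg, alphabet = ww$al)
  expect_equal(rec4$sum_f, sum(f_indep))
  recs <- as.list(rec4)
  expect_true(all(vapply(recs, function(r) r$value$sum_f, numeric(1)) ==
                  rec4$sum_f))
})

test_that("map phase is independent of the worker count", {
  ww <- make_world()
  r1 <- with_seed(2, map_phase(ww$pop, 2, ww$w$datasets, ww$cfg, k = 4,
                               workers = 1L, alphabet = ww$al))
  r4 <- with_seed(2, map_phase(ww$pop, 2, ww$w$datasets, ww$cfg, k = 4,
                               workers = 4L, alphabet = ww$al))
  expect_identical(r1$fits, r4$fits)
  expect_identical(r1$keys, r4$keys)
  expect_identical(r1$sum_f, r4$sum_f)
})

test_that("k=1 reduce phase reproduces the serial generation bit-for-bit", {
  ww <- make_world()
  rec <- with_seed(3, map_phase(ww$pop, 1, ww$w$datasets, ww$cfg, k = 1,
                                alphabet = ww$al))
  off_mr <- reduce_phase(rec, ww$cfg, gamma = 0.7, alphabet = ww$al,
                         seed_base = 5, generation = 2L)
  off_serial <- with_seed(derive_seed(5, 2L, 0L),
                          reproduce_group(rec$chroms, rec$fits, rec$sum_f,
                                          ww$cfg, 0.7, ww$al))
  expect_identical(lapply(off_mr, serialize_chromosome),
                   lapply(off_serial, serialize_chromosome))
})

test_that("reduce phase conserves the population size", {
  ww <- make_world()
  for (k in c(1, 4, 100)) {   # k >= population: singleton groups still work
    rec <- with_seed(4, map_phase(ww$pop, 1, ww$w$datasets, ww$cfg, k = k,
                                  alphabet = ww$al))
    off <- reduce_phase(rec, ww$cfg, gamma = 0.5, alphabet = ww$al,
                        seed_base = 5, generation = 0L)
    expect_length(off, length(ww$pop))
    for (ch in off) expect_silent(validate_chromosome(ch, ww$al, 2,
                                                      ww$cfg$intervals))
  }
})

test_that("evolve: no-op loop, monotone trace, determinism", {
  w <- toy_world()
  cfg0 <- evolution_config(population_size = 30, max_iterations = 0,
                           partitions = 3, seed = 9)
  r0 <- evolve(1, w$datasets, cfg0)
  expect_equal(nrow(r0$trace), 1)
  expect_equal(r0$fitness, max(r0$trace$best))

  cfg <- evolution_config(population_size = 30, max_iterations = 5,
                          partitions = 3, seed = 9)
  r1 <- evolve(1, w$datasets, cfg)
  expect_true(all(diff(r1$trace$best) >= 0))
  r2 <- evolve(1, w$datasets, cfg)
  expect_identical(serialize_chromosome(r1$best), serialize_chromosome(r2$best))
  expect_identical(r1$trace, r2$trace)
})

test_that("evolve logs and checkpoints per generation", {
  w <- toy_world()
  dir <- local_tmpdir()
  cfg <- evolution_config(population_size = 20, max_iterations = 2,
                          partitions = 2, seed = 3)
  expect_message(r <- evolve(1, w$datasets, cfg, verbose = TRUE,
                             checkpoint_dir = dir), "gen 0")
  files <- list.files(dir, pattern = "^gen-")
  expect_length(files, nrow(r$trace))
  line1 <- strsplit(readLines(file.path(dir, files[1]))[1], "\t")[[1]]
  expect_silent(deserialize_chromosome(line1[2]))
  expect_equal(nchar(r$trace$best_chromosome[1]) > 0, TRUE)
})
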