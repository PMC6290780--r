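# Synthetic benchmark generator: ground-truth time-delayed S-system
# networks with spec-matched edge and delayed-edge counts, plus replicate
# time-series datasets. Stands in for external benchmark generators so the
# whole inference pipeline is testable offline.

#' Specification of a synthetic time-delayed regulatory network
#'
#' Benchmark-sized examples: (50 genes, 128 edges, 10 delayed),
#' (100, 212, 16), (150, 345, 25).
#'
#' @param n_genes number of genes.
#' @param n_edges number of directed regulatory edges (no self-loops).
#' @param n_delayed how many edges carry a positive delay.
#' @param tau_max largest delay, in sampling intervals.
#' @param rate_interval,kinetic_interval intervals the rate constants and
#'   kinetic orders are drawn from.
#' @param exponent_floor minimum |exponent| of a truth edge, so every truth
#'   edge is recoverable above the extraction threshold.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(n_genes, n_edges, n_delayed, tau_max = 3L,
                         rate_interval = c(0, 3), kinetic_interval = c(0, 1),
                         exponent_floor = 0.1) {
  n_genes <- as.integer(n_genes)
  n_edges <- as.integer(n_edges)
  n_delayed <- as.integer(n_delayed)
  if (n_edges > n_genes * (n_genes - 1))
    stop("invalid configuration: more edges than ordered non-self pairs")
  if (n_delayed > n_edges || n_delayed < 0)
    stop("invalid configuration: n_delayed must lie in [0, n_edges]")
  if (exponent_floor >= kinetic_interval[2])
    stop("invalid configuration: exponent floor above kinetic interval")
  structure(list(n_genes = n_genes, n_edges = n_edges, n_delayed = n_delayed,
                 tau_max = as.integer(tau_max),
                 rate_interval = as.numeric(rate_interval),
                 kinetic_interval = as.numeric(kinetic_interval),
                 exponent_floor = exponent_floor),
            class = "network_spec")
}

#' Generate a ground-truth TDSS network
#'
#' Topology: preferential attachment on out-degree (a few regulator hubs,
#' scale-free-like out-degree distribution), no self-loops, exactly
#' `n_edges` edges. Each edge joins the production or consumption term of
#' its target (equal probability) with an exponent in
#' `[exponent_floor, kinetic upper bound]`; exactly `n_delayed` randomly
#' chosen edges get a delay from `{1..tau_max}`, the rest are instantaneous.
#' Every gene additionally carries first-order self-degradation in its
#' consumption term (not part of the truth edge set), which keeps the
#' dynamics bounded; genes without production edges get basal production.
#'
#' @param spec a [network_spec()].
#' @return list with `equations` (one `tdss_equation` per gene), `truth`
#'   (an [edge_set()] with exactly the specified cardinalities) and `spec`.
#' @export
generate_network <- function(spec) {
  N <- spec$n_genes
  # --- topology: preferential attachment on out-degree
  chosen <- matrix(FALSE, N, N)
  reg <- integer(spec$n_edges)
  tgt <- integer(spec$n_edges)
  outdeg <- rep(0, N)
  for (e in seq_len(spec$n_edges)) {
    repeat {
      r <- sample.int(N, 1, prob = outdeg + 1)
      t <- sample.int(N, 1)
      if (t != r && !chosen[r, t]) break
    }
    chosen[r, t] <- TRUE
    outdeg[r] <- outdeg[r] + 1
    reg[e] <- r; tgt[e] <- t
  }
  role <- sample(c("production", "consumption"), spec$n_edges, replace = TRUE)
  delay <- integer(spec$n_edges)
  if (spec$n_delayed > 0) {
    which_delayed <- sample.int(spec$n_edges, spec$n_delayed)
    delay[which_delayed] <- sample.int(spec$tau_max, spec$n_delayed,
                                       replace = TRUE)
  }
  expo <- stats::runif(spec$n_edges, spec$exponent_floor,
                       min(1, spec$kinetic_interval[2]))
  truth <- edge_set(reg, tgt, role, expo, delay)

  # --- parameterization: self-degradation keeps the dynamics bounded; rates
  # give relaxation time constants of a few sampling intervals, so the
  # transients from random initial conditions span the sampled window
  # instead of dying within the first sample
  alpha <- stats::runif(N, 0.5, 1.2)
  beta <- stats::runif(N, 0.4, 0.9)
  self_h <- stats::runif(N, 0.5, 1.0)
  equations <- lapply(seq_len(N), function(i) {
    pe <- which(tgt == i & role == "production")
    ce <- which(tgt == i & role == "consumption")
    pf <- if (length(pe)) cbind(gene = reg[pe], exponent = expo[pe],
                                delay = delay[pe]) else empty_factors()
    cf <- rbind(cbind(gene = i, exponent = self_h[i], delay = 0),
                if (length(ce)) cbind(gene = reg[ce], exponent = expo[ce],
                                      delay = delay[ce]))
    colnames(cf) <- c("gene", "exponent", "delay")
    structure(list(target = i,
                   production = new_tdss_term(alpha[i], pf),
                   consumption = new_tdss_term(beta[i], cf)),
              class = "tdss_equation")
  })
  list(equations = equations, truth = truth, spec = spec)
}

#' Generate replicate time-series datasets from a TDSS network
#'
#' For each replicate, positive initial conditions are drawn uniformly from
#' `[0.5, 1.5]`, the full delay system is integrated over a uniform grid,
#' and (optionally) multiplicative log-normal noise of scale `noise_sd` is
#' applied. A replicate whose integration blows up is retried with fresh
#' initial conditions up to `max_retries` times.
#'
#' @param net result of [generate_network()] (or a list of `tdss_equation`).
#' @param n_replicates number of replicate series (benchmark default 10).
#' @param n_timepoints samples per series (benchmark default 21).
#' @param t_span time interval covered (benchmark default `c(0, 20)`).
#' @param noise_sd standard deviation of log-normal measurement noise
#'   (0 = noise-free).
#' @param cfg an [integrator_config()].
#' @param max_retries initial-condition resampling attempts per replicate.
#' @return list of [time_series_dataset()].
#' @export
generate_datasets <- function(net, n_replicates = 10L, n_timepoints = 21L,
                              t_span = c(0, 20), noise_sd = 0,
                              cfg = integrator_config(), max_retries = 5L) {
  equations <- if (!is.null(net$equations)) net$equations else net
  N <- length(equations)
  if (n_timepoints < 2) stop("need at least two time points")
  times <- seq(t_span[1], t_span[2], length.out = n_timepoints)
  lapply(seq_len(n_replicates), function(r) {
    for (attempt in seq_len(max_retries + 1L)) {
      x0 <- stats::runif(N, 0.5, 1.5)
      ds <- tryCatch(simulate_network(equations, x0, times, cfg,
                                      replicate_id = r),
                     error = function(e) e)
      if (!inherits(ds, "error")) {
        if (noise_sd > 0) {
          noisy <- ds$values * exp(matrix(stats::rnorm(length(ds$values), 0,
                                                       noise_sd),
                                          nrow = N))
          ds$values <- pmax(noisy, cfg$eps_pos)
        }
        return(ds)
      }
    }
    stop("replicate ", r, " failed after ", max_retries, " retries: ",
         conditionMessage(ds))
  })
}
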