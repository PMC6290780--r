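# Per-gene decomposition driver and edge extraction.

#' Construct an edge set
#'
#' @param regulator,target integer gene indices (1-based).
#' @param role `"production"` or `"consumption"` term of the target's model.
#' @param exponent kinetic-order magnitude carried by the edge.
#' @param delay integer lag in sampling intervals.
#' @return data.frame of class `edge_set` with columns `regulator`, `target`,
#'   `role`, `exponent`, `delay`, `class` (`"instantaneous"` if delay 0,
#'   `"delayed"` otherwise).
#' @export
edge_set <- function(regulator = integer(), target = integer(),
                     role = character(), exponent = numeric(),
                     delay = integer()) {
  df <- data.frame(regulator = as.integer(regulator),
                   target = as.integer(target),
                   role = as.character(role),
                   exponent = as.numeric(exponent),
                   delay = as.integer(delay))
  df$class <- ifelse(df$delay > 0, "delayed", "instantaneous")
  class(df) <- c("edge_set", "data.frame")
  df
}

# merge duplicate (regulator, target) rows keeping the largest |exponent|
merge_edges <- function(df) {
  if (nrow(df) == 0) return(df)
  ord <- order(df$target, df$regulator, -abs(df$exponent))
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(df[, c("regulator", "target")])
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("edge_set", "data.frame")
  df
}

#' Extract regulatory edges from a fitted TDSS equation
#'
#' Every factor `(j, exponent, tau)` of either term with
#' `|exponent| >= epsilon` yields a directed edge `j -> target` labelled
#' with its term role, exponent and delay; duplicates are merged keeping the
#' representative with the largest `|exponent|`. Constant (`R`) factors
#' never produce edges.
#'
#' @param eq a `tdss_equation` with a valid `target`.
#' @param epsilon exponent magnitude threshold (default 0.05).
#' @return an [edge_set()].
#' @export
extract_edges <- function(eq, epsilon = 0.05) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  rows <- list()
  for (role in c("production", "consumption")) {
    f <- eq[[role]]$factors
    if (nrow(f) == 0) next
    keep <- abs(f[, "exponent"]) >= epsilon
    if (!any(keep)) next
    rows[[role]] <- edge_set(regulator = f[keep, "gene"],
                             target = rep(eq$target, sum(keep)),
                             role = rep(role, sum(keep)),
                             exponent = f[keep, "exponent"],
                             delay = f[keep, "delay"])
  }
  if (length(rows) == 0) return(edge_set())
  merge_edges(do.call(rbind, rows))
}

#' Infer a time-delayed gene regulatory network
#'
#' Decomposition strategy: each target gene's TDSS model is optimized
#' independently with [evolve()] against the observed trajectories of all
#' genes, then the fitted equations are converted to edges and unioned. Each
#' gene's run uses seed `cfg$seed + gene index`, so per-gene results are
#' independent of gene order. A failed gene is recorded and skipped.
#'
#' @param datasets list of [time_series_dataset()] replicates sharing genes
#'   and time grid.
#' @param cfg an [evolution_config()].
#' @param workers forked workers for fitness evaluation.
#' @param epsilon edge-extraction exponent threshold, see [extract_edges()].
#' @return object of class `tdss_inference`: list with `edges` (merged
#'   [edge_set()]), `equations` (per-gene fitted models), `fitness`
#'   (per-gene best fitness), `traces`, `failed` (indices of failed genes).
#' @export
infer_network <- function(datasets, cfg, workers = 1L, epsilon = 0.05) {
  if (length(datasets) < 1) stop("need at least one dataset")
  N <- nrow(datasets[[1]]$values)
  for (ds in datasets)
    if (nrow(ds$values) != N || length(ds$times) != length(datasets[[1]]$times))
      stop("datasets disagree on gene count or time grid")
  equations <- vector("list", N)
  fits <- rep(NA_real_, N)
  traces <- vector("list", N)
  failed <- integer()
  edges <- list()
  for (i in seq_len(N)) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed + i, 0L)
    res <- tryCatch(evolve(i, datasets, cfg_i, workers = workers),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("gene ", i, " failed: ", conditionMessage(res))
      failed <- c(failed, i)
      next
    }
    equations[[i]] <- res$equation
    fits[i] <- res$fitness
    traces[[i]] <- res$trace
    edges[[length(edges) + 1]] <- extract_edges(res$equation, epsilon)
  }
  all_edges <- if (length(edges)) merge_edges(do.call(rbind, edges)) else edge_set()
  structure(list(edges = all_edges, equations = equations, fitness = fits,
                 traces = traces, failed = failed, n_genes = N),
            class = "tdss_inference")
}

#' @export
print.tdss_inference <- function(x, ...) {
  cat(sprintf("TDSS network inference: %d genes, %d edges (%d delayed), %d failed genes\n",
              x$n_genes, nrow(x$edges), sum(x$edges$class == "delayed"),
              length(x$failed)))
  invisible(x)
}
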