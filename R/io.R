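# File formats: expression matrices (TSV, one file per replicate), edge
# lists (TSV / SIF) and the JSON run configuration.
#
# Expression matrix format: first row = tab-separated time values; each
# following row = gene id, TAB, tab-separated expression values.

#' Write a time-series dataset as a tab-separated expression matrix
#'
#' @param ds a [time_series_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(fmt_num(ds$times), collapse = "\t"), con)
  for (i in seq_len(nrow(ds$values)))
    writeLines(paste(c(rownames(ds$values)[i], fmt_num(ds$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

parse_expression_file <- function(path, replicate_id) {
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("parse error in ", path, ": need a time row and at least one gene row")
  times <- suppressWarnings(as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]]))
  if (any(is.na(times)))
    stop("parse error in ", path, " line 1: nonnumeric time value")
  n_t <- length(times)
  vals <- matrix(NA_real_, length(lines) - 1, n_t)
  ids <- character(length(lines) - 1)
  for (k in 2:length(lines)) {
    cells <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(cells) != n_t + 1)
      stop("parse error in ", path, " line ", k, ": expected ", n_t + 1,
           " columns, found ", length(cells))
    ids[k - 1] <- cells[1]
    v <- suppressWarnings(as.numeric(cells[-1]))
    if (any(is.na(v)))
      stop("parse error in ", path, " line ", k, ": nonnumeric expression value")
    if (any(v <= 0))
      stop("parse error in ", path, " line ", k,
           ": expression levels must be positive")
    vals[k - 1, ] <- v
  }
  rownames(vals) <- ids
  time_series_dataset(times, vals, replicate_id)
}

#' Read replicate expression matrices
#'
#' Parses each file, validates the uniform time grid and positivity, and
#' enforces the first file's gene order on the rest.
#'
#' @param paths character vector of file paths, one per replicate.
#' @return list of [time_series_dataset()].
#' @export
read_expression_matrices <- function(paths) {
  if (length(paths) == 0) stop("no input files")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  ref <- parse_expression_file(paths[1], 1L)
  out <- vector("list", length(paths))
  out[[1]] <- ref
  for (k in seq_along(paths)[-1]) {
    ds <- parse_expression_file(paths[k], k)
    if (!setequal(rownames(ds$values), rownames(ref$values)))
      stop("parse error in ", paths[k], ": gene set differs from ", paths[1])
    if (length(ds$times) != length(ref$times) ||
        max(abs(ds$times - ref$times)) > 1e-8)
      stop("parse error in ", paths[k], ": time grid differs from ", paths[1])
    ds$values <- ds$values[rownames(ref$values), , drop = FALSE]
    out[[k]] <- ds
  }
  out
}

#' Write an edge set as TSV or SIF
#'
#' TSV columns: `regulator`, `target`, `role`, `exponent`, `delay`, `class`;
#' rows ordered by target then regulator. SIF lines use interaction word
#' `regulates` (`regulates-delayed` for positive delays).
#'
#' @param edges an [edge_set()].
#' @param path output file.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  ord <- order(edges$target, edges$regulator)
  edges <- edges[ord, , drop = FALSE]
  if (format == "tsv") {
    df <- as.data.frame(edges)
    df$exponent <- fmt_num(df$exponent)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- sprintf("g%d\t%s\tg%d", edges$regulator,
                     ifelse(edges$delay > 0, "regulates-delayed", "regulates"),
                     edges$target)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' @param path input file.
#' @return an [edge_set()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(edge_set())
  edge_set(df$regulator, df$target, df$role, df$exponent, df$delay)
}

#' Run configuration with benchmark defaults
#'
#' Bundles the [evolution_config()] defaults (population 2000, 200
#' iterations, p_c 0.7, p_m 0.3, rates [0,3], kinetic orders [0,1], delays
#' [0,3], 200 partitions) with pipeline options.
#'
#' @param ... overrides for any field of [evolution_config()].
#' @param workers forked workers for fitness evaluation.
#' @param epsilon edge-extraction exponent threshold.
#' @param include_self,strict_delay metric flags, see [confusion()].
#' @return list of class `run_config`.
#' @export
run_config <- function(..., workers = 1L, epsilon = 0.05,
                       include_self = FALSE, strict_delay = FALSE) {
  cfg <- evolution_config(...)
  cfg$workers <- as.integer(workers)
  cfg$epsilon <- epsilon
  cfg$include_self <- include_self
  cfg$strict_delay <- strict_delay
  class(cfg) <- c("run_config", "evolution_config")
  cfg
}

#' Serialize / parse a run configuration (JSON)
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path`; `read_run_config` a
#'   [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  flat <- list(population_size = cfg$population_size,
               max_iterations = cfg$max_iterations,
               p_c = cfg$p_c, p_m = cfg$p_m,
               rate_interval = cfg$intervals$rate,
               kinetic_interval = cfg$intervals$kinetic,
               delay_interval = c(0, cfg$intervals$tau_max),
               partitions = cfg$partitions, head_length = cfg$head_length,
               arities = cfg$arities, use_constant = cfg$use_constant,
               sigma_frac = cfg$sigma_frac, gamma0 = cfg$gamma0,
               seed = cfg$seed, substeps = cfg$integrator$substeps,
               eps_pos = cfg$integrator$eps_pos, workers = cfg$workers,
               epsilon = cfg$epsilon, include_self = cfg$include_self,
               strict_delay = cfg$strict_delay)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(population_size = x$population_size,
             max_iterations = x$max_iterations,
             p_c = x$p_c, p_m = x$p_m,
             rate_interval = x$rate_interval,
             kinetic_interval = x$kinetic_interval,
             delay_interval = x$delay_interval,
             partitions = x$partitions, head_length = x$head_length,
             arities = x$arities, use_constant = x$use_constant,
             sigma_frac = x$sigma_frac, gamma0 = x$gamma0,
             seed = x$seed, substeps = x$substeps, eps_pos = x$eps_pos,
             workers = x$workers, epsilon = x$epsilon,
             include_self = x$include_self, strict_delay = x$strict_delay)
}
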