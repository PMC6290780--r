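# RGEP genes: fixed-length head/tail symbol strings plus per-position
# parameter slots (kinetic order, binary-coded delay) and one rate constant.

#' Tail length of an RGEP gene
#'
#' With head length `h` and maximum function arity `n`, a tail of
#' `(n - 1) * h + 1` terminals guarantees every head fills into a complete
#' expression tree.
#'
#' @param n maximum arity in the function set (>= 2).
#' @param h head length (>= 1).
#' @return integer tail length.
#' @export
tail_length <- function(n, h) {
  if (length(n) != 1 || length(h) != 1 || is.na(n) || is.na(h) ||
      n < 2 || h < 1)
    stop("invalid configuration: need n >= 2 and h >= 1")
  as.integer((n - 1) * h + 1)
}

# number of bits per delay slot; requires tau_max + 1 to be a power of two so
# every bit pattern decodes to a legal delay
delay_bit_width <- function(tau_max) {
  if (tau_max < 0) stop("invalid configuration: tau_max must be >= 0")
  if (tau_max == 0) return(1L)
  w <- as.integer(ceiling(log2(tau_max + 1)))
  if (bitwShiftL(1L, w) != tau_max + 1L)
    stop("invalid configuration: tau_max + 1 must be a power of two ",
         "so the binary delay coding cannot overflow the interval")
  w
}

#' Parameter intervals for chromosome coding regions
#'
#' @param rate interval for rate constants (alpha, beta).
#' @param kinetic interval for kinetic orders (exponents).
#' @param delay integer interval `[0, tau_max]` for delays, counted in
#'   sampling intervals; `tau_max + 1` must be a power of two.
#' @return list of class `param_intervals`.
#' @export
param_intervals <- function(rate = c(0, 3), kinetic = c(0, 1),
                            delay = c(0, 3)) {
  stopifnot(length(rate) == 2, length(kinetic) == 2, length(delay) == 2)
  if (rate[1] > rate[2] || kinetic[1] > kinetic[2] || delay[1] > delay[2])
    stop("invalid configuration: empty parameter interval")
  if (delay[1] != 0) stop("invalid configuration: delay interval must start at 0")
  structure(list(rate = as.numeric(rate), kinetic = as.numeric(kinetic),
                 tau_max = as.integer(delay[2])),
            class = "param_intervals")
}

#' Create a random RGEP gene
#'
#' Head symbols are sampled uniformly from the union of function and terminal
#' sets, tail symbols uniformly from the terminal set. Each of the `h + t`
#' positions carries a kinetic-order slot (uniform in the kinetic interval)
#' and a fixed-width binary delay slot (uniform over legal delays); the gene
#' carries one rate constant (uniform in the rate interval).
#'
#' @param alphabet a [symbol_alphabet()].
#' @param h head length.
#' @param intervals a [param_intervals()].
#' @return object of class `rgep_gene`.
#' @export
random_gene <- function(alphabet, h, intervals) {
  if (length(alphabet$functions) == 0 || length(alphabet$terminals) == 0)
    stop("invalid configuration: empty function or terminal set")
  t_len <- tail_length(alphabet$max_arity, h)
  L <- h + t_len
  width <- delay_bit_width(intervals$tau_max)
  head <- sample(c(alphabet$functions, alphabet$terminals), h, replace = TRUE)
  tail <- sample(alphabet$terminals, t_len, replace = TRUE)
  structure(list(
    head = head, tail = tail,
    rate = stats::runif(1, intervals$rate[1], intervals$rate[2]),
    korders = stats::runif(L, intervals$kinetic[1], intervals$kinetic[2]),
    delay_bits = as.integer(stats::runif(L * width) < 0.5),
    bit_width = width),
    class = "rgep_gene")
}

# decode the per-position delay integers from the bit string (MSB first)
gene_delays <- function(gene) {
  w <- gene$bit_width
  bits <- matrix(gene$delay_bits, nrow = w)
  as.integer(colSums(bits * 2 ^ ((w - 1):0)))
}

gene_symbols <- function(gene) c(gene$head, gene$tail)

#' Validate an RGEP gene against its alphabet and intervals
#'
#' Checks tail length, head/tail symbol legality, and that the rate constant,
#' kinetic orders and decoded delays lie in their intervals.
#'
#' @param gene an `rgep_gene`.
#' @inheritParams random_gene
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_gene <- function(gene, alphabet, h, intervals) {
  t_len <- tail_length(alphabet$max_arity, h)
  if (length(gene$head) != h) stop("head length mismatch")
  if (length(gene$tail) != t_len) stop("tail length violates (n-1)h+1")
  if (!all(gene$head %in% c(alphabet$functions, alphabet$terminals)))
    stop("illegal head symbol")
  if (!all(gene$tail %in% alphabet$terminals))
    stop("illegal tail symbol (functions forbidden in tail)")
  if (gene$rate < intervals$rate[1] || gene$rate > intervals$rate[2])
    stop("rate constant outside interval")
  if (any(gene$korders < intervals$kinetic[1] - 1e-12) ||
      any(gene$korders > intervals$kinetic[2] + 1e-12))
    stop("kinetic order outside interval")
  if (length(gene$korders) != h + t_len ||
      length(gene$delay_bits) != (h + t_len) * gene$bit_width)
    stop("parameter slot count mismatch")
  if (!all(gene$delay_bits %in% c(0L, 1L))) stop("non-binary delay bit")
  d <- gene_delays(gene)
  if (any(d < 0 | d > intervals$tau_max)) stop("delay outside [0, tau_max]")
  invisible(TRUE)
}
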