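# Chromosomes: two RGEP genes joined by subtraction. gene1 decodes to the
# production term (rate alpha), gene2 to the consumption term (rate beta).

#' Create a random chromosome
#'
#' @inheritParams random_gene
#' @return object of class `chromosome` with elements `gene1`, `gene2`,
#'   `fitness` (NA until evaluated) and `partition_id` (NA until mapped).
#' @export
random_chromosome <- function(alphabet, h, intervals) {
  structure(list(gene1 = random_gene(alphabet, h, intervals),
                 gene2 = random_gene(alphabet, h, intervals),
                 fitness = NA_real_, partition_id = NA_integer_),
            class = "chromosome")
}

#' @rdname validate_gene
#' @param chrom a `chromosome`.
#' @export
validate_chromosome <- function(chrom, alphabet, h, intervals) {
  validate_gene(chrom$gene1, alphabet, h, intervals)
  validate_gene(chrom$gene2, alphabet, h, intervals)
  invisible(TRUE)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

serialize_gene <- function(gene) {
  paste0(paste(gene$head, collapse = " "), "|",
         paste(gene$tail, collapse = " "), ";r=", fmt_num(gene$rate),
         ";k=", paste(fmt_num(gene$korders), collapse = ","),
         ";d=", paste(gene$delay_bits, collapse = ""))
}

deserialize_gene <- function(txt) {
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  ht <- strsplit(parts[1], "|", fixed = TRUE)[[1]]
  head <- strsplit(trimws(ht[1]), " ", fixed = TRUE)[[1]]
  tail <- strsplit(trimws(ht[2]), " ", fixed = TRUE)[[1]]
  rate <- as.numeric(sub("^r=", "", parts[2]))
  korders <- as.numeric(strsplit(sub("^k=", "", parts[3]), ",")[[1]])
  bits <- as.integer(strsplit(sub("^d=", "", parts[4]), "")[[1]])
  structure(list(head = head, tail = tail, rate = rate, korders = korders,
                 delay_bits = bits,
                 bit_width = length(bits) %/% length(korders)),
            class = "rgep_gene")
}

#' One-line chromosome serialization
#'
#' Grammar: `gene1 - gene2` where each gene is
#' `HEAD|TAIL;r=RATE;k=K1,K2,...;d=BITS` (symbols space-separated, kinetic
#' orders comma-separated, delay bits concatenated MSB-first per slot).
#' Numbers are printed with 17 significant digits so the round trip is exact.
#'
#' @param chrom a `chromosome`.
#' @return single string.
#' @export
serialize_chromosome <- function(chrom) {
  paste(serialize_gene(chrom$gene1), "-", serialize_gene(chrom$gene2))
}

#' @rdname serialize_chromosome
#' @param txt string produced by [serialize_chromosome()].
#' @export
deserialize_chromosome <- function(txt) {
  halves <- strsplit(txt, " - ", fixed = TRUE)[[1]]
  structure(list(gene1 = deserialize_gene(halves[1]),
                 gene2 = deserialize_gene(halves[2]),
                 fitness = NA_real_, partition_id = NA_integer_),
            class = "chromosome")
}

#' @export
print.chromosome <- function(x, ...) {
  cat("RGEP chromosome (fitness:",
      if (is.na(x$fitness)) "unset" else format(x$fitness), ")\n")
  cat(" ", serialize_chromosome(x), "\n")
  invisible(x)
}
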