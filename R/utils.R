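# Shared low-level helpers: seeded RNG scopes, rounding, k-mer codes.

DNA_BASES <- c("A", "C", "G", "T")

# Run `code` under set.seed(seed), restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero
#'
#' Rounding used for all reported percentages and Z-scores, matching the
#' printed precision of the composition and hotspot tables (base `round()`
#' rounds half to even, which does not).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded with halves moved away from zero.
#' @examples
#' round_half_away(2.5)    # 3
#' round_half_away(-2.5)   # -3
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count, rounded
#'
#' `100 * num / den` rounded half away from zero; 0 when the denominator is 0.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1, the table convention).
#' @return numeric percentage.
#' @examples
#' pct_round(22, 113)  # 19.5
#' @export
pct_round <- function(num, den, digits = 1) {
  ifelse(den == 0, 0, round_half_away(100 * num / den, digits))
}

# Map a DNA string to integer codes 0..3 (A,C,G,T); NA for anything else.
dna_to_int <- function(seq) {
  x <- utf8ToInt(seq)
  out <- rep(NA_integer_, length(x))
  out[x == 65L] <- 0L  # A
  out[x == 67L] <- 1L  # C
  out[x == 71L] <- 2L  # G
  out[x == 84L] <- 3L  # T
  out
}

# All k-mer codes of a DNA string as base-4 numbers (exact in doubles for
# k <= 26). Positions with ambiguous bases yield NA.
kmer_codes <- function(seq, k) {
  v <- dna_to_int(seq)
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code + v[(1L + j):(m + j)] * 4^j
  code
}

# Random DNA of length n with P(G or C) = gc.
random_dna <- function(n, gc = 0.5) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Total length of the union of integer intervals (1-based closed).
union_width <- function(starts, ends) {
  if (!length(starts)) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Normalize a genome argument (toy_genome list or DNAStringSet) to DNAStringSet.
as_genome_seqs <- function(genome) {
  if (inherits(genome, "toy_genome")) return(genome$genome)
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome)) return(Biostrings::DNAStringSet(genome))
  stop("`genome` must be a toy_genome, DNAStringSet, or named character vector")
}
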