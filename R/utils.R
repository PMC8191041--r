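#' @useDynLib forktrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rgeom median quantile sd approx setNames dnorm
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Alphabet codes: signal-level k-mers are spelled over A,C,G,T plus 'B' for
# the BrdU analogue substituted at a thymidine position.
.BASES <- c("A", "C", "G", "T", "B")
.base_code_table <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 0L
  v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L
  v[utf8ToInt("T")] <- 3L
  v[utf8ToInt("B")] <- 4L
  v
})

seq_codes <- function(sequence, allow_analogue = TRUE) {
  ints <- utf8ToInt(sequence)
  if (any(ints > 126L | ints < 1L)) stopf("sequence contains non-ASCII characters")
  codes <- .base_code_table[ints]
  if (anyNA(codes)) {
    bad <- unique(intToUtf8(ints[is.na(codes)], multiple = TRUE))
    stopf("sequence contains invalid characters: %s", paste(bad, collapse = ", "))
  }
  if (!allow_analogue && any(codes == 4L)) stopf("sequence contains analogue base 'B' where only ACGT is allowed")
  codes
}

# Map every k-mer window of a code vector to its index in the 5^k table
# (1-based; A=0,C=1,G=2,T=3,B=4 read as a base-5 number, leftmost high).
kmer_indices <- function(codes, k = 6L) {
  n <- length(codes) - k + 1L
  if (n < 1L) stopf("sequence shorter than k-mer length %d", k)
  out <- numeric(n)
  mult <- 5^((k - 1L):0L)
  for (j in seq_len(k)) out <- out + codes[j:(n + j - 1L)] * mult[j]
  as.integer(out + 1)
}

kmer_index_one <- function(kmer, k = 6L) {
  codes <- seq_codes(kmer)
  if (length(codes) != k) stopf("k-mer '%s' does not have length %d", kmer, k)
  kmer_indices(codes, k)
}

decode_kmer <- function(index, k = 6L) {
  x <- index - 1L
  chars <- character(k)
  for (j in k:1) {
    chars[j] <- .BASES[x %% 5L + 1L]
    x <- x %/% 5L
  }
  paste(chars, collapse = "")
}

all_canonical_kmers <- function(k = 6L) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[, k:1])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

format_prob <- function(p) sprintf("%.6f", p)
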