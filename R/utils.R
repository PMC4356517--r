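#' @importFrom stats pchisq rbinom runif setNames
#' @importFrom utils head read.delim tail write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  seed = NULL runs expr against the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Seeded random DNA of length n (used for synthetic filler and consensus).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Longest common prefix length of two strings, in bytes.
common_prefix_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Longest common suffix length of two strings, in bytes.
common_suffix_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Fixed decimal formatting for text outputs (6 significant digits, LF files).
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

stop2 <- function(...) stop(..., call. = FALSE)
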