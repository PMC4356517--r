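# Shared fixtures and independent brute-force oracles.

# Standard reporter fixture at a given divergence (substitution-only pair).
fixture <- function(divergence = 5, mode = "evenly_spaced",
                    cons_seed = 101L, div_seed = 102L, cas_seed = 103L) {
  cons <- synthetic_alu_consensus(300L, seed = cons_seed)
  div <- if (divergence == 0) cons
         else generate_diverged_alu(cons, divergence, mode, seed = div_seed)
  pair <- align_pair(div, cons)
  cassette <- build_cassette(pair, seed = cas_seed)
  list(cons = cons, div = div, pair = pair, cassette = cassette,
       imap = build_interval_map(pair))
}

# Brute-force Hamming distance by positional comparison.
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# Brute-force microhomology: try every shifted placement of the deletion and
# count those producing the identical product string.
oracle_microhomology <- function(s, left, right, max_shift = 30L) {
  n <- nchar(s)
  prod0 <- paste0(substr(s, 1, left), substr(s, right + 1, n))
  equiv <- integer(0)
  for (off in -max_shift:max_shift) {
    l <- left + off; r <- right + off
    if (l < 0 || r > n) next
    p <- paste0(substr(s, 1, l), substr(s, r + 1, n))
    if (p == prod0) equiv <- c(equiv, off)
  }
  # offsets of equivalent placements form a contiguous run including 0
  list(len = max(equiv) - min(equiv), left = left + min(equiv),
       right = right + min(equiv))
}

# Enumeration oracle for the crossover locator: a genotype vector maps to
# interval j iff it is consistent with the monotone pattern
# (1 x j, 2 x (k - j)) at every observed site; among consistent j the largest
# is reported (first parent-2 site).  Inconsistent with all j -> COMPLEX.
oracle_locate <- function(gv) {
  k <- length(gv)
  if (k == 0L) return(0L)
  if (mean(is.na(gv)) > 0.10) return("UNRESOLVED")
  if (all(is.na(gv))) return("UNRESOLVED")
  consistent <- vapply(0:k, function(j) {
    pat <- c(rep(1L, j), rep(2L, k - j))
    all(is.na(gv) | gv == pat)
  }, logical(1))
  if (!any(consistent)) return("COMPLEX")
  max(which(consistent)) - 1L
}

# All genotype vectors of length n over {1, 2, NA}.
all_genotype_vectors <- function(n) {
  if (n == 0L) return(list(integer(0)))
  grid <- do.call(expand.grid, rep(list(c(1L, 2L, NA_integer_)), n))
  lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
}
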