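#' Measure junction microhomology by shift equivalence
#'
#' The microhomology at a deletion junction is the maximal `m` such that
#' shifting both breakpoints together by any offset in `[0, m]` yields the
#' identical product sequence: shared flanking sequence makes the exact
#' breakpoint placement ambiguous over `m + 1` equivalent placements.
#' Breakpoints are reported at the leftmost equivalent placement (the same
#' normalization VCF uses for indels).
#'
#' @param cassette_sequence Full cassette DNA string.
#' @param left_breakpoint,right_breakpoint Any valid placement of the
#'   deletion, 0-based half-open.
#' @return List with `microhomology_len`, `left`, `right` (leftmost-aligned).
#' @export
measure_microhomology <- function(cassette_sequence, left_breakpoint,
                                  right_breakpoint) {
  s <- charToRaw(cassette_sequence)
  n <- length(s)
  l <- as.integer(left_breakpoint); r <- as.integer(right_breakpoint)
  stopifnot(l >= 0, r > l, r <= n)
  # forward shifts: product invariant while s[l] == s[r] (0-based)
  b <- 0L
  while (r + b < n && s[l + b + 1L] == s[r + b + 1L]) b <- b + 1L
  # backward shifts: while s[l-1] == s[r-1]
  a <- 0L
  while (l - a > 0L && s[l - a] == s[r - a]) a <- a + 1L
  list(microhomology_len = a + b, left = l - a, right = r - a)
}

# Anchor a product to the cassette: longest exact prefix/suffix match; the
# unmatched middle defines the deletion (and any untemplated insertion).
# Returns NULL when the product carries no net deletion.
normalize_deletion <- function(cassette_sequence, product) {
  clen <- nchar(cassette_sequence)
  plen <- nchar(product)
  p <- common_prefix_len(product, cassette_sequence)
  sfx <- common_suffix_len(product, cassette_sequence)
  if (plen >= clen && p >= plen) return(NULL)     # unmodified cassette
  if (p + sfx >= plen) {
    # pure deletion; overlap of the anchors is the junction microhomology
    d <- clen - plen
    if (d <= 0) return(NULL)
    left <- plen - sfx
    list(left = left, right = left + d, deletion_size = d,
         microhomology = p - left, insertion = "",
         prefix = p, suffix = sfx)
  } else {
    ins <- substr(product, p + 1L, plen - sfx)
    left <- p
    right <- clen - sfx
    if (right <= left) return(NULL)
    list(left = left, right = right, deletion_size = right - left,
         microhomology = 0L, insertion = ins, prefix = p, suffix = sfx)
  }
}

#' Locate the crossover interval from a genotype vector
#'
#' Maps a per-diagnostic-site parent-of-origin vector (1, 2, or `NA` for
#' missing) to the homology interval holding the junction.  Conventions: an
#' all-parent-2 vector maps to interval 0 and all-parent-1 to the last
#' interval (index = site count); exactly one parent-1 to parent-2 switch
#' whose first parent-2 site has index `i` maps to interval `i` (the span
#' between sites `i - 1` and `i`).  Any parent-2 to parent-1 transition, or
#' more than one switch, is `"COMPLEX"`; more than 10\% missing genotypes is
#' `"UNRESOLVED"`.
#'
#' @param genotype_vector Integer vector over `{1, 2, NA}`, one entry per
#'   diagnostic site (an empty vector maps to interval 0, the single
#'   interval of an undiverged pair).
#' @return Integer interval index, or `"COMPLEX"`, or `"UNRESOLVED"`.
#' @export
locate_crossover <- function(genotype_vector) {
  k <- length(genotype_vector)
  if (k == 0L) return(0L)
  miss <- is.na(genotype_vector)
  if (mean(miss) > 0.10) return("UNRESOLVED")
  obs <- genotype_vector[!miss]
  if (length(obs) == 0L) return("UNRESOLVED")
  if (any(diff(obs) < 0)) return("COMPLEX")          # a 2 -> 1 transition
  if (sum(diff(obs) != 0) >= 2) return("COMPLEX")    # unreachable once monotone
  first2 <- which(!miss & genotype_vector == 2L)
  if (length(first2) == 0L) return(k)                # all parent 1
  as.integer(first2[1] - 1L)
}

# Genotype the Alu span of a product at every diagnostic site.
# Walks the alignment columns starting at the cassette's alu1.start; returns
# the genotype vector, the non-diagnostic identity fraction, the 0-based end
# of the consumed span in the product, or NULL if the walk runs off the end.
genotype_alu_span <- function(product, cassette, pair) {
  a1 <- feature_span(cassette, "alu1")
  start <- unname(a1["start"])
  pch <- strsplit(product, "")[[1]]
  g1 <- strsplit(pair$aligned1, "")[[1]]
  g2 <- strsplit(pair$aligned2, "")[[1]]
  sites <- pair$sites
  L <- pair$length
  k <- nrow(sites)

  # fast path: substitution-only alignment -> fixed-length positional compare
  if (k == 0L || all(sites$type == "substitution")) {
    if (start + L > length(pch)) return(NULL)
    span <- pch[(start + 1L):(start + L)]
    diag_cols <- sites$col_start + 1L               # 1-based columns
    nd <- setdiff(seq_len(L), diag_cols)
    gv <- integer(0)
    if (k > 0L) {
      gv <- ifelse(span[diag_cols] == g1[diag_cols], 1L,
                   ifelse(span[diag_cols] == g2[diag_cols], 2L, NA_integer_))
    }
    nd_match <- if (length(nd)) mean(span[nd] == g1[nd]) else 1
    return(list(genotype = as.integer(gv), nondiag_identity = nd_match,
                span_end = start + L))
  }

  # general path: column walk handling indel diagnostic sites
  site_of_col <- rep(NA_integer_, L)
  for (i in seq_len(k))
    site_of_col[(sites$col_start[i] + 1L):sites$col_end[i]] <- i
  q <- start                                         # 0-based product cursor
  gv <- rep(NA_integer_, k)
  nd_total <- 0L; nd_match <- 0L
  col <- 1L
  np <- length(pch)
  while (col <= L) {
    si <- site_of_col[col]
    if (is.na(si)) {                                 # shared column
      if (q >= np) return(NULL)
      nd_total <- nd_total + 1L
      if (pch[q + 1L] == g1[col]) nd_match <- nd_match + 1L
      q <- q + 1L; col <- col + 1L
    } else if (sites$type[si] == "substitution") {
      if (q >= np) return(NULL)
      b <- pch[q + 1L]
      gv[si] <- if (b == g1[col]) 1L else if (b == g2[col]) 2L else NA_integer_
      q <- q + 1L; col <- col + 1L
    } else {                                         # indel run: pick parent
      cols <- (sites$col_start[si] + 1L):sites$col_end[si]
      c1 <- g1[cols]; c1 <- c1[c1 != "-"]
      c2 <- g2[cols]; c2 <- c2[c2 != "-"]
      ctx_cols <- which(is.na(site_of_col) & seq_len(L) > max(cols))[1:8]
      ctx <- g1[ctx_cols[!is.na(ctx_cols)]]
      fits <- function(cand) {
        piece <- c(cand, ctx)
        if (q + length(piece) > np) piece <- piece[seq_len(np - q)]
        length(piece) == 0L ||
          all(pch[(q + 1L):(q + length(piece))] == piece)
      }
      f1 <- fits(c1); f2 <- fits(c2)
      if (f1 && (!f2 || length(c1) >= length(c2))) {
        gv[si] <- 1L; q <- q + length(c1)
      } else if (f2) {
        gv[si] <- 2L; q <- q + length(c2)
      } else {
        q <- q + length(c2)                          # unreadable site
      }
      col <- sites$col_end[si] + 1L
    }
  }
  list(genotype = gv,
       nondiag_identity = if (nd_total) nd_match / nd_total else 1,
       span_end = q)
}

empty_call <- function(event_class = "UNRESOLVED") {
  structure(list(event_class = event_class,
                 crossover_interval = NA_integer_, patch_alleles = NULL,
                 left_breakpoint = NA_integer_, right_breakpoint = NA_integer_,
                 breakpoint_ambiguity = NA_integer_,
                 microhomology_len = NA_integer_,
                 deletion_size = NA_integer_, insertion = "",
                 genotype_vector = NULL, segment_index = NA_integer_,
                 topology = NA_character_),
            class = "junction_call")
}

#' Call a repair event from a product sequence
#'
#' The reverse of the simulator: anchors a sequenced repair product to the
#' cassette by its longest exact prefix and suffix match (the unmatched
#' middle is the deletion), then decides whether the product carries an
#' intact — full-length, chimeric — Alu element at the junction.  If so the
#' product is a recombination event: its diagnostic sites are genotyped for
#' parent of origin and the crossover is localized to a homology interval
#' (single crossover) or flagged as a complex chimera (>= 2 parent switches).
#' Otherwise it is an NHEJ deletion, annotated with junction microhomology
#' and leftmost-aligned breakpoints.
#'
#' The intact-Alu test requires the product to contain, at the alu1 locus, a
#' span matching a parental allele at every readable diagnostic site,
#' matching both parents at >= `min_identity` of non-diagnostic positions,
#' and running directly into the cassette sequence downstream of alu2.
#'
#' @param product Product DNA string.
#' @param cassette A `reporter_cassette`.
#' @param pair The `alu_pair` (defaults to the one stored in the cassette).
#' @param min_anchor Minimum exact prefix/suffix anchor in bp (default 30);
#'   products anchoring below this are `UNRESOLVED`.
#' @param min_identity Non-diagnostic identity required by the intact-Alu
#'   test (default 0.99; tolerance for simulated sequencing noise).
#' @return A `junction_call` with fields `event_class`
#'   (`RECOMB_SINGLE_CROSSOVER`, `RECOMB_COMPLEX_CHIMERA`, `NHEJ_DELETION`
#'   or `UNRESOLVED`), `crossover_interval`, `patch_alleles`,
#'   `left_breakpoint`, `right_breakpoint`, `breakpoint_ambiguity`,
#'   `microhomology_len`, `deletion_size`, `genotype_vector`,
#'   `segment_index`, `topology`.
#' @export
call_junction <- function(product, cassette, pair = cassette$pair,
                          min_anchor = 30L, min_identity = 0.99) {
  nd <- normalize_deletion(cassette$sequence, product)
  if (is.null(nd)) return(empty_call())
  if (nd$prefix < min_anchor || nd$suffix < min_anchor) return(empty_call())

  call <- empty_call("NHEJ_DELETION")
  call$left_breakpoint <- nd$left
  call$right_breakpoint <- nd$right
  call$deletion_size <- nd$deletion_size
  call$microhomology_len <- nd$microhomology
  call$breakpoint_ambiguity <- nd$microhomology
  call$insertion <- nd$insertion

  a1 <- feature_span(cassette, "alu1")
  a2 <- feature_span(cassette, "alu2")
  if (nd$prefix >= a1["start"]) {
    gt <- genotype_alu_span(product, cassette, pair)
    if (!is.null(gt) && gt$nondiag_identity >= min_identity) {
      # intact Alu also requires the product to continue into the cassette
      # sequence downstream of alu2
      down_prod <- substr(product, gt$span_end + 1L, nchar(product))
      down_cass <- substr(cassette$sequence, a2["end"] + 1L, cassette$length)
      if (down_prod == down_cass) {
        loc <- locate_crossover(gt$genotype)
        call$genotype_vector <- gt$genotype
        if (nchar(nd$insertion) > 0L) {
          # the unexplained middle is chimeric Alu sequence, not an untemplated
          # insertion: the deletion spans from the first changed position
          call$insertion <- ""
          call$deletion_size <- cassette$length - nchar(product)
          call$right_breakpoint <- call$left_breakpoint + call$deletion_size
          call$microhomology_len <- 0L
          call$breakpoint_ambiguity <- 0L
        }
        if (identical(loc, "UNRESOLVED")) {
          call$event_class <- "UNRESOLVED"
        } else if (identical(loc, "COMPLEX")) {
          call$event_class <- "RECOMB_COMPLEX_CHIMERA"
          call$patch_alleles <- gt$genotype
        } else {
          call$event_class <- "RECOMB_SINGLE_CROSSOVER"
          call$crossover_interval <- loc
          call$patch_alleles <- gt$genotype
          imap <- build_interval_map(pair)
          call$segment_index <- imap$segment_of_interval[loc + 1L]
        }
        return(call)
      }
    }
  }
  call$topology <- classify_nhej_topology(call, cassette)
  call
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> %s", x$event_class))
  if (!is.na(x$crossover_interval))
    cat(sprintf(", crossover interval %d (segment %d)",
                x$crossover_interval, x$segment_index))
  if (!is.na(x$deletion_size))
    cat(sprintf(", deletion %d bp [%d, %d), microhomology %d bp",
                x$deletion_size, x$left_breakpoint, x$right_breakpoint,
                x$microhomology_len))
  cat("\n")
  invisible(x)
}

#' Classify the topology of an NHEJ deletion relative to the Alu spans
#'
#' @param call A `junction_call` of class `NHEJ_DELETION`.
#' @param cassette The `reporter_cassette`.
#' @param mode `"leftmost"` uses the leftmost-aligned breakpoints strictly;
#'   `"any_placement"` counts a breakpoint as in-Alu when any shift within
#'   the microhomology ambiguity window places it inside the span.
#' @return `"both_Alus"`, `"one_Alu"` or `"no_Alu"`.
#' @export
classify_nhej_topology <- function(call, cassette,
                                   mode = c("leftmost", "any_placement")) {
  mode <- match.arg(mode)
  if (!is.na(call$event_class) && call$event_class != "NHEJ_DELETION")
    stop2("topology is defined for NHEJ_DELETION calls only")
  a1 <- feature_span(cassette, "alu1")
  a2 <- feature_span(cassette, "alu2")
  offs <- if (mode == "leftmost") 0L else 0L:call$breakpoint_ambiguity
  in_span <- function(x, sp) any(x + offs >= sp["start"] & x + offs < sp["end"])
  l_in <- in_span(call$left_breakpoint, a1)
  r_in <- in_span(call$right_breakpoint, a2)
  if (l_in && r_in) "both_Alus" else if (l_in || r_in) "one_Alu" else "no_Alu"
}

#' Call every product in a colony set or FASTA
#'
#' @param products A `colony_set`, a named character vector of sequences, or
#'   a FASTA path.
#' @param cassette A `reporter_cassette`.
#' @param pair The `alu_pair` (defaults to the cassette's).
#' @param ... Passed to [call_junction()].
#' @return A data.frame of calls, one row per product, order preserved, with
#'   columns `colony_id, event_class, crossover_interval, patch_alleles,
#'   left_bp, right_bp, deletion_size, microhomology_len,
#'   breakpoint_ambiguity, genotype_vector, segment_index, topology`.
#' @export
call_colony_set <- function(products, cassette, pair = cassette$pair, ...) {
  if (inherits(products, "colony_set")) products <- products$sequences
  if (is.character(products) && length(products) == 1L &&
      file.exists(products)) {
    ss <- Biostrings::readDNAStringSet(products)
    products <- setNames(as.character(ss), names(ss))
  }
  calls <- lapply(products, call_junction, cassette = cassette, pair = pair, ...)
  data.frame(
    colony_id = if (is.null(names(products)))
      sprintf("colony_%04d", seq_along(products)) else names(products),
    event_class = vapply(calls, `[[`, character(1), "event_class"),
    crossover_interval = vapply(calls, function(x)
      as.integer(x$crossover_interval), integer(1)),
    patch_alleles = vapply(calls, function(x)
      if (is.null(x$patch_alleles)) NA_character_
      else paste(x$patch_alleles, collapse = ","), character(1)),
    left_bp = vapply(calls, function(x) as.integer(x$left_breakpoint),
                     integer(1)),
    right_bp = vapply(calls, function(x) as.integer(x$right_breakpoint),
                      integer(1)),
    deletion_size = vapply(calls, function(x) as.integer(x$deletion_size),
                           integer(1)),
    microhomology_len = vapply(calls, function(x)
      as.integer(x$microhomology_len), integer(1)),
    breakpoint_ambiguity = vapply(calls, function(x)
      as.integer(x$breakpoint_ambiguity), integer(1)),
    genotype_vector = vapply(calls, function(x)
      if (is.null(x$genotype_vector)) NA_character_
      else paste(ifelse(is.na(x$genotype_vector), ".", x$genotype_vector),
                 collapse = ","), character(1)),
    segment_index = vapply(calls, function(x) as.integer(x$segment_index),
                           integer(1)),
    topology = vapply(calls, function(x)
      if (is.na(x$topology)) NA_character_ else x$topology, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
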