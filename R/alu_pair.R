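#' Construct an Alu sequence object
#'
#' Light container for a single repeat sequence: an id and an ungapped DNA
#' string.  Alu elements are ~300 bp primate SINEs; the default synthetic
#' consensus used throughout the package is 300 bp so that an element divides
#' into three equal 100-bp reporting segments.
#'
#' @param bases DNA string over A/C/G/T (no gaps, no ambiguity codes).
#' @param id Text label.
#' @return An object of class `alu_seq` with fields `id`, `bases`, `length`.
#' @export
alu_sequence <- function(bases, id = "alu") {
  bases <- toupper(as.character(bases))
  if (nchar(bases) < 50)
    stop2("an Alu sequence must be at least 50 bp (got ", nchar(bases), ")")
  if (grepl("[^ACGT]", bases))
    stop2("sequence contains characters outside {A,C,G,T}")
  structure(list(id = id, bases = bases, length = nchar(bases)),
            class = "alu_seq")
}

#' @export
print.alu_seq <- function(x, ...) {
  cat(sprintf("<alu_seq> %s: %d bp\n", x$id, x$length))
  cat(" ", substr(x$bases, 1, 60), if (x$length > 60) "...", "\n")
  invisible(x)
}

#' Synthetic Alu consensus
#'
#' Generates a seeded random DNA sequence standing in for a repeat consensus.
#' Alu elements are GC-rich; the default composition reflects that.  Use
#' [read_alu_fasta()] to supply a real consensus instead.
#'
#' @param length Sequence length in bp (default 300).
#' @param seed Integer seed.
#' @param gc GC fraction (default 0.58).
#' @return An `alu_seq`.
#' @export
synthetic_alu_consensus <- function(length = 300L, seed = 1L, gc = 0.58) {
  alu_sequence(with_seed(seed, random_dna(length, gc = gc)),
               id = sprintf("synthetic_consensus_%dbp", length))
}

#' Generate a diverged copy of a consensus element
#'
#' Produces the second parent of a homeologous repeat pair at a requested
#' divergence.  Three substitution patterns are supported:
#' \describe{
#'   \item{evenly_spaced}{`k = round(length * pct/100)` substitutions spread
#'     evenly, at 0-based positions `round(i * length / k) - 1`; at whole
#'     spacings this is `s-1, 2s-1, ...` (5\% on 300 bp gives one
#'     substitution every 20 bp).}
#'   \item{random}{`k` substitutions at seeded, uniformly sampled distinct
#'     positions.}
#'   \item{scrambled}{a seeded permutation of the consensus (an unrelated
#'     sequence of identical composition; `divergence_pct` is ignored).}
#' }
#' Substituted bases are drawn seeded-uniformly from the three non-reference
#' bases.  Draw order: positions, then bases.
#'
#' @param consensus An `alu_seq`.
#' @param divergence_pct Requested divergence, percent of positions.
#' @param mode One of `"evenly_spaced"`, `"random"`, `"scrambled"`.
#' @param seed Integer seed.
#' @return An `alu_seq` carrying the substitutions.
#' @export
generate_diverged_alu <- function(consensus, divergence_pct,
                                  mode = c("evenly_spaced", "random", "scrambled"),
                                  seed = 1L) {
  stopifnot(inherits(consensus, "alu_seq"))
  mode <- match.arg(mode)
  L <- consensus$length
  ch <- strsplit(consensus$bases, "")[[1]]

  if (mode == "scrambled") {
    perm <- with_seed(seed, sample.int(L))
    return(alu_sequence(paste(ch[perm], collapse = ""),
                        id = paste0(consensus$id, "_scrambled")))
  }

  if (divergence_pct < 0 || divergence_pct > 100)
    stop2("divergence_pct must be in [0, 100]")
  k <- round(L * divergence_pct / 100)
  if (divergence_pct == 0 || k == 0) {
    if (divergence_pct > 0)
      stop2("divergence ", divergence_pct,
            "% is unrepresentable at length ", L, " (0 substitutions)")
    return(alu_sequence(consensus$bases, id = paste0(consensus$id, "_0pct")))
  }

  if (mode == "evenly_spaced") {
    # k sites spread evenly: 0-based positions round(i * L / k) - 1, which
    # reduces to s - 1, 2s - 1, ... at whole spacings (5% on 300 bp gives one
    # substitution every 20 bp)
    pos <- round(seq_len(k) * L / k)  # 1-based
    if (anyDuplicated(pos) || pos[k] > L)
      stop2("divergence ", divergence_pct,
            "% cannot be evenly spaced on length ", L)
    bases <- with_seed(seed, vapply(pos, function(p) {
      sample(setdiff(DNA_BASES, ch[p]), 1L)
    }, character(1)))
  } else {                            # random
    drawn <- with_seed(seed, {
      pos <- sort(sample.int(L, k))
      bases <- vapply(pos, function(p) sample(setdiff(DNA_BASES, ch[p]), 1L),
                      character(1))
      list(pos = pos, bases = bases)
    })
    pos <- drawn$pos; bases <- drawn$bases
  }
  ch[pos] <- bases
  alu_sequence(paste(ch, collapse = ""),
               id = sprintf("%s_%gpct_%s", consensus$id, divergence_pct, mode))
}

#' Globally align two repeat sequences into an Alu pair
#'
#' End-to-end (Needleman-Wunsch) pairwise alignment via
#' [Biostrings::pairwiseAlignment()].  Alignment columns are classified as
#' match, mismatch or indel; each maximal indel run is collapsed to a single
#' diagnostic site, since a run of inserted/deleted bases bounds junction
#' mappability exactly like one diagnostic substitution.
#'
#' Equal-length pairs are compared positionally (no gaps) by default:
#' reporter constructs are built by substitution, and for unrelated
#' equal-length sequences (a scrambled element) a global aligner would
#' otherwise find spurious gapped alignments that understate the divergence.
#' Set `force_alignment = TRUE` to run the gapped aligner regardless.
#'
#' Divergence convention: `divergence_pct = 100 * (mismatch columns +
#' collapsed indel runs) / total alignment columns`.
#'
#' @param alu1,alu2 `alu_seq` objects (parent 1 and parent 2).
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters.
#'   Defaults (+1/-1, open 4, extend 1) suit repeats of 70-100\% identity.
#' @param force_alignment Run the gapped aligner even for equal-length pairs.
#' @return An object of class `alu_pair` with fields `alu1`, `alu2`,
#'   `aligned1`, `aligned2` (gapped strings), `columns` (per-column
#'   data.frame), `sites` (diagnostic-site table), `diagnostic_sites`
#'   (0-based chimera-coordinate start of each site), `divergence_pct`, and
#'   `length` (alignment columns).
#' @export
align_pair <- function(alu1, alu2, match = 1, mismatch = -1,
                       gap_opening = 4, gap_extension = 1,
                       force_alignment = FALSE) {
  stopifnot(inherits(alu1, "alu_seq"), inherits(alu2, "alu_seq"))
  if (alu1$length == 0 || alu2$length == 0) stop2("empty sequence")

  if (alu1$length == alu2$length && !force_alignment)
    return(new_alu_pair(alu1, alu2, alu1$bases, alu2$bases))

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(alu1$bases, alu2$bases,
                                       substitutionMatrix = mat,
                                       gapOpening = gap_opening,
                                       gapExtension = gap_extension,
                                       type = "global")
  new_alu_pair(alu1, alu2,
               as.character(Biostrings::alignedPattern(aln)),
               as.character(Biostrings::alignedSubject(aln)))
}

# Build the alu_pair structure from two equal-length gapped strings.
new_alu_pair <- function(alu1, alu2, aligned1, aligned2) {
  g1 <- strsplit(aligned1, "")[[1]]
  g2 <- strsplit(aligned2, "")[[1]]
  L <- length(g1)
  stopifnot(length(g2) == L)

  cls <- ifelse(g1 == "-" | g2 == "-", "indel",
                ifelse(g1 == g2, "match", "mismatch"))
  pos1 <- cumsum(g1 != "-") - 1L; pos1[g1 == "-"] <- NA_integer_
  pos2 <- cumsum(g2 != "-") - 1L; pos2[g2 == "-"] <- NA_integer_
  columns <- data.frame(col = seq_len(L) - 1L, base1 = g1, base2 = g2,
                        pos1 = pos1, pos2 = pos2, class = cls,
                        stringsAsFactors = FALSE)

  # diagnostic sites: each mismatch column, each maximal indel run (collapsed)
  diag <- cls != "match"
  runs <- rle(ifelse(diag, cls, "match"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != "match"
  site_start <- integer(0); site_end <- integer(0); site_type <- character(0)
  for (i in which(keep)) {
    if (runs$values[i] == "mismatch") {
      # mismatch runs are NOT collapsed: one site per column
      site_start <- c(site_start, seq(starts[i], ends[i]))
      site_end <- c(site_end, seq(starts[i], ends[i]) + 1L)
      site_type <- c(site_type, rep("substitution", runs$lengths[i]))
    } else {
      site_start <- c(site_start, starts[i])
      site_end <- c(site_end, ends[i] + 1L)
      site_type <- c(site_type, "indel")
    }
  }
  o <- order(site_start)
  sites <- data.frame(site = seq_along(site_start) - 1L,
                      col_start = site_start[o] - 1L,   # 0-based half-open
                      col_end = site_end[o] - 1L,
                      type = site_type[o],
                      stringsAsFactors = FALSE)

  n_diag_cols <- sum(cls == "mismatch") + sum(sites$type == "indel")
  structure(list(
    alu1 = alu1, alu2 = alu2,
    aligned1 = aligned1, aligned2 = aligned2,
    columns = columns, sites = sites,
    diagnostic_sites = sites$col_start,
    divergence_pct = 100 * n_diag_cols / L,
    length = L
  ), class = "alu_pair")
}

#' @export
print.alu_pair <- function(x, ...) {
  cat(sprintf("<alu_pair> %s vs %s: %d aligned columns, %d diagnostic sites, %.2f%% divergence\n",
              x$alu1$id, x$alu2$id, x$length, nrow(x$sites), x$divergence_pct))
  invisible(x)
}

#' Percent divergence of an aligned pair
#'
#' 100 x (mismatch columns + collapsed indel runs) / alignment columns.
#'
#' @param pair An `alu_pair`.
#' @return Numeric percent.
#' @export
divergence_percent <- function(pair) {
  stopifnot(inherits(pair, "alu_pair"))
  pair$divergence_pct
}

#' Map homology intervals and reporting segments
#'
#' A recombination junction between two diverged repeats can only be localized
#' to the span between consecutive diagnostic sites (a homology interval).
#' With k diagnostic sites the element carries k + 1 intervals, including the
#' spans before the first and after the last site; interval boundaries sit at
#' the diagnostic sites, so the intervals tile the element.  Reporting
#' segments are fixed-length spans (default 100 bp; the final segment is
#' truncated when the element length is not a multiple), and each interval is
#' assigned to the segment containing its midpoint.
#'
#' @param pair An `alu_pair`.
#' @param segment_length Reporting segment length in bp (default 100).
#' @return An object of class `interval_map` with fields `starts`, `ends`
#'   (0-based half-open interval spans in chimera coordinates),
#'   `segment_edges`, `segment_of_interval` (0-based segment index per
#'   interval), `n_segments`, `length`.
#' @export
build_interval_map <- function(pair, segment_length = 100L) {
  stopifnot(inherits(pair, "alu_pair"))
  L <- pair$length
  sites <- pair$diagnostic_sites
  starts <- c(0L, sites)
  ends <- c(sites, L)
  n_seg <- max(1L, as.integer(ceiling(L / segment_length)))
  edges <- c(seq(0L, by = segment_length, length.out = n_seg), L)
  mid <- (starts + ends) / 2
  seg <- pmin(floor(mid / segment_length), n_seg - 1L)
  structure(list(starts = starts, ends = ends,
                 segment_edges = edges,
                 segment_length = segment_length,
                 segment_of_interval = as.integer(seg),
                 n_segments = n_seg, length = L),
            class = "interval_map")
}

#' @export
print.interval_map <- function(x, ...) {
  cat(sprintf("<interval_map> %d intervals over %d bp, %d segments of %d bp\n",
              length(x$starts), x$length, x$n_segments, x$segment_length))
  invisible(x)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return A list of `alu_seq` (one per record).
#' @export
read_alu_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    alu_sequence(as.character(ss[[i]]), id = names(ss)[i])
  })
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs An `alu_seq` or list of them, or a named character vector.
#' @param path Output path.
#' @export
write_alu_fasta <- function(seqs, path) {
  if (inherits(seqs, "alu_seq")) seqs <- list(seqs)
  if (is.list(seqs)) {
    v <- vapply(seqs, function(s) s$bases, character(1))
    names(v) <- vapply(seqs, function(s) s$id, character(1))
    seqs <- v
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
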