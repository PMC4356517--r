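ISCEI_SITE <- "TAGGGATAACAGGGTAAT"   # 18-bp I-SceI recognition sequence
POLYA_LEN <- 50L
LINKER_LEN <- 10L                    # unannotated filler, I-SceI site -> alu2

#' Assemble the recombination reporter cassette
#'
#' Builds the single-copy selection construct: a promoter driving a
#' neomycin-resistance marker terminated by a polyA signal, flanked by the two
#' diverged Alu elements in direct orientation, with an I-SceI cut site just
#' upstream of the second Alu and a promoterless puromycin-resistance gene
#' downstream.  Deletion of the intervening marker (by recombination between
#' the Alus, or by an NHEJ deletion of comparable size) places the puro gene
#' under the promoter, so only deletion products inside a bounded size window
#' are selectable.
#'
#' Feature layout (0-based half-open, single strand, direct repeats):
#' promoter, alu1, neoR, polyA, sceI_site, alu2, puroR.  The spacer from
#' alu1 end to alu2 start equals `spacer_length` (default ~1100 bp) and holds
#' neoR, then the polyA signal (50 bp), then the 18-bp I-SceI site.  Filler
#' and marker sequence is seeded-random synthetic DNA; the Alu spans carry the
#' pair's parent sequences verbatim.
#'
#' @param pair An `alu_pair`; parents fill the alu1/alu2 spans.
#' @param spacer_length bp between alu1 end and alu2 start (>= 69 so the
#'   polyA and I-SceI site fit after a non-empty neoR).
#' @param promoter_length,reporter_length Promoter and puroR lengths in bp.
#' @param window Detectable-deletion window `c(min_bp, max_bp)`; deletions
#'   outside it are not selectable (default 897-1881 bp).
#' @param seed Seed for the synthetic filler sequence.
#' @return An object of class `reporter_cassette`: `features` (data.frame
#'   `name`, `start`, `end`), `sequence`, `length`,
#'   `detectable_deletion_window`.
#' @export
build_cassette <- function(pair, spacer_length = 1100L,
                           promoter_length = 1200L, reporter_length = 600L,
                           window = c(897L, 1881L), seed = 1L) {
  stopifnot(inherits(pair, "alu_pair"))
  if (spacer_length < nchar(ISCEI_SITE))
    stop2("spacer_length must be at least ", nchar(ISCEI_SITE),
          " bp to hold the I-SceI recognition site")
  neo_len <- spacer_length - POLYA_LEN - nchar(ISCEI_SITE) - LINKER_LEN
  if (neo_len < 1L)
    stop2("spacer_length ", spacer_length,
          " cannot hold neoR + polyA + I-SceI site without overlap")
  if (promoter_length < 1L || reporter_length < 1L)
    stop2("promoter and reporter lengths must be positive")
  if (window[1] > window[2] || window[1] < 0)
    stop2("invalid detectable-deletion window")

  len1 <- pair$alu1$length
  len2 <- pair$alu2$length
  # a short unannotated linker keeps the I-SceI site strictly inside the
  # spacer (not abutting alu2)
  widths <- c(promoter_length, len1, neo_len, POLYA_LEN, nchar(ISCEI_SITE),
              LINKER_LEN, len2, reporter_length)
  edges <- cumsum(c(0L, widths))
  features <- data.frame(
    name = c("promoter", "alu1", "neoR", "polyA", "sceI_site", "alu2", "puroR"),
    start = as.integer(edges[c(1, 2, 3, 4, 5, 7, 8)]),
    end = as.integer(edges[c(2, 3, 4, 5, 6, 8, 9)]),
    stringsAsFactors = FALSE)

  filler <- with_seed(seed, list(
    promoter = random_dna(promoter_length, gc = 0.55),
    neoR = random_dna(neo_len, gc = 0.55),
    polyA = paste0(random_dna(POLYA_LEN - 6L, gc = 0.3), "AATAAA"),
    linker = random_dna(LINKER_LEN, gc = 0.5),
    puroR = random_dna(reporter_length, gc = 0.55)))
  sequence <- paste0(filler$promoter, pair$alu1$bases, filler$neoR,
                     filler$polyA, ISCEI_SITE, filler$linker,
                     pair$alu2$bases, filler$puroR)
  stopifnot(nchar(sequence) == edges[9])

  structure(list(features = features, sequence = sequence,
                 length = as.integer(edges[9]),
                 detectable_deletion_window = as.integer(window),
                 pair = pair),
            class = "reporter_cassette")
}

#' @export
print.reporter_cassette <- function(x, ...) {
  cat(sprintf("<reporter_cassette> %d bp, detectable deletions %d-%d bp\n",
              x$length, x$detectable_deletion_window[1],
              x$detectable_deletion_window[2]))
  print(x$features, row.names = FALSE)
  invisible(x)
}

feature_span <- function(cassette, name) {
  i <- match(name, cassette$features$name)
  c(start = cassette$features$start[i], end = cassette$features$end[i])
}

# substring in 0-based half-open coordinates
seq_slice <- function(s, start, end) substr(s, start + 1L, end)

#' Write / read a cassette as JSON
#'
#' Canonical on-disk representation: features, sequence, window.  Round-trips
#' bit-for-bit.
#'
#' @param cassette A `reporter_cassette`.
#' @param path Output JSON path.
#' @export
write_cassette_json <- function(cassette, path) {
  pair <- cassette$pair
  obj <- list(
    features = cassette$features,
    sequence = cassette$sequence,
    detectable_deletion_window = cassette$detectable_deletion_window,
    pair = list(alu1_id = pair$alu1$id, alu1 = pair$alu1$bases,
                alu2_id = pair$alu2$id, alu2 = pair$alu2$bases,
                aligned1 = pair$aligned1, aligned2 = pair$aligned2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cassette_json
#' @param path JSON path written by [write_cassette_json()].
#' @return A `reporter_cassette`.
#' @export
read_cassette_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pair <- new_alu_pair(alu_sequence(obj$pair$alu1, obj$pair$alu1_id),
                       alu_sequence(obj$pair$alu2, obj$pair$alu2_id),
                       obj$pair$aligned1, obj$pair$aligned2)
  features <- as.data.frame(obj$features, stringsAsFactors = FALSE)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  structure(list(features = features, sequence = obj$sequence,
                 length = nchar(obj$sequence),
                 detectable_deletion_window =
                   as.integer(obj$detectable_deletion_window),
                 pair = pair),
            class = "reporter_cassette")
}

#' Export cassette annotation as GFF3
#'
#' 1-based inclusive coordinates per GFF3 convention, via
#' [rtracklayer::export()].
#'
#' @param cassette A `reporter_cassette`.
#' @param path Output `.gff3` path.
#' @export
write_cassette_gff3 <- function(cassette, path) {
  f <- cassette$features
  gr <- GenomicRanges::GRanges(
    seqnames = "cassette",
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = "+")
  gr$type <- "region"
  gr$ID <- f$name
  gr$Name <- f$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
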