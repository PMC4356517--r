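#' Event-class mixture preset for the colony simulator
#'
#' Describes the population of repair outcomes a batch of selectable colonies
#' is drawn from: the proportion of single-crossover recombination chimeras,
#' complex (patchy) chimeras, and NHEJ deletions, plus the crossover-position
#' and breakpoint distributions.
#'
#' The crossover-position distribution is a two-component mixture: with
#' probability `crossover_bias` an interval from the first reporting segment
#' (the 5' 100 bp of the element), otherwise uniform over all homology
#' intervals.  `crossover_bias = 0` is the null (uniform) model.  NHEJ
#' breakpoints are uniform over the deletable region; with
#' `mh_seeking = TRUE` candidate junctions are resampled with weight
#' `2^microhomology`, emulating the microhomology preference of MMEJ.
#'
#' @param p_single,p_complex,p_nhej Class probabilities (must sum to 1).
#' @param crossover_bias Weight of the 5'-segment component in `[0, 1]`.
#' @param mh_seeking Logical; weight NHEJ junctions by microhomology.
#' @return A `mixture_preset` object.
#' @export
mixture_preset <- function(p_single = 1, p_complex = 0, p_nhej = 0,
                           crossover_bias = 0, mh_seeking = FALSE) {
  p <- c(single = p_single, complex = p_complex, nhej = p_nhej)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop2("class probabilities must be non-negative and sum to 1")
  if (crossover_bias < 0 || crossover_bias > 1)
    stop2("crossover_bias must be in [0, 1]")
  structure(list(p = p, crossover_bias = crossover_bias,
                 mh_seeking = isTRUE(mh_seeking)),
            class = "mixture_preset")
}

#' @export
print.mixture_preset <- function(x, ...) {
  cat(sprintf("<mixture_preset> single %.2f / complex %.2f / NHEJ %.2f; 5' bias %.2f%s\n",
              x$p["single"], x$p["complex"], x$p["nhej"], x$crossover_bias,
              if (x$mh_seeking) "; microhomology-seeking NHEJ" else ""))
  invisible(x)
}

#' Crossover-bias weight achieving a target first-segment probability
#'
#' Solves the two-component mixture of [mixture_preset()] for the weight `w`
#' such that the total probability of a crossover falling in the first
#' reporting segment equals `target` (e.g. 0.6 for a 60\% 5' junction bias).
#'
#' @param imap An `interval_map`.
#' @param target Desired probability of segment 1.
#' @return Weight in `[0, 1]`.
#' @export
bias_weight_for_segment1 <- function(imap, target) {
  f1 <- mean(imap$segment_of_interval == 0L)
  if (target <= f1) return(0)
  min(1, (target - f1) / (1 - f1))
}

# One crossover-interval draw under the preset's position distribution.
draw_crossover_interval <- function(imap, crossover_bias) {
  n <- length(imap$starts)
  seg1 <- which(imap$segment_of_interval == 0L)
  if (crossover_bias > 0 && length(seg1) > 0 && runif(1) < crossover_bias)
    seg1[sample.int(length(seg1), 1L)] - 1L
  else
    sample.int(n, 1L) - 1L
}

# Chimeric element from a per-diagnostic-site parent-of-origin vector.
# Non-diagnostic columns are shared; at each site the chosen parent's column
# content (gaps dropped) is used.
chimera_from_alleles <- function(pair, alleles) {
  sites <- pair$sites
  stopifnot(length(alleles) == nrow(sites), all(alleles %in% c(1L, 2L)))
  g1 <- strsplit(pair$aligned1, "")[[1]]
  g2 <- strsplit(pair$aligned2, "")[[1]]
  take1 <- rep(TRUE, pair$length)             # col -> take parent1's content
  for (i in seq_len(nrow(sites))) {
    if (alleles[i] == 2L) {
      cols <- (sites$col_start[i] + 1L):sites$col_end[i]
      take1[cols] <- FALSE
    }
  }
  out <- ifelse(take1, g1, g2)
  paste(out[out != "-"], collapse = "")
}

new_repair_event <- function(event_class, product, cassette,
                             crossover_interval = NA_integer_,
                             patch_alleles = NULL,
                             left_bp, right_bp, microhomology_len,
                             insertion = "") {
  left_bp <- as.integer(left_bp); right_bp <- as.integer(right_bp)
  ev <- structure(list(
    event_class = event_class,
    crossover_interval = crossover_interval,
    patch_alleles = patch_alleles,
    left_breakpoint = left_bp, right_breakpoint = right_bp,
    microhomology_len = as.integer(microhomology_len),
    deletion_size = right_bp - left_bp,
    insertion = insertion,
    product_sequence = product,
    detectable = NA), class = "repair_event")
  ev$detectable <- selection_filter(ev, cassette)
  ev
}

#' @export
print.repair_event <- function(x, ...) {
  cat(sprintf("<repair_event> %s: deletion %d bp [%d, %d), microhomology %d bp, %sdetectable\n",
              x$event_class, x$deletion_size, x$left_breakpoint,
              x$right_breakpoint, x$microhomology_len,
              if (x$detectable) "" else "not "))
  invisible(x)
}

#' Simulate a single-crossover recombination product
#'
#' Single-strand annealing (or in-register MMEJ) between the two Alus deletes
#' everything between the crossover points, leaving one chimeric element:
#' parent-1 alleles at every diagnostic site 5' of the crossover interval,
#' parent-2 alleles at and 3' of it.  The junction itself is unmappable
#' within the chosen homology interval.
#'
#' @param cassette A `reporter_cassette`.
#' @param pair The `alu_pair` in the cassette.
#' @param interval_index 0-based homology-interval index (see
#'   [build_interval_map()]); interval `i` lies between diagnostic sites
#'   `i - 1` and `i`.
#' @return A `repair_event` of class `RECOMB_SINGLE_CROSSOVER`.
#' @export
simulate_recombination_product <- function(cassette, pair, interval_index) {
  imap <- build_interval_map(pair)
  n_int <- length(imap$starts)
  if (interval_index < 0 || interval_index >= n_int)
    stop2("interval_index must be in [0, ", n_int - 1, "]")
  k <- nrow(pair$sites)
  alleles <- c(rep(1L, interval_index), rep(2L, k - interval_index))
  product <- assemble_recomb_product(cassette, pair, alleles)
  nd <- recomb_breakpoints(cassette, product)
  new_repair_event("RECOMB_SINGLE_CROSSOVER", product, cassette,
                   crossover_interval = as.integer(interval_index),
                   patch_alleles = alleles,
                   left_bp = nd$left, right_bp = nd$right,
                   microhomology_len = nd$microhomology)
}

# Breakpoint truth for a recombination product.  A single crossover anchors
# as a pure deletion (leftmost-aligned with its homology-interval ambiguity);
# a patchy chimera leaves an unexplained middle, in which case the deletion
# is taken to span from the first changed position with no ambiguity.
recomb_breakpoints <- function(cassette, product) {
  nd <- normalize_deletion(cassette$sequence, product)
  if (nchar(nd$insertion) > 0L) {
    d <- cassette$length - nchar(product)
    nd <- list(left = nd$left, right = nd$left + d, deletion_size = d,
               microhomology = 0L, insertion = "")
  }
  nd
}

# promoter..alu1.start + chimera + alu2.end..cassette end
assemble_recomb_product <- function(cassette, pair, alleles) {
  a1 <- feature_span(cassette, "alu1")
  a2 <- feature_span(cassette, "alu2")
  paste0(seq_slice(cassette$sequence, 0L, a1["start"]),
         chimera_from_alleles(pair, alleles),
         seq_slice(cassette$sequence, a2["end"], cassette$length))
}

#' Simulate a complex (patchy) chimera
#'
#' Complex chimeras carry interleaved patches of both parental alleles
#' (at least two parent switches along the element), the signature of
#' heteroduplex mismatch processing during homeologous recombination.
#'
#' @param cassette A `reporter_cassette`.
#' @param pair The `alu_pair`.
#' @param patch_alleles Integer vector over `{1, 2}`, one entry per
#'   diagnostic site; must contain >= 2 parent switches (fewer is a
#'   single-crossover event).
#' @return A `repair_event` of class `RECOMB_COMPLEX_CHIMERA`.
#' @export
simulate_complex_chimera <- function(cassette, pair, patch_alleles) {
  patch_alleles <- as.integer(patch_alleles)
  k <- nrow(pair$sites)
  if (length(patch_alleles) != k)
    stop2("patch_alleles must have one entry per diagnostic site (", k, ")")
  n_switch <- sum(diff(patch_alleles) != 0)
  if (n_switch < 2)
    stop2("patch vector has ", n_switch,
          " parent switch(es); that is a single-crossover event")
  product <- assemble_recomb_product(cassette, pair, patch_alleles)
  nd <- recomb_breakpoints(cassette, product)
  new_repair_event("RECOMB_COMPLEX_CHIMERA", product, cassette,
                   patch_alleles = patch_alleles,
                   left_bp = nd$left, right_bp = nd$right,
                   microhomology_len = nd$microhomology)
}

#' Simulate an NHEJ deletion product
#'
#' Joins the cassette across `[left_breakpoint, right_breakpoint)` with an
#' optional untemplated insertion.  Junction microhomology is not imposed; it
#' emerges from the flanking sequence and is measured by shift-equivalence
#' ([measure_microhomology()]).  Stored breakpoints are leftmost-aligned.
#'
#' Repair events are classified by junction content: an in-register joint
#' (one Alu-length deletion whose junction falls within the element) produces
#' a sequence indistinguishable from a single-crossover recombination
#' product, and the returned event is labelled `RECOMB_SINGLE_CROSSOVER`
#' accordingly.
#'
#' @param cassette A `reporter_cassette`.
#' @param left_breakpoint,right_breakpoint 0-based cassette coordinates,
#'   `promoter.end <= left < right <= puroR.start`.
#' @param insertion Untemplated DNA inserted at the junction (default none).
#' @return A `repair_event` of class `NHEJ_DELETION`.
#' @export
simulate_nhej_deletion <- function(cassette, left_breakpoint, right_breakpoint,
                                   insertion = "") {
  pr <- feature_span(cassette, "promoter")
  pu <- feature_span(cassette, "puroR")
  if (left_breakpoint < pr["end"] || right_breakpoint > pu["start"] ||
      left_breakpoint >= right_breakpoint)
    stop2("breakpoints must satisfy promoter.end <= left < right <= puroR.start")
  s <- cassette$sequence
  product <- paste0(seq_slice(s, 0L, left_breakpoint), insertion,
                    seq_slice(s, right_breakpoint, cassette$length))
  if (nchar(insertion) == 0L) {
    mh <- measure_microhomology(s, left_breakpoint, right_breakpoint)
    left <- mh$left; right <- mh$right; mlen <- mh$microhomology_len
    # an in-register joint (deletion spanning exactly alu1.start..alu2.start
    # with the junction inside the element) yields a product byte-identical
    # to a single-crossover recombination junction; events are classified by
    # junction content, so label it as such
    a1 <- feature_span(cassette, "alu1")
    a2 <- feature_span(cassette, "alu2")
    pair <- cassette$pair
    sub_only <- pair$length == pair$alu1$length &&
      pair$length == pair$alu2$length
    if (sub_only &&
        right_breakpoint - left_breakpoint == a2["start"] - a1["start"] &&
        left <= a1["end"] && left + mlen >= a1["start"]) {
      cross <- max(0L, left - unname(a1["start"]))   # junction offset in element
      alleles <- ifelse(pair$diagnostic_sites < cross, 1L, 2L)
      if (length(alleles) == 0L) alleles <- integer(0)
      return(new_repair_event("RECOMB_SINGLE_CROSSOVER", product, cassette,
                              crossover_interval = sum(alleles == 1L),
                              patch_alleles = alleles,
                              left_bp = left, right_bp = right,
                              microhomology_len = mlen))
    }
  } else {
    left <- left_breakpoint; right <- right_breakpoint; mlen <- 0L
  }
  new_repair_event("NHEJ_DELETION", product, cassette,
                   left_bp = left, right_bp = right,
                   microhomology_len = mlen, insertion = insertion)
}

#' Selection filter: is a repair product recoverable as a resistant colony?
#'
#' A product is selectable (detectable) iff the deletion (a) removes the
#' entire polyA and I-SceI-site features, (b) leaves the promoter and puroR
#' features intact, and (c) has a size inside the cassette's
#' detectable-deletion window (default 897-1881 bp).  Smaller deletions leave
#' the marker terminator in place (no puroR expression); larger ones destroy
#' the promoter or the puroR gene.
#'
#' @param event A `repair_event`.
#' @param cassette The `reporter_cassette`.
#' @return Logical flag.
#' @export
selection_filter <- function(event, cassette) {
  l <- event$left_breakpoint; r <- event$right_breakpoint
  d <- event$deletion_size
  pa <- feature_span(cassette, "polyA")
  sc <- feature_span(cassette, "sceI_site")
  pr <- feature_span(cassette, "promoter")
  pu <- feature_span(cassette, "puroR")
  removes_polyA_sce <- l <= pa["start"] && r >= sc["end"]
  intact_flanks <- l >= pr["end"] && r <= pu["start"]
  w <- cassette$detectable_deletion_window
  unname(removes_polyA_sce && intact_flanks && d >= w[1] && d <= w[2])
}

#' Simulate a set of selectable colonies
#'
#' Draws repair events from a [mixture_preset()] and keeps exactly `n`
#' selectable ones; non-detectable draws are rejection-sampled away (their
#' count is recorded — the analogue of repair events the reporter cannot
#' recover).  A single seeded RNG stream is used, with a fixed draw order
#' per event: class, then positions (crossover interval, patch alleles or
#' breakpoints), then bases.
#'
#' @param cassette A `reporter_cassette`.
#' @param pair The `alu_pair`.
#' @param n Number of selectable colonies to emit.
#' @param preset A `mixture_preset`.
#' @param seed Integer seed.
#' @return A `colony_set`: `events` (truth table data.frame), `sequences`
#'   (named character vector of product sequences), `rejections`, `preset`.
#' @export
simulate_colony_set <- function(cassette, pair, n, preset = mixture_preset(),
                                seed = 1L) {
  stopifnot(inherits(preset, "mixture_preset"), n >= 1)
  imap <- build_interval_map(pair)
  k <- nrow(pair$sites)
  if (preset$p["complex"] > 0 && k < 3)
    stop2("complex chimeras need >= 3 diagnostic sites")
  pr_end <- unname(feature_span(cassette, "promoter")["end"])
  pu_start <- unname(feature_span(cassette, "puroR")["start"])

  with_seed(seed, {
    events <- vector("list", n)
    rejections <- 0L
    for (i in seq_len(n)) {
      # class is drawn once per colony; non-detectable position draws are
      # rejected within the class, so the emitted class mixture is unbiased
      cls <- sample(c("single", "complex", "nhej"), 1L, prob = preset$p)
      repeat {
        ev <- switch(cls,
          single = simulate_recombination_product(
            cassette, pair,
            draw_crossover_interval(imap, preset$crossover_bias)),
          complex = {
            repeat {
              alleles <- sample(c(1L, 2L), k, replace = TRUE)
              if (sum(diff(alleles) != 0) >= 2) break
            }
            simulate_complex_chimera(cassette, pair, alleles)
          },
          nhej = draw_nhej_event(cassette, pr_end, pu_start,
                                 preset$mh_seeking))
        if (ev$detectable) break
        rejections <- rejections + 1L
      }
      events[[i]] <- ev
    }
    structure(list(events = events_to_table(events),
                   sequences = setNames(
                     vapply(events, `[[`, character(1), "product_sequence"),
                     sprintf("colony_%04d", seq_len(n))),
                   rejections = rejections, preset = preset),
              class = "colony_set")
  })
}

draw_nhej_event <- function(cassette, pr_end, pu_start, mh_seeking) {
  # uniform over breakpoint pairs: two distinct cut positions in
  # [promoter.end, puroR.start], ordered
  draw1 <- function() {
    bp <- pr_end + sample.int(pu_start - pr_end + 1L, 2L) - 1L
    c(min(bp), max(bp))
  }
  if (mh_seeking) {
    cand <- replicate(16L, draw1())
    mh <- vapply(seq_len(ncol(cand)), function(j) {
      measure_microhomology(cassette$sequence, cand[1, j], cand[2, j])$microhomology_len
    }, integer(1))
    j <- sample.int(ncol(cand), 1L, prob = 2^pmin(mh, 10L))
    bp <- cand[, j]
  } else bp <- draw1()
  simulate_nhej_deletion(cassette, bp[1], bp[2])
}

events_to_table <- function(events) {
  data.frame(
    colony_id = sprintf("colony_%04d", seq_along(events)),
    event_class = vapply(events, `[[`, character(1), "event_class"),
    crossover_interval = vapply(events, function(e)
      if (is.na(e$crossover_interval[1])) NA_integer_
      else as.integer(e$crossover_interval), integer(1)),
    patch_alleles = vapply(events, function(e)
      if (is.null(e$patch_alleles)) NA_character_
      else paste(e$patch_alleles, collapse = ","), character(1)),
    left_bp = vapply(events, function(e) as.integer(e$left_breakpoint),
                     integer(1)),
    right_bp = vapply(events, function(e) as.integer(e$right_breakpoint),
                      integer(1)),
    deletion_size = vapply(events, function(e) as.integer(e$deletion_size),
                           integer(1)),
    microhomology_len = vapply(events, function(e)
      as.integer(e$microhomology_len), integer(1)),
    detectable = vapply(events, `[[`, logical(1), "detectable"),
    stringsAsFactors = FALSE)
}

#' @export
print.colony_set <- function(x, ...) {
  cat(sprintf("<colony_set> %d colonies (%d non-detectable draws rejected)\n",
              nrow(x$events), x$rejections))
  print(table(x$events$event_class))
  invisible(x)
}

#' Write a colony set to FASTA + truth TSV
#'
#' @param set A `colony_set`.
#' @param fasta_path Products FASTA (one record per colony).
#' @param tsv_path Truth table TSV.
#' @export
write_colony_set <- function(set, fasta_path, tsv_path) {
  write_alu_fasta(set$sequences, fasta_path)
  write_tsv(set$events, tsv_path)
  invisible(c(fasta_path, tsv_path))
}

# TSV dialect: tab-separated, UTF-8, LF, header mandatory, NA for absent.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", colClasses = NA)
}
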