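#' Expected and observed junction counts per reporting segment
#'
#' Builds the observed-vs-expected table underlying the junction-distribution
#' test.  Junctions are observable only at homology-interval resolution, so
#' the null ("junctions at random throughout the element") can be weighted
#' two ways: `per_interval` spreads the total evenly over homology intervals
#' (each interval assigned to the segment containing its midpoint);
#' `per_bp` spreads it proportionally to segment length.  Both conserve the
#' total: expected counts sum to n.
#'
#' @param interval_map An `interval_map`.
#' @param calls Either a calls data.frame from [call_colony_set()] (rows
#'   with a non-missing `segment_index` — mappable recombination junctions —
#'   are used) or an integer vector of 0-based segment indices.
#' @param weighting `"per_interval"` (default) or `"per_bp"`.
#' @return A `segment_counts` data.frame with columns `segment`, `observed`,
#'   `expected`, `n_total`.
#' @export
expected_counts <- function(interval_map, calls,
                            weighting = c("per_interval", "per_bp")) {
  weighting <- match.arg(weighting)
  seg_idx <- if (is.data.frame(calls)) {
    keep <- grepl("^RECOMB", calls$event_class) & !is.na(calls$segment_index)
    calls$segment_index[keep]
  } else as.integer(calls[!is.na(calls)])
  n <- length(seg_idx)
  if (n == 0L) stop2("no mappable recombination calls")
  m <- interval_map$n_segments
  observed <- tabulate(seg_idx + 1L, nbins = m)
  frac <- if (weighting == "per_interval") {
    tabulate(interval_map$segment_of_interval + 1L, nbins = m) /
      length(interval_map$starts)
  } else {
    diff(interval_map$segment_edges) / interval_map$length
  }
  out <- data.frame(segment = paste0("segment_", seq_len(m)),
                    observed = observed, expected = n * frac,
                    n_total = n, stringsAsFactors = FALSE)
  class(out) <- c("segment_counts", "data.frame")
  out
}

#' Chi-square goodness of fit on segment counts
#'
#' Tests observed junction counts against the expected counts of a random
#' junction distribution: `statistic = sum((obs - exp)^2 / exp)` on
#' `segments - 1` degrees of freedom, upper-tail p-value.  Per-segment
#' significance marks come from a post-hoc one-segment-vs-rest chi-square
#' (1 df) at `alpha`, with no multiple-testing correction.
#'
#' @param counts A `segment_counts` data.frame (or any data.frame with
#'   `observed` and `expected` columns).
#' @param alpha Significance level for the per-segment flags (default 0.05).
#' @return A `gof_result`: `statistic`, `df`, `p_value`,
#'   `per_segment_flags` (logical), `per_segment_p`.
#' @export
chi_square_gof <- function(counts, alpha = 0.05) {
  obs <- counts$observed; ex <- counts$expected
  if (any(ex <= 0)) stop2("all expected counts must be positive")
  stat <- sum((obs - ex)^2 / ex)
  df <- length(obs) - 1L
  n <- sum(obs)
  seg_p <- vapply(seq_along(obs), function(i) {
    o2 <- c(obs[i], n - obs[i]); e2 <- c(ex[i], n - ex[i])
    if (any(e2 <= 0)) return(NA_real_)
    pchisq(sum((o2 - e2)^2 / e2), df = 1, lower.tail = FALSE)
  }, numeric(1))
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE),
                 per_segment_flags = !is.na(seg_p) & seg_p < alpha,
                 per_segment_p = seg_p, alpha = alpha),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Chi-square goodness of fit: X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (any(x$per_segment_flags))
    cat("  segments significant at alpha =", x$alpha, ":",
        which(x$per_segment_flags), "\n")
  invisible(x)
}

#' Pathway proportions from a calls table
#'
#' The fraction of resolved repair junctions that contain an intact
#' (chimeric) Alu — i.e. recombination events, single-crossover plus complex
#' chimeras — versus NHEJ deletions.  `UNRESOLVED` calls are excluded.
#'
#' @param calls Calls data.frame from [call_colony_set()].
#' @return Named numeric: `recombination_pct`, `nhej_pct` (sum to 100).
#' @export
pathway_proportions <- function(calls) {
  cls <- calls$event_class
  resolved <- cls[cls != "UNRESOLVED" & !is.na(cls)]
  if (length(resolved) == 0L) stop2("all calls are UNRESOLVED")
  recomb <- mean(grepl("^RECOMB", resolved)) * 100
  c(recombination_pct = recomb, nhej_pct = 100 - recomb)
}

#' Fold decrease in colony counts relative to a reference
#'
#' `reference_count / test_count`, rounded to the nearest integer, or to one
#' decimal place when the quotient is below 2 (the rounding convention used
#' when reporting reporter-assay colony counts).
#'
#' @param reference_count Reference (undiverged) colony count.
#' @param test_count Test colony count (> 0).
#' @return Rounded fold decrease.  Vectorized over `test_count`.
#' @export
fold_decrease <- function(reference_count, test_count) {
  if (any(test_count <= 0)) stop2("test_count must be positive")
  q <- reference_count / test_count
  ifelse(q < 2, round(q, 1), round(q))
}

#' Split a colony count by pathway proportions
#'
#' @param colony_count Total selectable colonies.
#' @param proportions Numeric length-2 vector of percentages summing to 100
#'   (recombination, NHEJ).
#' @return Named numeric: recombination- and NHEJ-adjusted counts.
#' @export
adjusted_colony_counts <- function(colony_count, proportions) {
  if (abs(sum(proportions) - 100) > 1e-9)
    stop2("proportions must sum to 100")
  setNames(colony_count * proportions / 100,
           c("recombination_adjusted", "nhej_adjusted"))
}

#' Summary report over a calls table and optional colony counts
#'
#' Assembles the quantitative layer in one object: pathway proportions,
#' per-segment observed/expected tables with the goodness-of-fit result, and
#' (when a colony-count table is supplied) fold decreases relative to a
#' reference row plus pathway-adjusted colony counts.
#'
#' @param calls Calls data.frame.
#' @param interval_map An `interval_map`.
#' @param colony_counts Optional data.frame with columns `construct`,
#'   `divergence_pct`, `colonies_mean`, `colonies_se`.
#' @param weighting Passed to [expected_counts()].
#' @param reference_construct Row of `colony_counts` to use as the
#'   fold-decrease reference (default: the row with the smallest
#'   `divergence_pct`).
#' @return A `repair_report` list.
#' @export
repair_report <- function(calls, interval_map, colony_counts = NULL,
                          weighting = "per_interval",
                          reference_construct = NULL) {
  prop <- pathway_proportions(calls)
  seg <- gof <- NULL
  if (any(grepl("^RECOMB", calls$event_class) & !is.na(calls$segment_index))) {
    seg <- expected_counts(interval_map, calls, weighting = weighting)
    gof <- chi_square_gof(seg)
  }
  colonies <- NULL
  if (!is.null(colony_counts)) {
    ref_i <- if (is.null(reference_construct))
      which.min(colony_counts$divergence_pct)
    else match(reference_construct, colony_counts$construct)
    ref <- colony_counts$colonies_mean[ref_i]
    colonies <- colony_counts
    colonies$fold_decrease <- ifelse(
      seq_len(nrow(colonies)) == ref_i, NA_real_,
      fold_decrease(ref, colonies$colonies_mean))
  }
  structure(list(proportions = prop, segments = seg, gof = gof,
                 colonies = colonies, weighting = weighting,
                 n_calls = nrow(calls),
                 n_unresolved = sum(calls$event_class == "UNRESOLVED")),
            class = "repair_report")
}

#' @export
print.repair_report <- function(x, ...) {
  cat(sprintf("<repair_report> %d calls (%d unresolved)\n", x$n_calls,
              x$n_unresolved))
  cat(sprintf("  recombination %.1f%% / NHEJ %.1f%%\n",
              x$proportions["recombination_pct"], x$proportions["nhej_pct"]))
  if (!is.null(x$segments)) {
    print(as.data.frame(x$segments), row.names = FALSE)
    print(x$gof)
  }
  if (!is.null(x$colonies)) print(x$colonies, row.names = FALSE)
  invisible(x)
}
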