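#' Build a run configuration
#'
#' A persisted, fully seeded description of a simulate/call/stats run;
#' re-running the same config reproduces every output byte-for-byte.
#'
#' @param consensus_fasta Optional FASTA path supplying the consensus element
#'   (first record); `NULL` uses a synthetic consensus.
#' @param consensus_length,consensus_seed Geometry and seed of the synthetic
#'   consensus when no FASTA is given.
#' @param divergence_pct,divergence_mode,divergence_seed Parameters of
#'   [generate_diverged_alu()].
#' @param spacer_length,promoter_length,reporter_length,window,cassette_seed
#'   Cassette geometry, see [build_cassette()].
#' @param p_single,p_complex,p_nhej,crossover_bias,mh_seeking Mixture preset,
#'   see [mixture_preset()].
#' @param n_colonies Number of selectable colonies to simulate.
#' @param colony_seed Seed of the colony draw.
#' @param segment_length Reporting segment length (bp).
#' @param weighting Expected-count weighting for the stats stage.
#' @return A `run_config` list.
#' @export
run_config <- function(consensus_fasta = NULL, consensus_length = 300L,
                       consensus_seed = 101L, divergence_pct = 5,
                       divergence_mode = "evenly_spaced",
                       divergence_seed = 102L, spacer_length = 1100L,
                       promoter_length = 1200L, reporter_length = 600L,
                       window = c(897L, 1881L), cassette_seed = 103L,
                       p_single = 1, p_complex = 0, p_nhej = 0,
                       crossover_bias = 0, mh_seeking = FALSE,
                       n_colonies = 100L, colony_seed = 104L,
                       segment_length = 100L,
                       weighting = "per_interval") {
  cfg <- as.list(environment())
  mixture_preset(p_single, p_complex, p_nhej, crossover_bias, mh_seeking)
  if (n_colonies < 1) stop2("n_colonies must be >= 1")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

# Materialize the pair and cassette a config describes.
config_cassette <- function(cfg) {
  consensus <- if (!is.null(cfg$consensus_fasta))
    read_alu_fasta(cfg$consensus_fasta)[[1]]
  else
    synthetic_alu_consensus(cfg$consensus_length, seed = cfg$consensus_seed)
  diverged <- generate_diverged_alu(consensus, cfg$divergence_pct,
                                    mode = cfg$divergence_mode,
                                    seed = cfg$divergence_seed)
  pair <- align_pair(diverged, consensus)   # parent 1 diverged, parent 2 consensus
  build_cassette(pair, spacer_length = cfg$spacer_length,
                 promoter_length = cfg$promoter_length,
                 reporter_length = cfg$reporter_length,
                 window = cfg$window, seed = cfg$cassette_seed)
}

#' Pipeline stage: simulate a colony set to disk
#'
#' Writes `products.fasta`, `truth.tsv` and `cassette.json` into `out_dir`;
#' logs the rejection count and realized divergence to stderr.
#'
#' @param cfg A `run_config` (or path to its JSON).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the three paths.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cassette <- config_cassette(cfg)
  preset <- mixture_preset(cfg$p_single, cfg$p_complex, cfg$p_nhej,
                           cfg$crossover_bias, cfg$mh_seeking)
  set <- simulate_colony_set(cassette, cassette$pair, cfg$n_colonies,
                             preset = preset, seed = cfg$colony_seed)
  paths <- c(fasta = file.path(out_dir, "products.fasta"),
             truth = file.path(out_dir, "truth.tsv"),
             cassette = file.path(out_dir, "cassette.json"))
  write_colony_set(set, paths["fasta"], paths["truth"])
  write_cassette_json(cassette, paths["cassette"])
  message(sprintf("simulated %d colonies (%d non-detectable draws rejected); realized divergence %.2f%%",
                  cfg$n_colonies, set$rejections,
                  cassette$pair$divergence_pct))
  invisible(paths)
}

#' Pipeline stage: call junctions from a products FASTA
#'
#' @param products_fasta Products FASTA path.
#' @param cassette_json Cassette JSON written by [cmd_simulate()] /
#'   [write_cassette_json()].
#' @param out_tsv Output calls TSV path.
#' @return Invisibly, `out_tsv`.
#' @export
cmd_call <- function(products_fasta, cassette_json, out_tsv) {
  cassette <- read_cassette_json(cassette_json)
  ss <- Biostrings::readDNAStringSet(products_fasta)
  if (length(ss) == 0L) {
    calls <- call_colony_set(character(0), cassette)
  } else {
    calls <- call_colony_set(setNames(as.character(ss), names(ss)), cassette)
  }
  write_tsv(calls, out_tsv)
  invisible(out_tsv)
}

#' Pipeline stage: statistics report
#'
#' @param calls_tsv Calls TSV from [cmd_call()].
#' @param cassette_json Cassette JSON (supplies the interval map).
#' @param out_prefix Output prefix; writes `<prefix>_report.json` and
#'   `<prefix>_summary.tsv`.
#' @param colony_tsv Optional colony-count TSV with columns
#'   `construct, divergence_pct, colonies_mean, colonies_se`.
#' @param weighting Expected-count weighting.
#' @param segment_length Reporting segment length (bp).
#' @return Invisibly, the `repair_report`.
#' @export
cmd_stats <- function(calls_tsv, cassette_json, out_prefix,
                      colony_tsv = NULL, weighting = "per_interval",
                      segment_length = 100L) {
  calls <- read_tsv(calls_tsv)
  req <- c("colony_id", "event_class", "segment_index")
  miss <- setdiff(req, names(calls))
  if (length(miss))
    stop2("calls TSV lacks required column(s): ", paste(miss, collapse = ", "))
  cassette <- read_cassette_json(cassette_json)
  imap <- build_interval_map(cassette$pair, segment_length = segment_length)
  colonies <- NULL
  if (!is.null(colony_tsv)) {
    colonies <- read_tsv(colony_tsv)
    creq <- c("construct", "divergence_pct", "colonies_mean")
    cmiss <- setdiff(creq, names(colonies))
    if (length(cmiss))
      stop2("colony TSV lacks required column(s): ",
            paste(cmiss, collapse = ", "))
  }
  rep <- repair_report(calls, imap, colony_counts = colonies,
                       weighting = weighting)
  write_report(rep, out_prefix)
  invisible(rep)
}

# report JSON + summary TSV with fixed formatting (6 significant digits, LF)
write_report <- function(rep, out_prefix) {
  obj <- list(
    n_calls = rep$n_calls, n_unresolved = rep$n_unresolved,
    weighting = rep$weighting,
    proportions = as.list(rep$proportions))
  if (!is.null(rep$segments)) {
    obj$segments <- as.data.frame(rep$segments)
    obj$gof <- list(statistic = rep$gof$statistic, df = rep$gof$df,
                    p_value = rep$gof$p_value,
                    per_segment_flags = rep$gof$per_segment_flags)
  }
  if (!is.null(rep$colonies)) obj$colonies <- rep$colonies
  jsonlite::write_json(obj, paste0(out_prefix, "_report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       na = "null")
  summary_df <- data.frame(
    metric = c("n_calls", "n_unresolved", "recombination_pct", "nhej_pct",
               if (!is.null(rep$gof)) c("gof_statistic", "gof_p_value")),
    value = c(rep$n_calls, rep$n_unresolved,
              rep$proportions["recombination_pct"],
              rep$proportions["nhej_pct"],
              if (!is.null(rep$gof)) c(rep$gof$statistic, rep$gof$p_value)),
    stringsAsFactors = FALSE)
  write_tsv(summary_df, paste0(out_prefix, "_summary.tsv"))
  invisible(out_prefix)
}

#' Render a plain-text report of segment and proportion tables
#'
#' @param rep A `repair_report`.
#' @param width Bar width in characters.
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(rep, width = 40L) {
  lines <- c(sprintf("Repair junction report (%d calls, %d unresolved)",
                     rep$n_calls, rep$n_unresolved),
             sprintf("  Alu/Alu recombination: %5.1f %%",
                     rep$proportions["recombination_pct"]),
             sprintf("  NHEJ:                  %5.1f %%",
                     rep$proportions["nhej_pct"]))
  if (!is.null(rep$segments)) {
    mx <- max(rep$segments$observed, rep$segments$expected)
    lines <- c(lines, "", "Junction distribution (observed | expected):")
    for (i in seq_len(nrow(rep$segments))) {
      o <- rep$segments$observed[i]; e <- rep$segments$expected[i]
      bar <- strrep("#", round(width * o / mx))
      lines <- c(lines, sprintf("  %s %4d | %6.1f %s%s",
                                rep$segments$segment[i], o, e, bar,
                                if (rep$gof$per_segment_flags[i]) " *" else ""))
    }
    lines <- c(lines, sprintf("  chi-square = %.3f, df = %d, p = %.4g",
                              rep$gof$statistic, rep$gof$df, rep$gof$p_value))
  }
  if (!is.null(rep$colonies)) {
    lines <- c(lines, "", "Colony counts:")
    lines <- c(lines, utils::capture.output(
      print(rep$colonies, row.names = FALSE)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
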