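# End-to-end pipeline: configuration, scoring, significance and prediction
# output.

#' Pipeline configuration
#'
#' Defaults follow the parameter study on mononucleosome data: a 2001 bp
#' background window (`w_bg = 1000`), `b = 128`, `s = 17`,
#' `gamma_bg = gamma_sup = 0.9`, `tau = 5`, nominal FDR 0.05.
#'
#' @param b Binding-region length (bp).
#' @param s Support-region length (bp).
#' @param w_bg Background window half-width (bp).
#' @param gamma_bg Background truncation probability in (0, 1].
#' @param gamma_sup Support truncation probability in (0, 1].
#' @param tau Null-fit lower truncation percentile in `[0, 50)`.
#' @param fdr Nominal false discovery rate in (0, 1).
#' @param min_sep Minimum separation of prediction starts (bp); set to `b`
#'   for non-overlapping predictions.
#' @param fdr_method `"BH"` or `"adaptive"`.
#' @param signed_root Use signed square-root region scores (default TRUE).
#' @param min_scores Minimum number of valid scores for the null fit.
#' @param seed Optional seed recorded with the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(b = 128, s = 17, w_bg = 1000, gamma_bg = 0.9,
                       gamma_sup = 0.9, tau = 5, fdr = 0.05, min_sep = 5,
                       fdr_method = c("BH", "adaptive"), signed_root = TRUE,
                       min_scores = 1000, seed = NULL) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(b >= 1, s >= 1, w_bg >= 1,
            gamma_bg > 0, gamma_bg <= 1, gamma_sup > 0, gamma_sup <= 1,
            tau >= 0, tau < 50, fdr > 0, fdr < 1, min_sep >= 1,
            min_scores >= 2)
  structure(list(b = as.integer(b), s = as.integer(s),
                 w_bg = as.integer(w_bg), gamma_bg = gamma_bg,
                 gamma_sup = gamma_sup, tau = tau, fdr = fdr,
                 min_sep = as.integer(min_sep), fdr_method = fdr_method,
                 signed_root = signed_root, min_scores = min_scores,
                 seed = seed),
            class = "run_config")
}

#' Write a resolved configuration next to a run's outputs
#' @param config A [run_config()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "NULL" else paste(v, collapse = ","), character(1))
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' Run scoring and significance on counted read starts
#'
#' Computes the background track, scores every candidate position, fits the
#' empirical null to all valid scores genome-wide, converts scores to p- and
#' q-values and extracts discrete predictions.
#'
#' @param counts A `strand_counts` object.
#' @param config A [run_config()].
#' @return A `nucleocall_result` list with `predictions`, `track`,
#'   `background`, `null_fit`, `p` and `q` (per-chromosome lists) and
#'   `config`. With fewer valid scores than `config$min_scores` the result
#'   carries empty predictions and a warning is raised.
#' @export
nucleosome_pipeline <- function(counts, config = run_config()) {
  stopifnot(inherits(counts, "strand_counts"),
            inherits(config, "run_config"))
  geometry <- binding_geometry(config$b, config$s, config$gamma_sup)
  bg <- background_track(counts, config$w_bg, config$gamma_bg)
  track <- score_genome(counts, bg, geometry,
                        signed_root = config$signed_root)
  all_scores <- unlist(lapply(track$track, function(tr) tr$S[tr$valid]),
                       use.names = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      dyad = integer(), score = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (length(all_scores) < config$min_scores) {
    warning("only ", length(all_scores),
            " valid scores; no significance fit, no predictions")
    return(structure(list(predictions = empty, track = track,
                          background = bg, null_fit = NULL, p = NULL,
                          q = NULL, config = config),
                     class = "nucleocall_result"))
  }
  fit <- fit_null(all_scores, tau = config$tau,
                  min_scores = config$min_scores)
  p <- lapply(track$track, function(tr) score_pvalues(tr$S, fit))
  pooled <- unlist(p, use.names = FALSE)
  q_pooled <- rep(NA_real_, length(pooled))
  ok <- !is.na(pooled)
  q_pooled[ok] <- adjust_fdr(pooled[ok], method = config$fdr_method)
  q <- utils::relist(q_pooled, p)
  names(q) <- names(p)
  preds <- call_nucleosomes(track, q, p = p, fdr = config$fdr,
                            min_sep = config$min_sep)
  structure(list(predictions = preds, track = track, background = bg,
                 null_fit = fit, p = p, q = q, config = config),
            class = "nucleocall_result")
}

#' @export
print.nucleocall_result <- function(x, ...) {
  cat("nucleocall result:", nrow(x$predictions), "predictions at FDR",
      x$config$fdr, "\n")
  if (!is.null(x$null_fit)) print(x$null_fit)
  invisible(x)
}

#' Detect nucleosomes from alignments
#'
#' Convenience wrapper: counts read 5' starts and runs
#' [nucleosome_pipeline()]. An empty alignment set yields an empty
#' prediction set with a warning.
#'
#' @param alignments Data.frame of alignments (see [load_alignments()]) or a
#'   BED/BAM path.
#' @param genome A `GenomeInfo` named vector or a chromosome-sizes TSV path.
#' @param config A [run_config()].
#' @return A `nucleocall_result`.
#' @export
detect_nucleosomes <- function(alignments, genome,
                               config = run_config()) {
  if (is.character(genome)) genome <- read_chrom_sizes(genome)
  if (is.character(alignments))
    alignments <- load_alignments(alignments, genome = genome)
  counts <- read_starts(alignments, genome)
  nucleosome_pipeline(counts, config)
}
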