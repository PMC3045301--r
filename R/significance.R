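# Empirical null, p/q-values and discrete prediction extraction.
#
# Under the null the combined score would be a sum of three approximately
# standard-normal terms, but the terms are dependent (shared background,
# cross-strand truncation), so the null is modelled as N(mu, sigma) with mu
# the sample median of valid scores and sigma fitted by maximum likelihood to
# the deviations of the lower half, truncated to a percentile band to guard
# against outliers from read-rich binding regions.

#' Fit the empirical null distribution of nucleosome scores
#'
#' `mu` is the sample median. Scores between the `tau`-th and 50th percentile
#' are converted to deviations `mu - S` in `[0, B]` (with `B` the distance
#' from the median to the `tau`-th percentile) and the scale of a half-normal
#' distribution truncated to that interval is estimated by bounded 1-D
#' likelihood maximization (tolerance 1e-8).
#'
#' @param scores Numeric vector of valid scores.
#' @param tau Lower truncation percentile in `[0, 50)` (default 5).
#' @param min_scores Minimum number of scores required (default 1000).
#' @return A `null_fit` list with `mu`, `sigma`, `tau`, `n`.
#' @export
fit_null <- function(scores, tau = 5, min_scores = 1000) {
  scores <- scores[!is.na(scores)]
  if (tau < 0 || tau >= 50) stop("tau must be in [0, 50)")
  if (length(scores) < min_scores)
    stop("need at least ", min_scores, " valid scores to fit the null (got ",
         length(scores), ")")
  mu <- median(scores)
  lo <- quantile(scores, tau / 100, names = FALSE)
  d <- mu - scores[scores >= lo & scores <= mu]
  B <- mu - lo
  if (B <= 0 || all(d == 0))
    stop("scores are degenerate; null scale is undefined")
  n <- length(d)
  ssq <- sum(d^2)
  negll <- function(sigma) {
    n * log(sigma) + ssq / (2 * sigma^2) +
      n * log(2 * pnorm(B / sigma) - 1)
  }
  # bracket depends on the fitting band only, so scores above the median
  # cannot influence the result even numerically
  opt <- optimize(negll, interval = c(1e-6 * B, 100 * B), tol = 1e-8)
  structure(list(mu = mu, sigma = opt$minimum, tau = tau, n = n),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("empirical null: N(mu = %.4f, sigma = %.4f), tau = %g, n = %d\n",
              x$mu, x$sigma, x$tau, x$n))
  invisible(x)
}

#' Upper-tail p-values under the fitted null
#'
#' @param scores Numeric scores (NA allowed; propagated).
#' @param fit A [fit_null()] result.
#' @return p-values `P[N(mu, sigma) >= S]`.
#' @export
score_pvalues <- function(scores, fit) {
  stopifnot(inherits(fit, "null_fit"))
  pnorm(scores, mean = fit$mu, sd = fit$sigma, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' `"BH"` is the Benjamini-Hochberg step-up. `"adaptive"` additionally
#' multiplies by the estimated proportion of true nulls
#' `pi0 = min(1, 2 * mean(p > 0.5))`, the deterministic median-based
#' estimator.
#'
#' @param p Vector of p-values in (0, 1] (NA allowed).
#' @param method `"BH"` (default) or `"adaptive"`.
#' @return q-values, capped at 1.
#' @export
adjust_fdr <- function(p, method = c("BH", "adaptive")) {
  method <- match.arg(method)
  q <- p.adjust(p, method = "BH")
  if (method == "adaptive") {
    pi0 <- min(1, 2 * mean(p > 0.5, na.rm = TRUE))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Extract discrete nucleosome predictions
#'
#' Among valid positions with `q <= fdr`, predictions are selected greedily
#' in order of decreasing score (ties to the leftmost start) such that no two
#' selected starts lie within `min_sep` bp of each other. The reported dyad
#' is `start + floor(b / 2)`.
#'
#' @param track A `score_track` with per-position vectors.
#' @param q Named list (per chromosome) of q-values parallel to the track's
#'   candidate positions.
#' @param p Optional parallel list of p-values carried into the output.
#' @param fdr Nominal false discovery rate (default 0.05).
#' @param min_sep Minimum separation between prediction starts in bp
#'   (default 5; use `b` for strictly non-overlapping predictions).
#' @return Data.frame of predictions sorted by chromosome and start:
#'   `chrom`, `start`, `dyad`, `score`, `p`, `q`.
#' @export
call_nucleosomes <- function(track, q, p = NULL, fdr = 0.05, min_sep = 5) {
  stopifnot(inherits(track, "score_track"), fdr > 0, fdr < 1, min_sep >= 1)
  b <- track$geometry$b
  out <- lapply(names(track$track), function(ch) {
    tr <- track$track[[ch]]
    qv <- q[[ch]]
    cand <- which(tr$valid & !is.na(qv) & qv <= fdr)
    if (!length(cand))
      return(data.frame(chrom = character(), start = integer(),
                        dyad = integer(), score = numeric(),
                        p = numeric(), q = numeric(),
                        stringsAsFactors = FALSE))
    ord <- cand[order(-tr$S[cand], tr$pos[cand])]
    maxpos <- max(tr$pos) + 1L
    blocked <- logical(maxpos + 2L * min_sep)
    keep <- integer(0)
    for (i in ord) {
      pp <- tr$pos[i]
      if (!blocked[pp + 1L]) {
        keep <- c(keep, i)
        lo <- max(0L, pp - min_sep + 1L)
        blocked[(lo + 1L):(pp + min_sep)] <- TRUE
      }
    }
    keep <- keep[order(tr$pos[keep])]
    data.frame(chrom = ch, start = tr$pos[keep],
               dyad = tr$pos[keep] + b %/% 2L,
               score = tr$S[keep],
               p = if (is.null(p)) NA_real_ else p[[ch]][keep],
               q = qv[keep], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write predictions as BED6 and/or TSV
#'
#' The BED name column carries the q-value and the BED score the nucleosome
#' score linearly rescaled to 0-1000.
#'
#' @param predictions Data.frame from [call_nucleosomes()].
#' @param bed,tsv Output paths (either may be NULL).
#' @param b Binding-region length used (for the BED interval width).
#' @return Invisibly, the prediction data.frame.
#' @export
write_predictions <- function(predictions, bed = NULL, tsv = NULL, b = 128) {
  if (!is.null(tsv))
    write.table(predictions, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(bed)) {
    if (nrow(predictions)) {
      rng <- range(predictions$score)
      scaled <- if (diff(rng) > 0)
        round(1000 * (predictions$score - rng[1]) / diff(rng))
      else rep(1000L, nrow(predictions))
    } else scaled <- integer(0)
    bed_df <- data.frame(predictions$chrom, predictions$start,
                         predictions$start + b,
                         signif(predictions$q, 4), scaled, ".")
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(predictions)
}
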