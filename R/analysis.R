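# Downstream analyses of predictions: dinucleotide composition around dyads,
# phasing at annotated anchors, adjacent-prediction distances, evaluation
# against simulated truth, total-correlation repeatability, and Pareto-front
# parameter selection.

BASES <- c("A", "C", "G", "T")
DINUCLEOTIDES <- paste0(rep(BASES, each = 4), BASES)

#' Position-specific dinucleotide profile
#'
#' For equal-length sequences centred on predicted dyads, the observed count
#' `o[i, j]` of dinucleotide `j` starting at offset `i` is compared to the
#' expectation `e[j]` (genome-wide relative abundance times the number of
#' sequences) via standardized residuals
#' `S_ij = (o_ij - e_j) / sqrt(e_j)`; their per-position sum of squares
#' `S_i = sum_j S_ij^2` is asymptotically chi-squared with 15 degrees of
#' freedom under the null of genome-like composition. Pairs containing
#' characters outside ACGT are masked.
#'
#' @param sequences Character vector of equal-length nucleotide strings.
#' @param genome_freq Named relative abundances of the 16 dinucleotides
#'   (normalised internally); uniform by default.
#' @param dyad_index 1-based index of the dyad base within each sequence
#'   (default the centre); offsets in the output are first-base positions
#'   relative to it.
#' @return A data.frame with `offset`, the 16 observed-count columns, and
#'   `S_i`; the residual matrix is attached as attribute `residuals`.
#' @export
dinucleotide_profile <- function(sequences,
                                 genome_freq = NULL,
                                 dyad_index = NULL) {
  n <- length(sequences)
  if (!n) stop("no sequences")
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop("sequences must have equal length")
  if (L < 2) stop("sequences must contain at least one dinucleotide")
  if (is.null(genome_freq))
    genome_freq <- stats::setNames(rep(1 / 16, 16), DINUCLEOTIDES)
  if (!all(DINUCLEOTIDES %in% names(genome_freq)))
    stop("genome_freq must name all 16 dinucleotides")
  freq <- genome_freq[DINUCLEOTIDES] / sum(genome_freq[DINUCLEOTIDES])
  if (is.null(dyad_index)) dyad_index <- (L + 1) %/% 2
  m <- matrix(match(unlist(strsplit(toupper(sequences), "")), BASES),
              nrow = n, byrow = TRUE)
  first <- m[, -L, drop = FALSE]
  second <- m[, -1, drop = FALSE]
  code <- (first - 1L) * 4L + second  # NA where either base is ambiguous
  o <- t(vapply(seq_len(L - 1),
                function(i) tabulate(code[, i][!is.na(code[, i])], 16),
                numeric(16)))
  colnames(o) <- DINUCLEOTIDES
  e <- freq * n
  observed_any <- colSums(o) > 0
  if (any(e == 0 & observed_any))
    stop("dinucleotide(s) observed but expected count is zero: ",
         paste(DINUCLEOTIDES[e == 0 & observed_any], collapse = ", "))
  resid <- sweep(sweep(o, 2, e), 2, sqrt(e), "/")
  S_i <- rowSums(resid^2)
  out <- data.frame(offset = seq_len(L - 1) - dyad_index, o,
                    S_i = S_i, check.names = FALSE)
  attr(out, "residuals") <- resid
  attr(out, "expected") <- e
  out
}

#' Extract dyad-centred sequences from a genome
#'
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes) or a
#'   FASTA path.
#' @param predictions Prediction data.frame with `chrom` and `dyad`
#'   (0-based).
#' @param flank Half-window in bp (default 500; sequences are
#'   `2 * flank + 1` bp). Predictions whose window leaves the chromosome are
#'   dropped.
#' @return Character vector of sequences.
#' @export
dyad_sequences <- function(genome, predictions, flank = 500) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  keep <- predictions$chrom %in% names(genome)
  predictions <- predictions[keep, , drop = FALSE]
  lens <- Biostrings::width(genome)[match(predictions$chrom, names(genome))]
  ok <- predictions$dyad - flank >= 0 &
    predictions$dyad + flank <= lens - 1
  predictions <- predictions[ok, , drop = FALSE]
  if (!nrow(predictions)) return(character(0))
  as.character(Biostrings::subseq(
    genome[predictions$chrom],
    start = predictions$dyad - flank + 1,
    end = predictions$dyad + flank + 1))
}

#' Genome-wide relative dinucleotide abundances
#'
#' Counted on the forward strand of the supplied reference.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return Named relative frequencies of the 16 dinucleotides.
#' @export
genome_dinucleotide_freq <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  counts <- colSums(Biostrings::dinucleotideFrequency(genome))
  counts[DINUCLEOTIDES] / sum(counts[DINUCLEOTIDES])
}

#' Centred moving average
#'
#' @param x Numeric vector.
#' @param k Odd window size.
#' @return Smoothed vector (NA at the ends).
#' @export
moving_average <- function(x, k = 3) {
  stopifnot(k >= 1, k %% 2 == 1)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Phasing profile of predictions around anchors
#'
#' Counts prediction dyads at each offset relative to anchor positions,
#' oriented by the anchor strand: for forward-strand anchors the offset is
#' `dyad - anchor`, for reverse-strand anchors `anchor - dyad`, so positive
#' offsets always point downstream in the feature's reading direction.
#'
#' @param predictions Prediction data.frame with `chrom` and `dyad`.
#' @param anchors Anchor data.frame from [load_anchors()] (columns `chrom`,
#'   `position`, `strand`).
#' @param half_window Offset range in bp (default 1000).
#' @param k Moving-average window for the smoothed column (default 3).
#' @return Data.frame with `offset` (-half_window..half_window), `count` and
#'   `smooth`.
#' @export
phasing_profile <- function(predictions, anchors, half_window = 1000,
                            k = 3) {
  offsets <- (-half_window):half_window
  counts <- numeric(length(offsets))
  for (ch in unique(anchors$chrom)) {
    dy <- sort(predictions$dyad[predictions$chrom == ch])
    if (!length(dy)) next
    anc <- anchors[anchors$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(anc))) {
      lo <- findInterval(anc$position[i] - half_window - 1, dy) + 1
      hi <- findInterval(anc$position[i] + half_window, dy)
      if (hi < lo) next
      off <- dy[lo:hi] - anc$position[i]
      if (anc$strand[i] == "-") off <- -off
      off <- off[off >= -half_window & off <= half_window]
      tab <- tabulate(off + half_window + 1, length(offsets))
      counts <- counts + tab
    }
  }
  data.frame(offset = offsets, count = counts,
             smooth = moving_average(counts, k))
}

#' Distances between adjacent prediction dyads
#'
#' @param predictions Prediction data.frame with `chrom` and `dyad`.
#' @return Integer vector of per-chromosome consecutive dyad distances.
#' @export
adjacent_distances <- function(predictions) {
  unlist(lapply(split(predictions$dyad, predictions$chrom),
                function(d) diff(sort(d))), use.names = FALSE)
}

#' Evaluate predictions against a simulated truth table
#'
#' Each truth dyad is matched to its nearest prediction dyad; it counts as
#' detected when the signed distance (prediction minus truth) is within
#' `tol`. The spatial resolution is the standard deviation of signed
#' distances over detected stable dyads.
#'
#' @param predictions Prediction data.frame with `dyad` (single-chromosome,
#'   or with `chrom` matching `truth$chrom` if present).
#' @param truth A [truth_table()].
#' @param tol Detection tolerance in bp (default 100).
#' @return List with per-truth-row `detected` flags and `nearest` signed
#'   distances, `n_stable`, `n_stable_detected`, `pct_stable`, `distances`
#'   (signed, detected stable), `sd_distance` and `median_abs_distance`.
#' @export
evaluate_predictions <- function(predictions, truth, tol = 100) {
  stopifnot(tol > 0)
  dy <- sort(predictions$dyad)
  nearest <- rep(NA_real_, nrow(truth))
  if (length(dy)) {
    i <- findInterval(truth$dyad, dy)
    lo <- pmax(i, 1)
    hi <- pmin(i + 1, length(dy))
    dlo <- dy[lo] - truth$dyad
    dhi <- dy[hi] - truth$dyad
    nearest <- ifelse(abs(dhi) < abs(dlo), dhi, dlo)
  }
  stable <- truth$stable
  det <- !is.na(nearest) & abs(nearest) <= tol
  dist_stable <- nearest[stable & det]
  list(detected = det,
       n_stable = sum(stable),
       n_stable_detected = sum(stable & det),
       pct_stable = if (sum(stable)) 100 * sum(stable & det) / sum(stable)
                    else NA_real_,
       n_detected = sum(det),
       distances = dist_stable,
       sd_distance = if (length(dist_stable) > 1) sd(dist_stable)
                     else NA_real_,
       median_abs_distance = if (length(dist_stable))
                               median(abs(dist_stable)) else NA_real_,
       nearest = nearest)
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Total-correlation repeatability of detections across samples
#'
#' For k binary detection vectors over the same nucleosome index, the total
#' correlation `C_tot` is the sum of marginal empirical entropies minus the
#' joint empirical entropy (in bits; the ratio is base-invariant). It is
#' normalised by `C_max`, the total correlation after sorting each vector in
#' descending order — the detection-count-preserving rearrangement that
#' maximises repeated detections. Returns 0 when `C_max = 0`.
#'
#' @param detections A k-row logical/0-1 matrix, or a list of equal-length
#'   vectors.
#' @return Repeatability ratio in `[0, 1]`.
#' @export
repeatability <- function(detections) {
  if (is.list(detections)) detections <- do.call(rbind, detections)
  mode(detections) <- "integer"
  if (nrow(detections) < 2) stop("need at least two detection vectors")
  total_correlation <- function(m) {
    marg <- sum(apply(m, 1, function(v) entropy_bits(table(v))))
    joint <- entropy_bits(table(apply(m, 2, paste, collapse = "")))
    marg - joint
  }
  c_tot <- total_correlation(detections)
  sorted <- t(apply(detections, 1, sort, decreasing = TRUE))
  c_max <- total_correlation(sorted)
  if (c_max <= 0) return(0)
  c_tot / c_max
}

#' Pareto front of parameter-sweep points
#'
#' Each point carries `M`, the number of predictions in the control sample
#' (taken as false positives), and `m`, the number in the treatment. The
#' front keeps the non-dominated staircase: for every control level the
#' parameter set with the most treatment predictions among those with no
#' more control predictions.
#'
#' @param points Data.frame with columns `M` and `m` (extra columns kept).
#' @return The subset forming the front, sorted by `M`, deduplicated.
#' @export
pareto_front <- function(points) {
  if (!nrow(points)) stop("empty point set")
  best_le <- vapply(seq_len(nrow(points)), function(i)
    max(points$m[points$M <= points$M[i]]), numeric(1))
  keep <- points$m == best_le
  # smallest control count per treatment level
  min_M <- vapply(seq_len(nrow(points)), function(i)
    min(points$M[points$m >= points$m[i]]), numeric(1))
  keep <- keep & points$M == min_M
  out <- points[keep, , drop = FALSE]
  out <- out[!duplicated(out[, c("M", "m")]), , drop = FALSE]
  out <- out[order(out$M), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sweep model parameters against a control sample
#'
#' Runs the full pipeline for every grid row on both samples at a fixed FDR
#' and records the prediction counts (`m` treatment, `M` control) and their
#' ratio. Failing runs are recorded as NA and the sweep continues.
#'
#' @param treatment,control `strand_counts` objects.
#' @param grid Data.frame of parameter combinations; columns among `b`, `s`,
#'   `w_bg`, `gamma_bg`, `gamma_sup` (missing ones taken from `config`).
#' @param config Base [run_config()].
#' @return List with `points` (the grid plus `m`, `M`, `ratio`) and `front`
#'   (the [pareto_front()] of complete rows).
#' @export
parameter_sweep <- function(treatment, control, grid,
                            config = run_config()) {
  n_pred <- function(counts, cfg) {
    res <- nucleosome_pipeline(counts, cfg)
    nrow(res$predictions)
  }
  m <- M <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in intersect(names(grid), c("b", "s", "w_bg", "gamma_bg",
                                        "gamma_sup")))
      cfg[[nm]] <- grid[[nm]][i]
    cfg <- do.call(run_config, cfg[setdiff(names(cfg), "resolved")])
    m[i] <- tryCatch(n_pred(treatment, cfg), error = function(e) NA_real_)
    M[i] <- tryCatch(n_pred(control, cfg), error = function(e) NA_real_)
  }
  points <- cbind(grid, m = m, M = M,
                  ratio = ifelse(m > 0, M / m, NA_real_))
  complete <- points[!is.na(points$m) & !is.na(points$M), , drop = FALSE]
  list(points = points,
       front = if (nrow(complete)) pareto_front(complete) else complete)
}
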