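# Local background model: strand-specific windowed read-start counts,
# robustified against isolated large peaks by a Poisson-quantile cap on the
# change between adjacent non-overlapping windows.

#' Sliding-window read-start counts
#'
#' Sums counts in a window of half-width `half_width` centred at every
#' position; the window is truncated at the chromosome ends (only existing
#' positions contribute).
#'
#' @param counts Integer vector of per-position counts.
#' @param half_width Window half-width in bp (window length
#'   `2 * half_width + 1`).
#' @return Numeric vector of the same length with windowed counts.
#' @export
windowed_counts <- function(counts, half_width) {
  if (length(half_width) != 1 || is.na(half_width) || half_width < 0)
    stop("half_width must be a single non-negative integer")
  n <- length(counts)
  if (n == 0) return(numeric(0))
  cs <- c(0, cumsum(as.numeric(counts)))
  i <- seq_len(n)
  cs[pmin(i + half_width, n) + 1] - cs[pmax(i - half_width - 1, 0) + 1]
}

#' Largest count below a Poisson CDF bound
#'
#' Returns the largest integer `j >= 0` with `P[X <= j | lambda] <= gamma`,
#' or `-1` when even `j = 0` exceeds the bound (e.g. `lambda = 0` with
#' `gamma < 1`, since then `P[X <= 0] = 1`). For `gamma = 1` the bound never
#' binds and `Inf` is returned.
#'
#' @param gamma Probability in (0, 1].
#' @param lambda Poisson rate (a count per window).
#' @return Integer-valued cap (possibly `-1` or `Inf`).
#' @export
poisson_cap <- function(gamma, lambda) {
  if (length(gamma) != 1 || gamma <= 0 || gamma > 1)
    stop("gamma must be a single probability in (0, 1]")
  vapply(lambda, function(l) .pois_cap_cpp(gamma, l), numeric(1))
}

#' Robust background estimate
#'
#' Scans each chromosome left to right. Where the raw windowed estimate of
#' the adjacent non-overlapping window (centred `2 * half_width + 1` bp to
#' the left) is positive, the windowed count is capped at the largest value `j`
#' whose Poisson CDF at the predecessor rate does not exceed `gamma`; where
#' no `j >= 0` satisfies the bound the estimate falls back to 0. The first
#' `2 * half_width + 1` positions have no predecessor and are left unchanged.
#'
#' @param lambda_hat Windowed counts from [windowed_counts()] with the same
#'   `half_width`.
#' @param half_width Background window half-width in bp.
#' @param gamma Probability in (0, 1] bounding the allowed rate increase.
#' @return Numeric vector of robust per-window background counts.
#' @export
robust_background <- function(lambda_hat, half_width, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (!length(lambda_hat)) return(numeric(0))
  .robust_scan_cpp(as.numeric(lambda_hat), as.integer(2 * half_width + 1),
                   gamma)
}

#' Background track for a strand_counts object
#'
#' @param counts A `strand_counts` object.
#' @param half_width Background window half-width `w_bg` (default 1000,
#'   i.e. a 2001 bp window).
#' @param gamma Cut-off probability `gamma_bg` (default 0.9).
#' @return A `background_track`: per chromosome and strand the raw
#'   (`lambda_hat`) and robust (`lambda_tilde`) windowed counts.
#' @export
background_track <- function(counts, half_width = 1000, gamma = 0.9) {
  stopifnot(inherits(counts, "strand_counts"))
  tracks <- lapply(counts$counts, function(x) {
    lapply(x, function(y) {
      lh <- windowed_counts(y, half_width)
      list(lambda_hat = lh,
           lambda_tilde = robust_background(lh, half_width, gamma))
    })
  })
  structure(list(tracks = tracks, half_width = half_width, gamma = gamma),
            class = "background_track")
}

#' Export background rate tracks to bedGraph
#'
#' @param bg A `background_track`.
#' @param path Output bedGraph file.
#' @param strand `"fwd"` or `"rev"`.
#' @param which `"lambda_tilde"` (robust) or `"lambda_hat"` (raw).
#' @return The path, invisibly.
#' @export
export_background_bedgraph <- function(bg, path, strand = c("fwd", "rev"),
                                       which = c("lambda_tilde",
                                                 "lambda_hat")) {
  strand <- match.arg(strand)
  which <- match.arg(which)
  grl <- lapply(names(bg$tracks), function(ch) {
    v <- bg$tracks[[ch]][[strand]][[which]]
    GenomicRanges::GRanges(ch, IRanges::IRanges(seq_along(v), width = 1),
                           score = v)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
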