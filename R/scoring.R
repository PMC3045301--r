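# Three-region likelihood-ratio scoring. A candidate nucleosome starting at
# position i (0-based) has a forward support region [i-s, i-1] on the forward
# strand, a binding region [i, i+b-1] on both strands and a reverse support
# region [i+b, i+b+s-1] on the reverse strand. Each region's read count is
# contrasted with the local background by a two-sample Poisson LRT; the
# signed square roots of the three statistics add up to the nucleosome score.

#' Binding-site geometry
#'
#' @param b Binding-region length in bp (default 128, the optimum selected on
#'   mononucleosome data; 147 with `s = 10` is the canonical-footprint
#'   alternative).
#' @param s Support-region length in bp (default 17).
#' @param gamma_sup Cut-off probability for the cross-strand truncation of
#'   support-region estimates (default 0.9).
#' @return A `binding_geometry` list.
#' @export
binding_geometry <- function(b = 128, s = 17, gamma_sup = 0.9) {
  stopifnot(b >= 1, s >= 1, gamma_sup > 0, gamma_sup <= 1)
  structure(list(b = as.integer(b), s = as.integer(s),
                 gamma_sup = gamma_sup),
            class = "binding_geometry")
}

#' Region read counts for all candidate positions
#'
#' Candidate starts are all 0-based positions `i` in `[s, L - b - s]` so that
#' all three regions fit on the chromosome. Counts are exact integers from
#' cumulative-sum differences.
#'
#' @param fwd,rev Integer vectors of per-position 5'-start counts.
#' @param geometry A [binding_geometry()].
#' @return List with `pos` (0-based candidate starts), `x_fwd`, `x_bind`,
#'   `x_rev`; empty vectors when the chromosome is shorter than `b + 2s`.
#' @export
region_counts <- function(fwd, rev, geometry) {
  b <- geometry$b; s <- geometry$s
  L <- length(fwd)
  stopifnot(length(rev) == L)
  if (L < b + 2 * s)
    return(list(pos = integer(0), x_fwd = numeric(0),
                x_bind = numeric(0), x_rev = numeric(0)))
  csF <- c(0, cumsum(as.numeric(fwd)))
  csR <- c(0, cumsum(as.numeric(rev)))
  csB <- csF + csR
  p <- s:(L - b - s)
  list(pos = p,
       x_fwd = csF[p + 1] - csF[p + 1 - s],
       x_bind = csB[p + b + 1] - csB[p + 1],
       x_rev = csR[p + b + s + 1] - csR[p + b + 1])
}

#' Maximum-likelihood estimates for the two-sample Poisson comparison
#'
#' For counts `x0`, `x1` observed over window lengths `t0`, `t1`, the rate
#' ratio estimate is `phi_hat = x1 t0 / (x0 t1)` (undefined when `x0 = 0`),
#' the free background estimate is `lambda0_hat = x0`, and under equal rates
#' the pooled estimate is `lambda_pooled = t0 (x0 + x1) / (t0 + t1)`.
#'
#' @param x0,x1 Non-negative counts.
#' @param t0,t1 Window lengths (bp), both `>= 1`.
#' @return List with `phi_hat` (NA when undefined), `lambda0_hat`,
#'   `lambda_pooled`.
#' @export
mle_estimates <- function(x0, t0, x1, t1) {
  if (any(t0 < 1) || any(t1 < 1)) stop("window lengths must be >= 1")
  if (any(x0 < 0) || any(x1 < 0)) stop("counts must be non-negative")
  phi <- ifelse(x0 > 0, x1 * t0 / (x0 * t1), NA_real_)
  list(phi_hat = phi, lambda0_hat = x0,
       lambda_pooled = t0 * (x0 + x1) / (t0 + t1))
}

xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- x[pos] * log(x[pos])
  out[is.na(x)] <- NA_real_
  out
}

#' Two-sample Poisson likelihood-ratio statistic
#'
#' `W = 2 {x0 (ln x0 - ln t0) + x1 (ln x1 - ln t1) +
#' (x0 + x1)(ln(t0 + t1) - ln(x0 + x1))}` with the convention
#' `0 ln 0 = 0`. Vectorised; `NA` where `x0 + x1 = 0` (the statistic is
#' undefined for two empty windows). Tiny negative rounding (< 1e-12) is
#' clamped to 0.
#'
#' @param x0,x1 Non-negative counts (rate estimates are allowed, so
#'   non-integer values are accepted).
#' @param t0,t1 Window lengths, both `>= 1`.
#' @return Non-negative statistic, asymptotically chi-squared with 1 df under
#'   equal rates.
#' @export
lrt_statistic <- function(x0, t0, x1, t1) {
  if (any(t0 < 1) || any(t1 < 1)) stop("window lengths must be >= 1")
  W <- 2 * (xlogx(x0) - x0 * log(t0) + xlogx(x1) - x1 * log(t1) +
              (x0 + x1) * log(t0 + t1) - xlogx(x0 + x1))
  W[!is.na(W) & W < 0] <- 0
  # exactly equal estimated rates collapse the alternative onto the null
  W[!is.na(x0) & !is.na(x1) & x1 * t0 == x0 * t1] <- 0
  W[!is.na(x0 + x1) & (x0 + x1) == 0] <- NA_real_
  W
}

#' Cross-truncated support-region estimates
#'
#' A peak on one strand is only trusted to the extent the other strand shows
#' a comparable peak: the forward estimate is the largest `j` with
#' `0 < j <= x_fwd` whose Poisson CDF at rate `x_rev` does not exceed
#' `gamma`; symmetrically for the reverse estimate. When the feasible set is
#' empty (no read in the region, or the partner estimate is 0 so the CDF
#' bound is unsatisfiable) the estimate is `NA` and the position is invalid.
#'
#' @param x_fwd,x_rev Support-region counts (vectors).
#' @param gamma_sup Probability in (0, 1].
#' @return List with numeric vectors `fwd` and `rev` (NA where undefined).
#' @export
truncated_support_estimates <- function(x_fwd, x_rev, gamma_sup) {
  stopifnot(gamma_sup > 0, gamma_sup <= 1)
  cap_lookup <- function(partner) {
    u <- sort(unique(partner))
    caps <- poisson_cap(gamma_sup, u)
    caps[match(partner, u)]
  }
  cf <- cap_lookup(x_rev)
  cr <- cap_lookup(x_fwd)
  fwd <- pmin(x_fwd, cf)
  fwd[x_fwd < 1 | cf < 1] <- NA_real_
  rev <- pmin(x_rev, cr)
  rev[x_rev < 1 | cr < 1] <- NA_real_
  list(fwd = fwd, rev = rev)
}

#' Score a genome for candidate nucleosome positions
#'
#' For each candidate start the support scores are the signed square roots of
#' the LRT statistics comparing the truncated support estimates (over `s` bp)
#' to the strand-specific robust background (over the `2 w_bg + 1` bp
#' window), positive when the support rate per bp exceeds the background rate
#' per bp. The binding score compares the pooled-strand binding count (over
#' `b` bp) to the summed strand backgrounds (over `2 (2 w_bg + 1)` bp) and is
#' positive when the binding region is depleted. A position is valid only
#' with at least one read in each support region, positive robust background
#' on both strands and both truncated estimates defined.
#'
#' @param counts A `strand_counts` object.
#' @param bg A matching [background_track()].
#' @param geometry A [binding_geometry()].
#' @param signed_root Use the signed square root of each region statistic
#'   (default; gives approximately standard-normal region scores under the
#'   null). `FALSE` uses the literal signed statistic.
#' @return A `score_track`: per chromosome a list with `pos`, region counts,
#'   region scores `S_fwd`, `S_bind`, `S_rev`, combined `S` and `valid`.
#' @export
score_genome <- function(counts, bg, geometry, signed_root = TRUE) {
  stopifnot(inherits(counts, "strand_counts"),
            inherits(bg, "background_track"))
  t0 <- 2 * bg$half_width + 1
  chroms <- names(counts$counts)
  track <- lapply(chroms, function(ch) {
    x <- counts$counts[[ch]]
    rc <- region_counts(x$fwd, x$rev, geometry)
    if (!length(rc$pos))
      return(c(rc, list(S_fwd = numeric(0), S_bind = numeric(0),
                        S_rev = numeric(0), S = numeric(0),
                        valid = logical(0))))
    bgF <- bg$tracks[[ch]]$fwd$lambda_tilde[rc$pos + 1]
    bgR <- bg$tracks[[ch]]$rev$lambda_tilde[rc$pos + 1]
    sup <- truncated_support_estimates(rc$x_fwd, rc$x_rev,
                                       geometry$gamma_sup)
    valid <- rc$x_fwd >= 1 & rc$x_rev >= 1 & bgF > 0 & bgR > 0 &
      !is.na(sup$fwd) & !is.na(sup$rev)
    s <- geometry$s; b <- geometry$b
    transf <- if (signed_root) sqrt else identity
    Wf <- lrt_statistic(bgF, t0, sup$fwd, s)
    Sf <- ifelse(sup$fwd / s > bgF / t0, 1, -1) * transf(Wf)
    Wr <- lrt_statistic(bgR, t0, sup$rev, s)
    Sr <- ifelse(sup$rev / s > bgR / t0, 1, -1) * transf(Wr)
    Wb <- lrt_statistic(bgF + bgR, 2 * t0, rc$x_bind, b)
    Sb <- ifelse(rc$x_bind / b > (bgF + bgR) / (2 * t0), -1, 1) * transf(Wb)
    S <- Sf + Sb + Sr
    S[!valid] <- NA_real_
    Sf[!valid] <- NA_real_; Sb[!valid] <- NA_real_; Sr[!valid] <- NA_real_
    c(rc, list(S_fwd = Sf, S_bind = Sb, S_rev = Sr, S = S, valid = valid))
  })
  names(track) <- chroms
  structure(list(track = track, geometry = geometry,
                 half_width = bg$half_width, signed_root = signed_root),
            class = "score_track")
}

#' Export the combined score track to bedGraph
#'
#' Only valid positions are written.
#'
#' @param track A `score_track`.
#' @param path Output bedGraph file.
#' @return The path, invisibly.
#' @export
export_score_bedgraph <- function(track, path) {
  grl <- lapply(names(track$track), function(ch) {
    tr <- track$track[[ch]]
    keep <- tr$valid
    GenomicRanges::GRanges(ch,
                           IRanges::IRanges(tr$pos[keep] + 1, width = 1),
                           score = tr$S[keep])
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
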