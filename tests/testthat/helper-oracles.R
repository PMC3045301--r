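# Independent oracles: brute-force or numeric reference implementations used
# to pin expected values. Deliberately written without reusing the package's
# code paths.

# largest j >= 0 with ppois(j, lambda) <= gamma by direct scan, -1 if none
oracle_pois_cap <- function(gamma, lambda, jmax = 500) {
  if (gamma >= 1) return(Inf)
  best <- -1
  for (j in 0:jmax) if (ppois(j, lambda) <= gamma) best <- j
  best
}

# windowed counts by direct summation
oracle_window <- function(y, w) {
  n <- length(y)
  vapply(seq_len(n), function(i)
    sum(y[max(1, i - w):min(n, i + w)]), numeric(1))
}

# robust background rule by per-position brute force
oracle_robust <- function(lh, stride, gamma) {
  out <- lh
  for (i in seq_along(lh)) {
    if (i <= stride) next
    pred <- lh[i - stride]
    if (pred <= 0) next
    best <- -1
    for (j in 0:ceiling(lh[i])) {
      if (j <= lh[i] && ppois(j, pred) <= gamma) best <- j
    }
    out[i] <- max(best, 0)
  }
  out
}

# support truncation by brute-force scan over 0 < j <= x
oracle_support_trunc <- function(x, partner, gamma) {
  feasible <- integer(0)
  if (x >= 1)
    feasible <- Filter(function(j) ppois(j, partner) <= gamma, seq_len(x))
  if (!length(feasible)) NA_real_ else max(feasible)
}

# numeric likelihood-ratio statistic: nested 1-D maximizations of the
# two-sample Poisson log likelihoods over (phi, lambda0) and lambda
oracle_lrt_numeric <- function(x0, t0, x1, t1) {
  ll1 <- function(lphi, llam0) {
    lam0 <- exp(llam0)
    phi <- exp(lphi)
    -lam0 + (x0 + x1) * llam0 - phi * lam0 * t1 / t0 + x1 * lphi +
      x1 * log(t1 / t0)
  }
  inner <- function(lphi) {
    optimize(function(llam0) ll1(lphi, llam0),
             interval = c(-60, log(2 * (x0 + x1) + 10)),
             maximum = TRUE, tol = 1e-10)$objective
  }
  m1 <- optimize(inner, interval = c(-45, 45), maximum = TRUE,
                 tol = 1e-9)$maximum
  l1 <- inner(m1)
  l0 <- optimize(function(llam) {
    lam <- exp(llam)
    -lam + (x0 + x1) * llam - lam * t1 / t0 + x1 * log(t1 / t0)
  }, interval = c(-60, log(2 * (x0 + x1) + 10)), maximum = TRUE,
  tol = 1e-10)$objective
  max(0, 2 * (l1 - l0))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  v <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(v)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# O(n^2) dominance filter for the Pareto front
oracle_pareto <- function(points) {
  n <- nrow(points)
  keep <- vapply(seq_len(n), function(i) {
    !any(points$M <= points$M[i] & points$m >= points$m[i] &
           (points$M < points$M[i] | points$m > points$m[i]))
  }, logical(1))
  out <- points[keep, c("M", "m"), drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out$M), , drop = FALSE]
}

# position-by-position naive scoring (direct sums, brute-force caps)
oracle_score <- function(fwd, rev, b, s, w, gamma_bg, gamma_sup) {
  L <- length(fwd)
  t0 <- 2 * w + 1
  lhF <- oracle_window(fwd, w); lhR <- oracle_window(rev, w)
  ltF <- oracle_robust(lhF, t0, gamma_bg)
  ltR <- oracle_robust(lhR, t0, gamma_bg)
  Wexpr <- function(x0, t0, x1, t1) {
    if (x1 * t0 == x0 * t1) return(0)
    term <- function(x, t) if (x > 0) x * (log(x) - log(t)) else 0
    max(0, 2 * (term(x0, t0) + term(x1, t1) +
                  (x0 + x1) * (log(t0 + t1) - log(x0 + x1))))
  }
  pos <- s:(L - b - s)
  res <- lapply(pos, function(i) {
    xf <- sum(fwd[(i - s):(i - 1) + 1])
    xb <- sum(fwd[i:(i + b - 1) + 1]) + sum(rev[i:(i + b - 1) + 1])
    xr <- sum(rev[(i + b):(i + b + s - 1) + 1])
    bf <- ltF[i + 1]; br <- ltR[i + 1]
    capF <- oracle_pois_cap(gamma_sup, xr)
    capR <- oracle_pois_cap(gamma_sup, xf)
    lf <- if (xf >= 1 && capF >= 1) min(xf, capF) else NA_real_
    lr <- if (xr >= 1 && capR >= 1) min(xr, capR) else NA_real_
    valid <- xf >= 1 && xr >= 1 && bf > 0 && br > 0 &&
      !is.na(lf) && !is.na(lr)
    if (!valid) return(c(NA_real_, FALSE))
    Sf <- (if (lf / s > bf / t0) 1 else -1) * sqrt(Wexpr(bf, t0, lf, s))
    Sr <- (if (lr / s > br / t0) 1 else -1) * sqrt(Wexpr(br, t0, lr, s))
    Sb <- (if (xb / b > (bf + br) / (2 * t0)) -1 else 1) *
      sqrt(Wexpr(bf + br, 2 * t0, xb, b))
    c(Sf + Sb + Sr, TRUE)
  })
  list(pos = pos,
       S = vapply(res, `[`, numeric(1), 1),
       valid = as.logical(vapply(res, `[`, numeric(1), 2)))
}

# quick uniform-background strand_counts fixture
make_uniform_counts <- function(n_reads, L, seed, chrom = "sim") {
  set.seed(seed)
  p5 <- sample.int(L, n_reads, replace = TRUE) - 1L
  fwd <- runif(n_reads) < 0.5
  aln <- data.frame(chrom = chrom, strand = ifelse(fwd, "+", "-"),
                    start = ifelse(fwd, p5, pmax(0L, p5 - 35L)),
                    length = ifelse(fwd, 36L, p5 - pmax(0L, p5 - 35L) + 1L),
                    stringsAsFactors = FALSE)
  read_starts(aln, stats::setNames(L, chrom))
}
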