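test_that("region counts respect the three-region boundaries", {
  geom <- binding_geometry(b = 10, s = 3)
  L <- 50
  fwd <- integer(L); rev <- integer(L)
  rc0 <- region_counts(fwd, rev, geom)
  expect_equal(rc0$pos, 3:(50 - 13))
  expect_true(all(rc0$x_fwd == 0) && all(rc0$x_bind == 0) &&
                all(rc0$x_rev == 0))

  i <- 20
  fwd[i - 1 + 1] <- 1L  # forward read at i-1: last base of fwd support
  rev[i + 10 + 1] <- 1L  # reverse read at i+b: first base of rev support
  rc <- region_counts(fwd, rev, geom)
  at <- match(i, rc$pos)
  expect_equal(rc$x_fwd[at], 1)
  expect_equal(rc$x_rev[at], 1)
  expect_equal(rc$x_bind[at], 0)
  # the same reads fall into the binding region of shifted candidates
  expect_equal(rc$x_bind[match(i - 5, rc$pos)], 1)  # fwd read at 19 in [15,24]
  expect_equal(rc$x_bind[match(i + 5, rc$pos)], 1)  # rev read at 30 in [25,34]

  short <- region_counts(integer(10), integer(10), geom)
  expect_length(short$pos, 0)
})

test_that("maximum-likelihood estimates follow the closed forms", {
  est <- mle_estimates(4, 2, 6, 3)
  expect_equal(est$phi_hat, 1)
  expect_equal(est$lambda0_hat, 4)
  expect_equal(est$lambda_pooled, 4)  # 2 * 10 / 5
  expect_true(is.na(mle_estimates(0, 2, 6, 3)$phi_hat))
  expect_error(mle_estimates(4, 0, 6, 3), "window lengths")
})

test_that("likelihood-ratio statistic matches pinned values", {
  expect_identical(lrt_statistic(10, 100, 1, 10), 0)  # equal rates, exact
  expect_equal(lrt_statistic(100, 2001, 10, 17), 30.205, tolerance = 1e-4)
  expect_equal(lrt_statistic(10, 10, 0, 10), 20 * log(2), tolerance = 1e-12)
  expect_true(is.na(lrt_statistic(0, 10, 0, 10)))
  expect_true(all(lrt_statistic(c(3, 7), 50, c(9, 2), 25) >= 0))
})

test_that("support estimates are cross-truncated by the partner strand", {
  est <- truncated_support_estimates(20, 10, 0.9)
  expect_equal(est$fwd, 13)
  expect_equal(est$rev, 10)  # cap(0.9, 20) = 25 > 10
  expect_equal(truncated_support_estimates(5, 10, 0.9)$fwd, 5)
  expect_true(is.na(truncated_support_estimates(5, 0, 0.9)$fwd))
  expect_true(is.na(truncated_support_estimates(0, 5, 0.9)$fwd))
  # gamma = 1: the bound never binds
  expect_equal(truncated_support_estimates(20, 1, 1)$fwd, 20)
})

test_that("genome scoring agrees with a naive per-position implementation", {
  set.seed(21)
  L <- 10000L
  fwd <- rpois(L, 0.05); rev <- rpois(L, 0.05)
  centres <- c(2000, 5000, 8000)
  for (c0 in centres) {  # plant crude nucleosome patterns
    fwd[c0 - 75 + round(rnorm(10, 0, 4)) + 1] <- 3
    rev[c0 + 74 + round(rnorm(10, 0, 4)) + 1] <- 3
  }
  w <- 50L
  geom <- binding_geometry(b = 128, s = 17, gamma_sup = 0.9)
  aln_counts <- structure(list(
    counts = list(sim = list(fwd = fwd, rev = rev)),
    genome = c(sim = L), n_reads = sum(fwd) + sum(rev), n_skipped = 0L),
    class = "strand_counts")
  bg <- background_track(aln_counts, half_width = w, gamma = 0.9)
  tr <- score_genome(aln_counts, bg, geom)$track$sim
  ref <- oracle_score(fwd, rev, b = 128, s = 17, w = w,
                      gamma_bg = 0.9, gamma_sup = 0.9)
  expect_equal(tr$pos, ref$pos)
  expect_equal(tr$valid, ref$valid)
  expect_equal(tr$S, ref$S)
})

test_that("an overfull binding region drives the score negative", {
  # supports at background level, binding region far above background
  t0 <- 2001
  Wb <- lrt_statistic(100, 2 * t0, 60, 128)
  expect_gt(Wb, 0)
  # construct directly: sign rule makes S_bind negative
  Sb <- ifelse(60 / 128 > 100 / (2 * t0), -1, 1) * sqrt(Wb)
  expect_lt(Sb, 0)
  expect_lt(Sb + 0 + 0, 0)  # supports contribute zero at equal rates
})

test_that("adding a forward support read never decreases the forward score", {
  sfwd <- function(x_fwd, x_rev, bgF, t0 = 2001, s = 17, g = 0.9) {
    lt <- truncated_support_estimates(x_fwd, x_rev, g)$fwd
    if (is.na(lt)) return(NA_real_)
    W <- lrt_statistic(bgF, t0, lt, s)
    ifelse(lt / s > bgF / t0, 1, -1) * sqrt(W)
  }
  set.seed(4)
  for (k in 1:200) {
    x_rev <- sample(1:30, 1)
    bgF <- sample(1:200, 1)
    x_fwd <- sample(1:30, 1)
    s1 <- sfwd(x_fwd, x_rev, bgF)
    s2 <- sfwd(x_fwd + 1, x_rev, bgF)
    if (!is.na(s1) && !is.na(s2)) expect_gte(s2, s1 - 1e-12)
  }
})
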