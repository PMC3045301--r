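test_that("dinucleotide statistic reproduces the hand-computed toy case", {
  prof <- dinucleotide_profile(c("AA", "AA"))
  expect_equal(prof$S_i, 30)  # (2-.125)^2/.125 + 15*(.125)^2/.125
  expect_equal(sum(prof[1, 2:17]), 2)
})

test_that("matching observed and expected counts give zero statistic", {
  # 16 sequences, one of each dinucleotide: o = e = 1 everywhere
  bases <- c("A", "C", "G", "T")
  seqs <- as.vector(outer(bases, bases, function(a, b) paste0(a, b)))
  prof <- dinucleotide_profile(seqs)
  expect_equal(prof$S_i, 0)
})

test_that("ambiguous bases are masked and degenerate expectations error", {
  prof <- dinucleotide_profile(c("AN", "AA"))
  expect_equal(sum(prof[1, 2:17]), 1)  # the AN pair is masked
  freq <- stats::setNames(rep(1 / 15, 16),
                          colnames(prof)[2:17])
  freq["TT"] <- 0
  expect_error(dinucleotide_profile(c("TT", "TT"), genome_freq = freq),
               "expected count is zero")
})

test_that("a planted periodic AA signal stands out over random flanks", {
  set.seed(41)
  n <- 2000; L <- 301; centre <- 151
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  for (off in seq(-70, 70, by = 10)) {
    m[, centre + off] <- "A"
    m[, centre + off + 1] <- "A"
  }
  seqs <- apply(m, 1, paste, collapse = "")
  prof <- dinucleotide_profile(seqs, dyad_index = centre)
  inside <- abs(prof$offset) <= 73
  flank <- abs(prof$offset) > 73 & abs(prof$offset) <= 140
  expect_gt(mean(prof$S_i[inside]), qchisq(0.99, 15))
  expect_equal(mean(prof$S_i[flank]), 15, tolerance = 0.1)
})

test_that("phasing profiles orient offsets by anchor strand", {
  preds <- data.frame(chrom = "c", dyad = c(1100, 3900))
  anchors <- data.frame(chrom = "c", position = c(1000, 4000),
                        strand = c("+", "-"), kind = "TSS")
  prof <- phasing_profile(preds, anchors, half_window = 500)
  # dyad 1100 lies +100 of the forward anchor; dyad 3900 lies 100 upstream
  # of the reverse anchor, which orientation maps to +100 as well
  expect_equal(prof$count[prof$offset == 100], 2)
  expect_equal(sum(prof$count), 2)

  empty <- phasing_profile(preds[0, ], anchors, half_window = 500)
  expect_true(all(empty$count == 0))
})

test_that("adjacent distances are per-chromosome sorted differences", {
  preds <- data.frame(chrom = c("c", "c", "c"), dyad = c(400, 100, 112))
  expect_equal(sort(adjacent_distances(preds)), c(12, 288))
  expect_length(adjacent_distances(preds[1, ]), 0)
  two <- data.frame(chrom = c("a", "b"), dyad = c(1, 5000))
  expect_length(adjacent_distances(two), 0)
})

test_that("evaluation matches truth dyads to nearest predictions", {
  truth <- truth_table(dyad = c(1000L, 2000L, 3000L),
                       kind = rep("stable", 3), sd = 0, genome_length = 1e4)
  exact <- data.frame(chrom = "c", dyad = truth$dyad)
  ev <- evaluate_predictions(exact, truth)
  expect_equal(ev$pct_stable, 100)
  expect_equal(ev$sd_distance, 0)
  expect_equal(ev$median_abs_distance, 0)

  shifted <- data.frame(chrom = "c", dyad = truth$dyad + 50)
  ev2 <- evaluate_predictions(shifted, truth)
  expect_equal(ev2$pct_stable, 100)
  expect_equal(ev2$sd_distance, 0)
  expect_true(all(ev2$distances == 50))

  ev3 <- evaluate_predictions(exact[0, ], truth)
  expect_equal(ev3$n_stable_detected, 0)
})

test_that("repeatability reproduces the hand-computed entropies", {
  X <- rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_equal(repeatability(X), 0.5)  # C_tot = 1 bit, C_max = 2 bits
  expect_equal(repeatability(rbind(c(1, 0, 1), c(1, 0, 1))), 1)
  expect_equal(repeatability(matrix(0, 3, 4)), 0)
  # invariant to a common permutation of the nucleosome index
  set.seed(43)
  Y <- matrix(rbinom(30, 1, 0.5), 3, 10)
  perm <- sample(10)
  expect_equal(repeatability(Y), repeatability(Y[, perm]))
})

test_that("pareto front equals the dominance-filter oracle", {
  pts <- data.frame(M = c(10, 5, 12, 5), m = c(100, 80, 90, 60))
  fr <- pareto_front(pts)
  expect_equal(fr$M, c(5, 10))
  expect_equal(fr$m, c(80, 100))
  expect_equal(pareto_front(pts[1, ])$M, 10)
  same <- data.frame(M = rep(3, 4), m = rep(7, 4))
  expect_equal(nrow(pareto_front(same)), 1)

  set.seed(44)
  for (k in 1:50) {
    pts <- data.frame(M = sample(0:50, sample(1:25, 1), replace = TRUE))
    pts$m <- sample(0:200, nrow(pts), replace = TRUE)
    fr <- pareto_front(pts)[, c("M", "m")]
    or <- oracle_pareto(pts)
    rownames(fr) <- rownames(or) <- NULL
    expect_equal(fr, or)
  }
})
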