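test_that("feature tiling matches weights and spacing", {
  p <- sim_params(genome_length = 1e4, weights = c(stable = 1),
                  n_reads = 0, seed = 1)
  fe <- simulate_features(p)
  expect_true(abs(nrow(fe$truth) - 50) <= 2)  # ~200 bp stable features
  expect_true(all(diff(fe$truth$dyad) == 200))
  expect_true(all(fe$truth$stable))

  p_nfr <- sim_params(genome_length = 1e4, weights = c(nfr = 1),
                      n_reads = 0, seed = 1)
  expect_equal(nrow(simulate_features(p_nfr)$truth), 0)

  expect_error(simulate_features(
    sim_params(genome_length = 50, weights = c(stable = 1), seed = 1)),
    "too short")
})

test_that("phased arrays have growing positional spread along the array", {
  p <- sim_params(genome_length = 5e4, weights = c(phased = 1),
                  n_reads = 0, seed = 2)
  tr <- simulate_features(p)$truth
  expect_true(all(tr$kind == "phased"))
  expect_false(any(tr$stable))
  # within one 5 kb array: spread increases from 10 by 2 per dyad
  first <- tr[tr$dyad < 5000, ]
  expect_equal(first$sd, pmin(40, 10 + 2 * (seq_len(nrow(first)) - 1)))
})

test_that("the simulator is deterministic given a seed", {
  p <- sim_params(genome_length = 2e4, n_reads = 2000, seed = 42)
  a <- simulate_experiment(p)
  b <- simulate_experiment(p)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
})

test_that("fragment geometry pins forward and reverse 5' ends", {
  tt <- truth_table(dyad = 5000L, kind = "stable", sd = 0,
                    genome_length = 1e4)
  p <- sim_params(genome_length = 1e4, fragment_sd = 0,
                  background_fraction = 0, n_reads = 400, seed = 3)
  rd <- simulate_reads(tt, p)
  expect_equal(nrow(rd), 400)
  fwd <- rd[rd$strand == "+", ]
  rev <- rd[rd$strand == "-", ]
  # fragment [c - 75, c + 74]: forward 5' = leftmost; reverse 5' = rightmost
  expect_true(all(fwd$start == 5000 - 75))
  expect_true(all(rev$start + rev$length - 1 == 5000 + 74))
})

test_that("zero reads and impossible configurations are handled", {
  p <- sim_params(genome_length = 1e4, n_reads = 0, seed = 1)
  tt <- truth_table(integer(0), character(0), numeric(0), 1e4)
  expect_equal(nrow(simulate_reads(tt, p)), 0)
  p2 <- sim_params(genome_length = 1e4, n_reads = 10,
                   background_fraction = 0, seed = 1)
  expect_error(simulate_reads(tt, p2), "empty truth")
})

test_that("pure background reads are uniform and strand-balanced", {
  p <- sim_params(genome_length = 1e5, n_reads = 1e5,
                  background_fraction = 1, seed = 4)
  tt <- truth_table(integer(0), character(0), numeric(0), 1e5)
  rd <- simulate_reads(tt, p)
  five <- ifelse(rd$strand == "+", rd$start, rd$start + rd$length - 1L)
  counts <- table(cut(five, breaks = seq(0, 1e5, length.out = 21),
                      include.lowest = TRUE))
  gof <- suppressWarnings(chisq.test(as.numeric(counts)))
  expect_gt(gof$p.value, 0.01)
  # strand balance within 4 binomial sd
  n <- nrow(rd)
  expect_lt(abs(sum(rd$strand == "+") - n / 2), 4 * sqrt(n / 4))
})

test_that("read-start densities mirror around an isolated stable dyad", {
  tt <- truth_table(dyad = 50000L, kind = "stable", sd = 3,
                    genome_length = 1e5)
  p <- sim_params(genome_length = 1e5, background_fraction = 0,
                  fragment_sd = 0, n_reads = 20000, seed = 5)
  rd <- simulate_reads(tt, p)
  is_rev <- rd$strand == "-"
  up <- 50000 - rd$start[!is_rev]                               # 75 - jitter
  down <- rd$start[is_rev] + rd$length[is_rev] - 1 - 50000      # 74 + jitter
  se <- 4 * 3 / sqrt(nrow(rd) / 2)
  expect_lt(abs(mean(up) - 75), se)
  expect_lt(abs(mean(down) - 74), se)
  expect_equal(sd(up), sd(down), tolerance = 0.1)
})
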