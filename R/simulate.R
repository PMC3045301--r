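# Strand-specific read simulator. A synthetic genome is tiled with chromatin
# features (stable nucleosomes, phased arrays, fuzzy regions, nucleosome-free
# regions); each nucleosome is a dyad plus a positional spread, emulating a
# population of cells in which positions are distributions rather than fixed
# points. Reads arise from ~150 bp fragments centred on a jittered dyad and
# are observed from one fragment 5' end, plus a uniform background fraction.

#' Simulation parameters
#'
#' All defaults are the package's declared study conditions. The feature mix
#' follows the relative feature-count proportions of large nucleosome
#' simulations (about one quarter stable single nucleosomes, a third phased
#' arrays, the rest fuzzy regions and short nucleosome-free gaps) and yields
#' roughly 100 stable dyads per Mb. Phased arrays place dyads every
#' `spacing` bp with a positional spread that starts at `phased_sd` and grows
#' by `phased_sd_growth` per nucleosome away from the array anchor (capped at
#' `phased_sd_max`), so phasing decays along the array.
#'
#' @param genome_length Genome length in bp.
#' @param weights Named non-negative weights over feature kinds
#'   `stable`, `phased`, `fuzzy`, `nfr`; normalised to sum to 1.
#' @param spacing Mean nucleosome spacing in bp (default 200).
#' @param footprint Nucleosome footprint in bp (147; informational).
#' @param stable_sd Positional spread (sd, bp) of stable dyads (default 5).
#' @param phased_sd,phased_sd_growth,phased_sd_max Spread model for phased
#'   arrays (defaults 10, +2 per dyad, cap 40).
#' @param fuzzy_sd Spread of fuzzy-region dyads (default 50).
#' @param feature_lengths Named lengths (bp) of one feature of each kind;
#'   `stable` defaults to `spacing`, `phased` and `fuzzy` to 5000, `nfr`
#'   to 120.
#' @param fragment_mean,fragment_sd Fragment length distribution
#'   (Normal(150, 10), rounded).
#' @param read_length Read length in bp (default 36).
#' @param background_fraction Fraction of reads drawn uniformly from the
#'   genome (default 0.2).
#' @param enrichment Named per-kind relative read enrichment per nucleosome
#'   (default equal).
#' @param n_reads Total number of reads to simulate.
#' @param chrom Chromosome name used in outputs (default `"sim"`).
#' @param seed Optional integer seed; all sampling is reproducible given it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(genome_length = 1e6,
                       weights = c(stable = 0.25, phased = 0.36,
                                   fuzzy = 0.14, nfr = 0.25),
                       spacing = 200,
                       footprint = 147,
                       stable_sd = 5,
                       phased_sd = 10, phased_sd_growth = 2,
                       phased_sd_max = 40,
                       fuzzy_sd = 50,
                       feature_lengths = NULL,
                       fragment_mean = 150, fragment_sd = 10,
                       read_length = 36,
                       background_fraction = 0.2,
                       enrichment = c(stable = 1, phased = 1, fuzzy = 1),
                       n_reads = 1e5,
                       chrom = "sim",
                       seed = NULL) {
  if (is.null(feature_lengths))
    feature_lengths <- c(stable = spacing, phased = 5000, fuzzy = 5000,
                         nfr = 120)
  kinds <- c("stable", "phased", "fuzzy", "nfr")
  if (!all(names(weights) %in% kinds)) stop("unknown feature kind in weights")
  w <- stats::setNames(numeric(4), kinds)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, sum > 0")
  w <- w / sum(w)
  stopifnot(genome_length > 0, spacing >= 1,
            stable_sd >= 0, phased_sd >= 0, fuzzy_sd >= 0,
            fragment_sd >= 0, read_length >= 1,
            background_fraction >= 0, background_fraction <= 1,
            n_reads >= 0)
  structure(list(genome_length = as.integer(genome_length), weights = w,
                 spacing = as.integer(spacing), footprint = footprint,
                 stable_sd = stable_sd, phased_sd = phased_sd,
                 phased_sd_growth = phased_sd_growth,
                 phased_sd_max = phased_sd_max, fuzzy_sd = fuzzy_sd,
                 feature_lengths = feature_lengths,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 read_length = as.integer(read_length),
                 background_fraction = background_fraction,
                 enrichment = enrichment, n_reads = as.integer(n_reads),
                 chrom = chrom, seed = seed),
            class = "sim_params")
}

#' Construct a truth table directly
#'
#' @param dyad Integer dyad positions (0-based).
#' @param kind Feature kind per dyad (`stable`, `phased` or `fuzzy`).
#' @param sd Per-dyad positional spread in bp.
#' @param genome_length Genome length for bounds checking.
#' @return Data.frame with columns `dyad`, `kind`, `sd`, `stable`.
#' @export
truth_table <- function(dyad, kind, sd, genome_length) {
  if (length(dyad)) {
    kind <- rep_len(kind, length(dyad))
    sd <- rep_len(sd, length(dyad))
  }
  if (length(dyad) && (any(dyad < 0) || any(dyad >= genome_length)))
    stop("dyads must lie within the genome")
  data.frame(dyad = as.integer(dyad), kind = as.character(kind),
             sd = as.numeric(sd), stable = kind == "stable",
             stringsAsFactors = FALSE)
}

#' Tile a genome with chromatin features
#'
#' Features are laid end-to-end, each kind drawn by weight, until no further
#' feature fits. Stable features hold one dyad at their centre; phased and
#' fuzzy regions hold dyads every `spacing` bp (first at `spacing / 2` into
#' the region); nucleosome-free regions hold none.
#'
#' @param params A [sim_params()] object.
#' @return List with `features` (data.frame `start`, `end`, `kind`; 0-based
#'   half-open) and `truth` (a [truth_table()]).
#' @export
simulate_features <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  flen <- params$feature_lengths
  active <- names(params$weights)[params$weights > 0]
  if (params$genome_length < min(flen[active]))
    stop("genome too short for a single feature")
  L <- params$genome_length
  spacing <- params$spacing
  # generous draw of feature kinds, then cut at the genome end
  n_guess <- ceiling(L / min(flen[active])) + 10L
  kinds <- sample(names(params$weights), n_guess, replace = TRUE,
                  prob = params$weights)
  ends <- cumsum(flen[kinds])
  n_fit <- sum(ends <= L)
  if (n_fit == 0) stop("genome too short for a single feature")
  kinds <- kinds[seq_len(n_fit)]
  starts <- c(0, ends[seq_len(n_fit)])[seq_len(n_fit)]
  feat <- data.frame(start = as.integer(starts),
                     end = as.integer(starts + flen[kinds]),
                     kind = kinds, stringsAsFactors = FALSE)
  dyads <- integer(0); dk <- character(0); dsd <- numeric(0)
  for (i in seq_len(nrow(feat))) {
    k <- feat$kind[i]
    if (k == "nfr") next
    if (k == "stable") {
      dyads <- c(dyads, feat$start[i] + (feat$end[i] - feat$start[i]) %/% 2L)
      dk <- c(dk, k); dsd <- c(dsd, params$stable_sd)
    } else {
      dd <- seq(feat$start[i] + spacing %/% 2L, feat$end[i] - 1L,
                by = spacing)
      dyads <- c(dyads, dd); dk <- c(dk, rep(k, length(dd)))
      if (k == "phased") {
        dsd <- c(dsd, pmin(params$phased_sd_max,
                           params$phased_sd +
                             (seq_along(dd) - 1) * params$phased_sd_growth))
      } else {
        dsd <- c(dsd, rep(params$fuzzy_sd, length(dd)))
      }
    }
  }
  list(features = feat,
       truth = truth_table(dyads, dk, dsd, L))
}

#' Simulate strand-specific reads from a truth table
#'
#' Each read is background with probability `background_fraction` (uniform 5'
#' start, fair-coin strand); otherwise a dyad is drawn (weighted by the
#' feature enrichment), jittered by its positional spread, a fragment length
#' is drawn from Normal(`fragment_mean`, `fragment_sd`) and rounded, the
#' fragment is centred on the jittered dyad (`right = c + floor((len-1)/2)`,
#' `left = right - len + 1`; for a 150 bp fragment `[c-75, c+74]`), and a
#' fair coin picks which fragment 5' end is read: the left end as a
#' forward-strand read or the right end as a reverse-strand read. Reads
#' falling off the genome are redrawn.
#'
#' @param truth A [truth_table()] (possibly from [simulate_features()]).
#' @param params A [sim_params()] object.
#' @return Data.frame of alignments (`chrom`, `strand`, `start` 0-based
#'   leftmost, `length`) plus `origin` (row index into `truth`, 0 for
#'   background).
#' @export
simulate_reads <- function(truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed + 1L)
  n <- params$n_reads
  L <- params$genome_length
  rl <- params$read_length
  if (n == 0)
    return(cbind(empty_alignments(), data.frame(origin = integer(0))))
  if (nrow(truth) == 0 && params$background_fraction < 1)
    stop("empty truth table: only background reads can be simulated ",
         "(set background_fraction = 1)")
  is_bg <- runif(n) < params$background_fraction
  n_bg <- sum(is_bg); n_sig <- n - n_bg
  out_start <- integer(n); out_strand <- character(n); origin <- integer(n)
  if (n_bg) {
    fwd <- runif(n_bg) < 0.5
    # uniform 5' start; leftmost differs by strand
    p5 <- sample.int(L, n_bg, replace = TRUE) - 1L
    left <- ifelse(fwd, p5, p5 - rl + 1L)
    redo <- which(left < 0L | left + rl > L)
    while (length(redo)) {
      p5r <- sample.int(L, length(redo), replace = TRUE) - 1L
      fwd[redo] <- runif(length(redo)) < 0.5
      left[redo] <- ifelse(fwd[redo], p5r, p5r - rl + 1L)
      redo <- redo[left[redo] < 0L | left[redo] + rl > L]
    }
    out_start[is_bg] <- left
    out_strand[is_bg] <- ifelse(fwd, "+", "-")
    origin[is_bg] <- 0L
  }
  if (n_sig) {
    prob <- params$enrichment[truth$kind]
    idx <- sample.int(nrow(truth), n_sig, replace = TRUE, prob = prob)
    draw <- function(k) {
      centre <- round(rnorm(length(k), truth$dyad[k], truth$sd[k]))
      flen <- pmax(rl, round(rnorm(length(k), params$fragment_mean,
                                       params$fragment_sd)))
      right <- centre + (flen - 1L) %/% 2L
      left <- right - flen + 1L
      fwd <- runif(length(k)) < 0.5
      list(left = ifelse(fwd, left, right - rl + 1L),
           frag_ok = left >= 0L & right < L, fwd = fwd)
    }
    d <- draw(idx)
    left <- d$left; fwd <- d$fwd
    bad <- which(!d$frag_ok | left < 0L | left + rl > L)
    iter <- 0L
    while (length(bad)) {
      iter <- iter + 1L
      if (iter > 1000L) stop("cannot place reads within the genome")
      d2 <- draw(idx[bad])
      left[bad] <- d2$left; fwd[bad] <- d2$fwd
      ok <- d2$frag_ok & d2$left >= 0L & d2$left + rl <= L
      bad <- bad[!ok]
    }
    out_start[!is_bg] <- left
    out_strand[!is_bg] <- ifelse(fwd, "+", "-")
    origin[!is_bg] <- idx
  }
  data.frame(chrom = params$chrom, strand = out_strand,
             start = as.integer(out_start), length = rl,
             origin = origin, stringsAsFactors = FALSE)
}

#' Run the simulator end to end
#'
#' @param params A [sim_params()] object.
#' @return List with `features`, `truth`, `reads` and `genome`
#'   (a `GenomeInfo`).
#' @export
simulate_experiment <- function(params) {
  fe <- simulate_features(params)
  reads <- simulate_reads(fe$truth, params)
  list(features = fe$features, truth = fe$truth, reads = reads,
       genome = genome_info(stats::setNames(params$genome_length,
                                            params$chrom)))
}

#' Write a truth table to TSV
#' @param truth A [truth_table()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a chromosome-sizes table
#' @param genome A `GenomeInfo` named vector.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), unname(genome)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
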