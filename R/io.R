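# Input/output: alignments, chromosome sizes, annotation anchors, and the
# conversion of alignments into per-strand read-5'-start count arrays.
#
# Internal coordinates are 0-based throughout; BED stays 0-based half-open at
# the boundary, GFF (1-based inclusive) is converted on read.

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length (bp).
#' @return Named integer vector of chromosome lengths (a `GenomeInfo`).
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  genome_info(stats::setNames(tab$length, tab$chrom))
}

#' Validate a named vector of chromosome lengths
#'
#' @param lengths Named numeric vector, one entry per chromosome.
#' @return The validated named integer vector.
#' @export
genome_info <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names")
  if (any(lengths <= 0))
    stop("chromosome lengths must be positive")
  stats::setNames(as.integer(lengths), names(lengths))
}

#' Load read alignments from BED or BAM
#'
#' Only chromosome, strand, 0-based leftmost position and alignment length are
#' retained. BED input must carry a strand in column 6. BAM input keeps
#' primary, mapped records only.
#'
#' @param path Path to a BED6 or BAM file.
#' @param format `"auto"` (by extension), `"bed"` or `"bam"`.
#' @param genome Optional `GenomeInfo`; records on chromosomes absent from it
#'   are reported via a warning and dropped.
#' @return A data.frame with columns `chrom`, `strand` (`"+"`/`"-"`), `start`
#'   (0-based leftmost) and `length`.
#' @export
load_alignments <- function(path, format = c("auto", "bed", "bam"),
                            genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (format == "bed") {
    if (file.size(path) == 0 || length(readLines(path, n = 1)) == 0) {
      aln <- empty_alignments()
    } else {
      gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                     error = function(e)
                       stop("failed to parse BED file '", path, "': ",
                            conditionMessage(e)))
      strand <- as.character(BiocGenerics::strand(gr))
      bad <- which(!strand %in% c("+", "-"))
      if (length(bad))
        stop("missing strand in BED record(s) ",
             paste(head(bad, 5), collapse = ", "), " of '", path, "'")
      aln <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = strand,
        start = BiocGenerics::start(gr) - 1L,
        length = BiocGenerics::width(gr),
        stringsAsFactors = FALSE)
    }
  } else {
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)
    par <- Rsamtools::ScanBamParam(
      what = c("rname", "strand", "pos", "qwidth"), flag = flags)
    rec <- Rsamtools::scanBam(path, param = par)[[1]]
    keep <- !is.na(rec$pos)
    aln <- data.frame(
      chrom = as.character(rec$rname)[keep],
      strand = as.character(rec$strand)[keep],
      start = rec$pos[keep] - 1L,
      length = rec$qwidth[keep],
      stringsAsFactors = FALSE)
  }
  if (nrow(aln) && (any(aln$start < 0) || any(aln$length <= 0)))
    stop("invalid alignment coordinates in '", path, "'")
  if (!is.null(genome) && nrow(aln)) {
    known <- aln$chrom %in% names(genome)
    if (any(!known)) {
      warning(sum(!known), " record(s) on chromosomes absent from the ",
              "genome table were skipped (",
              paste(unique(aln$chrom[!known]), collapse = ", "), ")")
      aln <- aln[known, , drop = FALSE]
    }
  }
  aln
}

empty_alignments <- function() {
  data.frame(chrom = character(), strand = character(),
             start = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Count read 5' starts per strand
#'
#' A forward-strand read contributes at its leftmost coordinate; a
#' reverse-strand read at its rightmost aligned coordinate
#' (`start + length - 1`), the fragment end sequencing actually observed.
#'
#' @param alignments Data.frame as returned by [load_alignments()].
#' @param genome `GenomeInfo` named vector of chromosome lengths.
#' @return A `strand_counts` object: per chromosome a list with integer
#'   vectors `fwd` and `rev` of length equal to the chromosome, plus counts of
#'   retained and skipped reads.
#' @export
read_starts <- function(alignments, genome) {
  genome <- genome_info(genome)
  known <- alignments$chrom %in% names(genome)
  if (any(!known)) {
    warning(sum(!known), " read(s) on unknown chromosomes skipped")
    alignments <- alignments[known, , drop = FALSE]
  }
  five <- ifelse(alignments$strand == "+",
                 alignments$start,
                 alignments$start + alignments$length - 1L)
  inb <- five >= 0L & five < genome[alignments$chrom]
  if (any(!inb)) {
    warning(sum(!inb), " read(s) with out-of-bounds 5' position skipped")
  }
  counts <- lapply(names(genome), function(ch) {
    sel <- inb & alignments$chrom == ch
    L <- genome[[ch]]
    list(fwd = tabulate(five[sel & alignments$strand == "+"] + 1L, L),
         rev = tabulate(five[sel & alignments$strand == "-"] + 1L, L))
  })
  names(counts) <- names(genome)
  structure(list(counts = counts, genome = genome,
                 n_reads = sum(inb), n_skipped = sum(!inb) + sum(!known)),
            class = "strand_counts")
}

#' @export
print.strand_counts <- function(x, ...) {
  cat("strand_counts:", length(x$counts), "chromosome(s),",
      x$n_reads, "reads retained,", x$n_skipped, "skipped\n")
  invisible(x)
}

#' Total retained reads in a strand_counts object
#' @param counts A `strand_counts` object.
#' @return Integer total of both strand arrays over all chromosomes.
#' @export
total_reads <- function(counts) {
  sum(vapply(counts$counts, function(x) sum(x$fwd) + sum(x$rev), numeric(1)))
}

#' Load TSS/TES anchors from a GFF3 file
#'
#' For forward-strand features the transcription start site is the feature
#' start and the end site the feature end; on the reverse strand the two are
#' swapped. Coordinates are converted to the internal 0-based convention.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param feature_types Character vector of feature types to keep
#'   (e.g. `"gene"`).
#' @return Data.frame with columns `chrom`, `position` (0-based), `strand`
#'   and `kind` (`"TSS"`/`"TES"`).
#' @export
load_anchors <- function(path, feature_types = "gene") {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  gr <- tryCatch(rtracklayer::import(path, format = "GFF"),
                 error = function(e)
                   stop("failed to parse GFF file '", path, "': ",
                        conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (!length(gr))
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  s0 <- BiocGenerics::start(gr) - 1L
  e0 <- BiocGenerics::end(gr) - 1L
  fwd <- strand == "+"
  out <- rbind(
    data.frame(chrom = chrom, position = ifelse(fwd, s0, e0),
               strand = strand, kind = "TSS", stringsAsFactors = FALSE),
    data.frame(chrom = chrom, position = ifelse(fwd, e0, s0),
               strand = strand, kind = "TES", stringsAsFactors = FALSE))
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Write alignments to a BED6 file
#'
#' @param alignments Data.frame with `chrom`, `strand`, `start` (0-based
#'   leftmost) and `length`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_reads_bed <- function(alignments, path) {
  bed <- data.frame(alignments$chrom,
                    alignments$start,
                    alignments$start + alignments$length,
                    sprintf("read_%d", seq_len(nrow(alignments))),
                    0L,
                    alignments$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse duplicate reads
#'
#' Keeps one read per (chromosome, strand, 5' position) triple. Duplicates
#' are kept by default elsewhere; this implements the opt-in deduplication.
#'
#' @param alignments Data.frame as returned by [load_alignments()].
#' @return The deduplicated data.frame.
#' @export
dedup_alignments <- function(alignments) {
  five <- ifelse(alignments$strand == "+", alignments$start,
                 alignments$start + alignments$length - 1L)
  alignments[!duplicated(data.frame(alignments$chrom, alignments$strand,
                                    five)), , drop = FALSE]
}
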