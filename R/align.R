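#' Build an exact-match index over both strands of a genome
#'
#' Wraps the genome together with precomputed reverse complements so that
#' repeated half placements avoid re-deriving the minus strand.  Minus
#' strand matches are reported in forward-strand coordinates.
#'
#' @param genome a loaded genome (`DNAStringSet` or FASTA path).
#' @param config an `rsw_config`.
#' @return an object of class `rsw_seed_index`.
#' @export
build_seed_index <- function(genome, config) {
  genome <- load_genome(genome)
  config <- validate_config(config)
  if (length(genome) == 0L) stop("empty genome")
  structure(list(
    genome = genome,
    revcomp = Biostrings::reverseComplement(genome),
    chrom_len = stats::setNames(Biostrings::width(genome), names(genome)),
    min_half = config$min_half
  ), class = "rsw_seed_index")
}

#' @export
print.rsw_seed_index <- function(x, ...) {
  cat(sprintf("exact-match index over %d chromosome(s), %d bp total\n",
              length(x$genome), sum(x$chrom_len)))
  invisible(x)
}

# All zero-mismatch occurrences of `seq` on both strands, as a data frame
# chrom/strand/start/end sorted by (chromosome file order, start, + first).
# N never matches.
exact_occurrences <- function(seq, index) {
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}: ", seq)
  m <- nchar(seq)
  if (grepl("N", seq, fixed = TRUE))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  pat <- Biostrings::DNAString(seq)
  rows <- vector("list", 2L * length(index$genome))
  k <- 0L
  for (ci in seq_along(index$genome)) {
    chrom <- names(index$genome)[ci]
    n <- index$chrom_len[[ci]]
    fwd <- Biostrings::start(Biostrings::matchPattern(pat, index$genome[[ci]]))
    if (length(fwd)) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom, strand = "+", start = fwd,
                              end = fwd + m - 1L, stringsAsFactors = FALSE)
    }
    # a hit at position p of the reverse-complemented chromosome is a minus
    # strand occurrence at forward coordinates [n - p - m + 2, n - p + 1]
    rcp <- Biostrings::start(Biostrings::matchPattern(pat, index$revcomp[[ci]]))
    if (length(rcp)) {
      st <- sort(n - rcp - m + 2L)
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom, strand = "-", start = st,
                              end = st + m - 1L, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(k)])
  ci <- match(out$chrom, names(index$genome))
  out[order(ci, out$start, out$strand), , drop = FALSE]
}

#' Place one split half on the genome with zero mismatches
#'
#' Finds every exact occurrence of `seq` on both strands.  A half with
#' more than `max_locations` occurrences is promiscuous: its status is
#' `"overflow"` and no hits are reported (mirroring an aligner's
#' discard-above-m behaviour).  Otherwise hits (at most `report_limit`)
#' are returned sorted by position, + strand before -.
#'
#' @param seq DNA string of the half (length >= `min_half`); N never matches.
#' @param index an `rsw_seed_index`.
#' @param config an `rsw_config`.
#' @return list with `status` (`"mapped"`, `"unmapped"` or `"overflow"`),
#'   `n_occurrences`, and `hits` (data frame `chrom`, `strand`, `start`,
#'   `end`).
#' @export
align_half <- function(seq, index, config) {
  config <- validate_config(config)
  occ <- exact_occurrences(seq, index)
  n <- nrow(occ)
  if (n == 0L)
    list(status = "unmapped", n_occurrences = 0L, hits = occ)
  else if (n > config$max_locations)
    list(status = "overflow", n_occurrences = n, hits = occ[0L, , drop = FALSE])
  else
    list(status = "mapped", n_occurrences = n,
         hits = utils::head(occ, config$report_limit))
}

#' Place every half of a split table on the genome
#'
#' Batch form of [align_half()]: each unique half sequence is placed once.
#'
#' @param splits data frame from [enumerate_splits_all()].
#' @param index an `rsw_seed_index`.
#' @param config an `rsw_config`.
#' @return list with `hits` (data frame `read_id`, `split_offset`, `side`,
#'   `chrom`, `strand`, `start`, `end`, mapped halves only) and `stats`
#'   (named counts of mapped / unmapped / overflow halves).
#' @export
align_halves <- function(splits, index, config) {
  config <- validate_config(config)
  halves <- data.frame(
    read_id = rep(splits$read_id, 2L),
    split_offset = rep(splits$split_offset, 2L),
    side = rep(c("left", "right"), each = nrow(splits)),
    seq = c(splits$left_seq, splits$right_seq),
    stringsAsFactors = FALSE
  )
  uniq <- unique(halves$seq)
  placed <- lapply(uniq, align_half, index = index, config = config)
  names(placed) <- uniq
  status <- vapply(placed, `[[`, "", "status")
  stats <- c(halves_total = nrow(halves),
             halves_mapped = sum(status[halves$seq] == "mapped"),
             halves_unmapped = sum(status[halves$seq] == "unmapped"),
             halves_overflow = sum(status[halves$seq] == "overflow"))
  rows <- lapply(which(status == "mapped"), function(u) {
    h <- placed[[u]]$hits
    idx <- which(halves$seq == uniq[u])
    do.call(rbind, lapply(idx, function(i)
      cbind(halves[i, c("read_id", "split_offset", "side"), drop = FALSE],
            h, row.names = NULL)))
  })
  hits <- do.call(rbind, c(rows, list(
    data.frame(read_id = character(), split_offset = integer(),
               side = character(), chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE))))
  rownames(hits) <- NULL
  list(hits = hits, stats = stats)
}

#' Emulate the first-pass alignment that defines the unmapped read set
#'
#' The pipeline's input is the set of reads that fail full-length
#' alignment against the expanded genome (reference plus exon-junction
#' library).  On synthetic, error-free data this pass is emulated by exact
#' full-length matching of each raw read, in either orientation, against
#' the genome and the junction library; reads with no placement (or
#' containing N) form the unmapped set.
#'
#' @param reads data frame `read_id`, `seq` (raw, untrimmed), optional `qual`.
#' @param genome a loaded genome.
#' @param junctions junction library `DNAStringSet` from
#'   [build_junction_library()] (may be empty).
#' @return logical vector: is each read unmapped?
#' @export
mark_unmapped <- function(reads, genome, junctions = Biostrings::DNAStringSet()) {
  if (nrow(reads) == 0L) return(logical(0))
  genome <- load_genome(genome)
  subject <- c(genome, junctions)
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  unmapped <- rep(TRUE, nrow(reads))
  ok <- which(!has_n)
  if (length(ok)) {
    widths <- nchar(reads$seq[ok])
    for (w in unique(widths)) {
      sel <- ok[widths == w]
      fw <- Biostrings::DNAStringSet(reads$seq[sel])
      counts <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(fw), subject)) +
        rowSums(Biostrings::vcountPDict(
          Biostrings::PDict(Biostrings::reverseComplement(fw)), subject))
      unmapped[sel] <- counts == 0L
    }
  }
  unmapped
}

#' Export split halves as FASTA for an external aligner
#'
#' Record names encode read id, split offset and side as
#' `read_id|offset|side`, the naming scheme [read_half_alignments()]
#' expects back.
#'
#' @param splits data frame from [enumerate_splits_all()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_halves_fasta <- function(splits, path) {
  seqs <- Biostrings::DNAStringSet(c(splits$left_seq, splits$right_seq))
  names(seqs) <- c(sprintf("%s|%d|left", splits$read_id, splits$split_offset),
                   sprintf("%s|%d|right", splits$read_id, splits$split_offset))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Ingest externally produced half alignments from SAM
#'
#' Drop-in replacement for the built-in placement step when halves were
#' aligned with an external zero-mismatch aligner.  Query names must
#' follow the `read_id|offset|side` scheme of [write_halves_fasta()].
#' Flags are interpreted minimally: the unmapped bit (0x4) and the strand
#' bit (0x10); POS is 1-based and the placement spans the query width.
#'
#' @param path path to a SAM file.
#' @return hits data frame in the layout of [align_halves()]'s `hits`.
#' @export
read_half_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "seq"))
  a <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !bitwAnd(a$flag, 4L) & !is.na(a$pos)
  qn <- strsplit(a$qname[keep], "|", fixed = TRUE)
  if (length(qn) && any(lengths(qn) != 3L))
    stop("SAM query names must encode read_id|offset|side")
  w <- Biostrings::width(a$seq)[keep]
  data.frame(
    read_id = vapply(qn, `[[`, "", 1L),
    split_offset = as.integer(vapply(qn, `[[`, "", 2L)),
    side = vapply(qn, `[[`, "", 3L),
    chrom = as.character(a$rname[keep]),
    strand = ifelse(bitwAnd(a$flag[keep], 16L) > 0L, "-", "+"),
    start = a$pos[keep],
    end = a$pos[keep] + w - 1L,
    stringsAsFactors = FALSE
  )
}
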