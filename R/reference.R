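#' Load a reference genome from FASTA
#'
#' Reads a multi-record FASTA into a named `DNAStringSet`, upper-cased.
#' Record order follows file order; names are the first whitespace-delimited
#' token of each header.
#'
#' @param path path to a FASTA file, or an already-loaded `DNAStringSet`
#'   (returned as-is after validation).
#' @return a named `DNAStringSet`, alphabet restricted to A, C, G, T, N.
#' @export
load_genome <- function(path) {
  if (methods::is(path, "DNAStringSet")) {
    genome <- path
  } else {
    genome <- Biostrings::readDNAStringSet(path, format = "fasta")
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome name(s) in genome: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  if (any(Biostrings::width(genome) == 0L))
    stop("empty genome record(s)")
  af <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  extra <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
  if (sum(extra) > 0L)
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(names(extra)[extra > 0], collapse = ", "))
  genome
}

#' Load gene models from a refFlat table
#'
#' refFlat is the tab-delimited UCSC gene-model dialect: geneName, name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds, with 0-based half-open coordinates and trailing-comma exon
#' lists.  Coordinates are converted to 1-based inclusive here, exactly
#' once; everything downstream is 1-based inclusive.
#'
#' @param path path to a refFlat file (no header).
#' @return a data frame of class `rsw_genes` with one row per transcript:
#'   `gene`, `tx`, `chrom`, `strand`, `tx_start`, `tx_end` and list columns
#'   `exon_starts`, `exon_ends` (1-based inclusive).
#' @export
load_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "integer",
                                          "integer", "integer", "integer",
                                          "character", "character"))
  names(tab) <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                  "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  parse_list <- function(s) lapply(strsplit(s, ",", fixed = TRUE),
                                   function(v) as.integer(v[nzchar(v)]))
  starts0 <- parse_list(tab$exonStarts)
  ends0 <- parse_list(tab$exonEnds)
  if (any(lengths(starts0) != tab$exonCount) ||
      any(lengths(ends0) != tab$exonCount))
    stop("exonCount disagrees with exonStarts/exonEnds list length")
  if (any(tab$txStart > tab$txEnd)) stop("txStart > txEnd")
  models <- data.frame(
    gene = tab$geneName, tx = tab$name, chrom = tab$chrom,
    strand = tab$strand,
    tx_start = tab$txStart + 1L, tx_end = tab$txEnd,
    stringsAsFactors = FALSE
  )
  # 0-based half-open -> 1-based inclusive: start+1, end unchanged
  models$exon_starts <- lapply(starts0, function(v) v + 1L)
  models$exon_ends <- ends0
  validate_gene_models(models)
}

#' Assemble a gene-model set from in-memory columns
#'
#' Used by the simulator and by tests; applies the same invariants as
#' [load_gene_models()].  All coordinates are 1-based inclusive.
#'
#' @param models data frame with columns `gene`, `tx`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` and list columns `exon_starts`, `exon_ends`.
#' @return the validated `rsw_genes` data frame.
#' @export
validate_gene_models <- function(models) {
  stopifnot(is.data.frame(models),
            all(c("gene", "tx", "chrom", "strand", "tx_start", "tx_end",
                  "exon_starts", "exon_ends") %in% names(models)))
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    if (length(s) < 1L) stop("transcript with no exons: ", models$tx[i])
    if (length(s) != length(e)) stop("exon start/end length mismatch: ", models$tx[i])
    if (any(e < s)) stop("exon end < start: ", models$tx[i])
    if (is.unsorted(s, strictly = TRUE) ||
        any(s[-1L] <= e[-length(e)]))
      stop("exons unsorted or overlapping: ", models$tx[i])
    if (s[1L] < models$tx_start[i] || e[length(e)] > models$tx_end[i])
      stop("exons outside transcript span: ", models$tx[i])
  }
  rownames(models) <- NULL
  class(models) <- c("rsw_genes", "data.frame")
  models
}

#' Write gene models as a refFlat table
#'
#' Inverse of [load_gene_models()]: internal 1-based inclusive coordinates
#' are emitted as refFlat's 0-based half-open dialect.
#'
#' @param models an `rsw_genes` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    paste(models$gene[i], models$tx[i], models$chrom[i], models$strand[i],
          models$tx_start[i] - 1L, models$tx_end[i],
          models$tx_start[i] - 1L, models$tx_end[i],
          length(s),
          paste0(paste(s - 1L, collapse = ","), ","),
          paste0(paste(e, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Derive the set of annotated introns from gene models
#'
#' Each pair of adjacent exons of a transcript contributes one intron
#' (donor exon end + 1 .. acceptor exon start - 1); introns shared by
#' several transcripts are stored once.  The index backs the novelty
#' filter: a candidate gap sitting within a small tolerance of an
#' annotated intron is not a novel splice.
#'
#' @param models an `rsw_genes` data frame.
#' @return data frame of class `rsw_introns`: `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive), deduplicated on (chrom, start, end).
#' @export
build_known_intron_index <- function(models) {
  rows <- lapply(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    n <- length(s)
    if (n < 2L) return(NULL)
    data.frame(chrom = models$chrom[i], strand = models$strand[i],
               start = e[-n] + 1L, end = s[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, c(rows, list(
    data.frame(chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE))))
  if (nrow(introns) && any(introns$end < introns$start))
    stop("zero-length intron implies abutting exons in input models")
  introns <- introns[!duplicated(introns[c("chrom", "start", "end")]), ,
                     drop = FALSE]
  introns <- introns[order(introns$chrom, introns$start, introns$end), ,
                     drop = FALSE]
  rownames(introns) <- NULL
  class(introns) <- c("rsw_introns", "data.frame")
  introns
}

#' Match intervals against annotated introns with a boundary tolerance
#'
#' An interval matches an intron when *both* of its boundaries lie within
#' `tolerance` bp of the corresponding intron boundary (start vs start,
#' end vs end), on the same chromosome; intron strand is ignored.
#'
#' @param introns an `rsw_introns` data frame.
#' @param chrom,start,end parallel vectors describing query intervals
#'   (1-based inclusive).
#' @param tolerance per-boundary tolerance in bp.
#' @return logical vector: does each query match some annotated intron?
#' @export
matches_known_intron <- function(introns, chrom, start, end, tolerance) {
  n <- length(start)
  if (n == 0L) return(logical(0))
  if (nrow(introns) == 0L) return(rep(FALSE, n))
  vapply(seq_len(n), function(i) {
    k <- introns$chrom == chrom[i] &
      abs(introns$start - start[i]) <= tolerance &
      abs(introns$end - end[i]) <= tolerance
    any(k)
  }, logical(1))
}

#' Build the exon-junction library
#'
#' For every adjacent-exon junction of every transcript, concatenates the
#' last `flank` bases of the upstream exon with the first `flank` bases of
#' the downstream exon, where `flank = read_length - 4` (flanks 4 nt
#' shorter than the raw read length, so a read must overhang a junction by
#' at least 4 nt to be caught by the library).  Flanks are truncated at
#' exon boundaries.  Sequences are emitted on the genome's + strand
#' regardless of transcript strand; the record name carries chrom, flank
#' coordinates and strand.
#'
#' @param models an `rsw_genes` data frame.
#' @param genome a loaded genome (`DNAStringSet`).
#' @param read_length raw (untrimmed) read length in nt.
#' @return a named `DNAStringSet` of junction sequences (possibly empty).
#' @export
build_junction_library <- function(models, genome, read_length) {
  flank <- as.integer(read_length) - 4L
  if (flank < 1L) stop("junction flank (read_length - 4) must be >= 1")
  seqs <- character(0)
  nms <- character(0)
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    n <- length(s)
    if (n < 2L) next
    chrom <- models$chrom[i]
    chr_seq <- genome[[chrom]]
    for (j in seq_len(n - 1L)) {
      up_start <- max(s[j], e[j] - flank + 1L)
      dn_end <- min(e[j + 1L], s[j + 1L] + flank - 1L)
      seq <- paste0(
        as.character(Biostrings::subseq(chr_seq, up_start, e[j])),
        as.character(Biostrings::subseq(chr_seq, s[j + 1L], dn_end))
      )
      seqs <- c(seqs, seq)
      nms <- c(nms, sprintf("%s:%d-%d|%d-%d(%s)", chrom, up_start, e[j],
                            s[j + 1L], dn_end, models$strand[i]))
    }
  }
  keep <- !duplicated(nms)
  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- nms[keep]
  out
}

#' Per-gene genomic spans
#'
#' Gene extent for the "same matched gene" pairing requirement: the union
#' span (min txStart .. max txEnd) of all transcripts sharing a gene
#' symbol on one chromosome.
#'
#' @param models an `rsw_genes` data frame.
#' @return data frame `gene`, `chrom`, `start`, `end`.
#' @export
gene_spans <- function(models) {
  if (nrow(models) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(models$gene, models$chrom, sep = "\r")
  start <- tapply(models$tx_start, key, min)
  end <- tapply(models$tx_end, key, max)
  parts <- strsplit(names(start), "\r", fixed = TRUE)
  out <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                    chrom = vapply(parts, `[[`, "", 2L),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
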