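#' Read single-end reads from FASTQ
#'
#' Sanger Phred+33 qualities are kept as strings alongside the sequence.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return data frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- data.frame(read_id = sub("\\s.*$", "", names(x)),
                    seq = unname(toupper(as.character(x))),
                    qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write reads to FASTQ
#'
#' @param reads data frame with `read_id`, `seq` and optionally `qual`
#'   (missing qualities are written as maximal, "I").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads) && !all(is.na(reads$qual))) reads$qual
          else strrep("I", nchar(reads$seq))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual),
               con, sep = "\n")
  invisible(path)
}

#' Trim the 3' end of each read
#'
#' Removes the last `trim_bases` bases (and quality characters) of every
#' read; trailing cycles carry the worst base quality on the platforms
#' this pipeline targets.
#'
#' @param reads data frame with `read_id`, `seq`, optional `qual`.
#' @param trim_bases number of bases to remove (default 2).
#' @return the trimmed data frame; read ids unchanged.
#' @export
trim_reads <- function(reads, trim_bases = 2L) {
  trim_bases <- as.integer(trim_bases)
  if (trim_bases == 0L) return(reads)
  len <- nchar(reads$seq)
  if (any(len <= trim_bases))
    stop("read(s) shorter than trim_bases + 1")
  reads$seq <- substr(reads$seq, 1L, len - trim_bases)
  if ("qual" %in% names(reads))
    reads$qual <- substr(reads$qual, 1L, len - trim_bases)
  reads
}

#' Enumerate every admissible left/right split of a read
#'
#' Cuts the (already trimmed) read at each consecutive offset so that both
#' halves respect the configured half-length bounds: one split per offset
#' in `min_half .. L - min_half` (clipped to `max_half` when the caller
#' narrows it), ordered by offset.  Enumeration depends only on the read
#' length, never on its content; halves containing N are enumerated and
#' simply find no exact placement downstream.
#'
#' @param read_id,seq identity and sequence of one trimmed read.
#' @param config an `rsw_config`.
#' @return data frame `read_id`, `split_offset` (left-half length),
#'   `left_seq`, `right_seq`; zero rows if the read admits no split.
#' @export
enumerate_splits <- function(read_id, seq, config) {
  config <- validate_config(config)
  L <- nchar(seq)
  if (L < 2L * config$min_half)
    stop(sprintf("read %s of length %d admits no split (min_half = %d)",
                 read_id, L, config$min_half))
  lo <- max(config$min_half, L - config$max_half)
  hi <- min(config$max_half, L - config$min_half)
  offs <- seq.int(lo, hi)
  data.frame(read_id = read_id, split_offset = offs,
             left_seq = substr(rep(seq, length(offs)), 1L, offs),
             right_seq = substr(rep(seq, length(offs)), offs + 1L, L),
             stringsAsFactors = FALSE)
}

#' Enumerate splits for a whole read set
#'
#' @param reads data frame with `read_id`, `seq` (trimmed).
#' @param config an `rsw_config`.
#' @return row-bound data frame of [enumerate_splits()] results.
#' @export
enumerate_splits_all <- function(reads, config) {
  config <- validate_config(config)
  if (nrow(reads) == 0L)
    return(data.frame(read_id = character(), split_offset = integer(),
                      left_seq = character(), right_seq = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(reads)), function(i)
    enumerate_splits(reads$read_id[i], reads$seq[i], config)))
}
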