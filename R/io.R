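candidate_tsv_cols <- c("rank", "gene", "chrom", "strand", "splice_length",
                        "region_start", "region_end", "n_support",
                        "n_support_control", "novel", "read_ids")

#' Write a candidate table as TSV
#'
#' Columns: rank, gene, chrom, strand, splice_length, region_start,
#' region_end, n_support, n_support_control, novel, read_ids (comma
#' joined).  Coordinates are 1-based inclusive, as everywhere in this
#' package.  Missing optional columns are written as NA.
#'
#' @param x an `rsw_report` or a candidate data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  cands <- if (inherits(x, "rsw_report")) x$candidates else x
  for (col in candidate_tsv_cols)
    if (!col %in% names(cands))
      cands[[col]] <- rep(if (col == "novel") TRUE else NA, nrow(cands))
  utils::write.table(cands[candidate_tsv_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' Round-trips all fields exactly.
#'
#' @param path TSV path.
#' @return candidate data frame.
#' @export
read_candidates <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = c(rank = "integer", gene = "character",
                                   chrom = "character", strand = "character",
                                   splice_length = "integer",
                                   region_start = "integer",
                                   region_end = "integer",
                                   n_support = "integer",
                                   n_support_control = "integer",
                                   novel = "logical", read_ids = "character"))
}

#' Export candidate regions as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention (start - 1, end unchanged).  Score is the read
#' support.
#'
#' @param x an `rsw_report` or a candidate data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cands <- if (inherits(x, "rsw_report")) x$candidates else x
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   cands$chrom, cands$region_start - 1L, cands$region_end,
                   paste0(cands$gene, "_len", cands$splice_length),
                   cands$n_support, cands$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Export supporting half alignments as a genome-browser custom track
#'
#' Writes a track header followed by one BED6 line per placed half of
#' each supporting pair.
#'
#' @param report an `rsw_report`.
#' @param path output path.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
write_custom_track <- function(report, path, name = "rsw_half_alignments") {
  p <- report$pairs[report$pairs$pass_min_gap, , drop = FALSE]
  lines <- c(sprintf('track name="%s" visibility=2', name),
             sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     rep(p$chrom, 2L),
                     c(p$left_start, p$right_start) - 1L,
                     c(p$left_end, p$right_end),
                     paste0(rep(p$read_id, 2L), "/",
                            rep(c("L", "R"), each = nrow(p))),
                     rep(p$strand, 2L)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration echo, input file digests, per-stage counts
#' and the package version as JSON.
#'
#' @param report an `rsw_report`.
#' @param path output path.
#' @param inputs named character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(report, path, inputs = character(0)) {
  digests <- if (length(inputs))
    as.list(stats::setNames(unname(tools::md5sum(inputs)), names(inputs)))
  else list()
  cfg <- report$config
  manifest <- list(
    tool = "rsw",
    version = as.character(utils::packageVersion("rsw")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    input_md5 = digests,
    stage_counts = as.list(report$stats),
    genome_digest = report$genome_digest
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
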