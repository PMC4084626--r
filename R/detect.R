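#' Detect candidate non-canonical spliced regions in one sample
#'
#' Runs the full read-split-walk over one read set: (optionally) emulate
#' the first-pass alignment that defines the unmapped set, trim, split
#' each unmapped read at every admissible offset, place the halves on the
#' genome with zero mismatches, pair and gap them, consolidate equal-gap
#' reads into regions, filter against annotated introns and by read
#' support, and rank by support.
#'
#' @param reads raw reads: a data frame (`read_id`, `seq`, optional
#'   `qual`) or a FASTQ path.
#' @param genome reference genome (`DNAStringSet` or FASTA path).
#' @param models gene models (`rsw_genes` or refFlat path).
#' @param config an `rsw_config`; its `read_length` must equal the
#'   trimmed length of the input reads.
#' @param phase1 if `TRUE` (default), reads placeable full-length on the
#'   expanded genome (reference + exon-junction library) are removed
#'   first, leaving the unmapped set; pass `FALSE` when `reads` already
#'   is an unmapped set (e.g. an external aligner's leftover FASTQ).
#' @param half_hits optional pre-computed half placements (from
#'   [read_half_alignments()]); skips the built-in placement step.
#' @return an object of class `rsw_report`: list with `candidates` (novel
#'   ranked candidates), `all_candidates`, `pairs`, `stats` (per-stage
#'   counts), `config`, and `genome_digest`.
#' @examples
#' sim <- simulate_rsw_fixture(seed = 1)
#' rep <- rsw_detect(sim$reads, sim$genome, sim$models, rsw_config(33))
#' rep
#' @export
rsw_detect <- function(reads, genome, models, config, phase1 = TRUE,
                       half_hits = NULL) {
  config <- validate_config(config)
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  genome <- load_genome(genome)
  if (is.character(models) && length(models) == 1L)
    models <- load_gene_models(models)
  stats <- c(reads_in = nrow(reads))

  if (phase1) {
    junctions <- build_junction_library(models, genome,
                                        config$read_length + config$trim_bases)
    unmapped <- mark_unmapped(reads, genome, junctions)
    reads <- reads[unmapped, , drop = FALSE]
  }
  stats <- c(stats, reads_unmapped = nrow(reads))

  reads <- trim_reads(reads, config$trim_bases)
  if (nrow(reads) && any(nchar(reads$seq) != config$read_length))
    stop("trimmed read length disagrees with config$read_length")

  if (is.null(half_hits)) {
    splits <- enumerate_splits_all(reads, config)
    index <- build_seed_index(genome, config)
    aligned <- align_halves(splits, index, config)
    hits <- aligned$hits
    stats <- c(stats, splits = nrow(splits), aligned$stats)
  } else {
    hits <- half_hits
    stats <- c(stats, splits = NA_integer_, halves_total = NA_integer_,
               halves_mapped = nrow(hits), halves_unmapped = NA_integer_,
               halves_overflow = NA_integer_)
  }

  pairs <- select_pairs(hits, models, config)
  stats <- c(stats, pairs = sum(pairs$pass_min_gap))
  cands <- consolidate_regions(pairs, config)
  introns <- build_known_intron_index(models)
  flt <- filter_candidates(cands, pairs, introns, config)
  stats <- c(stats, flt$stats)

  structure(list(candidates = flt$candidates,
                 all_candidates = flt$all_candidates,
                 pairs = pairs,
                 stats = stats,
                 config = config,
                 genome_digest = genome_digest(genome)),
            class = "rsw_report")
}

# order-sensitive digest of the reference the run was made against,
# used to refuse comparisons across different references
genome_digest <- function(genome) {
  lens <- Biostrings::width(genome)
  first <- substr(as.character(Biostrings::subseq(
    genome, 1L, pmin(lens, 64L))), 1L, 64L)
  paste(sprintf("%s:%d:%s", names(genome), lens, first), collapse = ";")
}

#' @export
print.rsw_report <- function(x, n = 10L, ...) {
  cat("read-split-walk report\n")
  st <- x$stats
  cat(sprintf("  reads in: %s   unmapped: %s   valid pairs: %s\n",
              st[["reads_in"]], st[["reads_unmapped"]], st[["pairs"]]))
  cat(sprintf("  regions: %s consolidated -> %s supported -> %s novel\n",
              st[["consolidated"]], st[["min_support"]], st[["novel"]]))
  if (nrow(x$candidates) == 0L) {
    cat("  no novel candidate spliced regions\n")
  } else {
    cat(sprintf("  top %d candidate(s):\n", min(n, nrow(x$candidates))))
    cols <- intersect(c("rank", "gene", "chrom", "strand", "splice_length",
                        "region_start", "region_end", "n_support",
                        "n_support_control"), names(x$candidates))
    print(utils::head(x$candidates[cols], n), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rsw_report <- function(object, ...) {
  out <- list(stats = object$stats,
              n_candidates = nrow(object$candidates),
              support = if (nrow(object$candidates))
                summary(object$candidates$n_support) else NULL,
              config = object$config)
  class(out) <- "summary.rsw_report"
  out
}

#' @export
print.summary.rsw_report <- function(x, ...) {
  cat("read-split-walk run summary\n\nstage counts:\n")
  print(x$stats)
  cat(sprintf("\nnovel candidates: %d\n", x$n_candidates))
  if (!is.null(x$support)) {
    cat("read support distribution:\n")
    print(x$support)
  }
  invisible(x)
}

#' Contrast a case run against a negative-control run
#'
#' Retains case candidates with no matching evidence in the control run.
#' Control evidence is consulted at the *pair* level (not only
#' consolidated control candidates), so even a single control read at the
#' same gap vetoes; a control match whose gap is shorter than the minimum
#' gap (splice length < 2 under defaults) does not veto, since such gaps
#' are split-point homology rather than splicing.  A control gap matches
#' when both its boundaries lie within `control_variance` bp of the case
#' region's boundaries.
#'
#' @param case,control `rsw_report` objects produced with identical
#'   configurations over the same reference.
#' @return an `rsw_report` whose candidates carry an added
#'   `n_support_control` column (distinct control reads at the matched
#'   locus; 0 for retained candidates unless the only matches were
#'   sub-minimum-gap).
#' @export
rsw_compare <- function(case, control) {
  stopifnot(inherits(case, "rsw_report"), inherits(control, "rsw_report"))
  if (!identical(case$genome_digest, control$genome_digest))
    stop("case and control runs were made against different references")
  cfg <- case$config
  cands <- case$candidates
  cp <- control$pairs
  veto <- logical(nrow(cands))
  ctrl_n <- integer(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    m <- cp[cp$chrom == cands$chrom[i] &
              abs(cp$gap_start - cands$region_start[i]) <= cfg$control_variance &
              abs(cp$gap_end - cands$region_end[i]) <= cfg$control_variance, ,
            drop = FALSE]
    real <- m[m$pass_min_gap, , drop = FALSE]
    veto[i] <- nrow(real) > 0L
    ctrl_n[i] <- length(unique(real$read_id))
  }
  cands$n_support_control <- ctrl_n
  kept <- rank_candidates(cands[!veto, , drop = FALSE])
  structure(list(candidates = kept,
                 all_candidates = cands,
                 pairs = case$pairs,
                 stats = c(case$stats, control_vetoed = sum(veto)),
                 config = cfg,
                 genome_digest = case$genome_digest),
            class = "rsw_report")
}

#' Intersect the candidate lists of two runs
#'
#' Keeps regions present in both runs (two treatments, or the two ends of
#' a paired-end dataset): candidates match when they lie in the same
#' gene, have identical splice length, and share at least one splice
#' boundary to within `control_variance` bp.
#'
#' @param a,b `rsw_report` objects over the same reference.
#' @return an `rsw_report` whose candidates are the matched pairs of
#'   regions, with support counts from both runs (`n_support`,
#'   `n_support_b`); ranking follows run `a`'s support.
#' @export
rsw_combine <- function(a, b) {
  stopifnot(inherits(a, "rsw_report"), inherits(b, "rsw_report"))
  if (!identical(a$genome_digest, b$genome_digest))
    stop("runs were made against different references")
  cfg <- a$config
  ca <- a$candidates
  cb <- b$candidates
  keep <- logical(nrow(ca))
  nb <- integer(nrow(ca))
  for (i in seq_len(nrow(ca))) {
    m <- cb[cb$gene == ca$gene[i] & cb$chrom == ca$chrom[i] &
              cb$splice_length == ca$splice_length[i] &
              (abs(cb$region_start - ca$region_start[i]) <= cfg$control_variance |
                 abs(cb$region_end - ca$region_end[i]) <= cfg$control_variance), ,
            drop = FALSE]
    keep[i] <- nrow(m) > 0L
    nb[i] <- if (nrow(m)) max(m$n_support) else 0L
  }
  ca$n_support_b <- nb
  kept <- rank_candidates(ca[keep, , drop = FALSE])
  structure(list(candidates = kept,
                 all_candidates = ca,
                 pairs = a$pairs,
                 stats = c(a$stats, combined = nrow(kept)),
                 config = cfg,
                 genome_digest = a$genome_digest),
            class = "rsw_report")
}
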