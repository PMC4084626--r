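#' Gap interval and splice length between two half placements
#'
#' The spliced region is the interval between the nearest ends of the two
#' halves: `gap_start = upstream_end + 1`, `gap_end = downstream_start - 1`,
#' and the splice length is the number of genomic bases strictly between
#' the halves, `gap_end - gap_start + 1`.  For the Xbp1 control geometry
#' (upstream half ending chr11:5424281, downstream half starting
#' chr11:5424308) this yields gap chr11:5424282-5424307, length 26.
#'
#' Vectorised over its arguments.
#'
#' @param upstream_end end coordinate of the half with lower genomic
#'   coordinates (1-based inclusive).
#' @param downstream_start start coordinate of the half with higher
#'   genomic coordinates; must exceed `upstream_end`.
#' @return data frame `gap_start`, `gap_end`, `splice_length`.  Adjacent
#'   halves give splice length 0 (rejected later by the minimum-gap rule).
#' @examples
#' compute_splice_length(5424281, 5424308)  # gap 5424282..5424307, length 26
#' @export
compute_splice_length <- function(upstream_end, downstream_start) {
  if (any(downstream_start <= upstream_end))
    stop("downstream_start must exceed upstream_end (inverted or overlapping placement)")
  gap_start <- as.integer(upstream_end) + 1L
  gap_end <- as.integer(downstream_start) - 1L
  data.frame(gap_start = gap_start, gap_end = gap_end,
             splice_length = gap_end - gap_start + 1L)
}

#' Select validly paired left/right placements for each read
#'
#' For every split of every read whose two halves both mapped, emits each
#' (left hit, right hit) combination that passes the pairing rules:
#' same chromosome; same strand; both halves overlap at least one common
#' gene; consistent orientation (on + the left half must lie upstream of
#' the right half, on - downstream; inverted placements are discarded);
#' nearest-end distance (the gap span) at most `max_distance`.  Pairs
#' whose gap is shorter than `min_gap` (0-1 bp under defaults -- likely
#' split-point homology, not splicing) are retained in the table with
#' `pass_min_gap = FALSE` so that downstream case/control comparison can
#' still consult them, but they never reach consolidation.
#'
#' @param hits half-placement data frame (from [align_halves()] or
#'   [read_half_alignments()]).
#' @param models an `rsw_genes` data frame (gene spans define "same gene").
#' @param config an `rsw_config`.
#' @return data frame of paired split alignments: `read_id`,
#'   `split_offset`, `chrom`, `strand`, `gene`, half coordinates,
#'   `gap_start`, `gap_end`, `splice_length`, `pass_min_gap`.
#' @export
select_pairs <- function(hits, models, config) {
  config <- validate_config(config)
  empty <- data.frame(read_id = character(), split_offset = integer(),
                      chrom = character(), strand = character(),
                      gene = character(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      gap_start = integer(), gap_end = integer(),
                      splice_length = integer(), pass_min_gap = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  spans <- gene_spans(models)
  left <- hits[hits$side == "left", , drop = FALSE]
  right <- hits[hits$side == "right", , drop = FALSE]
  key <- function(h) paste(h$read_id, h$split_offset, h$chrom, h$strand,
                           sep = "\r")
  # join left x right hits of the same read/split on chrom+strand
  lk <- key(left); rk <- key(right)
  ridx <- split(seq_len(nrow(right)), rk)
  rows <- vector("list", nrow(left))
  for (i in seq_len(nrow(left))) {
    js <- ridx[[lk[i]]]
    if (is.null(js)) next
    out <- vector("list", length(js))
    for (u in seq_along(js)) {
      j <- js[u]
      plus <- left$strand[i] == "+"
      up_end <- if (plus) left$end[i] else right$end[j]
      dn_start <- if (plus) right$start[j] else left$start[i]
      if (dn_start <= up_end) next  # inverted or overlapping placement
      gap <- compute_splice_length(up_end, dn_start)
      if (gap$splice_length > config$max_distance) next
      genes_l <- spans$gene[spans$chrom == left$chrom[i] &
                              spans$start <= left$end[i] &
                              spans$end >= left$start[i]]
      genes_r <- spans$gene[spans$chrom == right$chrom[j] &
                              spans$start <= right$end[j] &
                              spans$end >= right$start[j]]
      shared <- intersect(genes_l, genes_r)
      if (length(shared) == 0L) next
      out[[u]] <- data.frame(
        read_id = left$read_id[i], split_offset = left$split_offset[i],
        chrom = left$chrom[i], strand = left$strand[i],
        gene = sort(shared)[1L],
        left_start = left$start[i], left_end = left$end[i],
        right_start = right$start[j], right_end = right$end[j],
        gap_start = gap$gap_start, gap_end = gap$gap_end,
        splice_length = gap$splice_length,
        pass_min_gap = gap$splice_length >= config$min_gap,
        stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) rows[[i]] <- do.call(rbind, out)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  pairs[order(pairs$chrom, pairs$gap_start, pairs$gap_end, pairs$read_id,
              pairs$split_offset), , drop = FALSE]
}

#' Consolidate equal-gap paired reads into candidate spliced regions
#'
#' Pairs are grouped by (chromosome, strand, gene, splice length) and
#' clustered by single linkage on the gap start coordinate: two gaps join
#' one cluster when their starts differ by at most `slip_threshold`
#' (splice lengths being equal, end differences are identical).  Each
#' cluster becomes one candidate whose region runs from the smallest gap
#' start to the largest gap end of its members; support counts distinct
#' read ids (a read pairing twice into one cluster counts once, while a
#' read with valid pairings in two clusters supports both and is flagged
#' ambiguous).
#'
#' @param pairs data frame from [select_pairs()]; only rows with
#'   `pass_min_gap` are clustered.
#' @param config an `rsw_config`.
#' @return candidate data frame: `chrom`, `strand`, `gene`,
#'   `splice_length`, `region_start`, `region_end`, `n_support`,
#'   `read_ids` (comma-joined, sorted), `ambiguous_reads` (count of
#'   supporting reads shared with another cluster).
#' @export
consolidate_regions <- function(pairs, config) {
  config <- validate_config(config)
  empty <- data.frame(chrom = character(), strand = character(),
                      gene = character(), splice_length = integer(),
                      region_start = integer(), region_end = integer(),
                      n_support = integer(), read_ids = character(),
                      ambiguous_reads = integer(), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pass_min_gap, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  grp <- paste(pairs$chrom, pairs$strand, pairs$gene, pairs$splice_length,
               sep = "\r")
  rows <- lapply(split(seq_len(nrow(pairs)), grp), function(idx) {
    g <- pairs[idx, , drop = FALSE]
    g <- g[order(g$gap_start), , drop = FALSE]
    # 1-d single linkage: a new cluster starts where the sorted gap starts
    # jump by more than the slip threshold
    brk <- c(0L, cumsum(diff(g$gap_start) > config$slip_threshold))
    do.call(rbind, lapply(split(seq_len(nrow(g)), brk), function(ii) {
      cl <- g[ii, , drop = FALSE]
      ids <- sort(unique(cl$read_id))
      data.frame(chrom = cl$chrom[1L], strand = cl$strand[1L],
                 gene = cl$gene[1L], splice_length = cl$splice_length[1L],
                 region_start = min(cl$gap_start), region_end = max(cl$gap_end),
                 n_support = length(ids),
                 read_ids = paste(ids, collapse = ","),
                 ambiguous_reads = 0L, stringsAsFactors = FALSE)
    }))
  })
  cands <- do.call(rbind, rows)
  rownames(cands) <- NULL
  # reads supporting more than one cluster
  idlists <- strsplit(cands$read_ids, ",", fixed = TRUE)
  all_ids <- unlist(idlists)
  multi <- unique(all_ids[duplicated(all_ids)])
  cands$ambiguous_reads <- vapply(idlists, function(v)
    sum(v %in% multi), integer(1))
  cands[order(cands$chrom, cands$region_start, cands$region_end), ,
        drop = FALSE]
}

#' Apply the novelty and support filters to consolidated candidates
#'
#' A candidate is not novel when one of its supporting gap intervals has
#' both boundaries within `junction_proximity` bp of an annotated intron
#' (the splice is then an already-known junction, possibly boundary-
#' shifted by alignment slippage).  Candidates supported by fewer than
#' `min_support` distinct reads are dropped.  Per-stage counts are
#' recorded.
#'
#' @param cands candidate data frame from [consolidate_regions()].
#' @param pairs the pair table the candidates were built from (used to
#'   test each supporting gap against the intron index).
#' @param introns an `rsw_introns` data frame.
#' @param config an `rsw_config`.
#' @return list with `candidates` (novel, supported candidates, ranked),
#'   `all_candidates` (novelty-annotated, support-filtered superset
#'   including known regions), and `stats` (named stage counts).
#' @export
filter_candidates <- function(cands, pairs, introns, config) {
  config <- validate_config(config)
  n0 <- nrow(cands)
  if (n0 == 0L) {
    cands$novel <- logical(0)
    return(list(candidates = rank_candidates(cands),
                all_candidates = cands,
                stats = c(consolidated = 0L, min_support = 0L, novel = 0L)))
  }
  supported <- cands[cands$n_support >= config$min_support, , drop = FALSE]
  # a candidate is known if any supporting gap matches an annotated intron
  supported$novel <- vapply(seq_len(nrow(supported)), function(i) {
    ids <- strsplit(supported$read_ids[i], ",", fixed = TRUE)[[1L]]
    g <- pairs[pairs$pass_min_gap &
                 pairs$chrom == supported$chrom[i] &
                 pairs$strand == supported$strand[i] &
                 pairs$gene == supported$gene[i] &
                 pairs$splice_length == supported$splice_length[i] &
                 pairs$gap_start >= supported$region_start[i] &
                 pairs$gap_end <= supported$region_end[i] &
                 pairs$read_id %in% ids, , drop = FALSE]
    !any(matches_known_intron(introns, g$chrom, g$gap_start, g$gap_end,
                              config$junction_proximity))
  }, logical(1))
  novel <- supported[supported$novel, , drop = FALSE]
  list(candidates = rank_candidates(novel),
       all_candidates = supported,
       stats = c(consolidated = n0, min_support = nrow(supported),
                 novel = nrow(novel)))
}

#' Rank candidates by read support
#'
#' Descending support; ties broken by ascending splice length, then by
#' chromosome and region start -- a deterministic total order.
#'
#' @param cands candidate data frame.
#' @return the same data frame ordered, with a `rank` column (1 = top).
#' @export
rank_candidates <- function(cands) {
  ord <- order(-cands$n_support, cands$splice_length, cands$chrom,
               cands$region_start)
  cands <- cands[ord, , drop = FALSE]
  cands$rank <- seq_len(nrow(cands))
  rownames(cands) <- NULL
  cands
}
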