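# Independent oracles, pure base R (no Biostrings), used to cross-check the
# pipeline's search and selection code paths.

oracle_revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

# all exact occurrences of `q` on both strands of a genome given as a named
# character vector; overlapping occurrences included; N never matches
oracle_occurrences <- function(q, chroms) {
  m <- nchar(q)
  if (grepl("N", q, fixed = TRUE))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  rcq <- oracle_revcomp(q)
  rows <- list()
  for (chrom in names(chroms)) {
    s <- chroms[[chrom]]
    n <- nchar(s)
    if (n < m) next
    windows <- substring(s, 1:(n - m + 1L), m:n)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") q else rcq
      st <- which(windows == pat)
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, start = st, end = st + m - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  ci <- match(out$chrom, names(chroms))
  out <- out[order(ci, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# literal-rules re-implementation of the whole selection stage: enumerate
# every split placement by naive scan and apply the pairing, consolidation,
# novelty and support rules exactly as stated
oracle_pipeline <- function(unmapped_trimmed, chroms, models, introns, config) {
  L <- config$read_length
  span <- gene_spans(models)
  pairs <- list()
  for (r in seq_len(nrow(unmapped_trimmed))) {
    id <- unmapped_trimmed$read_id[r]
    seq <- unmapped_trimmed$seq[r]
    for (off in config$min_half:(L - config$min_half)) {
      lh <- substr(seq, 1L, off)
      rh <- substr(seq, off + 1L, L)
      locc <- oracle_occurrences(lh, chroms)
      rocc <- oracle_occurrences(rh, chroms)
      if (nrow(locc) == 0L || nrow(locc) > config$max_locations) next
      if (nrow(rocc) == 0L || nrow(rocc) > config$max_locations) next
      for (i in seq_len(nrow(locc))) for (j in seq_len(nrow(rocc))) {
        if (locc$chrom[i] != rocc$chrom[j]) next
        if (locc$strand[i] != rocc$strand[j]) next
        if (locc$strand[i] == "+") {
          up_end <- locc$end[i]; dn_start <- rocc$start[j]
        } else {
          up_end <- rocc$end[j]; dn_start <- locc$start[i]
        }
        if (dn_start <= up_end) next
        gap_start <- up_end + 1L; gap_end <- dn_start - 1L
        sl <- gap_end - gap_start + 1L
        if (sl > config$max_distance) next
        if (sl < config$min_gap) next
        gl <- span$gene[span$chrom == locc$chrom[i] &
                          span$start <= locc$end[i] & span$end >= locc$start[i]]
        gr <- span$gene[span$chrom == rocc$chrom[j] &
                          span$start <= rocc$end[j] & span$end >= rocc$start[j]]
        shared <- sort(intersect(gl, gr))
        if (!length(shared)) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          read_id = id, chrom = locc$chrom[i], strand = locc$strand[i],
          gene = shared[1L], gap_start = gap_start, gap_end = gap_end,
          splice_length = sl, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs)) return(NULL)
  p <- do.call(rbind, pairs)
  grp <- split(p, paste(p$chrom, p$strand, p$gene, p$splice_length, sep = "\r"))
  cands <- list()
  for (g in grp) {
    g <- g[order(g$gap_start), , drop = FALSE]
    cl <- cumsum(c(0L, diff(g$gap_start) > config$slip_threshold))
    for (cc in split(g, cl)) {
      ids <- sort(unique(cc$read_id))
      known <- any(vapply(seq_len(nrow(cc)), function(k)
        any(introns$chrom == cc$chrom[k] &
              abs(introns$start - cc$gap_start[k]) <= config$junction_proximity &
              abs(introns$end - cc$gap_end[k]) <= config$junction_proximity),
        logical(1)))
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = cc$chrom[1L], strand = cc$strand[1L], gene = cc$gene[1L],
        splice_length = cc$splice_length[1L],
        region_start = min(cc$gap_start), region_end = max(cc$gap_end),
        n_support = length(ids), read_ids = paste(ids, collapse = ","),
        novel = !known, stringsAsFactors = FALSE)
    }
  }
  cands <- do.call(rbind, cands)
  cands <- cands[cands$n_support >= config$min_support & cands$novel, ,
                 drop = FALSE]
  cands <- cands[order(-cands$n_support, cands$splice_length, cands$chrom,
                       cands$region_start), , drop = FALSE]
  rownames(cands) <- NULL
  cands
}

# naive first-pass emulation: a read maps iff it (or its reverse complement)
# is a substring of some chromosome or junction-library record
oracle_unmapped <- function(seqs, chroms, junction_seqs) {
  refs <- c(unname(chroms), unname(junction_seqs))
  vapply(seqs, function(s) {
    if (grepl("N", s, fixed = TRUE)) return(TRUE)
    pats <- c(s, oracle_revcomp(s))
    !any(vapply(refs, function(ref)
      any(grepl(pats[1L], ref, fixed = TRUE), grepl(pats[2L], ref, fixed = TRUE)),
      logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}
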