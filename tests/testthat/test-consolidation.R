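pair_row <- function(read_id, gap_start, gap_end, gene = "g1",
                     chrom = "chr1", strand = "+") {
  data.frame(read_id = read_id, split_offset = 15L, chrom = chrom,
             strand = strand, gene = gene,
             left_start = gap_start - 15L, left_end = gap_start - 1L,
             right_start = gap_end + 1L, right_end = gap_end + 18L,
             gap_start = gap_start, gap_end = gap_end,
             splice_length = gap_end - gap_start + 1L,
             pass_min_gap = TRUE, stringsAsFactors = FALSE)
}

test_that("equal-length gaps within the slip threshold merge to one region", {
  cfg <- rsw_config(33)  # slip 11
  p <- rbind(pair_row("r1", 100, 125), pair_row("r2", 107, 132))
  cands <- consolidate_regions(p, cfg)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$region_start, 100L)
  expect_equal(cands$region_end, 132L)
  expect_equal(cands$n_support, 2L)
  expect_equal(cands$read_ids, "r1,r2")
})

test_that("gaps beyond the slip threshold or of different length stay apart", {
  cfg <- rsw_config(33)
  p <- rbind(pair_row("r1", 100, 125), pair_row("r2", 120, 145))  # diff 20 > 11
  expect_equal(nrow(consolidate_regions(p, cfg)), 2L)
  # same starts, different splice length: separate groups
  p2 <- rbind(pair_row("r1", 100, 125), pair_row("r2", 100, 130))
  expect_equal(nrow(consolidate_regions(p2, cfg)), 2L)
  # chain linkage: 100, 110, 120 merge pairwise through neighbours
  p3 <- rbind(pair_row("r1", 100, 125), pair_row("r2", 110, 135),
              pair_row("r3", 120, 145))
  c3 <- consolidate_regions(p3, cfg)
  expect_equal(nrow(c3), 1L)
  expect_equal(c3$region_start, 100L)
  expect_equal(c3$region_end, 145L)
})

test_that("one read counts once per cluster but may support two clusters", {
  cfg <- rsw_config(33)
  p <- rbind(pair_row("r1", 100, 125), pair_row("r1", 103, 128),
             pair_row("r2", 105, 130))
  cands <- consolidate_regions(p, cfg)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$n_support, 2L)
  expect_equal(cands$ambiguous_reads, 0L)
  # r1 also pairs validly far away: it supports both clusters, flagged
  p2 <- rbind(p, pair_row("r1", 500, 525), pair_row("r3", 505, 530))
  c2 <- consolidate_regions(p2, cfg)
  expect_equal(nrow(c2), 2L)
  expect_equal(c2$n_support, c(2L, 2L))
  expect_equal(c2$ambiguous_reads, c(1L, 1L))
})

test_that("consolidation conserves reads and region bounds contain member gaps", {
  set.seed(8)
  cfg <- rsw_config(33)
  rows <- lapply(1:60, function(i)
    pair_row(sprintf("r%02d", sample(30, 1)), s <- sample(5000, 1), s + 25))
  p <- do.call(rbind, rows)
  cands <- consolidate_regions(p, cfg)
  expect_lte(sum(cands$n_support), length(unique(p$read_id)) +
               sum(cands$ambiguous_reads))
  for (i in seq_len(nrow(cands))) {
    members <- p[p$gap_start >= cands$region_start[i] &
                   p$gap_end <= cands$region_end[i], ]
    ids <- strsplit(cands$read_ids[i], ",")[[1]]
    expect_true(all(ids %in% members$read_id))
  }
  # every member gap lies inside its cluster's region by construction
  expect_true(all(cands$region_start <= cands$region_end))
})

test_that("known-junction candidates are flagged not novel; weak support drops", {
  cfg <- rsw_config(33)
  introns <- data.frame(chrom = "chr1", strand = "+",
                        start = 100L, end = 125L, stringsAsFactors = FALSE)
  class(introns) <- c("rsw_introns", "data.frame")
  p_known <- rbind(pair_row("r1", 100, 125), pair_row("r2", 103, 128))
  p_far <- rbind(pair_row("r3", 510, 535), pair_row("r4", 512, 537),
                 pair_row("r5", 514, 539))
  p_weak <- pair_row("r6", 900, 925)
  p <- rbind(p_known, p_far, p_weak)
  cands <- consolidate_regions(p, cfg)
  expect_equal(nrow(cands), 3L)
  flt <- filter_candidates(cands, p, introns, cfg)
  # known region excluded from novel set but kept, annotated, in the superset
  expect_equal(nrow(flt$candidates), 1L)
  expect_equal(flt$candidates$region_start, 510L)
  expect_equal(flt$all_candidates$novel,
               flt$all_candidates$region_start != 100L)
  expect_equal(unname(flt$stats), c(3L, 2L, 1L))
  # a candidate 10 bp away from the intron at both ends stays novel
  p10 <- rbind(pair_row("r7", 110, 135), pair_row("r8", 112, 137))
  f10 <- filter_candidates(consolidate_regions(p10, cfg), p10, introns, cfg)
  expect_equal(nrow(f10$candidates), 1L)
})

test_that("boundary-slipped members can reveal a known junction", {
  # the consensus gap matches an annotated intron but one slipped member
  # does not: any matching member marks the candidate known
  cfg <- rsw_config(33)
  introns <- data.frame(chrom = "chr1", strand = "+",
                        start = 200L, end = 225L, stringsAsFactors = FALSE)
  class(introns) <- c("rsw_introns", "data.frame")
  p <- rbind(pair_row("r1", 200, 225), pair_row("r2", 210, 235))
  flt <- filter_candidates(consolidate_regions(p, cfg), p, introns, cfg)
  expect_equal(nrow(flt$candidates), 0L)
})

test_that("ranking is by support, then splice length, then position", {
  cands <- data.frame(
    chrom = c("chr2", "chr1", "chr1", "chr2"), strand = "+",
    gene = c("a", "b", "c", "d"),
    splice_length = c(26L, 1797L, 26L, 26L),
    region_start = c(10L, 20L, 30L, 5L), region_end = c(40L, 1850L, 60L, 35L),
    n_support = c(21L, 4L, 4L, 4L), read_ids = "x", ambiguous_reads = 0L,
    stringsAsFactors = FALSE)
  r <- rank_candidates(cands)
  expect_equal(r$rank, 1:4)
  expect_equal(r$n_support, c(21L, 4L, 4L, 4L))
  # among the tied trio: splice length 26 before 1797, then chr1 before chr2
  expect_equal(r$gene, c("a", "c", "d", "b"))
  expect_equal(rank_candidates(cands[1, ])$rank, 1L)
})
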