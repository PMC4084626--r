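hit_row <- function(read_id, offset, side, chrom, strand, start, end) {
  data.frame(read_id = read_id, split_offset = offset, side = side,
             chrom = chrom, strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

# single-gene model spanning a wide interval, for pairing tests that place
# hits at arbitrary coordinates
wide_models <- function(chrom = "chr11", start = 5400001L, end = 5450000L,
                        gene = "Xbp1") {
  m <- data.frame(gene = gene, tx = paste0(gene, "_tx"), chrom = chrom,
                  strand = "+", tx_start = start, tx_end = end,
                  stringsAsFactors = FALSE)
  m$exon_starts <- list(start)
  m$exon_ends <- list(end)
  validate_gene_models(m)
}

test_that("the gap rule reproduces the Xbp1 control geometry", {
  g <- compute_splice_length(5424281, 5424308)
  expect_equal(g$gap_start, 5424282L)
  expect_equal(g$gap_end, 5424307L)
  expect_equal(g$splice_length, 26L)
  # single-base gap and adjacency
  expect_equal(compute_splice_length(100, 102)$splice_length, 1L)
  expect_equal(compute_splice_length(100, 101)$splice_length, 0L)
  expect_error(compute_splice_length(100, 100), "exceed")
  expect_error(compute_splice_length(100, 90), "exceed")
})

test_that("pair selection keeps the Xbp1-like geometry and computes its gap", {
  cfg <- rsw_config(33)
  hits <- rbind(
    hit_row("r1", 15, "left", "chr11", "+", 5424267, 5424281),
    hit_row("r1", 15, "right", "chr11", "+", 5424308, 5424325))
  p <- select_pairs(hits, wide_models(), cfg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene, "Xbp1")
  expect_equal(p$gap_start, 5424282L)
  expect_equal(p$gap_end, 5424307L)
  expect_equal(p$splice_length, 26L)
  expect_true(p$pass_min_gap)
})

test_that("pairs violating chromosome, strand, orientation or distance are dropped", {
  cfg <- rsw_config(33)
  models <- validate_gene_models(rbind(wide_models(), wide_models("chr12")))
  base_l <- hit_row("r1", 15, "left", "chr11", "+", 1000100, 1000114)
  # different chromosome
  p <- select_pairs(rbind(base_l,
                          hit_row("r1", 15, "right", "chr12", "+",
                                  1000200, 1000217)),
                    validate_gene_models(rbind(
                      wide_models("chr11", 1000001L, 1100000L, "g1"),
                      wide_models("chr12", 1000001L, 1100000L, "g1"))), cfg)
  expect_equal(nrow(p), 0L)
  m1 <- wide_models("chr11", 1000001L, 1100000L, "g1")
  # opposite strands
  p <- select_pairs(rbind(base_l, hit_row("r1", 15, "right", "chr11", "-",
                                          1000200, 1000217)), m1, cfg)
  expect_equal(nrow(p), 0L)
  # inverted orientation on +: right before left
  p <- select_pairs(rbind(base_l, hit_row("r1", 15, "right", "chr11", "+",
                                          999900, 999917)), m1, cfg)
  expect_equal(nrow(p), 0L)
  # beyond max_distance
  p <- select_pairs(rbind(base_l, hit_row("r1", 15, "right", "chr11", "+",
                                          1041000, 1041017)), m1, cfg)
  expect_equal(nrow(p), 0L)
  # no shared gene
  p <- select_pairs(rbind(base_l, hit_row("r1", 15, "right", "chr11", "+",
                                          1000200, 1000217)),
                    wide_models("chr11", 2000001L, 2100000L, "far"), cfg)
  expect_equal(nrow(p), 0L)
})

test_that("adjacent and single-base gaps fail the minimum-gap rule but stay tabled", {
  cfg <- rsw_config(33)
  m1 <- wide_models("chr11", 1000001L, 1100000L, "g1")
  for (gap in 0:1) {
    hits <- rbind(hit_row("r1", 15, "left", "chr11", "+", 1000100, 1000114),
                  hit_row("r1", 15, "right", "chr11", "+",
                          1000115 + gap, 1000132 + gap))
    p <- select_pairs(hits, m1, cfg)
    expect_equal(nrow(p), 1L)
    expect_equal(p$splice_length, gap)
    expect_false(p$pass_min_gap)
    expect_equal(nrow(consolidate_regions(p, cfg)), 0L)
  }
})

test_that("minus-strand pairs treat the left half as the downstream placement", {
  cfg <- rsw_config(33)
  m1 <- validate_gene_models(within(wide_models("chr11", 1000001L, 1100000L,
                                                "g1"), strand <- "-"))
  hits <- rbind(hit_row("r1", 15, "left", "chr11", "-", 1000200, 1000214),
                hit_row("r1", 15, "right", "chr11", "-", 1000100, 1000117))
  p <- select_pairs(hits, m1, cfg)
  expect_equal(nrow(p), 1L)
  expect_equal(p$gap_start, 1000118L)
  expect_equal(p$gap_end, 1000199L)
  expect_equal(p$splice_length, 82L)
  # the mirrored (inverted on -) arrangement is rejected
  hits_inv <- rbind(hit_row("r1", 15, "left", "chr11", "-", 1000100, 1000114),
                    hit_row("r1", 15, "right", "chr11", "-", 1000200, 1000217))
  expect_equal(nrow(select_pairs(hits_inv, m1, cfg)), 0L)
})

test_that("multi-location halves yield every admissible pair combination", {
  cfg <- rsw_config(33)
  m1 <- wide_models("chr11", 1000001L, 1100000L, "g1")
  hits <- rbind(hit_row("r1", 15, "left", "chr11", "+", 1000100, 1000114),
                hit_row("r1", 15, "right", "chr11", "+", 1000200, 1000217),
                hit_row("r1", 15, "right", "chr11", "+", 1000400, 1000417))
  p <- select_pairs(hits, m1, cfg)
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$gap_end), c(1000199L, 1000399L))
})
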