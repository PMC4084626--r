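test_that("exact placement finds forward, reverse and absent occurrences", {
  g <- Biostrings::DNAStringSet(c(chrT = "ACGTACGT"))
  cfg <- rsw_config(22, min_half = 4, junction_proximity = 4)
  idx <- build_seed_index(g, cfg)
  hit <- align_half("ACGT", idx, cfg)
  expect_equal(hit$status, "mapped")
  fw <- hit$hits[hit$hits$strand == "+", ]
  expect_equal(fw$start, c(1L, 5L))
  expect_equal(align_half("AAAA", idx, cfg)$status, "unmapped")
  # revcomp of a unique k-mer: one minus-strand hit at forward coordinates
  g2 <- Biostrings::DNAStringSet(c(chrT = "TTTTTACGTACCGGTTTTTT"))
  idx2 <- build_seed_index(g2, rsw_config(24, min_half = 12,
                                          junction_proximity = 5))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTACCGGTTT")))
  h <- align_half(rc, idx2, rsw_config(24, min_half = 12,
                                       junction_proximity = 5))
  expect_equal(h$status, "mapped")
  expect_equal(h$hits$strand, "-")
  expect_equal(h$hits$start, 6L)
  expect_equal(h$hits$end, 17L)
})

test_that("promiscuous halves overflow above max_locations and report no hits", {
  unit <- "GATTACAGATTA"
  g <- Biostrings::DNAStringSet(c(chrT = paste0(strrep(unit, 11), "CCCCCC")))
  cfg <- rsw_config(24, min_half = 12, junction_proximity = 5)
  idx <- build_seed_index(g, cfg)
  h <- align_half(unit, idx, cfg)
  expect_equal(h$status, "overflow")
  expect_equal(h$n_occurrences, 11L)
  expect_equal(nrow(h$hits), 0L)
  # exactly at the cap: still mapped
  g10 <- Biostrings::DNAStringSet(c(chrT = paste0(strrep(unit, 10), "CCCCCC")))
  h10 <- align_half(unit, build_seed_index(g10, cfg), cfg)
  expect_equal(h10$status, "mapped")
  expect_equal(nrow(h10$hits), 10L)
})

test_that("a single mismatch leaves a half unmapped and N never matches", {
  set.seed(3)
  chr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrT = chr))
  cfg <- rsw_config(33)
  idx <- build_seed_index(g, cfg)
  q <- substr(chr, 50, 65)
  expect_equal(align_half(q, idx, cfg)$status, "mapped")
  mm <- q
  substr(mm, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(q, 8, 8))[1]
  # if the mutated 16-mer happens to exist elsewhere this would map; it does not
  expect_equal(align_half(mm, idx, cfg)$status, "unmapped")
  qn <- q; substr(qn, 3, 3) <- "N"
  expect_equal(align_half(qn, idx, cfg)$status, "unmapped")
  expect_error(align_half("ACGTXACGTACG", idx, cfg), "outside")
})

test_that("hit sets equal the naive both-strand scan on random genomes", {
  set.seed(99)
  cfg <- rsw_config(33)
  for (rep in 1:8) {
    n <- sample(500:3000, 1)
    chroms <- c(chrA = paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = ""),
                chrB = paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                             collapse = ""))
    idx <- build_seed_index(Biostrings::DNAStringSet(chroms), cfg)
    for (k in 1:10) {
      m <- sample(c(6, 8, 11, 14), 1)
      q <- if (k %% 2 == 0) {
        st <- sample(n - m, 1)           # planted: guaranteed hits
        substr(chroms[["chrA"]], st, st + m - 1)
      } else paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                   collapse = "")
      got <- align_half(q, idx, cfg)
      want <- oracle_occurrences(q, chroms)
      if (nrow(want) > cfg$max_locations) {
        expect_equal(got$status, "overflow")
        expect_equal(got$n_occurrences, nrow(want))
      } else if (nrow(want) == 0) {
        expect_equal(got$status, "unmapped")
      } else {
        expect_equal(got$status, "mapped")
        expect_equal(got$hits, want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("batch half placement agrees with one-at-a-time placement", {
  set.seed(5)
  chr <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrQ = chr))
  cfg <- rsw_config(33)
  idx <- build_seed_index(g, cfg)
  starts <- sample(3900, 6)
  reads <- data.frame(read_id = sprintf("r%d", 1:6),
                      seq = substr(rep(chr, 6), starts, starts + 32),
                      stringsAsFactors = FALSE)
  splits <- enumerate_splits_all(reads, cfg)
  batch <- align_halves(splits, idx, cfg)
  for (i in sample(nrow(splits), 10)) {
    for (side in c("left", "right")) {
      seq <- if (side == "left") splits$left_seq[i] else splits$right_seq[i]
      single <- align_half(seq, idx, cfg)
      sub <- batch$hits[batch$hits$read_id == splits$read_id[i] &
                          batch$hits$split_offset == splits$split_offset[i] &
                          batch$hits$side == side, c("chrom", "strand",
                                                     "start", "end")]
      expect_equal(nrow(sub), nrow(single$hits))
      if (nrow(sub)) expect_equal(sub, single$hits, ignore_attr = TRUE)
    }
  }
  expect_equal(unname(batch$stats[["halves_total"]]), 2L * nrow(splits))
})

test_that("first-pass emulation separates junction and excision spanning reads", {
  g <- toy_genome()
  m <- toy_models()
  lib <- build_junction_library(m, g, 35L)
  chr <- as.character(g[["chr1"]])
  # read fully inside an exon: maps
  inside <- substr(chr, 110, 144)
  # read crossing alpha's first known junction with 10 nt overhang: in library
  junc <- paste0(substr(chr, 191, 200), substr(chr, 301, 325))
  # read spanning a fake 26 nt excision inside exon 3: maps nowhere
  exc <- paste0(substr(chr, 520, 539), substr(chr, 566, 580))
  # junction crosser with only 2 nt overhang: misses genome AND library
  stub <- paste0(substr(chr, 199, 200), substr(chr, 301, 333))
  reads <- data.frame(read_id = c("in", "junc", "exc", "stub"),
                      seq = c(inside, junc, exc, stub),
                      stringsAsFactors = FALSE)
  um <- mark_unmapped(reads, g, lib)
  expect_equal(um, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(um, oracle_unmapped(reads$seq, c(chr1 = chr),
                                   as.character(lib)))
})
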