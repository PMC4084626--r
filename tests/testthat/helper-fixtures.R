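# Shared in-code fixtures.  Expensive simulated runs are memoised so that
# several test files can reuse one computation within a test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a tiny hand-written two-gene reference used by unit tests
toy_models <- function() {
  m <- data.frame(
    gene = c("alpha", "beta"), tx = c("txA", "txB"),
    chrom = c("chr1", "chr1"), strand = c("+", "-"),
    tx_start = c(101L, 1001L), tx_end = c(700L, 1600L),
    stringsAsFactors = FALSE)
  m$exon_starts <- list(c(101L, 301L, 501L), c(1001L, 1401L))
  m$exon_ends <- list(c(200L, 400L, 700L), c(1200L, 1600L))
  validate_gene_models(m)
}

toy_genome <- function(seed = 7L) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")))
}

# the standard seeded case/control fixture (one 26 nt excision, penetrance
# 0.5, 50x coverage, 35 nt raw reads -> 33 nt trimmed)
std_fixture <- function() memo("std_fixture", simulate_rsw_fixture(seed = 1))

std_case_report <- function() memo("std_case", {
  s <- std_fixture()
  rsw_detect(s$reads, s$genome, s$models, s$config)
})

std_control_report <- function() memo("std_control", {
  s <- std_fixture()
  rsw_detect(s$control_reads, s$genome, s$models, s$config)
})

# fixture carrying the main excision plus three weakly penetrant ones, so
# that low-support candidates exist alongside the strong one
noise_fixture <- function() memo("noise_fixture", simulate_rsw_fixture(
  seed = 2, noise_genes = c(gene02 = 0.06, gene03 = 0.09, gene04 = 0.12)))

noise_report <- function() memo("noise_report", {
  s <- noise_fixture()
  rsw_detect(s$reads, s$genome, s$models, rsw_config(33, rng_seed = 2))
})
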