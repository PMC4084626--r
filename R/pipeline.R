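#' Run one pipeline subcommand end to end
#'
#' Orchestrates the file-level pipeline behind the command-line wrapper:
#'
#' * `detect`: FASTQ (+ genome FASTA + refFlat) -> candidate TSV, BED and
#'   a JSON run manifest.
#' * `compare`: a case and a control detect run (re-run here from their
#'   inputs) -> differential candidate TSV.
#' * `combine`: two detect runs -> intersection candidate TSV.
#' * `simulate`: write a seeded synthetic fixture bundle.
#' * `build-junctions`: refFlat + genome -> exon-junction library FASTA.
#'
#' All parameters are echoed to the manifest; re-running with identical
#' inputs and seeds reproduces identical outputs.
#'
#' @param subcommand one of `"detect"`, `"compare"`, `"combine"`,
#'   `"simulate"`, `"build-junctions"`.
#' @param config an `rsw_config`, or a path to a key=value config file
#'   (not needed for `simulate`).
#' @param fastq,fastq2 input reads (FASTQ); `fastq2` is the control or
#'   second-run input for `compare`/`combine`.
#' @param genome reference genome FASTA path.
#' @param models refFlat gene-model path.
#' @param out_dir output directory.
#' @param prefix file-name prefix for outputs.
#' @param phase1 emulate the first-pass alignment (see [rsw_detect()]).
#' @param read_length,seed simulate-only: raw read length and seed.
#' @return the resulting `rsw_report` (detect/compare/combine), the
#'   fixture file list (simulate), or the junction FASTA path
#'   (build-junctions), invisibly.
#' @export
run_pipeline <- function(subcommand = c("detect", "compare", "combine",
                                        "simulate", "build-junctions"),
                         config = NULL, fastq = NULL, fastq2 = NULL,
                         genome = NULL, models = NULL,
                         out_dir = ".", prefix = "rsw",
                         phase1 = TRUE, read_length = 35L, seed = 1L) {
  subcommand <- match.arg(subcommand)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_config(config)

  if (subcommand == "simulate") {
    fixture <- simulate_rsw_fixture(seed = seed, read_length = read_length)
    paths <- write_fixture(fixture, out_dir)
    return(invisible(paths))
  }

  stopifnot(!is.null(genome), !is.null(models))
  if (subcommand == "build-junctions") {
    g <- load_genome(genome)
    m <- load_gene_models(models)
    lib <- build_junction_library(m, g, read_length)
    path <- file.path(out_dir, paste0(prefix, "_junctions.fa"))
    Biostrings::writeXStringSet(lib, path)
    return(invisible(path))
  }

  stopifnot(!is.null(config), !is.null(fastq))
  report <- rsw_detect(fastq, genome, models, config, phase1 = phase1)

  if (subcommand %in% c("compare", "combine")) {
    stopifnot(!is.null(fastq2))
    other <- rsw_detect(fastq2, genome, models, config, phase1 = phase1)
    report <- if (subcommand == "compare") rsw_compare(report, other)
              else rsw_combine(report, other)
  }

  write_candidates(report, file.path(out_dir, paste0(prefix, "_candidates.tsv")))
  write_bed(report, file.path(out_dir, paste0(prefix, "_candidates.bed")))
  inputs <- Filter(function(p) is.character(p) && length(p) == 1L && file.exists(p),
                   list(fastq = fastq, fastq2 = fastq2, genome = genome,
                        models = models))
  write_manifest(report, file.path(out_dir, paste0(prefix, "_manifest.json")),
                 inputs = unlist(inputs))
  invisible(report)
}
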