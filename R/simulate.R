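# run code under a local, seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference: genome plus multi-exon gene models
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T; genes are placed
#' without overlap, alternating strand, each with `exons_per_gene` exons
#' separated by introns of at least 50 nt.  Deterministic for a fixed
#' seed.  Optionally plants tandem copies of one repeat unit in
#' intergenic space so that multi-mapping (overflow) behaviour can be
#' exercised.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in nt.
#' @param n_genes total number of genes (distributed round-robin over
#'   chromosomes).
#' @param exons_per_gene exons per transcript (1 gives intron-less models).
#' @param rng_seed integer seed.
#' @param exon_length,intron_length exon and intron sizes in nt
#'   (`intron_length` must be >= 50).
#' @param repeat_copies if positive, this many tandem copies of one
#'   random `repeat_unit` nt sequence are written into intergenic space
#'   of the first chromosome.
#' @param repeat_unit repeat unit length in nt.
#' @return list with `genome` (`DNAStringSet`) and `models` (`rsw_genes`).
#' @export
generate_reference <- function(n_chroms = 2L, chrom_length = 20000L,
                               n_genes = 6L, exons_per_gene = 3L,
                               rng_seed = 1L,
                               exon_length = 300L, intron_length = 120L,
                               repeat_copies = 0L, repeat_unit = 20L) {
  stopifnot(n_chroms >= 1L, chrom_length >= 1L, n_genes >= 0L,
            exons_per_gene >= 1L, intron_length >= 50L || exons_per_gene == 1L)
  gene_span <- exons_per_gene * exon_length +
    (exons_per_gene - 1L) * intron_length
  per_chrom <- ceiling(n_genes / n_chroms)
  margin <- 200L
  if (per_chrom * (gene_span + margin) + margin +
      (if (repeat_copies > 0L) repeat_copies * repeat_unit + margin else 0L) >
      chrom_length)
    stop("chromosomes too short to place the requested genes without overlap")
  with_seed(rng_seed, {
    genome <- Biostrings::DNAStringSet(
      vapply(seq_len(n_chroms), function(i) random_dna(chrom_length), ""))
    names(genome) <- sprintf("chr%s", LETTERS[seq_len(n_chroms)])
    rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      ci <- ((g - 1L) %% n_chroms) + 1L
      slot <- (g - 1L) %/% n_chroms
      tx_start <- margin + slot * (gene_span + margin) + 1L
      exon_starts <- tx_start + (seq_len(exons_per_gene) - 1L) *
        (exon_length + intron_length)
      rows[[g]] <- data.frame(
        gene = sprintf("gene%02d", g), tx = sprintf("tx%02d", g),
        chrom = names(genome)[ci],
        strand = if (g %% 2L == 1L) "+" else "-",
        tx_start = tx_start, tx_end = tx_start + gene_span - 1L,
        stringsAsFactors = FALSE)
      rows[[g]]$exon_starts <- list(exon_starts)
      rows[[g]]$exon_ends <- list(exon_starts + exon_length - 1L)
    }
    models <- if (n_genes > 0L) do.call(rbind, rows) else
      data.frame(gene = character(), tx = character(), chrom = character(),
                 strand = character(), tx_start = integer(),
                 tx_end = integer(),
                 exon_starts = I(list()), exon_ends = I(list()),
                 stringsAsFactors = FALSE)
    if (repeat_copies > 0L) {
      unit <- random_dna(repeat_unit)
      tract <- strrep(unit, repeat_copies)
      pos <- chrom_length - nchar(tract) - 10L
      s <- as.character(genome[[1L]])
      substr(s, pos, pos + nchar(tract) - 1L) <- tract
      genome[[1L]] <- Biostrings::DNAString(s)
      attr(models, "repeat_unit") <- unit
    }
    list(genome = genome, models = validate_gene_models(models))
  })
}

#' Plan implanted non-canonical excisions (the simulation ground truth)
#'
#' Each excision is placed strictly inside the widest exon of its gene,
#' centred, with at least `clearance` nt to either exon boundary -- so it
#' is non-canonical by construction and beyond the reach of the
#' known-junction novelty filter.
#'
#' @param models an `rsw_genes` data frame.
#' @param genes character vector of gene symbols to implant into.
#' @param excision_length excised interval length in nt (default 26, the
#'   Xbp1-like scenario).
#' @param penetrance fraction of the gene's transcripts carrying the
#'   excision, in (0, 1]; recycled over `genes`.
#' @param clearance minimum distance from the excision to the host exon's
#'   boundaries (default 20 nt).
#' @return data frame of class `rsw_truth`: `gene`, `chrom`, `strand`,
#'   `gap_start`, `gap_end`, `splice_length`, `penetrance`.
#' @export
plan_excisions <- function(models, genes, excision_length = 26L,
                           penetrance = 0.5, clearance = 20L) {
  stopifnot(all(genes %in% models$gene),
            all(penetrance > 0), all(penetrance <= 1))
  penetrance <- rep_len(penetrance, length(genes))
  rows <- lapply(seq_along(genes), function(k) {
    m <- models[models$gene == genes[k], , drop = FALSE][1L, ]
    widths <- m$exon_ends[[1L]] - m$exon_starts[[1L]] + 1L
    e <- which.max(widths)
    if (widths[e] < excision_length + 2L * clearance)
      stop("widest exon of ", genes[k], " too small for the excision")
    mid <- m$exon_starts[[1L]][e] + widths[e] %/% 2L
    gap_start <- mid - excision_length %/% 2L
    data.frame(gene = genes[k], chrom = m$chrom, strand = m$strand,
               gap_start = gap_start,
               gap_end = gap_start + excision_length - 1L,
               splice_length = excision_length,
               penetrance = penetrance[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rsw_truth", "data.frame")
  out
}

# mature (exon-joined, sense-strand) transcript sequence; if `drop` is a
# genomic interval c(start, end) inside one exon, it is excised first
mature_sequence <- function(genome, model, drop = NULL) {
  s <- model$exon_starts[[1L]]; e <- model$exon_ends[[1L]]
  if (!is.null(drop)) {
    host <- which(s <= drop[1L] & e >= drop[2L])
    if (length(host) != 1L)
      stop("excision does not lie inside a single exon")
    s <- append(s[-host], c(s[host], drop[2L] + 1L), after = host - 1L)
    e <- append(e[-host], c(drop[1L] - 1L, e[host]), after = host - 1L)
    o <- order(s); s <- s[o]; e <- e[o]
  }
  chr <- genome[[model$chrom]]
  seq <- paste(vapply(seq_along(s), function(i)
    as.character(Biostrings::subseq(chr, s[i], e[i])), ""), collapse = "")
  if (model$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

#' Simulate single-end reads from synthetic transcripts
#'
#' Reads are drawn uniformly along each mature (exon-joined) transcript.
#' For genes listed in the ground truth, a `penetrance` fraction of that
#' gene's reads comes from the excised (spliced) form of the transcript
#' instead.  Per-base substitution errors are optional; qualities are
#' written as Phred+33 "I".  Fully seeded: identical parameters and seed
#' give byte-identical output.
#'
#' @param genome synthetic genome (`DNAStringSet`).
#' @param models `rsw_genes` data frame.
#' @param truth `rsw_truth` from [plan_excisions()], or `NULL` for a
#'   splice-free (control-like) sample.
#' @param read_length raw read length in nt (default 35; reads are later
#'   trimmed by the pipeline's `trim_bases`).
#' @param coverage mean fold-coverage per transcript (default 50).
#' @param error_rate per-base substitution probability (default 0).
#' @param rng_seed integer seed.
#' @param orientation `"sense"` (default) emits reads on the transcript's
#'   sense strand; `"random"` flips each read to its reverse complement
#'   with probability 1/2.
#' @return list with `reads` (data frame `read_id`, `seq`, `qual`) and
#'   `provenance` (per-read template, gene and offset ground truth).
#' @export
simulate_reads <- function(genome, models, truth = NULL, read_length = 35L,
                           coverage = 50, error_rate = 0, rng_seed = 1L,
                           orientation = c("sense", "random")) {
  orientation <- match.arg(orientation)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  if (!is.null(truth) && nrow(truth) == 0L) truth <- NULL
  with_seed(rng_seed, {
    reads <- list(); prov <- list(); serial <- 0L
    for (i in seq_len(nrow(models))) {
      m <- models[i, , drop = FALSE]
      tx_un <- mature_sequence(genome, m)
      if (nchar(tx_un) < read_length)
        stop("read_length exceeds transcript length for ", m$tx)
      t_row <- if (!is.null(truth)) which(truth$gene == m$gene) else integer(0)
      n <- max(1L, as.integer(round(coverage * nchar(tx_un) / read_length)))
      n_spliced <- if (length(t_row))
        as.integer(round(truth$penetrance[t_row[1L]] * n)) else 0L
      templates <- list(unspliced = tx_un)
      counts <- c(unspliced = n - n_spliced)
      if (n_spliced > 0L) {
        templates$spliced <- mature_sequence(
          genome, m, drop = c(truth$gap_start[t_row[1L]],
                              truth$gap_end[t_row[1L]]))
        counts <- c(counts, spliced = n_spliced)
      }
      for (tmpl in names(templates)) {
        k <- counts[[tmpl]]
        if (k == 0L) next
        tseq <- templates[[tmpl]]
        starts <- sample.int(nchar(tseq) - read_length + 1L, k, replace = TRUE)
        seqs <- substr(rep(tseq, k), starts, starts + read_length - 1L)
        if (error_rate > 0) {
          for (r in seq_len(k)) {
            nerr <- stats::rbinom(1L, read_length, error_rate)
            if (nerr > 0L) {
              pos <- sample.int(read_length, nerr)
              for (p in pos) {
                cur <- substr(seqs[r], p, p)
                substr(seqs[r], p, p) <- sample(setdiff(c("A","C","G","T"), cur), 1L)
              }
            }
          }
        }
        if (orientation == "random") {
          flip <- stats::runif(k) < 0.5
          if (any(flip))
            seqs[flip] <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAStringSet(seqs[flip])))
        }
        ids <- sprintf("r%06d", serial + seq_len(k))
        serial <- serial + k
        reads[[length(reads) + 1L]] <- data.frame(
          read_id = ids, seq = seqs, qual = strrep("I", read_length),
          stringsAsFactors = FALSE)
        prov[[length(prov) + 1L]] <- data.frame(
          read_id = ids, gene = m$gene, tx = m$tx, template = tmpl,
          offset = starts, stringsAsFactors = FALSE)
      }
    }
    empty_reads <- data.frame(read_id = character(), seq = character(),
                              qual = character(), stringsAsFactors = FALSE)
    empty_prov <- data.frame(read_id = character(), gene = character(),
                             tx = character(), template = character(),
                             offset = integer(), stringsAsFactors = FALSE)
    list(reads = if (length(reads)) do.call(rbind, reads) else empty_reads,
         provenance = if (length(prov)) do.call(rbind, prov) else empty_prov)
  })
}

#' One-call synthetic case/control fixture
#'
#' Generates a reference, implants one Xbp1-like 26 nt mid-exon excision
#' at the given penetrance, and simulates a case sample (carrying the
#' excision) plus a control sample (penetrance effectively 0: no spliced
#' transcripts).  The scenario mirrors a splice-competent heterozygote
#' against a splice-incompetent knockout.
#'
#' @param seed integer seed driving every random choice.
#' @param excision_length excised length in nt (default 26).
#' @param penetrance fraction of target-gene transcripts spliced (default 0.5).
#' @param coverage fold-coverage (default 50).
#' @param read_length raw read length (default 35 -> 33 after trimming).
#' @param error_rate per-base substitution probability (default 0).
#' @param noise_genes optional named numeric vector of additional
#'   excisions: names are gene symbols, values their penetrance (used to
#'   build fixtures with low-support candidates).
#' @param ... passed to [generate_reference()].
#' @return list: `genome`, `models`, `truth`, `reads` (case),
#'   `control_reads`, `provenance`, `config` (a matching `rsw_config`).
#' @export
simulate_rsw_fixture <- function(seed = 1L, excision_length = 26L,
                                 penetrance = 0.5, coverage = 50,
                                 read_length = 35L, error_rate = 0,
                                 noise_genes = NULL, ...) {
  ref <- generate_reference(rng_seed = seed, ...)
  target <- ref$models$gene[1L]
  genes <- c(target, names(noise_genes))
  pens <- c(penetrance, unname(noise_genes))
  truth <- plan_excisions(ref$models, genes, excision_length = excision_length,
                          penetrance = pens)
  case <- simulate_reads(ref$genome, ref$models, truth,
                         read_length = read_length, coverage = coverage,
                         error_rate = error_rate, rng_seed = seed + 1L)
  ctrl <- simulate_reads(ref$genome, ref$models, truth = NULL,
                         read_length = read_length, coverage = coverage,
                         error_rate = error_rate, rng_seed = seed + 2L)
  cfg <- rsw_config(read_length - 2L, rng_seed = seed)
  list(genome = ref$genome, models = ref$models, truth = truth,
       reads = case$reads, control_reads = ctrl$reads,
       provenance = case$provenance, config = cfg)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits genome FASTA, refFlat gene models, case and control FASTQ, and
#' the ground-truth table as plain text files consumed unchanged by the
#' command-line pipeline.
#'
#' @param fixture a list from [simulate_rsw_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             models = file.path(dir, "genes.refflat"),
             case = file.path(dir, "case.fastq"),
             control = file.path(dir, "control.fastq"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(fixture$genome, paths[["genome"]])
  write_refflat(fixture$models, paths[["models"]])
  write_fastq(fixture$reads, paths[["case"]])
  write_fastq(fixture$control_reads, paths[["control"]])
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
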