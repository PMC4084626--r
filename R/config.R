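#' Run configuration for the read-split-walk pipeline
#'
#' Collects every tunable parameter of the pipeline and derives the
#' length-dependent defaults.  `read_length` is the read length *after*
#' trimming (e.g. 35 nt raw reads trimmed by 2 give `read_length = 33`).
#'
#' Derived defaults:
#' * `max_half = read_length - min_half`, so that the left/right halves
#'   sweep every admissible cut (11..22 for 33 nt reads, 11..66 for 77 nt
#'   reads).  Runs that bound both halves by thirds of the read (99 nt
#'   reads with halves 33..66) are obtained by overriding `min_half = 33`.
#' * `slip_threshold` — the maximum boundary slippage tolerated when
#'   consolidating equal-length gaps — defaults to 11 for 33 nt reads and
#'   27 for 77 nt reads (the two calibrated values); any other read length
#'   falls back to `round(read_length / 3)`.
#' * `junction_flank = read_length + trim_bases - 4`: the exon-junction
#'   library carries flanks 4 nt shorter than the *raw* read length.
#'
#' @param read_length trimmed read length in nt.
#' @param trim_bases number of 3' bases removed from each raw read (default 2).
#' @param min_half minimum length of either half of a split (default 11).
#' @param max_half maximum length of either half (default `read_length - min_half`).
#' @param max_mismatches_halves mismatches allowed when placing halves
#'   (default 0; the zero-mismatch contract is what makes the walk specific).
#' @param max_locations a half mapping to more than this many genomic
#'   locations is discarded as promiscuous (default 10).
#' @param report_limit cap on reported placements per half (default 11;
#'   the overflow rule at `max_locations` triggers first under defaults).
#' @param max_distance maximum nearest-end distance (gap span) between the
#'   two halves, in bp (default 40000, the rodent-scale intron bound; use
#'   50000 for human).
#' @param min_gap minimum gap length in bp for a pair to count as spliced
#'   (default 2; 0-1 bp gaps arise from sequence homology at the cut).
#' @param slip_threshold consolidation slippage tolerance in bp (see above).
#' @param junction_proximity candidates with both gap boundaries within this
#'   many bp of an annotated intron are not novel (default 5).
#' @param min_support minimum number of distinct supporting reads (default 2).
#' @param control_variance boundary tolerance in bp when matching regions
#'   between two runs (case vs control, or two treatments; default 5).
#' @param junction_flank flank width of the exon-junction library (see above).
#' @param rng_seed optional integer seed recorded in the config and used by
#'   operations that draw random numbers.
#'
#' @return An object of class `rsw_config` (a named list).
#' @examples
#' rsw_config(33)                 # 35 nt raw reads
#' rsw_config(99, min_half = 33)  # 101 nt paired-end data, per-end runs
#' @export
rsw_config <- function(read_length,
                       trim_bases = 2L,
                       min_half = 11L,
                       max_half = NULL,
                       max_mismatches_halves = 0L,
                       max_locations = 10L,
                       report_limit = 11L,
                       max_distance = 40000L,
                       min_gap = 2L,
                       slip_threshold = NULL,
                       junction_proximity = 5L,
                       min_support = 2L,
                       control_variance = 5L,
                       junction_flank = NULL,
                       rng_seed = NULL) {
  cfg <- list(
    read_length = as.integer(read_length),
    trim_bases = as.integer(trim_bases),
    min_half = as.integer(min_half),
    max_half = if (is.null(max_half)) NULL else as.integer(max_half),
    max_mismatches_halves = as.integer(max_mismatches_halves),
    max_locations = as.integer(max_locations),
    report_limit = as.integer(report_limit),
    max_distance = as.integer(max_distance),
    min_gap = as.integer(min_gap),
    slip_threshold = if (is.null(slip_threshold)) NULL else as.integer(slip_threshold),
    junction_proximity = as.integer(junction_proximity),
    min_support = as.integer(min_support),
    control_variance = as.integer(control_variance),
    junction_flank = if (is.null(junction_flank)) NULL else as.integer(junction_flank),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  class(cfg) <- "rsw_config"
  validate_config(cfg)
}

#' Validate a run configuration and fill derived defaults
#'
#' Idempotent: validating an already-validated configuration returns it
#' unchanged.
#'
#' @param config an `rsw_config` or a named list of the same fields.
#' @return the validated `rsw_config` with `max_half`, `slip_threshold` and
#'   `junction_flank` filled in.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "rsw_config")) {
    config <- do.call(rsw_config, config)
    return(config)
  }
  cfg <- config
  L <- cfg$read_length
  if (is.na(L) || L < 2L)
    stop("read_length must be a positive integer >= 2")
  if (cfg$min_half < 1L)
    stop("min_half must be >= 1")
  if (2L * cfg$min_half > L)
    stop(sprintf("2*min_half (%d) exceeds read_length (%d): no split admissible",
                 2L * cfg$min_half, L))
  if (is.null(cfg$max_half)) cfg$max_half <- L - cfg$min_half
  if (cfg$max_half + cfg$min_half > L)
    stop("min_half + max_half exceeds read_length")
  if (is.null(cfg$slip_threshold)) {
    cfg$slip_threshold <- if (L == 33L) 11L else if (L == 77L) 27L
                          else as.integer(round(L / 3))
  }
  if (is.null(cfg$junction_flank)) cfg$junction_flank <- L + cfg$trim_bases - 4L
  if (cfg$junction_flank < 1L)
    stop("junction_flank must be >= 1")
  for (f in c("trim_bases", "max_mismatches_halves", "max_locations",
              "report_limit", "max_distance", "min_gap", "slip_threshold",
              "junction_proximity", "min_support", "control_variance"))
    if (cfg[[f]] < 0L) stop(sprintf("%s must be non-negative", f))
  if (cfg$junction_proximity > cfg$min_half)
    stop("junction_proximity must not exceed min_half")
  cfg
}

#' @export
print.rsw_config <- function(x, ...) {
  cat("read-split-walk configuration\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", f, if (is.null(v)) "<unset>" else format(v)))
  }
  invisible(x)
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#' Keys mirror the arguments of [rsw_config()].
#'
#' @param path path to the configuration file.
#' @return validated `rsw_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(rsw_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(args) <- keys
  do.call(rsw_config, args)
}

#' Write a configuration as a flat key=value file
#'
#' @param config an `rsw_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     vapply(config[keep], format, "")), path)
  invisible(path)
}
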