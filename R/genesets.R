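#' Z-score transform a binned ChIP coverage track
#'
#' Stabilises binned coverage with `log2(x + 1)` (optional) and standardises
#' over all bins, so enrichment is expressed in track-wide standard
#' deviations.
#'
#' @param x Numeric vector of binned coverage values.
#' @param log_transform Apply `log2(x + 1)` before standardising
#'   (default TRUE).
#' @return A `chip_track` list: `z` (per-bin z-scores), `mean`, `sd`,
#'   `log_transform`.
#' @export
zscore_track <- function(x, log_transform = TRUE) {
  x <- as.numeric(x)
  if (sum(is.finite(x)) < 2) stop("need at least two finite coverage bins")
  y <- if (log_transform) log2(x + 1) else x
  mu <- mean(y, na.rm = TRUE)
  s <- stats::sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero variance: z-scores are undefined")
  structure(list(z = (y - mu) / s, mean = mu, sd = s,
                 log_transform = log_transform),
            class = "chip_track")
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"))
}

#' Classify promoter activity from ChIP evidence
#'
#' A gene is called active when a ChIP peak overlaps its promoter window
#' `[TSS - window, TSS + window]`, or when the mean coverage z-score over the
#' window reaches `z_min`; otherwise inactive. Genes with no covering
#' evidence (no peak set given and no coverage bins overlapping the window)
#' are left `unknown` and reported via `message()`.
#'
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and optionally `class`.
#' @param peaks Optional peak set: data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param coverage Optional binned coverage: data.frame with `chrom`, `start`,
#'   `end`, `score` (raw counts; z-scored internally via [zscore_track()]).
#' @param promoter_window Half-width of the promoter window, bp (default 100).
#' @param z_min Z-score threshold for activity (default 1.64, one-sided 5%).
#' @param log_transform Passed to [zscore_track()].
#' @return `genes` with added columns `activity`
#'   (`active`/`inactive`/`unknown`) and `promoter_z` (mean window z-score or
#'   NA).
#' @export
classify_activity <- function(genes, peaks = NULL, coverage = NULL,
                              promoter_window = 100, z_min = 1.64,
                              log_transform = TRUE) {
  stopifnot(all(c("id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (is.null(peaks) && is.null(coverage)) {
    stop("need peak or coverage evidence to classify activity")
  }
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  win <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(0L, tss - promoter_window) + 1L,
                              end = tss + promoter_window + 1L))
  peak_hit <- rep(FALSE, nrow(genes))
  if (!is.null(peaks) && nrow(peaks)) {
    pg <- GenomicRanges::GRanges(
      seqnames = peaks$chrom,
      ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    peak_hit <- GenomicRanges::countOverlaps(win, pg) > 0
  }
  mean_z <- rep(NA_real_, nrow(genes))
  covered <- rep(!is.null(peaks), nrow(genes))
  if (!is.null(coverage) && nrow(coverage)) {
    zt <- zscore_track(coverage$score, log_transform = log_transform)
    cg <- GenomicRanges::GRanges(
      seqnames = coverage$chrom,
      ranges = IRanges::IRanges(start = coverage$start + 1L,
                                end = coverage$end))
    ov <- GenomicRanges::findOverlaps(win, cg)
    if (length(ov)) {
      agg <- tapply(zt$z[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), mean)
      mean_z[as.integer(names(agg))] <- agg
    }
    covered <- covered | !is.na(mean_z)
  }
  activity <- ifelse(!covered, "unknown",
                     ifelse(peak_hit | (!is.na(mean_z) & mean_z >= z_min),
                            "active", "inactive"))
  if (any(activity == "unknown")) {
    message("classify_activity: ", sum(activity == "unknown"),
            " gene(s) outside the coverage track left 'unknown'")
  }
  genes$activity <- activity
  genes$promoter_z <- mean_z
  genes
}

#' Select short genes and a size-matched seeded random control set
#'
#' Subsets genes strictly shorter than `max_len` bp (e.g. pol II genes
#' shorter than 100 bp, whose promoter chromatin can be compared against
#' length-unselected genes) and draws an equally sized uniform random control
#' set from the remaining genes, reproducibly for a fixed seed.
#'
#' @param genes data.frame with `start` and `end` (0-based half-open) or a
#'   `length_bp` column.
#' @param max_len Strict length bound, bp (default 100).
#' @param seed Integer seed for the control draw.
#' @return List with `short`, `control` (both data.frames) and `seed`.
#' @export
select_short_genes <- function(genes, max_len = 100, seed = 1) {
  len <- if ("length_bp" %in% names(genes)) genes$length_bp else genes$end - genes$start
  sel <- len < max_len
  short <- genes[sel, , drop = FALSE]
  rest <- genes[!sel, , drop = FALSE]
  if (nrow(rest) < nrow(short)) {
    stop("complement (", nrow(rest), ") smaller than the short-gene set (",
         nrow(short), "); cannot draw a size-matched control")
  }
  control <- with_seed(seed, {
    rest[sample.int(nrow(rest), nrow(short)), , drop = FALSE]
  })
  list(short = short, control = control, seed = as.integer(seed))
}
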