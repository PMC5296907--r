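#' Call nucleosomes and footprints on single molecules
#'
#' Finds maximal runs of protected sites on each molecule and classifies each
#' run's protected span. The span is the open interval between the nearest
#' flanking accessible sites (exclusive); where a run has no flanking
#' accessible site the span is truncated at the outermost informative site, so
#' no protection is extrapolated beyond the evidence. Missing sites neither
#' break runs nor confer accessibility.
#'
#' Classification follows the run-length rules of the assay: a continuous
#' inaccessible span of at least `nucleosome_bp` (146 bp, one nucleosomal
#' wrap) is a nucleosome; a span of more than 25 but fewer than 146 bp whose
#' interval intersects the window around the TSS or TTS is a footprint
#' (sub-nucleosomal bound protein); any other protected span is reported as
#' `unclassified_protected`.
#'
#' Two guards target the bisulfite noise floor: a run must contain at least
#' `min_sites` protected sites (an isolated protected site is within reach of
#' enzyme inefficiency), and with `denoise = TRUE` an isolated accessible site
#' whose informative neighbours are both protected is treated as missing
#' rather than accessible, since at the assay's ~0.9% inconversion rate such
#' singletons inside long protected runs are overwhelmingly conversion
#' failures.
#'
#' @param ms A `molecule_states` object (one or many molecules).
#' @param ref Optional `reference_locus` supplying TSS/TTS anchors.
#' @param anchors Optional numeric vector of anchor coordinates (0-based);
#'   overrides `ref`.
#' @param anchor_window Half-width of the footprint eligibility window around
#'   each anchor, bp (default 150).
#' @param nucleosome_bp Minimum nucleosome span, bp (default 146).
#' @param footprint_min_bp Minimum footprint span, bp (default 26, i.e.
#'   spans > 25 bp).
#' @param min_sites Minimum protected sites per run (default 2).
#' @param denoise Reclassify isolated accessible sites inside protected runs
#'   as missing (default TRUE).
#' @return data.frame of called regions with columns `molecule_id`, `start`,
#'   `end` (0-based half-open), `span_bp`, `n_sites`, `label`.
#' @export
call_regions <- function(ms, ref = NULL, anchors = NULL, anchor_window = 150,
                         nucleosome_bp = 146, footprint_min_bp = 26,
                         min_sites = 2, denoise = TRUE) {
  stopifnot(inherits(ms, "molecule_states"))
  if (is.null(anchors)) {
    anchors <- if (!is.null(ref)) c(ref$tss_offset, ref$tts_offset) else numeric(0)
  }
  out <- vector("list", n_molecules(ms))
  for (i in seq_len(n_molecules(ms))) {
    out[[i]] <- regions_one(ms$positions, ms$acc[i, ], ms$molecule_id[i],
                            anchors, anchor_window, nucleosome_bp,
                            footprint_min_bp, min_sites, denoise)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- empty_regions()
  }
  rownames(res) <- NULL
  res
}

empty_regions <- function() {
  data.frame(molecule_id = character(0), start = integer(0), end = integer(0),
             span_bp = integer(0), n_sites = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

regions_one <- function(pos, st, id, anchors, anchor_window, nucleosome_bp,
                        footprint_min_bp, min_sites, denoise) {
  keep <- !is.na(st)
  pos <- pos[keep]
  st <- st[keep]
  n <- length(st)
  if (n == 0) return(NULL)
  if (denoise && n >= 3) {
    left <- c(NA_integer_, st[-n])
    right <- c(st[-1], NA_integer_)
    iso <- which(st == 1L & !is.na(left) & left == 0L & !is.na(right) & right == 0L)
    if (length(iso)) {
      pos <- pos[-iso]
      st <- st[-iso]
      n <- length(st)
    }
  }
  r <- rle(st == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values & r$lengths >= min_sites)) {
    i1 <- starts[k]
    i2 <- ends[k]
    start <- if (i1 > 1) pos[i1 - 1] + 1L else pos[i1]
    end <- if (i2 < n) pos[i2 + 1] else pos[i2] + 1L
    span <- end - start
    anchored <- length(anchors) > 0 &&
      any(start <= anchors + anchor_window & end > anchors - anchor_window)
    label <- if (span >= nucleosome_bp) {
      "nucleosome"
    } else if (span >= footprint_min_bp && anchored) {
      "footprint"
    } else {
      "unclassified_protected"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      molecule_id = id, start = as.integer(start), end = as.integer(end),
      span_bp = as.integer(span), n_sites = r$lengths[k], label = label,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Summarize nucleosome occupancy over a window across molecules
#'
#' A molecule counts as occupied when one of its called nucleosomes overlaps
#' the window by at least `min_overlap` of the window width; the summary is
#' the occupied count over the molecules analysed (the "k of n molecules
#' occupied" readout of single-molecule maps).
#'
#' @param regions Region calls from [call_regions()].
#' @param window Length-2 numeric, 0-based half-open interval on the
#'   reference.
#' @param n_molecules Total number of molecules analysed (the denominator;
#'   molecules without any call still count toward it).
#' @param min_overlap Required overlap as a fraction of window width
#'   (default 0.5).
#' @return List with `k_occupied`, `n_molecules`, `fraction`, `window`.
#' @export
occupancy_summary <- function(regions, window, n_molecules, min_overlap = 0.5) {
  if (n_molecules == 0) stop("occupancy undefined for zero molecules")
  stopifnot(length(window) == 2, window[1] < window[2])
  need <- min_overlap * (window[2] - window[1])
  nuc <- regions[regions$label == "nucleosome", , drop = FALSE]
  ol <- overlap_len(nuc$start, nuc$end, window[1], window[2])
  k <- length(unique(nuc$molecule_id[ol >= need]))
  list(k_occupied = k, n_molecules = as.integer(n_molecules),
       fraction = k / n_molecules, window = window, min_overlap = min_overlap)
}

#' Deterministic molecule ordering for single-molecule displays
#'
#' Orders molecules for stacked lollipop-style panels: by their
#' occupied-window pattern (molecules sharing nucleosome configurations group
#' together, fully occupied patterns first), then by molecule id. The order
#' depends only on the calls, not on input order.
#'
#' @param regions Region calls from [call_regions()].
#' @param molecule_ids All molecule ids to order (calls may cover a subset).
#' @param windows Optional list of length-2 windows defining the occupancy
#'   pattern; when `NULL`, molecules are ordered by total nucleosome-covered
#'   bp (descending), then id.
#' @param min_overlap Window overlap fraction defining "occupied".
#' @return Character vector of molecule ids in display order.
#' @export
sort_for_display <- function(regions, molecule_ids, windows = NULL,
                             min_overlap = 0.5) {
  ids <- sort(unique(as.character(molecule_ids)))
  nuc <- regions[regions$label == "nucleosome", , drop = FALSE]
  if (!is.null(windows)) {
    key <- vapply(ids, function(id) {
      r <- nuc[nuc$molecule_id == id, , drop = FALSE]
      bits <- vapply(windows, function(w) {
        need <- min_overlap * (w[2] - w[1])
        if (nrow(r) && any(overlap_len(r$start, r$end, w[1], w[2]) >= need)) "1" else "0"
      }, character(1))
      paste(bits, collapse = "")
    }, character(1))
    ids[order(key, ids, decreasing = c(TRUE, FALSE), method = "radix")]
  } else {
    key <- vapply(ids, function(id) {
      r <- nuc[nuc$molecule_id == id, , drop = FALSE]
      if (nrow(r)) sum(r$span_bp) else 0L
    }, numeric(1))
    ids[order(-key, ids, method = "radix")]
  }
}
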