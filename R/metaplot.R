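#' Build a metaplot profile object from per-bin counts
#'
#' Low-level constructor for anchored percent-accessibility profiles; used by
#' [build_metaplot()] and for constructing profiles directly in analyses and
#' checks.
#'
#' @param bin_start Signed bp offsets of bin left edges (bins are half-open,
#'   `[bin_start, bin_start + bin)`).
#' @param acc,prot,miss Per-bin counts of accessible / protected / missing
#'   site-observations.
#' @param bin Bin width, bp.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param min_coverage Minimum `acc + prot` for a defined percent value.
#' @param smoothing Smoothing window recorded on the object (0 = raw).
#' @return A `nome_metaplot` data.frame with columns `bin_start`, `center`,
#'   `acc`, `prot`, `miss`, `coverage`, `percent`.
#' @export
metaplot_profile <- function(bin_start, acc, prot, miss = 0, bin = 10,
                             anchor = "TSS", min_coverage = 1, smoothing = 0) {
  stopifnot(length(acc) == length(bin_start), length(prot) == length(bin_start))
  if (length(miss) == 1) miss <- rep(miss, length(bin_start))
  coverage <- acc + prot
  percent <- ifelse(coverage >= min_coverage, 100 * acc / coverage, NA_real_)
  out <- data.frame(bin_start = bin_start, center = bin_start + bin / 2,
                    acc = acc, prot = prot, miss = miss,
                    coverage = coverage, percent = percent)
  attr(out, "bin") <- bin
  attr(out, "anchor") <- anchor
  attr(out, "min_coverage") <- min_coverage
  attr(out, "smoothing") <- smoothing
  class(out) <- c("nome_metaplot", "data.frame")
  out
}

normalize_annotation <- function(loci) {
  if (inherits(loci, "reference_locus")) loci <- list(loci)
  if (is.data.frame(loci)) {
    ann <- lapply(seq_len(nrow(loci)), function(i) {
      list(locus_id = loci$locus_id[i], strand = loci$strand[i],
           tss_offset = loci$tss[i] %||% loci$tss_offset[i],
           tts_offset = loci$tts[i] %||% loci$tts_offset[i],
           length = if ("length" %in% names(loci)) loci$length[i] else NULL)
    })
    names(ann) <- loci$locus_id
    return(ann)
  }
  ann <- lapply(loci, function(l) {
    list(locus_id = l$locus_id, strand = l$strand,
         tss_offset = l$tss_offset, tts_offset = l$tts_offset,
         length = if (!is.null(l$sequence)) nchar(l$sequence) else l$length %||% NULL)
  })
  names(ann) <- vapply(ann, `[[`, character(1), "locus_id")
  ann
}

#' Aggregate single-molecule states into an anchored accessibility metaplot
#'
#' Maps every informative accessibility site of every molecule to a signed
#' offset from the locus anchor (TSS or TTS), negating offsets for
#' minus-strand loci so that positive offsets always point downstream, and
#' pools site-observations across molecules and loci into offset bins.
#' Percent accessibility per bin is `100 * accessible / (accessible +
#' protected)`, i.e. the percentage of enzymatically methylated GpC
#' observations across all reads covering the bin; missing observations are
#' counted but do not enter the ratio.
#'
#' @param states A `molecule_states` object or list of them (one per locus).
#' @param loci Matching `reference_locus` objects (or a data.frame with
#'   columns `locus_id`, `strand`, `tss`, `tts`).
#' @param anchor `"TSS"` or `"TTS"`.
#' @param flank Maximum absolute offset retained, bp.
#' @param bin Offset bin width, bp (default 10).
#' @param min_coverage Minimum pooled coverage per bin for a defined percent.
#' @return A `nome_metaplot` (see [metaplot_profile()]).
#' @export
build_metaplot <- function(states, loci, anchor = c("TSS", "TTS"),
                           flank = 1000, bin = 10, min_coverage = 20) {
  anchor <- match.arg(anchor)
  if (inherits(states, "molecule_states")) states <- list(states)
  ann <- normalize_annotation(loci)
  bstart <- seq.int(-(ceiling(flank / bin) * bin),
                    ceiling(flank / bin) * bin - bin, by = bin)
  acc_tot <- prot_tot <- miss_tot <- stats::setNames(numeric(length(bstart)),
                                                     bstart)
  for (ms in states) {
    a <- ann[[ms$locus_id]]
    if (is.null(a)) stop("no annotation for locus ", ms$locus_id)
    if (is.null(a$strand) || is.na(a$strand) || !a$strand %in% c("+", "-")) {
      stop("locus ", ms$locus_id, " lacks a valid strand")
    }
    apos <- if (anchor == "TSS") a$tss_offset else a$tts_offset
    if (!is.null(a$length) && (apos < 0 || apos >= a$length)) {
      stop("anchor lies outside locus ", ms$locus_id)
    }
    if (!length(ms$positions)) next
    off <- if (a$strand == "+") ms$positions - apos else apos - ms$positions
    sel <- off >= bstart[1] & off < bstart[length(bstart)] + bin
    if (!any(sel)) next
    b <- as.character(floor(off[sel] / bin) * bin)
    acc_n <- colSums(ms$acc == 1L, na.rm = TRUE)[sel]
    prot_n <- colSums(ms$acc == 0L, na.rm = TRUE)[sel]
    miss_n <- colSums(is.na(ms$acc))[sel]
    ab <- tapply(acc_n, b, sum)
    pb <- tapply(prot_n, b, sum)
    mb <- tapply(miss_n, b, sum)
    acc_tot[names(ab)] <- acc_tot[names(ab)] + ab
    prot_tot[names(pb)] <- prot_tot[names(pb)] + pb
    miss_tot[names(mb)] <- miss_tot[names(mb)] + mb
  }
  metaplot_profile(bstart, unname(acc_tot), unname(prot_tot),
                   unname(miss_tot), bin = bin, anchor = anchor,
                   min_coverage = min_coverage)
}

#' Smooth a metaplot profile with a coverage-weighted running mean
#'
#' Centred running mean over a window of `window` bp. Each neighbouring bin
#' contributes with weight proportional to the length of its overlap with the
#' window times its coverage, so the smoothed percent is the pooled
#' accessible fraction over the window; edges use the available support.
#'
#' @param mp A `nome_metaplot`.
#' @param window Smoothing window, bp (default 20); must be at least the bin
#'   width.
#' @return A smoothed `nome_metaplot` (attribute `smoothing` records the
#'   window).
#' @export
smooth_profile <- function(mp, window = 20) {
  stopifnot(inherits(mp, "nome_metaplot"))
  bin <- attr(mp, "bin")
  if (window < bin) stop("smoothing window (", window,
                         " bp) must not be smaller than the bin width (", bin, " bp)")
  nb <- nrow(mp)
  reach <- ceiling(window / (2 * bin)) + 1L
  sa <- sp <- sm <- sc <- numeric(nb)
  for (i in seq_len(nb)) {
    js <- max(1L, i - reach):min(nb, i + reach)
    w <- overlap_len(mp$bin_start[js], mp$bin_start[js] + bin,
                     mp$center[i] - window / 2, mp$center[i] + window / 2)
    sa[i] <- sum(w * mp$acc[js])
    sp[i] <- sum(w * mp$prot[js])
    sm[i] <- sum(w * mp$miss[js])
    sc[i] <- sum(w)
  }
  # rescale to average per-bin units so the coverage gate stays comparable
  scale <- ifelse(sc > 0, bin / sc, 0)
  out <- metaplot_profile(mp$bin_start, sa * scale, sp * scale, sm * scale,
                          bin = bin, anchor = attr(mp, "anchor"),
                          min_coverage = attr(mp, "min_coverage"),
                          smoothing = window)
  # percent from the unscaled pooled sums (identical ratio, kept explicit)
  out$percent <- ifelse(out$coverage >= attr(mp, "min_coverage") & (sa + sp) > 0,
                        100 * sa / (sa + sp), NA_real_)
  out
}

#' Detect the nucleosome-depleted region around the anchor
#'
#' The NDR is the maximal contiguous offset interval containing the anchor in
#' which percent accessibility stays at or above `theta` times the profile
#' maximum within `search_flank` of the anchor. If the anchor bin itself is
#' below threshold (or undefined), no NDR is reported -- an explicit empty
#' result, not an error.
#'
#' @param mp A (smoothed) `nome_metaplot`.
#' @param theta Fraction of the local maximum defining "open" (default 0.6).
#' @param search_flank Flank for the reference maximum, bp (default 1000).
#' @param min_percent Absolute accessibility floor, percentage points
#'   (default 25): on a uniformly closed profile the relative threshold is
#'   vacuous, so the anchor must also clear this floor for an NDR to exist.
#' @return List with `found`, `start`, `end` (offset bp, half-open),
#'   `threshold` and `max_reference`.
#' @export
detect_ndr <- function(mp, theta = 0.6, search_flank = 1000,
                       min_percent = 25) {
  stopifnot(inherits(mp, "nome_metaplot"))
  bin <- attr(mp, "bin")
  local <- abs(mp$center) <= search_flank
  if (!any(local & !is.na(mp$percent))) {
    return(list(found = FALSE, start = NA_real_, end = NA_real_,
                threshold = NA_real_, max_reference = NA_real_))
  }
  mx <- max(mp$percent[local], na.rm = TRUE)
  thr <- max(theta * mx, min_percent)
  i0 <- which(mp$bin_start <= 0 & mp$bin_start + bin > 0)
  ok <- !is.na(mp$percent) & mp$percent >= thr
  if (!length(i0) || !ok[i0]) {
    return(list(found = FALSE, start = NA_real_, end = NA_real_,
                threshold = thr, max_reference = mx))
  }
  l <- i0
  while (l > 1 && ok[l - 1]) l <- l - 1
  r <- i0
  while (r < nrow(mp) && ok[r + 1]) r <- r + 1
  list(found = TRUE, start = mp$bin_start[l], end = mp$bin_start[r] + bin,
       threshold = thr, max_reference = mx)
}

# Local minima (leftmost index of flat runs) of a numeric vector.
local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  res <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] < y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1L
      if (j < n && y[j + 1] > y[i]) res <- c(res, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  res
}

# Trough prominence: smaller of the maximal rises to the nearest
# lower-or-equal point (or edge) on each side.
trough_prominence <- function(y, i) {
  rise <- function(idx) {
    if (!length(idx)) return(Inf)
    m <- -Inf
    for (j in idx) {
      if (y[j] < y[i]) break
      m <- max(m, y[j])
    }
    if (is.infinite(m) && m < 0) Inf else m - y[i]
  }
  left <- rise(rev(seq_len(i - 1)))
  right <- rise(seq.int(i + 1, length(y)))
  min(left, right)
}

#' Locate nucleosome centers and phasing from a metaplot
#'
#' Troughs of the smoothed profile mark positioned nucleosomes. Local minima
#' with prominence of at least `prominence` percentage points are found (ties
#' broken leftmost); because a well-positioned nucleosome produces a wide,
#' flat-bottomed valley, each trough's center is then refined to the
#' coverage-weighted centroid of the contiguous valley floor (bins within
#' `floor_tol` points of the minimum). The -1/+1 nucleosomes are the troughs
#' nearest the NDR on each side, and the phasing period is the median spacing
#' of successive troughs per side when at least two exist.
#'
#' @param mp A smoothed `nome_metaplot`.
#' @param prominence Minimum trough prominence, percentage points (default 5).
#' @param floor_tol Valley-floor tolerance, percentage points (default 2).
#' @param ndr Optional [detect_ndr()] result; its bounds split upstream from
#'   downstream troughs (the anchor is used when absent).
#' @return A `profile_features` list: `troughs` (data.frame with `center`,
#'   `raw_offset`, `value`, `prominence`), `minus_one`, `plus_one`,
#'   `phasing_period`.
#' @export
locate_nucleosome_centers <- function(mp, prominence = 5, floor_tol = 2,
                                      ndr = NULL) {
  stopifnot(inherits(mp, "nome_metaplot"))
  segs <- split(seq_len(nrow(mp)), cumsum(is.na(mp$percent)))
  troughs <- list()
  for (seg in segs) {
    seg <- seg[!is.na(mp$percent[seg])]
    if (length(seg) < 3) next
    y <- mp$percent[seg]
    for (i in local_minima(y)) {
      pr <- trough_prominence(y, i)
      if (pr < prominence) next
      lo <- i
      while (lo > 1 && !is.na(y[lo - 1]) && y[lo - 1] <= y[i] + floor_tol) lo <- lo - 1
      hi <- i
      while (hi < length(y) && !is.na(y[hi + 1]) && y[hi + 1] <= y[i] + floor_tol) hi <- hi + 1
      idx <- seg[lo:hi]
      wts <- mp$coverage[idx]
      if (all(wts == 0)) wts <- rep(1, length(idx))
      troughs[[length(troughs) + 1L]] <- data.frame(
        center = stats::weighted.mean(mp$center[idx], wts),
        raw_offset = mp$center[seg[i]],
        value = y[i],
        prominence = pr)
    }
  }
  tr <- if (length(troughs)) do.call(rbind, troughs) else {
    data.frame(center = numeric(0), raw_offset = numeric(0),
               value = numeric(0), prominence = numeric(0))
  }
  tr <- tr[order(tr$center), , drop = FALSE]
  rownames(tr) <- NULL
  lo_bound <- if (!is.null(ndr) && isTRUE(ndr$found)) ndr$start else 0
  hi_bound <- if (!is.null(ndr) && isTRUE(ndr$found)) ndr$end else 0
  up <- tr$center[tr$center < lo_bound]
  dn <- tr$center[tr$center >= hi_bound]
  minus_one <- if (length(up)) max(up) else NA_real_
  plus_one <- if (length(dn)) min(dn) else NA_real_
  spac <- c(if (length(up) >= 2) diff(sort(up)),
            if (length(dn) >= 2) diff(sort(dn)))
  structure(list(troughs = tr,
                 minus_one = minus_one,
                 plus_one = plus_one,
                 phasing_period = if (length(spac)) stats::median(spac) else NA_real_),
            class = "profile_features")
}

#' Compare native and salt-washed accessibility profiles
#'
#' Computes the per-bin accessibility gain of the salt condition over the
#' native condition and flags maximal intervals where the gain reaches
#' `min_delta` percentage points over at least `min_bins` consecutive bins.
#' Because a high-salt wash removes chromatin-associated proteins but not
#' histones, flagged intervals are protein-footprint candidates, while
#' nucleosomal protection is expected to be unchanged.
#'
#' Bins with undefined percent in either profile (below-coverage gaps between
#' informative sites) carry no evidence in either direction, so they neither
#' extend nor break a run; "consecutive" refers to consecutive defined bins.
#'
#' @param mp_native,mp_salt `nome_metaplot` objects on identical bins and
#'   anchor.
#' @param min_delta Minimum gain, percentage points (default 10).
#' @param min_bins Minimum consecutive defined bins (default 2).
#' @return data.frame of flagged intervals: `start`, `end` (offset bp),
#'   `n_bins`, `mean_delta`, `max_delta`.
#' @export
compare_conditions <- function(mp_native, mp_salt, min_delta = 10,
                               min_bins = 2) {
  stopifnot(inherits(mp_native, "nome_metaplot"),
            inherits(mp_salt, "nome_metaplot"))
  if (!identical(mp_native$bin_start, mp_salt$bin_start) ||
      !identical(attr(mp_native, "bin"), attr(mp_salt, "bin")) ||
      !identical(attr(mp_native, "anchor"), attr(mp_salt, "anchor"))) {
    stop("profiles have mismatched bins or anchors and cannot be compared")
  }
  bin <- attr(mp_native, "bin")
  d <- mp_salt$percent - mp_native$percent
  def <- which(!is.na(d))
  hit <- d[def] >= min_delta
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values & r$lengths >= min_bins)) {
    idx <- def[starts[k]:ends[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      start = mp_native$bin_start[idx[1]],
      end = mp_native$bin_start[idx[length(idx)]] + bin,
      n_bins = length(idx),
      mean_delta = mean(d[idx]),
      max_delta = max(d[idx]))
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(start = numeric(0), end = numeric(0), n_bins = integer(0),
               mean_delta = numeric(0), max_delta = numeric(0))
  }
}
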