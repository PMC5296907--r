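#' Classify reference cytosine contexts (GCH / HCG / GCG)
#'
#' Scans every cytosine on both strands of the reference and assigns it to one
#' channel. `GCH` (GpC not followed by G) reports chromatin accessibility via
#' M.CviPI; `HCG` (CpG not preceded by G) reports endogenous methylation in
#' single-enzyme mode, and becomes a second accessibility channel in dual
#' (M.CviPI + M.SssI) mode; `GCG` overlaps both dinucleotides, so enzymatic
#' and endogenous signals are confounded and the site is excluded from state
#' calling. Sites inside primer masks are dropped. Minus-strand sites are
#' recorded at the plus-strand position of the paired G and flagged with
#' `strand = "-"`.
#'
#' @param ref A [make_reference()]-style `reference_locus`.
#' @param mode `"single"` or `"dual"`; controls the channel assigned to HCG.
#' @return A `site_contexts` data.frame with columns `position` (0-based),
#'   `strand`, `context` (`GCH`/`HCG`/`GCG`) and `channel`
#'   (`accessibility`/`endogenous`/`excluded`).
#' @examples
#' ref <- make_reference(600, gpc_spacing = 10, cpg_spacing = 25, seed = 7)
#' table(classify_contexts(ref)$context)
#' @export
classify_contexts <- function(ref, mode = c("single", "dual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "reference_locus"))
  s <- seq_chars(ref$sequence)
  L <- length(s)
  res <- list()

  idx <- which(s == "C")
  idx <- idx[idx > 1 & idx < L]
  if (length(idx)) {
    prv <- s[idx - 1]
    nxt <- s[idx + 1]
    ctx <- ifelse(prv == "G" & nxt == "G", "GCG",
                  ifelse(prv == "G", "GCH",
                         ifelse(nxt == "G", "HCG", NA_character_)))
    keep <- !is.na(ctx)
    res$plus <- data.frame(position = idx[keep] - 1L, strand = "+",
                           context = ctx[keep], stringsAsFactors = FALSE)
  }
  jdx <- which(s == "G")
  jdx <- jdx[jdx > 1 & jdx < L]
  if (length(jdx)) {
    # bottom-strand C at top position p: 5' neighbour is complement(top[p+1]),
    # 3' neighbour is complement(top[p-1])
    up <- s[jdx + 1]
    dn <- s[jdx - 1]
    ctx <- ifelse(up == "C" & dn == "C", "GCG",
                  ifelse(up == "C", "GCH",
                         ifelse(dn == "C", "HCG", NA_character_)))
    keep <- !is.na(ctx)
    res$minus <- data.frame(position = jdx[keep] - 1L, strand = "-",
                            context = ctx[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(position = integer(0), strand = character(0),
                      context = character(0), stringsAsFactors = FALSE)
  }
  for (m in ref$primer_masks) {
    out <- out[!(out$position >= m[1] & out$position < m[2]), , drop = FALSE]
  }
  out$channel <- ifelse(out$context == "GCG", "excluded",
                        ifelse(out$context == "GCH", "accessibility",
                               if (mode == "dual") "accessibility" else "endogenous"))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("site_contexts", "data.frame")
  out
}

#' Construct a molecule-states object directly
#'
#' Low-level constructor for per-molecule, per-site states, used when states
#' come from a source other than [call_states()] (e.g. a precomputed table, or
#' programmatic construction of molecules with arbitrary site spacing).
#'
#' Accessibility states are coded `1` (accessible / enzymatically methylated),
#' `0` (protected / unmethylated) and `NA` (missing); endogenous states `1`
#' (methylated), `0` (unmethylated), `NA`.
#'
#' @param positions Sorted 0-based positions of the accessibility-channel sites.
#' @param acc Integer matrix (molecules x sites) or a vector for one molecule.
#' @param locus_id,molecule_id Identifiers.
#' @param endo_positions,endo Optional endogenous-channel sites and states.
#' @param conversion_qc Optional per-molecule conversion QC fraction.
#' @param strand,mode Read strand and enzyme mode metadata.
#' @return A `molecule_states` object.
#' @export
molecule_states <- function(positions, acc, locus_id = "locus",
                            molecule_id = NULL, endo_positions = integer(0),
                            endo = NULL, conversion_qc = NULL,
                            strand = "+", mode = "single") {
  if (is.vector(acc)) acc <- matrix(acc, nrow = 1)
  stopifnot(ncol(acc) == length(positions), !is.unsorted(positions))
  n <- nrow(acc)
  if (is.null(molecule_id)) molecule_id <- sprintf("mol%05d", seq_len(n))
  if (is.null(endo)) endo <- matrix(NA_integer_, n, length(endo_positions))
  if (is.vector(endo)) endo <- matrix(endo, nrow = 1)
  if (is.null(conversion_qc)) conversion_qc <- rep(NA_real_, n)
  structure(list(locus_id = locus_id,
                 molecule_id = molecule_id,
                 strand = strand,
                 mode = mode,
                 positions = as.integer(positions),
                 acc = acc,
                 endo_positions = as.integer(endo_positions),
                 endo = endo,
                 conversion_qc = conversion_qc),
            class = "molecule_states")
}

#' @export
print.molecule_states <- function(x, ...) {
  cat("<molecule_states> ", nrow(x$acc), " molecules at ", x$locus_id, ": ",
      length(x$positions), " accessibility sites, ",
      length(x$endo_positions), " endogenous sites (strand ", x$strand,
      ", mode ", x$mode, ")\n", sep = "")
  invisible(x)
}

n_molecules <- function(ms) nrow(ms$acc)

#' Call per-molecule methylation states from bisulfite reads
#'
#' Converts full-length bisulfite amplicon reads (aligned to the reference by
#' construction) into ternary per-site states. At each context site of the
#' read's strand, a retained cytosine is called methylated -- which on the
#' accessibility channel means the site was accessible to the enzyme -- and a
#' converted (thymine) base unmethylated/protected; any other base is missing.
#' Bottom-strand reads are read out at the paired-G positions (G = methylated,
#' A = converted).
#'
#' Per-molecule conversion QC is the converted fraction of cytosines outside
#' any informative or ambiguous context (HCH cytosines), which have no
#' enzymatic or endogenous route to methylation and so measure bisulfite
#' conversion efficiency directly.
#'
#' @param reads A `bisulfite_reads` object or character vector of read
#'   sequences (then assumed top-strand).
#' @param ref The `reference_locus` the reads are aligned to.
#' @param contexts Optional precomputed [classify_contexts()] table.
#' @param mode `"single"` or `"dual"`; defaults to the context table's mode.
#' @return A `molecule_states` object (see [molecule_states()]).
#' @export
call_states <- function(reads, ref, contexts = NULL, mode = NULL) {
  if (is.character(reads)) {
    reads <- structure(list(reads = reads,
                            molecule_id = sprintf("mol%05d", seq_along(reads)),
                            strand = "+", mode = mode %||% "single",
                            locus_id = ref$locus_id, meta = list()),
                       class = "bisulfite_reads")
  }
  mode <- mode %||% reads$mode
  if (is.null(contexts)) contexts <- classify_contexts(ref, mode = mode)
  if (!identical(attr(contexts, "mode"), mode)) {
    contexts <- classify_contexts(ref, mode = mode)
  }
  L <- nchar(ref$sequence)
  if (any(nchar(reads$reads) != L)) {
    stop("read/reference length mismatch: all reads must span the full amplicon")
  }
  rs <- reads$strand
  one <- if (rs == "+") "C" else "G"
  zero <- if (rs == "+") "T" else "A"
  onstrand <- contexts[contexts$strand == rs, , drop = FALSE]
  acc_pos <- onstrand$position[onstrand$channel == "accessibility"]
  endo_pos <- onstrand$position[onstrand$channel == "endogenous"]

  mat <- do.call(rbind, strsplit(reads$reads, "", fixed = TRUE))
  state_at <- function(pos) {
    if (!length(pos)) {
      return(matrix(NA_integer_, nrow(mat), 0))
    }
    sub <- mat[, pos + 1, drop = FALSE]
    st <- matrix(NA_integer_, nrow(sub), ncol(sub))
    st[sub == one] <- 1L
    st[sub == zero] <- 0L
    colnames(st) <- pos
    st
  }
  acc <- state_at(acc_pos)
  endo <- state_at(endo_pos)

  refc <- seq_chars(ref$sequence)
  target <- if (rs == "+") "C" else "G"
  qc_pos <- setdiff(which(refc == target) - 1L, onstrand$position)
  if (length(qc_pos)) {
    sub <- mat[, qc_pos + 1, drop = FALSE]
    den <- rowSums(sub == one | sub == zero)
    qc <- rowSums(sub == zero) / den
    qc[den == 0] <- NA_real_
  } else {
    qc <- rep(NA_real_, nrow(mat))
  }

  uninformative <- if (ncol(acc)) rowSums(!is.na(acc)) == 0 else rep(TRUE, nrow(mat))
  if (any(uninformative)) {
    warning(sum(uninformative), " molecule(s) with zero informative ",
            "accessibility sites; returned with all-missing states")
  }

  molecule_states(positions = acc_pos, acc = acc,
                  locus_id = ref$locus_id, molecule_id = reads$molecule_id,
                  endo_positions = endo_pos, endo = endo,
                  conversion_qc = qc, strand = rs, mode = mode)
}

#' Filter molecules on bisulfite conversion QC and informative coverage
#'
#' Removes molecules whose conversion QC falls below `min_conversion` (poorly
#' converted clones would otherwise read as spuriously inaccessible... i.e.
#' spuriously methylated) or that carry fewer than `min_informative` observed
#' accessibility sites.
#'
#' @param ms A `molecule_states` object.
#' @param min_conversion Minimum conversion fraction (default 0.95). Molecules
#'   with undeterminable QC (no QC cytosines) are retained.
#' @param min_informative Minimum number of non-missing accessibility sites.
#' @return The filtered `molecule_states`; removal counts are reported via
#'   `message()` and attached as attribute `"removed"`.
#' @export
filter_molecules <- function(ms, min_conversion = 0.95, min_informative = 5) {
  stopifnot(inherits(ms, "molecule_states"))
  qc_fail <- !is.na(ms$conversion_qc) & ms$conversion_qc < min_conversion
  info <- if (ncol(ms$acc)) rowSums(!is.na(ms$acc)) else rep(0L, n_molecules(ms))
  cov_fail <- info < min_informative
  keep <- !qc_fail & !cov_fail
  message("filter_molecules: removed ", sum(qc_fail), " on conversion QC, ",
          sum(cov_fail & !qc_fail), " on informative-site count; ",
          sum(keep), "/", length(keep), " retained")
  out <- ms
  out$molecule_id <- ms$molecule_id[keep]
  out$acc <- ms$acc[keep, , drop = FALSE]
  out$endo <- ms$endo[keep, , drop = FALSE]
  out$conversion_qc <- ms$conversion_qc[keep]
  attr(out, "removed") <- c(conversion = sum(qc_fail),
                            informative = sum(cov_fail & !qc_fail))
  out
}

#' Check a locus for dual-enzyme eligibility
#'
#' Dual (M.CviPI + M.SssI) accessibility readout is only valid where
#' endogenous CpG sites are unmethylated, since endogenous methylation is
#' indistinguishable from enzymatic CpG labelling. Given single-enzyme or
#' untreated molecules with a populated endogenous channel, this computes the
#' mean HCG methylation across molecules and sites and compares it to the
#' eligibility bound.
#'
#' @param ms A `molecule_states` with endogenous states (single-enzyme mode).
#' @param threshold Maximum mean endogenous methylation for eligibility
#'   (default 0.10).
#' @return List with `eligible`, `mean_endogenous`, `threshold`, `n_sites`,
#'   `n_molecules`.
#' @export
check_dual_eligibility <- function(ms, threshold = 0.10) {
  stopifnot(inherits(ms, "molecule_states"))
  if (length(ms$endo_positions) == 0 || ncol(ms$endo) == 0) {
    stop("no endogenous (HCG) sites observed; dual-enzyme eligibility is undecidable")
  }
  vals <- ms$endo[!is.na(ms$endo)]
  if (!length(vals)) {
    stop("endogenous channel has no observed states; eligibility is undecidable")
  }
  m <- mean(vals)
  list(eligible = m <= threshold,
       mean_endogenous = m,
       threshold = threshold,
       n_sites = length(ms$endo_positions),
       n_molecules = n_molecules(ms))
}
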