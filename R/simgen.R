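#' Construct a synthetic reference locus with controlled informative-site density
#'
#' Builds an uppercase ACGT sequence in which accessibility-informative GpC
#' sites (GCH trinucleotides) and endogenous-methylation CpG sites (HCG
#' trinucleotides) are placed at approximately regular spacing on an A/T
#' background that itself contains no GpC or CpG dinucleotides. Ambiguous GCG
#' trinucleotides are never created. Both ends of the sequence are reserved as
#' primer regions free of any informative site, mirroring amplicon primers
#' designed to avoid GpC and CpG.
#'
#' GCH sites are planted as `GCA` motifs; HCG sites as `TCG` motifs. When
#' `gpc_spacing <= 2` the densest clean tiling (one GCH every 3 bp) is used,
#' since a GpC at every single base is chemically impossible without creating
#' ambiguous GCG context.
#'
#' @param length Total reference length in bp (>= 200).
#' @param gpc_spacing Approximate spacing between accessibility (GCH) sites, bp.
#' @param cpg_spacing Approximate spacing between endogenous (HCG) sites, bp;
#'   `0` places none.
#' @param qc_spacing Approximate spacing of non-informative cytosines (HCH on
#'   either strand, planted as `TCA`/`AGA` motifs) that report bisulfite
#'   conversion efficiency; `0` places none.
#' @param seed Integer seed; the sequence is reproducible for a fixed seed.
#' @param primer_len Length of the informative-site-free primer mask at each
#'   end, bp.
#' @param gene_length Distance from TSS to TTS, bp.
#' @param tss_offset,tts_offset 0-based offsets of the first transcribed base
#'   and the termination site; defaults centre the gene on the locus.
#' @param strand `"+"` or `"-"`.
#' @param locus_id,gene_class Identifier and gene class
#'   (`tRNA`, `non_tRNA`, `polII`, `polII_short`).
#' @return A `reference_locus` object: list with `locus_id`, `sequence`,
#'   `tss_offset`, `tts_offset`, `strand`, `primer_masks` (list of 0-based
#'   half-open intervals), and `gene_class`.
#' @examples
#' ref <- make_reference(600, gpc_spacing = 10, cpg_spacing = 25, seed = 7)
#' nchar(ref$sequence)
#' @export
make_reference <- function(length, gpc_spacing, cpg_spacing = 0, seed = 1,
                           qc_spacing = 50, primer_len = 30, gene_length = 100,
                           tss_offset = NULL, tts_offset = NULL,
                           strand = c("+", "-"), locus_id = "locus1",
                           gene_class = c("tRNA", "non_tRNA", "polII", "polII_short")) {
  strand <- match.arg(strand)
  gene_class <- match.arg(gene_class)
  if (length < 200) stop("reference length must be >= 200 bp")
  if (gpc_spacing < 1) stop("gpc_spacing must be >= 1")
  lo <- primer_len                 # first usable 0-based position
  hi <- length - primer_len        # one past last usable position
  if (gpc_spacing > hi - lo - 3) {
    stop("gpc_spacing ", gpc_spacing, " bp is impossible for a usable region of ",
         hi - lo, " bp")
  }
  if (cpg_spacing > 0 && cpg_spacing > hi - lo - 3) {
    stop("cpg_spacing ", cpg_spacing, " bp is impossible for a usable region of ",
         hi - lo, " bp")
  }

  if (is.null(tss_offset)) tss_offset <- (length - gene_length) %/% 2
  if (is.null(tts_offset)) tts_offset <- tss_offset + gene_length
  if (!(tss_offset < tts_offset && tss_offset >= 0 && tts_offset < length)) {
    stop("require 0 <= tss_offset < tts_offset < length")
  }

  s <- with_seed(seed, {
    s <- sample(c("A", "T"), length, replace = TRUE)
    # occupied marks motif bases plus one flanking base on each side, so that
    # later placements cannot create unintended dinucleotide contexts.
    occupied <- rep(FALSE, length)
    step <- if (gpc_spacing <= 2) 3 else gpc_spacing
    gpc_starts <- seq.int(lo, hi - 3, by = step)
    # jitter placement within the spacing grid (keeps approximate density but
    # decorrelates site phases across loci, as in real sequence)
    jmax <- max(0L, (step - 3L) %/% 2L)
    if (jmax > 0) {
      gpc_starts <- gpc_starts + sample.int(2L * jmax + 1L,
                                            length(gpc_starts),
                                            replace = TRUE) - jmax - 1L
      gpc_starts <- pmin(pmax(gpc_starts, lo), hi - 3L)
    }
    for (p in gpc_starts) {
      s[(p + 1):(p + 3)] <- c("G", "C", "A")
    }
    occ_idx <- unique(as.vector(outer(gpc_starts, -1:3, `+`)))
    occ_idx <- occ_idx[occ_idx >= 0 & occ_idx < length]
    occupied[occ_idx + 1] <- TRUE
    place_motif <- function(motif, spacing, phase) {
      if (spacing <= 0) return(invisible())
      ideal <- seq.int(lo + phase, hi - 3, by = spacing)
      nudges <- c(0, as.vector(rbind(seq_len(spacing %/% 2),
                                     -seq_len(spacing %/% 2))))
      for (p0 in ideal) {
        for (dp in nudges) {
          p <- p0 + dp
          if (p < lo || p + 3 > hi) next
          span <- (p - 1):(p + 3)
          span <- span[span >= 0 & span < length]
          if (any(occupied[span + 1])) next
          s[(p + 1):(p + 3)] <<- motif
          occupied[span + 1] <<- TRUE
          break
        }
      }
    }
    place_motif(c("T", "C", "G"), cpg_spacing, step %/% 2)
    place_motif(c("T", "C", "A"), qc_spacing, 1)
    place_motif(c("A", "G", "A"), qc_spacing, 2)
    s
  })

  structure(list(
    locus_id = locus_id,
    sequence = paste(s, collapse = ""),
    tss_offset = as.integer(tss_offset),
    tts_offset = as.integer(tts_offset),
    strand = strand,
    primer_masks = list(c(0L, as.integer(primer_len)),
                        c(as.integer(length - primer_len), as.integer(length))),
    gene_class = gene_class
  ), class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat("<reference_locus> ", x$locus_id, ": ", nchar(x$sequence), " bp, strand ",
      x$strand, ", TSS ", x$tss_offset, ", TTS ", x$tts_offset,
      ", class ", x$gene_class, "\n", sep = "")
  invisible(x)
}

#' Architecture configuration for the single-molecule simulator
#'
#' Describes the chromatin architecture and chemistry parameters used to
#' generate synthetic molecules. All genomic offsets are in bp relative to the
#' TSS, signed along the direction of transcription (positive = downstream).
#'
#' @param nucleosome_dyads data.frame with columns `offset` (dyad position
#'   relative to TSS), `jitter_sd` (per-molecule positional jitter, bp, drawn
#'   from a truncated normal), and `occupancy_prob` (per-molecule probability
#'   that the nucleosome is present).
#' @param footprints data.frame with columns `center`, `width` (bp),
#'   `presence_prob`, and `salt_labile` (logical: removed by a high-salt wash).
#' @param ndr Optional length-2 numeric, TSS-relative bounds `c(start, end)` of
#'   a remodeler-enforced nucleosome-depleted region: nucleosomal protection is
#'   excluded from this interval (protein footprints are not).
#' @param nucleosome_len Nucleosomal protection extent in bp (default 146, the
#'   length of DNA wrapped around the histone core); protection spans
#'   `[dyad - 73, dyad + 73)` for the default.
#' @param enzyme_efficiency Probability that an unprotected target cytosine is
#'   methylated by the exogenous enzyme(s).
#' @param endogenous_cpg_meth Endogenous CpG methylation: either a scalar
#'   per-site probability, or `list(alleles = <probs>, mix = <weights>)` for
#'   allele-structured patterns (e.g. `list(alleles = c(1, 0),
#'   mix = c(0.5, 0.5))` for a monoallelically methylated locus).
#' @param inconversion_rate Probability that an unmethylated cytosine survives
#'   bisulfite conversion (the assay's false-methylation noise floor;
#'   default 0.009).
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed recorded in the emitted truth object.
#' @return An `arch_config` object (validated list).
#' @export
arch_config <- function(nucleosome_dyads = data.frame(offset = numeric(0),
                                                      jitter_sd = numeric(0),
                                                      occupancy_prob = numeric(0)),
                        footprints = data.frame(center = numeric(0),
                                                width = numeric(0),
                                                presence_prob = numeric(0),
                                                salt_labile = logical(0)),
                        ndr = NULL,
                        nucleosome_len = 146,
                        enzyme_efficiency = 0.95,
                        endogenous_cpg_meth = 0,
                        inconversion_rate = 0.009,
                        n_molecules = 100,
                        seed = 1) {
  stopifnot(is.data.frame(nucleosome_dyads),
            all(c("offset", "jitter_sd", "occupancy_prob") %in% names(nucleosome_dyads)),
            is.data.frame(footprints),
            all(c("center", "width", "presence_prob", "salt_labile") %in% names(footprints)))
  if (nucleosome_len < 1) stop("nucleosome_len must be >= 1")
  if (nrow(nucleosome_dyads) && any(nucleosome_dyads$jitter_sd < 0)) {
    stop("jitter_sd must be >= 0")
  }
  if (!is_prob(c(nucleosome_dyads$occupancy_prob, footprints$presence_prob,
                 enzyme_efficiency, inconversion_rate))) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (is.list(endogenous_cpg_meth)) {
    stopifnot(is_prob(endogenous_cpg_meth$alleles),
              length(endogenous_cpg_meth$mix) == length(endogenous_cpg_meth$alleles),
              abs(sum(endogenous_cpg_meth$mix) - 1) < 1e-8)
  } else if (!is_prob(endogenous_cpg_meth)) {
    stop("endogenous_cpg_meth must be a probability or an allele specification")
  }
  if (!is.null(ndr)) {
    stopifnot(length(ndr) == 2, ndr[1] < ndr[2])
  }
  structure(list(nucleosome_dyads = nucleosome_dyads,
                 footprints = footprints,
                 ndr = ndr,
                 nucleosome_len = as.integer(nucleosome_len),
                 enzyme_efficiency = enzyme_efficiency,
                 endogenous_cpg_meth = endogenous_cpg_meth,
                 inconversion_rate = inconversion_rate,
                 n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed)),
            class = "arch_config")
}

#' Canonical tRNA-like promoter architecture
#'
#' Convenience constructor for the architecture seen at active Type II (tRNA)
#' pol III promoters: a -1 nucleosome with dyad at -150 bp, a +1 nucleosome
#' with dyad at +220 bp, and a nucleosome-depleted region spanning
#' approximately -100 to +200 bp relative to the TSS.
#'
#' @param occupancy Per-molecule occupancy probability of both nucleosomes.
#' @param jitter_sd Dyad positional jitter, bp.
#' @param ndr NDR bounds relative to TSS (see [arch_config()]); `NULL` disables
#'   the remodeler-enforced clearing.
#' @param footprints Optional footprint table (see [arch_config()]); use
#'   [trna_footprints()] for the canonical TSS-proximal pair.
#' @param n_molecules,seed,... Passed to [arch_config()].
#' @return An `arch_config`.
#' @export
trna_architecture <- function(occupancy = 0.8, jitter_sd = 20,
                              ndr = c(-100, 200), footprints = NULL,
                              n_molecules = 200, seed = 1, ...) {
  if (is.null(footprints)) {
    footprints <- data.frame(center = numeric(0), width = numeric(0),
                             presence_prob = numeric(0), salt_labile = logical(0))
  }
  arch_config(
    nucleosome_dyads = data.frame(offset = c(-150, 220),
                                  jitter_sd = jitter_sd,
                                  occupancy_prob = occupancy),
    footprints = footprints,
    ndr = ndr,
    n_molecules = n_molecules,
    seed = seed,
    ...
  )
}

#' TSS-proximal footprint pair of an active tRNA promoter
#'
#' Two sub-nucleosomal footprints flanking the TSS inside the NDR: an upstream
#' salt-resistant footprint (TFIIIB-like, immediately upstream of the TSS) and
#' a downstream salt-labile footprint (polymerase/TFIIIC-like). A high-salt
#' wash removes chromatin-associated proteins but not histones, so only the
#' labile footprint disappears under the salt condition.
#'
#' @param presence_prob Per-molecule presence probability of each footprint.
#' @return Footprint data.frame suitable for [arch_config()].
#' @export
trna_footprints <- function(presence_prob = 0.9) {
  data.frame(center = c(-25, 30),
             width = c(40, 50),
             presence_prob = presence_prob,
             salt_labile = c(FALSE, TRUE))
}

# Map a TSS-relative half-open offset interval [s_off, e_off) to 0-based
# half-open reference coordinates, respecting locus strand. Vectorised.
map_interval <- function(ref, s_off, e_off) {
  if (ref$strand == "+") {
    cbind(ref$tss_offset + s_off, ref$tss_offset + e_off)
  } else {
    cbind(ref$tss_offset - e_off + 1, ref$tss_offset - s_off + 1)
  }
}

# Truncated-normal dyad draw (rejection sampling within [dmin, dmax]).
rtrunc_norm <- function(n, mean, sd, dmin, dmax) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < dmin | x > dmax
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, dmin), dmax)
}

# Build per-molecule protection masks from realised dyads / presence flags.
# `fp_keep`: logical per footprint row; FALSE drops the footprint entirely
# (used for the salt condition).
build_masks <- function(ref, cfg, dyads, occupied, fp_present, fp_keep) {
  L <- nchar(ref$sequence)
  n <- nrow(occupied) %||% nrow(fp_present)
  if (is.null(n)) n <- cfg$n_molecules
  pos <- matrix(0:(L - 1), n, L, byrow = TRUE)
  half_lo <- cfg$nucleosome_len %/% 2
  nucmask <- matrix(FALSE, n, L)
  if (!is.null(dyads) && ncol(dyads) > 0) {
    for (j in seq_len(ncol(dyads))) {
      iv <- map_interval(ref, dyads[, j] - half_lo,
                         dyads[, j] - half_lo + cfg$nucleosome_len)
      nucmask <- nucmask | (pos >= iv[, 1] & pos < iv[, 2] & occupied[, j])
    }
    if (!is.null(cfg$ndr)) {
      niv <- map_interval(ref, cfg$ndr[1], cfg$ndr[2])
      cols <- which(0:(L - 1) >= niv[1] & 0:(L - 1) < niv[2])
      if (length(cols)) nucmask[, cols] <- FALSE
    }
  }
  fpmask <- matrix(FALSE, n, L)
  fp <- cfg$footprints
  if (nrow(fp)) {
    for (i in seq_len(nrow(fp))) {
      if (!fp_keep[i]) next
      s_off <- fp$center[i] - fp$width[i] %/% 2
      iv <- map_interval(ref, s_off, s_off + fp$width[i])
      fpmask <- fpmask | (pos >= iv[1] & pos < iv[2] & fp_present[, i])
    }
  }
  nucmask | fpmask
}

#' Simulate single molecules with known protection ground truth
#'
#' For each molecule, every configured nucleosome is independently occupied
#' with its `occupancy_prob` and its dyad drawn from a truncated normal
#' centred on the configured TSS-relative offset; footprints are present with
#' their `presence_prob`. The per-molecule protection mask is the union of the
#' occupied nucleosomes' `[dyad - len/2, dyad + len/2)` intervals (excluded
#' from the configured NDR, if any) and the present footprint intervals.
#'
#' @param ref A [make_reference()] locus.
#' @param cfg An [arch_config()].
#' @param seed Seed for this draw; defaults to `cfg$seed`.
#' @return A `sim_truth` object: list with `masks` (molecules x positions
#'   logical matrix, `TRUE` = protected), `dyads` (realised TSS-relative dyad
#'   offsets), `occupied`, `footprint_present`, `condition`, the `config`, the
#'   `ref`, and the `seed` used. Reproducible for a fixed seed.
#' @export
simulate_molecules <- function(ref, cfg, seed = cfg$seed) {
  stopifnot(inherits(ref, "reference_locus"), inherits(cfg, "arch_config"))
  nd <- cfg$nucleosome_dyads
  fp <- cfg$footprints
  if (nrow(nd) == 0 && nrow(fp) == 0) {
    stop("nothing to simulate: no nucleosomes and no footprints configured")
  }
  L <- nchar(ref$sequence)
  n <- cfg$n_molecules
  half_lo <- cfg$nucleosome_len %/% 2
  # allowable TSS-relative dyad range keeping protection within the reference
  if (ref$strand == "+") {
    dmin <- half_lo - ref$tss_offset
    dmax <- (L - 1) - (cfg$nucleosome_len - half_lo) - ref$tss_offset + 1
  } else {
    dmin <- half_lo - ((L - 1) - ref$tss_offset)
    dmax <- ref$tss_offset - (cfg$nucleosome_len - half_lo) + 1
  }
  out <- with_seed(seed, {
    occupied <- matrix(FALSE, n, max(1, nrow(nd)))[, seq_len(nrow(nd)), drop = FALSE]
    dyads <- matrix(0, n, nrow(nd))
    for (j in seq_len(nrow(nd))) {
      occupied[, j] <- stats::runif(n) < nd$occupancy_prob[j]
      dyads[, j] <- round(rtrunc_norm(n, nd$offset[j], nd$jitter_sd[j], dmin, dmax))
    }
    fp_present <- matrix(FALSE, n, max(1, nrow(fp)))[, seq_len(nrow(fp)), drop = FALSE]
    for (i in seq_len(nrow(fp))) {
      fp_present[, i] <- stats::runif(n) < fp$presence_prob[i]
    }
    list(occupied = occupied, dyads = dyads, fp_present = fp_present)
  })
  masks <- build_masks(ref, cfg, out$dyads, out$occupied, out$fp_present,
                       fp_keep = rep(TRUE, nrow(fp)))
  structure(list(masks = masks,
                 dyads = out$dyads,
                 occupied = out$occupied,
                 footprint_present = out$fp_present,
                 condition = "native",
                 config = cfg,
                 ref = ref,
                 seed = seed),
            class = "sim_truth")
}

#' Derive the salt-washed condition from simulated truth
#'
#' A 400 mM NaCl wash removes chromatin-associated proteins but not histones:
#' footprints flagged `salt_labile` are removed from every molecule while all
#' nucleosomal protection and salt-resistant footprints are retained.
#'
#' @param truth A `sim_truth` from [simulate_molecules()].
#' @return A `sim_truth` with recomputed `masks` and `condition = "salt"`.
#' @export
simulate_salt_condition <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  fp <- truth$config$footprints
  keep <- if (nrow(fp)) !fp$salt_labile else logical(0)
  truth$masks <- build_masks(truth$ref, truth$config, truth$dyads,
                             truth$occupied, truth$footprint_present,
                             fp_keep = keep)
  truth$condition <- "salt"
  truth
}

# Per-molecule endogenous CpG methylation probability vector.
endo_prob_per_molecule <- function(cfg, n) {
  e <- cfg$endogenous_cpg_meth
  if (is.list(e)) {
    allele <- sample.int(length(e$alleles), n, replace = TRUE, prob = e$mix)
    e$alleles[allele]
  } else {
    rep(e, n)
  }
}

# Mean endogenous methylation level implied by the configuration.
endo_level <- function(cfg) {
  e <- cfg$endogenous_cpg_meth
  if (is.list(e)) sum(e$alleles * e$mix) else e
}

#' Apply enzymatic labelling and bisulfite conversion to protection masks
#'
#' Emulates the assay chemistry on each simulated molecule. Unprotected
#' accessibility-channel cytosines (GCH; plus HCG in dual mode, where both
#' M.CviPI and M.SssI are used) are methylated with probability
#' `enzyme_efficiency`. Endogenous CpG methylation is applied to HCG (and GCG)
#' cytosines per the configuration. Every unmethylated cytosine is then
#' converted to thymine with probability `1 - inconversion_rate`; methylated
#' cytosines are unchanged. Protected cytosines can therefore appear
#' methylated only through bisulfite conversion failure.
#'
#' Reads are emitted full-length in top-strand orientation. With
#' `strand = "bottom"` the chemistry is applied to the bottom strand of the
#' amplicon and the read is reported in top-strand coordinates (converted
#' bottom-strand cytosines appear as `A` at `G` positions), which is how
#' aligned bottom-strand bisulfite reads present.
#'
#' @param ref The [make_reference()] locus.
#' @param masks Logical molecules x positions protection matrix (e.g.
#'   `truth$masks`).
#' @param cfg The [arch_config()] holding chemistry parameters.
#' @param mode `"single"` (M.CviPI only) or `"dual"` (M.CviPI + M.SssI).
#' @param strand `"top"` or `"bottom"`: which amplicon strand the reads derive
#'   from.
#' @param seed Optional seed for the chemistry draw.
#' @return A `bisulfite_reads` object: list with `reads` (character vector),
#'   `molecule_id`, `strand` (`"+"`/`"-"`), `mode`, `locus_id` and `meta`
#'   (records an eligibility warning when dual mode is requested on a locus
#'   whose endogenous CpG methylation exceeds 10%, since dual-enzyme
#'   accessibility readout requires endogenously unmethylated CpGs).
#' @export
apply_chemistry <- function(ref, masks, cfg, mode = c("single", "dual"),
                            strand = c("top", "bottom"), seed = NULL) {
  mode <- match.arg(mode)
  strand <- match.arg(strand)
  stopifnot(inherits(ref, "reference_locus"), inherits(cfg, "arch_config"))
  L <- nchar(ref$sequence)
  if (ncol(masks) != L) stop("protection masks do not match reference length")
  n <- nrow(masks)
  rs <- if (strand == "top") "+" else "-"
  ctx <- classify_contexts(ref, mode = mode)
  ctx <- ctx[ctx$strand == rs, , drop = FALSE]
  gch <- ctx$position[ctx$context == "GCH"]
  hcg <- ctx$position[ctx$context == "HCG"]
  gcg <- ctx$position[ctx$context == "GCG"]
  refc <- seq_chars(ref$sequence)

  meta <- list(warnings = character(0))
  lev <- endo_level(cfg)
  if (mode == "dual" && lev > 0.10) {
    meta$warnings <- paste0(
      "dual-enzyme mode requested but configured endogenous CpG methylation (",
      signif(lev, 3), ") exceeds the 0.10 eligibility bound; accessibility ",
      "readout at HCG sites is confounded at this locus")
  }

  reads <- with_seed(seed, {
    meth <- matrix(FALSE, n, L)
    bern <- function(k, p) stats::runif(k) < p
    if (length(gch)) {
      sub <- !masks[, gch + 1, drop = FALSE]
      meth[, gch + 1] <- sub & bern(length(sub), cfg$enzyme_efficiency)
    }
    p_mol <- endo_prob_per_molecule(cfg, n)
    for (set in list(hcg, gcg)) {
      if (!length(set)) next
      endo <- matrix(stats::runif(n * length(set)) < p_mol, n, length(set))
      enz <- !masks[, set + 1, drop = FALSE] &
        bern(n * length(set), cfg$enzyme_efficiency)
      meth[, set + 1] <- if (identical(set, gcg) || mode == "dual") endo | enz else endo
    }
    # GCG cytosines are GpC targets of M.CviPI in either mode; HCG cytosines
    # are only enzymatically targeted (by M.SssI) in dual mode.
    mat <- matrix(refc, n, L, byrow = TRUE)
    if (strand == "top") {
      cpos <- which(refc == "C")
      m <- meth[, cpos, drop = FALSE]
      conv <- !m & bern(n * length(cpos), 1 - cfg$inconversion_rate)
      sub <- mat[, cpos, drop = FALSE]
      sub[conv] <- "T"
      mat[, cpos] <- sub
    } else {
      gpos <- which(refc == "G")
      m <- meth[, gpos, drop = FALSE]
      conv <- !m & bern(n * length(gpos), 1 - cfg$inconversion_rate)
      sub <- mat[, gpos, drop = FALSE]
      sub[conv] <- "A"
      mat[, gpos] <- sub
    }
    apply(mat, 1, paste, collapse = "")
  })

  structure(list(reads = reads,
                 molecule_id = sprintf("mol%05d", seq_len(n)),
                 strand = rs,
                 mode = mode,
                 locus_id = ref$locus_id,
                 meta = meta),
            class = "bisulfite_reads")
}

#' @export
print.bisulfite_reads <- function(x, ...) {
  cat("<bisulfite_reads> ", length(x$reads), " reads from ", x$locus_id,
      " (strand ", x$strand, ", mode ", x$mode, ")\n", sep = "")
  if (length(x$meta$warnings)) cat("  warning: ", x$meta$warnings, "\n", sep = "")
  invisible(x)
}
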