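# Readers and writers for the plain-text artifact formats used by the
# pipeline. Coordinates are 0-based half-open throughout (BED convention);
# offsets relative to an anchor are signed integers with 0 at the anchor base.

#' Write a reference locus as FASTA
#' @param ref A `reference_locus`.
#' @param path Output file.
#' @export
write_locus_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$locus_id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write bisulfite reads as FASTA (one record per molecule)
#' @param reads A `bisulfite_reads` object.
#' @param path Output file.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$reads)
  names(x) <- paste(reads$molecule_id, reads$locus_id, reads$strand, sep = "|")
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read bisulfite reads from a FASTA written by [write_reads_fasta()]
#' @param path FASTA file; record names are `molecule|locus|strand`.
#' @param mode Enzyme mode metadata to attach.
#' @return A `bisulfite_reads` object.
#' @export
read_reads_fasta <- function(path, mode = "single") {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  strand <- parts[[1]][3]
  if (is.na(strand)) strand <- "+"
  locus <- parts[[1]][2]
  if (is.na(locus)) locus <- "locus"
  structure(list(reads = unname(as.character(x)),
                 molecule_id = vapply(parts, `[`, character(1), 1),
                 strand = strand,
                 mode = mode,
                 locus_id = locus,
                 meta = list()),
            class = "bisulfite_reads")
}

#' Write per-molecule states as a long-format TSV
#'
#' Columns: `molecule_id`, `locus_id`, `position` (0-based), `channel`
#' (`accessibility`/`endogenous`), `state` (`accessible`/`protected`/
#' `methylated`/`unmethylated`/`missing`).
#'
#' @param ms A `molecule_states` object.
#' @param path Output file.
#' @export
write_states_tsv <- function(ms, path) {
  rows <- list()
  decode_acc <- c("protected", "accessible")
  decode_endo <- c("unmethylated", "methylated")
  if (ncol(ms$acc)) {
    st <- as.vector(t(ms$acc))
    rows$acc <- data.frame(
      molecule_id = rep(ms$molecule_id, each = ncol(ms$acc)),
      locus_id = ms$locus_id,
      position = rep(ms$positions, times = nrow(ms$acc)),
      channel = "accessibility",
      state = ifelse(is.na(st), "missing", decode_acc[st + 1L]))
  }
  if (ncol(ms$endo)) {
    st <- as.vector(t(ms$endo))
    rows$endo <- data.frame(
      molecule_id = rep(ms$molecule_id, each = ncol(ms$endo)),
      locus_id = ms$locus_id,
      position = rep(ms$endo_positions, times = nrow(ms$endo)),
      channel = "endogenous",
      state = ifelse(is.na(st), "missing", decode_endo[st + 1L]))
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a states TSV back into a `molecule_states` object
#' @param path File written by [write_states_tsv()].
#' @param strand,mode Metadata to attach.
#' @return A `molecule_states` object.
#' @export
read_states_tsv <- function(path, strand = "+", mode = "single") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- unique(df$molecule_id)
  encode <- c(accessible = 1L, protected = 0L, methylated = 1L,
              unmethylated = 0L)
  build <- function(sub) {
    pos <- sort(unique(sub$position))
    m <- matrix(NA_integer_, length(ids), length(pos),
                dimnames = list(ids, pos))
    st <- encode[sub$state]
    m[cbind(match(sub$molecule_id, ids), match(sub$position, pos))] <- st
    list(positions = pos, states = m)
  }
  a <- build(df[df$channel == "accessibility", , drop = FALSE])
  e <- build(df[df$channel == "endogenous", , drop = FALSE])
  molecule_states(positions = a$positions, acc = a$states,
                  locus_id = df$locus_id[1], molecule_id = ids,
                  endo_positions = e$positions, endo = e$states,
                  strand = strand, mode = mode)
}

#' Write called regions as BED
#'
#' BED6+1: chrom (locus id), start, end, name (molecule id), score (span bp),
#' strand (`.`), label.
#'
#' @param regions Output of [call_regions()].
#' @param locus_id Chromosome/locus name for column 1.
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, locus_id, path) {
  df <- data.frame(chrom = locus_id, start = regions$start, end = regions$end,
                   name = regions$molecule_id,
                   score = pmin(1000L, regions$span_bp), strand = ".",
                   label = regions$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a metaplot profile as TSV with a provenance header
#' @param mp A `nome_metaplot`.
#' @param path Output file.
#' @param extra Named list of extra header fields to echo.
#' @export
write_profile_tsv <- function(mp, path, extra = list()) {
  hdr <- c(anchor = attr(mp, "anchor"), bin = attr(mp, "bin"),
           min_coverage = attr(mp, "min_coverage"),
           smoothing = attr(mp, "smoothing"), unlist(extra))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(hdr), "=", hdr), con)
  utils::write.table(as.data.frame(mp), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a metaplot profile TSV written by [write_profile_tsv()]
#' @param path Input file.
#' @return A `nome_metaplot`.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  hl <- grep("^# ", lines)
  hdr <- strsplit(sub("^# ", "", lines[hl]), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        vapply(hdr, `[`, character(1), 1))
  df <- utils::read.table(text = lines[-hl], sep = "\t", header = TRUE)
  mp <- metaplot_profile(df$bin_start, df$acc, df$prot, df$miss,
                         bin = as.numeric(kv[["bin"]]),
                         anchor = kv[["anchor"]],
                         min_coverage = as.numeric(kv[["min_coverage"]]),
                         smoothing = as.numeric(kv[["smoothing"]]))
  mp$percent <- df$percent
  mp
}

#' Read a BED6 gene annotation into the gene table used by [classify_activity()]
#'
#' Uses `rtracklayer` when available, falling back to a plain BED6 column
#' read.
#'
#' @param path BED6 file (strand required).
#' @return data.frame with `id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `length_bp`.
#' @export
read_genes_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(id = gr$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    df <- data.frame(id = raw[[4]], chrom = raw[[1]], start = raw[[2]],
                     end = raw[[3]], strand = raw[[6]],
                     stringsAsFactors = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene annotation requires an explicit strand for every record")
  }
  df$length_bp <- df$end - df$start
  df
}
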