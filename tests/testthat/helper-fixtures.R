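# Fixtures and independent oracles used across the suite. Oracles are written
# in a deliberately different style from the package code (explicit loops,
# regex scans) so agreement is evidence, not tautology.

# Wrap an arbitrary sequence string as a reference locus (no primer masks).
ref_from_seq <- function(seq, tss = 0, tts = nchar(seq) - 1, strand = "+",
                         locus_id = "mini") {
  structure(list(locus_id = locus_id, sequence = seq,
                 tss_offset = as.integer(tss), tts_offset = as.integer(tts),
                 strand = strand, primer_masks = list(),
                 gene_class = "tRNA"),
            class = "reference_locus")
}

# A molecule with an informative site at every base and one protected run.
dense_molecule <- function(total = 600, prot_start, prot_len,
                           locus_id = "dense", molecule_id = "m1") {
  st <- rep(1L, total)
  if (prot_len > 0) st[(prot_start + 1):(prot_start + prot_len)] <- 0L
  molecule_states(positions = 0:(total - 1), acc = st, locus_id = locus_id,
                  molecule_id = molecule_id)
}

# Independent region scanner: explicit state machine over informative sites.
brute_regions <- function(pos, st, anchors = numeric(0), anchor_window = 150,
                          nucleosome_bp = 146, footprint_min_bp = 26,
                          min_sites = 2, denoise = TRUE) {
  keep <- which(!is.na(st))
  pos <- pos[keep]
  st <- st[keep]
  if (denoise && length(st) >= 3) {
    drop <- c()
    for (i in seq_along(st)) {
      if (st[i] == 1 && i > 1 && i < length(st) &&
          st[i - 1] == 0 && st[i + 1] == 0) {
        drop <- c(drop, i)
      }
    }
    if (length(drop)) {
      pos <- pos[-drop]
      st <- st[-drop]
    }
  }
  out <- NULL
  i <- 1
  n <- length(st)
  while (i <= n) {
    if (st[i] == 0) {
      j <- i
      while (j < n && st[j + 1] == 0) j <- j + 1
      if (j - i + 1 >= min_sites) {
        start <- if (i == 1) pos[1] else pos[i - 1] + 1
        end <- if (j == n) pos[n] + 1 else pos[j + 1]
        span <- end - start
        near <- FALSE
        for (a in anchors) {
          if (start <= a + anchor_window && end > a - anchor_window) near <- TRUE
        }
        lab <- if (span >= nucleosome_bp) "nucleosome"
               else if (span >= footprint_min_bp && near) "footprint"
               else "unclassified_protected"
        out <- rbind(out, data.frame(start = start, end = end, span_bp = span,
                                     n_sites = j - i + 1, label = lab))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Regex oracle: 0-based context-site positions per strand. Minus-strand sites
# are reported at the top-strand position of the paired G.
oracle_positions <- function(seq) {
  scan <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  L <- nchar(seq)
  pats <- c(GCH = "(?=GC[ACT])", HCG = "(?=[ACT]CG)", GCG = "(?=GCG)")
  # 1-based match start g puts the C at g+1 (1-based), i.e. g in 0-based
  plus <- lapply(pats, function(p) scan(seq, p))
  rseq <- revcomp_str(seq)
  # 0-based C index m on the reverse complement maps to top position L-1-m
  minus <- lapply(pats, function(p) sort(L - 1L - scan(rseq, p)))
  list(plus = plus, minus = minus)
}
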