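make_sym_states <- function(strand, tss = 500, L = 1000, prot_off = NULL) {
  # sites every 5 bp in gene-offset space, mirrored onto the reference per
  # strand; prot_off: TSS-relative half-open offset interval set protected
  offs <- seq(-400, 395, by = 5)
  pos <- if (strand == "+") tss + offs else tss - offs
  ord <- order(pos)
  st <- rep(1L, length(offs))
  if (!is.null(prot_off)) {
    st[offs >= prot_off[1] & offs < prot_off[2]] <- 0L
  }
  ms <- molecule_states(pos[ord], matrix(rep(st[ord], 20), 20, byrow = TRUE),
                        locus_id = paste0("sym", strand))
  ann <- data.frame(locus_id = paste0("sym", strand), strand = strand,
                    tss = tss, tts = tss + 100)
  list(ms = ms, ann = ann)
}

test_that("metaplot pools observations and respects strand orientation", {
  p <- make_sym_states("+")
  mp <- build_metaplot(p$ms, p$ann, flank = 400, min_coverage = 1)
  expect_true(all(mp$percent[mp$coverage > 0] == 100))
  # conservation: every mapped site-observation is accessible+protected+missing
  expect_equal(sum(mp$acc + mp$prot + mp$miss), 20 * length(seq(-400, 395, 5)))
  # a plus and a minus locus with mirrored architecture give identical profiles
  pp <- make_sym_states("+", prot_off = c(-150, 0))
  pm <- make_sym_states("-", prot_off = c(-150, 0))
  mp_p <- build_metaplot(pp$ms, pp$ann, flank = 400, min_coverage = 1)
  mp_m <- build_metaplot(pm$ms, pm$ann, flank = 400, min_coverage = 1)
  expect_equal(mp_p$percent, mp_m$percent)
  expect_equal(mp_p$coverage, mp_m$coverage)
  # errors: missing strand, anchor outside locus
  bad_ann <- pp$ann
  bad_ann$strand <- "."
  expect_error(build_metaplot(pp$ms, bad_ann, flank = 400), "strand")
  out_ann <- pp$ann
  out_ann$tss <- 5000
  out_ann$length <- 1000
  expect_error(build_metaplot(pp$ms, out_ann, flank = 400), "outside")
})

test_that("TTS anchoring equals TSS anchoring shifted by the gene length", {
  # constant gene length (100 bp, a bin multiple) across loci
  states <- list()
  ann <- NULL
  for (i in 1:3) {
    p <- make_sym_states("+", prot_off = c(50 * i, 50 * i + 80))
    p$ms$locus_id <- paste0("g", i)
    p$ann$locus_id <- paste0("g", i)
    states[[i]] <- p$ms
    ann <- rbind(ann, p$ann)
  }
  tss_mp <- build_metaplot(states, ann, anchor = "TSS", flank = 300,
                           min_coverage = 1)
  tts_mp <- build_metaplot(states, ann, anchor = "TTS", flank = 300,
                           min_coverage = 1)
  shift <- 100 / attr(tss_mp, "bin")
  n <- nrow(tss_mp)
  expect_equal(tts_mp$percent[seq_len(n - shift)],
               tss_mp$percent[(shift + 1):n])
})

test_that("smoothing is a coverage-weighted window mean with closed-form limits", {
  flat <- metaplot_profile(seq(-100, 90, 10), acc = rep(80, 20),
                           prot = rep(20, 20))
  sm <- smooth_profile(flat, 20)
  expect_equal(sm$percent, flat$percent)
  # impulse of height h spreads to a plateau of h * bin / window
  acc <- rep(0, 41)
  acc[21] <- 50
  imp <- metaplot_profile(seq(-200, 200, 10), acc = acc,
                          prot = 50 - acc, min_coverage = 1)
  for (w in c(20, 40)) {
    smw <- smooth_profile(imp, w)
    expect_equal(max(smw$percent), 100 * 10 / w, tolerance = 1e-10)
  }
  # smoothing twice ~ single pass with the convolved (triangular) kernel
  set.seed(5)
  acc2 <- runif(41, 10, 90)
  prof <- metaplot_profile(seq(-200, 200, 10), acc = acc2, prot = 100 - acc2,
                           min_coverage = 1)
  twice <- smooth_profile(smooth_profile(prof, 30), 30)
  y <- prof$percent
  tri <- stats::convolve(c(y[1], y[1], y, y[41], y[41]),
                         rev(c(1, 4, 6, 4, 1) / 16), type = "filter")
  mid <- 5:37
  expect_equal(twice$percent[mid], tri[mid], tolerance = 2.5)
  expect_error(smooth_profile(prof, 5), "bin width")
})

test_that("NDR detection returns exact bounds on constructed profiles", {
  bins <- seq(-300, 290, 10)
  open <- bins >= -100 & bins < 200
  prof <- metaplot_profile(bins, acc = ifelse(open, 95, 0),
                           prot = ifelse(open, 5, 100), min_coverage = 1)
  ndr <- detect_ndr(prof)
  expect_true(ndr$found)
  expect_equal(ndr$start, -100)
  expect_equal(ndr$end, 200)
  # fully closed profile: explicit no-NDR result, not an error
  closed <- metaplot_profile(bins, acc = rep(2, length(bins)),
                             prot = rep(98, length(bins)), min_coverage = 1)
  expect_false(detect_ndr(closed)$found)
})

test_that("trough detection finds constructed and simulated nucleosome centers", {
  bins <- seq(-400, 390, 10)
  y <- rep(90, length(bins))
  y[bins >= -220 & bins < -80] <- 20  # flat-bottomed valley centred at -150
  prof <- metaplot_profile(bins, acc = y, prot = 100 - y, min_coverage = 1)
  fe <- locate_nucleosome_centers(prof)
  expect_equal(nrow(fe$troughs), 1)
  expect_equal(fe$troughs$center, -145, tolerance = 6)
  expect_gt(fe$troughs$prominence, 60)
  expect_equal(fe$minus_one, fe$troughs$center)
  # monotone profile: no troughs
  mono <- metaplot_profile(bins, acc = seq(5, 95, length.out = length(bins)),
                           prot = 100 - seq(5, 95, length.out = length(bins)),
                           min_coverage = 1)
  expect_equal(nrow(locate_nucleosome_centers(mono)$troughs), 0)
  # shallow dips below the prominence bound are ignored
  y2 <- rep(80, length(bins))
  y2[30] <- 77
  shallow <- metaplot_profile(bins, acc = y2, prot = 100 - y2,
                              min_coverage = 1)
  expect_equal(nrow(locate_nucleosome_centers(shallow)$troughs), 0)
})

test_that("aggregate profile matches the analytic generative expectation", {
  # moderate-scale simulation against the closed-form protection probability
  arch <- trna_architecture(occupancy = 0.8, jitter_sd = 20,
                            ndr = c(-100, 200), n_molecules = 150)
  states <- list()
  loci <- list()
  for (i in 1:6) {
    ref <- make_reference(1200, gpc_spacing = 16, cpg_spacing = 60,
                          seed = 400 + i, locus_id = paste0("t", i))
    tr <- simulate_molecules(ref, arch, seed = 500 + i)
    rd <- apply_chemistry(ref, tr$masks, arch, seed = 600 + i)
    states[[i]] <- call_states(rd, ref)
    loci[[i]] <- ref
  }
  mp <- build_metaplot(states, loci, flank = 450, min_coverage = 30)
  # closed form: site at offset x is nucleosome-protected iff an occupied
  # dyad lies in [x - 72, x + 73]; protection is clipped inside the NDR
  p_prot <- function(x) {
    if (x >= -100 && x < 200) return(0)
    p <- 1
    for (mu in c(-150, 220)) {
      cover <- stats::pnorm(x + 73.5, mu, 20) - stats::pnorm(x - 72.5, mu, 20)
      p <- p * (1 - 0.8 * cover)
    }
    1 - p
  }
  for (i in which(!is.na(mp$percent))) {
    xs <- mp$bin_start[i] + 0:9
    pp <- mean(vapply(xs, p_prot, numeric(1)))
    expected <- 100 * (0.95 * (1 - pp) + 0.009 * pp)
    expect_lt(abs(mp$percent[i] - expected), 6)
  }
})

test_that("condition comparison flags constructed gains only", {
  bins <- seq(-200, 190, 10)
  base <- metaplot_profile(bins, acc = rep(20, length(bins)),
                           prot = rep(80, length(bins)), min_coverage = 1)
  expect_equal(nrow(compare_conditions(base, base)), 0)
  gain <- ifelse(bins >= 0 & bins < 50, 80, 20)
  salt <- metaplot_profile(bins, acc = gain, prot = 100 - gain,
                           min_coverage = 1)
  fl <- compare_conditions(base, salt)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$start, 0)
  expect_equal(fl$end, 50)
  expect_equal(fl$mean_delta, 60)
  # single-bin gains are not flagged
  spike <- ifelse(bins == 100, 80, 20)
  salt2 <- metaplot_profile(bins, acc = spike, prot = 100 - spike,
                            min_coverage = 1)
  expect_equal(nrow(compare_conditions(base, salt2)), 0)
  # mismatched binning is an error
  other <- metaplot_profile(seq(-200, 195, 5), acc = rep(20, 80),
                            prot = rep(80, 80), bin = 5, min_coverage = 1)
  expect_error(compare_conditions(base, other), "mismatch")
})
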