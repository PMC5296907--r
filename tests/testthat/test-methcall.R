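test_that("context classification follows the GCH/HCG/GCG rules", {
  ctx <- classify_contexts(ref_from_seq("AGCAA"))
  plus_acc <- ctx[ctx$channel == "accessibility" & ctx$strand == "+", ]
  expect_equal(nrow(plus_acc), 1)
  expect_equal(plus_acc$position, 2L)
  expect_equal(plus_acc$context, "GCH")
  # the GpC dinucleotide is its own reverse complement: the bottom strand
  # carries the mirror site at the paired G
  expect_equal(ctx$position[ctx$strand == "-"], 1L)
  # GCG is ambiguous on both strands: no usable site
  ctx2 <- classify_contexts(ref_from_seq("GCG"))
  expect_true(all(ctx2$channel == "excluded" | nrow(ctx2) == 0))
  expect_equal(sum(ctx2$channel != "excluded"), 0)
  # minus-strand GCH: GC on the bottom strand of ..TGC.. (C pairs G at pos 1)
  ctx3 <- classify_contexts(ref_from_seq("TGCT"))
  minus <- ctx3[ctx3$strand == "-", ]
  plus <- ctx3[ctx3$strand == "+", ]
  expect_equal(plus$context, "GCH")   # the top GC itself
  expect_equal(minus$context, "GCH")  # and its bottom-strand mirror
  expect_equal(minus$position, 1L)
})

test_that("context channels match an independent regex scan and partition all Cs", {
  ref <- make_reference(600, gpc_spacing = 10, cpg_spacing = 25, seed = 7,
                        primer_len = 0)
  ctx <- classify_contexts(ref)
  o <- oracle_positions(ref$sequence)
  for (cc in c("GCH", "HCG", "GCG")) {
    expect_setequal(ctx$position[ctx$context == cc & ctx$strand == "+"],
                    o$plus[[cc]])
    expect_setequal(ctx$position[ctx$context == cc & ctx$strand == "-"],
                    o$minus[[cc]])
  }
  # every interior C on either strand is GCH, HCG, GCG or uninformative;
  # context classes are disjoint
  expect_equal(anyDuplicated(ctx[c("position", "strand")]), 0)
  chars <- strsplit(ref$sequence, "")[[1]]
  n_ctx_plus <- sum(ctx$strand == "+")
  hch_plus <- sum(chars == "C") - n_ctx_plus
  expect_gte(hch_plus, 0)
  # dual mode reassigns HCG to the accessibility channel (never fewer sites)
  single <- classify_contexts(ref, mode = "single")
  dual <- classify_contexts(ref, mode = "dual")
  expect_gte(sum(dual$channel == "accessibility"),
             sum(single$channel == "accessibility"))
  expect_equal(sum(dual$channel == "accessibility"),
               sum(single$channel %in% c("accessibility", "endogenous")))
})

test_that("state calling round-trips the protection mask in the noise-free limit", {
  ref <- make_reference(800, gpc_spacing = 8, cpg_spacing = 30, seed = 3)
  cfg <- arch_config(
    nucleosome_dyads = data.frame(offset = c(-150, 220), jitter_sd = 0,
                                  occupancy_prob = 1),
    enzyme_efficiency = 1, inconversion_rate = 0,
    n_molecules = 5, seed = 4)
  tr <- simulate_molecules(ref, cfg)
  for (mode in c("single", "dual")) {
    rd <- apply_chemistry(ref, tr$masks, cfg, mode = mode, seed = 6)
    ms <- call_states(rd, ref, mode = mode)
    for (i in 1:5) {
      truth_at_sites <- ifelse(tr$masks[i, ms$positions + 1], 0L, 1L)
      expect_identical(unname(ms$acc[i, ]), truth_at_sites)
    }
  }
  # bottom-strand reads round-trip at minus-strand sites
  rdb <- apply_chemistry(ref, tr$masks, cfg, strand = "bottom", seed = 6)
  msb <- call_states(rdb, ref)
  expect_equal(msb$strand, "-")
  expect_gt(length(msb$positions), 0)
  for (i in 1:5) {
    truth_at_sites <- ifelse(tr$masks[i, msb$positions + 1], 0L, 1L)
    expect_identical(unname(msb$acc[i, ]), truth_at_sites)
  }
  # all-T read: everything protected
  allt <- gsub("C", "T", ref$sequence, fixed = TRUE)
  ms_t <- call_states(allt, ref)
  expect_true(all(ms_t$acc == 0L))
  expect_error(call_states(substr(ref$sequence, 1, 100), ref), "mismatch")
})

test_that("accessible fraction at open sites matches the enzyme efficiency", {
  ref <- make_reference(600, gpc_spacing = 10, seed = 2)
  cfg <- arch_config(
    nucleosome_dyads = data.frame(offset = 0, jitter_sd = 0,
                                  occupancy_prob = 0),
    enzyme_efficiency = 0.95, inconversion_rate = 0,
    n_molecules = 1000, seed = 12)
  masks <- matrix(FALSE, 1000, 600)
  ms <- call_states(apply_chemistry(ref, masks, cfg, seed = 13), ref)
  frac <- colMeans(ms$acc == 1L)
  se <- sqrt(0.95 * 0.05 / 1000)
  expect_true(all(abs(frac - 0.95) < 4 * se))
  expect_lt(abs(mean(ms$acc == 1L) - 0.95), 3 * se / sqrt(ncol(ms$acc)))
})

test_that("molecule filtering matches an independent recount", {
  set.seed(41)
  n <- 100
  qc <- round(runif(n, 0.4, 1), 3)
  info <- sample(0:20, n, replace = TRUE)
  acc <- t(vapply(info, function(k) {
    v <- rep(NA_integer_, 20)
    if (k > 0) v[seq_len(k)] <- 1L
    v
  }, integer(20)))
  ms <- molecule_states(positions = 0:19, acc = acc,
                        conversion_qc = qc)
  out <- suppressMessages(filter_molecules(ms, min_conversion = 0.95,
                                           min_informative = 5))
  expect_equal(nrow(out$acc), sum(qc >= 0.95 & info >= 5))
  expect_identical(out$molecule_id,
                   ms$molecule_id[qc >= 0.95 & info >= 5])
})

test_that("dual-enzyme eligibility reflects endogenous methylation structure", {
  ref <- make_reference(700, gpc_spacing = 10, cpg_spacing = 20, seed = 5)
  base <- list(
    nucleosome_dyads = data.frame(offset = 0, jitter_sd = 0,
                                  occupancy_prob = 0),
    enzyme_efficiency = 1, inconversion_rate = 0, n_molecules = 200)
  run <- function(endo, seed) {
    cfg <- do.call(arch_config, c(base, list(endogenous_cpg_meth = endo,
                                             seed = seed)))
    masks <- matrix(FALSE, 200, 700)
    call_states(apply_chemistry(ref, masks, cfg, seed = seed + 1), ref)
  }
  unmeth <- run(0, 21)
  el <- check_dual_eligibility(unmeth)
  expect_true(el$eligible)
  expect_equal(el$mean_endogenous, 0)
  # fully methylated locus: ineligible, GpC-only analysis required
  meth <- run(1, 22)
  expect_false(check_dual_eligibility(meth)$eligible)
  # monoallelic 50/50 methylation: mean near 0.5, ineligible
  allelic <- run(list(alleles = c(1, 0), mix = c(0.5, 0.5)), 23)
  el3 <- check_dual_eligibility(allelic)
  expect_false(el3$eligible)
  expect_lt(abs(el3$mean_endogenous - 0.5), 0.1)
  # per-molecule means should be bimodal at 0 and 1 for the allelic pattern
  permol <- rowMeans(allelic$endo, na.rm = TRUE)
  expect_true(all(permol %in% c(0, 1)))
  # no HCG sites: undecidable
  nohcg <- make_reference(600, gpc_spacing = 10, cpg_spacing = 0, seed = 6)
  cfgn <- do.call(arch_config, c(base, list(seed = 30)))
  msn <- call_states(apply_chemistry(nohcg, matrix(FALSE, 200, 600), cfgn,
                                     seed = 31), nohcg)
  expect_error(check_dual_eligibility(msn), "undecidable")
  # dual mode on a methylated locus records the eligibility warning
  cfgm <- do.call(arch_config, c(base, list(endogenous_cpg_meth = 0.8,
                                            seed = 32)))
  rdw <- apply_chemistry(ref, matrix(FALSE, 200, 700), cfgm, mode = "dual",
                         seed = 33)
  expect_match(rdw$meta$warnings, "eligibility")
})
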