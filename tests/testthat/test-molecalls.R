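test_that("span thresholds are exact at the nucleosome and footprint bounds", {
  # dense molecules: informative site at every base, TSS at 300
  for (span in c(140, 145, 146, 150)) {
    m <- dense_molecule(600, prot_start = 300 - span %/% 2, prot_len = span)
    reg <- call_regions(m, anchors = c(300, 400))
    expect_equal(nrow(reg), 1)
    expect_equal(reg$span_bp, span)
    expect_equal(reg$label,
                 if (span >= 146) "nucleosome" else "footprint")
  }
  # the flanking accessible sites of a 146 bp span sit 147 bp apart
  m <- dense_molecule(600, prot_start = 227, prot_len = 146)
  reg <- call_regions(m, anchors = c(300, 400))
  expect_equal(reg$end - (reg$start - 1), 147)
  # footprint lower bound: >25 bp at the anchor
  for (span in c(20, 25, 26, 40)) {
    m <- dense_molecule(600, prot_start = 300 - span %/% 2, prot_len = span)
    reg <- call_regions(m, anchors = c(300, 400))
    expect_equal(reg$label,
                 if (span > 25) "footprint" else "unclassified_protected")
  }
  # same span far from both anchors: never a footprint
  m <- dense_molecule(600, prot_start = 60, prot_len = 40)
  reg <- call_regions(m, anchors = c(300, 400))
  expect_equal(reg$label, "unclassified_protected")
  # fully accessible molecule: no calls
  m <- dense_molecule(600, prot_start = 0, prot_len = 0)
  expect_equal(nrow(call_regions(m, anchors = 300)), 0)
  # a single isolated protected site never forms a region
  st <- rep(1L, 50)
  st[25] <- 0L
  m1 <- molecule_states(0:49, st)
  expect_equal(nrow(call_regions(m1, anchors = 25)), 0)
})

test_that("call_regions agrees with a brute-force scanner on random molecules", {
  set.seed(77)
  for (rep in 1:300) {
    n_sites <- sample(2:30, 1)
    pos <- sort(sample(0:400, n_sites))
    st <- sample(c(0L, 1L, NA_integer_), n_sites, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
    ms <- molecule_states(pos, st)
    got <- call_regions(ms, anchors = c(100, 200))
    want <- brute_regions(pos, st, anchors = c(100, 200))
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[c("start", "end", "span_bp", "n_sites", "label")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("turning an accessible site protected never shortens the longest span", {
  set.seed(99)
  for (rep in 1:100) {
    n_sites <- sample(5:30, 1)
    pos <- sort(sample(0:300, n_sites))
    st <- sample(c(0L, 1L), n_sites, replace = TRUE)
    ms <- molecule_states(pos, st)
    base <- call_regions(ms, anchors = numeric(0), denoise = FALSE)
    base_max <- if (nrow(base)) max(base$span_bp) else 0
    flip <- which(st == 1L)
    if (!length(flip)) next
    i <- sample(flip, 1)
    st2 <- st
    st2[i] <- 0L
    after <- call_regions(molecule_states(pos, st2), anchors = numeric(0),
                          denoise = FALSE)
    after_max <- if (nrow(after)) max(after$span_bp) else 0
    expect_gte(after_max, base_max)
  }
})

test_that("occupancy summary counts molecules whose nucleosome covers the window", {
  mk <- function(n, prot_start, prot_len) {
    acc <- matrix(1L, n, 600)
    acc[, (prot_start + 1):(prot_start + prot_len)] <- 0L
    molecule_states(0:599, acc)
  }
  ms <- mk(12, 200, 150)
  reg <- call_regions(ms, anchors = 300)
  occ <- occupancy_summary(reg, c(200, 350), n_molecules = 12)
  expect_equal(occ$k_occupied, 12)
  expect_equal(occ$fraction, 1)
  # window disjoint from every call
  occ0 <- occupancy_summary(reg, c(450, 600), n_molecules = 12)
  expect_equal(occ0$k_occupied, 0)
  expect_error(occupancy_summary(reg, c(200, 350), n_molecules = 0),
               "zero molecules")
  # below the overlap fraction: not occupied
  occ_half <- occupancy_summary(reg, c(340, 560), n_molecules = 12)
  expect_equal(occ_half$k_occupied, 0)
})

test_that("occupancy recovered from simulated molecules is binomial around truth", {
  ref <- make_reference(1000, gpc_spacing = 16, seed = 3)
  win <- c(ref$tss_offset + 147, ref$tss_offset + 293)
  cfg <- arch_config(
    nucleosome_dyads = data.frame(offset = 220, jitter_sd = 0,
                                  occupancy_prob = 0.5),
    n_molecules = 12, seed = 1)
  ks <- vapply(1:150, function(r) {
    tr <- simulate_molecules(ref, cfg, seed = 1000 + r)
    ms <- call_states(apply_chemistry(ref, tr$masks, cfg, seed = 2000 + r), ref)
    reg <- call_regions(ms, ref)
    occupancy_summary(reg, win, n_molecules = 12)$k_occupied
  }, numeric(1))
  # k ~ Binomial(12, ~0.5) (calling loses a small fraction to noise)
  expect_lt(abs(mean(ks) / 12 - 0.5), 0.06)
  expect_gt(stats::var(ks), 12 * 0.5 * 0.5 * 0.4)
  expect_true(all(ks >= 0 & ks <= 12))
})

test_that("display order is deterministic and permutation invariant", {
  set.seed(11)
  n <- 20
  acc <- matrix(1L, n, 500)
  occupied <- runif(n) < 0.5
  acc[occupied, 101:260] <- 0L
  ms <- molecule_states(0:499, acc)
  reg <- call_regions(ms, anchors = 180)
  ord1 <- sort_for_display(reg, ms$molecule_id, windows = list(c(100, 260)))
  ord2 <- sort_for_display(reg, ms$molecule_id, windows = list(c(100, 260)))
  expect_identical(ord1, ord2)
  # shuffled input rows give the same order
  perm <- sample(nrow(reg))
  ord3 <- sort_for_display(reg[perm, ], rev(ms$molecule_id),
                           windows = list(c(100, 260)))
  expect_identical(ord1, ord3)
  # occupied molecules come first
  occ_ids <- ms$molecule_id[occupied]
  expect_identical(sort(ord1[seq_along(occ_ids)]), sort(occ_ids))
})
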