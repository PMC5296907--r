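#' Assemble and validate a pipeline run configuration
#'
#' Collects every tunable of the end-to-end demonstration pipeline --
#' simulation architecture, chemistry, calling thresholds, aggregation
#' parameters -- into one validated object. All thresholds are echoed into
#' the run summary for provenance.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_loci,n_molecules Simulated loci and molecules per locus.
#' @param mode `"single"` or `"dual"` enzyme treatment.
#' @param ref_length,gpc_spacing,cpg_spacing,gene_length Reference geometry
#'   (see [make_reference()]).
#' @param architecture An [arch_config()]; defaults to the tRNA-like promoter
#'   with TSS-proximal footprints and no remodeler-enforced NDR clearing (the
#'   NDR emerges from the nucleosome positions).
#' @param salt Also simulate the salt-washed condition and compare.
#' @param thresholds Named list of calling/aggregation thresholds; partial
#'   lists are completed with defaults (nucleosome_bp 146, footprint_min_bp
#'   26, anchor_window 150, ndr_theta 0.6, prominence 5, min_delta 10,
#'   z_min 1.64, eligibility 0.10, min_conversion 0.95, min_informative 5).
#' @param bin,smoothing,flank,min_coverage Metaplot parameters.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, n_loci = 4, n_molecules = 60,
                       mode = "single", ref_length = 1200, gpc_spacing = 16,
                       cpg_spacing = 60, gene_length = 100,
                       architecture = NULL, salt = TRUE,
                       thresholds = list(), bin = 10, smoothing = 20,
                       flank = 500, min_coverage = 20) {
  if (is.null(architecture)) {
    architecture <- trna_architecture(ndr = NULL,
                                      footprints = trna_footprints(),
                                      n_molecules = n_molecules, seed = seed)
  }
  defaults <- list(nucleosome_bp = 146, footprint_min_bp = 26,
                   anchor_window = 150, ndr_theta = 0.6, prominence = 5,
                   min_delta = 10, z_min = 1.64, eligibility = 0.10,
                   min_conversion = 0.95, min_informative = 5)
  thresholds <- utils::modifyList(defaults, thresholds)
  cfg <- list(seed = seed, n_loci = n_loci, n_molecules = n_molecules,
              mode = mode, ref_length = ref_length,
              gpc_spacing = gpc_spacing, cpg_spacing = cpg_spacing,
              gene_length = gene_length, architecture = architecture,
              salt = salt, thresholds = thresholds, bin = bin,
              smoothing = smoothing, flank = flank,
              min_coverage = min_coverage)
  required <- c("seed", "n_loci", "n_molecules", "mode", "ref_length",
                "gpc_spacing", "architecture")
  for (f in required) {
    if (is.null(cfg[[f]])) stop("config missing required field '", f, "'")
  }
  if (!mode %in% c("single", "dual")) stop("config field 'mode' must be single or dual")
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the simulate-call-aggregate-compare pipeline
#'
#' End-to-end demonstration run: simulates loci with known architecture,
#' applies the chemistry, calls per-molecule states and regions, aggregates
#' TSS-anchored metaplots for the native (and optionally salt-washed)
#' condition, detects the NDR and nucleosome centers, compares conditions,
#' summarises occupancy at the configured dyads, and writes all artifacts
#' plus a machine-readable JSON summary. Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; artifacts land in `out_dir`
#'   (reference FASTA, reads FASTA, states TSV, calls BED, occupancy TSV,
#'   profile TSVs, features JSON, `summary.json`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  arch <- cfg$architecture
  arch$n_molecules <- cfg$n_molecules

  loci <- list()
  states_native <- list()
  states_salt <- list()
  regions_native <- list()
  pipeline_stage("simulate+call", {
    for (i in seq_len(cfg$n_loci)) {
      ref <- make_reference(cfg$ref_length, cfg$gpc_spacing, cfg$cpg_spacing,
                            seed = derive_seed(cfg$seed, i),
                            gene_length = cfg$gene_length,
                            locus_id = sprintf("locus%02d", i))
      truth <- simulate_molecules(ref, arch,
                                  seed = derive_seed(cfg$seed, 1000 + i))
      reads <- apply_chemistry(ref, truth$masks, arch, mode = cfg$mode,
                               seed = derive_seed(cfg$seed, 2000 + i))
      ms <- call_states(reads, ref)
      loci[[i]] <- ref
      states_native[[i]] <- ms
      regions_native[[i]] <- call_regions(
        ms, ref, anchor_window = th$anchor_window,
        nucleosome_bp = th$nucleosome_bp,
        footprint_min_bp = th$footprint_min_bp)
      if (i == 1) {
        write_locus_fasta(ref, file.path(out_dir, "reference_locus01.fa"))
        write_reads_fasta(reads, file.path(out_dir, "reads_locus01.fa"))
        write_states_tsv(ms, file.path(out_dir, "states_locus01.tsv"))
        write_regions_bed(regions_native[[i]], ref$locus_id,
                          file.path(out_dir, "calls_locus01.bed"))
      }
      if (cfg$salt) {
        salt_truth <- simulate_salt_condition(truth)
        salt_reads <- apply_chemistry(ref, salt_truth$masks, arch,
                                      mode = cfg$mode,
                                      seed = derive_seed(cfg$seed, 3000 + i))
        states_salt[[i]] <- call_states(salt_reads, ref)
      }
    }
  })

  mp_native <- mp_salt <- NULL
  features <- ndr <- ndr_salt <- flags <- NULL
  pipeline_stage("aggregate", {
    mp_native <- build_metaplot(states_native, loci, anchor = "TSS",
                                 flank = cfg$flank, bin = cfg$bin,
                                 min_coverage = cfg$min_coverage)
    sm <- smooth_profile(mp_native, cfg$smoothing)
    ndr <- detect_ndr(sm, theta = th$ndr_theta)
    write_profile_tsv(mp_native, file.path(out_dir, "profile_native.tsv"),
                      extra = list(condition = "native"))
    if (cfg$salt) {
      mp_salt <- build_metaplot(states_salt, loci, anchor = "TSS",
                                 flank = cfg$flank, bin = cfg$bin,
                                 min_coverage = cfg$min_coverage)
      ndr_salt <- detect_ndr(smooth_profile(mp_salt, cfg$smoothing),
                             theta = th$ndr_theta)
      flags <- compare_conditions(mp_native, mp_salt,
                                  min_delta = th$min_delta)
      write_profile_tsv(mp_salt, file.path(out_dir, "profile_salt.tsv"),
                        extra = list(condition = "salt"))
    }
    # TSS-proximal footprints can mask the native NDR at the anchor; the
    # salt-condition NDR then delimits the nucleosome-free zone for -1/+1
    # assignment
    ndr_for_troughs <- if (isTRUE(ndr$found) || is.null(ndr_salt)) ndr else ndr_salt
    features <- locate_nucleosome_centers(sm, prominence = th$prominence,
                                          ndr = ndr_for_troughs)
  })

  occ <- NULL
  pipeline_stage("occupancy", {
    nd <- arch$nucleosome_dyads
    occ <- lapply(seq_len(nrow(nd)), function(j) {
      half <- arch$nucleosome_len %/% 2
      k <- 0L
      n <- 0L
      for (i in seq_len(cfg$n_loci)) {
        iv <- map_interval(loci[[i]], nd$offset[j] - half,
                           nd$offset[j] - half + arch$nucleosome_len)
        s <- occupancy_summary(regions_native[[i]], c(iv[1], iv[2]),
                               n_molecules = cfg$n_molecules)
        k <- k + s$k_occupied
        n <- n + s$n_molecules
      }
      list(dyad_offset = nd$offset[j], k_occupied = k, n_molecules = n,
           fraction = k / n)
    })
  })

  summary <- list(
    config = list(seed = cfg$seed, n_loci = cfg$n_loci,
                  n_molecules = cfg$n_molecules, mode = cfg$mode,
                  ref_length = cfg$ref_length, gpc_spacing = cfg$gpc_spacing,
                  cpg_spacing = cfg$cpg_spacing, bin = cfg$bin,
                  smoothing = cfg$smoothing, flank = cfg$flank,
                  min_coverage = cfg$min_coverage, thresholds = th),
    ndr = ndr,
    ndr_salt = ndr_salt,
    troughs = features$troughs,
    minus_one = features$minus_one,
    plus_one = features$plus_one,
    phasing_period = features$phasing_period,
    occupancy = occ,
    salt_flagged = flags,
    n_regions_locus01 = nrow(regions_native[[1]]))
  pipeline_stage("summarize", {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, null = "null",
                         dataframe = "columns")
    feat_out <- list(ndr = ndr, troughs = features$troughs,
                     minus_one = features$minus_one,
                     plus_one = features$plus_one)
    jsonlite::write_json(feat_out, file.path(out_dir, "features.json"),
                         auto_unbox = TRUE, digits = 10, null = "null",
                         dataframe = "columns")
  })
  invisible(summary)
}
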