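# cli_pipeline: end-to-end orchestration over synthetic fixtures, with
# per-stage manifests and a funnel summary mirroring the screen's shape
# (input size -> pharmacophore survivors -> z-selected -> consensus pass ->
# representatives).

PIPELINE_KEYS <- c("seed", "n_actives", "n_decoys", "jitter",
                   "exclusion_cutoff", "feature_radius", "proj_radius",
                   "min_match", "z_sd", "consensus_threshold",
                   "similarity_threshold", "tpx2_conc", "read_time_s",
                   "contact_cutoff", "cons_min", "ddg_window",
                   "n_inconsistent", "n_hits", "msa_n_seqs")

#' Pipeline configuration
#'
#' All tunables default to the campaign's printed values: 4 Angstrom
#' exclusion cutoff, 1.0/1.4 Angstrom feature/projection radii, minimum 3
#' matched features, selection at more than 2 SD above the mean score,
#' 2.0 Angstrom consensus threshold, 1 uM competitor, 10 s competition
#' read point. Unknown keys are rejected.
#'
#' @param seed master seed; per-stage seeds are derived from it by fixed
#'   offsets so stages stay independently reproducible.
#' @param n_actives,n_decoys synthetic library composition.
#' @param jitter active placement jitter (Angstrom).
#' @param exclusion_cutoff,feature_radius,proj_radius,min_match hypothesis
#'   construction parameters.
#' @param z_sd z-score selection threshold in standard deviations.
#' @param consensus_threshold pairwise pose RMSD threshold (Angstrom).
#' @param similarity_threshold Tanimoto clustering threshold.
#' @param tpx2_conc competitor concentration (M).
#' @param read_time_s competition read point (s).
#' @param contact_cutoff,cons_min,ddg_window hot-spot stage parameters.
#' @param n_inconsistent,n_hits mock docking composition.
#' @param msa_n_seqs synthetic alignment depth.
#' @export
pipeline_config <- function(seed = 1, n_actives = 20, n_decoys = 80,
                            jitter = 0.4, exclusion_cutoff = 4.0,
                            feature_radius = 1.0, proj_radius = 1.4,
                            min_match = 3, z_sd = 2, consensus_threshold = 2.0,
                            similarity_threshold = 0.7, tpx2_conc = 1e-6,
                            read_time_s = 10, contact_cutoff = 4.5,
                            cons_min = 7, ddg_window = c(2, 4),
                            n_inconsistent = 3, n_hits = 2, msa_n_seqs = 12) {
  cfg <- list(seed = seed, n_actives = n_actives, n_decoys = n_decoys,
              jitter = jitter, exclusion_cutoff = exclusion_cutoff,
              feature_radius = feature_radius, proj_radius = proj_radius,
              min_match = min_match, z_sd = z_sd,
              consensus_threshold = consensus_threshold,
              similarity_threshold = similarity_threshold,
              tpx2_conc = tpx2_conc, read_time_s = read_time_s,
              contact_cutoff = contact_cutoff, cons_min = cons_min,
              ddg_window = ddg_window, n_inconsistent = n_inconsistent,
              n_hits = n_hits, msa_n_seqs = msa_n_seqs)
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a configuration list (e.g., parsed from YAML).
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(PIPELINE_KEYS, names(cfg))
  if (length(missing))
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  if (cfg$min_match < 1) stop("min_match must be >= 1")
  if (cfg$n_actives < 0 || cfg$n_decoys < 0) stop("library sizes must be >= 0")
  if (cfg$consensus_threshold <= 0) stop("consensus_threshold must be > 0")
  if (cfg$jitter >= cfg$feature_radius)
    stop("jitter must be smaller than feature_radius")
  if (length(cfg$ddg_window) != 2) stop("ddg_window must have 2 elements")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param file YAML path.
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  base <- pipeline_config()
  for (k in names(raw)) base[[k]] <- raw[[k]]
  validate_pipeline_config(base)
  base
}

stage_seed <- function(cfg, stage_index) cfg$seed + 1000L * stage_index

#' Run the full screening cascade on synthetic fixtures
#'
#' Executes hotspot -> hypothesis -> pharmacophore screen -> mock docking ->
#' z-score selection -> consensus filter -> clustering, writing one
#' manifest per stage plus a funnel summary (`summary.json`) under
#' `outdir`. Identical (config, seed) yields byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @param quiet suppress per-stage log lines (they go to stderr).
#' @return the summary list, invisibly; on stage failure an error naming
#'   the stage is raised, leaving manifests of completed work in place.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  logline <- function(stage, ...) {
    if (!quiet) message(sprintf("[ppiscreen] %-10s %s", stage, paste0(...)))
  }
  run_stage <- function(stage, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifests[[stage]] <<- res$manifest
    jsonlite::write_json(res$manifest, file.path(outdir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logline(stage, res$manifest$log)
    res$value
  }

  toy <- run_stage("fixtures", function() {
    tc <- make_toy_complex(toy_complex_spec(seed = stage_seed(config, 1)))
    writeLines(tc$pdb, file.path(outdir, "toy_complex.pdb"))
    list(value = tc,
         manifest = list(stage = "fixtures", params = list(seed = stage_seed(config, 1)),
                         outputs = "toy_complex.pdb",
                         counts = list(atoms = tc$declared$n_atoms),
                         log = sprintf("%d atoms", tc$declared$n_atoms)))
  })

  hot <- run_stage("hotspot", function() {
    msa <- make_anchor_msa(n_seqs = config$msa_n_seqs,
                           seed = stage_seed(config, 2))
    prof <- conservation_profile(msa)
    ala <- alanine_scan(toy$structure, toy$anchor,
                        contact_cutoff = config$contact_cutoff)
    hs <- rank_hotspots(prof, ala, cons_min = config$cons_min,
                        ddg_window = config$ddg_window)
    write_hotspot_report(prof, ala, hs, file.path(outdir, "hotspots.tsv"))
    list(value = hs,
         manifest = list(stage = "hotspot",
                         params = list(contact_cutoff = config$contact_cutoff,
                                       cons_min = config$cons_min,
                                       ddg_window = config$ddg_window),
                         outputs = "hotspots.tsv",
                         counts = list(hotspots = nrow(hs)),
                         log = sprintf("%d hot spot(s): %s", nrow(hs),
                                       paste(hs$resname, hs$resno, collapse = ", "))))
  })

  hyp <- run_stage("build_ph", function() {
    h <- build_hypothesis(toy$structure, toy$anchor,
                          exclusion_cutoff = config$exclusion_cutoff,
                          essential_residues = hot$resno,
                          feature_radius = config$feature_radius,
                          proj_radius = config$proj_radius,
                          min_match = config$min_match)
    ph_write_json(h, file.path(outdir, "hypothesis.json"))
    list(value = h,
         manifest = list(stage = "build_ph",
                         params = list(exclusion_cutoff = config$exclusion_cutoff,
                                       feature_radius = config$feature_radius,
                                       proj_radius = config$proj_radius,
                                       min_match = config$min_match,
                                       essential = hot$resno),
                         outputs = "hypothesis.json",
                         counts = list(features = length(h$features),
                                       points = ph_n_points(h),
                                       exclusions = nrow(h$exclusions)),
                         log = sprintf("%d features / %d points, %d exclusions",
                                       length(h$features), ph_n_points(h),
                                       nrow(h$exclusions))))
  })

  lib <- run_stage("library", function() {
    l <- make_library(library_spec(n_actives = config$n_actives,
                                   n_decoys = config$n_decoys,
                                   jitter = config$jitter,
                                   seed = stage_seed(config, 3)), hyp,
                      sdf_file = file.path(outdir, "library.sdf"),
                      labels_file = file.path(outdir, "labels.tsv"))
    list(value = l,
         manifest = list(stage = "library",
                         params = list(n_actives = config$n_actives,
                                       n_decoys = config$n_decoys,
                                       jitter = config$jitter,
                                       seed = stage_seed(config, 3)),
                         outputs = c("library.sdf", "labels.tsv"),
                         counts = list(compounds = length(l$mols)),
                         log = sprintf("%d compounds (%d actives, %d decoys)",
                                       length(l$mols), config$n_actives,
                                       config$n_decoys)))
  })

  survivors <- run_stage("screen", function() {
    s <- ph_screen(lib$mols, hyp)
    writeLines(s, file.path(outdir, "ph_survivors.txt"))
    list(value = s,
         manifest = list(stage = "screen", params = list(mode = "align"),
                         outputs = "ph_survivors.txt",
                         counts = list(input = length(lib$mols), survivors = length(s)),
                         log = sprintf("%d/%d survive the pharmacophore",
                                       length(s), length(lib$mols))))
  })

  dock <- run_stage("docking", function() {
    surv_mols <- lib$mols[survivors]
    hits <- utils::head(survivors, config$n_hits)
    incons <- utils::tail(survivors,
                          min(config$n_inconsistent, max(0, length(survivors) - config$n_hits)))
    d <- make_mock_docking(surv_mols,
                           mock_engine_spec(inconsistent_ids = incons,
                                            hit_ids = hits,
                                            seed = stage_seed(config, 4)))
    write_score_table(d$scores, file.path(outdir, "scores.tsv"))
    list(value = d,
         manifest = list(stage = "docking",
                         params = c(list(seed = stage_seed(config, 4),
                                         engines = c("dovis", "vina", "moldock")),
                                    docking_adapter_defaults()),
                         outputs = "scores.tsv",
                         counts = list(compounds = length(surv_mols),
                                       poses = length(d$poses)),
                         log = sprintf("%d poses over 3 engines", length(d$poses))))
  })

  selected <- run_stage("zselect", function() {
    sc <- dock$scores[dock$scores$engine == "dovis", ]
    scores <- stats::setNames(sc$pki, sc$compound)
    sel <- zscore_select(scores, z = config$z_sd)
    writeLines(sel, file.path(outdir, "zselected.txt"))
    list(value = sel,
         manifest = list(stage = "zselect",
                         params = list(z = config$z_sd, engine = "dovis"),
                         outputs = "zselected.txt",
                         counts = list(input = length(scores), selected = length(sel)),
                         log = sprintf("%d/%d above mean + %gSD", length(sel),
                                       length(scores), config$z_sd)))
  })

  consensus <- run_stage("consensus", function() {
    keep <- vapply(dock$poses, function(p) p$compound %in% selected, logical(1))
    cr <- consensus_filter(dock$poses[keep], hyp,
                           threshold = config$consensus_threshold)
    utils::write.table(cr, file.path(outdir, "consensus.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = cr,
         manifest = list(stage = "consensus",
                         params = list(threshold = config$consensus_threshold),
                         outputs = "consensus.tsv",
                         counts = list(input = length(selected),
                                       pass = sum(cr$pass)),
                         log = sprintf("%d/%d pass consensus + absolute refilter",
                                       sum(cr$pass), nrow(cr))))
  })

  reps <- run_stage("cluster", function() {
    passing <- consensus$compound[consensus$pass]
    if (length(passing) == 0) {
      df <- data.frame(compound = character(), cluster = integer(),
                       score = numeric(), representative = logical())
    } else {
      sc <- dock$scores[dock$scores$engine == "dovis", ]
      scores <- stats::setNames(sc$pki, sc$compound)
      df <- cluster_and_pick(lib$mols[passing], scores,
                             similarity_threshold = config$similarity_threshold)
    }
    utils::write.table(df, file.path(outdir, "representatives.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(value = df,
         manifest = list(stage = "cluster",
                         params = list(similarity_threshold = config$similarity_threshold),
                         outputs = "representatives.tsv",
                         counts = list(clusters = length(unique(df$cluster)),
                                       representatives = sum(df$representative)),
                         log = sprintf("%d cluster(s), %d representative(s)",
                                       length(unique(df$cluster)),
                                       sum(df$representative))))
  })

  summary <- list(
    config = config,
    truth = list(actives = sum(lib$labels$active),
                 decoys = sum(!lib$labels$active),
                 planted_hits = dock$truth$compound[dock$truth$hit],
                 inconsistent = dock$truth$compound[!dock$truth$consistent]),
    funnel = list(input = length(lib$mols),
                  ph_survivors = length(survivors),
                  z_selected = length(selected),
                  consensus_pass = sum(consensus$pass),
                  representatives = sum(reps$representative)),
    hotspots = hot$resno,
    representatives = reps$compound[reps$representative]
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("summary", sprintf("funnel %d -> %d -> %d -> %d -> %d",
                             summary$funnel$input, summary$funnel$ph_survivors,
                             summary$funnel$z_selected, summary$funnel$consensus_pass,
                             summary$funnel$representatives))
  invisible(summary)
}
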