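## End-to-end pipeline: superpose -> DCCM -> region classification ->
## weighted network -> allosteric pathways -> centrality -> ensemble model
## -> consensus.  Configuration defaults mirror the analysis conventions
## used throughout the package (last-10% window, 5.7 A / 0.5 contact
## pruning, 7.0 A centrality network, 8/4 folding units, overall stability
## 5 kcal/mol at 25 C); the resolved configuration and its hash are written
## into the run manifest, and a fixed config plus fixed inputs reproduces
## every output byte for byte.

#' Default pipeline configuration
#'
#' @param structure,trajectory input PDB paths (a single-model structure
#'   and a multi-model trajectory).
#' @param sites mutation-site residues (node indices or labels) whose
#'   networks and pathways are analysed.
#' @param seed integer seed (stamps the manifest; stages are themselves
#'   deterministic).
#' @return a named list of configuration values.
#' @export
default_config <- function(structure = NULL, trajectory = NULL,
                           sites = NULL, seed = 1L) {
  list(structure = structure, trajectory = trajectory, sites = sites,
       seed = seed,
       scheme_dccm = "CA", scheme_network = "CB",
       window = NULL, window_fraction = 0.10,
       superpose_reference = "mean",
       contact_cutoff = 5.7, freq_threshold = 0.5,
       cost_transform = "neglog",
       centrality_cutoff = 7.0,
       tier_thresholds = c(yellow = 0.4, orange = 0.55, red = 0.7),
       anti_threshold = -0.4,
       eam_window = 8L, eam_min_terminal = 4L,
       eam_overall_dg = 5, eam_temperature = 298.15,
       eam_energies = "uniform",   # or "contact"
       ddg_cutoff = 0.2, ddg_mode = "absolute")
}

stage_msg <- function(stage, t0, hash) {
  message(sprintf("[%s] done in %.2fs (config %s)", stage,
                  as.numeric(proc.time()[3L]) - t0, hash))
}

#' Run the full dynamic-network pipeline
#'
#' Executes every stage on the configured inputs and writes all tabular
#' outputs plus a JSON manifest into `out_dir`.  Any stage failure aborts
#' with the stage name in the error message.  Identical configuration and
#' inputs produce byte-identical output trees.
#'
#' @param config configuration list (see [default_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$structure) || !file.exists(cfg$structure))
    stop("pipeline config: structure file missing (",
         cfg$structure %||% "NULL", ")")
  if (is.null(cfg$trajectory) || !file.exists(cfg$trajectory))
    stop("pipeline config: trajectory file missing (",
         cfg$trajectory %||% "NULL", ")")
  if (is.null(cfg$sites) || length(cfg$sites) == 0L)
    stop("pipeline config: no mutation sites given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(proc.time()[3L])
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_msg(stage, t0, hash)
    r
  }

  io <- run_stage("read", {
    list(structure = read_structure(cfg$structure),
         trajectory = read_trajectory(cfg$trajectory))
  })
  n <- n_residues(io$structure)
  sites <- vapply(cfg$sites, function(s)
    resolve_residue(list(labels = residue_labels(io$structure)), s),
    integer(1L))

  traj <- run_stage("superpose",
                    superpose_frames(io$trajectory,
                                     cfg$superpose_reference))
  dccm <- run_stage("dccm", {
    w <- cfg[["window"]]   # exact: NULL means "use the window fraction"
    if (is.null(w)) {
      FF <- traj$n_frames
      w <- c(max(1L, FF - max(2L, ceiling(cfg$window_fraction * FF)) + 1L),
             FF)
    }
    compute_dccm(traj, window = w, scheme = cfg$scheme_dccm)
  })
  regions <- run_stage("classify", {
    per_site <- lapply(sites, function(s)
      classify_regions(dccm, s, cfg$tier_thresholds, cfg$anti_threshold))
    names(per_site) <- residue_labels(io$structure)[sites]
    list(per_site = per_site, combined = combine_regions(per_site))
  })
  network <- run_stage("network", {
    freqs <- contact_frequencies(traj, cfg$contact_cutoff,
                                 cfg$scheme_network)
    build_weighted_network(dccm, freqs, cfg$freq_threshold,
                           cfg$cost_transform)
  })
  pathways <- run_stage("pathways", {
    pw <- lapply(seq_along(sites), function(k) {
      targets <- regions$per_site[[k]]
      allosteric_pathways(network, sites[k], targets)
    })
    names(pw) <- names(regions$per_site)
    pw
  })
  centrality <- run_stage("centrality", {
    nets <- build_contact_network(traj, cfg$centrality_cutoff,
                                  cfg$scheme_network)
    list(bc = betweenness_profile(nets), L = reachability_profile(nets))
  })
  eam <- run_stage("eam", {
    part <- make_partition(n, cfg$eam_window, cfg$eam_min_terminal)
    energies <- switch(cfg$eam_energies,
                       uniform = NULL,
                       contact = contact_unit_energies(
                         io$structure, part, cfg$eam_overall_dg,
                         cfg$centrality_cutoff),
                       stop("unknown eam_energies mode"))
    ens <- enumerate_ensemble(part, energies, cfg$eam_overall_dg,
                              cfg$eam_temperature)
    scans <- lapply(sites, function(s)
      mutation_scan(ens, s, resid = io$structure$residues$resid[s]))
    names(scans) <- names(regions$per_site)
    sus <- lapply(seq_along(scans), function(k)
      susceptible_regions(scans[[k]], cfg$ddg_cutoff, cfg$ddg_mode,
                          exclude_site = sites[k]))
    names(sus) <- names(scans)
    list(ensemble = ens, stability = residue_stability(ens), scans = scans,
         susceptible = sus, combined = combine_regions(sus))
  })
  consensus <- run_stage("consensus", {
    rep_md_eam <- consistency_percent(regions$combined, eam$combined,
                                      c(query = "dccm", reference = "eam"))
    list(md_vs_eam = rep_md_eam,
         common = common_regions(regions$combined, eam$combined),
         track = render_track(list(dccm = regions$combined,
                                   eam = eam$combined,
                                   common = common_regions(
                                     regions$combined, eam$combined)), n))
  })

  run_stage("write", {
    out <- function(f) file.path(out_dir, f)
    write_matrix_tsv(dccm$values, out("dccm.tsv"))
    for (nm in names(regions$per_site))
      write_region_tsv(regions$per_site[[nm]],
                       out(sprintf("regions_%s.tsv", nm)))
    write_region_tsv(regions$combined, out("regions_combined.tsv"))
    write_edge_tsv(network, out("network_edges.tsv"))
    for (nm in names(pathways)) {
      pw <- pathways[[nm]]
      df <- do.call(rbind, lapply(names(pw$paths), function(tg) {
        p <- pw$paths[[tg]]
        data.frame(target = tg, found = p$found,
                   cost = ifelse(p$found, p$cost, NA_real_),
                   path = paste(p$labels, collapse = "-"))
      }))
      write_tsv_file(df %||% data.frame(), out(sprintf("pathways_%s.tsv",
                                                       nm)))
    }
    write_centrality_tsv(centrality$bc, centrality$L,
                         out("centrality.tsv"))
    eam_tab <- eam$stability
    for (nm in names(eam$scans))
      eam_tab[[paste0("ddG_", nm)]] <- eam$scans[[nm]]$ddG
    write_tsv_file(eam_tab, out("eam_residue.tsv"))
    write_region_tsv(eam$combined, out("eam_regions_combined.tsv"))
    write_track_tsv(consensus$track, out("consensus_track.tsv"))
    jsonlite::write_json(
      list(md_vs_eam = list(percent = consensus$md_vs_eam$percent,
                            jaccard = consensus$md_vs_eam$jaccard,
                            recovered = consensus$md_vs_eam$recovered,
                            reference_size =
                              consensus$md_vs_eam$reference_size,
                            query_size = consensus$md_vs_eam$query_size)),
      out("consensus.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(config = cfg, config_hash = hash,
                     n_residues = n, n_frames = traj$n_frames,
                     sites = unname(sites),
                     outputs = sort(setdiff(list.files(out_dir),
                                            "manifest.json")))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    NULL
  })
  invisible(list(config = cfg, hash = hash, dccm = dccm, regions = regions,
                 network = network, pathways = pathways,
                 centrality = centrality, eam = eam,
                 consensus = consensus))
}
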