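dynamics_param_defaults <- function() {
  list(n_frames = 5000L, stiffen_factor = 5, network_cutoff = 6,
       contact_cutoff = 6, occupancy_min = 0.5, corr_min = 0.05,
       spm_threshold = 0.3, bandwidth = "auto",
       distance_modes = c(4.4, 7.8), distance_sigma = 0.3,
       distance_n = 10000L)
}

kinetics_param_defaults <- function() {
  # generating parameters: WT holoenzyme saturation, WT melt, the two
  # regulator titrations (quadratic and Hill) and the fold tables
  list(mm = list(k_cat = 1.72, K_M = 0.44),
       melt = list(LL = 0, UL = 1, T_m = 55, c = 2),
       binding = list(V_max = 1, G = 0.42, K_D = 0.44),
       hill = list(V_max = 1, K_half = 8.1, h = 1.68),
       s_grid = NULL, t_grid = NULL, z_grid_binding = NULL, z_grid_hill = NULL,
       noise_sd = 0)
}

#' Pipeline configuration
#'
#' Validates a parameter list against the chosen workflow's known keys
#' (unknown keys are rejected) and fills defaults. All randomness flows
#' from the single `seed`, split internally per stage.
#'
#' @param workflow `"dynamics"` or `"kinetics"`.
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param params named list overriding stage parameters; see
#'   the package vignette for the meaning and default of each.
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(workflow = c("dynamics", "kinetics"),
                            out_dir, seed = 1L, params = list()) {
  workflow <- match.arg(workflow)
  defaults <- if (workflow == "dynamics") dynamics_param_defaults()
              else kinetics_param_defaults()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop_("unknown parameter key(s): %s",
                             paste(unknown, collapse = ", "))
  merged <- utils::modifyList(defaults, params)
  structure(list(workflow = workflow, out_dir = out_dir,
                 seed = as.integer(seed), params = merged,
                 version = as.character(utils::packageVersion("allonet"))),
            class = "PipelineConfig")
}

stage_seed <- function(config, offset) {
  as.integer((as.numeric(config$seed) * 1000 + offset) %% 2147483647)
}

manifest_entry <- function(paths) {
  lapply(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
}

finish_manifest <- function(config, outputs, extra = list()) {
  man <- c(list(workflow = config$workflow, version = config$version,
                seed = config$seed, parameters = config$params,
                timestamp = format(Sys.time(), tz = "UTC"),
                outputs = manifest_entry(outputs)),
           extra)
  path <- file.path(config$out_dir, paste0(config$workflow, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man$manifest_path <- path
  invisible(man)
}

#' Run the dynamics workflow
#'
#' Toy-dimer version of the ensemble analysis chain: build the
#' elastic-network dimer and its regulator-bound (interface-stiffened)
#' variant, sample Gaussian ensembles, superpose, compute DCCMs and their
#' Spearman comparison, build residue graphs, SPM, CPL, node-weakening
#' table, DFI profiles, and a bimodal side-chain--ligand distance
#' distribution. Every stage output is written under `config$out_dir` and
#' recorded (with MD5 hashes, seeds and the parameter values actually
#' used) in a JSON run manifest.
#'
#' @param config a `PipelineConfig` with `workflow = "dynamics"`.
#' @return the run manifest, invisibly.
#' @export
run_dynamics_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"), config$workflow == "dynamics")
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  path <- function(f) file.path(config$out_dir, f)

  net_apo <- make_toy_dimer(cutoff = p$network_cutoff)
  net_bound <- stiffen_intersubunit(net_apo, p$stiffen_factor)
  cov_apo <- network_covariance(net_apo, mode = "scalar")
  cov_bound <- network_covariance(net_bound, mode = "scalar")

  traj_apo <- sample_ensemble(cov_apo, p$n_frames, seed = stage_seed(config, 1L))
  traj_bound <- sample_ensemble(cov_bound, p$n_frames, seed = stage_seed(config, 2L))
  write_ensemble(traj_apo, path("ensemble_nonactivated.csv")); out <- c(out, path("ensemble_nonactivated.csv"))
  write_ensemble(traj_bound, path("ensemble_activated.csv")); out <- c(out, path("ensemble_activated.csv"))

  dccm_apo <- compute_dccm(traj_apo, superpose = FALSE)
  dccm_bound <- compute_dccm(traj_bound, superpose = FALSE)
  write_correlation_matrix(dccm_apo, path("dccm_nonactivated.tsv"))
  write_correlation_matrix(dccm_bound, path("dccm_activated.tsv"))
  out <- c(out, path("dccm_nonactivated.tsv"), path("dccm_activated.tsv"))

  comp <- compare_dccm_spearman(dccm_apo, dccm_bound)

  graphs <- list(nonactivated = build_residue_graph(traj_apo, dccm_apo,
                                                    p$contact_cutoff, p$occupancy_min, p$corr_min),
                 activated = build_residue_graph(traj_bound, dccm_bound,
                                                 p$contact_cutoff, p$occupancy_min, p$corr_min))
  spm_summary <- list()
  for (nm in names(graphs)) {
    spm <- compute_spm(graphs[[nm]], threshold = p$spm_threshold)
    export_graph(graphs[[nm]], graphml_path = path(sprintf("graph_%s.graphml", nm)),
                 edges_path = path(sprintf("edges_%s.tsv", nm)), spm = spm)
    out <- c(out, path(sprintf("graph_%s.graphml", nm)), path(sprintf("edges_%s.tsv", nm)))
    inter <- node_subunit(spm$edges$i) != node_subunit(spm$edges$j)
    spm_summary[[nm]] <- list(
      n_spm_edges = sum(spm$edges$in_spm),
      n_inter_subunit_spm_edges = sum(spm$edges$in_spm & inter),
      cpl = characteristic_path_length(graphs[[nm]])$cpl)
  }
  nw <- node_weakening(graphs$activated, candidates = net_apo$interface)
  write_node_weakening(nw, path("node_weakening_interface.csv"))
  out <- c(out, path("node_weakening_interface.csv"))

  for (nm in names(graphs)) {
    cov <- if (nm == "nonactivated") cov_apo else cov_bound
    prof <- dfi_profile(perturbation_response_matrix(cov))
    write_dfi(prof, path(sprintf("dfi_%s.csv", nm)))
    out <- c(out, path(sprintf("dfi_%s.csv", nm)))
  }

  dist <- simulate_distance_series(p$distance_modes, sigma = p$distance_sigma,
                                   n = p$distance_n, seed = stage_seed(config, 3L),
                                   point_a = "R56:CZ", point_b = "PRPP:PA")
  write_distance_series(dist, path("distance_R56_PRPP.csv"))
  out <- c(out, path("distance_R56_PRPP.csv"))
  dd <- distance_distribution(dist, bandwidth = p$bandwidth)

  finish_manifest(config, out, extra = list(
    spearman = list(rho = comp$rho, n = comp$n, region = comp$region),
    spm = spm_summary,
    node_weakening_top = nw$table$node[1],
    distance_modes_detected = dd$modes))
}

#' Run the kinetics workflow
#'
#' Generates datasets from the four measurement models (Michaelis-Menten
#' saturation, thermal melt, tight-binding activation titration, Hill
#' sigmoid) at the configured generating parameters, fits each with the
#' corresponding fit routine, writes one JSON fit report per model plus a
#' fold-change table, and records a manifest.
#'
#' @param config a `PipelineConfig` with `workflow = "kinetics"`.
#' @return the run manifest, invisibly.
#' @export
run_kinetics_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"), config$workflow == "kinetics")
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  path <- function(f) file.path(config$out_dir, f)

  s_grid <- p$s_grid %||% (p$mm$K_M * c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16))
  t_grid <- p$t_grid %||% seq(25, 93, by = 1)
  zb <- p$z_grid_binding %||% seq(0, 5.1, length.out = 12)
  zh <- p$z_grid_hill %||% seq(0, 26.9, length.out = 12)

  fits <- list(
    mm = fit_michaelis(simulate_rate_data("eq1", p$mm, s_grid, p$noise_sd,
                                          seed = stage_seed(config, 11L))),
    melt = fit_melting(simulate_rate_data("eq2", p$melt, t_grid, p$noise_sd,
                                          seed = stage_seed(config, 12L))),
    binding = fit_binding(simulate_rate_data("eq3", p$binding, zb, p$noise_sd,
                                             seed = stage_seed(config, 13L))),
    hill = fit_hill(simulate_rate_data("eq5", p$hill, zh, p$noise_sd,
                                       seed = stage_seed(config, 14L))))
  for (nm in names(fits)) {
    write_fit_json(fits[[nm]], path(sprintf("fit_%s.json", nm)))
    out <- c(out, path(sprintf("fit_%s.json", nm)))
  }

  folds <- rate_fold_tables()
  write.csv(folds, path("fold_changes.csv"), row.names = FALSE, quote = FALSE)
  out <- c(out, path("fold_changes.csv"))

  finish_manifest(config, out, extra = list(
    recovered = list(k_cat = fits$mm$k_cat, K_M = fits$mm$K_M,
                     T_m = fits$melt$T_m, K_D_app = fits$binding$K_D_app,
                     K_half = fits$hill$K_half, h = fits$hill$h)))
}

#' Catalytic-impairment and activation fold tables
#'
#' Recomputes the impairment folds (WT catalytic-subunit rate over each
#' variant's rate) and the activation folds (holoenzyme k_cat over the
#' corresponding nonactivated rate) from the measured rate constants of
#' the HisGS variants, with both the exact ratio and the integer fold.
#'
#' @param rates optional data.frame overriding the built-in measured rate
#'   constants (columns `variant`, `v_alone` in 1/s, `k_cat_holo` in 1/s;
#'   WT row required).
#' @return data.frame with one row per variant and columns for both
#'   tables.
#' @export
rate_fold_tables <- function(rates = NULL) {
  rates <- rates %||% data.frame(
    variant = c("WT", "C115S", "R32A", "R56A", "R56A/K57A"),
    v_alone = c(0.0586, 0.0005, 0.0023, 0.0014, 0.00023),
    k_cat_holo = c(1.72, 0.93, 0.48, 0.35, 0.12))
  wt <- rates$v_alone[rates$variant == "WT"]
  if (!length(wt)) stop_("rates must contain a WT row")
  do.call(rbind, lapply(seq_len(nrow(rates)), function(r) {
    imp <- fold_change(wt, rates$v_alone[r],
                       num_label = "WT v/E_T", den_label = rates$variant[r])
    act <- fold_change(rates$k_cat_holo[r], rates$v_alone[r],
                       num_label = paste(rates$variant[r], "k_cat (holo)"),
                       den_label = paste(rates$variant[r], "v/E_T"))
    data.frame(variant = rates$variant[r],
               impairment_fold = imp$fold,
               impairment_fold_int = imp$fold_rounded,
               activation_fold = act$fold,
               activation_fold_int = act$fold_rounded)
  }))
}
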