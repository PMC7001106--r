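# Configuration-driven orchestration: mixed-bilayer simulation -> density /
# site detection / contacts -> umbrella + WHAM per species -> alchemical MBAR
# -> PMF-vs-FEP consistency -> geometry metrics.  Every stage writes its
# table under the output directory and registers ground truth + results in a
# JSON manifest; identical config + seed reproduces the manifest bit for bit.

#' Default run configuration
#'
#' Two presets: `"ci"` (reduced sampling for quick runs) and `"reference"`
#' (the sampling used for the headline depth-recovery numbers).  The planted
#' well depths are the reference PMF well-depth magnitudes for the four
#' anionic species (PIP2 37, PIP3 28, PIP 20, PS 9 kJ/mol).
#'
#' @param preset `"ci"` or `"reference"`.
#' @return Nested configuration list.
#' @export
default_config <- function(preset = c("ci", "reference")) {
  preset <- match.arg(preset)
  ref <- preset == "reference"
  list(
    preset = preset,
    seed = 1L,
    bilayer = list(lipids_per_leaflet = if (ref) 200L else 60L,
                   box = c(12, 12, 6)),
    wells = list(PIP2 = list(depth = 37, sigma = 0.3),
                 PIP3 = list(depth = 28, sigma = 0.3),
                 PIP = list(depth = 20, sigma = 0.3),
                 PS = list(depth = 9, sigma = 0.3)),
    protein = list(core_radius = 1.5, wall_k = 200),
    dynamics = list(D = 0.1, dt = 0.01,
                    n_steps = if (ref) 40000L else 8000L,
                    save_every = 20L, temperature = 310),
    density = list(spacing = 0.1, threshold = 0.35, min_peak = 0.05),
    contacts = list(on_cutoff = 0.55, off_cutoff = 1.0),
    umbrella = list(n_windows = 38L, range = c(-0.7, 3.0), k = 500,
                    lateral_k = 100, dt = 0.004,
                    steps_per_window = if (ref) 68000L else 16000L,
                    burn_in_fraction = 0.25,
                    bin_width = 0.05, bulk_interval = c(2.5, 3.0)),
    fep = list(pair = c("PIP2", "PIP"), n_windows = 21L,
               steps_per_window = if (ref) 22000L else 8000L,
               burn_in_fraction = 0.1, dt = 0.002)
  )
}

#' Read a run configuration from YAML
#'
#' Values in the file override the preset defaults (shallow-merged per
#' section); the resolved configuration is what [run_pipeline()] serializes
#' next to its outputs, so no run depends on silent defaults.
#'
#' @param path YAML file path.
#' @return Resolved configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(if (!is.null(user$preset)) user$preset else "ci")
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(base[[sec]])) {
      for (key in names(user[[sec]])) base[[sec]][[key]] <- user[[sec]][[key]]
    } else {
      base[[sec]] <- user[[sec]]
    }
  }
  validate_config(base)
  base
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed),
            cfg$bilayer$lipids_per_leaflet >= 1,
            length(cfg$bilayer$box) == 3,
            all(vapply(cfg$wells, function(w) w$depth >= 0 && w$sigma > 0,
                       logical(1))),
            cfg$umbrella$n_windows >= 2, cfg$umbrella$k > 0,
            cfg$fep$n_windows >= 2,
            cfg$contacts$off_cutoff >= cfg$contacts$on_cutoff)
  invisible(cfg)
}

# derived per-stage RNG streams: one root seed, documented offsets, so any
# stage can be re-run in isolation with the same stream
stage_seed <- function(root, stage) {
  offsets <- c(bilayer = 101L, binding = 211L, umbrella = 307L, fep = 401L,
               geometry = 503L, bootstrap = 601L)
  (as.integer(root) * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

#' Build the planted tetramer-mimetic system for one species
#'
#' A mixed bilayer (mimetic composition) merged with the protein core and
#' four symmetry-related wells acting on `species`.
#'
#' @param cfg Configuration list (see [default_config()]).
#' @param species Species whose planted well is used.
#' @param four_fold Four wells (default) or one.
#' @return List with `system`, `potentials`, `anchors`, `ground_truth`.
#' @export
build_planted_system <- function(cfg, species = "PIP2", four_fold = TRUE) {
  w <- cfg$wells[[species]]
  if (is.null(w)) stop("no planted well configured for species ", species)
  site <- make_planted_site_system(w$depth, w$sigma, species = species,
                                   four_fold = four_fold,
                                   box = cfg$bilayer$box,
                                   core_radius = cfg$protein$core_radius,
                                   wall_k = cfg$protein$wall_k)
  bl <- build_bilayer(bilayer_spec(lipids_per_leaflet =
                                     cfg$bilayer$lipids_per_leaflet,
                                   box = cfg$bilayer$box),
                      seed = stage_seed(cfg$seed, "bilayer"))
  sys <- merge_systems(site$anchor_system, bl)
  list(system = sys, potentials = site$potentials, anchors = site$anchors,
       ground_truth = list(species = species, depth = w$depth,
                           sigma = w$sigma))
}

#' Umbrella + WHAM well-depth recovery for one planted species
#'
#' The complete PMF protocol on a single planted well: build the site system,
#' run the window ladder, reconstruct with WHAM, and report the bulk-zeroed
#' well depth.
#'
#' @param depth Planted well depth (kJ/mol, magnitude).
#' @param sigma Well width (nm). Default 0.3.
#' @param cfg Configuration (umbrella section + protein geometry).
#' @param seed RNG seed.
#' @param n_boot Bootstrap resamples for the depth error (0 = skip).
#' @return List with `pmf`, `depth` (recovered, kJ/mol), `error`
#'   (bootstrap SD or NA), `uset`.
#' @export
recover_planted_depth <- function(depth, sigma = 0.3,
                                  cfg = default_config("reference"),
                                  seed = 1L, n_boot = 0L) {
  um <- cfg$umbrella
  site <- make_planted_site_system(depth, sigma, species = "TAGGED",
                                   four_fold = FALSE, box = cfg$bilayer$box,
                                   core_radius = cfg$protein$core_radius,
                                   wall_k = cfg$protein$wall_k)
  sys <- site$anchor_system
  rc <- reaction_coordinate(anchor_ids = 1L, axis = c(1, 0))
  spec <- umbrella_spec(n_windows = um$n_windows, range = um$range, k = um$k,
                        lateral_k = um$lateral_k,
                        steps_per_window = um$steps_per_window,
                        burn_in_fraction = um$burn_in_fraction)
  uset <- run_umbrella_sampling(sys, site$potentials, rc, spec,
                                params = dynamics_params(dt = um$dt,
                                                         save_every = 1L,
                                                         min_sigma = sigma),
                                seed = seed)
  pmf <- wham(uset, bin_width = um$bin_width,
              bulk_interval = um$bulk_interval)
  err <- if (n_boot > 0) {
    bootstrap_well_depth_error(uset, n_boot = n_boot,
                               seed = stage_seed(seed, "bootstrap"),
                               bin_width = um$bin_width,
                               bulk_interval = um$bulk_interval)
  } else NA_real_
  list(pmf = pmf, depth = well_depth(pmf), error = err, uset = uset)
}

#' Alchemical ddG between two planted species
#'
#' Runs the lambda ladder interpolating the two species' site wells (same
#' anchor, same width unless configured otherwise) and estimates the
#' bound-state ddG with MBAR.
#'
#' @param depth_a,depth_b Planted depths (kJ/mol) of the two endpoints.
#' @param sigma Well width (nm).
#' @param cfg Configuration (fep section + protein geometry).
#' @param seed RNG seed.
#' @return List with `ddg` (kJ/mol, positive = B binds more weakly),
#'   `error`, `mbar`, `samples`.
#' @export
fep_planted_ddg <- function(depth_a, depth_b, sigma = 0.3,
                            cfg = default_config("reference"), seed = 1L) {
  fp <- cfg$fep
  site_a <- make_planted_site_system(depth_a, sigma, four_fold = FALSE,
                                     box = cfg$bilayer$box,
                                     core_radius = cfg$protein$core_radius,
                                     wall_k = cfg$protein$wall_k)
  site_b <- make_planted_site_system(depth_b, sigma, four_fold = FALSE,
                                     box = cfg$bilayer$box,
                                     core_radius = cfg$protein$core_radius,
                                     wall_k = cfg$protein$wall_k)
  rc <- reaction_coordinate(anchor_ids = 1L, axis = c(1, 0))
  samples <- run_alchemical(site_a$anchor_system,
                            alchemical_mix(site_a$potentials,
                                           site_b$potentials),
                            rc, n_windows = fp$n_windows,
                            steps_per_window = fp$steps_per_window,
                            burn_in_fraction = fp$burn_in_fraction,
                            params = dynamics_params(dt = fp$dt,
                                                     save_every = 1L,
                                                     min_sigma = sigma),
                            seed = seed)
  est <- mbar_ddg(samples)
  list(ddg = est$dG, error = est$error, mbar = est, samples = samples)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: mixed-bilayer build; binding simulation with
#' four planted wells; density map + site detection + distance traces +
#' contact durations; umbrella/WHAM depth recovery per configured species;
#' alchemical MBAR for the configured pair; PMF-vs-FEP consistency; geometry
#' metrics on deterministic fixtures.  Outputs (TSV/OpenDX/JSON) land under
#' `out_dir`; the manifest records planted ground truth next to every
#' recovered value.
#'
#' @param cfg Configuration list ([default_config()] or [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("binding", "mapping", "pmf", "fep", "geometry")` to run; earlier
#'   stages are loaded from `out_dir` when skipped.
#' @return The manifest (list), invisibly written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(cfg = default_config("ci"), out_dir = tempfile("memsite_run_"),
                         stages = c("binding", "mapping", "pmf", "fep",
                                    "geometry")) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yml"))
  manifest <- list(seed = cfg$seed, preset = cfg$preset, stages = list())
  t_all <- proc.time()[3]

  traj_path <- file.path(out_dir, "binding_trajectory.txt")
  if ("binding" %in% stages) {
    t0 <- proc.time()[3]
    planted <- build_planted_system(cfg, species = "PIP2", four_fold = TRUE)
    dyn <- cfg$dynamics
    traj <- simulate_dynamics(planted$system, planted$potentials,
                              params = dynamics_params(
                                D = dyn$D, dt = dyn$dt,
                                temperature = dyn$temperature,
                                n_steps = dyn$n_steps,
                                save_every = dyn$save_every,
                                seed = stage_seed(cfg$seed, "binding"),
                                min_sigma = min(vapply(cfg$wells, `[[`,
                                                       numeric(1), "sigma"))))
    write_trajectory(traj, traj_path)
    manifest$stages$binding <- list(
      n_frames = n_frames(traj),
      n_lipids = sum(planted$system$particles$role == "lipid_head"),
      pip2_fraction = overall_mole_fraction(planted$system, "PIP2"),
      ground_truth = list(wells = cfg$wells,
                          anchors = planted$anchors),
      seconds = round(proc.time()[3] - t0, 2))
    message("stage binding: ", n_frames(traj), " frames [",
            manifest$stages$binding$seconds, " s]")
  }

  if ("mapping" %in% stages) {
    t0 <- proc.time()[3]
    traj <- read_trajectory(traj_path)
    dmap <- occupancy_density(traj, role = "lipid_head", species = "PIP2",
                              spacing = cfg$density$spacing)
    write_density_map(dmap, file.path(out_dir, "pip2_density.dx"))
    sites <- detect_sites(dmap, threshold = cfg$density$threshold,
                          min_peak = cfg$density$min_peak)
    utils::write.table(as.data.frame(sites), file.path(out_dir, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dser <- distance_to_site_series(traj, species = "PIP2",
                                    site_of = "eventual")
    utils::write.table(dser, file.path(out_dir, "pip2_site_distance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ctab <- residue_contact_durations(traj, species = "PIP2",
                                      on_cutoff = cfg$contacts$on_cutoff,
                                      off_cutoff = cfg$contacts$off_cutoff,
                                      residue_roles = "site_anchor")
    contact_table_report(ctab, file.path(out_dir, "pip2_contacts.tsv"))
    manifest$stages$mapping <- list(
      n_sites = nrow(sites),
      site_centers = sites[, c("x", "y")],
      max_mean_contact = max(ctab$mean_duration),
      seconds = round(proc.time()[3] - t0, 2))
    message("stage mapping: ", nrow(sites), " site(s) detected [",
            manifest$stages$mapping$seconds, " s]")
  }

  if ("pmf" %in% stages) {
    t0 <- proc.time()[3]
    pmf_rows <- list()
    for (sp in names(cfg$wells)) {
      w <- cfg$wells[[sp]]
      rec <- recover_planted_depth(w$depth, w$sigma, cfg,
                                   seed = stage_seed(cfg$seed, "umbrella"))
      utils::write.table(
        data.frame(s = rec$pmf$s, G = rec$pmf$G, error = rec$pmf$error),
        file.path(out_dir, paste0("pmf_", sp, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      pmf_rows[[sp]] <- list(planted = -w$depth,
                             recovered = rec$depth)
      message("stage pmf (", sp, "): planted ", -w$depth, ", recovered ",
              round(rec$depth, 2), " kJ/mol")
    }
    depths <- vapply(pmf_rows, `[[`, numeric(1), "recovered")
    ddg <- list()
    if (all(c("PIP2", "PIP") %in% names(depths))) {
      ddg$PIP2_to_PIP <- unname(depths["PIP"] - depths["PIP2"])
    }
    if (all(c("PIP2", "PIP3") %in% names(depths))) {
      ddg$PIP2_to_PIP3 <- unname(depths["PIP3"] - depths["PIP2"])
    }
    manifest$stages$pmf <- list(wells = pmf_rows, ddg_pmf = ddg,
                                seconds = round(proc.time()[3] - t0, 2))
  }

  if ("fep" %in% stages) {
    t0 <- proc.time()[3]
    pair <- cfg$fep$pair
    fep <- fep_planted_ddg(cfg$wells[[pair[1]]]$depth,
                           cfg$wells[[pair[2]]]$depth,
                           sigma = cfg$wells[[pair[1]]]$sigma, cfg,
                           seed = stage_seed(cfg$seed, "fep"))
    cons <- NULL
    if (!is.null(manifest$stages$pmf)) {
      key <- paste0(pair[1], "_to_", pair[2])
      pmf_val <- manifest$stages$pmf$ddg_pmf[[key]]
      if (!is.null(pmf_val)) cons <- consistency_check(fep$ddg, pmf_val)
    }
    utils::write.table(
      data.frame(lambda = fep$samples$lambda,
                 f_reduced = fep$mbar$f),
      file.path(out_dir, "fep_lambda_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$fep <- list(pair = pair, ddg_fep = fep$ddg,
                                error = fep$error, consistency = cons,
                                seconds = round(proc.time()[3] - t0, 2))
    message("stage fep: ddG(", pair[1], "->", pair[2], ") = ",
            round(fep$ddg, 2), " +/- ", round(fep$error, 2), " kJ/mol")
  }

  if ("geometry" %in% stages) {
    t0 <- proc.time()[3]
    hb <- make_geometry_fixtures("hbond",
                                 seed = stage_seed(cfg$seed, "geometry"))
    roles <- attr(hb, "hbond_roles")
    hbs <- hbond_series(hb, roles$donors, roles$hydrogens, roles$acceptors,
                        path = file.path(out_dir, "hbond_series.tsv"))
    lp <- make_geometry_fixtures("ligand_pose", jitter = 0.02,
                                 seed = stage_seed(cfg$seed, "geometry"))
    pr <- attr(lp, "pose_roles")
    rser <- ligand_rmsd_series(lp, pr$copies, pr$fit)
    utils::write.table(rser, file.path(out_dir, "ligand_rmsd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$geometry <- list(
      hbonds_frame1 = sum(hbs[1, -1]),
      rmsd_final = as.numeric(rser[nrow(rser), -1]),
      seconds = round(proc.time()[3] - t0, 2))
    message("stage geometry: ", sum(hbs[1, -1]), " H-bonds in fixture [",
            manifest$stages$geometry$seconds, " s]")
  }

  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Acceptance report from a pipeline manifest
#'
#' Compares every recovered quantity in a stored manifest against its planted
#' ground truth: overall PIP2 mole fraction (exact), per-species well-depth
#' recovery, the PMF-route relative free energies, and the FEP-vs-PMF
#' consistency.  Self-contained: it reads only the manifest, so re-running it
#' on stored results reproduces the same report.
#'
#' @param manifest A manifest list from [run_pipeline()] (or read back from
#'   `manifest.json`).
#' @param tol_depth Well-depth recovery tolerance (kJ/mol). Default 2.
#' @param tol_ddg ddG tolerance (kJ/mol). Default 2.
#' @param tol_consistency FEP-vs-PMF agreement tolerance (kJ/mol). Default 3.
#' @return `data.frame` with columns `check`, `value`, `expected`, `tol`,
#'   `pass`.
#' @export
acceptance_report <- function(manifest, tol_depth = 2, tol_ddg = 2,
                              tol_consistency = 3) {
  rows <- list()
  add <- function(check, value, expected, tol) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, value = value, expected = expected, tol = tol,
      pass = is.finite(value) && abs(value - expected) <= tol)
  }
  if (!is.null(manifest$stages$binding)) {
    add("overall_pip2_fraction", manifest$stages$binding$pip2_fraction,
        0.05, 1e-12)
  }
  if (!is.null(manifest$stages$pmf)) {
    for (sp in names(manifest$stages$pmf$wells)) {
      w <- manifest$stages$pmf$wells[[sp]]
      add(paste0("depth_recovery_", sp), w$recovered, w$planted, tol_depth)
    }
    gt <- manifest$stages$pmf$wells
    for (key in names(manifest$stages$pmf$ddg_pmf)) {
      pair <- strsplit(key, "_to_")[[1]]
      add(paste0("ddg_pmf_", key), manifest$stages$pmf$ddg_pmf[[key]],
          gt[[pair[2]]]$planted - gt[[pair[1]]]$planted, tol_ddg)
    }
  }
  if (!is.null(manifest$stages$fep)) {
    pair <- unlist(manifest$stages$fep$pair)
    gt <- manifest$stages$pmf$wells
    if (!is.null(gt)) {
      add(paste0("ddg_fep_", pair[1], "_to_", pair[2]),
          manifest$stages$fep$ddg_fep,
          gt[[pair[2]]]$planted - gt[[pair[1]]]$planted, tol_ddg)
      key <- paste0(pair[1], "_to_", pair[2])
      pmf_val <- manifest$stages$pmf$ddg_pmf[[key]]
      if (!is.null(pmf_val)) {
        add("fep_vs_pmf_consistency",
            manifest$stages$fep$ddg_fep - pmf_val, 0, tol_consistency)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
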