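# Config-driven end-to-end runs: simulate -> TS detection -> pocket volumes
# -> contacts -> cross-condition statistics, with deterministic seeded
# outputs and a checksum manifest.

.allowed_keys <- list(
  top = c("base_seed", "conditions", "sim", "start_distance", "ts",
          "volume", "contacts"),
  condition = c("pocket", "start_distance"),
  sim = c("dt_ps", "friction_per_ps", "temperature_K", "n_steps",
          "record_stride", "n_replicates"),
  ts = c("d_max", "attack_angle_center", "attack_angle_tol",
         "linearity_center", "linearity_tol"),
  volume = c("enabled", "spacing", "distance_cut", "contiguity", "hull",
             "proximity_mode", "fraction", "n_subsamples", "threshold",
             "selector", "spheres", "bin_edges"),
  contacts = c("enabled", "cutoff", "group_a", "group_b"),
  sphere = c("center", "radius")
)

.check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a nested list (or a YAML file path) with a
#' `conditions` block naming at least one condition (e.g. an open- and an
#' occluded-pocket system), shared `sim`, `ts`, `volume` and `contacts`
#' blocks, and a global `base_seed`. Unknown keys raise a hard error
#' listing them.
#'
#' @param config nested list or path to a YAML file.
#' @return validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .check_keys(config, .allowed_keys$top, "top level")
  if (is.null(config$conditions) || length(config$conditions) < 1L)
    stop("config needs at least one condition")
  if (is.null(names(config$conditions)) || any(names(config$conditions) == ""))
    stop("conditions must be named")
  for (nm in names(config$conditions))
    .check_keys(config$conditions[[nm]], .allowed_keys$condition,
                paste0("conditions$", nm))
  for (blk in c("sim", "ts", "volume", "contacts"))
    if (!is.null(config[[blk]]))
      .check_keys(config[[blk]], .allowed_keys[[blk]], blk)
  for (sp in config$volume$spheres)
    .check_keys(sp, .allowed_keys$sphere, "volume$spheres")

  defaults <- list(
    base_seed = 1L, start_distance = 27,
    sim = list(dt_ps = 0.02, friction_per_ps = 1, temperature_K = 300,
               n_steps = 5000, record_stride = 50, n_replicates = 100),
    ts = list(d_max = 4, attack_angle_center = 109, attack_angle_tol = 30,
              linearity_center = 180, linearity_tol = 30),
    volume = list(enabled = TRUE, spacing = 0.4, distance_cut = 0.4,
                  contiguity = 3, hull = TRUE, proximity_mode = "vdw",
                  fraction = 0.1, n_subsamples = 3, threshold = 70,
                  selector = "heavy",
                  spheres = list(list(center = c(0, 0, 2), radius = 3),
                                 list(center = c(0, 0, -2), radius = 3)),
                  bin_edges = c(0, 25, 70)),
    contacts = list(enabled = TRUE, cutoff = 4.5,
                    group_a = "resid 500 and heavy",
                    group_b = "resid 36 and heavy")
  )
  out <- utils::modifyList(defaults, config)
  for (blk in c("sim", "ts", "volume", "contacts"))
    out[[blk]] <- utils::modifyList(defaults[[blk]], config[[blk]] %||% list())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.volume_config_from <- function(v) {
  grid_config(
    spacing = v$spacing, distance_cut = v$distance_cut,
    contiguity_criterion = v$contiguity, convex_hull_exclusion = v$hull,
    proximity_mode = v$proximity_mode,
    inclusion = lapply(v$spheres, function(s)
      inclusion_sphere(as.numeric(s$center), s$radius)))
}

# docked reference pose: deterministic (T = 0) open-pocket association run
.reference_pose <- function(cfg) {
  sys <- make_toy_association_system("open", cfg$start_distance)
  p <- sim_params(dt_ps = cfg$sim$dt_ps,
                  friction_per_ps = cfg$sim$friction_per_ps,
                  temperature_K = 0, n_steps = cfg$sim$n_steps,
                  record_stride = cfg$sim$n_steps, seed = 1)
  traj <- run_replicate(sys, sys$forces, p)
  lig <- which(sys$mobile)
  traj$frames[[length(traj$frames)]][lig, , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Per condition: a seeded replicate ensemble of the steered toy system, a
#' per-frame TS table and per-replicate summary (with minimum docked-pose
#' RMSD against the deterministic bound pose), success counts, optional
#' pocket-volume subsampling and contact occupancies. Across conditions
#' (each vs. the first, reference condition): binomial comparison of
#' success counts, equal-variance t-test on subsampled large-volume
#' fractions, and t-test on per-replicate contact occupancies. With
#' `out_dir`, all tables are written as TSV, statistics as JSON, plus a
#' manifest with an md5 checksum per output file; reruns with the same
#' config are byte-identical.
#'
#' @param config nested list or YAML path (see [pipeline_config()]).
#' @param out_dir optional output directory.
#' @param verbose print progress to stderr.
#' @return result bundle (list): conditions, stats, manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  cfg <- pipeline_config(config)
  say <- function(...) if (verbose) message(...)
  cond_names <- names(cfg$conditions)
  gcfg <- .volume_config_from(cfg$volume)
  crit <- ts_criteria(cfg$ts$d_max, cfg$ts$attack_angle_center,
                      cfg$ts$attack_angle_tol, cfg$ts$linearity_center,
                      cfg$ts$linearity_tol)
  ref_lig_pose <- .reference_pose(cfg)

  results <- list()
  for (ci in seq_along(cond_names)) {
    nm <- cond_names[ci]
    cc <- cfg$conditions[[nm]]
    say("condition ", nm, ": simulating ", cfg$sim$n_replicates, " replicates")
    sys <- make_toy_association_system(cc$pocket,
                                       cc$start_distance %||% cfg$start_distance)
    params <- sim_params(dt_ps = cfg$sim$dt_ps,
                         friction_per_ps = cfg$sim$friction_per_ps,
                         temperature_K = cfg$sim$temperature_K,
                         n_steps = cfg$sim$n_steps,
                         record_stride = cfg$sim$record_stride)
    cond_seed <- cfg$base_seed + (ci - 1L) * 100000L
    lig <- which(sys$mobile)
    rec_heavy <- atom_group(which(!sys$mobile & sys$atoms$is_heavy),
                            "receptor heavy")
    ref_coords <- sys$coords
    ref_coords[lig, ] <- ref_lig_pose

    ts_frames <- list(); ts_summary <- list()
    pooled_frames <- list()   # (replicate, frame index) for volume sampling
    contact_fracs <- numeric(0)
    cspec <- if (isTRUE(cfg$contacts$enabled))
      contact_spec(select_atoms(sys$atoms, cfg$contacts$group_a),
                   select_atoms(sys$atoms, cfg$contacts$group_b),
                   cutoff = cfg$contacts$cutoff) else NULL
    vol_group <- select_atoms(sys$atoms, cfg$volume$selector)
    trajs <- vector("list", cfg$sim$n_replicates)

    for (r in seq_len(cfg$sim$n_replicates)) {
      p <- params
      p$seed <- as.integer(cond_seed + r)
      tryCatch({
        traj <- run_replicate(sys, sys$forces, p)
        sc <- scan_trajectory(traj, sys$ts_map, crit, replicate_id = r)
        min_rmsd <- NA_real_
        if (sc$outcome$successful) {
          pf <- sc$frames$frame_index[sc$frames$passed]
          min_rmsd <- min(vapply(pf, function(f)
            docking_rmsd(traj$frames[[f]], ref_coords, rec_heavy, lig),
            numeric(1)))
        }
        ts_frames[[r]] <- cbind(replicate = r, sc$frames)
        ts_summary[[r]] <- data.frame(
          replicate = r, successful = sc$outcome$successful,
          first_passing_frame = sc$outcome$first_passing_frame,
          n_passing = sc$outcome$n_passing_frames, min_rmsd = min_rmsd)
        if (!is.null(cspec))
          contact_fracs[r] <- contact_fraction(traj, cspec)
        trajs[[r]] <- traj
      }, error = function(e) {
        stop("pipeline stage 'simulate/scan' failed in condition '", nm,
             "', replicate ", r, ": ", conditionMessage(e))
      })
    }
    ts_frames <- do.call(rbind, ts_frames)
    ts_summary <- do.call(rbind, ts_summary)
    k <- sum(ts_summary$successful)

    vol <- NULL
    if (isTRUE(cfg$volume$enabled)) {
      say("condition ", nm, ": pocket volumes")
      index <- do.call(rbind, lapply(seq_along(trajs), function(r)
        data.frame(replicate = r, frame = seq_along(trajs[[r]]$frames))))
      rows <- list(); fracs <- numeric(0)
      for (s in seq_len(cfg$volume$n_subsamples)) {
        pick <- sample_frames(nrow(index), cfg$volume$fraction,
                              seed = cond_seed + 5000L + s)
        vols <- vapply(pick, function(i) {
          fr <- get_frame(trajs[[index$replicate[i]]], index$frame[i])
          pocket_volume(fr, vol_group, gcfg)$volume
        }, numeric(1))
        rows[[s]] <- data.frame(subsample = s,
                                replicate = index$replicate[pick],
                                frame = index$frame[pick],
                                volume = vols)
        fracs[s] <- mean(vols >= cfg$volume$threshold)
      }
      vol_table <- do.call(rbind, rows)
      vol <- list(table = vol_table, large_fractions = fracs,
                  distribution = volume_distribution(vol_table$volume,
                                                     cfg$volume$bin_edges))
    }

    contacts <- if (!is.null(cspec)) summarize_replicates(contact_fracs) else NULL
    results[[nm]] <- list(
      ts_frames = ts_frames, ts_summary = ts_summary,
      success_count = k, n_replicates = cfg$sim$n_replicates,
      volume = vol, contacts = contacts)
  }

  # cross-condition statistics: each condition vs. the first (reference)
  stats_out <- list()
  ref <- results[[1]]
  for (nm in cond_names[-1]) {
    alt <- results[[nm]]
    entry <- list(reference = cond_names[1], alternative = nm)
    entry$binomial <- unclass(compare_success_counts(
      ref$success_count, ref$n_replicates,
      alt$success_count, alt$n_replicates))
    if (!is.null(alt$volume) && !is.null(ref$volume)) {
      fold <- large_volume_fold(alt$volume$table$volume,
                                ref$volume$table$volume,
                                cfg$volume$threshold)
      tt <- ttest_equal_var_two_tailed(alt$volume$large_fractions,
                                       ref$volume$large_fractions)
      entry$volume <- list(fold = fold$fold, frac_alt = fold$frac_alt,
                           frac_ref = fold$frac_ref,
                           t = tt$t, df = tt$df, p = tt$p_two_tailed)
    }
    if (!is.null(alt$contacts) && !is.null(ref$contacts)) {
      tt <- ttest_equal_var_two_tailed(alt$contacts$fractions,
                                       ref$contacts$fractions)
      entry$contacts <- list(mean_alt = alt$contacts$mean,
                             mean_ref = ref$contacts$mean,
                             t = tt$t, df = tt$df, p = tt$p_two_tailed)
    }
    stats_out[[nm]] <- entry
  }

  bundle <- list(conditions = results, stats = stats_out,
                 base_seed = cfg$base_seed, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wt <- function(df, name) {
      path <- file.path(out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <<- c(files, path)
    }
    for (nm in cond_names) {
      r <- results[[nm]]
      wt(r$ts_frames, paste0(nm, "_ts_frames.tsv"))
      wt(r$ts_summary, paste0(nm, "_ts_summary.tsv"))
      if (!is.null(r$volume)) wt(r$volume$table, paste0(nm, "_volumes.tsv"))
      if (!is.null(r$contacts))
        wt(data.frame(replicate = seq_along(r$contacts$fractions),
                      fraction = r$contacts$fractions),
           paste0(nm, "_contacts.tsv"))
    }
    sane <- rapply(stats_out, function(x)
      if (is.numeric(x) && any(!is.finite(x))) as.character(x) else x,
      how = "replace")
    json_path <- file.path(out_dir, "stats.json")
    jsonlite::write_json(sane, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, json_path)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           base_seed = cfg$base_seed,
                           package_version = as.character(
                             utils::packageVersion("steermd")))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$manifest <- manifest
  }
  bundle
}
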