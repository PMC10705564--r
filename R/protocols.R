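#' IVES configuration
#'
#' Defaults mirror the published protocol: 20 seed poses / receptor
#' conformations, a maximum of 300 poses per conformation per docking run,
#' a single iteration, and an 8 A movable shell.
#'
#' @param n_seeds number of seed poses N (= ensemble size).
#' @param max_poses_per_conf pose cap per conformation per docking run.
#' @param iterations number of seed/minimize/redock rounds.
#' @param shell_radius movable-shell radius (Angstrom).
#' @param seed_scorer "docking_score" (rank by the docking energy) or
#'   "external_hook" (rank by `hook`'s scores, ascending).
#' @param hook function(list of poses) -> numeric scores, used when
#'   `seed_scorer = "external_hook"`.
#' @return A `gi_ives_config` list.
#' @export
ives_config <- function(n_seeds = 20L, max_poses_per_conf = 300L,
                        iterations = 1L, shell_radius = 8.0,
                        seed_scorer = c("docking_score", "external_hook"),
                        hook = NULL) {
  seed_scorer <- match.arg(seed_scorer)
  stopifnot(n_seeds >= 1, iterations >= 1, max_poses_per_conf >= 1,
            shell_radius > 0)
  if (seed_scorer == "external_hook" && !is.function(hook))
    stop("external_hook seed scorer requires a `hook` function")
  structure(list(n_seeds = as.integer(n_seeds),
                 max_poses_per_conf = as.integer(max_poses_per_conf),
                 iterations = as.integer(iterations),
                 shell_radius = shell_radius,
                 seed_scorer = seed_scorer, hook = hook),
            class = "gi_ives_config")
}

# deterministic sub-run seed from a master seed and a stage label
derive_seed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

protocol_result <- function(poses, ensemble = list(), run_log = list()) {
  structure(list(poses = poses, ensemble = ensemble, run_log = run_log),
            class = "gi_result")
}

# recompute every pose's energy with `params` on `receptor`, resort
rescore_pose_set <- function(set, receptor, ligand, params) {
  poses <- lapply(set$poses, function(p) {
    bd <- score_pose(receptor, ligand, p$coords, params)
    p$score <- bd$total; p$breakdown <- bd
    p
  })
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "score"))]
  for (k in seq_along(poses)) poses[[k]]$provenance$rank <- k
  new_pose_set(poses, ligand, set$cluster_cutoff)
}

#' "Default" baseline: one normal-potential docking run, 20-pose cap
#'
#' @param receptor,ligand,box structures and search box.
#' @param scoring base [scoring_params()] (mode is forced to "normal").
#' @param sampler a [sampler_config()]; its `seed` is the master seed.
#' @param max_poses baseline pose cap (default 20).
#' @return A `gi_result` whose poses carry `potential = "normal"`.
#' @export
run_default <- function(receptor, ligand, box, scoring = scoring_params(),
                        sampler = sampler_config(), max_poses = 20L) {
  params <- scoring; params$mode <- "normal"
  cfg <- sampler
  cfg$seed <- derive_seed(sampler$seed, "stage:normal")
  t0 <- proc.time()[["elapsed"]]
  set <- sample_poses(receptor, ligand, box, params, cfg)
  set$poses <- set$poses[seq_len(min(length(set$poses), max_poses))]
  protocol_result(set, run_log = list(list(
    stage = "default/normal", n_poses = length(set$poses),
    elapsed = proc.time()[["elapsed"]] - t0)))
}

#' GLOW: pool normal- and softened-potential docking runs
#'
#' Runs the rigid sampler twice — once with the normal potential and once
#' with the softened (clash-capped) potential — on independently derived
#' seeds, rescores the soft run's poses under the normal potential so one
#' scale ranks the pool, and merges with leader clustering. The normal
#' branch shares its derived seed with [run_default()], so the baseline's
#' poses are contained in GLOW's pool.
#'
#' @inheritParams run_default
#' @return A `gi_result`; pose provenance records the generating potential.
#' @export
run_glow <- function(receptor, ligand, box, scoring = scoring_params(),
                     sampler = sampler_config()) {
  run_log <- list()
  t0 <- proc.time()[["elapsed"]]
  p_norm <- scoring; p_norm$mode <- "normal"
  p_soft <- scoring; p_soft$mode <- "soft"
  cfg_n <- sampler; cfg_n$seed <- derive_seed(sampler$seed, "stage:normal")
  cfg_s <- sampler; cfg_s$seed <- derive_seed(sampler$seed, "stage:soft")
  set_n <- sample_poses(receptor, ligand, box, p_norm, cfg_n)
  run_log[[1]] <- list(stage = "glow/normal", n_poses = length(set_n$poses),
                       elapsed = proc.time()[["elapsed"]] - t0)
  t1 <- proc.time()[["elapsed"]]
  set_s <- sample_poses(receptor, ligand, box, p_soft, cfg_s)
  set_s <- rescore_pose_set(set_s, receptor, ligand, p_norm)
  run_log[[2]] <- list(stage = "glow/soft", n_poses = length(set_s$poses),
                       elapsed = proc.time()[["elapsed"]] - t1)
  merged <- merge_pose_sets(list(set_n, set_s), sampler$cluster_cutoff,
                            sampler$max_poses)
  run_log[[3]] <- list(stage = "glow/merge", n_poses = length(merged$poses),
                       elapsed = 0)
  protocol_result(merged, run_log = run_log)
}

#' Select seed poses for receptor minimization
#'
#' Takes the top `n` poses of a clustered, score-sorted set. With the
#' `external_hook` scorer the poses are reordered by the hook's scores
#' (ascending, ties broken by prior rank) before truncation. If fewer than
#' `n` poses exist, all are returned with a warning.
#'
#' @param poses a `gi_pose_set`.
#' @param n number of seeds requested.
#' @param scorer "docking_score" or "external_hook".
#' @param hook scoring function for `external_hook`.
#' @return List of `gi_pose`.
#' @export
select_seed_poses <- function(poses, n, scorer = c("docking_score", "external_hook"),
                              hook = NULL) {
  scorer <- match.arg(scorer)
  pl <- if (inherits(poses, "gi_pose_set")) poses$poses else poses
  if (length(pl) == 0L) stop("cannot select seed poses from an empty pose set")
  if (scorer == "external_hook") {
    if (!is.function(hook)) stop("external_hook requires a `hook` function")
    s <- hook(pl)
    pl <- pl[order(s, seq_along(pl))]
  }
  if (length(pl) < n)
    warning(sprintf("only %d poses available for %d requested seeds",
                    length(pl), n), call. = FALSE)
  pl[seq_len(min(n, length(pl)))]
}

#' IVES: iterative ensemble sampling via pocket-minimized conformations
#'
#' Stage 1 docks the ligand rigidly with the softened potential, allowing
#' clashing-but-plausible poses. The top N seed poses each guide a
#' constrained minimization of the input receptor (residues within
#' `shell_radius` of the seed move; ligand and the rest stay fixed), giving
#' an ensemble of N conformations. The ligand is then redocked onto every
#' member with both potentials (pose cap per conformation per run), soft
#' poses are rescored under the normal potential on their generating
#' conformation, and everything — stage-1 poses included — is merged by
#' leader clustering. Additional iterations re-seed from the merged set and
#' repeat against the input receptor. Per-conformation runs use seeds
#' derived from the master seed and stage labels, so results are independent
#' of processing order.
#'
#' @inheritParams run_default
#' @param ives an [ives_config()].
#' @param mcfg a [minimize_config()].
#' @param .process_order optional permutation of the ensemble processing
#'   order (order-independence checks).
#' @return A `gi_result` with merged poses and the final iteration's
#'   receptor ensemble (provenance attributes: seed rank, iteration).
#' @export
run_ives <- function(receptor, ligand, box, scoring = scoring_params(),
                     sampler = sampler_config(), ives = ives_config(),
                     mcfg = minimize_config(), .process_order = NULL) {
  p_norm <- scoring; p_norm$mode <- "normal"
  p_soft <- scoring; p_soft$mode <- "soft"
  run_log <- list()
  t0 <- proc.time()[["elapsed"]]
  cfg_s <- sampler
  cfg_s$seed <- derive_seed(sampler$seed, "stage:soft")
  cfg_s$max_poses <- ives$max_poses_per_conf
  stage1 <- sample_poses(receptor, ligand, box, p_soft, cfg_s,
                         conformation_id = 0L, iteration = 0L)
  run_log[[1]] <- list(stage = "ives/initial-soft",
                       n_poses = length(stage1$poses),
                       elapsed = proc.time()[["elapsed"]] - t0)
  stage1_rescored <- rescore_pose_set(stage1, receptor, ligand, p_norm)
  seed_source <- stage1
  merged <- stage1_rescored
  ensemble <- list()

  for (it in seq_len(ives$iterations)) {
    seeds <- select_seed_poses(seed_source, ives$n_seeds,
                               scorer = ives$seed_scorer, hook = ives$hook)
    ensemble <- vector("list", length(seeds))
    conf_sets <- vector("list", length(seeds))
    ord <- if (is.null(.process_order)) seq_along(seeds) else .process_order
    stopifnot(setequal(ord, seq_along(seeds)))
    for (k in ord) {
      t1 <- proc.time()[["elapsed"]]
      shell <- select_movable_residues(receptor, seeds[[k]], ives$shell_radius)
      conf <- minimize_pocket(receptor, ligand, seeds[[k]], shell, p_norm, mcfg)
      attr(conf, "provenance") <- list(seed_rank = k, iteration = it,
                                       frozen = shell$frozen)
      ensemble[[k]] <- conf
      cfg_n <- sampler
      cfg_n$seed <- derive_seed(sampler$seed, sprintf("iter%d:conf%d:normal", it, k))
      cfg_n$max_poses <- ives$max_poses_per_conf
      cfg_k_s <- sampler
      cfg_k_s$seed <- derive_seed(sampler$seed, sprintf("iter%d:conf%d:soft", it, k))
      cfg_k_s$max_poses <- ives$max_poses_per_conf
      set_n <- sample_poses(conf, ligand, box, p_norm, cfg_n,
                            conformation_id = k, iteration = it)
      set_s <- sample_poses(conf, ligand, box, p_soft, cfg_k_s,
                            conformation_id = k, iteration = it)
      set_s <- rescore_pose_set(set_s, conf, ligand, p_norm)
      conf_sets[[k]] <- merge_pose_sets(list(set_n, set_s),
                                        sampler$cluster_cutoff,
                                        2L * ives$max_poses_per_conf)
      run_log[[length(run_log) + 1L]] <- list(
        stage = sprintf("ives/iter%d/conf%d", it, k),
        n_poses = length(conf_sets[[k]]$poses),
        elapsed = proc.time()[["elapsed"]] - t1)
    }
    all_sets <- c(list(merged), conf_sets)
    cap <- sum(vapply(all_sets, function(s) length(s$poses), integer(1)))
    merged <- merge_pose_sets(all_sets, sampler$cluster_cutoff, max(cap, 1L))
    run_log[[length(run_log) + 1L]] <- list(
      stage = sprintf("ives/iter%d/merge", it),
      n_poses = length(merged$poses), elapsed = 0)
    seed_source <- merged
  }
  protocol_result(merged, ensemble = ensemble, run_log = run_log)
}

#' Write a protocol result to an output directory
#'
#' Writes `poses.sdf` (tagged pose set), `report.json` (per-stage counts,
#' timings and pose provenance) and, for IVES, `ensemble/conf_###.pdb` with
#' a `provenance.json` sidecar (seed-pose rank, iteration, frozen residues).
#'
#' @param result a `gi_result`.
#' @param ligand the `gi_ligand` the poses instantiate.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_protocol_result <- function(result, ligand, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(result$poses$poses) > 0)
    write_poses(result$poses, ligand, file.path(dir, "poses.sdf"))
  report <- list(
    n_poses = length(result$poses$poses),
    n_ensemble = length(result$ensemble),
    stages = result$run_log,
    poses = lapply(result$poses$poses, function(p)
      c(list(score = p$score), p$provenance))
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(result$ensemble) > 0) {
    ens_dir <- file.path(dir, "ensemble")
    dir.create(ens_dir, showWarnings = FALSE)
    prov <- list()
    for (k in seq_along(result$ensemble)) {
      write_receptor(result$ensemble[[k]],
                     file.path(ens_dir, sprintf("conf_%03d.pdb", k)))
      pk <- attr(result$ensemble[[k]], "provenance")
      prov[[k]] <- list(file = sprintf("conf_%03d.pdb", k),
                        seed_rank = pk$seed_rank, iteration = pk$iteration)
    }
    jsonlite::write_json(prov, file.path(ens_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
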