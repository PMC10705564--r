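#' Define a rectangular search box
#'
#' @param center 3-vector, box centre (Angstrom).
#' @param half_widths 3-vector of positive half-widths (Angstrom).
#' @return A `gi_box` list.
#' @export
search_box <- function(center, half_widths) {
  center <- as.numeric(center); half_widths <- as.numeric(half_widths)
  stopifnot(length(center) == 3, length(half_widths) == 3)
  if (!all(half_widths > 0)) stop("box half-widths must be positive")
  structure(list(center = center, half_widths = half_widths), class = "gi_box")
}

#' Auto-box around a reference coordinate set
#'
#' Rectangular box covering the coordinates with a margin added per side.
#'
#' @param coords reference coordinates (e.g. a known ligand pose).
#' @param margin Angstrom added on each side (default 4).
#' @return A [search_box()].
#' @export
autobox <- function(coords, margin = 4) {
  coords <- as.matrix(coords)
  lo <- apply(coords, 2, min); hi <- apply(coords, 2, max)
  search_box((lo + hi) / 2, (hi - lo) / 2 + margin)
}

#' Sampler configuration
#'
#' @param seed master RNG seed; chain k uses stream `seed + k - 1`.
#' @param n_chains independent Monte-Carlo chains.
#' @param n_steps Metropolis steps per chain.
#' @param temperature Metropolis temperature (energy units).
#' @param max_poses cap on returned poses.
#' @param cluster_cutoff RMSD dedup cutoff (Angstrom).
#' @return A `gi_sampler_config` list.
#' @export
sampler_config <- function(seed = 1L, n_chains = 8L, n_steps = 2000L,
                           temperature = 0.3, max_poses = 300L,
                           cluster_cutoff = 1.0) {
  stopifnot(n_chains >= 1, temperature > 0, max_poses >= 1,
            cluster_cutoff >= 0)
  if (n_steps < 1) stop("n_steps must be >= 1")
  structure(list(seed = as.integer(seed) %% .Machine$integer.max,
                 n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps),
                 temperature = temperature,
                 max_poses = as.integer(max_poses),
                 cluster_cutoff = cluster_cutoff),
            class = "gi_sampler_config")
}

#' Rigid-receptor stochastic pose search
#'
#' Runs `n_chains` independent Metropolis Monte-Carlo chains. Each chain
#' starts from a random placement (uniform centroid position in the box,
#' uniform random orientation, uniform torsion angles) and proposes one move
#' per step — a translation (<= 0.5 A), a rotation (<= 15 degrees) or a
#' single-torsion twist (<= 30 degrees), chosen uniformly; the ligand
#' centroid is constrained to the box. Each chain's best state is polished by
#' a coordinate-wise shrinking-step descent. Accepted states are pooled
#' across chains, deduplicated by leader clustering at `cluster_cutoff`, and
#' truncated to `max_poses`. Fully reproducible given `config$seed`.
#'
#' @param receptor a `gi_receptor` (possibly with zero atoms).
#' @param ligand a `gi_ligand`.
#' @param box a [search_box()]; the ligand's bounding radius must not exceed
#'   the largest half-width.
#' @param params a [scoring_params()].
#' @param config a [sampler_config()].
#' @param conformation_id,iteration provenance labels for the output poses.
#' @return A `gi_pose_set`: poses sorted by ascending score, pairwise RMSD
#'   above the cluster cutoff.
#' @export
sample_poses <- function(receptor, ligand, box, params, config,
                         conformation_id = 0L, iteration = 0L) {
  if (bounding_radius(ligand$coords) > max(box$half_widths))
    stop("ligand is larger than the search box")
  e_cap_signed <- if (params$mode == "soft") params$e_cap else -1
  n_tor <- length(ligand$torsions)
  energy_of <- function(state)
    score_total(receptor$coords, receptor$radius,
                state_coords(ligand, state), ligand$radius,
                ligand$internal_pairs, params, e_cap_signed)

  stride <- max(1L, config$n_steps %/% 250L)
  all_coords <- list(); all_scores <- numeric(0)
  all_chain <- integer(0); all_step <- integer(0)

  for (chain in seq_len(config$n_chains)) {
    set.seed((config$seed + chain - 1L) %% .Machine$integer.max)
    state <- list(
      t = box$center + runif(3, -1, 1) * box$half_widths,
      R = random_rotation(),
      theta = if (n_tor > 0) runif(n_tor, -pi, pi) else numeric(0)
    )
    e <- energy_of(state)
    best <- list(state = state, e = e)
    arch_c <- list(); arch_s <- numeric(0); arch_step <- integer(0)
    for (step in seq_len(config$n_steps)) {
      prop <- propose_move(state, box, n_tor)
      if (is.null(prop)) next   # centroid left the box: reject
      e2 <- energy_of(prop)
      de <- e2 - e
      if (de <= 0 || runif(1) < exp(-de / config$temperature)) {
        state <- prop; e <- e2
        if (e < best$e) best <- list(state = state, e = e)
        if (step %% stride == 0L) {
          arch_c[[length(arch_c) + 1L]] <- state_coords(ligand, state)
          arch_s <- c(arch_s, e); arch_step <- c(arch_step, step)
        }
      }
    }
    ref <- refine_state(best$state, best$e, energy_of, box, n_tor)
    arch_c[[length(arch_c) + 1L]] <- state_coords(ligand, ref$state)
    arch_s <- c(arch_s, ref$e); arch_step <- c(arch_step, 0L)  # refined first in ties
    all_coords <- c(all_coords, arch_c)
    all_scores <- c(all_scores, arch_s)
    all_chain <- c(all_chain, rep(chain, length(arch_s)))
    all_step <- c(all_step, arch_step)
  }

  # deterministic order: score, then chain index, then step
  ord <- order(all_scores, all_chain, all_step)
  keep <- cpp_leader_cluster(all_coords[ord], ligand$auto_perms,
                             config$cluster_cutoff)
  sel <- ord[keep][seq_len(min(sum(keep), config$max_poses))]
  poses <- lapply(seq_along(sel), function(k) {
    i <- sel[k]
    cc <- all_coords[[i]]
    bd <- score_pose(receptor, ligand, cc, params)
    new_pose(cc, score = bd$total, breakdown = bd,
             provenance = list(potential = params$mode,
                               conformation_id = conformation_id,
                               iteration = iteration, rank = k))
  })
  new_pose_set(poses, ligand, config$cluster_cutoff)
}

# one Metropolis proposal; NULL if the centroid would leave the box
propose_move <- function(state, box, n_tor) {
  kind <- 1L + floor(runif(1) * if (n_tor > 0) 3 else 2)
  if (kind == 1L) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    t2 <- state$t + u * runif(1, 0, 0.5)
    if (any(abs(t2 - box$center) > box$half_widths)) return(NULL)
    state$t <- t2
  } else if (kind == 2L) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    state$R <- axis_rotation(u, runif(1, -15, 15) * pi / 180) %*% state$R
  } else {
    k <- 1L + floor(runif(1) * n_tor)
    state$theta[k] <- state$theta[k] + runif(1, -30, 30) * pi / 180
  }
  state
}

# coordinate-wise shrinking-step descent over (t, orientation, torsions)
refine_state <- function(state, e, energy_of, box, n_tor,
                         step_t = 0.25, step_r = 0.15, step_tor = 0.25,
                         min_scale = 0.02) {
  axes <- diag(3)
  scale <- 1
  while (scale >= min_scale) {
    improved <- FALSE
    for (ax in 1:3) {
      for (sgn in c(1, -1)) {
        cand <- state
        cand$t[ax] <- state$t[ax] + sgn * step_t * scale
        if (any(abs(cand$t - box$center) > box$half_widths)) next
        e2 <- energy_of(cand)
        if (e2 < e) { state <- cand; e <- e2; improved <- TRUE }
      }
    }
    for (ax in 1:3) {
      for (sgn in c(1, -1)) {
        cand <- state
        cand$R <- axis_rotation(axes[ax, ], sgn * step_r * scale) %*% state$R
        e2 <- energy_of(cand)
        if (e2 < e) { state <- cand; e <- e2; improved <- TRUE }
      }
    }
    if (n_tor > 0) for (k in seq_len(n_tor)) {
      for (sgn in c(1, -1)) {
        cand <- state
        cand$theta[k] <- state$theta[k] + sgn * step_tor * scale
        e2 <- energy_of(cand)
        if (e2 < e) { state <- cand; e <- e2; improved <- TRUE }
      }
    }
    if (!improved) scale <- scale / 2
  }
  list(state = state, e = e)
}

# ---- pose sets --------------------------------------------------------------

#' Construct a pose set
#'
#' @param poses list of `gi_pose`, ascending score.
#' @param ligand the instantiated `gi_ligand`.
#' @param cluster_cutoff the dedup cutoff the set was clustered at.
#' @return A `gi_pose_set`.
#' @export
new_pose_set <- function(poses, ligand, cluster_cutoff = 1.0) {
  structure(list(poses = poses, ligand = ligand,
                 cluster_cutoff = cluster_cutoff),
            class = "gi_pose_set")
}

ligand_signature <- function(ligand)
  paste(c(ligand$element, t(ligand$bonds)), collapse = ",")

#' Deduplicate poses by greedy leader clustering
#'
#' Walks the poses best-to-worst and keeps a pose iff its symmetry-corrected
#' RMSD to every kept pose exceeds `cutoff`. Stable and deterministic; input
#' is (re)sorted by ascending score first.
#'
#' @param poses list of `gi_pose`.
#' @param cutoff RMSD cutoff in Angstrom (>= 0).
#' @param ligand `gi_ligand` supplying the automorphism group; if omitted,
#'   the identity mapping is used.
#' @return Filtered list of `gi_pose`, ascending score.
#' @export
cluster_poses <- function(poses, cutoff, ligand = NULL) {
  if (cutoff < 0) stop("cluster cutoff must be non-negative")
  if (length(poses) == 0L) return(poses)
  perms <- if (is.null(ligand)) matrix(seq_len(nrow(poses[[1]]$coords)), nrow = 1)
           else ligand$auto_perms
  ord <- order(vapply(poses, function(p) p$score, numeric(1)))
  poses <- poses[ord]
  keep <- cpp_leader_cluster(lapply(poses, `[[`, "coords"), perms, cutoff)
  poses[keep]
}

#' Merge pose sets
#'
#' Concatenates the sets' poses, sorts by ascending score, leader-clusters at
#' `cutoff` and truncates to `max_poses`. Provenance of each surviving pose
#' is preserved; all sets must instantiate the same ligand.
#'
#' @param sets list of `gi_pose_set`.
#' @param cutoff dedup RMSD cutoff (Angstrom).
#' @param max_poses cap on the merged set size.
#' @return A `gi_pose_set`.
#' @export
merge_pose_sets <- function(sets, cutoff, max_poses) {
  sets <- Filter(function(s) !is.null(s), sets)
  if (length(sets) == 0L) stop("no pose sets to merge")
  sig <- vapply(sets, function(s) ligand_signature(s$ligand), character(1))
  if (length(unique(sig)) != 1L)
    stop("pose sets instantiate different ligands; cannot merge")
  ligand <- sets[[1]]$ligand
  pooled <- do.call(c, lapply(sets, `[[`, "poses"))
  kept <- cluster_poses(pooled, cutoff, ligand)
  kept <- kept[seq_len(min(length(kept), max_poses))]
  for (k in seq_along(kept)) kept[[k]]$provenance$rank <- k
  new_pose_set(kept, ligand, cutoff)
}
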