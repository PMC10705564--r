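#' Symmetry-corrected ligand RMSD
#'
#' Heavy-atom RMSD between a pose and a reference in the shared receptor
#' frame (no re-superposition), minimized over the ligand bond-graph
#' automorphism group (element- and bond-order-preserving mappings,
#' enumeration capped at 10000; beyond the cap the identity mapping is used
#' with a warning at ligand construction). The uncorrected value is attached
#' as attribute `"naive"`.
#'
#' @param pose a `gi_pose` or coordinate matrix.
#' @param reference a `gi_pose` or coordinate matrix with the same atoms.
#' @param ligand the `gi_ligand` both instantiate.
#' @return RMSD in Angstrom, with attribute `naive` = identity-mapping RMSD.
#' @export
symmetry_rmsd <- function(pose, reference, ligand) {
  a <- if (inherits(pose, "gi_pose")) pose$coords else as.matrix(pose)
  b <- if (inherits(reference, "gi_pose")) reference$coords else as.matrix(reference)
  if (nrow(a) != nrow(b) || nrow(a) != nrow(ligand$coords))
    stop("pose/reference atom counts do not match the ligand")
  n <- nrow(a)
  naive <- cpp_sym_rmsd(a, b, matrix(seq_len(n), nrow = 1))
  structure(cpp_sym_rmsd(a, b, ligand$auto_perms), naive = naive)
}

#' Pose-set success against a reference pose
#'
#' Success iff the minimum symmetry-corrected RMSD over the poses is less
#' than or equal to `threshold` (inclusive, default 2.0 A). An empty set is
#' a failure with `min_rmsd = Inf`.
#'
#' @param poses a `gi_pose_set` or list of `gi_pose`.
#' @param reference the reference (correct) pose.
#' @param ligand the `gi_ligand`.
#' @param threshold success threshold in Angstrom.
#' @return List: `success`, `min_rmsd`, `min_rmsd_naive`, `best_pose` index.
#' @export
is_success <- function(poses, reference, ligand, threshold = 2.0) {
  pl <- if (inherits(poses, "gi_pose_set")) poses$poses else poses
  if (length(pl) == 0L)
    return(list(success = FALSE, min_rmsd = Inf, min_rmsd_naive = Inf,
                best_pose = NA_integer_))
  r <- vapply(pl, function(p) as.numeric(symmetry_rmsd(p, reference, ligand)),
              numeric(1))
  rn <- vapply(pl, function(p) attr(symmetry_rmsd(p, reference, ligand), "naive"),
               numeric(1))
  i <- which.min(r)
  list(success = r[i] <= threshold, min_rmsd = r[i], min_rmsd_naive = min(rn),
       best_pose = i)
}

#' Construct a cross-docking benchmark case
#'
#' @param receptor_dock the docking receptor (`gi_receptor`).
#' @param ligand the `gi_ligand`.
#' @param reference the correct pose (`gi_pose`).
#' @param box the [search_box()]; must contain the reference centroid.
#' @param case_id identifier string.
#' @param difficulty "typical" or "challenging".
#' @return A `gi_case` list.
#' @export
benchmark_case <- function(receptor_dock, ligand, reference, box, case_id,
                           difficulty = c("typical", "challenging")) {
  difficulty <- match.arg(difficulty)
  if (nrow(reference$coords) != nrow(ligand$coords))
    stop("reference pose does not match ligand atom count")
  ctr <- centroid(reference$coords)
  if (any(abs(ctr - box$center) > box$half_widths))
    stop("search box does not contain the reference pose centroid")
  structure(list(receptor_dock = receptor_dock, ligand = ligand,
                 reference = reference, box = box, case_id = case_id,
                 difficulty = difficulty),
            class = "gi_case")
}

#' Run a protocol over a benchmark
#'
#' Runs the chosen protocol on every case with a case-derived seed, measures
#' the minimum symmetry-corrected RMSD to each reference pose, and
#' aggregates the success rate (percent of cases with any pose within the
#' threshold). Per-case errors are recorded, not fatal.
#'
#' @param cases list of `gi_case`.
#' @param protocol "default", "glow" or "ives".
#' @param scoring base [scoring_params()].
#' @param sampler [sampler_config()] template (per-case seeds are derived
#'   from `seed` and the case id).
#' @param ives [ives_config()] (IVES only).
#' @param mcfg [minimize_config()] (IVES only).
#' @param seed master benchmark seed.
#' @param threshold success RMSD threshold (Angstrom, inclusive).
#' @return A `gi_benchmark_report`: `per_case` data frame (case_id,
#'   difficulty, min_rmsd, min_rmsd_naive, n_poses, success, error),
#'   `success_rate` in percent, plus the protocol and threshold used.
#' @export
run_benchmark <- function(cases, protocol = c("default", "glow", "ives"),
                          scoring = scoring_params(),
                          sampler = sampler_config(),
                          ives = ives_config(), mcfg = minimize_config(),
                          seed = sampler$seed, threshold = 2.0) {
  protocol <- match.arg(protocol)
  if (length(cases) < 1L) stop("need at least one benchmark case")
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cfg <- sampler
    cfg$seed <- derive_seed(seed, paste0("case:", cs$case_id))
    res <- tryCatch({
      r <- switch(protocol,
        default = run_default(cs$receptor_dock, cs$ligand, cs$box, scoring, cfg),
        glow = run_glow(cs$receptor_dock, cs$ligand, cs$box, scoring, cfg),
        ives = run_ives(cs$receptor_dock, cs$ligand, cs$box, scoring, cfg,
                        ives, mcfg))
      s <- is_success(r$poses, cs$reference, cs$ligand, threshold)
      data.frame(case_id = cs$case_id, difficulty = cs$difficulty,
                 min_rmsd = s$min_rmsd, min_rmsd_naive = s$min_rmsd_naive,
                 n_poses = length(r$poses$poses), success = s$success,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(case_id = cs$case_id, difficulty = cs$difficulty,
                 min_rmsd = NA_real_, min_rmsd_naive = NA_real_,
                 n_poses = 0L, success = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  per_case <- do.call(rbind, rows)
  if (all(!is.na(per_case$error)))
    stop("all benchmark cases failed to run; first error: ", per_case$error[1])
  structure(list(per_case = per_case,
                 success_rate = 100 * mean(per_case$success),
                 protocol = protocol, threshold = threshold, seed = seed),
            class = "gi_benchmark_report")
}

#' Write a benchmark report as JSON and TSV
#'
#' @param report a `gi_benchmark_report`.
#' @param json_path,tsv_path output paths (NULL to skip either).
#' @export
write_benchmark_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(protocol = report$protocol,
                              threshold = report$threshold,
                              success_rate = report$success_rate,
                              per_case = report$per_case),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(tsv_path)) {
    df <- report$per_case[, c("case_id", "min_rmsd", "success", "difficulty")]
    df$protocol <- report$protocol
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}

# ---- case manifest I/O ------------------------------------------------------

#' Write a benchmark case to a manifest directory
#'
#' Layout: `receptor.pdb`, `ligand.sdf`, `reference.sdf`, `case.yaml`
#' (box, difficulty, case id).
#'
#' @param case a `gi_case`.
#' @param dir output directory (created if needed).
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_receptor(case$receptor_dock, file.path(dir, "receptor.pdb"))
  lig_pose <- new_pose(case$ligand$coords, score = 0)
  write_poses(list(lig_pose), case$ligand, file.path(dir, "ligand.sdf"))
  write_poses(list(case$reference), case$ligand, file.path(dir, "reference.sdf"))
  yaml::write_yaml(list(case_id = case$case_id, difficulty = case$difficulty,
                        box = list(center = case$box$center,
                                   size = 2 * case$box$half_widths)),
                   file.path(dir, "case.yaml"))
  invisible(dir)
}

#' Read a benchmark case from a manifest directory
#'
#' @param dir directory written by [write_case()].
#' @return A `gi_case`.
#' @export
read_case <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "case.yaml"))
  receptor <- read_receptor(file.path(dir, "receptor.pdb"))
  ligand <- read_ligand(file.path(dir, "ligand.sdf"))
  ref <- read_poses(file.path(dir, "reference.sdf"), ligand)[[1]]
  benchmark_case(receptor, ligand, ref,
                 search_box(meta$box$center, unlist(meta$box$size) / 2),
                 case_id = meta$case_id, difficulty = meta$difficulty)
}
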