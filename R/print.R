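#' @export
print.gi_receptor <- function(x, ...) {
  cat(sprintf("<receptor> %d heavy atoms in %d residues\n",
              nrow(x$coords), length(x$residues)))
  invisible(x)
}

#' @export
print.gi_ligand <- function(x, ...) {
  cat(sprintf("<ligand> %d heavy atoms, %d bonds, %d rotatable torsion(s), %d graph automorphism(s)\n",
              nrow(x$coords), nrow(x$bonds), length(x$torsions),
              nrow(x$auto_perms)))
  invisible(x)
}

#' @export
print.gi_pose <- function(x, ...) {
  cat(sprintf("<pose> %d atoms, score %.4f (%s, conf %s, iter %s, rank %s)\n",
              nrow(x$coords), x$score, x$provenance$potential,
              x$provenance$conformation_id, x$provenance$iteration,
              x$provenance$rank))
  invisible(x)
}

#' @export
print.gi_pose_set <- function(x, ...) {
  n <- length(x$poses)
  cat(sprintf("<pose set> %d pose(s), cluster cutoff %.2f A\n", n,
              x$cluster_cutoff))
  if (n > 0) {
    s <- vapply(x$poses, `[[`, numeric(1), "score")
    cat(sprintf("  score range [%.4f, %.4f]\n", min(s), max(s)))
  }
  invisible(x)
}

#' @export
print.gi_result <- function(x, ...) {
  cat(sprintf("<protocol result> %d pose(s), %d ensemble member(s)\n",
              length(x$poses$poses), length(x$ensemble)))
  for (st in x$run_log)
    cat(sprintf("  %-22s %4d poses  %6.2fs\n", st$stage, st$n_poses,
                st$elapsed))
  invisible(x)
}

#' @export
print.gi_benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark report> protocol=%s threshold=%.1f A\n",
              x$protocol, x$threshold))
  cat(sprintf("  success rate: %.1f%% (%d/%d cases)\n", x$success_rate,
              sum(x$per_case$success), nrow(x$per_case)))
  print(x$per_case[, c("case_id", "difficulty", "min_rmsd", "n_poses",
                       "success")], row.names = FALSE)
  invisible(x)
}

#' @export
print.gi_energy <- function(x, ...) {
  cat(sprintf("<energy> total %.4f (att %.4f, rep %.4f, internal %.4f)\n",
              x$total, x$vdw_attractive, x$vdw_repulsive, x$internal))
  invisible(x)
}
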