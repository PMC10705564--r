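#' Minimizer configuration
#'
#' @param max_iters maximum descent sweeps over the movable atoms.
#' @param step0 initial per-atom step (Angstrom); halved when a sweep stalls.
#' @param tol energy-change convergence threshold per sweep.
#' @param tether_k harmonic positional restraint stiffness (energy/A^2).
#' @return A `gi_minimize_config` list.
#' @export
minimize_config <- function(max_iters = 200L, step0 = 0.2, tol = 1e-4,
                            tether_k = 1.0) {
  stopifnot(max_iters >= 1, step0 > 0, tol > 0, tether_k > 0)
  structure(list(max_iters = as.integer(max_iters), step0 = step0,
                 tol = tol, tether_k = tether_k),
            class = "gi_minimize_config")
}

#' Select the movable residue shell around a seed pose
#'
#' A residue is movable iff any of its heavy atoms lies within `radius`
#' (atom-to-atom) of any seed-pose heavy atom; all other residues are
#' frozen. The default 8 A radius matches the pocket shell used during
#' seed-guided receptor minimization.
#'
#' @param receptor a `gi_receptor`.
#' @param seed a `gi_pose` (or coordinate matrix).
#' @param radius shell radius in Angstrom (> 0).
#' @return A `gi_shell` list: `radius`, `movable` and `frozen` residue-id
#'   character vectors partitioning the receptor's residues.
#' @export
select_movable_residues <- function(receptor, seed, radius = 8.0) {
  if (radius <= 0) stop("shell radius must be positive")
  sc <- if (inherits(seed, "gi_pose")) seed$coords else as.matrix(seed)
  ids <- names(receptor$residues)
  movable <- vapply(receptor$residues, function(ix) {
    rc <- receptor$coords[ix, , drop = FALSE]
    for (a in seq_len(nrow(rc))) {
      d2 <- rowSums(sweep(sc, 2, rc[a, ])^2)
      if (any(d2 <= radius^2)) return(TRUE)
    }
    FALSE
  }, logical(1))
  structure(list(radius = radius,
                 movable = ids[movable],
                 frozen = ids[!movable]),
            class = "gi_shell")
}

# receptor-receptor contacts are judged at a reduced contact distance so
# covalently packed neighbours are not treated as clashes
REC_CONTACT_SCALE <- 0.6

#' Pocket minimization around a fixed seed pose
#'
#' Relaxes the movable shell of the receptor while the ligand seed pose and
#' all frozen residues stay exactly fixed. The objective is the normal-mode
#' receptor-ligand vdW energy, plus a soft-sphere overlap penalty between
#' movable atoms and all receptor atoms (contact distance scaled by 0.6 to
#' spare packed neighbours), plus harmonic tethers
#' `tether_k * sum(|x - x_start|^2)` over movable atoms. Derivative-free
#' greedy per-atom descent with a shrinking step; the final objective never
#' exceeds the initial one.
#'
#' @param receptor a `gi_receptor`.
#' @param ligand the `gi_ligand` the seed instantiates.
#' @param seed the seed `gi_pose` (kept fixed).
#' @param shell a [select_movable_residues()] result for this receptor/seed.
#' @param params [scoring_params()]; the receptor-ligand term always uses
#'   uncapped (normal) repulsion.
#' @param mcfg a [minimize_config()].
#' @return A new `gi_receptor`; frozen-residue coordinates are bit-identical
#'   to the input. Attributes `objective_initial`/`objective_final` carry the
#'   objective before and after descent.
#' @export
minimize_pocket <- function(receptor, ligand, seed, shell,
                            params = scoring_params(), mcfg = minimize_config()) {
  ids <- names(receptor$residues)
  if (!setequal(c(shell$movable, shell$frozen), ids) ||
      length(intersect(shell$movable, shell$frozen)) > 0)
    stop("shell does not partition this receptor's residues")
  mov_atoms <- sort(unname(unlist(receptor$residues[shell$movable],
                                  use.names = FALSE)))
  out <- receptor
  if (length(mov_atoms) == 0L) {
    attr(out, "objective_initial") <- attr(out, "objective_final") <- 0
    return(out)
  }
  sc <- if (inherits(seed, "gi_pose")) seed$coords else as.matrix(seed)
  lr <- ligand$radius
  X <- receptor$coords
  X0 <- X[mov_atoms, , drop = FALSE]
  rr <- receptor$radius
  cutoff <- params$cutoff
  is_mov <- rep(FALSE, nrow(X)); is_mov[mov_atoms] <- TRUE

  # energy terms attached to one movable atom at position p
  atom_energy <- function(a, p, X) {
    d <- sqrt(rowSums(sweep(sc, 2, p)^2))
    within <- d <= cutoff
    e <- 0
    if (any(within)) {
      dd <- d[within] - (rr[a] + lr[within])
      e <- e + sum(params$w_att * exp(-dd^2)) +
        sum(params$w_rep * ifelse(dd < 0, dd^2, 0))
    }
    dr <- sqrt(rowSums(sweep(X, 2, p)^2))
    dr[a] <- Inf
    ov <- REC_CONTACT_SCALE * (rr[a] + rr) - dr
    e + sum(pmax(ov, 0)^2)
  }
  tether <- function(a, p) mcfg$tether_k * sum((p - X0[match(a, mov_atoms), ])^2)
  # total objective (movable-movable overlap pairs counted once)
  total_obj <- function(X) {
    e <- 0
    for (a in mov_atoms) e <- e + atom_energy(a, X[a, ], X) + tether(a, X[a, ])
    for (i in seq_along(mov_atoms)) for (j in seq_len(i - 1L)) {
      a <- mov_atoms[i]; b <- mov_atoms[j]
      dr <- sqrt(sum((X[a, ] - X[b, ])^2))
      ov <- REC_CONTACT_SCALE * (rr[a] + rr[b]) - dr
      if (ov > 0) e <- e - ov^2   # counted twice in atom_energy sums
    }
    e
  }

  obj0 <- total_obj(X)
  obj <- obj0
  step <- mcfg$step0
  for (iter in seq_len(mcfg$max_iters)) {
    improved <- 0
    for (a in mov_atoms) {
      e_cur <- atom_energy(a, X[a, ], X) + tether(a, X[a, ])
      for (ax in 1:3) for (sgn in c(1, -1)) {
        p <- X[a, ]; p[ax] <- p[ax] + sgn * step
        e_new <- atom_energy(a, p, X) + tether(a, p)
        if (e_new < e_cur - 1e-12) {
          X[a, ] <- p
          improved <- improved + (e_cur - e_new)
          e_cur <- e_new
        }
      }
    }
    obj <- obj - improved
    if (improved < mcfg$tol) {
      step <- step / 2
      if (step < mcfg$step0 / 64) break
    }
  }
  out$coords <- X
  attr(out, "objective_initial") <- obj0
  attr(out, "objective_final") <- total_obj(X)
  out
}
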