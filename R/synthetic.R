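#' @title Synthetic cross-docking fixtures
#' @description Self-contained pseudo-receptor/ligand systems reproducing
#'   the central cross-docking failure mode: a correct ligand pose whose
#'   pocket atoms, displaced as in an apo-like structure, clash with it.
#' @name synthetic
NULL

# built-in all-carbon ligand templates (heavy atoms, Angstrom)
ligand_template <- function(name = c("rigid4", "flex6", "ring6")) {
  name <- match.arg(name)
  if (name == "rigid4") {
    # isobutane-like star: no rotatable torsions
    d <- 1.53 / sqrt(3)
    coords <- rbind(c(0, 0, 0), d * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)))
    bonds <- cbind(1L, 2:4, 1L)
  } else if (name == "flex6") {
    # two three-membered rings joined by one bond: exactly one torsion
    coords <- rbind(
      c(0, 0, 0), c(-1.299, 0.75, 0), c(-1.299, -0.75, 0),
      c(1.5, 0, 0), c(2.799, 0, 0.75), c(2.799, 0, -0.75))
    bonds <- rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1),
                   c(4, 5, 1), c(4, 6, 1), c(5, 6, 1), c(1, 4, 1))
  } else {
    a <- seq(0, 2 * pi, length.out = 7)[1:6]
    coords <- cbind(1.39 * cos(a), 1.39 * sin(a), 0)
    bonds <- cbind(1:6, c(2:6, 1L), 1L)
  }
  coords <- sweep(coords, 2, colMeans(coords))   # centroid at origin
  new_ligand(coords, rep("C", nrow(coords)), bonds)
}

#' Build a clash-free toy pocket around a reference ligand pose
#'
#' The ligand template sits at the origin in a low-internal-energy
#' conformation; `n_pocket_atoms` single-atom residues are placed on a
#' jittered spherical shell around `pocket_radius` covering all directions
#' except a 70-degree entrance cone (an open-mouthed cavity). Each atom is
#' adjusted radially to sit at a small positive surface gap (0.05-0.3 A) to
#' its nearest ligand atom, so the enclosed reference pose is clash-free and
#' in tight all-around contact — the binding-energy optimum. Atoms keep at
#' least 1.2 A mutual spacing. The reference pose is the placed ligand
#' itself. Deterministic per seed.
#'
#' @param template "rigid4" (no torsions), "flex6" (one torsion) or "ring6"
#'   (benzene-like, 12 automorphisms).
#' @param n_pocket_atoms number of pocket atoms (>= 6).
#' @param pocket_radius nominal shell radius (Angstrom); must exceed the
#'   ligand bounding radius. `NULL` (default) uses bounding radius + 3.5.
#' @param seed RNG seed.
#' @return List with `receptor`, `ligand`, `reference` (a `gi_pose`).
#' @export
make_toy_complex <- function(template = "rigid4", n_pocket_atoms = 48L,
                             pocket_radius = NULL, seed = 1L) {
  if (n_pocket_atoms < 6L) stop("need at least 6 pocket atoms")
  ligand <- ligand_template(template)
  br <- bounding_radius(ligand$coords)
  if (is.null(pocket_radius)) pocket_radius <- br + 3.5
  if (pocket_radius <= br)
    stop("pocket_radius must exceed the ligand bounding radius")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  mingap <- function(q)
    min(sqrt(rowSums(sweep(ligand$coords, 2, q)^2)) - (ligand$radius + 1.70))
  pos <- matrix(NA_real_, n_pocket_atoms, 3)
  for (k in seq_len(n_pocket_atoms)) {
    placed <- FALSE
    for (try in 1:400) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      if (u[3] < -0.342) next                    # entrance cone stays open
      t <- pocket_radius + runif(1, -0.3, 0.3)
      g <- mingap(u * t)
      gt <- runif(1, 0.05, 0.3)
      for (it in 1:40) {                         # radial solve: gap -> gt
        if (abs(g - gt) < 0.02) break
        t <- t - (g - gt) * 0.8
        g <- mingap(u * t)
      }
      if (g < 0.04) next
      p <- u * t
      if (k > 1L) {
        dmin <- min(sqrt(rowSums(sweep(pos[seq_len(k - 1L), , drop = FALSE],
                                       2, p)^2)))
        if (dmin < 1.2) next
      }
      pos[k, ] <- p; placed <- TRUE; break
    }
    if (!placed)
      stop("infeasible pocket geometry: radius too small for ",
           n_pocket_atoms, " atoms")
  }
  receptor <- new_receptor(pos, rep("C", n_pocket_atoms),
                           paste0("P_", seq_len(n_pocket_atoms)))
  reference <- new_pose(ligand$coords, score = 0,
                        provenance = list(potential = "normal",
                                          conformation_id = 0L,
                                          iteration = 0L, rank = 1L))
  list(receptor = receptor, ligand = ligand, reference = reference,
       template = template, seed = seed)
}

#' Derive an apo-like cross-docking case from a toy complex
#'
#' Displaces the `n_clash_atoms` pocket atoms nearest the ligand by
#' `clash_magnitude` Angstrom toward their nearest ligand atom, so the
#' reference pose now clashes with the docking structure. The case is
#' labelled "challenging" iff the normal-mode repulsion at the reference
#' pose exceeds the soft-mode per-pair cap `e_cap`.
#'
#' @param holo a [make_toy_complex()] result.
#' @param clash_magnitude displacement in Angstrom (>= 0).
#' @param n_clash_atoms how many pocket atoms to displace.
#' @param case_id identifier for the resulting case.
#' @param scoring [scoring_params()] used for the difficulty label.
#' @return A [benchmark_case()] (`gi_case`).
#' @export
make_cross_dock_case <- function(holo, clash_magnitude, n_clash_atoms = 2L,
                                 case_id = "case", scoring = scoring_params()) {
  if (clash_magnitude < 0) stop("clash_magnitude must be >= 0")
  rec <- holo$receptor
  if (n_clash_atoms > nrow(rec$coords))
    stop("n_clash_atoms exceeds the pocket atom count")
  ref <- holo$reference$coords
  ctr <- centroid(ref)
  dmin <- apply(rec$coords, 1, function(p)
    min(sqrt(rowSums(sweep(ref, 2, p)^2))))
  targets <- order(dmin)[seq_len(n_clash_atoms)]
  for (a in targets) {
    p <- rec$coords[a, ]
    if (clash_magnitude >= sqrt(sum((p - ctr)^2)))
      stop("clash_magnitude would move a pocket atom past the ligand centroid")
    j <- which.min(sqrt(rowSums(sweep(ref, 2, p)^2)))
    u <- ref[j, ] - p
    u <- u / sqrt(sum(u^2))
    rec$coords[a, ] <- p + clash_magnitude * u
  }
  e <- score_pose(rec, holo$ligand, ref, scoring_params("normal",
                                                        w_att = scoring$w_att,
                                                        w_rep = scoring$w_rep,
                                                        e_cap = scoring$e_cap,
                                                        cutoff = scoring$cutoff))
  difficulty <- if (e$vdw_repulsive > scoring$e_cap) "challenging" else "typical"
  benchmark_case(rec, holo$ligand, holo$reference,
                 autobox(ref, margin = 4), case_id, difficulty)
}

#' Generate a synthetic cross-docking benchmark
#'
#' Draws `n_cases` toy cross-docking cases with per-case derived seeds:
#' a `difficulty_mix` fraction with clash displacements in [1.0, 2.0] A
#' (challenging regime) and the rest in [0, 0.3] A (typical regime),
#' cycling through the ligand templates. Cases can be serialized to the
#' evaluation manifest layout.
#'
#' @param n_cases number of cases (>= 1).
#' @param seed master seed.
#' @param difficulty_mix fraction of cases in the challenging regime.
#' @param out_dir if non-NULL, write each case under `out_dir/<case_id>/`.
#' @param templates ligand templates to cycle through.
#' @return List of `gi_case`.
#' @export
make_benchmark <- function(n_cases, seed = 1L, difficulty_mix = 0.5,
                           out_dir = NULL,
                           templates = c("rigid4", "flex6", "ring6")) {
  if (n_cases < 1L) stop("n_cases must be >= 1")
  n_hard <- round(n_cases * difficulty_mix)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cseed <- derive_seed(seed, paste0("bench-case:", i))
    set.seed(cseed)
    hard <- i <= n_hard
    mag <- if (hard) runif(1, 1.0, 2.0) else runif(1, 0, 0.3)
    ncl <- if (hard) sample(6:9, 1) else sample(2:3, 1)
    tmpl <- templates[1L + (i - 1L) %% length(templates)]
    holo <- make_toy_complex(tmpl, seed = derive_seed(cseed, "holo"))
    cid <- sprintf("%s_%s_%02d", if (hard) "hard" else "easy", tmpl, i)
    cases[[i]] <- make_cross_dock_case(holo, mag, ncl, case_id = cid)
    if (!is.null(out_dir)) write_case(cases[[i]], file.path(out_dir, cid))
  }
  cases
}

#' The frozen clash-rescue fixture
#'
#' A fixed challenging cross-docking case: a rigid4 pocket whose eight
#' nearest pocket atoms are displaced 2.0 A into the reference ligand
#' volume, blocking the cavity under the normal potential. A single
#' normal-potential docking run misses the reference pose (min RMSD above
#' the 2 A success threshold) while the soft-potential pathways (GLOW,
#' IVES) recover it. Used by the regression tests and the acceptance
#' script.
#'
#' @return A `gi_case` plus the generating `holo` complex (attribute).
#' @export
challenge_fixture <- function() {
  holo <- make_toy_complex("rigid4", n_pocket_atoms = 48L,
                           pocket_radius = NULL, seed = 20231130L)
  case <- make_cross_dock_case(holo, clash_magnitude = 2.0, n_clash_atoms = 8L,
                               case_id = "frozen_challenge")
  attr(case, "holo") <- holo
  case
}
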