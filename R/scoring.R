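#' Scoring parameters for the steric potential
#'
#' A minimal two-term van der Waals scoring function in the surface distance
#' d = r - r0 (r0 = sum of the two atoms' vdW radii): a Gaussian attractive
#' well of unit depth centred at d = 0 and a quadratic repulsion d^2 for
#' d < 0. In `soft` mode the per-pair repulsion is capped at `e_cap`
#' (soft-core plateau), so clashes deeper than sqrt(e_cap) cost no extra —
#' the mechanism that lets clash-tolerant sampling keep poses a normal
#' potential would reject.
#'
#' @param mode "normal" (uncapped repulsion) or "soft" (capped).
#' @param w_att weight of the attractive term (negative favours contact).
#' @param w_rep weight of the repulsive term.
#' @param e_cap per-pair repulsion cap used in soft mode (energy units).
#' @param d_soft reserved offset for an alternative linear-switch softening;
#'   unused by the default cap form.
#' @param cutoff pairwise distance cutoff in Angstrom (>= 8).
#' @return A `gi_scoring_params` list.
#' @export
scoring_params <- function(mode = c("normal", "soft"), w_att = -0.8,
                           w_rep = 1.6, e_cap = 0.25, d_soft = 0,
                           cutoff = 8) {
  mode <- match.arg(mode)
  stopifnot(is.finite(w_att), is.finite(w_rep), e_cap > 0, cutoff >= 8)
  structure(list(mode = mode, w_att = w_att, w_rep = w_rep, e_cap = e_cap,
                 d_soft = d_soft, cutoff = cutoff),
            class = "gi_scoring_params")
}

#' Single-pair van der Waals energy components
#'
#' @param r interatomic distance (Angstrom, > 0).
#' @param r0 contact distance: sum of the two atoms' vdW radii.
#' @param params a [scoring_params()] object.
#' @return Named vector `c(att, rep)`: unweighted attractive and repulsive
#'   components (both zero beyond the cutoff).
#' @export
pair_vdw <- function(r, r0, params) {
  if (any(r <= 0)) stop("coincident atoms: pair distance must be > 0")
  d <- r - r0
  att <- exp(-(d / 0.5)^2)              # Gaussian well, sigma = 0.5 A
  rep <- ifelse(d < 0, d^2, 0)
  if (params$mode == "soft") rep <- pmin(rep, params$e_cap)
  beyond <- r > params$cutoff
  att[beyond] <- 0; rep[beyond] <- 0
  c(att = sum(att), rep = sum(rep))
}

#' Score a ligand pose against a receptor
#'
#' Sums the pair potential over all receptor-ligand heavy-atom pairs within
#' the cutoff (cell-list neighbour search), plus a ligand self-clash term
#' over atom pairs separated by at least 4 bonds. The internal term uses
#' uncapped repulsion in both modes, so softening never rewards
#' self-clashing conformers. For any pose, the soft-mode total is <= the
#' normal-mode total.
#'
#' @param receptor a `gi_receptor` (may have zero atoms).
#' @param ligand the `gi_ligand`.
#' @param pose a `gi_pose`, or a bare coordinate matrix.
#' @param params a [scoring_params()] object.
#' @return A `gi_energy` list: `vdw_attractive`, `vdw_repulsive` (unweighted
#'   sums), `internal` (weighted self-clash), and
#'   `total = w_att * vdw_attractive + w_rep * vdw_repulsive + internal`.
#' @export
score_pose <- function(receptor, ligand, pose, params) {
  coords <- if (inherits(pose, "gi_pose")) pose$coords else as.matrix(pose)
  if (nrow(coords) != nrow(ligand$coords))
    stop("pose has ", nrow(coords), " atoms; ligand has ", nrow(ligand$coords))
  e_cap <- if (params$mode == "soft") params$e_cap else -1
  pe <- cpp_pair_energy(coords, ligand$radius,
                        receptor$coords, receptor$radius,
                        params$cutoff, e_cap)
  internal <- if (nrow(ligand$internal_pairs) > 0)
    params$w_rep * cpp_internal_energy(coords, ligand$radius, ligand$internal_pairs)
  else 0
  att <- unname(pe["att"]); rep <- unname(pe["rep"])
  structure(list(vdw_attractive = att, vdw_repulsive = rep,
                 internal = internal,
                 total = params$w_att * att + params$w_rep * rep + internal),
            class = "gi_energy")
}

# fast path used inside the sampler: total energy only
score_total <- function(rec_coords, rec_radius, lig_coords, lig_radius,
                        internal_pairs, params, e_cap_signed) {
  pe <- cpp_pair_energy(lig_coords, lig_radius, rec_coords, rec_radius,
                        params$cutoff, e_cap_signed)
  internal <- if (nrow(internal_pairs) > 0)
    params$w_rep * cpp_internal_energy(lig_coords, lig_radius, internal_pairs)
  else 0
  params$w_att * pe[["att"]] + params$w_rep * pe[["rep"]] + internal
}

#' Load scoring parameters from a config list or YAML file
#'
#' Reads the `scoring:` block of a config (plus `sampler:` and protocol
#' blocks elsewhere).
#'
#' @param config a list (already parsed) or a YAML/JSON file path.
#' @param mode potential mode to instantiate.
#' @return A [scoring_params()] object.
#' @export
scoring_params_from_config <- function(config, mode = "normal") {
  cfg <- load_config(config)
  sc <- cfg$scoring
  if (is.null(sc)) sc <- list()
  do.call(scoring_params, c(list(mode = mode),
                            sc[intersect(names(sc),
                                         c("w_att", "w_rep", "e_cap", "d_soft", "cutoff"))]))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    if (grepl("\\.json$", config, ignore.case = TRUE))
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    return(yaml::read_yaml(config))
  }
  if (is.list(config)) return(config)
  if (is.null(config)) return(list())
  stop("config must be a list or a YAML/JSON file path")
}
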