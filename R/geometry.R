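# Rigid-body and torsion geometry helpers (heavy atoms, Angstrom).

# rotation matrix for `angle` radians about unit `axis` (Rodrigues)
axis_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}

# uniform random rotation from a normalized 4-normal quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# apply torsion angles (radians) to the ligand's reference conformation:
# each torsion rotates its moving set about the axis-atom line, in order
apply_torsions <- function(ligand, theta) {
  coords <- ligand$coords
  if (length(theta) == 0L) return(coords)
  for (k in seq_along(ligand$torsions)) {
    if (theta[k] == 0) next
    tor <- ligand$torsions[[k]]
    p1 <- coords[tor$axis[1], ]; p2 <- coords[tor$axis[2], ]
    R <- axis_rotation(p2 - p1, theta[k])
    mv <- tor$moving
    coords[mv, ] <- sweep(sweep(coords[mv, , drop = FALSE], 2, p1) %*% t(R), 2, p1, "+")
  }
  coords
}

# pose coordinates from a sampler state: torsioned conformation, centred,
# rotated by state$R, centroid placed at state$t
state_coords <- function(ligand, state) {
  base <- apply_torsions(ligand, state$theta)
  ctr <- colMeans(base)
  sweep(sweep(base, 2, ctr) %*% t(state$R), 2, state$t, "+")
}

centroid <- function(coords) colMeans(coords)

# largest distance from the centroid to any atom
bounding_radius <- function(coords) {
  d <- sweep(coords, 2, colMeans(coords))
  sqrt(max(rowSums(d^2)))
}
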