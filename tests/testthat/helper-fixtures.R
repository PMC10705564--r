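# In-code fixtures: tiny molecules and structures built at test time.

# write a minimal V2000 SDF for the given atoms/bonds; returns the path
write_test_sdf <- function(elements, coords, bonds, path = tempfile(fileext = ".sdf"),
                           name = "mol", n_records = 1L) {
  rec <- c(
    name, "  glowives-test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(elements), nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements),
    sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2], bonds[, 3]),
    "M  END", "$$$$")
  writeLines(rep(rec, n_records), path)
  path
}

sdf_butane <- function(path = tempfile(fileext = ".sdf")) {
  write_test_sdf(rep("C", 4),
                 rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.04, 1.44, 0),
                       c(3.57, 1.44, 0)),
                 cbind(1:3, 2:4, 1L), path, name = "butane")
}

sdf_benzene <- function(path = tempfile(fileext = ".sdf")) {
  a <- seq(0, 2 * pi, length.out = 7)[1:6]
  write_test_sdf(rep("C", 6), cbind(1.39 * cos(a), 1.39 * sin(a), 0),
                 cbind(1:6, c(2:6, 1L), rep(1L, 6)), path, name = "benzene")
}

# ethanol heavy atoms: C-C-O chain plus explicit hydrogens on the tail
sdf_ethanol <- function(path = tempfile(fileext = ".sdf")) {
  write_test_sdf(c("C", "C", "O", "H", "H", "H"),
                 rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.0, 1.3, 0),
                       c(-0.5, 0.9, 0), c(-0.5, -0.9, 0), c(2.9, 1.3, 0.4)),
                 rbind(c(1, 2, 1), c(2, 3, 1), c(1, 4, 1), c(1, 5, 1),
                       c(3, 6, 1)),
                 path, name = "ethanol")
}

# 3-residue toy PDB (9 backbone atoms), optionally with waters / extra records
write_test_pdb <- function(path = tempfile(fileext = ".pdb"),
                           waters = 0L, hetatm_only = FALSE) {
  atom_line <- function(serial, name, res, chain, resno, x, y, z, el,
                        record = "ATOM") {
    sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            record, serial, name, res, chain, resno, x, y, z, el)
  }
  lines <- character(0)
  if (!hetatm_only) {
    k <- 0
    for (r in 1:3) for (nm in c("N", "CA", "C")) {
      k <- k + 1
      el <- substr(nm, 1, 1)
      lines <- c(lines, atom_line(k, nm, "ALA", "A", r,
                                  3.8 * r + k * 0.1, k * 0.5, 0, el))
    }
  }
  if (hetatm_only)
    lines <- c(lines, atom_line(1, "C1", "LIG", "A", 90, 0, 0, 0, "C", "HETATM"),
               atom_line(2, "C2", "LIG", "A", 90, 1.5, 0, 0, "C", "HETATM"))
  if (waters > 0)
    for (w in seq_len(waters))
      lines <- c(lines, atom_line(100 + w, "O", "HOH", "W", w,
                                  20 + w, 20, 20, "O", "HETATM"))
  writeLines(c(lines, "END"), path)
  path
}

# brute-force oracle: a bond is rotatable iff single, acyclic (bridge) and
# both ends have >= 2 neighbours; tested by cutting each bond explicitly
oracle_rotatable <- function(elements, bonds) {
  n <- length(elements)
  adj <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  connected_without <- function(drop) {
    keep <- bonds[-drop, , drop = FALSE]
    seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(keep[keep[, 1] == v, 2], keep[keep[, 2] == v, 1])
      new <- nb[!seen[nb]]
      seen[new] <- TRUE; queue <- c(queue, new)
    }
    all(seen)
  }
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    if (bonds[b, 3] != 1L) next
    i <- min(bonds[b, 1:2]); j <- max(bonds[b, 1:2])
    if (length(adj[[i]]) < 2 || length(adj[[j]]) < 2) next
    if (connected_without(b)) next   # still connected: bond was in a ring
    out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

# brute-force all-pairs scoring oracle (R implementation, no neighbor search)
oracle_score <- function(receptor, ligand, coords, params) {
  att <- 0; rep_ <- 0
  if (nrow(receptor$coords) > 0) {
    for (i in seq_len(nrow(receptor$coords))) for (j in seq_len(nrow(coords))) {
      r <- sqrt(sum((receptor$coords[i, ] - coords[j, ])^2))
      if (r > params$cutoff) next
      d <- r - (receptor$radius[i] + ligand$radius[j])
      att <- att + exp(-(d / 0.5)^2)
      rp <- if (d < 0) d^2 else 0
      if (params$mode == "soft") rp <- min(rp, params$e_cap)
      rep_ <- rep_ + rp
    }
  }
  internal <- 0
  ip <- ligand$internal_pairs
  if (nrow(ip) > 0) for (k in seq_len(nrow(ip))) {
    r <- sqrt(sum((coords[ip[k, 1], ] - coords[ip[k, 2], ])^2))
    d <- r - (ligand$radius[ip[k, 1]] + ligand$radius[ip[k, 2]])
    if (d < 0) internal <- internal + params$w_rep * d^2
  }
  list(att = att, rep = rep_, internal = internal,
       total = params$w_att * att + params$w_rep * rep_ + internal)
}

# brute-force symmetry RMSD: enumerate all atom permutations preserving
# elements and the bond multiset, take the minimum RMSD
oracle_sym_rmsd <- function(a, b, elements, bonds) {
  n <- nrow(a)
  bond_key <- function(bd) {
    k <- apply(cbind(pmin(bd[, 1], bd[, 2]), pmax(bd[, 1], bd[, 2]), bd[, 3]),
               1, paste, collapse = "-")
    sort(k)
  }
  ref_key <- bond_key(bonds)
  perms <- gtools_permutations(n)
  best <- Inf
  for (p in perms) {
    if (any(elements[p] != elements)) next
    mapped <- cbind(p[bonds[, 1]], p[bonds[, 2]], bonds[, 3])
    if (!identical(bond_key(mapped), ref_key)) next
    r <- sqrt(mean(rowSums((a - b[p, , drop = FALSE])^2)))
    best <- min(best, r)
  }
  best
}

# all permutations of 1:n as a list (n small)
gtools_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in gtools_permutations(n - 1)) for (k in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# small deterministic pose cloud around a centre
jitter_poses <- function(coords, n, sd = 1.0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    cc <- coords + matrix(rnorm(length(coords), 0, sd), nrow(coords), 3)
    new_pose(cc, score = rnorm(1))
  })
}
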