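test_that("PDB receptor reading keeps protein atoms and drops waters", {
  p <- write_test_pdb()
  rec <- read_receptor(p)
  expect_s3_class(rec, "gi_receptor")
  expect_equal(nrow(rec$coords), 9)
  expect_length(rec$residues, 3)

  pw <- write_test_pdb(waters = 2)
  recw <- read_receptor(pw)
  expect_equal(recw$coords, rec$coords)
  expect_equal(recw$residue_id, rec$residue_id)
})

test_that("HETATM-only and malformed PDB files raise informative errors", {
  ph <- write_test_pdb(hetatm_only = TRUE)
  expect_error(read_receptor(ph), "empty structure")

  bad <- tempfile(fileext = ".pdb")
  lines <- readLines(write_test_pdb())
  substr(lines[2], 31, 38) <- "   xx.yy"
  writeLines(lines, bad)
  expect_error(read_receptor(bad), "line 2")
})

test_that("receptor residue partition is exact", {
  rec <- read_receptor(write_test_pdb())
  idx <- unlist(rec$residues, use.names = FALSE)
  expect_setequal(idx, seq_len(nrow(rec$coords)))
  expect_equal(anyDuplicated(idx), 0L)
})

test_that("ligand reading detects torsions on standard small molecules", {
  but <- read_ligand(sdf_butane())
  expect_length(but$torsions, 1)
  expect_equal(sort(but$torsions[[1]]$axis), c(2, 3))

  ben <- read_ligand(sdf_benzene())
  expect_length(ben$torsions, 0)

  # ethanol: hydrogens are dropped, leaving the heavy chain C-C-O; both
  # bonds then have a terminal end, so neither rotation can change
  # heavy-atom internal geometry (three atoms admit no dihedral)
  eth <- read_ligand(sdf_ethanol())
  expect_equal(nrow(eth$coords), 3)
  expect_length(eth$torsions, 0)
})

test_that("multi-record and bond-less ligand files error with guidance", {
  multi <- write_test_sdf(rep("C", 4),
                          rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.04, 1.44, 0),
                                c(3.57, 1.44, 0)),
                          cbind(1:3, 2:4, 1L), n_records = 2L)
  expect_error(read_ligand(multi), "record")
  expect_length(read_ligand(multi, record = 2)$torsions, 1)
})

test_that("rotatable-bond detection agrees with the exhaustive oracle", {
  # hand-picked topologies
  cases <- list(
    chain4 = list(el = rep("C", 4), bonds = cbind(1:3, 2:4, 1L)),
    ring6 = list(el = rep("C", 6), bonds = cbind(1:6, c(2:6, 1L), 1L)),
    tworings = list(el = rep("C", 6),
                    bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 1, 1),
                                  c(4, 5, 1), c(5, 6, 1), c(6, 4, 1),
                                  c(1, 4, 1)))
  )
  expect_length(detect_rotatable_bonds(
    new_ligand(matrix(rnorm(12), 4, 3) * 0 + cbind(1:4, 0, 0),
               cases$chain4$el, cases$chain4$bonds)), 1)

  # random connected graphs vs oracle
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    # random tree plus a few extra edges
    bonds <- cbind(2:n, vapply(2:n, function(i) sample(seq_len(i - 1), 1), 1L), 1L)
    extra <- sample(0:2, 1)
    for (e in seq_len(extra)) {
      ij <- sample(n, 2)
      if (any(bonds[, 1] == max(ij) & bonds[, 2] == min(ij))) next
      bonds <- rbind(bonds, c(max(ij), min(ij), 1L))
    }
    coords <- cbind(seq_len(n) * 2, (seq_len(n) %% 2), 0)  # geometry irrelevant
    lig <- new_ligand(coords, rep("C", n), bonds)
    got <- lapply(lig$torsions, `[[`, "axis")
    want <- oracle_rotatable(rep("C", n), lig$bonds)
    expect_equal(got, want, info = sprintf("trial %d", trial))
    # moving sets are proper non-empty subsets
    for (tor in lig$torsions) {
      expect_gt(length(tor$moving), 0)
      expect_lt(length(tor$moving), n)
    }
  }
})

test_that("pose SDF output round-trips coordinates, tags and provenance", {
  lig <- read_ligand(sdf_butane())
  poses <- lapply(1:3, function(k)
    new_pose(lig$coords + k, score = -k,
             breakdown = list(vdw_attractive = k, vdw_repulsive = 0.1 * k,
                              internal = 0, total = -k),
             provenance = list(potential = if (k == 2) "soft" else "normal",
                               conformation_id = k, iteration = 1L, rank = k)))
  path <- tempfile(fileext = ".sdf")
  write_poses(poses, lig, path)

  txt <- readLines(path)
  expect_equal(sum(grepl("^\\$\\$\\$\\$", txt)), 3)
  expect_equal(sum(grepl("<GI_potential>", txt)), 3)

  back <- read_poses(path, lig)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_lt(max(abs(back[[k]]$coords - poses[[k]]$coords)), 1e-3)
    expect_equal(back[[k]]$provenance$potential, poses[[k]]$provenance$potential)
    expect_equal(back[[k]]$provenance$conformation_id, k)
    expect_equal(back[[k]]$score, -k, tolerance = 1e-6)
  }
})

test_that("pose writing validates inputs", {
  lig <- read_ligand(sdf_butane())
  expect_error(write_poses(list(), lig, tempfile()), "empty")
  bad <- new_pose(lig$coords[1:3, ], score = 0)
  expect_error(write_poses(list(bad), lig, tempfile(fileext = ".sdf")),
               "atoms")
})
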