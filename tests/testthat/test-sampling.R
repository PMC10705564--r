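test_that("sampler is bitwise reproducible under a fixed seed", {
  holo <- make_toy_complex("rigid4", seed = 5)
  box <- autobox(holo$reference$coords)
  cfg <- sampler_config(seed = 9, n_chains = 2, n_steps = 200)
  s1 <- sample_poses(holo$receptor, holo$ligand, box, scoring_params(), cfg)
  s2 <- sample_poses(holo$receptor, holo$ligand, box, scoring_params(), cfg)
  expect_equal(length(s1$poses), length(s2$poses))
  for (k in seq_along(s1$poses)) {
    expect_identical(s1$poses[[k]]$coords, s2$poses[[k]]$coords)
    expect_identical(s1$poses[[k]]$score, s2$poses[[k]]$score)
  }
})

test_that("empty receptor gives a zero-energy floor for a rigid ligand", {
  lig <- glowives:::ligand_template("rigid4")
  empty <- new_receptor(matrix(numeric(0), 0, 3), character(0), character(0))
  set <- sample_poses(empty, lig, search_box(c(0, 0, 0), c(4, 4, 4)),
                      scoring_params(), sampler_config(seed = 1, n_chains = 2,
                                                       n_steps = 100))
  expect_equal(set$poses[[1]]$score, 0)
})

test_that("sampler input validation", {
  lig <- glowives:::ligand_template("rigid4")
  rec <- make_toy_complex("rigid4", seed = 1)$receptor
  expect_error(sample_poses(rec, lig, search_box(c(0, 0, 0), c(0.5, 0.5, 0.5)),
                            scoring_params(), sampler_config()),
               "larger than")
  expect_error(sampler_config(n_steps = 0), "n_steps")
})

test_that("sampler best energy matches an exhaustive grid oracle (1-atom)", {
  # single receptor atom at the origin; single-atom ligand
  rec <- new_receptor(matrix(c(0, 0, 0), 1, 3), "C", "R_1")
  lig <- new_ligand(matrix(c(0, 0, 0), 1, 3), "C", matrix(integer(0), 0, 3))
  box <- search_box(c(2, 0, 0), c(3, 3, 3))
  p <- scoring_params("normal")
  # exhaustive 0.1 A grid over the box
  g <- seq(-3, 3, by = 0.1)
  pts <- as.matrix(expand.grid(x = 2 + g, y = g, z = g))
  r <- sqrt(rowSums(pts^2))
  d <- r - 3.4
  e <- p$w_att * exp(-(d / 0.5)^2) + p$w_rep * ifelse(d < 0, d^2, 0)
  e[r > p$cutoff] <- 0
  oracle_best <- min(e)
  set <- sample_poses(rec, lig, box, p,
                      sampler_config(seed = 4, n_chains = 4, n_steps = 400))
  expect_lte(set$poses[[1]]$score, oracle_best + 0.05)
})

test_that("sampler best energy matches a translation-grid oracle (rigid ligand)", {
  holo <- make_toy_complex("rigid4", seed = 12)
  p <- scoring_params("normal")
  box <- autobox(holo$reference$coords, margin = 2)
  # translations of the reference orientation on a 0.1 A grid: an upper
  # bound on the global minimum the sampler must not exceed (plus slack)
  g <- seq(-1, 1, by = 0.1)
  best <- Inf
  for (dx in g) for (dy in g) for (dz in g) {
    cc <- sweep(holo$ligand$coords, 2, c(dx, dy, dz), "+")
    best <- min(best, score_pose(holo$receptor, holo$ligand, cc, p)$total)
  }
  set <- sample_poses(holo$receptor, holo$ligand, box, p,
                      sampler_config(seed = 4, n_chains = 6, n_steps = 800))
  expect_lte(set$poses[[1]]$score, best + 0.05)
})

test_that("leader clustering equals the brute-force oracle", {
  lig <- glowives:::ligand_template("ring6")
  poses <- jitter_poses(lig$coords, 10, sd = 1.2, seed = 8)
  cutoff <- 1.5
  got <- cluster_poses(poses, cutoff, lig)
  # brute force: walk sorted poses, keep iff min sym-RMSD to kept > cutoff
  ord <- order(vapply(poses, `[[`, numeric(1), "score"))
  kept <- list()
  for (p in poses[ord]) {
    ok <- TRUE
    for (q in kept) {
      r <- oracle_sym_rmsd(p$coords, q$coords, lig$element, lig$bonds)
      if (r <= cutoff) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- p
  }
  expect_equal(length(got), length(kept))
  for (k in seq_along(got))
    expect_identical(got[[k]]$coords, kept[[k]]$coords)
})

test_that("clustering keeps the better of identical poses and all distant ones", {
  lig <- glowives:::ligand_template("rigid4")
  a <- new_pose(lig$coords, score = -2)
  b <- new_pose(lig$coords, score = -1)
  out <- cluster_poses(list(b, a), cutoff = 0.5, lig)
  expect_length(out, 1)
  expect_equal(out[[1]]$score, -2)

  far <- new_pose(lig$coords + 10, score = 0)
  out2 <- cluster_poses(list(a, far), cutoff = 0.5, lig)
  expect_length(out2, 2)
  expect_error(cluster_poses(list(a), cutoff = -1, lig), "non-negative")
})

test_that("clustered output has all pairwise RMSDs above the cutoff", {
  holo <- make_toy_complex("ring6", seed = 3)
  cfg <- sampler_config(seed = 2, n_chains = 4, n_steps = 300,
                        cluster_cutoff = 1.0)
  set <- sample_poses(holo$receptor, holo$ligand, autobox(holo$reference$coords),
                      scoring_params(), cfg)
  n <- length(set$poses)
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    r <- symmetry_rmsd(set$poses[[i]], set$poses[[j]], holo$ligand)
    expect_gt(as.numeric(r), cfg$cluster_cutoff)
  }
  # scores ascending
  s <- vapply(set$poses, `[[`, numeric(1), "score")
  expect_true(!is.unsorted(s))
})

test_that("pose-set merging is idempotent, respects identity and sorts globally", {
  lig <- glowives:::ligand_template("rigid4")
  holo <- make_toy_complex("rigid4", seed = 5)
  set <- sample_poses(holo$receptor, holo$ligand, autobox(holo$reference$coords),
                      scoring_params(),
                      sampler_config(seed = 3, n_chains = 2, n_steps = 200))
  m1 <- merge_pose_sets(list(set, set), cutoff = set$cluster_cutoff,
                        max_poses = 300)
  expect_equal(length(m1$poses), length(set$poses))
  for (k in seq_along(set$poses))
    expect_identical(m1$poses[[k]]$coords, set$poses[[k]]$coords)

  empty <- new_pose_set(list(), holo$ligand)
  m2 <- merge_pose_sets(list(set, empty), cutoff = set$cluster_cutoff,
                        max_poses = 300)
  expect_equal(length(m2$poses), length(set$poses))

  # two disjoint 5-pose sets, cutoff 0: all 10 kept, globally sorted
  p1 <- jitter_poses(lig$coords, 5, sd = 2, seed = 1)
  p2 <- jitter_poses(lig$coords + 20, 5, sd = 2, seed = 2)
  m3 <- merge_pose_sets(list(new_pose_set(p1, lig), new_pose_set(p2, lig)),
                        cutoff = 0, max_poses = 100)
  expect_length(m3$poses, 10)
  s <- vapply(m3$poses, `[[`, numeric(1), "score")
  expect_true(!is.unsorted(s))

  other <- glowives:::ligand_template("ring6")
  expect_error(merge_pose_sets(list(set, new_pose_set(list(), other)),
                               1, 10), "different ligands")
})

test_that("pooling more chains never worsens the best score", {
  holo <- make_toy_complex("rigid4", seed = 5)
  box <- autobox(holo$reference$coords)
  s2 <- sample_poses(holo$receptor, holo$ligand, box, scoring_params(),
                     sampler_config(seed = 6, n_chains = 2, n_steps = 300))
  s4 <- sample_poses(holo$receptor, holo$ligand, box, scoring_params(),
                     sampler_config(seed = 6, n_chains = 4, n_steps = 300))
  expect_lte(s4$poses[[1]]$score, s2$poses[[1]]$score + 1e-12)
})
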