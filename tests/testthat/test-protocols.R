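# shared small-scale configuration for protocol tests
proto_sampler <- function(seed = 101L) sampler_config(seed = seed,
                                                      n_chains = 4,
                                                      n_steps = 500)

test_that("the Default baseline caps its pose list and is deterministic", {
  cs <- challenge_fixture()
  r1 <- run_default(cs$receptor_dock, cs$ligand, cs$box,
                    sampler = proto_sampler())
  expect_lte(length(r1$poses$poses), 20)
  expect_equal(r1$poses$poses[[1]]$provenance$potential, "normal")
  r2 <- run_default(cs$receptor_dock, cs$ligand, cs$box,
                    sampler = proto_sampler())
  for (k in seq_along(r1$poses$poses))
    expect_identical(r1$poses$poses[[k]]$coords, r2$poses$poses[[k]]$coords)
})

test_that("GLOW with a huge softening cap degenerates to two pooled normal runs", {
  holo <- make_toy_complex("rigid4", seed = 8)
  box <- autobox(holo$reference$coords)
  smp <- proto_sampler(7)
  sc <- scoring_params(e_cap = 1e9)
  g <- run_glow(holo$receptor, holo$ligand, box, scoring = sc, sampler = smp)
  # manual pooling of two normal-mode runs on the derived seeds
  p_norm <- scoring_params("normal", e_cap = 1e9)
  cfg_n <- smp; cfg_n$seed <- glowives:::derive_seed(smp$seed, "stage:normal")
  cfg_s <- smp; cfg_s$seed <- glowives:::derive_seed(smp$seed, "stage:soft")
  set_n <- sample_poses(holo$receptor, holo$ligand, box, p_norm, cfg_n)
  set_s <- sample_poses(holo$receptor, holo$ligand, box, p_norm, cfg_s)
  want <- merge_pose_sets(list(set_n, set_s), smp$cluster_cutoff, smp$max_poses)
  expect_equal(length(g$poses$poses), length(want$poses))
  for (k in seq_along(want$poses))
    expect_equal(g$poses$poses[[k]]$coords, want$poses[[k]]$coords,
                 tolerance = 1e-12)
})

test_that("GLOW's pool contains the baseline's reach (superset property)", {
  cs <- challenge_fixture()
  smp <- proto_sampler()
  rd <- run_default(cs$receptor_dock, cs$ligand, cs$box, sampler = smp)
  rg <- run_glow(cs$receptor_dock, cs$ligand, cs$box, sampler = smp)
  md <- is_success(rd$poses, cs$reference, cs$ligand)$min_rmsd
  mg <- is_success(rg$poses, cs$reference, cs$ligand)$min_rmsd
  expect_lte(mg, md + smp$cluster_cutoff)
  # provenance distinguishes the source runs
  pots <- vapply(rg$poses$poses, function(p) p$provenance$potential, "")
  expect_setequal(unique(pots), c("normal", "soft"))
})

test_that("seed-pose selection takes the top N with deterministic tie-breaks", {
  lig <- glowives:::ligand_template("rigid4")
  poses <- jitter_poses(lig$coords, 30, sd = 3, seed = 2)
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "score"))]
  for (k in seq_along(poses)) poses[[k]]$provenance$rank <- k
  ps <- new_pose_set(poses, lig)

  top5 <- select_seed_poses(ps, 5)
  expect_length(top5, 5)
  expect_equal(vapply(top5, `[[`, numeric(1), "score"),
               vapply(poses[1:5], `[[`, numeric(1), "score"))

  expect_warning(got <- select_seed_poses(new_pose_set(poses[1:3], lig), 20),
                 "3 poses")
  expect_length(got, 3)

  rev_hook <- function(pl) -vapply(pl, `[[`, numeric(1), "score")
  rev5 <- select_seed_poses(ps, 5, scorer = "external_hook", hook = rev_hook)
  expect_equal(vapply(rev5, `[[`, numeric(1), "score"),
               vapply(poses[30:26], `[[`, numeric(1), "score"))

  expect_error(select_seed_poses(new_pose_set(list(), lig), 5), "empty")
})

test_that("IVES produces a pocket-relaxed ensemble with exact frozen residues", {
  cs <- challenge_fixture()
  smp <- proto_sampler()
  res <- run_ives(cs$receptor_dock, cs$ligand, cs$box, sampler = smp,
                  ives = ives_config(n_seeds = 3, shell_radius = 3.55),
                  mcfg = minimize_config(max_iters = 60))
  expect_lte(length(res$ensemble), 3)
  expect_gt(length(res$poses$poses), 0)
  rec <- cs$receptor_dock
  for (conf in res$ensemble) {
    prov <- attr(conf, "provenance")
    expect_true(is.list(prov) && !is.null(prov$seed_rank))
    # the conformation's frozen residues match the input receptor exactly
    expect_gt(length(prov$frozen), 0)
    ix <- unlist(rec$residues[prov$frozen], use.names = FALSE)
    expect_identical(conf$coords[ix, ], rec$coords[ix, ])
  }
  # every pose's provenance names its generating stage
  for (p in res$poses$poses) {
    expect_true(p$provenance$potential %in% c("normal", "soft"))
    expect_true(p$provenance$conformation_id %in% 0:3)
  }
})

test_that("IVES merged poses are invariant to ensemble processing order", {
  cs <- challenge_fixture()
  smp <- proto_sampler()
  a <- run_ives(cs$receptor_dock, cs$ligand, cs$box, sampler = smp,
                ives = ives_config(n_seeds = 3),
                mcfg = minimize_config(max_iters = 40))
  b <- run_ives(cs$receptor_dock, cs$ligand, cs$box, sampler = smp,
                ives = ives_config(n_seeds = 3),
                mcfg = minimize_config(max_iters = 40),
                .process_order = c(3, 1, 2))
  expect_equal(length(a$poses$poses), length(b$poses$poses))
  for (k in seq_along(a$poses$poses))
    expect_identical(a$poses$poses[[k]]$coords, b$poses$poses[[k]]$coords)
})

test_that("a second IVES iteration never loses ground", {
  cs <- challenge_fixture()
  smp <- proto_sampler()
  r1 <- run_ives(cs$receptor_dock, cs$ligand, cs$box, sampler = smp,
                 ives = ives_config(n_seeds = 2),
                 mcfg = minimize_config(max_iters = 40))
  r2 <- run_ives(cs$receptor_dock, cs$ligand, cs$box, sampler = smp,
                 ives = ives_config(n_seeds = 2, iterations = 2),
                 mcfg = minimize_config(max_iters = 40))
  m1 <- is_success(r1$poses, cs$reference, cs$ligand)$min_rmsd
  m2 <- is_success(r2$poses, cs$reference, cs$ligand)$min_rmsd
  expect_lte(m2, m1 + smp$cluster_cutoff)
  expect_lte(length(r2$ensemble), 2)
})

test_that("protocol outputs serialize to SDF with full provenance", {
  cs <- challenge_fixture()
  res <- run_glow(cs$receptor_dock, cs$ligand, cs$box,
                  sampler = proto_sampler())
  path <- tempfile(fileext = ".sdf")
  write_poses(res$poses, cs$ligand, path)
  back <- read_poses(path, cs$ligand)
  expect_length(back, length(res$poses$poses))
  expect_equal(back[[1]]$provenance$rank, 1)
})
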