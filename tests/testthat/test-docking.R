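# Rigid poses, toy scoring, dock rounds, clustering, symmetrization.

test_that("zero-magnitude perturbation is the identity and seeded draws
           are reproducible", {
  p <- random_pose()
  q <- perturb_pose(p, 0, 0, seed = 1)
  expect_equal(q$rotation, p$rotation, tolerance = 1e-12)
  expect_equal(q$translation, p$translation, tolerance = 1e-12)
  a <- perturb_pose(p, 3, 8, seed = 99)
  b <- perturb_pose(p, 3, 8, seed = 99)
  expect_identical(a, b)
})

test_that("perturbation translations are uniform in a ball of the stated
           radius", {
  set.seed(20)
  p <- rigid_pose()
  d <- replicate(10000, {
    q <- perturb_pose(p, 3, 0)
    sqrt(sum(q$translation^2))
  })
  expect_lte(max(d), 3)
  # mean radius of a uniform ball of radius R is 3R/4
  expect_equal(mean(d), 3 * 3 / 4, tolerance = 0.05)
})

test_that("poses compose and invert consistently", {
  p <- random_pose(); q <- random_pose()
  x <- matrix(rnorm(9), ncol = 3)
  expect_equal(apply_pose(apply_pose(x, p), q),
               apply_pose(x, compose_poses(q, p)), tolerance = 1e-10)
  expect_equal(apply_pose(apply_pose(x, p), invert_pose(p)), x,
               tolerance = 1e-10)
})

test_that("a distant ligand scores zero clash and zero contacts, overlap
           scores positive clash", {
  tc <- get_toy()
  far <- score_complex(tc$receptor, tc$ligand,
                       rigid_pose(diag(3), c(100, 0, 0)))
  expect_equal(far$clash_score, 0)
  expect_equal(far$contact_energy, 0)
  a <- structure_from_xyz(matrix(c(0, 0, 0), ncol = 3), chain = "A")
  b <- structure_from_xyz(matrix(c(0.2, 0, 0), ncol = 3), chain = "E")
  ov <- score_complex(a, b, rigid_pose())
  expect_gt(ov$clash_score, 0)
})

test_that("contact energy at the planted pose equals -0.1 times the
           exhaustive pair count", {
  tc <- get_toy()
  sm <- score_complex(tc$receptor, tc$ligand, tc$pose)
  rx <- coords(tc$receptor)
  lx <- apply_pose(coords(tc$ligand), tc$pose)
  rrad <- vdw_radius(tc$receptor$atom$element)
  lrad <- vdw_radius(tc$ligand$atom$element)
  count <- 0
  for (i in seq_len(nrow(rx))) {
    for (j in seq_len(nrow(lx))) {
      d <- sqrt(sum((rx[i, ] - lx[j, ])^2))
      if (d >= 0.8 * (rrad[i] + lrad[j]) && d <= 5) count <- count + 1
    }
  }
  expect_equal(sm$contact_energy, -0.1 * count, tolerance = 1e-9)
})

test_that("all score components are invariant under a global rigid motion", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 6, seed = 7)
  set.seed(21)
  pose <- perturb_pose(tc$pose, 2, 10)
  base <- score_complex(tc$receptor, tc$ligand, pose, rs)
  g <- random_pose()
  moved <- score_complex(apply_pose(tc$receptor, g), tc$ligand,
                         compose_poses(g, pose), rs)
  expect_equal(moved$clash_score, base$clash_score, tolerance = 1e-6)
  expect_equal(moved$contact_energy, base$contact_energy, tolerance = 1e-9)
  expect_equal(moved$restraint_score, base$restraint_score, tolerance = 1e-6)
})

test_that("dock_round returns n_keep models with gates off and respects
           gate semantics", {
  tc <- get_toy()
  scorer <- kda:::make_scorer(tc$receptor, tc$ligand)
  seed_model <- scorer(tc$pose)
  set.seed(22)
  out <- dock_round(scorer, list(seed_model), n_generate = 30,
                    max_trans = 1, max_rot = 3, restraint_cutoff = Inf,
                    n_keep = 30, gates = FALSE)
  expect_length(out, 30)
  dg <- vapply(out, `[[`, numeric(1), "dG")
  expect_equal(dg, sort(dg))

  # a seed violating one restraint cannot found a lineage at cutoff 0
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 4,
                        consistent = FALSE, seed = 8)
  scorer_rs <- kda:::make_scorer(tc$receptor, tc$ligand, rs)
  bad_seed <- scorer_rs(tc$pose)
  expect_gt(bad_seed$restraint_score, 0)
  set.seed(23)
  expect_error(
    dock_round(scorer_rs, list(bad_seed), n_generate = 40, max_trans = 0.2,
               max_rot = 1, restraint_cutoff = 0, n_keep = 10),
    "relaxing"
  )
})

test_that("relaxing the restraint gate never removes a passing model", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 8, seed = 9)
  scorer <- kda:::make_scorer(tc$receptor, tc$ligand, rs)
  seed_model <- scorer(tc$pose)
  run_gate <- function(cutoff) {
    set.seed(31) # identical children across calls
    dock_round(scorer, list(seed_model), n_generate = 100, max_trans = 3,
               max_rot = 15, restraint_cutoff = cutoff, n_keep = 100)
  }
  tight <- run_gate(50)
  loose <- run_gate(350)
  key <- function(m) kda:::pose_hash(m$pose)
  expect_true(all(vapply(tight, key, "") %in% vapply(loose, key, "")))
})

test_that("one dock round does not lose ground on the restraint score", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 12, seed = 10)
  scorer <- kda:::make_scorer(tc$receptor, tc$ligand, rs)
  improved <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    set.seed(400 + i)
    start <- perturb_pose(tc$pose, 3, 15)
    seed_model <- scorer(start)
    out <- dock_round(scorer, list(seed_model), n_generate = 150,
                      max_trans = 2, max_rot = 6, restraint_cutoff = Inf,
                      n_keep = 150, gates = FALSE)
    best_restraint <- min(vapply(out, `[[`, numeric(1), "restraint_score"))
    if (best_restraint <= seed_model$restraint_score + 1e-9) {
      improved <- improved + 1
    }
  }
  expect_gte(improved / n_rep, 0.95)
})

test_that("the protocol converges immediately when started at the planted
           pose with zero perturbation", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 6, seed = 12)
  ps <- run_protocol(
    tc$receptor, list(tc$ligand), rs, list(tc$pose),
    schedule = list(n_iter = 2, cutoff = c(350, 100), trans = c(0, 0),
                    rot = c(0, 0)),
    n_generate = 20, n_keep = 10, seed = 5
  )
  expect_true(ps$converged)
  expect_equal(ps$iterations, 2)
  expect_equal(ps$ensemble[[1]]$dG, score_complex(
    tc$receptor, tc$ligand, tc$pose, rs)$dG, tolerance = 1e-9)
})

test_that("the schedule ramps linearly from 350/3A/8deg to 100/1A/3deg", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 6, seed = 12)
  ps <- run_protocol(
    tc$receptor, list(tc$ligand), rs, list(tc$pose),
    n_generate = 30, n_keep = 10, seed = 5, max_iter = 7,
    convergence = 0 # force the full ramp to execute
  )
  expect_equal(ps$trace$cutoff[1], 350)
  expect_equal(ps$trace$max_trans[1], 3)
  expect_equal(ps$trace$max_rot[1], 8)
  n <- nrow(ps$trace)
  expect_equal(ps$trace$cutoff[n], 100)
  expect_equal(ps$trace$max_trans[n], 1)
  expect_equal(ps$trace$max_rot[n], 3)
  expect_true(all(diff(ps$trace$cutoff) <= 0))
  expect_true(all(diff(ps$trace$max_trans) <= 0))
})

test_that("the protocol trace is exactly reproducible given the seed", {
  tc <- get_toy()
  rs <- make_restraints(tc$receptor, tc$ligand, tc$pose, n = 8, seed = 13)
  starts <- ring_start_poses(tc$pose, n = 4, seed = 2)
  run <- function() run_protocol(tc$receptor, list(tc$ligand), rs, starts,
                                 n_generate = 80, n_keep = 20, seed = 77,
                                 max_iter = 3,
                                 schedule = list(n_iter = 3,
                                                 cutoff = c(350, 100),
                                                 trans = c(3, 1),
                                                 rot = c(8, 3)))
  expect_equal(run()$trace, run()$trace, tolerance = 1e-12)
})

test_that("greedy clustering separates pose families and collapses in the
           cutoff limit", {
  tc <- get_toy()
  scorer <- kda:::make_scorer(tc$receptor, tc$ligand)
  fam1 <- tc$pose
  fam2 <- compose_poses(rigid_pose(diag(3), c(20, 0, 0)), tc$pose)
  set.seed(24)
  models <- c(
    lapply(1:5, function(i) scorer(perturb_pose(fam1, 0.5, 2))),
    lapply(1:4, function(i) scorer(perturb_pose(fam2, 0.5, 2)))
  )
  cl <- cluster_models(models, n_best = 9, rmsd_cutoff = 5,
                       ligand = tc$ligand)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, numeric(1), "size"), c(5, 4))

  all_same <- lapply(1:4, function(i) scorer(fam1))
  expect_length(cluster_models(all_same, 4, 1, tc$ligand), 1)
  expect_length(cluster_models(models, 9, 1e6, tc$ligand), 1)
  expect_error(cluster_models(models, 9, -1, tc$ligand), "positive")
})

test_that("C2 symmetrization adds a 180-degree ligand copy once", {
  tc <- get_toy()
  cx <- merge_structures(tc$receptor, apply_pose(tc$ligand, tc$pose))
  # the snug planted pose sits at the soft-core limit, so the C2 copy
  # legitimately triggers the clash advisory
  sym <- suppressWarnings(symmetrize_4to2(cx, "E"))
  expect_equal(length(unique(sym$atom$chain)), 6)
  new_chain <- setdiff(unique(sym$atom$chain), unique(cx$atom$chain))
  expect_length(new_chain, 1)

  # the two copies are exactly 180 degrees apart about the axis
  e_idx <- sym$atom$chain == "E"
  f_idx <- sym$atom$chain == new_chain
  rot <- apply_pose(coords(sym)[e_idx, , drop = FALSE],
                    axis_rotation_pose(c(0, 0, 1), 180))
  expect_equal(rot, coords(sym)[f_idx, , drop = FALSE], tolerance = 1e-9,
               ignore_attr = TRUE)

  # centroid distances to the axis match (geometric oracle)
  ca_e <- coords(sym)[e_idx & sym$atom$name == "CA", ]
  ca_f <- coords(sym)[f_idx & sym$atom$name == "CA", ]
  expect_equal(sqrt(sum(colMeans(ca_e)[1:2]^2)),
               sqrt(sum(colMeans(ca_f)[1:2]^2)), tolerance = 1e-6)

  # applying twice is rejected as a duplicate
  expect_warning(sym2 <- symmetrize_4to2(sym, "E"), "already")
  expect_equal(n_atoms(sym2), n_atoms(sym))
})
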