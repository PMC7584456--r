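# Contact numbers, SASA/dSASA, hydrogen bonds, association test and the
# helical-rotation null model.

test_that("contact numbers honour the closed-ball cutoff and match an
           exhaustive oracle", {
  far <- two_column_complex(gap = 100)
  cp <- contact_number(far, "A", "B")
  expect_true(all(cp$contacts == 0))

  near <- two_column_complex(gap = 3.9)
  cp <- contact_number(near, "A", "B")
  expect_true(all(cp$contacts[cp$group == "a"] == 1))
  out <- contact_number(two_column_complex(gap = 4.1), "A", "B")
  expect_true(all(out$contacts == 0))
  expect_error(contact_number(near, "A", "A"), "disjoint")

  # toy interface vs O(N^2) oracle
  tc <- get_toy()
  cx <- merge_structures(tc$receptor, apply_pose(tc$ligand, tc$pose))
  prof <- contact_number(cx, c("A", "B", "C", "D"), "E")
  hv <- !cx$atom$is_hydrogen
  at <- cx$atom[hv, ]; xyz <- coords(cx)[hv, ]
  lig <- at$chain == "E"
  for (row in sample(which(prof$group == "b"), 4)) {
    ridx <- which(lig & at$resid == prof$resid[row])
    partner <- which(!lig)
    cnt <- 0
    for (j in partner) {
      dmin <- min(sqrt(rowSums(sweep(xyz[ridx, , drop = FALSE], 2,
                                     xyz[j, ])^2)))
      if (dmin <= 4) cnt <- cnt + 1
    }
    expect_equal(prof$contacts[row], cnt)
  }
})

test_that("contact relation is symmetric at the pair level", {
  tc <- get_toy()
  cx <- merge_structures(tc$receptor, apply_pose(tc$ligand, tc$pose))
  hv <- !cx$atom$is_hydrogen
  at <- cx$atom[hv, ]; xyz <- coords(cx)[hv, ]
  a_res <- unique(at$resid[at$chain == "A"])
  e_res <- unique(at$resid[at$chain == "E"])
  for (i in sample(a_res, 3)) {
    for (j in sample(e_res, 3)) {
      ii <- which(at$chain == "A" & at$resid == i)
      jj <- which(at$chain == "E" & at$resid == j)
      d <- kda:::pairdist(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      expect_identical(any(d <= 4), any(t(d) <= 4))
    }
  }
})

test_that("single-atom SASA matches the analytic sphere and distant atoms
           are additive", {
  s1 <- structure_from_xyz(matrix(c(0, 0, 0), ncol = 3))
  a1 <- sasa(s1)$atom
  expect_equal(unname(a1), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  s2 <- structure_from_xyz(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(sum(sasa(s2)$atom), 2 * 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
})

test_that("two-sphere SASA matches the closed-form buried-cap area", {
  # equal spheres of extended radius R at centre distance d bury a cap
  # of height h = R - d/2 on each
  d <- 2.5
  R <- 1.7 + 1.4
  s <- structure_from_xyz(rbind(c(0, 0, 0), c(d, 0, 0)))
  got <- sasa(s, n_points = 4000)$atom
  expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_equal(unname(got[1]), expected, tolerance = 0.01 * expected)
  expect_equal(unname(got[2]), expected, tolerance = 0.01 * expected)
})

test_that("complexation can only lower SASA, per residue and in total", {
  tc <- get_toy()
  lig <- apply_pose(tc$ligand, tc$pose)
  cx <- merge_structures(tc$receptor, lig)
  free <- sasa(lig)$residue
  bound <- sasa(cx)$residue
  bound <- bound[bound$chain == "E", ]
  m <- match(paste(free$chain, free$resid), paste(bound$chain, bound$resid))
  expect_true(all(bound$sasa[m] <= free$sasa + 1e-6))
})

test_that("dSASA profile is zero for identical states and flags the wall-
           facing side of a helix", {
  tc <- get_toy()
  lig <- apply_pose(tc$ligand, tc$pose)
  same <- delta_sasa_interface(lig, lig, "E")
  expect_true(all(same$dsasa_pct == 0))
  expect_false(any(same$interface))

  cx <- merge_structures(tc$receptor, lig)
  prof <- delta_sasa_interface(lig, cx, "E")
  expect_true(any(prof$interface))
  # residues whose CB points toward the channel axis must be the buried
  # ones; the most exposed (outward) residue must not be flagged
  ca <- coords(lig)[lig$atom$name == "CA", ]
  cb <- coords(lig)[lig$atom$name == "CB", ]
  outward <- rowSums((cb[, 1:2] - ca[, 1:2]) * ca[, 1:2]) /
    sqrt(rowSums(ca[, 1:2]^2))
  expect_gt(prof$dsasa_pct[which.min(outward)],
            prof$dsasa_pct[which.max(outward)])
})

test_that("a fully occluded residue reports 100% dSASA", {
  lone <- structure_from_xyz(matrix(c(0, 0, 0), ncol = 3), chain = "E")
  shell_pts <- kda:::fibonacci_sphere(200) * 3.5
  shell <- structure_from_xyz(shell_pts, chain = "A")
  cx <- merge_structures(shell, lone)
  prof <- delta_sasa_interface(lone, cx, "E", n_points = 500)
  expect_equal(prof$dsasa_pct, 100, tolerance = 1e-6)
})

test_that("hydrogen bonds follow the distance and angle criteria", {
  hb_fixture <- function(d, with_h = FALSE, h_angle_deg = 180) {
    atom <- data.frame(
      serial = 1:2, name = c("OG1", "OH"), element = "O",
      resname = c("THR", "TYR"), chain = c("A", "B"), resid = c(1, 1),
      is_hydrogen = FALSE, stringsAsFactors = FALSE
    )
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    if (with_h) {
      atom <- rbind(atom, data.frame(
        serial = 3, name = "HG1", element = "H", resname = "THR",
        chain = "A", resid = 1, is_hydrogen = TRUE,
        stringsAsFactors = FALSE))
      # hydrogen 1 A from the donor; angle D-H...A set by h_angle_deg
      th <- (180 - h_angle_deg) * pi / 180
      xyz <- rbind(xyz, c(cos(th), sin(th), 0))
    }
    kda:::new_structure(atom, list(xyz))
  }
  expect_equal(nrow(detect_hbonds(hb_fixture(2.8), "A", "B")), 1)
  expect_equal(nrow(detect_hbonds(hb_fixture(4.0), "A", "B")), 0)
  good <- detect_hbonds(hb_fixture(2.8, with_h = TRUE, h_angle_deg = 170),
                        "A", "B")
  expect_equal(nrow(good), 1)
  expect_equal(good$angle, 170, tolerance = 1)
  bad <- detect_hbonds(hb_fixture(2.8, with_h = TRUE, h_angle_deg = 90),
                       "A", "B")
  expect_equal(nrow(bad), 0)
})

test_that("an idealized Tyr-OH to Thr-OG1 contact yields exactly one
           interface hydrogen bond", {
  atom <- data.frame(
    serial = 1:4,
    name = c("OH", "CZ", "OG1", "CB"),
    element = c("O", "C", "O", "C"),
    resname = c("TYR", "TYR", "THR", "THR"),
    chain = c("A", "A", "B", "B"),
    resid = c(267, 267, 58, 58),
    is_hydrogen = FALSE, stringsAsFactors = FALSE
  )
  xyz <- rbind(c(0, 0, 0), c(-1.4, 0, 0), c(2.7, 0, 0), c(4.1, 1.0, 0))
  s <- kda:::new_structure(atom, list(xyz))
  hb <- detect_hbonds(s, "A", "B")
  expect_equal(nrow(hb), 1)
  expect_match(hb$donor, "OH|OG1")
})

test_that("the chi-squared association test reproduces hand-computed
           degenerate cases and swaps labels symmetrically", {
  # perfectly proportional table -> no association
  iface <- rep(c(TRUE, FALSE), each = 10)
  impact <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(5, 5, 5, 5))
  res <- chi2_association(iface, impact)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  set.seed(30)
  a <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  b <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  r1 <- chi2_association(a, b)
  r2 <- chi2_association(!a, !b) # simultaneous row+column swap
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-12)

  expect_error(chi2_association(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "margin")
})

test_that("asymptotic chi-squared p-values agree with a permutation test
           at moderate n", {
  set.seed(31)
  n <- 60
  iface <- sample(c(TRUE, FALSE), n, replace = TRUE)
  impact <- iface
  flip <- sample(n, 20)
  impact[flip] <- !impact[flip]
  res <- chi2_association(iface, impact)
  stat_of <- function(x, y) {
    suppressWarnings(stats::chisq.test(table(x, y), correct = FALSE))$statistic
  }
  obs <- stat_of(iface, impact)
  perm <- replicate(4000, stat_of(iface, sample(impact)))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_equal(res$p, p_perm, tolerance = 0.05)
})

test_that("the rotation null scan is the identity analysis at 0 degrees,
           360-periodic, and prefers the true orientation", {
  tc <- get_toy()
  lig <- apply_pose(tc$ligand, tc$pose)
  cx <- merge_structures(tc$receptor, lig)
  prof0 <- delta_sasa_interface(lig, cx, "E", n_points = 480)

  # impact flags built from the true burial pattern, two discordant
  # positions, so angle 0 should show the strongest association
  impact <- impact_table(
    resid = prof0$resid,
    delta_v12 = ifelse(prof0$interface, 25, 2), dataset = "cho"
  )
  impact$impact[c(2, 9)] <- !impact$impact[c(2, 9)]

  scan <- rotation_null_scan(cx, "E", impact, angle_step = 90,
                             n_points = 480)
  expect_equal(scan$angle, c(0, 90, 180, 270))
  direct <- chi2_association(
    prof0$interface[match(impact$resid, prof0$resid)], impact$impact)
  expect_equal(scan$chisq[1], direct$chisq, tolerance = 1e-6)

  # full turn equals identity
  lig_idx <- which(cx$atom$chain == "E")
  ax <- kda:::helical_axis(cx, "E")
  cx360 <- cx
  cx360$models[[1]][lig_idx, ] <- apply_pose(
    coords(cx)[lig_idx, , drop = FALSE],
    axis_rotation_pose(ax$axis, 360, ax$center))
  prof360 <- delta_sasa_interface(lig, cx360, "E", n_points = 480)
  expect_equal(prof360$dsasa_pct, prof0$dsasa_pct, tolerance = 1e-6)

  # association is strongest at the as-modelled orientation
  expect_lt(scan$p[1], min(scan$p[-1], na.rm = TRUE))
})
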