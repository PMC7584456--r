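# Synthetic-data generators with exact ground truth: a C4-symmetric toy
# helical channel with a single-TM accessory helix at a known planted
# pose, restraint sets consistent or inconsistent with that pose,
# trajectories with scheduled contact persistence and block-correlated
# fluctuations, and Boltzmann-shaped G(V) datasets.
#
# The toy structures are poly-Ala (backbone N/CA/C/O plus CB): every
# analysis implemented here operates on heavy-atom geometry, and the
# CB is enough to carry an orientation-dependent burial pattern.

# Ideal alpha-helix along +z: rise 1.5 A/residue, twist 100 deg/residue.
# Cylindrical offsets (radius, phase offset deg, z offset) per atom.
.helix_atoms <- list(
  N  = c(1.50, -28, -0.90),
  CA = c(2.30,   0,  0.00),
  C  = c(1.60,  27,  0.60),
  O  = c(2.00,  23,  1.90),
  CB = c(3.30,  -5, -0.30)
)
.helix_elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

# Atom table + coordinates for one ideal poly-Ala helix whose axis is
# the z-axis through the origin, z-centred.
ideal_helix <- function(n_res, chain, start_resid = 1) {
  rows <- list(); xyz <- list()
  zmid <- (n_res + 1) / 2 * 1.5
  for (i in seq_len(n_res)) {
    phase <- (i - 1) * 100
    for (nm in names(.helix_atoms)) {
      p <- .helix_atoms[[nm]]
      ang <- (phase + p[2]) * pi / 180
      rows[[length(rows) + 1]] <- data.frame(
        serial = 0L, name = nm, element = .helix_elements[[nm]],
        resname = "ALA", chain = chain, resid = start_resid + i - 1,
        is_hydrogen = FALSE, stringsAsFactors = FALSE
      )
      xyz[[length(xyz) + 1]] <- c(p[1] * cos(ang), p[1] * sin(ang),
                                  i * 1.5 + p[3] - zmid)
    }
  }
  atom <- do.call(rbind, rows)
  atom$serial <- seq_len(nrow(atom))
  m <- do.call(rbind, xyz)
  colnames(m) <- c("x", "y", "z")
  new_structure(atom, list(m))
}

place_helix <- function(h, radius, angle_deg) {
  th <- angle_deg * pi / 180
  apply_pose(h, rigid_pose(diag(3),
                           c(radius * cos(th), radius * sin(th), 0)))
}

#' Build the C4 toy channel and its accessory helix
#'
#' The receptor is a tetramer (chains A-D, related by exact 90 degree
#' rotations about z) of ideal poly-Ala helices: an inner pore-lining
#' ring sized so the pore-radius profile plateaus near `pore_radius`,
#' and an outer ring offset in angle, which creates a cleft between
#' adjacent subunits analogous to the VSD-PD cleft that hosts the
#' accessory subunit. The ligand helix (chain E) is returned in its
#' canonical input frame (axis = z, centred at the origin) together
#' with the planted `RigidPose` that places it in the cleft at
#' van-der-Waals contact with the receptor.
#'
#' @param n_subunits number of receptor subunits (4; C4 symmetry).
#' @param helix_len residues per receptor helix (default 18).
#' @param pore_radius target pore radius (Angstrom, default 3.5).
#' @param ligand_len ligand helix length (default 16).
#' @param cleft_angle angular position of the ligand cleft (degrees,
#'   default 45, a groove between two outer helices backed by an inner
#'   pore-lining helix).
#' @return list with `receptor`, `ligand` (canonical frame), `pose`
#'   (planted `RigidPose`) and `spec` (the parameters used).
#' @export
make_toy_complex <- function(n_subunits = 4, helix_len = 18,
                             pore_radius = 3.5, ligand_len = 16,
                             cleft_angle = 45) {
  # innermost approach of a helix placed at axis distance R1 is
  # R1 - max(atom radius + vdW): CB ring at 3.3 + C radius 1.70
  r_inner <- pore_radius + 3.3 + 1.7
  if (r_inner <= 4) stop("pore radius too small for the helix packing")
  r_outer <- r_inner + 4.0
  chains <- LETTERS[seq_len(n_subunits)]
  # subunit 1: two pore-lining helices (0 and 45 deg) and two outer
  # helices interleaved at 22.5 and 67.5 deg; the two rings overlap
  # radially so the channel wall is dense, and the surface grooves
  # between adjacent outer helices (centred every 45 deg) are the only
  # pockets that can host the ligand. Remaining subunits are exact
  # rotated copies (the receptor is C4-symmetric to machine precision).
  sub1 <- Reduce(merge_structures_samechain, list(
    place_helix(ideal_helix(helix_len, chains[1], 1), r_inner, 0),
    place_helix(ideal_helix(helix_len, chains[1], 21), r_inner, 45),
    place_helix(ideal_helix(helix_len, chains[1], 41), r_outer, 22.5),
    place_helix(ideal_helix(helix_len, chains[1], 61), r_outer, 67.5)
  ))
  parts <- list(sub1)
  for (k in seq.int(2, n_subunits)) {
    base <- (k - 1) * 360 / n_subunits
    sk <- apply_pose(sub1, axis_rotation_pose(c(0, 0, 1), base))
    sk$atom$chain <- chains[k]
    parts[[k]] <- sk
  }
  receptor <- Reduce(merge_structures_samechain, parts)
  receptor$atom$serial <- seq_len(nrow(receptor$atom))

  ligand <- ideal_helix(ligand_len, "E", 1)
  # plant the ligand at the bottom of its groove: radial scan for the
  # lowest-energy insertion depth, then a local rigid-body relaxation,
  # so the planted pose is a genuine optimum of the toy energy (the
  # generator's contract is that the planted pose out-scores decoys)
  scorer <- make_scorer(receptor, ligand)
  th <- cleft_angle * pi / 180
  dir <- c(cos(th), sin(th), 0)
  radii <- seq(r_outer + 12, r_inner + 2, by = -0.1)
  dg <- vapply(radii, function(r)
    scorer(rigid_pose(diag(3), dir * r))$dG, numeric(1))
  p0 <- rigid_pose(diag(3), dir * radii[which.min(dg)])
  pose_from_par <- function(x) {
    R <- rotation_matrix(c(1, 0, 0), x[4]) %*%
      rotation_matrix(c(0, 1, 0), x[5]) %*%
      rotation_matrix(c(0, 0, 1), x[6])
    rigid_pose(R %*% p0$rotation, p0$translation + x[1:3])
  }
  opt <- stats::optim(rep(0, 6), function(x) scorer(pose_from_par(x))$dG,
                      method = "Nelder-Mead",
                      control = list(maxit = 1500, reltol = 1e-9))
  opt <- stats::optim(opt$par, function(x) scorer(pose_from_par(x))$dG,
                      method = "Nelder-Mead",
                      control = list(maxit = 1500, reltol = 1e-9))
  pose <- pose_from_par(opt$par)
  radius <- sqrt(sum(pose$translation[1:2]^2))
  list(
    receptor = receptor, ligand = ligand, pose = pose,
    spec = list(n_subunits = n_subunits, helix_len = helix_len,
                pore_radius = pore_radius, ligand_len = ligand_len,
                cleft_angle = cleft_angle, ligand_radius = radius)
  )
}

# merge that tolerates equal chain ids (within-receptor assembly).
merge_structures_samechain <- function(a, b) {
  atom <- rbind(a$atom, b$atom)
  atom$serial <- seq_len(nrow(atom))
  new_structure(atom, list(rbind(coords(a), coords(b))), a$metadata)
}

#' Coarse starting poses encircling the channel
#'
#' Rotates a reference placement about the channel axis to `n` evenly
#' spaced angles and adds a seeded random perturbation to each -- the
#' synthetic analogue of placing the accessory helix "near the
#' transmembrane region" before docking, without telling the protocol
#' which cleft is correct.
#'
#' @param pose reference `RigidPose` (e.g. the planted pose).
#' @param n number of poses (default 8).
#' @param axis channel axis.
#' @param jitter_trans,jitter_rot perturbation magnitudes (A / deg).
#' @param seed integer seed.
#' @return list of `RigidPose`.
#' @export
ring_start_poses <- function(pose, n = 8, axis = c(0, 0, 1),
                             jitter_trans = 2, jitter_rot = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ang <- (i - 1) * 360 / n
    p <- compose_poses(axis_rotation_pose(axis, ang), pose)
    perturb_pose(p, jitter_trans, jitter_rot)
  })
}

#' Generate restraints consistent or inconsistent with a planted pose
#'
#' Samples `n` receptor-ligand Calpha pairs. Consistent restraints have
#' a Calpha-Calpha distance at the planted pose of at most
#' `bound - 2` A (so the planted pose scores zero penalty);
#' inconsistent ones violate their bound by at least 3 A. Consistent
#' restraints are stratified across the ligand residues (each sampled
#' ligand residue contributes one restraint) and spread round-robin
#' over receptor segments (consecutive 20-residue blocks per chain,
#' i.e. one toy helix), mirroring experimental crosslink sets that span
#' the transmembrane helix end to end and touch several channel
#' helices from different subunits.
#'
#' @param receptor,ligand `Structure` objects (ligand in input frame).
#' @param pose planted `RigidPose`.
#' @param n number of restraints (default 12).
#' @param consistent sample satisfied (`TRUE`) or violated pairs.
#' @param kind restraint kind (sets the default bound: 12 or 15 A).
#' @param state state tag.
#' @param seed integer seed.
#' @return a `RestraintSet`.
#' @export
make_restraints <- function(receptor, ligand, pose, n = 12,
                            consistent = TRUE, kind = "disulfide",
                            state = "both", seed = 1) {
  bound <- default_bound(kind)
  rca <- which(receptor$atom$name == "CA")
  lca <- which(ligand$atom$name == "CA")
  d <- pairdist(coords(receptor)[rca, , drop = FALSE],
                apply_pose(coords(ligand)[lca, , drop = FALSE], pose))
  eligible <- if (consistent) which(d <= bound - 2, arr.ind = TRUE)
  else which(d >= bound + 3, arr.ind = TRUE)
  if (nrow(eligible) < n) {
    stop("only ", nrow(eligible), " qualifying Calpha pairs; asked for ", n)
  }
  set.seed(seed)
  if (consistent) {
    # stratify over ligand residues so restraints span the whole helix,
    # and round-robin over receptor 20-residue segments so several
    # receptor structural elements are restrained
    by_lig <- split(seq_len(nrow(eligible)), eligible[, 2])
    if (length(by_lig) < n) {
      stop("only ", length(by_lig), " ligand residues with qualifying ",
           "partners; asked for ", n)
    }
    seg <- paste(receptor$atom$chain[rca],
                 (receptor$atom$resid[rca] - 1) %/% 20)
    lig_pick <- sample(names(by_lig), n)
    used <- character(0)
    rows <- integer(0)
    for (lr in lig_pick) {
      cand <- by_lig[[lr]]
      hx <- seg[eligible[cand, 1]]
      tally <- vapply(hx, function(h) sum(used == h), numeric(1))
      cand <- cand[tally == min(tally)]
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      rows <- c(rows, pick)
      used <- c(used, seg[eligible[pick, 1]])
    }
    take <- eligible[rows, , drop = FALSE]
  } else {
    take <- eligible[sample.int(nrow(eligible), n), , drop = FALSE]
  }
  df <- data.frame(
    chain_a = receptor$atom$chain[rca[take[, 1]]],
    res_a = receptor$atom$resid[rca[take[, 1]]],
    chain_b = ligand$atom$chain[lca[take[, 2]]],
    res_b = ligand$atom$resid[lca[take[, 2]]],
    kind = kind, state = state, bound = bound, source = "synthetic",
    stringsAsFactors = FALSE
  )
  new_restraint_set(df)
}

#' Generate a trajectory with scheduled contacts and block correlations
#'
#' Frames are the base structure plus per-residue rigid Gaussian
#' displacements built from a factor model: residues of one block share
#' a common 3-vector factor with loading `sqrt(rho)` plus independent
#' noise with loading `sqrt(1-rho)`, giving an exact target
#' displacement correlation `rho` within blocks and 0 across blocks.
#' Scheduled contact pairs toggle the second residue between an "on"
#' separation (minimal heavy-atom distance `on_dist`) and an "off"
#' separation `off_dist` in exactly `round(persistence * n_frames)`
#' seeded frames; scheduled residues receive no noise so the realised
#' persistence equals the schedule exactly.
#'
#' @param base a `Structure`.
#' @param n_frames number of frames.
#' @param blocks list of residue-label vectors (`"chain|resid"`) or
#'   residue indices defining correlation blocks.
#' @param rho target within-block displacement correlation (-1, 1).
#' @param sigma per-coordinate fluctuation amplitude (Angstrom).
#' @param contact_schedule data frame `chain_a, res_a, chain_b, res_b,
#'   persistence` (+ optional `on_dist`, `off_dist`).
#' @param timestep ns per frame (metadata).
#' @param seed integer seed.
#' @return a `Trajectory`; ground truth in `attr(, "truth")`.
#' @export
make_trajectory <- function(base, n_frames = 200, blocks = NULL,
                            rho = 0.8, sigma = 0.3,
                            contact_schedule = NULL, timestep = 1,
                            seed = 1) {
  stopifnot(n_frames >= 1, rho > -1, rho < 1)
  set.seed(seed)
  rb <- residue_blocks(base)
  nres <- length(rb$labels)
  res_of_atom <- rep(NA_integer_, n_atoms(base))
  for (r in seq_len(nres)) res_of_atom[rb$idx[[r]]] <- r

  block_of <- rep(0L, nres)
  if (!is.null(blocks)) {
    for (b in seq_along(blocks)) {
      sel <- blocks[[b]]
      idx <- if (is.numeric(sel)) sel else match(sel, rb$labels)
      if (anyNA(idx)) stop("unknown residue in block ", b)
      block_of[idx] <- b
    }
  }
  sched_res <- integer(0)
  sched <- NULL
  if (!is.null(contact_schedule)) {
    sched <- contact_schedule
    if (is.null(sched$on_dist)) sched$on_dist <- 3.5
    if (is.null(sched$off_dist)) sched$off_dist <- 8
    sched$ia <- match(paste(sched$chain_a, sched$res_a, sep = "|"), rb$labels)
    sched$ib <- match(paste(sched$chain_b, sched$res_b, sep = "|"), rb$labels)
    if (anyNA(sched$ia) || anyNA(sched$ib)) {
      stop("contact schedule references unknown residues")
    }
    if (anyDuplicated(c(sched$ia, sched$ib))) {
      stop("each residue may appear in at most one scheduled pair")
    }
    sched$n_on <- round(sched$persistence * n_frames)
    sched$on_frames <- lapply(sched$n_on, function(k)
      sort(sample.int(n_frames, k)))
    sched_res <- c(sched$ia, sched$ib)
  }

  base_xyz <- coords(base)
  nblocks <- if (is.null(blocks)) 0 else length(blocks)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base_xyz
    factors <- if (nblocks) matrix(stats::rnorm(3 * nblocks), nblocks, 3)
    for (r in seq_len(nres)) {
      if (r %in% sched_res) next
      e <- stats::rnorm(3)
      disp <- if (block_of[r] > 0) {
        sigma * (sqrt(rho) * factors[block_of[r], ] + sqrt(1 - rho) * e)
      } else {
        sigma * e
      }
      xyz[rb$idx[[r]], ] <- sweep(xyz[rb$idx[[r]], , drop = FALSE], 2,
                                  disp, "+")
    }
    if (!is.null(sched)) {
      for (p in seq_len(nrow(sched))) {
        ia <- rb$idx[[sched$ia[p]]]; ib <- rb$idx[[sched$ib[p]]]
        d0 <- min(pairdist(base_xyz[ia, , drop = FALSE],
                           base_xyz[ib, , drop = FALSE]))
        ca <- colMeans(base_xyz[ia, , drop = FALSE])
        cb <- colMeans(base_xyz[ib, , drop = FALSE])
        u <- (cb - ca) / sqrt(sum((cb - ca)^2))
        target <- if (f %in% sched$on_frames[[p]]) sched$on_dist[p]
        else sched$off_dist[p]
        xyz[ib, ] <- sweep(xyz[ib, , drop = FALSE], 2,
                           u * (target - d0), "+")
      }
    }
    frames[[f]] <- xyz
  }
  t <- new_trajectory(base, frames, timestep)
  attr(t, "truth") <- list(
    blocks = blocks, rho = rho, sigma = sigma,
    schedule = if (is.null(sched)) NULL else data.frame(
      chain_a = sched$chain_a, res_a = sched$res_a,
      chain_b = sched$chain_b, res_b = sched$res_b,
      persistence = sched$n_on / n_frames
    )
  )
  t
}

#' Generate Boltzmann-shaped G(V) data with noise
#'
#' Per-cell activation curves from the three-parameter Boltzmann form
#' plus iid Gaussian noise on the normalized current.
#'
#' @param genotypes data frame with columns `genotype, v12, k, bottom`.
#' @param voltages test potentials (mV), default -80..60 in 10 mV steps.
#' @param n_cells cells per genotype (default 14).
#' @param sigma noise standard deviation (default 0.03).
#' @param seed integer seed.
#' @return `GVData` data frame (cell, genotype, voltage, current);
#'   ground truth in `attr(, "truth")`.
#' @export
make_gv_dataset <- function(genotypes, voltages = seq(-80, 60, by = 10),
                            n_cells = 14, sigma = 0.03, seed = 1) {
  set.seed(seed)
  out <- list()
  for (g in seq_len(nrow(genotypes))) {
    for (cell in seq_len(n_cells)) {
      y <- boltzmann_gv(voltages, genotypes$v12[g], genotypes$k[g],
                        genotypes$bottom[g]) +
        stats::rnorm(length(voltages), 0, sigma)
      out[[length(out) + 1]] <- data.frame(
        cell = paste0(genotypes$genotype[g], "_", cell),
        genotype = genotypes$genotype[g],
        voltage = voltages, current = y, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, out)
  attr(df, "truth") <- genotypes
  df
}
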