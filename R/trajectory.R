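# Trajectory container and per-frame analytics: RMSD series, contact
# persistence and the residue displacement correlation matrix that
# feeds the dynamical network.

#' Construct a Trajectory
#' @param topology a single-model `Structure` describing the atoms.
#' @param frames list of n_atoms x 3 coordinate matrices (>= 1).
#' @param timestep time per frame (ns, metadata only).
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, timestep = 1) {
  stopifnot(inherits(topology, "Structure"), length(frames) >= 1)
  for (f in frames) stopifnot(nrow(f) == n_atoms(topology), ncol(f) == 3)
  structure(list(topology = topology, frames = frames, timestep = timestep),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s) x %d atoms, dt = %g ns\n",
              length(x$frames), n_atoms(x$topology), x$timestep))
  invisible(x)
}

#' Number of frames
#' @param t a `Trajectory`.
#' @return integer.
#' @export
n_frames <- function(t) length(t$frames)

#' Load a trajectory from multi-model PDB or DCD
#'
#' A multi-model PDB is self-describing; a DCD needs `topology_path`
#' pointing to a matching PDB. `frame_range` selects frames before
#' `stride` subsampling; `last_frac` keeps the trailing fraction of the
#' trajectory (e.g. 0.8 to analyse the last 80% of frames, the package
#' analogue of analysing the last 400 ns of a 450 ns run).
#'
#' @param path coordinate file (`.pdb` or `.dcd`).
#' @param topology_path PDB topology (required for DCD).
#' @param stride keep every `stride`-th frame.
#' @param frame_range integer c(first, last), applied before striding.
#' @param last_frac trailing fraction of frames to keep (overrides
#'   `frame_range`).
#' @param timestep ns per frame in the input.
#' @return a `Trajectory`.
#' @export
load_trajectory <- function(path, topology_path = NULL, stride = 1,
                            frame_range = NULL, last_frac = NULL,
                            timestep = 1) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    if (is.null(topology_path)) stop("DCD input requires topology_path")
    topo <- read_structure(topology_path)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3 * n_atoms(topo)) {
      stop("atom-count mismatch: DCD has ", ncol(xyz) / 3,
           " atoms, topology has ", n_atoms(topo))
    }
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  } else {
    s <- read_structure(path)
    topo <- new_structure(s$atom, s$models[1], s$metadata)
    frames <- s$models
  }
  n <- length(frames)
  if (!is.null(last_frac)) {
    frame_range <- c(n - floor(last_frac * n) + 1, n)
  }
  if (!is.null(frame_range)) {
    frames <- frames[seq(max(1, frame_range[1]), min(n, frame_range[2]))]
  }
  frames <- frames[seq(1, length(frames), by = stride)]
  new_trajectory(topo, frames, timestep * stride)
}

#' Write a trajectory as multi-model PDB
#' @param t a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(t, path) {
  s <- new_structure(t$topology$atom, t$frames, t$topology$metadata)
  write_structure(s, path)
}

#' Per-frame RMSD to a reference after superposition
#'
#' Each frame is Kabsch-superposed onto the reference over `selection`
#' and the post-fit RMSD over the same selection is returned.
#'
#' @param t a `Trajectory`.
#' @param reference a `Structure` (defaults to the topology itself).
#' @param selection [select_atoms()] string (default all CA atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(t, reference = NULL, selection = "*:*:CA") {
  reference <- reference %||% t$topology
  ti <- which(select_atoms(t$topology, selection))
  ri <- which(select_atoms(reference, selection))
  tk <- atom_key(t$topology$atom[ti, ])
  rk <- atom_key(reference$atom[ri, ])
  common <- intersect(tk, rk)
  if (length(common) < 3) stop("selection pairs fewer than 3 atoms")
  ti <- ti[match(common, tk)]
  Q <- coords(reference)[ri[match(common, rk)], , drop = FALSE]
  vapply(t$frames, function(f) {
    kabsch_fit(f[ti, , drop = FALSE], Q)$rmsd
  }, numeric(1))
}

# Residue index blocks of heavy atoms for fast min-distance work.
residue_blocks <- function(s) {
  hv <- which(!s$atom$is_hydrogen)
  key <- res_key(s$atom[hv, , drop = FALSE])
  labs <- unique(key)
  list(
    idx = split(hv, factor(key, levels = labs)),
    labels = labs,
    chain = s$atom$chain[hv][!duplicated(key)],
    resid = s$atom$resid[hv][!duplicated(key)]
  )
}

#' Contact persistence over a trajectory
#'
#' Fraction of frames in which the minimal heavy-atom distance of a
#' residue pair is at most `cutoff` (default 4.5 A). `pairs` is a data
#' frame with columns `chain_a, res_a, chain_b, res_b`; when omitted,
#' all inter-chain-group pairs between `group_a` and `group_b` are
#' evaluated.
#'
#' @param t a `Trajectory`.
#' @param pairs residue-pair data frame, or `NULL`.
#' @param group_a,group_b chain sets used when `pairs` is `NULL`.
#' @param cutoff distance cutoff (Angstrom).
#' @return data frame of pairs with a `persistence` column in \[0, 1\].
#' @export
contact_persistence <- function(t, pairs = NULL, group_a = NULL,
                                group_b = NULL, cutoff = 4.5) {
  topo <- t$topology
  blocks <- residue_blocks(topo)
  if (is.null(pairs)) {
    stopifnot(!is.null(group_a), !is.null(group_b))
    ia <- which(blocks$chain %in% group_a)
    ib <- which(blocks$chain %in% group_b)
    pairs <- expand.grid(a = ia, b = ib)
    pairs <- data.frame(
      chain_a = blocks$chain[pairs$a], res_a = blocks$resid[pairs$a],
      chain_b = blocks$chain[pairs$b], res_b = blocks$resid[pairs$b]
    )
  }
  ka <- match(paste(pairs$chain_a, pairs$res_a, sep = "|"), blocks$labels)
  kb <- match(paste(pairs$chain_b, pairs$res_b, sep = "|"), blocks$labels)
  if (anyNA(ka) || anyNA(kb)) stop("pair references unknown residue")
  hits <- matrix(0, nrow(pairs), length(t$frames))
  for (f in seq_along(t$frames)) {
    xyz <- t$frames[[f]]
    for (p in seq_len(nrow(pairs))) {
      d <- min(pairdist(xyz[blocks$idx[[ka[p]]], , drop = FALSE],
                        xyz[blocks$idx[[kb[p]]], , drop = FALSE]))
      hits[p, f] <- d <= cutoff
    }
  }
  pairs$persistence <- rowMeans(hits)
  pairs
}

#' Residue displacement correlation matrix
#'
#' Frames are aligned by a two-pass procedure (fit to the first frame,
#' average, refit to the mean), then the normalised covariance of the
#' Calpha displacement vectors is computed:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`. Zero-variance nodes
#' get a zero row/column with a warning.
#'
#' @param t a `Trajectory` with at least 3 frames.
#' @param selection [select_atoms()] string (default CA atoms).
#' @param fit_selection selection used for the frame superposition
#'   (defaults to `selection`); aligning on a stable core region avoids
#'   leaking large concerted motions into the rigid-body fit.
#' @return symmetric matrix with entries in \[-1, 1\], dimnames
#'   `chain|resid`.
#' @export
correlation_matrix <- function(t, selection = "*:*:CA",
                               fit_selection = selection) {
  if (n_frames(t) < 3) stop("need at least 3 frames")
  idx <- which(select_atoms(t$topology, selection))
  fit_idx <- which(select_atoms(t$topology, fit_selection))
  if (length(idx) < 2) stop("selection must cover at least 2 atoms")
  if (length(fit_idx) < 3) stop("fit selection must cover at least 3 atoms")
  align_to <- function(f, ref_fit) {
    fit <- kabsch_fit(f[fit_idx, , drop = FALSE], ref_fit)
    sweep(tcrossprod(f[idx, , drop = FALSE], fit$rotation), 2,
          fit$translation, "+")
  }
  align_fit <- function(f, ref_fit) {
    fit <- kabsch_fit(f[fit_idx, , drop = FALSE], ref_fit)
    sweep(tcrossprod(f[fit_idx, , drop = FALSE], fit$rotation), 2,
          fit$translation, "+")
  }
  ref <- t$frames[[1]][fit_idx, , drop = FALSE]
  mean_fit <- Reduce(`+`, lapply(t$frames, align_fit, ref_fit = ref)) /
    length(t$frames)
  aligned <- lapply(t$frames, align_to, ref_fit = mean_fit)
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  n <- length(idx)
  F <- length(aligned)
  disp <- array(0, c(F, n, 3))
  for (f in seq_len(F)) disp[f, , ] <- aligned[[f]] - mean_xyz
  cov_ij <- matrix(0, n, n)
  for (k in 1:3) cov_ij <- cov_ij + crossprod(disp[, , k]) / F
  v <- diag(cov_ij)
  zero <- v < 1e-12
  if (any(zero)) warning(sum(zero), " zero-variance node(s); rows zeroed")
  denom <- sqrt(outer(v, v))
  C <- ifelse(denom > 0, cov_ij / denom, 0)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C)[!zero] <- 1
  labs <- res_key(t$topology$atom[idx, , drop = FALSE])
  dimnames(C) <- list(labs, labs)
  C
}
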