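# Static interface analytics: per-residue contact numbers, hydrogen
# bonds, the interface-vs-mutational-impact association test, and the
# helical-rotation null model used to validate the modelled orientation
# of the single-TM accessory helix.

#' Per-residue intermolecular contact numbers
#'
#' For each residue of one group, the number of heavy atoms of the
#' other group within `radius` (closed ball, default 4 A) of any of its
#' heavy atoms -- the contact-number convention used to map the binding
#' cleft. Set `atoms = "hetero"` to count only non-carbon partner atoms
#' (the stricter chemical reading of "heteroatom").
#'
#' @param s a `Structure`.
#' @param group_a,group_b disjoint chain sets.
#' @param radius contact radius (Angstrom, default 4).
#' @param atoms `"heavy"` (default) or `"hetero"` (non-C heavy atoms).
#' @param model model index.
#' @return a `ContactProfile` data frame: chain, resid, resname,
#'   group, contacts.
#' @export
contact_number <- function(s, group_a, group_b, radius = 4,
                           atoms = c("heavy", "hetero"), model = 1) {
  atoms <- match.arg(atoms)
  if (length(intersect(group_a, group_b))) {
    stop("group_a and group_b must be disjoint chain sets")
  }
  A <- chain_heavy(s, group_a, model)
  B <- chain_heavy(s, group_b, model)
  count_side <- function(X, Y, grp) {
    keepY <- if (atoms == "hetero") Y$atom$element != "C" else
      rep(TRUE, nrow(Y$atom))
    d <- pairdist(X$xyz, Y$xyz[keepY, , drop = FALSE])
    key <- res_key(X$atom)
    first <- !duplicated(key)
    cnt <- vapply(key[first], function(k) {
      rows <- key == k
      # partner atoms within radius of ANY atom of the residue
      sum(apply(d[rows, , drop = FALSE], 2, min) <= radius)
    }, numeric(1))
    data.frame(
      chain = X$atom$chain[first], resid = X$atom$resid[first],
      resname = X$atom$resname[first], group = grp,
      contacts = as.numeric(cnt), stringsAsFactors = FALSE
    )
  }
  out <- rbind(count_side(A, B, "a"), count_side(B, A, "b"))
  rownames(out) <- NULL
  structure(out, class = c("ContactProfile", "data.frame"))
}

.donor_acceptor_elements <- c("N", "O")

#' Detect interface hydrogen bonds
#'
#' Geometric hydrogen bonds between N/O atoms across the partner
#' interface: donor-acceptor distance at most `d_max` (default 3.5 A)
#' and, where a hydrogen is bonded to the donor candidate (within
#' 1.25 A), a donor-H...acceptor angle of at least `angle_min`
#' (default 120 degrees). Structures without hydrogens are evaluated
#' on the heavy-atom criterion alone.
#'
#' @param s a `Structure`.
#' @param group_a,group_b chain sets on either side of the interface.
#' @param d_max donor-acceptor distance cutoff (Angstrom).
#' @param angle_min minimal D-H...A angle (degrees).
#' @param model model index.
#' @return data frame: donor/acceptor identities, distance, angle
#'   (NA when no hydrogen was available).
#' @export
detect_hbonds <- function(s, group_a, group_b, d_max = 3.5,
                          angle_min = 120, model = 1) {
  xyz <- coords(s, model)
  polar <- function(chains) {
    which(s$atom$chain %in% chains &
            s$atom$element %in% .donor_acceptor_elements)
  }
  ia <- polar(group_a)
  ib <- polar(group_b)
  if (!length(ia) || !length(ib)) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      distance = numeric(0), angle = numeric(0)))
  }
  hyd <- which(s$atom$is_hydrogen)
  attached_h <- function(i) {
    if (!length(hyd)) return(integer(0))
    same <- hyd[s$atom$chain[hyd] == s$atom$chain[i] &
                  s$atom$resid[hyd] == s$atom$resid[i]]
    if (!length(same)) return(integer(0))
    d <- sqrt(rowSums((xyz[same, , drop = FALSE] -
                         matrix(xyz[i, ], length(same), 3, byrow = TRUE))^2))
    same[d <= 1.25]
  }
  d <- pairdist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hits <- which(d <= d_max, arr.ind = TRUE)
  out <- list()
  label <- function(i) paste0(s$atom$chain[i], ":", s$atom$resid[i],
                              s$atom$resname[i], ":", s$atom$name[i])
  for (r in seq_len(nrow(hits))) {
    i <- ia[hits[r, 1]]; j <- ib[hits[r, 2]]
    dist_ij <- d[hits[r, 1], hits[r, 2]]
    # the hydrogen-based angle criterion governs whenever either side
    # carries a hydrogen; the pure heavy-atom criterion applies only to
    # structures without hydrogens
    best <- NULL
    any_h <- FALSE
    for (pair in list(c(i, j), c(j, i))) {
      don <- pair[1]; acc <- pair[2]
      hs <- attached_h(don)
      if (length(hs)) {
        any_h <- TRUE
        ang <- max(vapply(hs, function(h) {
          v1 <- xyz[don, ] - xyz[h, ]
          v2 <- xyz[acc, ] - xyz[h, ]
          acos(pmin(1, pmax(-1, sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        }, numeric(1)))
        if (ang >= angle_min &&
            (is.null(best) || is.na(best$angle) || ang > best$angle)) {
          best <- list(donor = don, acceptor = acc, angle = ang)
        }
      }
    }
    if (is.null(best) && !any_h) {
      best <- list(donor = i, acceptor = j, angle = NA_real_)
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(
        donor = label(best$donor), acceptor = label(best$acceptor),
        distance = dist_ij, angle = best$angle, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      distance = numeric(0), angle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Mutational-impact table
#'
#' Flags positions whose mutation shifts the half-activation voltage by
#' more than the dataset-specific threshold: 20 mV for oocyte
#' literature data, 10 mV for CHO-K1 recordings.
#'
#' @param resid residue numbers (author numbering).
#' @param delta_v12 observed V1/2 shifts (mV).
#' @param dataset `"oocyte"` or `"cho"` per position (recycled).
#' @param thresholds named numeric vector of |dV1/2| thresholds (mV).
#' @return an `ImpactTable` data frame with logical `impact`.
#' @export
impact_table <- function(resid, delta_v12, dataset = "cho",
                         thresholds = c(oocyte = 20, cho = 10)) {
  dataset <- rep_len(dataset, length(resid))
  thr <- thresholds[dataset]
  out <- data.frame(
    resid = resid, delta_v12 = delta_v12, dataset = dataset,
    impact = abs(delta_v12) > unname(thr), stringsAsFactors = FALSE
  )
  structure(out, class = c("ImpactTable", "data.frame"))
}

#' Chi-squared association between interface and mutational impact
#'
#' Builds the 2x2 table of interface membership (dSASA > threshold)
#' against high-impact mutation flags over the same positions and
#' applies Pearson's chi-squared test (degrees of freedom 1), with and
#' without Yates continuity correction.
#'
#' @param interface_flags logical vector (interface membership).
#' @param impact_flags logical vector (high-impact mutation site).
#' @return list with `table`, `chisq`, `p`, `chisq_yates`, `p_yates`.
#' @export
chi2_association <- function(interface_flags, impact_flags) {
  stopifnot(length(interface_flags) == length(impact_flags))
  if (length(interface_flags) < 4) stop("need at least 4 positions")
  tab <- table(
    impact = factor(impact_flags, levels = c(TRUE, FALSE)),
    interface = factor(interface_flags, levels = c(TRUE, FALSE))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a margin of the 2x2 table is zero; consider Fisher's exact test")
  }
  plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(
    table = tab,
    chisq = unname(plain$statistic), p = plain$p.value,
    chisq_yates = unname(yates$statistic), p_yates = yates$p.value
  )
}

# Principal axis of the Calpha cloud of a chain set (unit vector) and
# its centroid.
helical_axis <- function(s, chains) {
  idx <- which(s$atom$chain %in% chains & s$atom$name == "CA")
  if (length(idx) < 8) stop("ligand too short for an axis fit (<8 CA atoms)")
  X <- coords(s)[idx, , drop = FALSE]
  ctr <- colMeans(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # orient along increasing residue number for determinism
  if (sum((X[nrow(X), ] - X[1, ]) * axis) < 0) axis <- -axis
  list(axis = axis, center = ctr)
}

#' Helical-rotation null model for the modelled orientation
#'
#' Rotates the ligand helix in place about its own screw axis (the
#' principal axis of its Calpha cloud) in steps of `angle_step`,
#' recomputing the dSASA interface profile and its chi-squared
#' association with the mutational-impact flags at every angle. Angle 0
#' is the as-modelled orientation; a genuine binding orientation should
#' associate with impact data at 0 and lose the association at rotated
#' decoy orientations.
#'
#' @param cx complex `Structure`.
#' @param ligand_chains single ligand chain (helix-dominated).
#' @param impact an [impact_table()] covering ligand residues.
#' @param angle_step scan step in degrees (default 30).
#' @param threshold dSASA interface threshold (percent).
#' @param probe,n_points passed to [sasa()].
#' @return data frame (angle, chisq, p, p_yates, n_interface); the
#'   per-angle SASA profiles are attached as attribute `profiles`.
#' @export
rotation_null_scan <- function(cx, ligand_chains, impact, angle_step = 30,
                               threshold = 20, probe = 1.4, n_points = 960) {
  lig <- extract_chains(cx, ligand_chains)
  ax <- helical_axis(cx, ligand_chains)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  res <- data.frame()
  profiles <- list()
  lig_idx <- which(cx$atom$chain %in% ligand_chains)
  for (a in angles) {
    rot <- axis_rotation_pose(ax$axis, a, ax$center)
    cx_a <- cx
    cx_a$models[[1]][lig_idx, ] <-
      apply_pose(coords(cx)[lig_idx, , drop = FALSE], rot)
    prof <- delta_sasa_interface(lig, cx_a, ligand_chains,
                                 threshold = threshold, probe = probe,
                                 n_points = n_points)
    m <- match(impact$resid, prof$resid)
    flags <- prof$interface[m]
    chi <- tryCatch(chi2_association(flags, impact$impact),
                    error = function(e) NULL)
    res <- rbind(res, data.frame(
      angle = a,
      chisq = if (is.null(chi)) NA_real_ else chi$chisq,
      p = if (is.null(chi)) NA_real_ else chi$p,
      p_yates = if (is.null(chi)) NA_real_ else chi$p_yates,
      n_interface = sum(prof$interface)
    ))
    profiles[[as.character(a)]] <- prof
  }
  attr(res, "profiles") <- profiles
  res
}
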