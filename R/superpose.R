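# Kabsch superposition and docking-accuracy metrics (interface RMSD,
# fraction of native contacts) computed relative to a reference complex.

kabsch_fit <- function(P, Q) {
  # Least-squares rigid transform x -> R x + t mapping P (mobile) onto
  # Q (reference); standard SVD solution with det(+1) correction.
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc)) # H = Pc' Qc
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  fit <- sweep(tcrossprod(Pc, R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Superpose two structures (Kabsch)
#'
#' Computes the least-squares rigid-body transform aligning `mobile`
#' onto `reference` over atoms selected by a [select_atoms()] string;
#' atoms are paired by (chain, resid, name) identity. Inputs are not
#' modified; apply the transform with [apply_superposition()].
#'
#' @param mobile,reference `Structure` objects.
#' @param selection selection string (default all heavy atoms named CA).
#' @param model_mobile,model_reference model indices.
#' @return an object of class `Superposition`: list with `rotation`
#'   (3x3, det +1), `translation` (Angstrom) and `rmsd` (Angstrom).
#' @export
superpose_kabsch <- function(mobile, reference, selection = "*:*:CA",
                             model_mobile = 1, model_reference = 1) {
  mi <- which(select_atoms(mobile, selection))
  ri <- which(select_atoms(reference, selection))
  mk <- atom_key(mobile$atom[mi, ])
  rk <- atom_key(reference$atom[ri, ])
  common <- intersect(mk, rk)
  missing <- union(setdiff(mk, rk), setdiff(rk, mk))
  if (length(common) < 3) {
    stop(
      "selection pairs fewer than 3 atoms",
      if (length(missing)) paste0("; unpaired: ",
        paste(utils::head(missing, 10), collapse = ", "))
    )
  }
  P <- coords(mobile, model_mobile)[mi[match(common, mk)], , drop = FALSE]
  Q <- coords(reference, model_reference)[ri[match(common, rk)], , drop = FALSE]
  # Degeneracy check: the paired set must be non-collinear.
  if (svd(sweep(Q, 2, colMeans(Q)))$d[2] < 1e-8 ||
      svd(sweep(P, 2, colMeans(P)))$d[2] < 1e-8) {
    stop("degenerate (collinear) atom selection; cannot superpose")
  }
  fit <- kabsch_fit(P, Q)
  structure(fit, class = "Superposition")
}

#' Apply a Superposition to a structure
#' @param s a `Structure`.
#' @param sp a `Superposition` from [superpose_kabsch()].
#' @return the transformed `Structure` (all models moved).
#' @export
apply_superposition <- function(s, sp) {
  s$models <- lapply(s$models, function(m) {
    sweep(tcrossprod(m, sp$rotation), 2, sp$translation, "+")
  })
  s
}

# Heavy-atom coordinates + atom table for a chain set.
chain_heavy <- function(s, chains, model = 1) {
  idx <- which(s$atom$chain %in% chains & !s$atom$is_hydrogen)
  if (!length(idx)) stop("no heavy atoms in chain(s) ", paste(chains, collapse = ","))
  list(atom = s$atom[idx, , drop = FALSE],
       xyz = coords(s, model)[idx, , drop = FALSE])
}

# Residues of partner A/B with any heavy atom within `cutoff` of the
# other partner. Returns residue keys per side.
interface_residues <- function(s, chains_a, chains_b, cutoff) {
  A <- chain_heavy(s, chains_a)
  B <- chain_heavy(s, chains_b)
  d <- pairdist(A$xyz, B$xyz)
  near_a <- apply(d, 1, min) <= cutoff
  near_b <- apply(d, 2, min) <= cutoff
  list(
    a = unique(res_key(A$atom[near_a, , drop = FALSE])),
    b = unique(res_key(B$atom[near_b, , drop = FALSE]))
  )
}

#' Interface RMSD relative to a reference complex
#'
#' Interface residues are defined on the reference: every residue of
#' either partner with a heavy atom within `cutoff` of the other
#' partner. The model is superposed on the partner-A (receptor) chains
#' and the heavy-atom RMSD is evaluated over the partner-B interface
#' residues, so a rigid 2 A displacement of the ligand reads out as
#' exactly 2 A.
#'
#' @param model,reference `Structure` objects sharing residue identities.
#' @param chains_a receptor chain set (superposition frame).
#' @param chains_b ligand chain set.
#' @param cutoff interface distance cutoff (Angstrom, default 10).
#' @return interface RMSD in Angstrom.
#' @export
interface_rmsd <- function(model, reference, chains_a, chains_b, cutoff = 10) {
  iface <- interface_residues(reference, chains_a, chains_b, cutoff)
  if (!length(iface$b)) stop("empty interface at cutoff ", cutoff, " A")
  fit <- superpose_kabsch(model, reference,
    selection = paste0(paste(chains_a, collapse = "+"), ":*:*"))
  model <- apply_superposition(model, fit)
  mB <- chain_heavy(model, chains_b)
  rB <- chain_heavy(reference, chains_b)
  sel_m <- res_key(mB$atom) %in% iface$b
  sel_r <- res_key(rB$atom) %in% iface$b
  km <- atom_key(mB$atom[sel_m, , drop = FALSE])
  kr <- atom_key(rB$atom[sel_r, , drop = FALSE])
  common <- intersect(km, kr)
  if (!length(common)) stop("no paired interface atoms between model and reference")
  P <- mB$xyz[sel_m, , drop = FALSE][match(common, km), , drop = FALSE]
  Q <- rB$xyz[sel_r, , drop = FALSE][match(common, kr), , drop = FALSE]
  sqrt(mean(rowSums((P - Q)^2)))
}

# Residue-pair contact set (keys "resA||resB") at a heavy-atom cutoff.
contact_pairs <- function(s, chains_a, chains_b, cutoff) {
  A <- chain_heavy(s, chains_a)
  B <- chain_heavy(s, chains_b)
  d <- pairdist(A$xyz, B$xyz) <= cutoff
  if (!any(d)) return(character(0))
  hits <- which(d, arr.ind = TRUE)
  unique(paste(res_key(A$atom)[hits[, 1]], res_key(B$atom)[hits[, 2]],
               sep = "||"))
}

#' Fraction of native residue contacts recovered
#'
#' A contact is a residue of one partner with any heavy atom within
#' `cutoff` (default 5 A) of any heavy atom of a residue of the other
#' partner. Returns the fraction of the reference's contacts present in
#' the model.
#'
#' @inheritParams interface_rmsd
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction in \[0, 1\].
#' @export
fraction_native_contacts <- function(model, reference, chains_a, chains_b,
                                     cutoff = 5) {
  ref <- contact_pairs(reference, chains_a, chains_b, cutoff)
  if (!length(ref)) stop("reference complex has no contacts at ", cutoff, " A")
  mod <- contact_pairs(model, chains_a, chains_b, cutoff)
  length(intersect(mod, ref)) / length(ref)
}
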