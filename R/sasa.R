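# Solvent-accessible surface area by Shrake-Rupley sphere sampling and
# the dSASA-based interface criterion: a residue belongs to the
# binding interface when complex formation buries more than 20% of its
# free-state SASA.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA is the unoccluded fraction of a deterministic
#' Fibonacci point set on the sphere of radius `r_vdw + probe`, scaled
#' by that sphere's area; residues sum their heavy atoms. Hydrogens are
#' excluded. Radii come from [vdw_radius()] (C 1.70, N 1.55, O 1.52,
#' S 1.80 A).
#'
#' @param s a `Structure`.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @param model model index.
#' @return list with `atom` (numeric vector over heavy atoms, named by
#'   serial) and `residue` (data frame chain/resid/resname/sasa).
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, model = 1) {
  hv <- which(!s$atom$is_hydrogen)
  if (!length(hv)) stop("no heavy atoms")
  xyz <- coords(s, model)[hv, , drop = FALSE]
  rad <- vdw_radius(s$atom$element[hv]) + probe
  pts <- fibonacci_sphere(n_points)
  n <- length(hv)
  nb_d2 <- pairdist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut2 <- (rad[i] + rad)^2
    nb <- which(nb_d2[i, ] < cut2 & seq_len(n) != i)
    surf <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      d2 <- pairdist2(surf, xyz[nb, , drop = FALSE])
      exposed <- rowSums(d2 < matrix(rad[nb]^2, n_points, length(nb),
                                     byrow = TRUE)) == 0
    } else {
      exposed <- rep(TRUE, n_points)
    }
    area[i] <- 4 * pi * rad[i]^2 * mean(exposed)
  }
  names(area) <- s$atom$serial[hv]
  key <- res_key(s$atom[hv, , drop = FALSE])
  first <- !duplicated(key)
  residue <- data.frame(
    chain = s$atom$chain[hv][first],
    resid = s$atom$resid[hv][first],
    resname = s$atom$resname[hv][first],
    sasa = as.numeric(tapply(area, factor(key, levels = key[first]), sum)),
    stringsAsFactors = FALSE
  )
  list(atom = area, residue = residue)
}

#' Interface detection by relative SASA loss
#'
#' For every residue of the ligand chains, the relative change
#' `dSASA% = 100 * max(0, SASA_free - SASA_complexed) / SASA_free`
#' (0 where the free SASA is 0; negative changes are clamped to 0 so
#' the interface flag is monotone in burial). Residues with dSASA%
#' above `threshold` (default 20) are flagged as part of the binding
#' interface.
#'
#' @param free `Structure` of the ligand alone.
#' @param complexed `Structure` of the complex containing the same
#'   ligand residues.
#' @param ligand_chains chain identifier(s) of the ligand in `complexed`.
#' @param threshold interface threshold in percent (default 20).
#' @param probe,n_points passed to [sasa()].
#' @return a `SasaProfile` data frame: chain, resid, resname,
#'   sasa_free, sasa_complexed, dsasa_pct, interface.
#' @export
delta_sasa_interface <- function(free, complexed, ligand_chains,
                                 threshold = 20, probe = 1.4,
                                 n_points = 960) {
  sf <- sasa(free, probe, n_points)$residue
  sc <- sasa(complexed, probe, n_points)$residue
  sc <- sc[sc$chain %in% ligand_chains, , drop = FALSE]
  kf <- paste(sf$chain, sf$resid)
  kc <- paste(sc$chain, sc$resid)
  if (!setequal(kf, kc)) {
    stop("free and complexed ligand residues do not match")
  }
  sc <- sc[match(kf, kc), , drop = FALSE]
  ds <- ifelse(sf$sasa > 0,
               100 * pmax(0, sf$sasa - sc$sasa) / sf$sasa, 0)
  out <- data.frame(
    chain = sf$chain, resid = sf$resid, resname = sf$resname,
    sasa_free = sf$sasa, sasa_complexed = sc$sasa,
    dsasa_pct = ds, interface = ds > threshold,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("SasaProfile", "data.frame"),
            threshold = threshold)
}
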