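# Pore-radius profile along the channel permeation axis: per z-slice,
# the radius of the largest probe sphere, centred in the slice plane,
# that overlaps no heavy atom's van der Waals sphere (the objective of
# HOLE evaluated at fixed z).

#' Pore radius profile of a channel structure
#'
#' For each slice position z along the axis, the clearance function
#' `f(x, y) = min_i (|p - atom_i| - r_i)` is maximised over the slice
#' plane by local optimisation started on the axis; the pore radius is
#' `max(0, f)` capped at `max_radius`. An occluded slice records
#' radius 0; an empty slice records `max_radius`.
#'
#' @param s a `Structure`.
#' @param axis channel axis direction (default z, the 4-fold symmetry
#'   axis of the toy channel).
#' @param anchor point on the axis (default origin).
#' @param z_range length-2 numeric range along the axis; defaults to
#'   the structure's extent.
#' @param step slice spacing (Angstrom, default 0.5).
#' @param max_radius search cap (Angstrom, default 15).
#' @param model model index.
#' @return a `PoreProfile` data frame: z (strictly increasing), radius,
#'   and the in-plane centre offsets cx, cy.
#' @export
pore_profile <- function(s, axis = c(0, 0, 1), anchor = c(0, 0, 0),
                         z_range = NULL, step = 0.5, max_radius = 15,
                         model = 1) {
  hv <- which(!s$atom$is_hydrogen)
  B <- axis_basis(axis)
  X <- sweep(coords(s, model)[hv, , drop = FALSE], 2, anchor) %*% B
  rad <- vdw_radius(s$atom$element[hv])
  if (is.null(z_range)) z_range <- range(X[, 3])
  zs <- seq(z_range[1], z_range[2], by = step)
  clearance <- function(xy, z) {
    d <- sqrt((X[, 1] - xy[1])^2 + (X[, 2] - xy[2])^2 + (X[, 3] - z)^2)
    min(d - rad)
  }
  out <- data.frame(z = zs, radius = NA_real_, cx = NA_real_, cy = NA_real_)
  for (i in seq_along(zs)) {
    z <- zs[i]
    f0 <- clearance(c(0, 0), z)
    if (f0 >= max_radius) {
      out$radius[i] <- max_radius; out$cx[i] <- 0; out$cy[i] <- 0
      next
    }
    opt <- stats::optim(c(0, 0), function(xy) -clearance(xy, z),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    out$radius[i] <- min(max(0, -opt$value), max_radius)
    out$cx[i] <- opt$par[1]; out$cy[i] <- opt$par[2]
  }
  structure(out, class = c("PoreProfile", "data.frame"))
}
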