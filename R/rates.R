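# Force-dependent reaction rates ----------------------------------------
#
# The four mechanochemical laws coupling the post-minimization force field
# back into the chemistry.  All reduce to the bare rate at zero force.

#' Brownian-ratchet polymerization rate
#'
#' A compressive load on a polymerizing filament end suppresses monomer
#' addition exponentially: \eqn{k = k_0 \exp(-F_{ext}/F_{poly,0})}.
#'
#' @param k0 bare polymerization rate
#' @param F_ext compressive boundary load on the end, pN (negative values
#'   are clamped to zero with a warning)
#' @param F_poly0 characteristic polymerization force, pN
#' @return modified rate, same units as \code{k0}
#' @export
ratchet_poly_rate <- function(k0, F_ext, F_poly0 = 1.5) {
  if (any(F_ext < 0)) {
    warning("negative load clamped to 0")
    F_ext <- pmax(F_ext, 0)
  }
  k0 * exp(-F_ext / F_poly0)
}

#' Slip-bond linker unbinding rate
#'
#' Stretching force accelerates crosslinker unbinding:
#' \eqn{k = k_0 \exp(F_{stretch}/F_{unbind})}.  Compression does not
#' trigger the slip bond (forces below zero leave the bare rate).
#'
#' @param k0 bare unbinding rate, s^-1
#' @param F_stretch signed axial force on the linker, pN (+ = stretched)
#' @param F_linker_unbind characteristic unbinding force, pN
#' @return modified rate, s^-1
#' @export
slip_unbind_rate <- function(k0, F_stretch, F_linker_unbind = 17.2) {
  k0 * exp(pmax(F_stretch, 0) / F_linker_unbind)
}

#' Catch-bond motor ensemble unbinding rate
#'
#' Parallel-cluster form: tension shared over the heads stabilizes the
#' ensemble, \eqn{k = \beta k_0/N \exp(-F/(N F_{unbind}))}.
#'
#' @param k0 bare per-head unbinding rate, s^-1
#' @param F_ext ensemble tension, pN (tension only; >= 0)
#' @param n_heads number of heads in the ensemble (>= 1)
#' @param beta dimensionless prefactor
#' @param F_nmii_unbind characteristic ensemble unbinding force, pN
#' @return modified rate, s^-1
#' @export
catch_unbind_rate <- function(k0, F_ext, n_heads, beta = 0.2,
                              F_nmii_unbind = 20) {
  if (any(n_heads < 1)) stop("n_heads must be >= 1")
  F_ext <- pmax(F_ext, 0)
  beta * k0 / n_heads * exp(-F_ext / (n_heads * F_nmii_unbind))
}

#' Hill force-velocity motor walking rate
#'
#' \eqn{k = k_0 (F_{stall} - F/N) / (F_{stall} + F/(N \xi))}, floored at 0;
#' equals \code{k0} when unloaded and 0 at the ensemble stall force
#' \eqn{N F_{stall}}.
#'
#' @param k0_walk unloaded walking rate, s^-1
#' @param F_pull pulling force opposing the walking direction, pN (>= 0)
#' @param n_heads number of heads in the ensemble
#' @param F_stall per-head stall force, pN
#' @param xi force-sharing factor
#' @return modified rate, s^-1
#' @export
hill_walk_rate <- function(k0_walk, F_pull, n_heads, F_stall = 12.62,
                           xi = 0.1) {
  F_pull <- pmax(F_pull, 0)
  per <- F_pull / n_heads
  pmax(0, k0_walk * (F_stall - per) / (F_stall + F_pull / (n_heads * xi)))
}
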