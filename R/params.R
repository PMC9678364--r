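#' Mechanical parameters of the network
#'
#' Constructor for the mechanical parameter set used by the energy model:
#' harmonic stretching of filament cylinders, cosine bending between
#' consecutive cylinders, an \eqn{r^{-4}} pairwise excluded-volume kernel,
#' harmonic motor/linker springs, and an exponential boundary repulsion
#' shifted inward by \code{a0_nm}.
#'
#' Defaults are the standard parameterization for non-muscle actomyosin at
#' room temperature: cylinder stretching 100 pN/nm, bending modulus
#' 672 pN nm (persistence length ~17 um at 108 nm segments), linker
#' stiffness 8 pN/nm, myosin stiffness 2.5 pN/nm per head, boundary
#' repulsion amplitude 100 pN nm with screening length 2.7 nm.
#'
#' @param K_fil_str filament (cylinder) stretching constant, pN/nm
#' @param K_fil_bend filament bending constant, pN nm
#' @param theta0 equilibrium bending angle, rad (straight filament)
#' @param K_vol excluded volume constant, pN nm^4
#' @param K_linker_str linker spring constant, pN/nm
#' @param K_nmii_str_per_head motor spring constant per head, pN/nm
#' @param eps_boundary boundary repulsion energy, pN nm
#' @param lambda_screen boundary screening length, nm
#' @param a0_nm inward shift of the repulsive barrier, nm
#' @return a list of class \code{"mech_params"}
#' @export
mech_params <- function(K_fil_str = 100, K_fil_bend = 672, theta0 = 0,
                        K_vol = 1e5, K_linker_str = 8,
                        K_nmii_str_per_head = 2.5,
                        eps_boundary = 100, lambda_screen = 2.7,
                        a0_nm = 100) {
  p <- list(K_fil_str = K_fil_str, K_fil_bend = K_fil_bend, theta0 = theta0,
            K_vol = K_vol, K_linker_str = K_linker_str,
            K_nmii_str_per_head = K_nmii_str_per_head,
            eps_boundary = eps_boundary, lambda_screen = lambda_screen,
            a0_nm = a0_nm)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1L, TRUE)))
  if (any(unlist(p[setdiff(names(p), "theta0")]) <= 0))
    stop("all mechanical constants must be strictly positive")
  if (theta0 != 0) stop("theta0 must be 0 (straight equilibrium)")
  class(p) <- "mech_params"
  p
}

#' Chemical rate parameters
#'
#' Rate constants for the four-reaction treadmilling scheme (barbed/pointed
#' end polymerization and depolymerization), two-step formin nucleation,
#' formin dissociation, destruction of 2-monomer filaments, crosslinker and
#' per-head motor (un)binding, unloaded motor walking, and diffusion of
#' soluble species.  Units: second-order constants in (uM s)^-1, first-order
#' in s^-1, diffusion in nm^2/s.
#'
#' @param D_diff diffusion coefficient of soluble species, nm^2/s (20 um^2/s)
#' @param k_on_BE,k_on_PE end polymerization rate constants, (uM s)^-1
#' @param k_off_BE,k_off_PE end depolymerization rates, s^-1
#' @param k_destruction destruction rate of 2-monomer filaments, s^-1
#' @param k_nu nucleation (step 1) rate per eligible formin, s^-1
#' @param k_off_formin formin dissociation rate, s^-1
#' @param k_on_linker linker binding rate constant, (uM s)^-1
#' @param k_off_linker linker unbinding rate, s^-1
#' @param k_on_head,k_off_head per-motor-head binding/unbinding rates, s^-1
#' @param k_walk0 unloaded motor walking rate, s^-1 (~0.2 um/s at 27 nm
#'   binding-site spacing)
#' @return a list of class \code{"chem_params"}
#' @export
chem_params <- function(D_diff = 20e6,
                        k_on_BE = 11.6, k_on_PE = 1.3,
                        k_off_BE = 1.4, k_off_PE = 2.4,
                        k_destruction = 1.9, k_nu = 0.005,
                        k_off_formin = 0.01,
                        k_on_linker = 0.7, k_off_linker = 0.3,
                        k_on_head = 0.2, k_off_head = 1.7,
                        k_walk0 = 7.4) {
  p <- as.list(environment())
  stopifnot(all(vapply(p, function(x) is.numeric(x) && length(x) == 1L, TRUE)))
  if (any(unlist(p) < 0)) stop("rates must be nonnegative")
  p$monomer_size <- 2.7           # nm per actin monomer, fixed
  p$max_monomers_per_cylinder <- 40L
  class(p) <- "chem_params"
  p
}

#' Mechanochemical coupling parameters
#'
#' Parameters of the four force-dependent rate laws: Brownian-ratchet
#' polymerization, slip-bond linker unbinding, catch-bond motor-ensemble
#' unbinding (parallel-cluster form) and the Hill force-velocity relation
#' for motor walking.
#'
#' @param F_poly0 characteristic polymerization force, pN
#' @param F_linker_unbind characteristic linker unbinding force, pN
#' @param beta motor unbinding prefactor (dimensionless)
#' @param gamma motor catch-bond force sensitivity, pN^-1; the
#'   characteristic ensemble unbinding force is taken as \code{1/gamma}
#' @param xi walking force-sharing factor (dimensionless)
#' @param F_stall per-head stall force, pN
#' @param duty_ratio motor head duty ratio in (0,1)
#' @param n_heads_range inclusive integer range of ensemble head counts
#' @return a list of class \code{"mechanochem_params"}
#' @export
mechanochem_params <- function(F_poly0 = 1.5, F_linker_unbind = 17.2,
                               beta = 0.2, gamma = 0.05, xi = 0.1,
                               F_stall = 12.62, duty_ratio = 0.1,
                               n_heads_range = c(15L, 30L)) {
  stopifnot(beta > 0, gamma > 0, xi > 0, F_poly0 > 0, F_stall > 0,
            F_linker_unbind > 0,
            duty_ratio > 0, duty_ratio < 1, length(n_heads_range) == 2L,
            n_heads_range[1] >= 1, n_heads_range[2] >= n_heads_range[1])
  p <- list(F_poly0 = F_poly0, F_linker_unbind = F_linker_unbind,
            beta = beta, gamma = gamma, xi = xi, F_stall = F_stall,
            duty_ratio = duty_ratio,
            n_heads_range = as.integer(n_heads_range),
            F_nmii_unbind = 1 / gamma)
  class(p) <- "mechanochem_params"
  p
}

#' Confinement geometry
#'
#' The mechanical boundary is an oblate cylinder (diameter x height) or a
#' sphere; the repulsive barrier is shifted inward by \code{a0_nm} so the
#' effective confinement is smaller than the mechanical surface (e.g.
#' mechanical height 400 nm with a0 = 100 nm confines the network to an
#' effective height of 200 nm).
#'
#' @param shape "oblate" or "sphere"
#' @param diameter_nm mechanical diameter, nm
#' @param height_nm mechanical height, nm (oblate only)
#' @param a0_nm inward shift of the barrier, nm
#' @return list of class \code{"boundary_geometry"} with effective
#'   radius/height fields precomputed
#' @export
boundary_geometry <- function(shape = c("oblate", "sphere"),
                              diameter_nm = 4000, height_nm = 400,
                              a0_nm = 100) {
  shape <- match.arg(shape)
  stopifnot(diameter_nm > 0, a0_nm >= 0)
  g <- list(shape = shape, diameter_nm = diameter_nm,
            height_nm = if (shape == "oblate") height_nm else NA_real_,
            a0_nm = a0_nm,
            R_eff = diameter_nm / 2 - a0_nm,
            half_height_eff = if (shape == "oblate")
              height_nm / 2 - a0_nm else NA_real_)
  if (g$R_eff <= 0 || (shape == "oblate" && g$half_height_eff <= 0))
    stop("effective confinement must have positive extent")
  class(g) <- "boundary_geometry"
  g
}

#' Effective confinement volume in liters
#' @param geom a \code{boundary_geometry}
#' @return volume of the effective (shifted) confinement, L
#' @export
effective_volume_L <- function(geom) {
  v_nm3 <- if (geom$shape == "oblate")
    pi * geom$R_eff^2 * (2 * geom$half_height_eff)
  else 4 / 3 * pi * geom$R_eff^3
  v_nm3 * 1e-24
}

#' Convert a molar concentration to an integer copy number
#'
#' @param conc_uM concentration in micromolar
#' @param volume_L volume in liters
#' @return \code{round(conc * 1e-6 * N_A * volume)}
#' @examples
#' concentration_to_copies(40, 2.27e-15)
#' @export
concentration_to_copies <- function(conc_uM, volume_L) {
  if (any(conc_uM < 0)) stop("concentration must be nonnegative")
  if (any(volume_L <= 0)) stop("volume must be positive")
  as.integer(round(conc_uM * 1e-6 * 6.022e23 * volume_L))
}

#' Convert an integer copy number to micromolar concentration
#' @param n copy number
#' @param volume_L volume in liters
#' @return concentration in uM
#' @export
copies_to_concentration <- function(n, volume_L) {
  n / (6.022e23 * volume_L) * 1e6
}
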