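#' Membrane diffusion model parameters
#'
#' Full parameterization of the four-regime Langevin simulator. Units are
#' micrometres, seconds and thermal energy kT throughout.
#'
#' The regimes emulate the environments a membrane receptor distinguishes:
#'
#' * `free` - unobstructed 2D Brownian motion at `D_free`.
#' * `corral` - Brownian motion inside a cytoskeletal compartment whose
#'   boundary is a soft Gaussian potential ridge of height `barrier_height`
#'   (kT) and width `barrier_width` centred at radius `corral_radius`;
#'   stalling at the ridge over-disperses the coarse-grained step sizes.
#' * `domain` - a "dressed" protein inside a lipid domain: diffusion is
#'   unconstrained within `domain_radius` of a domain centre (itself slowly
#'   diffusing at `domain_center_D`) and pulled back by a stiff elastic
#'   boundary layer with relaxation time `domain_relaxation_time /
#'   cholesterol`; the bounded, flat-bottomed motion under-disperses the
#'   coarse-grained step sizes.
#' * `pair` - two receptors coupled through a harmonic attraction of
#'   stiffness `pair_spring_k * cholesterol + pair_direct_k` (kT/um^2), with
#'   the pair centroid dressed in a lipid domain as above; the cholesterol
#'   scale stabilizes both the domain and the lipid-mediated coupling, while
#'   `pair_direct_k` models direct dimerization that survives cholesterol
#'   depletion.
#'
#' `cholesterol` in \[0, 1\] multiplies the domain and pair-coupling
#' stabilities; the drug presets of [cholesterol_preset()] map nystatin
#' (redistributed cholesterol) to 0.5 and methyl-beta-cyclodextrin
#' (depleted) to 0.1. These presets are interpretive labels, not fits.
#'
#' Defaults are illustrative order-of-magnitude choices for receptor
#' diffusion in a plasma membrane sampled at 25 ms (compartments of a few
#' hundred nm, lipid domains of ~100 nm, barriers of a few kT); none are
#' measured values.
#'
#' @param regime one of `"free"`, `"corral"`, `"domain"`, `"pair"`.
#' @param D_free microscopic diffusion coefficient, um^2/s.
#' @param corral_radius corral radius, um.
#' @param barrier_height barrier height in kT units.
#' @param barrier_width barrier ridge width, um.
#' @param domain_radius flat-bottom radius of the lipid domain, um.
#' @param domain_relaxation_time boundary-layer relaxation time at
#'   `cholesterol = 1`, seconds; the elastic pull-back rate is
#'   `cholesterol / domain_relaxation_time`, so `Inf` (or `cholesterol = 0`)
#'   recovers free diffusion.
#' @param domain_center_D diffusion coefficient of the domain centre, um^2/s.
#' @param pair_spring_k cholesterol-mediated pair coupling stiffness, kT/um^2.
#' @param pair_direct_k direct (cholesterol-independent) dimerization
#'   stiffness, kT/um^2.
#' @param cholesterol dimensionless stability scale in \[0, 1\].
#' @param sigma_loc radial RMS localization error, um (the per-axis error is
#'   `sigma_loc / sqrt(2)`).
#' @param frame_period camera frame period, seconds.
#' @param n_frames frames per simulated track.
#' @param substeps Euler-Maruyama integration substeps per frame.
#' @param seed integer seed; simulations are bit-reproducible given
#'   identical parameters.
#' @return a `membrane_params` list.
#' @seealso [simulate_free()], [simulate_corral()], [simulate_domain()],
#'   [simulate_pair()]
#' @export
membrane_params <- function(regime = c("free", "corral", "domain", "pair"),
                            D_free = 0.5,
                            corral_radius = 0.25,
                            barrier_height = 8,
                            barrier_width = 0.08,
                            domain_radius = 0.1,
                            domain_relaxation_time = 0.001,
                            domain_center_D = 0.005,
                            pair_spring_k = 1000,
                            pair_direct_k = 0,
                            cholesterol = 1,
                            sigma_loc = 0.04,
                            frame_period = 0.025,
                            n_frames = 400,
                            substeps = 50,
                            seed = 1L) {
  regime <- match.arg(regime)
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(is.numeric(D_free) && D_free > 0, "D_free must be > 0")
  chk(frame_period > 0, "frame_period must be > 0")
  chk(substeps >= 1 && substeps == round(substeps), "substeps must be an integer >= 1")
  chk(sigma_loc >= 0, "sigma_loc must be >= 0")
  chk(cholesterol >= 0 && cholesterol <= 1, "cholesterol must be in [0, 1]")
  chk(barrier_height >= 0, "barrier_height must be >= 0")
  chk(barrier_width > 0, "barrier_width must be > 0")
  chk(corral_radius > 0, "corral_radius must be > 0")
  chk(domain_radius > 0, "domain_radius must be > 0")
  chk(domain_relaxation_time > 0, "domain_relaxation_time must be > 0")
  chk(domain_center_D >= 0, "domain_center_D must be >= 0")
  chk(n_frames >= 2 && n_frames == round(n_frames), "n_frames must be an integer >= 2")
  if (regime == "pair") chk(pair_spring_k >= 0, "pair_spring_k must be >= 0")
  chk(pair_direct_k >= 0, "pair_direct_k must be >= 0")
  structure(list(
    regime = regime, D_free = D_free,
    corral_radius = corral_radius, barrier_height = barrier_height,
    barrier_width = barrier_width,
    domain_radius = domain_radius,
    domain_relaxation_time = domain_relaxation_time,
    domain_center_D = domain_center_D,
    pair_spring_k = pair_spring_k, pair_direct_k = pair_direct_k,
    cholesterol = cholesterol, sigma_loc = sigma_loc,
    frame_period = frame_period, n_frames = as.integer(n_frames),
    substeps = as.integer(substeps), seed = as.integer(seed)
  ), class = "membrane_params")
}

#' Cholesterol presets for drug treatments
#'
#' Maps the cholesterol-perturbing treatments used in live-cell work to a
#' dimensionless stability scale: `"native"` = 1, `"nystatin"`
#' (redistributed cholesterol) = 0.5, `"mbcd"` (methyl-beta-cyclodextrin,
#' depleted cholesterol) = 0.1. The values are interpretive presets, not
#' fitted to measurements.
#'
#' @param treatment one of `"native"`, `"nystatin"`, `"mbcd"`.
#' @return cholesterol scale in \[0, 1\].
#' @export
cholesterol_preset <- function(treatment = c("native", "nystatin", "mbcd")) {
  c(native = 1, nystatin = 0.5, mbcd = 0.1)[[match.arg(treatment)]]
}
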