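#' Model parameters
#'
#' Bundles every constant of the eco-evolutionary meta-community model:
#' the trait pool, the competition and feeding kernels, the allometric
#' population dynamics, the dispersal rule, and the nested loop lengths.
#'
#' @param trait_pool_size Size of the discrete trait pool.
#' @param traits_per_species Number of distinct traits per species.
#' @param lambda_eff Ecological efficiency \eqn{\lambda}: the proportion of
#'   consumed biomass convertible to consumer biomass.
#' @param delta_t Euler timestep \eqn{\Delta} of the population update.
#' @param a1,a2,a3 Competition-kernel constants. The kernel ranges over
#'   \eqn{[a1 \cdot a2, a1] = [0.6, 0.866]} with the defaults.
#' @param b1,b2 Feeding-kernel constants: the feeding window is a Gaussian in
#'   log-bodysize difference with mean 3 and standard deviation 1.5, so
#'   \code{b1 = 1/(1.5*sqrt(2*pi))} and \code{b2 = 2*1.5^2}.
#' @param saturation Functional-response saturation constant.
#' @param base_emigration Baseline per-step emigration fraction (before the
#'   bodysize scaling).
#' @param decline_emigration Coefficient of the decline-triggered emigration
#'   term.
#' @param founder_bodysize Bodysize \eqn{s_0} of the founder species; also
#'   the reference bodysize of the dispersal rule.
#' @param resource_bodysize Bodysize of every patch resource.
#' @param resource_abundance Fixed external population of each patch
#'   resource. Resources are non-dynamic: never updated, never dispersing.
#' @param extinction_threshold Local populations strictly below this value
#'   are culled at the end of an ecological step.
#' @param movement_threshold Minimum local population for any emigration.
#' @param evo_steps,eco_steps_per_evo,foraging_iters_per_eco Loop lengths of
#'   the nested evolutionary / ecological / foraging schedule.
#' @param foraging_tol Early-exit tolerance on the maximum absolute change
#'   in foraging efforts.
#'
#' @return An object of class \code{"model_params"} (a named list).
#' @export
#' @examples
#' p <- model_params()
#' p$a1 * p$a2  # lower endpoint of the competition kernel, 0.6
model_params <- function(trait_pool_size = 500L,
                         traits_per_species = 10L,
                         lambda_eff = 0.3,
                         delta_t = 0.1,
                         a1 = 0.866,
                         a2 = 0.6 / a1,
                         a3 = 0.6 * sqrt(2 * pi),
                         b1 = 1 / (1.5 * sqrt(2 * pi)),
                         b2 = 2 * 1.5^2,
                         saturation = 0.005,
                         base_emigration = 0.001,
                         decline_emigration = 0.03,
                         founder_bodysize = exp(1),
                         resource_bodysize = 1,
                         resource_abundance = 1e5,
                         extinction_threshold = 1,
                         movement_threshold = 1,
                         evo_steps = 10000L,
                         eco_steps_per_evo = 1000L,
                         foraging_iters_per_eco = 1000L,
                         foraging_tol = 1e-8) {
  p <- list(
    trait_pool_size = as.integer(trait_pool_size),
    traits_per_species = as.integer(traits_per_species),
    lambda_eff = lambda_eff, delta_t = delta_t,
    a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2,
    saturation = saturation,
    base_emigration = base_emigration,
    decline_emigration = decline_emigration,
    founder_bodysize = founder_bodysize,
    resource_bodysize = resource_bodysize,
    resource_abundance = resource_abundance,
    extinction_threshold = extinction_threshold,
    movement_threshold = movement_threshold,
    evo_steps = as.integer(evo_steps),
    eco_steps_per_evo = as.integer(eco_steps_per_evo),
    foraging_iters_per_eco = as.integer(foraging_iters_per_eco),
    foraging_tol = foraging_tol
  )
  class(p) <- "model_params"
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  stopifnot(
    p$trait_pool_size >= 2L,
    p$traits_per_species >= 1L,
    p$traits_per_species <= p$trait_pool_size,
    p$lambda_eff > 0, p$lambda_eff <= 1,
    p$delta_t > 0,
    p$saturation >= 0,
    p$base_emigration >= 0, p$decline_emigration >= 0,
    p$founder_bodysize > 0, p$resource_bodysize > 0,
    p$resource_abundance > 0,
    p$extinction_threshold >= 0, p$movement_threshold >= 0,
    p$foraging_tol >= 0
  )
  if (abs(p$a1 * p$a2 - 0.6) > 1e-9)
    warning("competition kernel floor a1*a2 differs from 0.6", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Meta-community model parameters\n")
  cat(sprintf("  trait pool %d, %d traits/species\n",
              x$trait_pool_size, x$traits_per_species))
  cat(sprintf("  lambda = %g, Delta = %g, saturation c = %g\n",
              x$lambda_eff, x$delta_t, x$saturation))
  cat(sprintf("  competition kernel [%g, %g], feeding window N(3, 1.5) in log-size\n",
              x$a1 * x$a2, x$a1))
  cat(sprintf("  emigration: base %g, decline %g, movement threshold %g\n",
              x$base_emigration, x$decline_emigration, x$movement_threshold))
  cat(sprintf("  resources: bodysize %g, abundance %g\n",
              x$resource_bodysize, x$resource_abundance))
  cat(sprintf("  loops: %d evolutionary x %d ecological x %d foraging (tol %g)\n",
              x$evo_steps, x$eco_steps_per_evo, x$foraging_iters_per_eco,
              x$foraging_tol))
  invisible(x)
}

#' Assembly configuration
#'
#' Loop lengths, lattice shape, seed, and the mutation kernel used by
#' \code{\link{assemble}}.
#'
#' @param evo_steps Number of evolutionary steps (speciation events).
#' @param eco_steps_per_evo Ecological steps between speciation events.
#' @param rows,cols Lattice shape.
#' @param seed Integer seed; the whole assembly is reproducible from it.
#' @param bodysize_factor Interval from which the child/parent bodysize
#'   ratio is drawn uniformly at speciation.
#'
#' @return An object of class \code{"assembly_config"}.
#' @export
assembly_config <- function(evo_steps = 10000L, eco_steps_per_evo = 1000L,
                            rows = 6L, cols = 6L, seed = NULL,
                            bodysize_factor = c(0.8, 1.2)) {
  stopifnot(evo_steps >= 1, eco_steps_per_evo >= 1, rows >= 1, cols >= 1,
            length(bodysize_factor) == 2,
            bodysize_factor[1] > 0,
            bodysize_factor[1] < bodysize_factor[2])
  structure(list(evo_steps = as.integer(evo_steps),
                 eco_steps_per_evo = as.integer(eco_steps_per_evo),
                 rows = as.integer(rows), cols = as.integer(cols),
                 seed = seed, bodysize_factor = bodysize_factor),
            class = "assembly_config")
}
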