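# Evolutionary assembly -------------------------------------------------------

#' Speciation event
#'
#' Selects one non-resource local population (a species-patch pair) with
#' probability proportional to its population size among those with
#' population of at least 1, deducts 1 from the parent, and introduces a
#' child species with population 1 in the same patch. The child inherits
#' nine of the parent's ten traits; the replaced trait is substituted by a
#' different random trait from the pool (also distinct from the retained
#' nine). The child's bodysize is the parent's multiplied by a uniform draw
#' from \code{bodysize_factor}.
#'
#' @param state A \code{"metacommunity"} state.
#' @param bodysize_factor Interval of the child/parent bodysize ratio.
#' @return The updated state; total population is conserved at the event.
#'   If no eligible parent exists the state is returned unchanged with a
#'   warning (the meta-community is extinct).
#' @export
speciation_event <- function(state, bodysize_factor = c(0.8, 1.2)) {
  act <- which(state$lattice$active)
  res <- state$species$is_resource
  N <- state$N[, act, drop = FALSE]
  N[res, ] <- 0
  N[N < 1] <- 0
  tot <- sum(N)
  if (tot <= 0) {
    warning("no eligible parent population: meta-community is extinct",
            call. = FALSE)
    return(state)
  }
  pick <- sample.int(length(N), 1L, prob = as.vector(N))
  i <- (pick - 1L) %% nrow(N) + 1L
  p <- act[(pick - 1L) %/% nrow(N) + 1L]

  parent_traits <- state$traits[i, ]
  drop_pos <- sample.int(length(parent_traits), 1L)
  keep <- parent_traits[-drop_pos]
  pool <- setdiff(seq_len(state$params$trait_pool_size), parent_traits)
  child_traits <- c(keep, pool[sample.int(length(pool), 1L)])
  child_size <- state$species$bodysize[i] *
    stats::runif(1L, bodysize_factor[1L], bodysize_factor[2L])

  state$N[i, p] <- state$N[i, p] - 1
  state <- add_species_row(state, child_traits, child_size,
                           is_resource = FALSE,
                           parent_id = state$species$id[i],
                           birth_step = state$evo_step + 1L)
  state$N[nrow(state$N), p] <- 1
  state$N_prev[i, p] <- state$N[i, p]
  state$N_prev[nrow(state$N), p] <- 1
  state <- mark_alive(state)
  state$evo_step <- state$evo_step + 1L
  state
}

#' Assemble a meta-community
#'
#' Runs the full evolutionary loop: starting from a fresh initialization
#' (36 resources and one founder on the default 6 x 6 lattice), alternates
#' \code{eco_steps_per_evo} ecological steps with one speciation event for
#' \code{evo_steps} evolutionary steps. Fully reproducible from the seed in
#' \code{config}.
#'
#' @param config \code{\link{assembly_config}}.
#' @param params \code{\link{model_params}}.
#' @param progress_every Print a progress line every this many evolutionary
#'   steps (0 for silence).
#' @return The assembled \code{"metacommunity"} state, with a per-
#'   evolutionary-step diversity log in \code{state$evo_log}.
#' @export
#' @examples
#' cfg <- assembly_config(evo_steps = 2, eco_steps_per_evo = 2,
#'                        rows = 2, cols = 2, seed = 1)
#' st <- assemble(cfg, model_params(foraging_iters_per_eco = 50))
assemble <- function(config = assembly_config(), params = model_params(),
                     progress_every = 0L) {
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- initialize_metacommunity(params, config$rows, config$cols)
  evo_log <- matrix(0, config$evo_steps, 3L)
  for (ev in seq_len(config$evo_steps)) {
    state <- run_ecology(state, config$eco_steps_per_evo, params, log = FALSE)
    state <- speciation_event(state, config$bodysize_factor)
    evo_log[ev, ] <- c(state$evo_step, global_diversity(state),
                       sum(state$N[!state$species$is_resource,
                                   state$lattice$active]))
    if (progress_every > 0L && ev %% progress_every == 0L)
      message(sprintf("evolutionary step %d: diversity %d", ev,
                      evo_log[ev, 2L]))
  }
  state$evo_log <- data.frame(evo_step = evo_log[, 1L],
                              global_diversity = evo_log[, 2L],
                              total_population = evo_log[, 3L])
  state$rng_state <- get(".Random.seed", envir = globalenv())
  state
}
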