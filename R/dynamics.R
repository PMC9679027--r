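# Ecological dynamics ---------------------------------------------------------
#
# One ecological time step is: iterated foraging fixed point in every patch,
# one Euler step of the allometric population dynamics, simultaneous
# dispersal between adjacent patches, and culling of local populations below
# the extinction threshold. N_prev (populations at the end of the previous
# ecological step) drives the decline-triggered emigration term.

#' Foraging fixed point within one patch
#'
#' Starting from efforts uniform over each consumer's locally present prey
#' set, alternately applies the ratio-dependent functional response and the
#' effort normalization (synchronously over all consumers) until the largest
#' absolute effort change falls below \code{params$foraging_tol} or
#' \code{params$foraging_iters_per_eco} iterations are reached.
#'
#' @param state A \code{"metacommunity"} state.
#' @param patch \code{c(row, col)} of a live patch.
#' @param params \code{\link{model_params}}.
#' @return A list with the locally present species rows (\code{present}),
#'   the rows of the consumers that have at least one local prey
#'   (\code{consumers}), their effort matrix \code{f} and functional
#'   response \code{g} (consumers x present), the per-consumer prey sets
#'   \code{K}, and the iteration count. Every consumer's efforts sum to 1.
#' @export
foraging_equilibrium <- function(state, patch, params = state$params) {
  p <- patch_index(state$lattice, patch[1L], patch[2L])
  if (!state$lattice$active[p]) stop("patch is not live", call. = FALSE)
  forage_patch(state, p, params)
}

forage_patch <- function(state, p, params) {
  pres <- which(state$N[, p] > 0)
  cons <- pres[!state$species$is_resource[pres]]
  if (length(cons)) {
    Sl <- state$S[cons, pres, drop = FALSE]
    has_prey <- rowSums(Sl > 0) > 0
    cons <- cons[has_prey]
    Sl <- Sl[has_prey, , drop = FALSE]
  }
  if (!length(cons)) {
    return(list(patch = p, present = pres, consumers = integer(0),
                f = matrix(0, 0, length(pres)),
                g = matrix(0, 0, length(pres)),
                K = list(), iterations = 0L))
  }
  fp <- forage_fixed_point(Sl, state$alpha[cons, cons, drop = FALSE],
                           state$N[cons, p], state$N[pres, p],
                           params$saturation,
                           params$foraging_iters_per_eco,
                           params$foraging_tol)
  K <- apply(Sl > 0, 1L, function(r) pres[r], simplify = FALSE)
  list(patch = p, present = pres, consumers = cons,
       f = fp$f, g = fp$g, K = K, iterations = fp$iterations)
}

forage_all <- function(state, params = state$params) {
  lapply(which(state$lattice$active), function(p)
    forage_patch(state, p, params))
}

#' One Euler step of the allometric population dynamics
#'
#' For every non-resource local population applies
#' \deqn{N \mapsto N + \Delta\,(-2 s_i^{-0.25} N
#'   + \lambda s_i^{-1} N \sum_j g_{i,j} s_j - \sum_k N_k g_{k,i})}
#' (mortality, feeding gain, predation loss), clamping at 0 from below.
#' Resource populations are fixed and never updated.
#'
#' @param state A \code{"metacommunity"} state.
#' @param forage List of per-patch foraging states for every live patch, as
#'   produced by \code{\link{foraging_equilibrium}}.
#' @param params \code{\link{model_params}}.
#' @return The updated state.
#' @export
population_update <- function(state, forage, params = state$params) {
  s <- state$species$bodysize
  res <- state$species$is_resource
  for (fo in forage) {
    pres <- fo$present
    if (!length(pres)) next
    p <- fo$patch
    Ncol <- state$N[, p]
    gain <- numeric(length(pres))   # sum_j g_{i,j} s_j per present species
    pred <- numeric(length(pres))   # sum_k N_k g_{k,i} per present species
    if (length(fo$consumers)) {
      gsum <- as.vector(fo$g %*% s[pres])
      gain[match(fo$consumers, pres)] <- gsum
      pred <- as.vector(crossprod(fo$g, Ncol[fo$consumers]))
    }
    upd <- pres[!res[pres]]
    if (!length(upd)) next
    k <- match(upd, pres)
    dN <- -2 * s[upd]^(-0.25) * Ncol[upd] +
      params$lambda_eff * Ncol[upd] * gain[k] / s[upd] - pred[k]
    state$N[upd, p] <- pmax(0, Ncol[upd] + params$delta_t * dN)
  }
  state
}

#' Per-neighbour emigration fraction (pure dispersal rule)
#'
#' \deqn{\mu = D^{-1} (s/s_0)\, r,\quad
#'   r = \max(0.001,\ 0.03 (N^{t-1} - N^t)/N^{t-1})}
#' when the population has declined since the previous ecological step and
#' \eqn{r = 0.001} otherwise; no movement at all below the movement
#' threshold or from a fully isolated patch. The total emigration fraction
#' \eqn{(s/s_0) r} is capped at 1.
#'
#' @param bodysize Species bodysize.
#' @param degree Number of live neighbours of the source patch.
#' @param n_prev,n_now Local population at the end of the previous
#'   ecological step and now.
#' @param params \code{\link{model_params}}.
#' @return Fraction of the local population sent to each neighbour.
#' @export
#' @examples
#' p <- model_params()
#' # base rate at the founder bodysize, degree 4
#' dispersal_fraction(p$founder_bodysize, 4, 100, 100, p)  # 0.00025
dispersal_fraction <- function(bodysize, degree, n_prev, n_now,
                               params = model_params()) {
  if (degree <= 0) return(0)
  if (n_now < params$movement_threshold) return(0)
  r <- if (n_prev > n_now && n_prev > 0)
    max(params$base_emigration,
        params$decline_emigration * (n_prev - n_now) / n_prev)
  else params$base_emigration
  min(1, bodysize / params$founder_bodysize * r) / degree
}

#' Maximum total emigration fraction per ecological step
#'
#' The cap of the dispersal rule: under maximal relative decline the decline
#' term reaches \code{decline_emigration}, so the total fraction of a local
#' population that can leave in one ecological step is
#' \eqn{\min(1, 0.03\, s / s_0)}.
#'
#' @param bodysize Species bodysize.
#' @param params \code{\link{model_params}}.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
#' @examples
#' max_emigration_fraction(3.69)   # about 4%
#' max_emigration_fraction(12.64)  # about 13.9%
max_emigration_fraction <- function(bodysize, params = model_params()) {
  min(1, params$decline_emigration * bodysize / params$founder_bodysize)
}

#' Emigration fraction of a species from a patch in a state
#'
#' Evaluates \code{\link{dispersal_fraction}} on the populations stored in
#' the state (current \code{N} against the previous ecological step's
#' \code{N_prev}).
#'
#' @param state A \code{"metacommunity"} state.
#' @param id Species id.
#' @param patch \code{c(row, col)} of the source patch.
#' @param params \code{\link{model_params}}.
#' @return Per-neighbour emigration fraction.
#' @export
emigration_fraction <- function(state, id, patch, params = state$params) {
  i <- species_row(state, id)
  p <- patch_index(state$lattice, patch[1L], patch[2L])
  if (state$species$is_resource[i]) return(0)
  dispersal_fraction(state$species$bodysize[i], state$lattice$degree[p],
                     state$N_prev[i, p], state$N[i, p], params)
}

#' Simultaneous dispersal between adjacent patches
#'
#' Applies the emigration/immigration exchange to every non-resource local
#' population at once. The step is a pure redistribution: each species'
#' global population is exactly conserved (before any culling). Resources
#' never move.
#'
#' @param state A \code{"metacommunity"} state.
#' @param params \code{\link{model_params}}.
#' @return The updated state.
#' @export
dispersal_step <- function(state, params = state$params) {
  act <- which(state$lattice$active)
  if (length(act) < 2L) return(state)
  res <- state$species$is_resource
  if (all(res)) return(state)
  N <- state$N[, act, drop = FALSE]
  Np <- state$N_prev[, act, drop = FALSE]

  r <- matrix(params$base_emigration, nrow(N), ncol(N))
  dec <- Np > N & Np > 0
  if (any(dec))
    r[dec] <- pmax(params$base_emigration,
                   params$decline_emigration * ((Np - N) / Np)[dec])
  r[N < params$movement_threshold] <- 0
  r[res, ] <- 0

  total_frac <- pmin(1, (state$species$bodysize / params$founder_bodysize) * r)
  D <- state$lattice$degree[act]
  pernb <- sweep(total_frac * N, 2L, pmax(D, 1L), "/")
  pernb[, D == 0L] <- 0

  inflow <- matrix(0, nrow(N), ncol(N))
  for (j in seq_along(act)) {
    nb <- match(state$lattice$nbrs[[act[j]]], act)
    if (length(nb))
      inflow[, j] <- rowSums(pernb[, nb, drop = FALSE])
  }
  newN <- N - total_frac * N + inflow
  newN[res, ] <- N[res, ]
  state$N[, act] <- newN
  state
}

cull_step <- function(state, params = state$params) {
  res <- state$species$is_resource
  sub <- state$N[!res, , drop = FALSE]
  sub[sub < params$extinction_threshold] <- 0
  state$N[!res, ] <- sub
  mark_alive(state)
}

#' One ecological time step
#'
#' Order: foraging fixed point in every live patch, then the Euler
#' population update, then dispersal, then culling of local populations
#' below the extinction threshold (species with zero population everywhere
#' become globally extinct), then \code{N_prev} is set to the new
#' populations.
#'
#' @param state A \code{"metacommunity"} state.
#' @param params \code{\link{model_params}}.
#' @return The updated state with its ecological step counter advanced.
#' @export
ecological_step <- function(state, params = state$params) {
  forage <- forage_all(state, params)
  state <- population_update(state, forage, params)
  state <- dispersal_step(state, params)
  state <- cull_step(state, params)
  state$N_prev <- state$N
  state$eco_step <- state$eco_step + 1L
  state
}

#' Run the ecological loop
#'
#' Applies \code{\link{ecological_step}} repeatedly, recording a global
#' diversity / total population time series in \code{state$log}.
#'
#' @param state A \code{"metacommunity"} state.
#' @param n_steps Number of ecological steps (\eqn{\ge 0}).
#' @param params \code{\link{model_params}}.
#' @param log Record the per-step time series.
#' @return The updated state.
#' @export
run_ecology <- function(state, n_steps, params = state$params, log = TRUE) {
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0L)
  if (n_steps == 0L) return(state)
  rows <- if (log) matrix(0, n_steps, 4L) else NULL
  res <- state$species$is_resource
  for (k in seq_len(n_steps)) {
    state <- ecological_step(state, params)
    if (log)
      rows[k, ] <- c(state$evo_step, state$eco_step, global_diversity(state),
                     sum(state$N[!res, state$lattice$active]))
  }
  if (log) {
    df <- data.frame(evo_step = rows[, 1L], eco_step = rows[, 2L],
                     global_diversity = rows[, 3L],
                     total_population = rows[, 4L])
    state$log <- if (is.null(state$log)) df else rbind(state$log, df)
  }
  state
}

# run at most max_steps ecological steps, exiting early once the largest
# relative change in any consumer population falls below tol
relax_ecology <- function(state, max_steps, tol = 1e-4,
                          params = state$params) {
  res <- state$species$is_resource
  for (k in seq_len(max_steps)) {
    before <- state$N[!res, , drop = FALSE]
    state <- ecological_step(state, params)
    after <- state$N[!res, , drop = FALSE]
    if (!length(after) ||
        max(abs(after - before) / pmax(before, 1)) < tol) break
  }
  state
}

#' Export the diversity time series
#'
#' Writes the per-step log as tab-separated records with columns
#' \code{evo_step}, \code{eco_step}, \code{global_diversity},
#' \code{total_population}.
#'
#' @param state A \code{"metacommunity"} state with a recorded log.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_diversity_log <- function(state, path) {
  if (is.null(state$log)) stop("state has no recorded log", call. = FALSE)
  utils::write.table(state$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
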