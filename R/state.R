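# Lattice and meta-community state -------------------------------------------
#
# Patches live on a rows x cols grid, addressed 1-based as (row, col) and
# stored column-wise in a linear index p = (col - 1) * rows + row. Adjacency
# is von-Neumann (no diagonals, no wrap); removed patches simply leave the
# active set and the adjacency is rebuilt.

patch_index <- function(lattice, x, y) (y - 1L) * lattice$rows + x

patch_coords <- function(lattice, p) {
  p <- as.integer(p)
  cbind(row = ((p - 1L) %% lattice$rows) + 1L,
        col = ((p - 1L) %/% lattice$rows) + 1L)
}

make_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1)
  lat <- list(rows = rows, cols = cols,
              active = rep(TRUE, rows * cols),
              nbrs = NULL, degree = NULL,
              resource_of = rep(NA_integer_, rows * cols))
  rebuild_adjacency(lat)
}

# neighbour lists and degrees over the active patch set
rebuild_adjacency <- function(lattice) {
  n <- lattice$rows * lattice$cols
  co <- patch_coords(lattice, seq_len(n))
  nbrs <- vector("list", n)
  for (p in seq_len(n)) {
    if (!lattice$active[p]) { nbrs[[p]] <- integer(0); next }
    x <- co[p, 1L]; y <- co[p, 2L]
    cand <- rbind(c(x - 1L, y), c(x + 1L, y), c(x, y - 1L), c(x, y + 1L))
    keep <- cand[, 1L] >= 1L & cand[, 1L] <= lattice$rows &
      cand[, 2L] >= 1L & cand[, 2L] <= lattice$cols
    q <- patch_index(lattice, cand[keep, 1L], cand[keep, 2L])
    nbrs[[p]] <- q[lattice$active[q]]
  }
  lattice$nbrs <- nbrs
  lattice$degree <- lengths(nbrs)
  lattice
}

#' Neighbours and degree of a patch
#'
#' @param state A meta-community state.
#' @param patch Length-2 vector \code{c(row, col)}.
#' @return A list with the live neighbour coordinates (one row per
#'   neighbour) and the patch degree.
#' @export
lattice_neighbors <- function(state, patch) {
  p <- patch_index(state$lattice, patch[1L], patch[2L])
  nb <- state$lattice$nbrs[[p]]
  list(neighbors = patch_coords(state$lattice, nb),
       degree = state$lattice$degree[[p]])
}

#' Number of lattice edges crossing the boundary of a patch set
#'
#' Counts edges between live patches inside and outside the given set;
#' used to characterize how exposed a block of reserves is to immigration
#' from perturbed surroundings.
#'
#' @param state A meta-community state.
#' @param patches Two-column matrix (or data.frame) of \code{(row, col)}
#'   coordinates.
#' @return Integer edge count.
#' @export
patch_set_boundary_edges <- function(state, patches) {
  patches <- as.matrix(patches)
  ids <- patch_index(state$lattice, patches[, 1L], patches[, 2L])
  sum(vapply(ids, function(p) {
    sum(!(state$lattice$nbrs[[p]] %in% ids))
  }, integer(1)))
}

# State constructor -----------------------------------------------------------
#
# The state carries the species table plus dense per-(species, patch)
# population matrices N and N_prev (previous ecological step, used by the
# decline-triggered dispersal rule), and incrementally maintained pairwise
# feeding-score and competition matrices.

new_state <- function(params, lattice, species_df, traits, N,
                      beta, evo_step = 0L, eco_step = 0L) {
  st <- list(params = params, beta = beta, lattice = lattice,
             species = species_df, traits = traits,
             S = NULL, alpha = NULL,
             N = N, N_prev = N,
             evo_step = as.integer(evo_step),
             eco_step = as.integer(eco_step),
             log = NULL, rng_state = NULL)
  class(st) <- "metacommunity"
  st$S <- matrix(0, nrow(species_df), nrow(species_df))
  st$alpha <- matrix(0, nrow(species_df), nrow(species_df))
  for (i in seq_len(nrow(species_df)))
    st <- refresh_interaction_row(st, i)
  st
}

# (re)compute row/column i of the S and alpha matrices against all species
refresh_interaction_row <- function(state, i) {
  p <- state$params
  tr_i <- state$traits[i, ]
  # v[t] = sum over i's traits of beta[., t]; pair sum with j is sum(v[traits_j])
  v <- colSums(state$beta[tr_i, , drop = FALSE])
  n <- nrow(state$species)
  ps <- vapply(seq_len(n), function(j) sum(v[state$traits[j, ]]), numeric(1))
  dl <- log(state$species$bodysize[i]) - log(state$species$bodysize)
  s_i_on_j <- feeding_kernel(ps, dl, p)
  s_j_on_i <- feeding_kernel(-ps, -dl, p)
  if (state$species$is_resource[i]) s_i_on_j[] <- 0
  s_j_on_i[state$species$is_resource] <- 0
  q <- vapply(seq_len(n), function(j) sum(state$traits[j, ] %in% tr_i),
              numeric(1))
  al <- competition_kernel(q, dl, p)
  state$S[i, ] <- s_i_on_j
  state$S[, i] <- s_j_on_i
  state$S[i, i] <- 0
  state$alpha[i, ] <- al
  state$alpha[, i] <- al
  state
}

# append one species (grows every per-species structure by one row)
add_species_row <- function(state, traits, bodysize, is_resource = FALSE,
                            parent_id = NA_integer_, birth_step = NA_integer_) {
  n <- nrow(state$species)
  id <- if (n) max(state$species$id) + 1L else 1L
  state$species <- rbind(state$species, data.frame(
    id = id, bodysize = bodysize, is_resource = is_resource,
    parent_id = as.integer(parent_id), birth_step = as.integer(birth_step),
    alive = FALSE))
  state$traits <- rbind(state$traits, as.integer(traits))
  np <- ncol(state$N)
  state$N <- rbind(state$N, rep(0, np))
  state$N_prev <- rbind(state$N_prev, rep(0, np))
  grow <- function(m) {
    m <- rbind(cbind(m, rep(0, n)), rep(0, n + 1L))
    m
  }
  state$S <- grow(state$S)
  state$alpha <- grow(state$alpha)
  refresh_interaction_row(state, n + 1L)
}

species_row <- function(state, id) match(id, state$species$id)

#' Initialize a meta-community
#'
#' Generates the trait-pair score matrix, one independently random resource
#' per patch (bodysize 1, fixed abundance), and a single founder species of
#' bodysize \eqn{e} with population 1 in patch (1, 1).
#'
#' By default the founder's trait set is redrawn until its feeding score on
#' the patch-(1, 1) resource is positive, so that assembly can proceed from
#' the founder rather than starting from a consumer that is guaranteed to
#' starve before the first speciation event; set
#' \code{viable_founder = FALSE} for a fully unconditioned draw.
#'
#' @param params \code{\link{model_params}}.
#' @param rows,cols Lattice shape.
#' @param viable_founder Redraw founder traits until it can feed on its
#'   home resource.
#' @return A \code{"metacommunity"} state.
#' @export
#' @examples
#' set.seed(1)
#' st <- initialize_metacommunity(model_params(), rows = 2, cols = 2)
#' nrow(st$species)  # 4 resources + 1 founder
initialize_metacommunity <- function(params = model_params(), rows = 6L,
                                     cols = 6L, viable_founder = TRUE) {
  lattice <- make_lattice(rows, cols)
  npatch <- lattice$rows * lattice$cols
  beta <- generate_score_matrix(params$trait_pool_size)

  traits <- t(vapply(seq_len(npatch), function(p) random_traits(params),
                     integer(params$traits_per_species)))
  species_df <- data.frame(
    id = seq_len(npatch),
    bodysize = rep(params$resource_bodysize, npatch),
    is_resource = TRUE,
    parent_id = NA_integer_, birth_step = NA_integer_,
    alive = TRUE)
  lattice$resource_of <- seq_len(npatch)

  # founder: bodysize s0, population 1 in patch (1,1)
  home <- traits[patch_index(lattice, 1L, 1L), ]
  repeat {
    ftr <- random_traits(params)
    if (!viable_founder) break
    ps <- trait_pair_sum(ftr, home, beta)
    if (ps > 0) break
  }
  traits <- rbind(traits, ftr)
  species_df <- rbind(species_df, data.frame(
    id = npatch + 1L, bodysize = params$founder_bodysize, is_resource = FALSE,
    parent_id = NA_integer_, birth_step = 0L, alive = TRUE))

  N <- matrix(0, npatch + 1L, npatch)
  for (p in seq_len(npatch)) N[p, p] <- params$resource_abundance
  N[npatch + 1L, patch_index(lattice, 1L, 1L)] <- 1

  new_state(params, lattice, species_df, traits, N, beta)
}

# global diversity: species with positive population anywhere (incl. resources)
global_diversity <- function(state) {
  sum(rowSums(state$N[, state$lattice$active, drop = FALSE]) > 0)
}

mark_alive <- function(state) {
  state$species$alive <-
    rowSums(state$N[, state$lattice$active, drop = FALSE]) > 0
  state
}

#' @export
print.metacommunity <- function(x, ...) {
  cat(sprintf("Meta-community: %d x %d lattice (%d live patches)\n",
              x$lattice$rows, x$lattice$cols, sum(x$lattice$active)))
  cat(sprintf("  %d species recorded (%d resources), global diversity %d\n",
              nrow(x$species), sum(x$species$is_resource),
              global_diversity(x)))
  cat(sprintf("  evolutionary step %d, ecological step %d\n",
              x$evo_step, x$eco_step))
  invisible(x)
}

#' @export
summary.metacommunity <- function(object, ...) {
  act <- object$lattice$active
  live <- rowSums(object$N[, act, drop = FALSE]) > 0
  cons <- live & !object$species$is_resource
  res <- list(
    patches = sum(act),
    global_diversity = global_diversity(object),
    consumers = sum(cons),
    resources = sum(live & object$species$is_resource),
    total_population = sum(object$N[!object$species$is_resource, act]),
    bodysize_range = if (any(cons))
      range(object$species$bodysize[cons]) else c(NA_real_, NA_real_),
    evo_step = object$evo_step, eco_step = object$eco_step)
  class(res) <- "summary.metacommunity"
  res
}

#' @export
print.summary.metacommunity <- function(x, ...) {
  cat(sprintf("%d live patches, global diversity %d (%d consumers + %d resources)\n",
              x$patches, x$global_diversity, x$consumers, x$resources))
  cat(sprintf("total consumer population %.4g", x$total_population))
  if (!is.na(x$bodysize_range[1]))
    cat(sprintf(", bodysizes %.3g-%.3g", x$bodysize_range[1],
                x$bodysize_range[2]))
  cat(sprintf("\nevolutionary step %d, ecological step %d\n",
              x$evo_step, x$eco_step))
  invisible(x)
}

#' @export
plot.metacommunity <- function(x, ...) {
  if (is.null(x$log) || !nrow(x$log))
    stop("no diversity log recorded yet; run the ecology first", call. = FALSE)
  graphics::plot(seq_len(nrow(x$log)), x$log$global_diversity, type = "l",
                 xlab = "ecological step (logged)",
                 ylab = "global diversity", ...)
  invisible(x)
}
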