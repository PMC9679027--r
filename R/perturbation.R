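# Perturbation experiments ----------------------------------------------------
#
# Every experiment operates on a copy of the supplied state (R's copy
# semantics make the reset contract automatic): a full deletion sweep
# leaves the source snapshot identical.

new_perturbation_record <- function(kind, target, before, after,
                                    pre_nonres, secondary,
                                    patches_invaded = NA_integer_,
                                    mode = NA_character_, extra = list()) {
  rec <- c(list(kind = kind, target = target, mode = mode,
                diversity_before = before, diversity_after = after,
                secondary_extinctions = secondary,
                relative_secondary_extinctions =
                  if (pre_nonres > 1L) secondary / (pre_nonres - 1L) else 0,
                patches_invaded = patches_invaded), extra)
  class(rec) <- "perturbation_record"
  rec
}

#' @export
print.perturbation_record <- function(x, ...) {
  cat(sprintf("%s perturbation of %s%s\n", x$kind,
              paste(x$target, collapse = ","),
              if (!is.na(x$mode)) paste0(" (", x$mode, ")") else ""))
  cat(sprintf("  global diversity %d -> %d; %d secondary extinctions (%.4f relative)\n",
              x$diversity_before, x$diversity_after,
              x$secondary_extinctions, x$relative_secondary_extinctions))
  if (!is.na(x$patches_invaded))
    cat(sprintf("  patches invaded: %d\n", x$patches_invaded))
  invisible(x)
}

extant_rows <- function(state) {
  which(rowSums(state$N[, state$lattice$active, drop = FALSE]) > 0)
}

#' Delete one species and record the secondary extinctions
#'
#' On a copy, zeroes every local population of the species, relaxes the
#' ecology, and counts the non-resource species (other than the primary)
#' that were extant before and are globally extinct afterwards. The
#' supplied state is never modified.
#'
#' @param state A \code{"metacommunity"} state.
#' @param id Species id of an extant non-resource species.
#' @param relax_steps Maximum ecological relaxation steps (with convergence
#'   early exit).
#' @param keep_state Attach the relaxed post-deletion state to the record
#'   (needed for the deletion-then-reintroduction invasion protocol).
#' @param params \code{\link{model_params}}.
#' @return A \code{"perturbation_record"}.
#' @export
delete_species <- function(state, id, relax_steps = 100L,
                           keep_state = FALSE, params = state$params) {
  i <- species_row(state, id)
  if (is.na(i)) stop("unknown species id", call. = FALSE)
  if (state$species$is_resource[i])
    stop("cannot delete a resource", call. = FALSE)
  before <- global_diversity(state)
  pre <- extant_rows(state)
  pre_nonres <- sum(!state$species$is_resource[pre])
  if (!(i %in% pre)) {
    rec <- new_perturbation_record("species-delete", id, before, before,
                                   pre_nonres, 0L)
    rec$note <- "species already extinct: no-op"
    return(rec)
  }
  work <- state
  work$N[i, ] <- 0
  work$N_prev[i, ] <- 0
  work <- mark_alive(work)
  work <- relax_ecology(work, relax_steps, params = params)
  post <- extant_rows(work)
  lost <- setdiff(setdiff(pre, post), i)
  secondary <- sum(!state$species$is_resource[lost])
  rec <- new_perturbation_record("species-delete", id, before,
                                 global_diversity(work),
                                 pre_nonres, secondary)
  if (keep_state) rec$state <- work
  rec
}

#' Reintroduce a species to every patch
#'
#' The whole-network invasion protocol: sets the species' population to
#' \code{intro_pop} in every live patch, relaxes the ecology, and records
#' the patches successfully invaded (population at least 1 at the end) plus
#' the secondary extinctions among the other species. Typically run on the
#' post-deletion state from \code{delete_species(..., keep_state = TRUE)}.
#'
#' @param state A \code{"metacommunity"} state.
#' @param id Species id (any recorded non-resource species).
#' @param intro_pop Introduced sub-population per patch.
#' @param relax_steps Maximum ecological relaxation steps.
#' @param keep_state Attach the relaxed state to the record.
#' @param params \code{\link{model_params}}.
#' @return A \code{"perturbation_record"} with \code{patches_invaded}.
#' @export
reintroduce_everywhere <- function(state, id, intro_pop = 1.0,
                                   relax_steps = 100L, keep_state = FALSE,
                                   params = state$params) {
  i <- species_row(state, id)
  if (is.na(i)) stop("unknown species id", call. = FALSE)
  if (state$species$is_resource[i])
    stop("cannot reintroduce a resource", call. = FALSE)
  before <- global_diversity(state)
  pre <- setdiff(extant_rows(state), i)
  pre_nonres <- sum(!state$species$is_resource[pre]) + 1L
  work <- state
  act <- work$lattice$active
  work$N[i, act] <- intro_pop
  work$N_prev[i, act] <- intro_pop
  work <- mark_alive(work)
  work <- relax_ecology(work, relax_steps, params = params)
  post <- extant_rows(work)
  lost <- setdiff(pre, post)
  secondary <- sum(!state$species$is_resource[lost])
  rec <- new_perturbation_record("species-invade", id, before,
                                 global_diversity(work), pre_nonres,
                                 secondary,
                                 patches_invaded = sum(work$N[i, act] >= 1))
  if (keep_state) rec$state <- work
  rec
}

#' Generate random species for invasion baselines
#'
#' Species with random distinct traits; bodysizes either uniform on a
#' range (the observed bodysize range of the assembled meta-communities by
#' default) or resampled with replacement from a supplied empirical list.
#'
#' @param n Number of species.
#' @param bodysize_dist \code{"uniform"} or \code{"resample"}.
#' @param range Bodysize bounds for the uniform mode.
#' @param empirical Bodysize list for the resample mode.
#' @param params \code{\link{model_params}}.
#' @return A list with a species data.frame and a trait matrix.
#' @export
generate_random_species <- function(n, bodysize_dist = c("uniform",
                                                         "resample"),
                                    range = c(0.81, 12.64),
                                    empirical = NULL,
                                    params = model_params()) {
  bodysize_dist <- match.arg(bodysize_dist)
  stopifnot(n >= 1)
  sizes <- switch(bodysize_dist,
    uniform = stats::runif(n, range[1L], range[2L]),
    resample = {
      if (is.null(empirical) || !length(empirical))
        stop("resample mode needs a non-empty empirical bodysize list",
             call. = FALSE)
      sample(empirical, n, replace = TRUE)
    })
  traits <- t(vapply(seq_len(n), function(k) random_traits(params),
                     integer(params$traits_per_species)))
  list(species = data.frame(id = seq_len(n), bodysize = sizes,
                            is_resource = FALSE),
       traits = traits)
}

#' Introduce a foreign species into a state
#'
#' Appends a species (random or hand-made) to the state's species table,
#' computing its feeding and competition scores against all residents, and
#' places \code{intro_pop} individuals in every live patch.
#'
#' @param state A \code{"metacommunity"} state.
#' @param traits Trait vector of the arriving species.
#' @param bodysize Its bodysize.
#' @param intro_pop Introduced sub-population per patch.
#' @return The modified state (a copy) with the new species last.
#' @export
introduce_species <- function(state, traits, bodysize, intro_pop = 1.0) {
  state <- add_species_row(state, traits, bodysize, is_resource = FALSE,
                           birth_step = state$evo_step)
  i <- nrow(state$N)
  state$N[i, state$lattice$active] <- intro_pop
  state$N_prev[i, state$lattice$active] <- intro_pop
  mark_alive(state)
}

#' Perturb a single patch
#'
#' Four modes: the disruption is a temporary pulse (the patch stays live
#' and open to recolonization) or a permanent press (the patch and its
#' resource are removed and neighbour degrees drop), and the residents are
#' either eliminated or displaced (divided evenly among the live
#' neighbours, added to their standing populations, then zeroed locally).
#' Displacing from a fully isolated patch falls back to elimination with a
#' warning. The supplied state is never modified.
#'
#' @param state A \code{"metacommunity"} state.
#' @param patch \code{c(row, col)} of a live patch.
#' @param permanence \code{"temporary"} or \code{"permanent"}.
#' @param fate \code{"eliminate"} or \code{"displace"}.
#' @param relax_steps Maximum ecological relaxation steps.
#' @param keep_state Attach the relaxed state to the record.
#' @param params \code{\link{model_params}}.
#' @return A \code{"perturbation_record"} with resident bookkeeping
#'   (\code{residents}, \code{unique_residents}, \code{unique_neighbors},
#'   \code{surviving_residents}).
#' @export
perturb_patch <- function(state, patch,
                          permanence = c("temporary", "permanent"),
                          fate = c("eliminate", "displace"),
                          relax_steps = 100L, keep_state = FALSE,
                          params = state$params) {
  permanence <- match.arg(permanence)
  fate <- match.arg(fate)
  p <- patch_index(state$lattice, patch[1L], patch[2L])
  if (!state$lattice$active[p]) stop("patch is not live", call. = FALSE)

  before <- global_diversity(state)
  pre <- extant_rows(state)
  pre_nonres <- sum(!state$species$is_resource[pre])
  res <- state$species$is_resource
  residents <- which(state$N[, p] > 0 & !res)
  nb <- state$lattice$nbrs[[p]]
  present_nb <- if (length(nb))
    which(rowSums(state$N[, nb, drop = FALSE] > 0) > 0 & !res) else integer(0)
  other <- setdiff(which(state$lattice$active), p)
  elsewhere <- if (length(other))
    which(rowSums(state$N[, other, drop = FALSE] > 0) > 0) else integer(0)
  unique_residents <- setdiff(residents, elsewhere)
  unique_neighbors <- setdiff(present_nb, residents)

  work <- state
  if (fate == "displace" && !length(nb)) {
    warning("displacement from an isolated patch falls back to elimination",
            call. = FALSE)
    fate <- "eliminate"
  }
  if (fate == "displace") {
    share <- work$N[residents, p] / length(nb)
    for (q in nb) work$N[residents, q] <- work$N[residents, q] + share
    work$N_prev[residents, nb] <- work$N[residents, nb]
  }
  work$N[residents, p] <- 0
  work$N_prev[residents, p] <- 0
  if (permanence == "permanent") {
    rid <- work$lattice$resource_of[p]
    if (!is.na(rid)) {
      r <- species_row(work, rid)
      work$N[r, p] <- 0
      work$N_prev[r, p] <- 0
    }
    work$lattice$active[p] <- FALSE
    work$lattice <- rebuild_adjacency(work$lattice)
  }
  work <- mark_alive(work)
  work <- relax_ecology(work, relax_steps, params = params)

  post <- extant_rows(work)
  lost <- setdiff(pre, post)
  secondary <- sum(!state$species$is_resource[lost])
  rec <- new_perturbation_record(
    "patch", patch, before, global_diversity(work), pre_nonres, secondary,
    mode = paste(permanence, fate, sep = "-"),
    extra = list(residents = length(residents),
                 unique_residents = length(unique_residents),
                 unique_neighbors = length(unique_neighbors),
                 surviving_residents = sum(residents %in% post)))
  if (keep_state) rec$state <- work
  rec
}

#' Displacement-versus-elimination differential of a patch
#'
#' Runs both fates of the same permanence from the same snapshot and
#' returns the relative global-diversity change under displacement minus
#' that under elimination. A positive value means re-settling the affected
#' residents into neighbouring patches preserves more global biodiversity
#' than eliminating them.
#'
#' @inheritParams perturb_patch
#' @return Signed fraction.
#' @export
displacement_vs_elimination_differential <- function(state, patch,
                                                     permanence = "temporary",
                                                     relax_steps = 100L,
                                                     params = state$params) {
  rel <- function(rec)
    (rec$diversity_after - rec$diversity_before) / rec$diversity_before
  d <- perturb_patch(state, patch, permanence, "displace", relax_steps,
                     params = params)
  e <- perturb_patch(state, patch, permanence, "eliminate", relax_steps,
                     params = params)
  rel(d) - rel(e)
}
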