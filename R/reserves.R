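# Reserve schemes and sequential disruption -----------------------------------

#' Resolve a nature-reserve scheme to a patch set
#'
#' Six patches are designated reserves, exempt from perturbation. Built-in
#' named layouts on the 6 x 6 default lattice:
#' \describe{
#'   \item{none}{the control: no reserves.}
#'   \item{remote-block}{the 2 x 3 corner block rows 1-2, columns 1-3; its
#'     5 boundary edges are the fewest of any 6-patch block, and patches
#'     (1,1) and (1,2) have no non-reserve neighbour at all.}
#'   \item{central-block}{a fully interior 2 x 3 block (10 boundary
#'     edges).}
#'   \item{max-dispersal-individuals}{six pairwise non-adjacent patches
#'     with summed degree 20.}
#'   \item{highest-diversity}{the six patches with the highest local
#'     diversity on the supplied state (ties broken by row-major order).}
#'   \item{lowest-average-range}{the six patches whose resident species
#'     have the lowest average range (ties row-major).}
#' }
#' The two dynamic selectors are resolved once, on the state supplied here,
#' and stay fixed for a whole perturbation sequence.
#'
#' @param state A \code{"metacommunity"} state.
#' @param scheme Scheme name, or a list \code{list(name =, patches =)} with
#'   a custom two-column \code{(row, col)} matrix.
#' @param n_reserves Number of reserves (6 on the default lattice).
#' @return Object of class \code{"reserve_scheme"}: name plus a resolved
#'   \code{n_reserves x 2} coordinate matrix.
#' @export
resolve_reserves <- function(state, scheme = "none", n_reserves = 6L) {
  if (is.list(scheme)) {
    patches <- as.matrix(scheme$patches)
    name <- scheme$name %||% "custom"
  } else {
    name <- scheme
    patches <- switch(scheme,
      "none" = matrix(integer(0), 0L, 2L),
      "remote-block" = cbind(rep(1:2, each = 3L), rep(1:3, 2L)),
      "central-block" = cbind(rep(3:4, each = 3L), rep(2:4, 2L)),
      "max-dispersal-individuals" =
        rbind(c(2, 2), c(2, 5), c(5, 2), c(5, 5), c(1, 1), c(6, 6)),
      "highest-diversity" = top_patches(state, n_reserves, "diversity"),
      "lowest-average-range" = top_patches(state, n_reserves, "range"),
      stop("unknown reserve scheme: ", scheme, call. = FALSE))
  }
  if (name != "none") {
    ids <- patch_index(state$lattice, patches[, 1L], patches[, 2L])
    if (nrow(patches) != n_reserves)
      stop("scheme must resolve to exactly ", n_reserves, " reserves",
           call. = FALSE)
    if (sum(state$lattice$active) < n_reserves)
      stop("fewer live patches than reserves", call. = FALSE)
    if (!all(state$lattice$active[ids]))
      stop("reserves must be live patches", call. = FALSE)
  }
  structure(list(name = name, patches = patches), class = "reserve_scheme")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rank live patches by local diversity (descending) or by average resident
# range (ascending); ties broken by row-major (row, col) order
top_patches <- function(state, n, what) {
  act <- which(state$lattice$active)
  co <- patch_coords(state$lattice, act)
  res <- state$species$is_resource
  rng <- species_range(state)
  score <- vapply(seq_along(act), function(k) {
    p <- act[k]
    if (what == "diversity") sum(state$N[, p] > 0)
    else {
      cons <- which(state$N[, p] > 0 & !res)
      if (length(cons)) mean(rng[cons]) else Inf
    }
  }, numeric(1))
  ord <- order(if (what == "diversity") -score else score,
               co[, 1L], co[, 2L])
  co[ord[seq_len(n)], , drop = FALSE]
}

#' Plan a perturbation sequence
#'
#' @param permanence \code{"temporary"} (pulse; patches may be hit
#'   repeatedly) or \code{"permanent"} (press; each hit removes a patch).
#' @param fate \code{"eliminate"} or \code{"displace"}.
#' @param scheme Reserve scheme name (see \code{\link{resolve_reserves}}).
#' @param rule \code{"targeted"} (always the currently most diverse
#'   eligible patch) or \code{"random"}.
#' @param n_events Number of perturbation events; defaults to 1000 for
#'   temporary sequences and to the number of non-reserve patches for
#'   permanent ones (30 with 6 reserves on the 6 x 6 lattice, 36 without).
#' @param seed Seed for the random target draws.
#' @param replicate Replicate index (bookkeeping only).
#' @return An object of class \code{"sequence_plan"}.
#' @export
sequence_plan <- function(permanence = c("temporary", "permanent"),
                          fate = c("eliminate", "displace"),
                          scheme = "none",
                          rule = c("targeted", "random"),
                          n_events = NULL, seed = NULL, replicate = 1L) {
  permanence <- match.arg(permanence)
  fate <- match.arg(fate)
  rule <- match.arg(rule)
  structure(list(permanence = permanence, fate = fate, scheme = scheme,
                 rule = rule, n_events = n_events, seed = seed,
                 replicate = as.integer(replicate)),
            class = "sequence_plan")
}

#' Run a sequential patch-disruption experiment
#'
#' Iterates \code{\link{perturb_patch}} over a sequence of targets with
#' ecological relaxation between events. Reserves resolved on the initial
#' state are exempt throughout. The targeted rule picks the currently
#' highest-diversity eligible patch (ties by smallest row-major
#' coordinate); the random rule draws uniformly from the eligible patches.
#' The sequence terminates early if no eligible patch remains.
#'
#' @param state A \code{"metacommunity"} state.
#' @param plan A \code{\link{sequence_plan}}.
#' @param relax_steps Maximum ecological relaxation steps between events.
#' @param params \code{\link{model_params}}.
#' @return An object of class \code{"sequence_result"}: the per-event
#'   trajectory (target, global diversity), the resolved reserves, the
#'   final diversity relative to the start, and a status.
#' @export
run_sequence <- function(state, plan, relax_steps = 100L,
                         params = state$params) {
  if (!is.null(plan$seed)) set.seed(plan$seed)
  reserves <- resolve_reserves(state, plan$scheme)
  rid <- if (nrow(reserves$patches))
    patch_index(state$lattice, reserves$patches[, 1L],
                reserves$patches[, 2L]) else integer(0)
  n_events <- plan$n_events %||% (if (plan$permanence == "temporary") 1000L
                                  else sum(state$lattice$active) - length(rid))
  start_div <- global_diversity(state)
  traj <- matrix(NA_real_, n_events, 3L)
  status <- "completed"
  work <- state
  for (ev in seq_len(n_events)) {
    eligible <- setdiff(which(work$lattice$active), rid)
    if (!length(eligible)) { status <- "exhausted"; break }
    target <- if (plan$rule == "targeted") {
      div <- vapply(eligible, function(p) sum(work$N[, p] > 0), numeric(1))
      co <- patch_coords(work$lattice, eligible)
      eligible[order(-div, co[, 1L], co[, 2L])[1L]]
    } else {
      eligible[sample.int(length(eligible), 1L)]
    }
    co <- patch_coords(work$lattice, target)
    rec <- perturb_patch(work, co[1L, ], plan$permanence, plan$fate,
                         relax_steps, keep_state = TRUE, params = params)
    work <- rec$state
    traj[ev, ] <- c(co[1L, 1L], co[1L, 2L], rec$diversity_after)
  }
  done <- !is.na(traj[, 3L])
  structure(list(
    plan = plan, reserves = reserves,
    trajectory = data.frame(event = seq_len(n_events)[done],
                            row = traj[done, 1L], col = traj[done, 2L],
                            global_diversity = traj[done, 3L]),
    diversity_start = start_div,
    diversity_final = if (any(done)) traj[max(which(done)), 3L] else start_div,
    relative_final = (if (any(done)) traj[max(which(done)), 3L]
                      else start_div) / start_div,
    n_events = sum(done), status = status,
    final_state = work), class = "sequence_result")
}

#' @export
print.sequence_result <- function(x, ...) {
  cat(sprintf("%s-%s sequence (%s rule, scheme %s): %d events, %s\n",
              x$plan$permanence, x$plan$fate, x$plan$rule,
              x$reserves$name, x$n_events, x$status))
  cat(sprintf("  global diversity %d -> %d (relative %.3f)\n",
              x$diversity_start, x$diversity_final, x$relative_final))
  invisible(x)
}

#' Enumerate the full sequential-disruption experiment plan
#'
#' Tabulates every (meta-community, perturbation mode, reserve scheme,
#' replicate) sequence with its event count - 1000 for temporary
#' sequences, and one event per non-reserve patch for permanent ones -
#' and returns the grand totals without running anything.
#'
#' @param n_metacommunities Number of assembled meta-communities.
#' @param schemes Character vector of scheme names; \code{"none"} is the
#'   reserve-free control.
#' @param replicates Named vector \code{c(targeted =, random =)} of
#'   sequence replicates per cell.
#' @param n_patches Lattice size.
#' @param n_reserves Reserves per non-control scheme.
#' @param temporary_events Events per temporary sequence.
#' @return A list with the plan table, \code{n_sequences}, and
#'   \code{total_events}.
#' @export
#' @examples
#' enumerate_experiment_plan()$total_events  # 4420680
enumerate_experiment_plan <- function(n_metacommunities = 15L,
                                      schemes = c("none", "remote-block",
                                                  "central-block",
                                                  "max-dispersal-individuals",
                                                  paste0("fixed-", 1:7),
                                                  "highest-diversity",
                                                  "lowest-average-range"),
                                      replicates = c(targeted = 1L,
                                                     random = 10L),
                                      n_patches = 36L, n_reserves = 6L,
                                      temporary_events = 1000L) {
  modes <- expand.grid(permanence = c("temporary", "permanent"),
                       fate = c("eliminate", "displace"),
                       stringsAsFactors = FALSE)
  rules <- rep(names(replicates), replicates)
  tab <- expand.grid(metacommunity = seq_len(n_metacommunities),
                     mode = paste(modes$permanence, modes$fate, sep = "-"),
                     scheme = schemes,
                     replicate = seq_along(rules),
                     stringsAsFactors = FALSE)
  tab$rule <- rules[tab$replicate]
  tab$n_events <- ifelse(grepl("^temporary", tab$mode), temporary_events,
                         ifelse(tab$scheme == "none", n_patches,
                                n_patches - n_reserves))
  list(table = tab, n_sequences = nrow(tab),
       total_events = sum(tab$n_events))
}
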