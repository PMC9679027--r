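# Community and species descriptors ------------------------------------------

#' Realized feeding links of a patch food web
#'
#' A consumer is linked to a locally present prey species when its feeding
#' score is positive and its converged foraging effort on that prey exceeds
#' \code{effort_threshold}. The adaptive forager abandons nominally possible
#' prey, so a pure score census would overcount feeding relationships; the
#' threshold is configurable and reported with the census.
#'
#' @param state A \code{"metacommunity"} state.
#' @param patch \code{c(row, col)} of a live patch.
#' @param effort_threshold Minimum converged effort for a link.
#' @param params \code{\link{model_params}}.
#' @return A list: \code{present} (species rows in the patch), \code{links}
#'   (two-column matrix of consumer/prey species rows), and the threshold.
#' @export
patch_links <- function(state, patch, effort_threshold = 0.01,
                        params = state$params) {
  fo <- foraging_equilibrium(state, patch, params)
  links <- which(fo$f > effort_threshold & fo$g > 0, arr.ind = TRUE)
  list(present = fo$present,
       links = cbind(consumer = fo$consumers[links[, 1L]],
                     prey = fo$present[links[, 2L]]),
       effort_threshold = effort_threshold)
}

#' Shortest-chain trophic levels of a patch food web
#'
#' The resource has level 0; every consumer's level is one more than the
#' minimum level among its realized local prey (the shortest food chain
#' down to the resource). Consumers with no realized chain to the resource
#' are flagged \code{NA}.
#'
#' @param web A link census from \code{\link{patch_links}}.
#' @param resource_rows Species rows that are resources.
#' @return Named numeric vector of levels indexed by species row; \code{NA}
#'   for unreachable consumers.
#' @export
shortest_chain_trophic_level <- function(web, resource_rows) {
  pres <- web$present
  lv <- rep(NA_real_, length(pres))
  names(lv) <- pres
  lv[pres %in% resource_rows] <- 0
  if (!nrow(web$links)) return(lv)
  # breadth-first relaxation over the consumer -> prey digraph
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(web$links))) {
      ci <- match(web$links[r, 1L], pres)
      pi <- match(web$links[r, 2L], pres)
      if (!is.na(lv[pi])) {
        cand <- lv[pi] + 1
        if (is.na(lv[ci]) || cand < lv[ci]) {
          lv[ci] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lv
}

#' Fraction of local omnivores
#'
#' An omnivore feeds on at least two local species with different
#' shortest-chain trophic levels.
#'
#' @param web A link census from \code{\link{patch_links}}.
#' @param levels Levels from \code{\link{shortest_chain_trophic_level}}.
#' @param resource_rows Species rows that are resources.
#' @return Fraction of non-resource present species that are omnivores
#'   (0 if there are none).
#' @export
omnivory_fraction <- function(web, levels, resource_rows) {
  cons <- setdiff(web$present, resource_rows)
  if (!length(cons)) return(0)
  omn <- vapply(cons, function(i) {
    prey <- web$links[web$links[, 1L] == i, 2L]
    if (length(prey) < 2L) return(FALSE)
    pl <- levels[as.character(prey)]
    pl <- pl[!is.na(pl)]
    length(unique(pl)) >= 2L
  }, logical(1))
  mean(omn)
}

#' Connectance and link density of a patch food web
#'
#' Link density is realized links per species; connectance is the realized
#' fraction \eqn{L/S^2} of all directed links (the denominator includes
#' self-links, which can never be realized).
#'
#' @param web A link census from \code{\link{patch_links}}.
#' @return Named vector with \code{connectance} and \code{link_density}.
#' @export
connectance_and_link_density <- function(web) {
  S <- length(web$present)
  L <- nrow(web$links)
  c(connectance = if (S > 0) L / S^2 else 0,
    link_density = if (S > 0) L / S else 0)
}

#' True local diversity of a patch
#'
#' The number of species (including the resource) that survive when the
#' patch is fully isolated from the rest of the meta-community: satellite
#' populations sustained only by immigration perish. Operates on a copy;
#' the original state is untouched.
#'
#' @param state A \code{"metacommunity"} state.
#' @param patch \code{c(row, col)} of a live patch.
#' @param relax_steps Ecological steps of isolated relaxation (with
#'   convergence early exit).
#' @param params \code{\link{model_params}}.
#' @return Integer species count.
#' @export
true_local_diversity <- function(state, patch, relax_steps = 200L,
                                 params = state$params) {
  p <- patch_index(state$lattice, patch[1L], patch[2L])
  if (!state$lattice$active[p]) stop("patch is not live", call. = FALSE)
  iso <- state
  iso$lattice$active[] <- FALSE
  iso$lattice$active[p] <- TRUE
  iso$lattice <- rebuild_adjacency(iso$lattice)
  iso$N[, -p] <- 0
  iso$N_prev[, -p] <- 0
  iso <- mark_alive(iso)
  if (relax_steps > 0L) iso <- relax_ecology(iso, relax_steps, params = params)
  sum(iso$N[, p] > 0)
}

#' Per-patch community metrics
#'
#' One row per live patch with the local descriptors: diversity (including
#' the resource), link density and connectance of the realized local web,
#' average and maximum shortest-chain trophic level, omnivory fraction,
#' and average population, bodysize, and range of the resident non-resource
#' species. True local diversity (an isolation experiment per patch) is
#' optional because it costs a relaxation run per patch.
#'
#' @param state A \code{"metacommunity"} state.
#' @param effort_threshold Link census threshold, see
#'   \code{\link{patch_links}}.
#' @param include_true_diversity Also compute
#'   \code{\link{true_local_diversity}} per patch.
#' @param relax_steps Relaxation length for the isolation experiment.
#' @param params \code{\link{model_params}}.
#' @return A data.frame with one row per live patch.
#' @export
patch_metrics <- function(state, effort_threshold = 0.01,
                          include_true_diversity = FALSE,
                          relax_steps = 200L, params = state$params) {
  act <- which(state$lattice$active)
  res_rows <- which(state$species$is_resource)
  rng <- species_range(state)
  out <- lapply(act, function(p) {
    co <- patch_coords(state$lattice, p)
    web <- patch_links(state, co[1L, ], effort_threshold, params)
    lv <- shortest_chain_trophic_level(web, res_rows)
    cl <- connectance_and_link_density(web)
    cons <- setdiff(web$present, res_rows)
    clv <- lv[as.character(cons)]
    clv <- clv[!is.na(clv)]
    data.frame(
      row = co[1L, 1L], col = co[1L, 2L],
      local_diversity = length(web$present),
      true_local_diversity = if (include_true_diversity)
        true_local_diversity(state, co[1L, ], relax_steps, params)
      else NA_integer_,
      link_density = unname(cl["link_density"]),
      connectance = unname(cl["connectance"]),
      avg_sctl = if (length(clv)) mean(clv) else NA_real_,
      max_sctl = if (length(clv)) max(clv) else NA_real_,
      omnivory_fraction = omnivory_fraction(web, lv, res_rows),
      avg_population = if (length(cons)) mean(state$N[cons, p]) else NA_real_,
      avg_bodysize = if (length(cons))
        mean(state$species$bodysize[cons]) else NA_real_,
      avg_range = if (length(cons)) mean(rng[cons]) else NA_real_)
  })
  do.call(rbind, out)
}

# patches (among live ones) where each species row holds population >= 1
species_range <- function(state) {
  rowSums(state$N[, state$lattice$active, drop = FALSE] >= 1)
}

#' Per-species metrics
#'
#' One row per extant non-resource species: range (patches held with
#' population at least 1), total population, biomass, population-weighted
#' shortest-chain trophic level across its local populations, and bodysize.
#'
#' @param state A \code{"metacommunity"} state.
#' @param effort_threshold Link census threshold.
#' @param params \code{\link{model_params}}.
#' @return A data.frame with one row per extant consumer species.
#' @export
species_metrics <- function(state, effort_threshold = 0.01,
                            params = state$params) {
  act <- which(state$lattice$active)
  res_rows <- which(state$species$is_resource)
  alive <- which(state$species$alive & !state$species$is_resource)
  # local SCTLs once per patch
  lvs <- lapply(act, function(p) {
    co <- patch_coords(state$lattice, p)
    shortest_chain_trophic_level(
      patch_links(state, co[1L, ], effort_threshold, params), res_rows)
  })
  out <- lapply(alive, function(i) {
    pops <- state$N[i, act]
    w <- 0; wl <- 0
    for (k in seq_along(act)) {
      if (pops[k] > 0) {
        l <- lvs[[k]][as.character(i)]
        if (!is.na(l)) { w <- w + pops[k]; wl <- wl + pops[k] * l }
      }
    }
    data.frame(id = state$species$id[i],
               range = sum(pops >= 1),
               population = sum(pops),
               biomass = sum(pops) * state$species$bodysize[i],
               sctl_weighted = if (w > 0) wl / w else NA_real_,
               bodysize = state$species$bodysize[i])
  })
  do.call(rbind, out)
}

#' Species-area curve over all lattice rectangles
#'
#' Enumerates every axis-aligned i x j rectangle of the full lattice,
#' computes the mean gamma-diversity (species present with population at
#' least 1, including resources) per distinct rectangle area, and fits the
#' power law \eqn{S = c A^z} by least squares on \eqn{(\ln A, \ln S)}.
#'
#' @param state A \code{"metacommunity"} state; every patch must be live
#'   (the enumeration is over a full rectangular lattice).
#' @return A list: \code{table} (area, mean diversity, number of
#'   placements), \code{c}, \code{z}, and \code{r_squared} of the fit.
#' @export
species_area_curve <- function(state) {
  lat <- state$lattice
  if (!all(lat$active))
    stop("species-area enumeration requires a full rectangular lattice",
         call. = FALSE)
  pres <- state$N >= 1
  areas <- list()
  for (i in seq_len(lat$rows)) for (j in seq_len(lat$cols)) {
    a <- i * j
    key <- as.character(a)
    for (x0 in seq_len(lat$rows - i + 1L)) for (y0 in seq_len(lat$cols - j + 1L)) {
      cells <- as.vector(outer(x0:(x0 + i - 1L), (y0:(y0 + j - 1L)),
                               function(x, y) patch_index(lat, x, y)))
      gam <- sum(rowSums(pres[, cells, drop = FALSE]) > 0)
      areas[[key]] <- c(areas[[key]], gam)
    }
  }
  a <- as.integer(names(areas))
  ord <- order(a)
  tab <- data.frame(area = a[ord],
                    mean_diversity = vapply(areas[ord], mean, numeric(1)),
                    n_rectangles = lengths(areas[ord]))
  ok <- tab$mean_diversity > 0
  fit <- stats::lm(log(mean_diversity) ~ log(area), data = tab[ok, ])
  list(table = tab,
       c = unname(exp(stats::coef(fit)[1L])),
       z = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared)
}

#' Fit a decay law to an extinction-event-size distribution
#'
#' Histograms the event sizes and fits the chosen law by least squares over
#' the bins from the peak-frequency bin to the last non-zero bin: log-log
#' for the power law, semi-log for the exponential, and a direct nonlinear
#' Gaussian fit for the normal law.
#'
#' @param sizes Numeric vector of event sizes.
#' @param law \code{"power"}, \code{"exponential"}, or \code{"normal"}.
#' @param breaks Histogram breaks for non-integer sizes (integer sizes are
#'   tabulated exactly).
#' @return A list of class \code{"event_size_fit"} with \code{available},
#'   the fitted parameters, \code{r_squared}, and the fitted bin table.
#'   When fewer than 3 usable bins remain, \code{available} is \code{FALSE}.
#' @export
fit_event_size_distribution <- function(sizes,
                                        law = c("power", "exponential",
                                                "normal"),
                                        breaks = 30L) {
  law <- match.arg(law)
  stopifnot(length(sizes) > 0)
  if (all(sizes == round(sizes))) {
    rng <- range(sizes)
    x <- seq(rng[1L], rng[2L])
    y <- as.vector(table(factor(sizes, levels = x)))
  } else {
    h <- graphics::hist(sizes, breaks = breaks, plot = FALSE)
    x <- h$mids
    y <- h$counts
  }
  peak <- which.max(y)
  last <- max(which(y > 0))
  x <- x[peak:last]; y <- y[peak:last]
  keep <- y > 0
  if (law == "power") keep <- keep & x > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    return(structure(list(available = FALSE, law = law),
                     class = "event_size_fit"))
  out <- switch(law,
    power = {
      f <- stats::lm(log(y) ~ log(x))
      list(params = c(amplitude = unname(exp(stats::coef(f)[1L])),
                      exponent = unname(stats::coef(f)[2L])),
           r_squared = summary(f)$r.squared)
    },
    exponential = {
      f <- stats::lm(log(y) ~ x)
      list(params = c(amplitude = unname(exp(stats::coef(f)[1L])),
                      rate = unname(stats::coef(f)[2L])),
           r_squared = summary(f)$r.squared)
    },
    normal = {
      st <- list(A = max(y), mu = stats::weighted.mean(x, y),
                 sigma = max(stats::sd(rep(x, y)), 1e-6))
      f <- try(stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
                          start = st), silent = TRUE)
      if (inherits(f, "try-error"))
        return(structure(list(available = FALSE, law = law),
                         class = "event_size_fit"))
      pr <- stats::predict(f)
      list(params = stats::coef(f),
           r_squared = 1 - sum((y - pr)^2) / sum((y - mean(y))^2))
    })
  structure(list(available = TRUE, law = law, params = out$params,
                 r_squared = out$r_squared,
                 bins = data.frame(size = x, frequency = y)),
            class = "event_size_fit")
}

#' @export
print.event_size_fit <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("event-size %s fit unavailable (too few non-zero bins)\n",
                x$law))
    return(invisible(x))
  }
  cat(sprintf("event-size %s fit over %d bins: R^2 = %.4f\n",
              x$law, nrow(x$bins), x$r_squared))
  print(signif(x$params, 5))
  invisible(x)
}

#' Write patch, species, and species-area tables
#'
#' Emits \code{patch_metrics.tsv}, \code{species_metrics.tsv}, and (for
#' full rectangular lattices) \code{sar.tsv} into a directory, each with a
#' header comment carrying the effort threshold used.
#'
#' @param state A \code{"metacommunity"} state.
#' @param dir Output directory (created if needed).
#' @param effort_threshold Link census threshold.
#' @param params \code{\link{model_params}}.
#' @return The directory, invisibly.
#' @export
write_metrics <- function(state, dir, effort_threshold = 0.01,
                          params = state$params) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# effort_threshold=%g", effort_threshold)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  wr(patch_metrics(state, effort_threshold, params = params),
     "patch_metrics.tsv")
  wr(species_metrics(state, effort_threshold, params = params),
     "species_metrics.tsv")
  if (all(state$lattice$active)) {
    sar <- species_area_curve(state)
    wr(sar$table, "sar.tsv")
  }
  invisible(dir)
}
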