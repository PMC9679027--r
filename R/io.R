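# Snapshots, fixtures, and the command-line surface ---------------------------

SNAPSHOT_FORMAT_VERSION <- 1L

#' Save a meta-community snapshot
#'
#' Writes a versioned single-file text container: header lines (format
#' version and an md5 content hash of the payload) followed by the state -
#' parameters, lattice, species table, score matrix, population matrices,
#' and the random-number-generator state - as base64-wrapped R
#' serialization (plain text, bit-exact for doubles). The round trip
#' \code{load_snapshot(save_snapshot(state))} reproduces the state
#' bit-exactly.
#'
#' @param state A \code{"metacommunity"} state.
#' @param path Output file.
#' @param capture_rng Store the current global RNG state in the snapshot.
#' @return The path, invisibly.
#' @export
save_snapshot <- function(state, path, capture_rng = TRUE) {
  if (capture_rng && is.null(state$rng_state) &&
      exists(".Random.seed", envir = globalenv()))
    state$rng_state <- get(".Random.seed", envir = globalenv())
  payload <- jsonlite::base64_enc(serialize(unclass(state), NULL))
  payload <- gsub("\n", "", payload, fixed = TRUE)
  hash <- payload_md5(payload)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("#metawebsim-snapshot v%d", SNAPSHOT_FORMAT_VERSION),
               sprintf("#md5 %s", hash),
               payload), con)
  invisible(path)
}

payload_md5 <- function(payload) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(payload, tmp, sep = "")
  unname(tools::md5sum(tmp))
}

#' Load a meta-community snapshot
#'
#' @param path Snapshot file written by \code{\link{save_snapshot}}.
#' @param restore_rng Restore the stored RNG state into the session.
#' @return The \code{"metacommunity"} state.
#' @export
load_snapshot <- function(path, restore_rng = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !startsWith(lines[1L], "#metawebsim-snapshot"))
    stop("snapshot format error: missing header", call. = FALSE)
  ver <- as.integer(sub("^#metawebsim-snapshot v", "", lines[1L]))
  if (is.na(ver) || ver > SNAPSHOT_FORMAT_VERSION)
    stop(sprintf("snapshot format error: version %s is newer than supported (%d)",
                 lines[1L], SNAPSHOT_FORMAT_VERSION), call. = FALSE)
  if (!startsWith(lines[2L], "#md5 "))
    stop("snapshot format error: missing hash line", call. = FALSE)
  stored_hash <- sub("^#md5 ", "", lines[2L])
  payload <- paste(lines[-(1:2)], collapse = "")
  if (payload_md5(payload) != stored_hash)
    stop("snapshot format error: payload hash mismatch (truncated or corrupt file)",
         call. = FALSE)
  state <- try(unserialize(jsonlite::base64_dec(payload)), silent = TRUE)
  if (inherits(state, "try-error"))
    stop("snapshot format error: payload does not deserialize", call. = FALSE)
  class(state) <- "metacommunity"
  if (restore_rng && !is.null(state$rng_state))
    assign(".Random.seed", state$rng_state, envir = globalenv())
  state
}

#' Content hash of a snapshotted state
#'
#' @param state A \code{"metacommunity"} state.
#' @return md5 hex digest of the state's serialized payload.
#' @export
snapshot_hash <- function(state) {
  payload_md5(gsub("\n", "",
                   jsonlite::base64_enc(serialize(unclass(state), NULL)),
                   fixed = TRUE))
}

# Fixtures --------------------------------------------------------------------

#' Deterministic tiny meta-communities for tests and demonstrations
#'
#' \describe{
#'   \item{single-patch-chain}{one patch holding resource -> A -> B with a
#'     hand-set score matrix guaranteeing exactly that chain (A eats only
#'     the resource, B eats only A).}
#'   \item{two-patch-subsidy}{a 1 x 2 source-sink pair: consumer A feeds on
#'     the patch-1 resource only; its patch-2 satellite population persists
#'     purely through immigration and perishes if the sink is isolated.}
#'   \item{grid-3x3-seeded}{a small assembled state at a fixed seed.}
#'   \item{invasion-playground}{an empty 6 x 6 resources-only state.}
#' }
#'
#' @param name Fixture id.
#' @return A \code{"metacommunity"} state.
#' @export
make_fixture <- function(name = c("single-patch-chain", "two-patch-subsidy",
                                  "grid-3x3-seeded", "invasion-playground")) {
  name <- match.arg(name)
  switch(name,
    "single-patch-chain" = fixture_chain(),
    "two-patch-subsidy" = fixture_subsidy(),
    "grid-3x3-seeded" = {
      cfg <- assembly_config(evo_steps = 15L, eco_steps_per_evo = 5L,
                             rows = 3L, cols = 3L, seed = 42L)
      assemble(cfg, model_params(foraging_iters_per_eco = 40L))
    },
    "invasion-playground" = {
      st <- initialize_metacommunity(model_params(), 6L, 6L)
      founder <- nrow(st$N)
      st$N[founder, ] <- 0
      st$N_prev[founder, ] <- 0
      mark_alive(st)
    })
}

# hand-set score matrix on a 30-trait pool: traits 1-10 resource, 11-20
# species A, 21-30 species B; every A-resource pair scores +0.06 (strong
# enough that A's productivity can sustain a predator), every B-A pair
# +0.02, every B-resource pair -0.02 (so B cannot shortcut to the
# resource), pairs within blocks 0
fixture_beta <- function(pool = 30L) {
  beta <- matrix(0, pool, pool)
  beta[11:20, 1:10] <- 0.06
  beta[21:30, 11:20] <- 0.02
  beta[21:30, 1:10] <- -0.02
  beta[1:10, 11:20] <- -0.06
  beta[11:20, 21:30] <- -0.02
  beta[1:10, 21:30] <- 0.02
  beta
}

fixture_chain <- function() {
  params <- model_params(trait_pool_size = 30L)
  lattice <- make_lattice(1L, 1L)
  lattice$resource_of <- 1L
  traits <- rbind(1:10, 11:20, 21:30)
  species_df <- data.frame(
    id = 1:3,
    bodysize = c(1, exp(3), exp(6)),
    is_resource = c(TRUE, FALSE, FALSE),
    parent_id = NA_integer_, birth_step = c(NA, 0L, 0L),
    alive = TRUE)
  N <- matrix(c(params$resource_abundance, 600, 15), 3L, 1L)
  new_state(params, lattice, species_df, traits, N, fixture_beta())
}

fixture_subsidy <- function() {
  params <- model_params(trait_pool_size = 30L)
  lattice <- make_lattice(1L, 2L)
  lattice$resource_of <- c(1L, 2L)
  # resource 2 gets the "B" trait block: A scores negatively on it
  traits <- rbind(1:10, 21:30, 11:20)
  species_df <- data.frame(
    id = 1:3,
    bodysize = c(1, 1, exp(3)),
    is_resource = c(TRUE, TRUE, FALSE),
    parent_id = NA_integer_, birth_step = c(NA, NA, 0L),
    alive = TRUE)
  R <- params$resource_abundance
  N <- rbind(c(R, 0), c(0, R), c(700, 50))
  new_state(params, lattice, species_df, traits, N, fixture_beta())
}

# Command-line surface --------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: metawebsim <command> [options]",
    "",
    "commands:",
    "  assemble --rows R --cols C --evo-steps N --eco-steps N --seed S --out FILE",
    "           [--foraging-iters N]",
    "  metrics  --snapshot FILE --out-dir DIR [--effort-threshold X]",
    "  perturb  --snapshot FILE --patch r,c --mode {temporary|permanent}-{eliminate|displace}",
    "           [--relax N]",
    "  sequence --snapshot FILE --scheme NAME --mode MODE --rule {targeted|random}",
    "           [--events N] [--relax N] [--seed S] [--out FILE]",
    "  plan     [--print-totals]",
    "  fixture  <name> --out FILE",
    sep = "\n")
}

parse_cli_opts <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        opts[[substring(a, 3L)]] <- TRUE
        i <- i + 1L
      } else {
        opts[[substring(a, 3L)]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

need_opt <- function(opts, name) {
  v <- opts[[name]]
  if (is.null(v) || isTRUE(v))
    stop(sprintf("missing required flag --%s", name), call. = FALSE)
  v
}

#' Command-line driver
#'
#' A thin dispatcher over the package's functions; the executable wrapper
#' lives at \code{system.file("cli", "metawebsim", package = "metawebsim")}.
#' Exit status 0 on success, 2 on usage errors, 1 on runtime errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { message(cli_usage()); return(invisible(2L)) }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  status <- tryCatch({
    switch(cmd,
      assemble = {
        cfg <- assembly_config(
          evo_steps = as.integer(need_opt(opts, "evo-steps")),
          eco_steps_per_evo = as.integer(need_opt(opts, "eco-steps")),
          rows = as.integer(opts[["rows"]] %||% 6L),
          cols = as.integer(opts[["cols"]] %||% 6L),
          seed = as.integer(need_opt(opts, "seed")))
        params <- model_params(foraging_iters_per_eco =
                                 as.integer(opts[["foraging-iters"]] %||% 1000L))
        st <- assemble(cfg, params,
                       progress_every = as.integer(opts[["progress"]] %||% 0L))
        save_snapshot(st, need_opt(opts, "out"))
        message("snapshot written; final diversity ", global_diversity(st))
        0L
      },
      metrics = {
        st <- load_snapshot(need_opt(opts, "snapshot"))
        write_metrics(st, need_opt(opts, "out-dir"),
                      as.numeric(opts[["effort-threshold"]] %||% 0.01))
        0L
      },
      perturb = {
        st <- load_snapshot(need_opt(opts, "snapshot"))
        patch <- as.integer(strsplit(need_opt(opts, "patch"), ",")[[1L]])
        mode <- strsplit(need_opt(opts, "mode"), "-")[[1L]]
        rec <- perturb_patch(st, patch, mode[1L], mode[2L],
                             as.integer(opts[["relax"]] %||% 100L))
        print(rec)
        0L
      },
      sequence = {
        st <- load_snapshot(need_opt(opts, "snapshot"))
        mode <- strsplit(need_opt(opts, "mode"), "-")[[1L]]
        plan <- sequence_plan(mode[1L], mode[2L],
                              scheme = need_opt(opts, "scheme"),
                              rule = need_opt(opts, "rule"),
                              n_events = if (!is.null(opts[["events"]]))
                                as.integer(opts[["events"]]),
                              seed = if (!is.null(opts[["seed"]]))
                                as.integer(opts[["seed"]]))
        res <- run_sequence(st, plan,
                            as.integer(opts[["relax"]] %||% 100L))
        print(res)
        if (!is.null(opts[["out"]]))
          utils::write.table(res$trajectory, opts[["out"]], sep = "\t",
                             quote = FALSE, row.names = FALSE)
        0L
      },
      plan = {
        pl <- enumerate_experiment_plan()
        message(sprintf("%d sequences, %d perturbation events",
                        pl$n_sequences, pl$total_events))
        0L
      },
      fixture = {
        if (!length(opts$positional))
          stop("fixture name required", call. = FALSE)
        st <- make_fixture(opts$positional[[1L]])
        save_snapshot(st, need_opt(opts, "out"))
        0L
      },
      {
        message("unknown command: ", cmd, "\n", cli_usage())
        return(invisible(2L))
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required flag|unknown|required", conditionMessage(e)))
      2L else 1L
  })
  invisible(status)
}
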