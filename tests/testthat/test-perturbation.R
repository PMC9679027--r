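relaxed_chain <- function() run_ecology(make_fixture("single-patch-chain"),
                                        300, log = FALSE)

test_that("species deletion counts secondary extinctions and never mutates its input", {
  st <- relaxed_chain()
  h <- snapshot_hash(st)
  # deleting the top predator removes nothing else
  top <- delete_species(st, 3, relax_steps = 150)
  expect_equal(top$secondary_extinctions, 0L)
  # deleting the herbivore starves the top predator
  mid <- delete_species(st, 2, relax_steps = 150)
  expect_equal(mid$secondary_extinctions, 1L)
  expect_equal(mid$relative_secondary_extinctions, 1)
  expect_identical(snapshot_hash(st), h)
  # guards
  expect_error(delete_species(st, 1), "resource")
  expect_error(delete_species(st, 99), "unknown")
})

test_that("secondary extinctions never exceed the remaining consumer richness", {
  set.seed(51)
  st <- make_fixture("grid-3x3-seeded")
  cons <- st$species$id[st$species$alive & !st$species$is_resource]
  pre <- length(cons)
  for (id in cons) {
    rec <- delete_species(st, id, relax_steps = 10)
    expect_lte(rec$secondary_extinctions, pre - 1L)
    expect_gte(rec$secondary_extinctions, 0L)
  }
})

test_that("reintroduction everywhere records invaded patches", {
  sb <- run_ecology(make_fixture("two-patch-subsidy"), 40, log = FALSE)
  del <- delete_species(sb, 3, relax_steps = 60, keep_state = TRUE)
  rec <- reintroduce_everywhere(del$state, 3, relax_steps = 150)
  # a formerly resident species re-enters at least one habitat; here the
  # source patch sustains it and the sink is re-subsidised
  expect_gte(rec$patches_invaded, 1L)
  expect_equal(rec$patches_invaded, 2L)
})

test_that("a universally fed consumer invades every patch of an empty network", {
  set.seed(52)
  st <- make_fixture("invasion-playground")
  # hand the invader trait-pair dominance over the whole pool: its traits
  # score +0.5 against every other trait
  tr <- 491:500
  st$beta[tr, -tr] <- 0.5
  st$beta[-tr, tr] <- -0.5
  st2 <- introduce_species(st, tr, bodysize = exp(3), intro_pop = 1)
  inv <- nrow(st2$N)
  expect_true(all(st2$S[inv, 1:36] > 0))
  st2 <- relax_ecology(st2, 150)
  expect_equal(sum(st2$N[inv, ] >= 1), 36L)
})

test_that("random species generation honours the bodysize modes", {
  set.seed(53)
  g <- generate_random_species(200, "uniform")
  expect_true(all(g$species$bodysize >= 0.81 & g$species$bodysize <= 12.64))
  expect_equal(dim(g$traits), c(200L, 10L))
  expect_true(all(apply(g$traits, 1, anyDuplicated) == 0))
  emp <- c(1.3, 2.4, 7.7)
  r <- generate_random_species(100, "resample", empirical = emp)
  expect_true(all(r$species$bodysize %in% emp))
  expect_error(generate_random_species(5, "resample"), "empirical")
})

test_that("patch elimination and displacement keep their arithmetic contracts", {
  set.seed(54)
  st <- run_ecology(make_fixture("two-patch-subsidy"), 30, log = FALSE)
  h <- snapshot_hash(st)

  # displacement conserves every species' global population at the event
  rec <- perturb_patch(st, c(1, 1), "temporary", "displace",
                       relax_steps = 0, keep_state = TRUE)
  expect_equal(rowSums(rec$state$N)[3], sum(st$N[3, ]))
  # D = 1 here: the whole resident population lands on the neighbour
  expect_equal(rec$state$N[3, 2], sum(st$N[3, ]))
  expect_equal(rec$state$N[3, 1], 0)

  # elimination strictly removes population
  rec2 <- perturb_patch(st, c(1, 1), "temporary", "eliminate",
                        relax_steps = 0, keep_state = TRUE)
  expect_equal(rec2$state$N[3, 1], 0)
  expect_lt(sum(rec2$state$N[3, ]), sum(st$N[3, ]))

  # the source state is untouched by either experiment
  expect_identical(snapshot_hash(st), h)

  # temporary leaves the live set unchanged; permanent shrinks it by one
  expect_equal(sum(rec2$state$lattice$active), 2L)
  rec3 <- perturb_patch(st, c(1, 1), "permanent", "eliminate",
                        relax_steps = 0, keep_state = TRUE)
  expect_equal(sum(rec3$state$lattice$active), 1L)
  # the removed patch's resource is gone and neighbour degree dropped
  expect_equal(rec3$state$N[1, 1], 0)
  expect_equal(rec3$state$lattice$degree[2], 0L)
})

test_that("even displacement splits residents among all neighbours", {
  set.seed(55)
  st <- initialize_metacommunity(model_params(), rows = 3, cols = 3)
  founder <- nrow(st$N)
  st$N[founder, ] <- 0
  st$N[founder, metawebsim:::patch_index(st$lattice, 2, 2)] <- 100
  st$N_prev <- st$N
  st <- metawebsim:::mark_alive(st)
  rec <- perturb_patch(st, c(2, 2), "temporary", "displace",
                       relax_steps = 0, keep_state = TRUE)
  nb <- metawebsim:::patch_index(st$lattice, c(1, 3, 2, 2), c(2, 2, 1, 3))
  expect_equal(unname(rec$state$N[founder, nb]), rep(25, 4))
  expect_equal(rec$state$N[founder, metawebsim:::patch_index(st$lattice, 2, 2)], 0)
})

test_that("displacing from an isolated patch falls back to elimination", {
  st <- run_ecology(make_fixture("single-patch-chain"), 10, log = FALSE)
  expect_warning(rec <- perturb_patch(st, c(1, 1), "temporary", "displace",
                                      relax_steps = 0, keep_state = TRUE),
                 "elimination")
  expect_equal(sum(rec$state$N[2:3, ]), 0)
})

test_that("the displacement-elimination differential separates constructed outcomes", {
  # zero non-resource residents: both fates coincide exactly
  empty <- make_fixture("invasion-playground")
  expect_equal(displacement_vs_elimination_differential(empty, c(2, 2),
                                                        relax_steps = 5), 0)

  # a unique resident that only survives via displacement: A sits on a
  # patch whose resource it cannot eat, next to one it can
  p <- model_params(trait_pool_size = 30L)
  sb <- make_fixture("two-patch-subsidy")
  sb$N[3, ] <- c(0, 400)        # A only in the sink patch (resource 2: inedible)
  sb$N_prev <- sb$N
  sb <- metawebsim:::mark_alive(sb)
  d <- displacement_vs_elimination_differential(sb, c(1, 2), "temporary",
                                                relax_steps = 120)
  expect_gt(d, 0)
})

test_that("displaced residents can exterminate unique neighbours", {
  # 1x3 row, dispersal constants zeroed so only forced eviction moves
  # anything. Strong generalist A holds patches 1 and 3; weaker consumer U
  # holds patch 2 only; both feed on every resource. Eliminating patch 1
  # costs nothing globally (A survives in patch 3), but displacing patch 1
  # dumps A's population into patch 2 where its competition drives U under
  # the sustainable intake.
  p <- model_params(trait_pool_size = 40L, base_emigration = 0,
                    decline_emigration = 0)
  lat <- metawebsim:::make_lattice(1L, 3L)
  lat$resource_of <- 1:3
  beta <- matrix(0, 40, 40)
  beta[11:20, 1:10] <- 0.09       # A on resources: strong
  beta[1:10, 11:20] <- -0.09
  beta[21:30, 1:10] <- 0.03       # U on resources: weak
  beta[1:10, 21:30] <- -0.03
  traits <- rbind(1:10, 1:10, 1:10, 11:20, 21:30)
  species_df <- data.frame(
    id = 1:5, bodysize = c(1, 1, 1, exp(3), exp(3)),
    is_resource = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    parent_id = NA_integer_, birth_step = c(NA, NA, NA, 0L, 0L),
    alive = TRUE)
  R <- p$resource_abundance
  N <- rbind(c(R, 0, 0), c(0, R, 0), c(0, 0, R),
             c(600, 0, 600), c(0, 1100, 0))
  st <- metawebsim:::new_state(p, lat, species_df, traits, N, beta)
  d <- displacement_vs_elimination_differential(st, c(1, 1), "temporary",
                                                relax_steps = 400)
  expect_lt(d, 0)
})

test_that("reserve layouts reproduce the lattice geometry of the schemes", {
  set.seed(56)
  st <- initialize_metacommunity(model_params(), 6, 6)
  remote <- resolve_reserves(st, "remote-block")
  expect_equal(nrow(remote$patches), 6L)
  expect_equal(patch_set_boundary_edges(st, remote$patches), 5L)
  central <- resolve_reserves(st, "central-block")
  expect_equal(patch_set_boundary_edges(st, central$patches), 10L)
  # remote block totally isolates (1,1) and (1,2)
  ids <- metawebsim:::patch_index(st$lattice, remote$patches[, 1],
                                  remote$patches[, 2])
  isolated <- remote$patches[vapply(seq_len(6), function(k)
    all(st$lattice$nbrs[[ids[k]]] %in% ids), logical(1)), , drop = FALSE]
  expect_equal(isolated, rbind(c(1L, 1L), c(1L, 2L)), ignore_attr = TRUE)
  # max-dispersal individuals: pairwise non-adjacent, summed degree 20
  mx <- resolve_reserves(st, "max-dispersal-individuals")
  mids <- metawebsim:::patch_index(st$lattice, mx$patches[, 1], mx$patches[, 2])
  expect_equal(sum(st$lattice$degree[mids]), 20L)
  for (k in seq_along(mids))
    expect_false(any(st$lattice$nbrs[[mids[k]]] %in% mids[-k]))
  # dynamic selectors resolve to six live patches
  hd <- resolve_reserves(st, "highest-diversity")
  expect_equal(nrow(hd$patches), 6L)
  expect_error(resolve_reserves(st, "no-such-scheme"), "unknown")
})

test_that("permanent sequences exhaust the non-reserve patches", {
  set.seed(57)
  st <- make_fixture("invasion-playground")
  plan <- sequence_plan("permanent", "eliminate", scheme = "remote-block",
                        rule = "random", seed = 3)
  res <- run_sequence(st, plan, relax_steps = 0)
  expect_equal(res$n_events, 30L)
  expect_equal(sum(res$final_state$lattice$active), 6L)
  # the survivors are exactly the reserves
  left <- which(res$final_state$lattice$active)
  expect_setequal(left, metawebsim:::patch_index(st$lattice,
                                                 res$reserves$patches[, 1],
                                                 res$reserves$patches[, 2]))

  # without reserves all 36 patches fall and global diversity reaches zero
  plan0 <- sequence_plan("permanent", "eliminate", scheme = "none",
                         rule = "targeted")
  res0 <- run_sequence(st, plan0, relax_steps = 0)
  expect_equal(res0$n_events, 36L)
  expect_equal(sum(res0$final_state$lattice$active), 0L)
  expect_equal(res0$diversity_final, 0)
  expect_equal(res0$relative_final, 0)
})

test_that("sequences are reproducible from their seed", {
  st <- make_fixture("invasion-playground")
  plan <- sequence_plan("temporary", "eliminate", scheme = "none",
                        rule = "random", n_events = 12, seed = 11)
  a <- run_sequence(st, plan, relax_steps = 0)
  b <- run_sequence(st, plan, relax_steps = 0)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("the experiment-plan enumerator reproduces the campaign totals", {
  pl <- enumerate_experiment_plan()
  expect_equal(pl$n_sequences, 8580L)
  expect_equal(pl$total_events, 4420680L)
  expect_equal(sum(pl$table$n_events), pl$total_events)
  # one meta-community, one mode, control only, one targeted sequence
  small <- enumerate_experiment_plan(n_metacommunities = 1,
                                     schemes = "none",
                                     replicates = c(targeted = 1L))
  small_tmp <- small$table[grepl("^temporary", small$table$mode), ]
  expect_equal(nrow(small_tmp), 2L)
  expect_true(all(small_tmp$n_events == 1000L))
})
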