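# hand-built local web: returns a state whose single patch realizes exactly
# the links implied by the block score matrix of the fixtures
chain_state <- function(steps = 5) {
  run_ecology(make_fixture("single-patch-chain"), steps, log = FALSE)
}

test_that("shortest-chain trophic levels follow realized chains", {
  st <- chain_state()
  web <- patch_links(st, c(1, 1))
  lv <- shortest_chain_trophic_level(web, which(st$species$is_resource))
  expect_equal(unname(lv[c("1", "2", "3")]), c(0, 1, 2))
})

test_that("a consumer feeding on both resource and herbivore has level one", {
  # hand-built 3-node web: A eats the resource; B eats both resource and A
  web <- list(present = 1:3,
              links = cbind(consumer = c(2L, 3L, 3L), prey = c(1L, 1L, 2L)))
  lv <- shortest_chain_trophic_level(web, 1L)
  expect_equal(unname(lv), c(0, 1, 1))    # the shortest chain wins
  # and with two prey on different levels B is an omnivore
  expect_equal(omnivory_fraction(web, lv, 1L), 0.5)
})

test_that("a hand-enumerated five-species web gives the counted omnivory fraction", {
  # resource 1; A(2), B(3) eat it; C(4) eats A and B (same level, not an
  # omnivore); D(5) eats resource and C (levels 0 and 2: omnivore)
  web <- list(present = 1:5,
              links = cbind(consumer = c(2L, 3L, 4L, 4L, 5L, 5L),
                            prey = c(1L, 1L, 2L, 3L, 1L, 4L)))
  lv <- shortest_chain_trophic_level(web, 1L)
  expect_equal(unname(lv), c(0, 1, 1, 2, 1))
  expect_equal(omnivory_fraction(web, lv, 1L), 0.25)
})

test_that("omnivory fraction is zero when every species has a single prey", {
  st <- chain_state()
  web <- patch_links(st, c(1, 1))
  lv <- shortest_chain_trophic_level(web, 1L)
  expect_equal(omnivory_fraction(web, lv, 1L), 0)
})

test_that("sctl equals breadth-first-search distance on random webs", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 10
    # random directed consumer->prey web over species 2..n anchored at 1
    links <- cbind(consumer = sample(2:n, 14, replace = TRUE),
                   prey = sample(1:n, 14, replace = TRUE))
    links <- unique(links[links[, 1] != links[, 2], , drop = FALSE])
    web <- list(present = 1:n, links = links)
    lv <- shortest_chain_trophic_level(web, 1L)
    g <- igraph::graph_from_edgelist(links, directed = TRUE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    d <- as.vector(igraph::distances(g, v = 1:n, to = 1, mode = "out"))
    d[is.infinite(d)] <- NA_real_
    expect_equal(unname(lv), d)
  }
})

test_that("connectance and link density use the directed convention", {
  st <- chain_state()
  web <- patch_links(st, c(1, 1))
  cl <- connectance_and_link_density(web)
  # 3 species, 2 links
  expect_equal(unname(cl["link_density"]), 2 / 3)
  expect_equal(unname(cl["connectance"]), 2 / 9)
  # 1 resource + 1 consumer with one link
  sb <- run_ecology(make_fixture("two-patch-subsidy"), 2, log = FALSE)
  cl1 <- connectance_and_link_density(patch_links(sb, c(1, 1)))
  expect_equal(unname(cl1["link_density"]), 0.5)
  expect_equal(unname(cl1["connectance"]), 0.25)
  # no consumers -> zero density
  empty <- make_fixture("invasion-playground")
  cl0 <- connectance_and_link_density(patch_links(empty, c(3, 3)))
  expect_equal(unname(cl0["link_density"]), 0)
})

test_that("true local diversity strips immigration-subsidised satellites", {
  sb <- run_ecology(make_fixture("two-patch-subsidy"), 40, log = FALSE)
  # the sink holds its consumer only through immigration
  expect_equal(sum(sb$N[, 2] > 0), 2)
  expect_equal(true_local_diversity(sb, c(1, 2), relax_steps = 150), 1)
  # the source community is self-sustaining
  expect_equal(true_local_diversity(sb, c(1, 1), relax_steps = 150), 2)
  # relax_steps = 0 reduces to the plain local diversity
  expect_equal(true_local_diversity(sb, c(1, 2), relax_steps = 0), 2)
  # and the probe never mutates the original state
  h <- snapshot_hash(sb)
  invisible(true_local_diversity(sb, c(1, 2), relax_steps = 10))
  expect_identical(snapshot_hash(sb), h)
})

test_that("species-area enumeration covers all rectangles of the grid", {
  set.seed(42)
  st <- initialize_metacommunity(model_params(), 6, 6)
  sar <- species_area_curve(st)
  expect_equal(nrow(sar$table), 18L)                  # 18 distinct areas
  expect_equal(sar$table$n_rectangles[sar$table$area == 1], 36L)
  expect_equal(sar$table$n_rectangles[sar$table$area == 36], 1L)
  # mean diversity is non-decreasing in area
  expect_true(all(diff(sar$table$mean_diversity) >= -1e-9))
})

test_that("flat occupancy yields a zero species-area exponent", {
  st <- initialize_metacommunity(model_params(), 6, 6)
  founder <- nrow(st$N)
  st$N[founder, ] <- 5   # founder everywhere: every patch has 2 species
  st <- metawebsim:::mark_alive(st)
  # make every species global: put every resource everywhere
  st$N[st$species$is_resource, ] <- 1
  # a perfectly flat curve triggers lm's perfect-fit warning; that is the point
  sar <- suppressWarnings(species_area_curve(st))
  expect_equal(sar$z, 0, tolerance = 1e-12)
  expect_equal(sar$table$mean_diversity, rep(37, 18))
})

test_that("species-area fit requires a full rectangular lattice", {
  st <- initialize_metacommunity(model_params(), 3, 3)
  st$lattice$active[5] <- FALSE
  st$lattice <- metawebsim:::rebuild_adjacency(st$lattice)
  expect_error(species_area_curve(st), "rectangular")
})

test_that("event-size fits recover exact laws and match a regression oracle", {
  # exact power law: f = 1000 * s^-2 over s = 1..6
  s <- 1:6
  f <- round(1000 * s^(-2))
  sizes <- rep(s, f)
  fit <- fit_event_size_distribution(sizes, "power")
  expect_true(fit$available)
  expect_equal(fit$r_squared, 1, tolerance = 1e-3)
  expect_lt(abs(fit$params["exponent"] - (-2)), 0.02)

  # exact exponential: f = 800 * exp(-0.9 s)
  f2 <- round(800 * exp(-0.9 * s))
  sizes2 <- rep(s, f2)
  fit2 <- fit_event_size_distribution(sizes2, "exponential")
  expect_equal(fit2$r_squared, 1, tolerance = 1e-3)
  expect_lt(abs(fit2$params["rate"] - (-0.9)), 0.02)

  # slope/intercept against a direct least-squares computation
  x <- log(fit$bins$size); y <- log(fit$bins$frequency)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(unname(fit$params["exponent"]), slope, tolerance = 1e-12)
  expect_equal(unname(fit$params["amplitude"]),
               exp(mean(y) - slope * mean(x)), tolerance = 1e-9)

  # fitting starts at the peak bin: a hump-shaped histogram drops the rise
  sizes3 <- rep(1:5, c(2, 9, 6, 3, 1))
  fit3 <- fit_event_size_distribution(sizes3, "exponential")
  expect_equal(fit3$bins$size[1], 2)

  # too few usable bins -> unavailable marker
  fit4 <- fit_event_size_distribution(rep(1:2, c(5, 3)), "power")
  expect_false(fit4$available)

  # gaussian bump recovered by the direct normal fit
  s5 <- 1:15
  f5 <- round(500 * exp(-(s5 - 8)^2 / (2 * 2.5^2)))
  fit5 <- fit_event_size_distribution(rep(s5, f5), "normal")
  expect_true(fit5$available)
  expect_gt(fit5$r_squared, 0.99)
})

test_that("patch and species tables carry consistent descriptors", {
  st <- run_ecology(make_fixture("two-patch-subsidy"), 30, log = FALSE)
  pm <- patch_metrics(st, include_true_diversity = TRUE, relax_steps = 120)
  expect_equal(nrow(pm), 2L)
  expect_true(all(pm$true_local_diversity <= pm$local_diversity))
  expect_true(all(pm$connectance >= 0 & pm$connectance <= 1))
  expect_equal(pm$local_diversity, c(2L, 2L))
  expect_equal(pm$avg_range, c(2, 2))    # consumer holds both patches

  sm <- species_metrics(st)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$range, 2)
  expect_equal(sm$population, sum(st$N[3, ]))
  expect_equal(sm$biomass, sum(st$N[3, ]) * st$species$bodysize[3])
  expect_equal(sm$sctl_weighted, 1)   # consumes the resource where it can
})

test_that("metric tables round-trip through the writer", {
  st <- run_ecology(make_fixture("two-patch-subsidy"), 5, log = FALSE)
  dir <- tempfile()
  write_metrics(st, dir)
  expect_true(file.exists(file.path(dir, "patch_metrics.tsv")))
  got <- utils::read.delim(file.path(dir, "patch_metrics.tsv"), comment.char = "#")
  expect_equal(nrow(got), 2L)
})
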