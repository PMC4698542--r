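test_that("default design encodes the printed group effects and SEM-derived SDs", {
  d <- default_design()
  expect_equal(d$groups, c(normal = 6L, fluoxetine = 8L, MD = 6L,
                           fluoxetine_MD = 8L))
  expect_length(d$proteins, 13L)
  expect_identical(d$loading_control, "GAPDH")

  # SD reconstructed as printed SEM x sqrt(n)
  expect_equal(d$effect["fluoxetine", "VGLUT1"], 0.71)
  expect_equal(d$noise_sd["fluoxetine", "VGLUT1"], 0.030 * sqrt(8))
  expect_equal(d$effect["MD", "VGLUT1"], 1.25)
  expect_equal(d$noise_sd["MD", "VGLUT1"], 0.084 * sqrt(6))
  expect_equal(d$effect["MD", "gephyrin"], 0.55)
  expect_equal(d$effect["fluoxetine_MD", "PSD95"], 1.46)

  # reference-group and loading-control conventions
  expect_true(all(d$effect["normal", ] == 1))
  expect_true(all(d$effect[, "GAPDH"] == 1))
  # proteins without a printed change sit at the null with SD 0.10
  expect_equal(unname(d$effect["fluoxetine", "synapsin"]), 1)
  expect_equal(unname(d$noise_sd["fluoxetine", "synapsin"]), 0.10)
})

test_that("design invariants are enforced", {
  expect_error(synthetic_design(c(a = 1L, b = 4L), c("p", "LC"), "LC"),
               "at least 2")
  eff <- matrix(c(1, 1, 1, 0.5), 2, 2,
                dimnames = list(c("a", "b"), c("p", "LC")))
  expect_error(synthetic_design(c(a = 3L, b = 3L), c("p", "LC"), "LC",
                                effect = eff),
               "loading-control")
  eff2 <- eff; eff2["a", "p"] <- 1.2; eff2["b", "LC"] <- 1
  expect_error(synthetic_design(c(a = 3L, b = 3L), c("p", "LC"), "LC",
                                effect = eff2),
               "reference group")
})

test_that("zero-noise generation reproduces design truth exactly", {
  d <- tiny_design(noise = 0, batch_sd = 0, loading_sd = 0)
  tab <- generate_table(d)
  samples <- tab[tab$group != "control", ]
  expect_equal(samples$raw_density,
               d$effect[cbind(samples$group, samples$protein)],
               ignore_attr = TRUE)
  # control lane carries the panel average for each protein
  ctrl <- tab[tab$group == "control" & tab$protein == "A", ]
  expect_equal(ctrl$raw_density, rep(mean(c(rep(1, 4), rep(1.5, 4))), 2),
               ignore_attr = TRUE)
})

test_that("a fixed seed gives bit-identical tables", {
  d <- tiny_design(seed = 42L)
  expect_identical(generate_table(d), generate_table(d))
  expect_false(identical(generate_table(d, seed = 1L),
                         generate_table(d, seed = 2L)))
})

test_that("group sample means land within 3 standard errors of design truth", {
  d <- default_design(seed = 5L, batch_sd = 0, loading_sd = 0)
  tab <- generate_table(d)
  samples <- tab[tab$group != "control", ]
  key <- paste(samples$group, samples$protein)
  mu <- tapply(samples$raw_density, key, mean)
  for (k in names(mu)) {
    parts <- strsplit(k, " ")[[1]]
    truth <- d$effect[parts[1], parts[2]]
    n <- d$groups[[parts[1]]]
    se <- max(d$noise_sd[parts[1], parts[2]] / sqrt(n), 1e-12)
    expect_lt(abs(mu[[k]] - truth), 3 * se + 0.02 * truth)
  }
})

test_that("batch factors are blot-wide and loading factors lane-specific", {
  # batch only: every band on a blot shares one multiplicative factor, so
  # within a blot the ratio to the design truth is constant across lanes
  d_batch <- tiny_design(noise = 0, batch_sd = 0.3, loading_sd = 0, seed = 3L)
  tab <- generate_table(d_batch)
  samples <- tab[tab$group != "control", ]
  ratio <- samples$raw_density / d_batch$effect[cbind(samples$group, samples$protein)]
  per_blot <- tapply(ratio, samples$blot_id, function(x) diff(range(x)))
  expect_true(all(per_blot < 1e-12))
  expect_gt(diff(range(tapply(ratio, samples$blot_id, mean))), 0)

  # loading only: the factor is shared across proteins within a lane but
  # differs between lanes of the same blot
  d_load <- tiny_design(noise = 0, batch_sd = 0, loading_sd = 0.2, seed = 3L)
  tab2 <- generate_table(d_load)
  s2 <- tab2[tab2$group != "control", ]
  r2 <- s2$raw_density / d_load$effect[cbind(s2$group, s2$protein)]
  lane_key <- paste(s2$blot_id, s2$lane_id)
  within_lane <- tapply(r2, lane_key, function(x) diff(range(x)))
  expect_true(all(within_lane < 1e-12))
  across_lanes <- tapply(r2, lane_key, mean)
  expect_gt(diff(range(across_lanes)), 0)
})

test_that("replicated blots share the animal effect but not batch factors", {
  d <- tiny_design(noise = 0.2, batch_sd = 0, loading_sd = 0,
                   replicates = 2L, seed = 9L)
  tab <- generate_table(d)
  s <- tab[tab$group != "control", ]
  expect_setequal(unique(s$blot_id), c("B1.1", "B2.1", "B1.2", "B2.2"))
  # with no batch/loading noise, replicate bands duplicate the animal effect
  key <- paste(s$animal_id, s$protein)
  spread <- tapply(s$raw_density, key, function(x) {
    expect_length(x, 2L); diff(range(x))
  })
  expect_true(all(unlist(spread) < 1e-12))
})
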