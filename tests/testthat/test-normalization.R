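test_that("all-equal bands normalize to exactly 1", {
  d <- tiny_design(noise = 0, batch_sd = 0, loading_sd = 0,
                   effect_treated_A = 1)
  nt <- normalize_blots(generate_table(d))
  expect_true(all(nt$value == 1))
})

test_that("a pure blot batch effect cancels exactly", {
  d <- tiny_design(noise = 0.2, batch_sd = 0, loading_sd = 0, seed = 2L)
  tab <- generate_table(d)
  nt1 <- normalize_blots(tab)
  tab2 <- tab
  scale3 <- tab2$blot_id == "B1"
  tab2$raw_density[scale3] <- tab2$raw_density[scale3] * 3
  nt2 <- normalize_blots(tab2)
  expect_equal(nt1$value, nt2$value, tolerance = 1e-12)
})

test_that("reference-group means are exactly 1 per protein", {
  d <- tiny_design(noise = 0.25, batch_sd = 0.3, loading_sd = 0.1, seed = 11L)
  nt <- normalize_blots(generate_table(d))
  ref <- nt[nt$group == "normal", ]
  mu <- tapply(ref$value, ref$protein, mean)
  expect_true(all(abs(mu - 1) < 1e-12))
  expect_true(all(nt$value > 0))
})

test_that("normalization recovers group means from batchy data", {
  d <- default_design(seed = 21L, batch_sd = 0.2, loading_sd = 0)
  nt <- normalize_blots(generate_table(d))
  gs <- summarize_groups(nt)
  for (i in seq_len(nrow(gs))) {
    truth <- d$effect[gs$group[i], gs$measure[i]]
    sem_truth <- d$noise_sd[gs$group[i], gs$measure[i]] /
      sqrt(d$groups[[gs$group[i]]])
    # reference scaling adds the normal group's own sampling error
    tol <- 3 * sqrt(sem_truth^2 + (0.10 / sqrt(6))^2 * truth^2) + 0.02
    expect_lt(abs(gs$mean[i] - truth), tol)
  }
})

test_that("missing control bands and unassigned blots are reported by name", {
  d <- tiny_design(seed = 2L)
  tab <- generate_table(d)
  no_ctrl <- tab[!(tab$blot_id == "B2" & tab$lane_id == "L01"), ]
  attr(no_ctrl, "control_lanes") <- NULL
  attr(no_ctrl, "blot_sets") <- attr(tab, "blot_sets")
  expect_error(normalize_blots(no_ctrl), "control-sample lane.*B2")

  expect_error(normalize_blots(tab, blot_sets = c(B1 = 1L)),
               "not assigned.*B2")
  expect_error(normalize_blots(tab, reference_group = "nope"),
               "reference group")
  neg <- tab; neg$raw_density[1] <- 0
  expect_error(normalize_blots(neg), "strictly positive")
})

test_that("summarize_groups computes n, mean, n-1 SD and SEM", {
  x <- data.frame(animal_id = paste0("a", 1:5), group = "g",
                  protein = "p", value = c(0.6, 0.8, 1.0, 1.2, 1.4))
  gs <- summarize_groups(x)
  expect_equal(gs$n, 5L)
  expect_equal(gs$mean, 1.0)
  expect_equal(gs$sd, sqrt(0.1), tolerance = 1e-12)
  expect_equal(gs$sem, sqrt(0.1) / sqrt(5), tolerance = 1e-12)

  same <- data.frame(animal_id = paste0("a", 1:4), group = "g",
                     protein = "p", value = rep(1, 4))
  gs2 <- summarize_groups(same)
  expect_equal(c(gs2$mean, gs2$sd, gs2$sem), c(1, 0, 0))

  one <- data.frame(animal_id = "a1", group = "g", protein = "p", value = 1)
  expect_error(summarize_groups(one), "fewer than 2")
})

test_that("zero-noise tables summarize to design truth exactly", {
  d <- tiny_design(noise = 0, batch_sd = 0.3, loading_sd = 0, seed = 5L)
  gs <- summarize_groups(normalize_blots(generate_table(d)))
  for (i in seq_len(nrow(gs))) {
    expect_equal(gs$mean[i], unname(d$effect[gs$group[i], gs$measure[i]]),
                 tolerance = 1e-12)
  }
})

test_that("loading-control QC separates a null control from a biased one", {
  cfg <- mc_config(pool_size = 2e4, reps = 1000, seed = 31L)

  # strongly biased "control" protein: effect 1.5 with SD 0.1 -> always
  # caught. The design's nominal loading control is A so GAPDH can carry a
  # group effect here.
  eff <- matrix(1, 2, 3, dimnames = list(c("normal", "treated"),
                                         c("A", "B", "GAPDH")))
  eff["treated", "GAPDH"] <- 1.5
  d_bad <- synthetic_design(c(normal = 4L, treated = 4L), c("A", "B", "GAPDH"),
                            loading_control = "A", effect = eff,
                            noise_sd = matrix(0.1, 2, 3,
                              dimnames = dimnames(eff)),
                            batch_sd = 0, loading_sd = 0, seed = 1L)
  qc_bad <- loading_control_qc(generate_table(d_bad), control_protein = "GAPDH",
                               config = cfg, reference_group = "normal")
  expect_false(qc_bad$pass)

  # unbiased control passes much more often than the biased one (which never
  # does); the absolute null pass rate is a property of the MC procedure
  # itself and is characterized in the acceptance suite
  passes <- vapply(1:12, function(s) {
    tab <- generate_table(tiny_design(noise = 0.08, seed = s))
    loading_control_qc(tab, config = cfg, reference_group = "normal")$pass
  }, logical(1))
  expect_gt(mean(passes), 0.25)
})

test_that("QC errors when control bands are missing and passes with one group", {
  d <- tiny_design(seed = 2L)
  tab <- generate_table(d)
  drop <- !(tab$protein == "GAPDH" & tab$animal_id == "treated_1")
  expect_error(loading_control_qc(tab[drop, ],
                                  config = mc_config(1000, 100, seed = 1)),
               "missing for animal.*treated_1")

  single <- tab[tab$group %in% c("normal", "control"), ]
  attr(single, "blot_sets") <- attr(tab, "blot_sets")
  attr(single, "control_lanes") <- attr(tab, "control_lanes")
  qc <- loading_control_qc(single, config = mc_config(1000, 100, seed = 1),
                           reference_group = "normal")
  expect_true(qc$pass)
  expect_null(qc$comparisons)
})
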