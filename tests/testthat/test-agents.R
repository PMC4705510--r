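test_that("agents with zero maximum speed never move", {
  sp <- grid_space(20, 20)
  rng <- rng_streams(1)
  ag <- cell_agents("bacterium", "infectious", 10, x = runif(10, 0, 20),
                    y = runif(10, 0, 20), speed_max = 0)
  moved <- move_agents(ag, sp, rng)
  expect_equal(moved$x, ag$x)
  expect_equal(moved$y, ag$y)
})

test_that("dead agents never move", {
  sp <- grid_space(20, 20)
  rng <- rng_streams(1)
  ag <- cell_agents("t_cell", "naive", 5, x = 10, y = 10)
  ag$alive <- FALSE
  ag$state <- "dead"
  moved <- move_agents(ag, sp, rng)
  expect_equal(moved$x, ag$x)
  expect_equal(moved$y, ag$y)
})

test_that("one-cycle displacements are bounded by speed_max with mean speed_max/2", {
  sp <- grid_space(1000, 1000)
  rng <- rng_streams(99)
  n <- 10000L
  # interior placement: no reflections, so displacement = drawn speed
  ag <- cell_agents("t_cell", "naive", n, x = 500, y = 500, speed_max = 1)
  moved <- move_agents(ag, sp, rng)
  d <- sqrt((moved$x - ag$x)^2 + (moved$y - ag$y)^2)
  expect_true(all(d <= 1 + 1e-12))
  # speed ~ U[0, 1]: mean 0.5, sd of the mean ~ 0.0029
  expect_lt(abs(mean(d) - 0.5), 0.02)
})

test_that("movement keeps every agent inside its impermeable compartment", {
  sp <- grid_space(10, 10)
  rng <- rng_streams(3)
  ag <- cell_agents("bacterium", "infectious", 200,
                    x = runif(200, 0, 10), y = runif(200, 0, 10),
                    speed_max = 3)
  for (k in 1:20) {
    ag <- move_agents(ag, sp, rng)
    expect_true(all(ag$x >= 0 & ag$x < 10))
    expect_true(all(ag$y >= 0 & ag$y < 10))
  }
})

test_that("permeable agents cross compartment walls and are reassigned", {
  comps <- list(compartment("lumen", 0, 5, 0, 10, permeable = "t_cell"),
                compartment("lamina_propria", 5, 10, 0, 10,
                            permeable = "t_cell"))
  sp <- grid_space(10, 10, comps)
  rng <- rng_streams(7)
  tc <- cell_agents("t_cell", "naive", 100, x = 4.9, y = 5, speed_max = 2)
  tc$compartment <- compartment_at(sp, tc$x, tc$y)
  bc <- cell_agents("bacterium", "infectious", 100, x = 4.9, y = 5,
                    speed_max = 2, id_start = 101L)
  bc$compartment <- compartment_at(sp, bc$x, bc$y)
  for (k in 1:5) {
    tc <- move_agents(tc, sp, rng)
    bc <- move_agents(bc, sp, rng)
  }
  # T cells may cross into the right compartment; bacteria never do
  expect_true(any(tc$compartment == 2L))
  expect_true(all(bc$compartment == 1L))
  expect_true(all(bc$x < 5))
})

test_that("chemotaxis with full weight climbs the gradient", {
  sp <- grid_space(50, 50)
  ramp <- value_layer("IL12", 50, 50,
                      values = matrix(rep(0:49, each = 50), 50, 50))
  rng <- rng_streams(5)
  ag <- cell_agents("t_cell", "naive", 500, x = 25, y = 25, speed_max = 1,
                    chemo_layer = "IL12", chemo_w = 1)
  moved <- move_agents(ag, sp, rng, layers = list(IL12 = ramp))
  # the ramp increases with x, so a fully biased step moves +x
  expect_true(all(moved$x >= 25))
  expect_gt(mean(moved$x - 25), 0.4)
})

test_that("an immature dendritic cell meeting an infectious bacterium becomes effector and releases IL-6 and IL-12", {
  dc <- cell_agents("dendritic_cell", "immature", 1, x = 3.4, y = 7.9)
  coh <- cell_agents("bacterium", "infectious", 1, x = 3.2, y = 7.5,
                     id_start = 2L)
  res <- dc_contact_update(dc, coh)
  expect_equal(res$agent$state, "effector")
  expect_setequal(res$deposits$layer, c("IL6", "IL12"))
  expect_equal(res$deposits$value, c(70, 70))
  expect_equal(unique(res$deposits$x), 3)
  expect_equal(unique(res$deposits$y), 7)
  expect_equal(unique(res$deposits$semantics), "set")
})

test_that("an immature dendritic cell meeting a tolerogenic bacterium becomes tolerogenic and releases TGF-beta", {
  dc <- cell_agents("dendritic_cell", "immature", 1, x = 0.5, y = 0.5)
  coh <- cell_agents("bacterium", "tolerogenic", 2, x = 0.1, y = 0.9,
                     id_start = 2L)
  res <- dc_contact_update(dc, coh)
  expect_equal(res$agent$state, "tolerogenic")
  expect_equal(res$deposits$layer, "TGFb")
  expect_equal(res$deposits$value, 70)
})

test_that("dendritic cells without bacterial contact, or already differentiated, are unchanged", {
  dc <- cell_agents("dendritic_cell", "immature", 1, x = 1, y = 1)
  none <- cell_agents("t_cell", "naive", 3, x = 1, y = 1, id_start = 2L)
  res <- dc_contact_update(dc, none)
  expect_equal(res$agent$state, "immature")
  expect_equal(nrow(res$deposits), 0L)

  eff <- dc
  eff$state <- "effector"
  bac <- cell_agents("bacterium", "tolerogenic", 1, x = 1, y = 1,
                     id_start = 9L)
  res2 <- dc_contact_update(eff, bac)
  expect_equal(res2$agent$state, "effector")
  expect_equal(nrow(res2$deposits), 0L)

  dead_bac <- bac
  dead_bac$alive <- FALSE
  res3 <- dc_contact_update(dc, dead_bac)
  expect_equal(res3$agent$state, "immature")
  expect_equal(nrow(res3$deposits), 0L)
})

test_that("mixed bacterial contact resolves by the configured tie break", {
  dc <- cell_agents("dendritic_cell", "immature", 1, x = 1, y = 1)
  both <- rbind(
    cell_agents("bacterium", "infectious", 1, x = 1, y = 1, id_start = 2L),
    cell_agents("bacterium", "tolerogenic", 1, x = 1, y = 1, id_start = 3L))
  expect_equal(dc_contact_update(dc, both)$agent$state, "effector")
  expect_equal(dc_contact_update(dc, both,
                                 tie_break = "tolerogenic")$agent$state,
               "tolerogenic")
})

test_that("naive T cells differentiate by the local cytokine milieu and release the marker cytokine", {
  service <- ode_service(build_reduced_model())
  tc <- cell_agents("t_cell", "naive", 1, x = 2.5, y = 6.5)

  th1 <- tcell_update(tc, c(IL12 = 70, TGFb = 0, IL6 = 0), service)
  expect_equal(th1$agent$state, "Th1")
  expect_equal(th1$deposits$layer, "IFNg")
  expect_equal(th1$deposits$x, 2)
  expect_equal(th1$deposits$y, 6)
  # the ODE-predicted release matches the closed form for the Th1 branch
  cf <- closed_form_th1(kinetic_params(), 70, 50)
  expect_equal(th1$deposits$value, unname(cf["IFNg"]), tolerance = 1e-6)

  treg <- tcell_update(tc, c(IL12 = 0, TGFb = 70, IL6 = 0), service)
  expect_equal(treg$agent$state, "Treg")
  expect_equal(treg$deposits$layer, "IL10")

  th17 <- tcell_update(tc, c(IL12 = 0, TGFb = 70, IL6 = 70), service)
  expect_equal(th17$agent$state, "Th17")
  expect_equal(th17$deposits$layer, "IL17")

  none <- tcell_update(tc, c(IL12 = 0, TGFb = 0, IL6 = 0), service)
  expect_equal(none$agent$state, "naive")
  expect_equal(nrow(none$deposits), 0L)
})

test_that("differentiated and dead T cells are inert, and a fixed release value is honoured", {
  service <- ode_service(build_reduced_model())
  tc <- cell_agents("t_cell", "naive", 1, x = 2.5, y = 6.5)
  th1 <- tc
  th1$state <- "Th1"
  res <- tcell_update(th1, c(IL12 = 70, TGFb = 0, IL6 = 0), service)
  expect_equal(res$agent$state, "Th1")
  expect_equal(nrow(res$deposits), 0L)

  dead <- tc
  dead$alive <- FALSE
  res2 <- tcell_update(dead, c(IL12 = 70, TGFb = 0, IL6 = 0), service)
  expect_equal(nrow(res2$deposits), 0L)

  fx <- tcell_update(tc, c(IL12 = 70, TGFb = 0, IL6 = 0), service,
                     fixed_value = 70)
  expect_equal(fx$deposits$value, 70)
})

test_that("generic transition rules fire deterministically at probability 0 and 1", {
  rng <- rng_streams(4)
  mac <- cell_agents("macrophage", "resting", 1, x = 1, y = 1)
  th1 <- cell_agents("t_cell", "Th1", 1, x = 1, y = 1, id_start = 2L)
  never <- transition_rule("macrophage", "resting",
                           trigger_contact("t_cell", "Th1"), "M1",
                           probability = 0)
  always <- transition_rule("macrophage", "resting",
                            trigger_contact("t_cell", "Th1"), "M1",
                            probability = 1,
                            secretions = list(list(layer = "IL12",
                                                   value = 5)))
  local <- c(IL12 = 0, TGFb = 0, IL6 = 0)
  expect_equal(apply_generic_rules(mac, list(never), th1, local,
                                   rng)$agent$state, "resting")
  fired <- apply_generic_rules(mac, list(always), th1, local, rng)
  expect_equal(fired$agent$state, "M1")
  expect_equal(fired$deposits$layer, "IL12")
  expect_equal(fired$deposits$value, 5)
  # trigger absent: nothing fires
  naive <- cell_agents("t_cell", "naive", 1, x = 1, y = 1, id_start = 3L)
  expect_equal(apply_generic_rules(mac, list(always), naive, local,
                                   rng)$agent$state, "resting")
})

test_that("rule firing frequency matches its probability", {
  rng <- rng_streams(8)
  th1 <- cell_agents("t_cell", "Th1", 1, x = 1, y = 1, id_start = 2L)
  rule <- transition_rule("macrophage", "resting",
                          trigger_contact("t_cell", "Th1"), "M1",
                          probability = 0.3)
  n <- 10000L
  hits <- 0L
  mac <- cell_agents("macrophage", "resting", 1, x = 1, y = 1)
  local <- c(IL12 = 0)
  for (k in seq_len(n)) {
    res <- apply_generic_rules(mac, list(rule), th1, local, rng)
    if (res$agent$state == "M1") hits <- hits + 1L
  }
  # binomial(10000, 0.3): 3 sigma ~ 137
  expect_lt(abs(hits - 3000), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("cytokine triggers respect the positivity threshold", {
  rule <- transition_rule("epithelial", "healthy",
                          trigger_cytokine("IFNg", threshold = 1),
                          "inflamed")
  ep <- cell_agents("epithelial", "healthy", 1, x = 1, y = 1)
  rng <- rng_streams(2)
  coh <- cell_agents("t_cell", "naive", 0, x = 1, y = 1)
  below <- apply_generic_rules(ep, list(rule), coh, c(IFNg = 0.5), rng)
  above <- apply_generic_rules(ep, list(rule), coh, c(IFNg = 2), rng)
  expect_equal(below$agent$state, "healthy")
  expect_equal(above$agent$state, "inflamed")
})

test_that("rng streams are independent and reproducible", {
  a <- rng_streams(123)
  b <- rng_streams(123)
  expect_equal(with_stream(a, "movement", function() runif(5)),
               with_stream(b, "movement", function() runif(5)))
  # consuming one stream does not disturb another
  c1 <- rng_streams(123)
  c2 <- rng_streams(123)
  with_stream(c1, "placement", function() runif(1000))
  expect_equal(with_stream(c1, "movement", function() runif(5)),
               with_stream(c2, "movement", function() runif(5)))
  expect_lt(derive_stream_seed(123, "movement"), 2^31)
})
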