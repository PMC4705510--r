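test_that("the reference scenario initializes the exact study populations on a 100x100 grid", {
  st <- init_scenario(scenario_preset("RM", seed = 3))
  ag <- st$agents
  expect_equal(nrow(ag), 5000L)
  expect_equal(sum(ag$type == "bacterium" & ag$state == "infectious"), 500L)
  expect_equal(sum(ag$type == "bacterium" & ag$state == "tolerogenic"), 500L)
  expect_equal(sum(ag$type == "t_cell" & ag$state == "naive"), 2000L)
  expect_equal(sum(ag$type == "dendritic_cell" & ag$state == "immature"),
               2000L)
  expect_true(all(ag$x >= 0 & ag$x < 100 & ag$y >= 0 & ag$y < 100))
  expect_equal(st$space$width, 100L)
  expect_equal(st$space$height, 100L)
  expect_setequal(names(st$layers),
                  c("IL12", "TGFb", "IL6", "IFNg", "IL17", "IL10"))
  for (ly in st$layers) {
    expect_equal(ly$ce, 0.98)
    expect_equal(ly$cd, 0.6)
    expect_true(all(ly$values == 0))
  }
  expect_equal(st$cycle, 0L)
  expect_length(st$reports, 1L)
})

test_that("an empty scenario runs and reports without agents", {
  st <- run_scenario(scenario_config(grid = c(5L, 5L),
                                     populations = list(), cycles = 3L))
  expect_equal(st$cycle, 3L)
  expect_length(st$reports, 4L)
  expect_equal(nrow(st$agents), 0L)
})

test_that("a scale with frequency f runs once every round(1/f) cycles starting at cycle 0", {
  expect_true(is_due(0, 1))
  expect_true(all(vapply(0:99, is_due, TRUE, frequency = 1)))
  due01 <- vapply(0:99, is_due, TRUE, frequency = 0.1)
  expect_equal(sum(due01), 10L)
  expect_equal(which(due01) - 1L, seq(0L, 90L, by = 10L))
  expect_equal(sum(vapply(0:299, is_due, TRUE, frequency = 0.3)), 100L)
  expect_error(is_due(0, 0), "\\(0, 1\\]")
  expect_error(is_due(0, 1.5), "\\(0, 1\\]")
  expect_error(is_due(0, -0.1), "\\(0, 1\\]")
})

test_that("the estimated cycle cost is the frequency-weighted sum of per-execution costs", {
  metrics <- list(
    executions = c(cellular = 1L, intercellular = 1L, intracellular = 1L),
    time = c(cellular = 2, intercellular = 3, intracellular = 5))
  all_on <- list(cellular = 1, intercellular = 1, intracellular = 1)
  expect_equal(estimate_cycle_cost(metrics, all_on), 10)
  hybrid <- list(cellular = 1, intercellular = 1, intracellular = 0.1)
  expect_equal(estimate_cycle_cost(metrics, hybrid), 5.5)
  # mean per-execution cost, not total
  m2 <- metrics
  m2$executions[["intracellular"]] <- 10L
  expect_equal(estimate_cycle_cost(m2, all_on), 5.5)
  expect_equal(estimate_cycle_cost(metrics, list(cellular = 1)), 2)
  empty <- list(executions = c(cellular = 0L), time = c(cellular = 0))
  expect_error(estimate_cycle_cost(empty, all_on), "empty")
})

test_that("identical seeds give byte-identical count trajectories and different seeds diverge", {
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  f3 <- tempfile(fileext = ".tsv")
  write_counts_tsv(run_scenario(small_scenario(seed = 5, cycles = 8)), f1)
  write_counts_tsv(run_scenario(small_scenario(seed = 5, cycles = 8)), f2)
  write_counts_tsv(run_scenario(small_scenario(seed = 6, cycles = 8)), f3)
  expect_equal(file_md5(f1), file_md5(f2))
  expect_false(file_md5(f1) == file_md5(f3))
})

test_that("deposits are buffered within a cycle, so co-located T cells sense last cycle's diffused field", {
  cfg <- scenario_config(grid = c(9L, 9L), populations = list(),
                         movement = FALSE, cycles = 2L, seed = 1L)
  st <- init_scenario(cfg)
  st$agents <- rbind(
    cell_agents("dendritic_cell", "immature", 1, x = 4.5, y = 4.5),
    cell_agents("bacterium", "infectious", 1, x = 4.5, y = 4.5,
                id_start = 2L),
    cell_agents("t_cell", "naive", 1, x = 4.5, y = 4.5, id_start = 3L))

  run_cycle(st)
  # the contact rule fires and its secretion lands at the shared cell...
  expect_equal(st$agents$state[1L], "effector")
  expect_equal(st$layers$IL12$values[5L, 5L], 70)
  expect_equal(st$layers$IL6$values[5L, 5L], 70)
  # ...but the co-located T cell saw the pre-deposit (zero) field
  expect_equal(st$agents$state[3L], "naive")

  run_cycle(st)
  # one diffusion step spreads the deposit: centre keeps
  # 0.98 * (70 + 0.6/4 * 4 * (0 - 70)) = 27.44, and the T cell now senses
  # IL-12 there and commits to Th1
  expect_equal(st$agents$state[3L], "Th1")
  expect_gt(st$layers$IFNg$values[5L, 5L], 0)
  # recurring secretion restores the effector cell's concentration
  expect_equal(st$layers$IL12$values[5L, 5L], 70)
})

test_that("diffused point-source concentrations in the engine match the hand-computed value", {
  cfg <- scenario_config(grid = c(9L, 9L), populations = list(),
                         movement = FALSE, cycles = 2L, seed = 1L,
                         secretion_recurs = FALSE)
  st <- init_scenario(cfg)
  st$agents <- rbind(
    cell_agents("dendritic_cell", "immature", 1, x = 4.5, y = 4.5),
    cell_agents("bacterium", "infectious", 1, x = 4.5, y = 4.5,
                id_start = 2L))
  run_cycle(st)
  run_cycle(st)
  expect_equal(st$layers$IL12$values[5L, 5L],
               0.98 * (70 + 0.6 / 4 * 4 * (0 - 70)), tolerance = 1e-12)
  expect_equal(st$layers$IL12$values[5L, 6L],
               0.98 * 0.6 / 4 * 70, tolerance = 1e-12)
})

test_that("agents are conserved and naive T cells only ever decrease", {
  st <- run_scenario(small_scenario(seed = 2, cycles = 12))
  df <- reports_to_df(st)
  totals <- tapply(df$count, df$cycle, sum)
  expect_true(all(totals == totals[[1L]]))
  naive <- df$count[df$type == "t_cell" & df$state == "naive"]
  expect_true(all(diff(naive) <= 0))
  idc <- df$count[df$type == "dendritic_cell" & df$state == "immature"]
  expect_true(all(diff(idc) <= 0))
  expect_length(st$reports, 13L)
})

test_that("without antigen-presenting cells no cytokine ever appears and T cells stay naive", {
  cfg <- scenario_config(
    grid = c(15L, 15L),
    populations = list(list(type = "t_cell", state = "naive",
                            count = 50L)),
    cycles = 10L, seed = 4L)
  st <- run_scenario(cfg)
  expect_true(all(st$agents$state == "naive"))
  for (ly in st$layers) expect_true(all(ly$values == 0))
  cm <- cost_metrics(st)
  expect_equal(cm$solver$integrations, 1L)  # all-zero inputs memoized once
  expect_equal(cm$solver$calls, 500L)       # 50 naive cells x 10 cycles
})

test_that("lowering the intracellular frequency reduces its executions by exactly that factor", {
  rm_st <- run_scenario(small_scenario(seed = 9, cycles = 20))
  df_st <- run_scenario(small_scenario(
    seed = 9, cycles = 20, frequencies = list(intracellular = 0.1)))
  ex_rm <- cost_metrics(rm_st)$executions
  ex_df <- cost_metrics(df_st)$executions
  expect_equal(ex_rm[["intracellular"]], 20L)
  expect_equal(ex_df[["intracellular"]], 2L)
  expect_equal(ex_df[["intracellular"]] / ex_rm[["intracellular"]], 0.1)
  expect_equal(ex_df[["cellular"]], 20L)
  expect_equal(ex_df[["intercellular"]], 20L)
})

test_that("per-type death removes agents at the configured rate", {
  cfg <- scenario_config(
    grid = c(30L, 30L),
    populations = list(list(type = "bacterium", state = "infectious",
                            count = 1000L)),
    death_prob = c(bacterium = 0.5), cycles = 1L, seed = 11L)
  st <- run_scenario(cfg)
  dead <- sum(!st$agents$alive)
  expect_equal(sum(st$agents$state == "dead"), dead)
  # binomial(1000, 0.5): 3 sigma ~ 47
  expect_lt(abs(dead - 500), 3 * sqrt(1000 * 0.25))
  expect_equal(nrow(st$agents), 1000L)
})

test_that("scenario configurations round-trip through their YAML form and rerun identically", {
  cfg <- small_scenario(seed = 14, cycles = 5,
                        frequencies = list(intracellular = 0.5))
  path <- tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  cfg2 <- read_scenario(path)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_counts_tsv(run_scenario(cfg), f1)
  write_counts_tsv(run_scenario(cfg2), f2)
  expect_equal(file_md5(f1), file_md5(f2))
})

test_that("invalid configurations fail validation with the offending field named", {
  expect_error(scenario_config(grid = c(0L, 10L)), "grid")
  expect_error(scenario_config(cycles = -1L), "cycles")
  expect_error(scenario_config(frequencies = list(intracellular = 0)),
               "frequencies")
  expect_error(scenario_config(frequencies = list(cellular = 2)),
               "frequencies")
  expect_error(scenario_config(
    populations = list(list(type = "unicorn", state = "x", count = 1))),
    "agent type")
  expect_error(scenario_config(
    populations = list(list(type = "t_cell", state = "angry", count = 1))),
    "state")
  expect_error(scenario_config(deposit_semantics = "multiply"),
               "deposit_semantics")
  expect_error(scenario_config(tcell_deposit = -3), "tcell_deposit")
  expect_error(scenario_preset("XX"), "RM, BM, MS, DF")
})
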