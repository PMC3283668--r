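test_that("a fire-free, dispersal-free, uncrowded step is pure projection", {
  toy <- make_toy("projection_only")
  set.seed(50)
  l <- empty_landscape(toy$species, edge = toy$edge)
  l$total_capacity <- toy$total_capacity
  l$cell_capacity <- floor(toy$total_capacity / l$n_cells)
  l$pop$toy[, 1] <- toy$v0
  for (s in seq_len(toy$steps))
    l <- step_generation(l, toy$regime, toy$dispersal)
  expect_equal(unname(l$pop$toy[, 1]), toy$expected)
  expect_true(all(l$pop$toy[, -1] == 0))
})

test_that("an empty landscape is absorbing", {
  set.seed(51)
  l <- empty_landscape(edge = 4L)
  for (g in 1:5) l <- step_generation(l, fire_regime(0.5, 2))
  expect_equal(total_population(l, "Triodia_sp"), 0)
})

test_that("the second of two certain fires burns the refractory fraction", {
  set.seed(52)
  l <- init_landscape(default_species("T_epactia"))
  reg <- fire_regime(1, 1)
  l <- step_generation(l, reg)
  expect_true(all(l$burnt_prev))
  fracs <- replicate(60, mean(step_generation(l, reg)$burnt_prev))
  se <- sqrt(0.3 * 0.7 / (60 * 256))
  expect_lt(abs(mean(fracs) - 0.3), 3 * se)
})

test_that("the over-capacity toy patch is squeezed to exactly its capacity", {
  toy <- make_toy("lottery_squeeze")
  set.seed(53)
  l <- empty_landscape(toy$species, edge = toy$edge)
  l$total_capacity <- toy$total_capacity
  l$cell_capacity <- toy$total_capacity
  l$pop$toy[3, 1] <- toy$init_adults
  l <- step_generation(l, toy$regime, toy$dispersal)
  expect_equal(unname(l$pop$toy[3, 1]), toy$expected_total)
})

test_that("runs are deterministic given the seed", {
  sps <- three_defaults()
  cfg <- sim_config(sps, fire_regime(0.3, 4), generations = 25L,
                    record_window = 5L, edge = 8L,
                    total_capacity = 64 * 3906, seed = 99L)
  r1 <- run_sim(cfg)
  r2 <- run_sim(cfg)
  expect_identical(r1$mean_pop, r2$mean_pop)
  expect_identical(r1$mean_occ, r2$mean_occ)
  expect_identical(r1$cell_counts, r2$cell_counts)
  expect_identical(r1$final_tsf, r2$final_tsf)
})

test_that("a one-generation run summarizes the post-step state", {
  sp <- default_species("T_epactia")
  cfg <- sim_config(sp, fire_regime(0, 1), generations = 1L,
                    record_window = 1L, edge = 4L,
                    total_capacity = 16 * 3906, seed = 5L)
  r <- run_sim(cfg, return_landscape = TRUE)
  expect_equal(unname(r$mean_pop["T_epactia"]),
               total_population(r$landscape, "T_epactia"))
  expect_equal(unname(r$mean_occ["T_epactia"]),
               occupancy(r$landscape, "T_epactia"))
})

test_that("the obligate seeder dies out without fire and without dispersal", {
  cfg <- sim_config(default_species("Triodia_sp"), fire_regime(0, 1),
                    dispersal = dispersal_config(1, 0),
                    generations = 60L, record_window = 5L, edge = 8L,
                    total_capacity = 64 * 3906, seed = 6L)
  r <- run_sim(cfg)
  expect_equal(unname(r$mean_pop["Triodia_sp"]), 0)
})

test_that("sweeps enumerate the configuration grid and stay reproducible", {
  sps <- three_defaults()
  expect_equal(length(firecoex:::species_sets(sps,
               c("single", "pairs", "all"))), 7L)

  sw <- sweep_sim(sps, fire_probs = c(0, 0.5), scales = c(1L, 2L),
                  replicates = 2L, generations = 3L, record_window = 1L,
                  edge = 4L, total_capacity = 16 * 3906, seed = 77L)
  # (3 singles x1 + 3 pairs x2 + all x3) species-rows x 2 probs x 2 scales x 2 reps
  expect_equal(nrow(sw$table), (3 + 6 + 3) * 2 * 2 * 2)
  # one cell_counts entry per full-community run
  expect_equal(length(sw$cell_counts), 2 * 2 * 2)

  # replicate rows are reproducible from their recorded child seeds
  row <- sw$table[sw$table$configuration == "single:T_epactia" &
                  sw$table$fire_prob == 0.5 & sw$table$scale == 1 &
                  sw$table$replicate == 2, ]
  cfg <- sim_config(default_species("T_epactia"), fire_regime(0.5, 1),
                    generations = 3L, record_window = 1L, edge = 4L,
                    total_capacity = 16 * 3906, seed = row$seed)
  expect_equal(unname(run_sim(cfg)$mean_pop["T_epactia"]), row$mean_pop)

  sw2 <- sweep_sim(sps, fire_probs = c(0, 0.5), scales = c(1L, 2L),
                   replicates = 2L, generations = 3L, record_window = 1L,
                   edge = 4L, total_capacity = 16 * 3906, seed = 77L)
  expect_identical(sw$table, sw2$table)
})

test_that("a 1x1x1 single-species sweep yields one table row", {
  sw <- sweep_sim(list(default_species("T_epactia")), fire_probs = 0.2,
                  scales = 1L, configurations = "single", replicates = 1L,
                  generations = 2L, record_window = 1L, edge = 4L,
                  total_capacity = 16 * 3906, seed = 3L)
  expect_equal(nrow(sw$table), 1L)
})

test_that("persistence summaries classify by replicate majority", {
  sps <- three_defaults()
  sw <- sweep_sim(list(sps$Triodia_sp), fire_probs = c(0.2, 0.9),
                  scales = 16L, configurations = "single", replicates = 3L,
                  generations = 40L, record_window = 5L, edge = 16L,
                  seed = 8L)
  ag <- summarize_sweep(sw)
  expect_true(all(ag$n_replicates == 3L))
  expect_true(is.logical(ag$persistent))
  expect_true(all(ag$mean_pop >= 0))
})
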