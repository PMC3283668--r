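test_that("burn mask honours the trivial regimes", {
  set.seed(1)
  n <- 16L^2
  prev <- rep(FALSE, n)
  ages <- rep(1L, n)

  expect_false(any(sample_burn_mask(ages, prev, fire_regime(0, 1))))
  expect_true(all(sample_burn_mask(ages, prev, fire_regime(1, 1))))
  expect_true(all(sample_burn_mask(ages, prev, fire_regime(1, 16))))

  expect_error(sample_burn_mask(ages, prev, fire_regime(0.5, 3)),
               "does not divide")
})

test_that("refractory cells burn at the fuel-memory rate", {
  set.seed(2)
  n <- 16L^2
  prev <- rep(TRUE, n)
  frac <- mean(replicate(200, mean(
    sample_burn_mask(rep(0L, n), prev, fire_regime(1, 1)))))
  se <- sqrt(0.3 * 0.7 / (200 * n))
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("stationary burnt fraction matches its closed form", {
  expect_equal(stationary_burn_fraction(fire_regime(0, 1)), 0)
  expect_equal(stationary_burn_fraction(fire_regime(1, 1, refractory = 1)), 1)
  expect_equal(stationary_burn_fraction(fire_regime(0.2, 1)), 0.2 / 1.14)
})

test_that("empirical burnt fraction matches the stationary closed form", {
  # single-cell chains, >= 1e4 generations, three Monte-Carlo SEs
  set.seed(3)
  for (f in c(0.1, 0.2, 0.5, 0.9)) {
    reg <- fire_regime(f, 1)
    sim <- simulate_fire_history(reg, 10000L, edge = 1L, record = "trace")
    emp <- mean(sim$burnt_frac)
    pi0 <- stationary_burn_fraction(reg)
    se <- sqrt(pi0 * (1 - pi0) / 10000)
    expect_lt(abs(emp - pi0), 3 * se)
  }
})

test_that("analytic age distribution is a distribution with the right shape", {
  reg <- fire_regime(0.2, 1)
  p <- age_distribution_analytic(reg, max_age = 40)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # no refractory protection and certain fire: point mass at age 0
  p1 <- age_distribution_analytic(fire_regime(1, 1, refractory = 1), 10)
  expect_equal(unname(p1[1]), 1)
  expect_equal(sum(p1[-1]), 0)
  expect_error(age_distribution_analytic(fire_regime(0, 1)), "fire_prob")
})

test_that("empirical age histogram matches the analytic distribution", {
  # ~1e5 weakly dependent samples: a 32x32 grid of independent scale-1
  # cells snapshotted every 25 generations after burn-in
  set.seed(4)
  reg <- fire_regime(0.2, 1)
  edge <- 32L
  n <- edge^2
  tsf <- rep(1L, n)
  prev <- rep(FALSE, n)
  advance <- function(k) {
    for (i in seq_len(k)) {
      m <- sample_burn_mask(tsf, prev, reg, edge)
      tsf <<- ifelse(m, 0L, tsf + 1L)
      prev <<- m
    }
  }
  advance(150L)
  samples <- integer(0)
  for (s in 1:98) {
    advance(25L)
    samples <- c(samples, tsf)
  }
  max_age <- 25L
  p <- age_distribution_analytic(reg, max_age)
  obs <- tabulate(pmin(samples, max_age) + 1L, nbins = max_age + 1L)
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("marginal per-cell burn probability is invariant to fire scale", {
  set.seed(5)
  n <- 16L^2
  prev <- rep(FALSE, n)
  for (sc in c(1L, 4L, 16L)) {
    reg <- fire_regime(0.3, sc)
    fracs <- replicate(2000, mean(sample_burn_mask(rep(1L, n), prev, reg)))
    se <- stats::sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - 0.3), 3 * se)
  }
})

test_that("cells burn together within blocks and independently across", {
  set.seed(6)
  reg <- fire_regime(0.5, 4L)
  n <- 16L^2
  prev <- rep(FALSE, n)
  bi <- firecoex:::block_index(16L, 4L)
  block_states <- replicate(2000, {
    m <- sample_burn_mask(rep(1L, n), prev, reg)
    per_block <- tapply(m, bi, mean)
    stopifnot(all(per_block %in% c(0, 1)))  # all-or-none within a block
    per_block
  })
  # across-block independence: pairwise correlation of block indicators ~ 0
  cors <- cor(t(block_states))
  off <- cors[upper.tri(cors)]
  # max over ~120 block pairs: use a 4-sigma band
  expect_lt(max(abs(off)), 4 / sqrt(2000))
})

test_that("fire response respects each functional group", {
  sps <- three_defaults()

  v <- c(500, 0, 100, 0, 0)
  expect_identical(apply_fire_response(v, sps$Triodia_sp, FALSE), v)

  # obligate seeder: adults die, the pool germinates
  set.seed(7)
  out <- apply_fire_response(c(500, 0, 100, 50, 25), sps$Triodia_sp, TRUE)
  expect_equal(out[2], 500 * sps$Triodia_sp$germination)
  expect_equal(sum(out[3:5]), 0)

  # facultative resprouter: adults resprout AND the pool germinates
  out <- apply_fire_response(c(500, 0, 100, 0, 0), sps$T_epactia, TRUE)
  expect_gt(sum(out[3:5]), 0)
  expect_equal(out[2], 500 * sps$T_epactia$germination)

  # obligate resprouter: adults survive and flush a ramet cohort
  v <- c(0, 100, 100, 0, 0, 0)
  out <- apply_fire_response(v, sps$T_bitextura, TRUE)
  surv <- sum(v[2:3]) * sps$T_bitextura$fire_survival[2]
  expect_equal(sum(out[2:6]), surv)
  expect_equal(out[1], surv * sps$T_bitextura$postfire_propagules)
})

test_that("vectorized fire response equals the straight-line oracle", {
  toy <- make_toy("fire_reset")
  set.seed(8)
  for (nm in names(toy$species)) {
    got <- apply_fire_response(toy$vectors[[nm]], toy$species[[nm]], TRUE)
    expect_equal(got, toy$expected[[nm]])
  }
})
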