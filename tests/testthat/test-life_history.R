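test_that("default species encode the stated life histories", {
  sps <- three_defaults()

  expect_equal(sps$T_epactia$climax_stage, 3L)
  expect_equal(sps$T_bitextura$climax_stage, 5L)
  expect_equal(sps$T_epactia$post_climax_survival, 0.9)
  expect_equal(sps$T_bitextura$post_climax_survival, 0.9)

  # obligate resprouter: virtually no seed -- its propagule row is clonal
  # ramet production and it has no seed or seedling stage at all
  expect_identical(sps$T_bitextura$stages[1], "ramet")
  expect_true(is.na(sps$T_bitextura$seedling_stage))
  expect_false(any(c("seed", "seedling") %in% sps$T_bitextura$stages))

  # obligate seeder senesces at 4: no survival out of its last year class
  A <- sps$Triodia_sp$matrix
  last <- ncol(A)
  expect_equal(sum(A[-1, last]), 0)
  expect_equal(sps$Triodia_sp$senescence_age, 4L)

  for (sp in sps) {
    A <- sp$matrix
    # survival/transition entries never exceed 1, column-wise
    expect_true(all(colSums(A[-1, , drop = FALSE]) <= 1 + 1e-12))
    # adult and ramet persistence entries equal 0.9
    n <- ncol(A)
    adult_from <- setdiff(sp$adult_stages, n)
    for (j in adult_from) expect_equal(max(A[-1, j]), 0.9)
    # complete life cycle grows: populations rebound between fires
    expect_gt(asymptotic_growth_rate(sp), 1)
  }
})

test_that("unknown species name errors and lists the valid names", {
  expect_error(default_species("T_nope"), "T_bitextura.*T_epactia.*Triodia_sp")
})

test_that("projection matches hand-computed and trivial cases", {
  m <- hand_matrix()
  expect_equal(project(c(10, 10), m), c(20, 14))
  expect_equal(project(c(3, 7), diag(2)), c(3, 7))
  expect_equal(project(c(0, 0), m), c(0, 0))
  expect_error(project(c(1, 2, 3), m), "dimension mismatch")
  expect_error(project(c(-1, 2), m), "non-negative")
})

test_that("projection is linear", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    m <- matrix(runif(n * n), n, n)
    v1 <- runif(n, 0, 10)
    v2 <- runif(n, 0, 10)
    a <- runif(1, 0, 3)
    b <- runif(1, 0, 3)
    expect_equal(project(a * v1 + b * v2, m),
                 a * project(v1, m) + b * project(v2, m))
  }
})

test_that("asymptotic growth rate is the dominant eigenvalue", {
  expect_equal(asymptotic_growth_rate(diag(3)), 1)
  expect_equal(asymptotic_growth_rate(diag(c(0.9, 0.5))), 0.9)
  # characteristic polynomial of the hand matrix: x^2 - 0.9 x - 1 = 0
  expect_equal(asymptotic_growth_rate(hand_matrix()),
               (0.9 + sqrt(0.81 + 4)) / 2)
  expect_error(asymptotic_growth_rate(matrix(1, 2, 3)), "square")
})

test_that("no-fire trajectories behave as each life history dictates", {
  sps <- three_defaults()

  # clonal resprouter: bounded-or-growing without fire
  sp <- sps$T_bitextura
  v <- numeric(6); v[2:6] <- 100
  v50 <- v
  for (i in 1:50) v50 <- drop(sp$matrix_sim %*% v50)
  expect_gte(sum(v50), sum(v))

  # obligate seeder without fire and without dispersal dies out exactly:
  # germination is fire-gated and every year class senesces
  sp <- sps$Triodia_sp
  v <- numeric(5); v[3:5] <- 100
  for (i in 1:6) v <- drop(sp$matrix_sim %*% v)
  expect_equal(sum(v), 0)
})

test_that("species JSON round-trips through read/write", {
  sps <- three_defaults()
  for (sp in sps) {
    path <- withr::local_tempfile(fileext = ".json")
    write_species(sp, path)
    back <- read_species(path)
    expect_equal(back[setdiff(names(back), "matrix_sim")],
                 sp[setdiff(names(sp), "matrix_sim")])
  }
})

test_that("bundled species files equal the in-code defaults", {
  dir <- system.file("extdata", "species", package = "firecoex")
  expect_true(nzchar(dir))
  for (nm in c("T_bitextura", "T_epactia", "Triodia_sp")) {
    sp <- read_species(file.path(dir, paste0(nm, ".json")))
    expect_equal(sp, default_species(nm))
  }
})
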