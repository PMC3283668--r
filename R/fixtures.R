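## Deterministic toy scenarios and synthetic sweep outputs. Every expected
## value here is produced by deliberately naive straight-line oracles
## (explicit loops, no code shared with the engine), so each engine
## contract can be checked in milliseconds without a full simulation.

## naive matrix-projection oracle: explicit element loops
naive_project <- function(A, v, steps = 1L) {
  for (s in seq_len(steps)) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      acc <- 0
      for (j in seq_along(v)) acc <- acc + A[i, j] * v[j]
      out[i] <- acc
    }
    v <- out
  }
  v
}

## naive fire-response oracle following the stated rules step by step
naive_fire_response <- function(v, sp) {
  out <- numeric(length(v))
  germ <- 0
  if (!is.na(sp$seedling_stage) && sp$fire_response != "obligate_resprouter")
    germ <- v[1] * sp$germination
  for (i in seq_along(v)) {
    keep <- if (i == 1 && germ > 0) v[1] - germ else v[i]
    out[i] <- keep * sp$fire_survival[i]
  }
  if (!is.na(sp$seedling_stage))
    out[sp$seedling_stage] <- out[sp$seedling_stage] + germ
  if (sp$postfire_propagules > 0) {
    adults <- 0
    for (i in sp$adult_stages) adults <- adults + out[i]
    out[1] <- out[1] + sp$postfire_propagules * adults
  }
  out
}

## integer-valued three-stage test species: with an even seed pool every
## engine quantity stays integral, so stochastic rounding is exact and a
## run is bit-comparable with the deterministic oracle
toy_species <- function() {
  A <- matrix(0, 3, 3,
              dimnames = list(c("seed", "juv", "adult"), NULL))
  A[1, 3] <- 2
  A[2, 1] <- 0.5
  A[3, 2] <- 0.5
  A[3, 3] <- 1.0
  species_params("toy", c("seed", "juv", "adult"), A,
                 fire_response = "facultative_resprouter",
                 dispersal_mode = "seed_global", climax_stage = 3L,
                 post_climax_survival = 1.0, adult_stages = 3L,
                 seedling_stage = 2L, germination = 1,
                 fire_gated_germination = FALSE,
                 fire_survival = c(0, 0, 0.5))
}

#' Deterministic toy scenarios
#'
#' Small scripted scenarios whose expected outcomes are computed by
#' independent straight-line oracles, used to exercise each engine
#' contract in isolation:
#'
#' * `"projection_only"`: a 2 x 2 landscape, no fire, no dispersal, no
#'   capacity pressure; three generations of the engine must equal the
#'   thrice-applied projection matrix.
#' * `"fire_reset"`: one-patch landscapes for each of the three default
#'   species with a scripted burn; checks each functional group's fire
#'   response against the oracle.
#' * `"lottery_squeeze"`: a one-patch landscape initialized at twice its
#'   carrying capacity; after one generation the patch must hold exactly
#'   the capacity.
#' * `"seeder_rescue"`: a 2 x 2 landscape with the obligate seeder in one
#'   patch only and no fire; empty patches can be colonized only through
#'   the global seed-dispersal component.
#'
#' @param name scenario name.
#' @return a list bundling the scenario's objects, oracle functions and
#'   expected values (see each scenario's fields).
#' @export
make_toy <- function(name) {
  switch(name,
    projection_only = {
      sp <- toy_species()
      v0 <- c(0, 0, 8)
      list(name = name, species = sp, v0 = v0, steps = 3L,
           edge = 2L, total_capacity = 4e6,
           regime = fire_regime(0, 1L),
           dispersal = dispersal_config(1, 0),
           expected = naive_project(sp$matrix, v0, 3L),
           oracle = naive_project)
    },
    fire_reset = {
      sps <- lapply(c("T_bitextura", "T_epactia", "Triodia_sp"),
                    default_species)
      names(sps) <- vapply(sps, `[[`, character(1), "name")
      vs <- lapply(sps, function(sp) {
        v <- numeric(length(sp$stages))
        v[1] <- 500                       # standing propagule pool
        v[sp$adult_stages] <- 100
        v
      })
      list(name = name, species = sps, vectors = vs,
           expected = Map(naive_fire_response, vs, sps),
           oracle = naive_fire_response)
    },
    lottery_squeeze = {
      sp <- toy_species()
      list(name = name, species = sp, edge = 1L, total_capacity = 100,
           init_adults = 200,
           regime = fire_regime(0, 1L),
           dispersal = dispersal_config(1, 0),
           expected_total = 100)
    },
    seeder_rescue = {
      sp <- default_species("Triodia_sp")
      list(name = name, species = sp, edge = 2L, total_capacity = 4 * 3906,
           source_cell = 1L, generations = 30L,
           regime = fire_regime(0, 1L),
           dispersal_closed = dispersal_config(1, 0),
           dispersal_open = dispersal_config(0.9, 0.1))
    },
    stop("unknown toy scenario '", name, "'"))
}

#' Fabricated sweep with a known diversity ridge
#'
#' Builds an `fc_sweep`-shaped object whose full-community per-patch
#' counts produce a Shannon-Wiener surface peaking exactly at `peak_prob`,
#' with a wider profile at smaller scales. Used to test
#' [diversity_surface()] and [ridge_location()] without running any
#' simulation.
#'
#' @param peak_prob peak fire probability, on the swept grid.
#' @param fire_probs swept probabilities (default 0-1 by 0.1).
#' @param scales swept scales (default `c(1, 4, 16)`).
#' @param replicates fabricated replicates per grid cell.
#' @param n_cells patches per fabricated run.
#' @param single_species fabricate a degenerate one-species community
#'   (every patch fails the all-present filter).
#' @return an object of class `fc_sweep`.
#' @export
make_synthetic_sweep <- function(peak_prob,
                                 fire_probs = round(seq(0, 1, by = 0.1), 10),
                                 scales = c(1L, 4L, 16L), replicates = 3L,
                                 n_cells = 64L, single_species = FALSE) {
  stopifnot(peak_prob %in% fire_probs)
  sp_names <- c("spA", "spB", "spC")
  rows <- list()
  cell_counts <- list()
  for (sc in scales) for (fp in fire_probs) for (r in seq_len(replicates)) {
    delta <- fp - peak_prob
    width <- 0.6 / sqrt(sc)               # wider ridge at smaller scales
    ## dominant share grows away from the peak; slightly faster below it so
    ## the argmax is unique on a symmetric grid
    g <- min(1, abs(delta) * (1 + 0.1 * (delta < 0)) / width)
    dom <- 1 / 3 + (0.6 - 1e-3 * r) * g
    p <- c(dom, rep((1 - dom) / 2, 2))
    counts <- matrix(rep(round(900 * p) + 1, each = n_cells),
                     nrow = n_cells, dimnames = list(NULL, sp_names))
    ## beyond the ridge width the two minority species drop out entirely,
    ## so those grid cells carry no all-present patches
    if (g >= 1) counts[, 2:3] <- 0
    if (single_species) counts[, 2:3] <- 0
    cell_counts[[sprintf("all|%.3f|%d|%d", fp, sc, r)]] <- counts
    rows[[length(rows) + 1L]] <- data.frame(
      configuration = "all", fire_prob = fp, scale = sc, replicate = r,
      seed = NA_integer_, species = sp_names,
      mean_pop = colSums(counts), mean_occ = colMeans(counts > 0))
  }
  structure(list(table = do.call(rbind, rows), cell_counts = cell_counts,
                 meta = list(fire_probs = fire_probs, scales = scales,
                             configurations = "all",
                             replicates = replicates, synthetic = TRUE)),
            class = "fc_sweep")
}
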