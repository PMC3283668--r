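#' Dispersal configuration
#'
#' Seed reproducers keep most seed beneath the parent plant (the
#' fire-gated local pool) and export a small fraction over long distances:
#' exported seed lands uniformly anywhere on the landscape and germinates
#' immediately, without needing fire. The clonal resprouter spreads only
#' into the four orthogonally neighbouring patches, with a per-neighbour
#' event probability that scales linearly with the source patch's adult
#' population relative to its carrying capacity.
#'
#' @param seed_local_fraction fraction of seed staying in the source patch
#'   (default 0.9).
#' @param seed_long_fraction fraction dispersing long-distance (default
#'   0.1); must sum to 1 with `seed_local_fraction`.
#' @param vegetative_rate_scale multiplier on the `N / K` per-neighbour
#'   vegetative event probability.
#' @param ramets_per_event ramets deposited in the neighbour patch by one
#'   vegetative dispersal event.
#' @return An object of class `fc_dispersal`.
#' @export
dispersal_config <- function(seed_local_fraction = 0.9,
                             seed_long_fraction = 0.1,
                             vegetative_rate_scale = 1,
                             ramets_per_event = 20) {
  if (abs(seed_local_fraction + seed_long_fraction - 1) > 1e-9)
    stop("seed_local_fraction and seed_long_fraction must sum to 1")
  stopifnot(seed_local_fraction >= 0, seed_long_fraction >= 0,
            vegetative_rate_scale >= 0, ramets_per_event >= 0)
  structure(list(seed_local_fraction = seed_local_fraction,
                 seed_long_fraction = seed_long_fraction,
                 vegetative_rate_scale = vegetative_rate_scale,
                 ramets_per_event = ramets_per_event),
            class = "fc_dispersal")
}

## 4-neighbour (von Neumann) index table; NA beyond the grid edge
## (absorbing boundary, no wraparound)
neighbour_index <- function(edge) {
  n <- edge * edge
  i <- seq_len(n)
  x <- (i - 1L) %% edge + 1L
  y <- (i - 1L) %/% edge + 1L
  cbind(ifelse(x > 1L, i - 1L, NA_integer_),
        ifelse(x < edge, i + 1L, NA_integer_),
        ifelse(y > 1L, i - edge, NA_integer_),
        ifelse(y < edge, i + edge, NA_integer_))
}

#' Vegetative (clonal) dispersal into neighbouring patches
#'
#' For every source patch, a dispersal event into each of its four
#' orthogonal neighbours occurs independently with probability
#' `vegetative_rate_scale * N / K`, where `N` is the source patch's adult
#' count and `K` the patch capacity. An event deposits `ramets_per_event`
#' new ramets into the neighbour's propagule stage. Ramets are new clonal
#' individuals: the source population is not debited.
#'
#' @param l an `fc_landscape`.
#' @param sp_name name of a species with `dispersal_mode
#'   = "vegetative_neighbour"`.
#' @param cfg a [dispersal_config()].
#' @return the updated landscape.
#' @export
disperse_vegetative <- function(l, sp_name, cfg = dispersal_config()) {
  check_species(l, sp_name)
  sp <- l$species[[sp_name]]
  if (sp$dispersal_mode != "vegetative_neighbour")
    stop("disperse_vegetative() requires dispersal_mode 'vegetative_neighbour'")
  p_event <- pmin(1, cfg$vegetative_rate_scale *
                       adult_counts(l, sp_name) / l$cell_capacity)
  if (all(p_event == 0) || cfg$ramets_per_event == 0) return(l)
  nb <- neighbour_index(l$edge)
  deposit <- numeric(l$n_cells)
  for (d in 1:4) {
    ok <- !is.na(nb[, d]) & p_event > 0
    ev <- ok & (stats::runif(l$n_cells) < p_event)
    if (any(ev)) {
      tgt <- nb[ev, d]
      deposit[tgt] <- deposit[tgt] + cfg$ramets_per_event
    }
  }
  l$pop[[sp_name]][1L, ] <- l$pop[[sp_name]][1L, ] + deposit
  l
}

#' Seed dispersal with a global long-distance component
#'
#' Each patch's seed pool is split: `seed_local_fraction` stays in the
#' patch's fire-gated pool, `seed_long_fraction` is exported. The exported
#' total (stochastically rounded to a whole number of seeds) is scattered
#' over patches drawn uniformly at random across the whole landscape, and
#' these immigrant seeds germinate immediately into the seedling stage --
#' no fire required.
#'
#' @param l an `fc_landscape`.
#' @param sp_name name of a species with `dispersal_mode = "seed_global"`.
#' @param cfg a [dispersal_config()].
#' @return the updated landscape.
#' @export
disperse_seed <- function(l, sp_name, cfg = dispersal_config()) {
  check_species(l, sp_name)
  sp <- l$species[[sp_name]]
  if (sp$dispersal_mode != "seed_global")
    stop("disperse_seed() requires dispersal_mode 'seed_global'")
  pool <- l$pop[[sp_name]][1L, ]
  exported <- cfg$seed_long_fraction * pool
  l$pop[[sp_name]][1L, ] <- pool - exported
  deposit_seed(l, sp_name, sum(exported))
}

## scatter an exported seed mass uniformly over the landscape; immigrant
## seed germinates immediately into the seedling stage
deposit_seed <- function(l, sp_name, exported_total) {
  sp <- l$species[[sp_name]]
  n_seeds <- stoch_round(exported_total)
  if (n_seeds > 0) {
    landed <- drop(stats::rmultinom(1L, size = n_seeds,
                                    prob = rep(1, l$n_cells)))
    l$pop[[sp_name]][sp$seedling_stage, ] <-
      l$pop[[sp_name]][sp$seedling_stage, ] +
      stoch_round(landed * sp$germination)
  }
  l
}
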