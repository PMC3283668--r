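#' Simulation run configuration
#'
#' Bundles everything one model run needs: the species set, the fire
#' regime, the dispersal settings, the landscape geometry and the run
#' protocol (generations, recording window, seed). The default protocol is
#' 200 generations with summaries averaged over the last 5.
#'
#' @param species an `fc_species` or list of 1-3 of them.
#' @param regime an [fire_regime()].
#' @param dispersal a [dispersal_config()].
#' @param generations generations per run (default 200).
#' @param record_window number of final generations averaged into the run
#'   summary (default 5).
#' @param edge landscape edge in cells (default 16).
#' @param total_capacity landscape carrying capacity (default `1e6`).
#' @param init_tsf initial time-since-fire (default 1).
#' @param occupancy_threshold adults needed for a patch to count as
#'   occupied / present (default 1).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `fc_config`.
#' @export
sim_config <- function(species, regime, dispersal = dispersal_config(),
                       generations = 200L, record_window = 5L,
                       edge = 16L, total_capacity = 1e6, init_tsf = 1L,
                       occupancy_threshold = 1, seed = NULL) {
  if (inherits(species, "fc_species")) species <- list(species)
  stopifnot(record_window >= 1, record_window <= generations)
  structure(list(species = species, regime = regime, dispersal = dispersal,
                 generations = as.integer(generations),
                 record_window = as.integer(record_window),
                 edge = as.integer(edge), total_capacity = total_capacity,
                 init_tsf = as.integer(init_tsf),
                 occupancy_threshold = occupancy_threshold, seed = seed),
            class = "fc_config")
}

#' Advance the landscape by one generation
#'
#' Applies, in order: (1) deterministic matrix projection of every patch
#' population (with in-situ germination masked for the fire-gated species);
#' (2) the stochastic burn mask and each species' fire response; (3)
#' dispersal, vegetative or seed-based according to the species' mode; (4)
#' the carrying-capacity lottery in every patch; then updates the fire
#' history (time-since-fire, previous-generation burn flags).
#'
#' @param l an `fc_landscape`.
#' @param regime an [fire_regime()].
#' @param dispersal a [dispersal_config()].
#' @param forced_mask optional logical vector overriding the stochastic
#'   burn mask (used by scripted test scenarios).
#' @return the landscape after one full generation.
#' @export
step_generation <- function(l, regime, dispersal = dispersal_config(),
                            forced_mask = NULL) {
  ## 1. projection (refreshes each seed pool: row 1 only receives fecundity)
  for (nm in names(l$species))
    l$pop[[nm]] <- l$species[[nm]]$matrix_sim %*% l$pop[[nm]]
  ## the long-distance share of each seed crop leaves the patch at seed
  ## shed, before any fire can consume it; it lands after the fire
  exported <- numeric(0)
  for (nm in names(l$species)) {
    if (l$species[[nm]]$dispersal_mode == "seed_global") {
      pool <- l$pop[[nm]][1L, ]
      exported[nm] <- dispersal$seed_long_fraction * sum(pool)
      l$pop[[nm]][1L, ] <- dispersal$seed_local_fraction * pool
    }
  }
  ## 2. fire
  mask <- if (is.null(forced_mask))
    sample_burn_mask(l$tsf, l$burnt_prev, regime, l$edge) else forced_mask
  for (nm in names(l$species))
    l$pop[[nm]] <- fire_response_pop(l$pop[[nm]], l$species[[nm]], mask)
  ## 3. dispersal
  for (nm in names(l$species)) {
    if (l$species[[nm]]$dispersal_mode == "vegetative_neighbour")
      l <- disperse_vegetative(l, nm, dispersal)
    else
      l <- deposit_seed(l, nm, exported[nm])
  }
  ## 4. competition for space
  l <- apply_competition(l)
  ## fire history bookkeeping
  l$tsf <- ifelse(mask, 0L, l$tsf + 1L)
  l$burnt_prev <- mask
  l
}

#' Execute one full model run
#'
#' Initializes the landscape, steps it for `generations` generations, and
#' summarizes the recording window: per-species mean total population and
#' mean occupancy over the last `record_window` generations, the
#' record-window mean per-patch adult counts (needed for diversity
#' analysis), and the final patch-age histogram. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg an [sim_config()].
#' @param return_landscape keep the final `fc_landscape` in the result.
#' @return An object of class `fc_run`.
#' @export
run_sim <- function(cfg, return_landscape = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  l <- init_landscape(cfg$species, edge = cfg$edge,
                      total_capacity = cfg$total_capacity,
                      init_tsf = cfg$init_tsf)
  sp_names <- names(l$species)
  rec_from <- cfg$generations - cfg$record_window + 1L
  pop_acc <- occ_acc <- stats::setNames(numeric(length(sp_names)), sp_names)
  cells_acc <- matrix(0, nrow = l$n_cells, ncol = length(sp_names),
                      dimnames = list(NULL, sp_names))
  for (g in seq_len(cfg$generations)) {
    l <- step_generation(l, cfg$regime, cfg$dispersal)
    if (g >= rec_from) {
      for (nm in sp_names) {
        ac <- adult_counts(l, nm)
        pop_acc[nm] <- pop_acc[nm] + sum(ac)
        occ_acc[nm] <- occ_acc[nm] + mean(ac >= cfg$occupancy_threshold)
        cells_acc[, nm] <- cells_acc[, nm] + ac
      }
    }
  }
  w <- cfg$record_window
  out <- list(species = sp_names,
              mean_pop = pop_acc / w,
              mean_occ = occ_acc / w,
              cell_counts = cells_acc / w,
              age_hist = age_histogram(l),
              final_tsf = l$tsf,
              config = cfg)
  if (return_landscape) out$landscape <- l
  structure(out, class = "fc_run")
}

#' @export
print.fc_run <- function(x, ...) {
  cat("<fc_run> p =", x$config$regime$fire_prob,
      "scale =", x$config$regime$scale,
      "| record-window means:\n")
  for (nm in x$species)
    cat(sprintf("  %-12s pop %10.1f  occupancy %.3f\n", nm,
                x$mean_pop[nm], x$mean_occ[nm]))
  invisible(x)
}

## deterministic per-run child seeds; stays below 2^31 - 1.
## Consecutive run indices must give statistically unrelated seeds: R's
## Mersenne-Twister state is filled from the seed by a linear congruence,
## so arithmetic seed sequences can leave replicate streams correlated.
## A splitmix-style avalanche hash breaks that structure (32-bit arithmetic
## emulated exactly in doubles: products are split so nothing exceeds 2^53).
derive_seed <- function(master, index) {
  mul32 <- function(a, b) {
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (lo * b + (hi * b %% 65536) * 65536) %% 4294967296
  }
  x <- (as.numeric(master) %% 4294967296) + mul32(as.numeric(index) %%
         4294967296, 2654435769)
  for (i in 1:2) {
    x <- (x + 2654435769) %% 4294967296
    x <- bitwXor64(x, floor(x / 65536))
    x <- mul32(x, 2246822519)
    x <- bitwXor64(x, floor(x / 8192))
    x <- mul32(x, 3266489917)
    x <- bitwXor64(x, floor(x / 32768))
  }
  as.integer(x %% 2147483646) + 1L
}

## xor of two non-negative doubles < 2^32, computed in 16-bit limbs
bitwXor64 <- function(a, b) {
  a_lo <- a %% 65536; a_hi <- (a - a_lo) / 65536
  b_lo <- b %% 65536; b_hi <- (b - b_lo) / 65536
  bitwXor(as.integer(a_lo), as.integer(b_lo)) +
    bitwXor(as.integer(a_hi %% 65536), as.integer(b_hi %% 65536)) * 65536
}

species_sets <- function(pool, configurations) {
  sets <- list()
  if ("single" %in% configurations)
    for (k in seq_along(pool))
      sets[[length(sets) + 1L]] <-
        list(label = paste0("single:", pool[[k]]$name), idx = k)
  if ("pairs" %in% configurations && length(pool) >= 2)
    for (cmb in utils::combn(length(pool), 2, simplify = FALSE))
      sets[[length(sets) + 1L]] <-
        list(label = paste0("pair:", paste(vapply(pool[cmb], `[[`,
             character(1), "name"), collapse = "+")), idx = cmb)
  if ("all" %in% configurations && length(pool) >= 2)
    sets[[length(sets) + 1L]] <- list(label = "all",
                                      idx = seq_along(pool))
  sets
}

#' Regime-grid sweep over species configurations
#'
#' Runs every combination of (species configuration, fire probability,
#' fire scale) with `replicates` independently seeded runs, and returns a
#' long table of record-window summaries plus, for the full-community
#' configuration, the per-patch adult counts needed to compute diversity
#' surfaces. Each run's seed is derived deterministically from the master
#' seed and recorded in the table, so any row can be reproduced in
#' isolation.
#'
#' @param species_pool list of `fc_species` (default: the three bundled
#'   species).
#' @param fire_probs fire probabilities to sweep (default 0-1 by 0.1).
#' @param scales fire scales to sweep (default `c(1, 2, 4, 8, 16)`).
#' @param configurations subset of `c("single", "pairs", "all")`.
#' @param replicates replicate runs per grid cell (default 20).
#' @param seed master seed.
#' @param keep_cells configurations for which per-patch counts are kept
#'   (default `"all"`; needed by [diversity_surface()]).
#' @param refractory fuel-memory modifier passed to every regime.
#' @param progress print one line per sweep cell to `stderr`.
#' @inheritParams sim_config
#' @return An object of class `fc_sweep`: `table` (one row per run and
#'   species), `cell_counts` (named list of patch-by-species matrices) and
#'   `meta`.
#' @export
sweep_sim <- function(species_pool = lapply(c("T_bitextura", "T_epactia",
                                              "Triodia_sp"), default_species),
                      fire_probs = round(seq(0, 1, by = 0.1), 10),
                      scales = c(1L, 2L, 4L, 8L, 16L),
                      configurations = c("single", "pairs", "all"),
                      replicates = 20L, generations = 200L,
                      record_window = 5L, edge = 16L,
                      dispersal = dispersal_config(), refractory = 0.3,
                      total_capacity = 1e6, seed = 1L,
                      keep_cells = "all", progress = FALSE) {
  stopifnot(length(fire_probs) > 0, length(scales) > 0)
  configurations <- match.arg(configurations, several.ok = TRUE)
  sets <- species_sets(species_pool, configurations)
  rows <- list()
  cell_counts <- list()
  run_index <- 0L
  for (set in sets) {
    sp_list <- species_pool[set$idx]
    for (sc in scales) for (fp in fire_probs) {
      if (progress)
        message(sprintf("sweep: %s scale=%d p=%.1f", set$label, sc, fp))
      for (rep_i in seq_len(replicates)) {
        run_index <- run_index + 1L
        child <- derive_seed(seed, run_index)
        cfg <- sim_config(sp_list, fire_regime(fp, sc, refractory),
                          dispersal = dispersal, generations = generations,
                          record_window = record_window, edge = edge,
                          total_capacity = total_capacity, seed = child)
        res <- run_sim(cfg)
        rows[[length(rows) + 1L]] <- data.frame(
          configuration = set$label, fire_prob = fp, scale = sc,
          replicate = rep_i, seed = child, species = res$species,
          mean_pop = unname(res$mean_pop), mean_occ = unname(res$mean_occ),
          row.names = NULL)
        if (set$label %in% keep_cells || identical(keep_cells, "every"))
          cell_counts[[sprintf("%s|%.3f|%d|%d", set$label, fp, sc, rep_i)]] <-
            res$cell_counts
      }
    }
  }
  structure(list(table = do.call(rbind, rows), cell_counts = cell_counts,
                 meta = list(fire_probs = fire_probs, scales = scales,
                             configurations = configurations,
                             replicates = replicates,
                             generations = generations,
                             record_window = record_window, edge = edge,
                             refractory = refractory, seed = seed)),
            class = "fc_sweep")
}

#' @export
print.fc_sweep <- function(x, ...) {
  m <- x$meta
  cat("<fc_sweep>", nrow(x$table), "rows |",
      length(m$fire_probs), "probs x", length(m$scales), "scales x",
      m$replicates, "replicates |",
      paste(m$configurations, collapse = "/"), "\n")
  invisible(x)
}

#' Aggregate a sweep over replicates
#'
#' Means and standard deviations of population and occupancy per
#' (configuration, species, fire probability, scale), plus the
#' majority-vote persistence classification: a grid cell is persistent for
#' a species when the record-window mean population is positive in more
#' than half of the replicates.
#'
#' @param sw an `fc_sweep`.
#' @return data.frame, one row per (configuration, species, fire_prob,
#'   scale).
#' @export
summarize_sweep <- function(sw) {
  tb <- sw$table
  key <- interaction(tb$configuration, tb$species, tb$fire_prob, tb$scale,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(tb, key), function(d) data.frame(
    configuration = d$configuration[1], species = d$species[1],
    fire_prob = d$fire_prob[1], scale = d$scale[1],
    n_replicates = nrow(d),
    mean_pop = mean(d$mean_pop), sd_pop = stats::sd(d$mean_pop),
    se_pop = stats::sd(d$mean_pop) / sqrt(nrow(d)),
    mean_occ = mean(d$mean_occ), sd_occ = stats::sd(d$mean_occ),
    persistent = mean(d$mean_pop > 0) > 0.5,
    row.names = NULL)))
  rownames(agg) <- NULL
  agg[order(agg$configuration, agg$species, agg$scale, agg$fire_prob), ]
}

#' Persistence thresholds on the fire-probability grid
#'
#' Helpers that turn the majority-vote persistence classification of a
#' single-species sweep into the threshold statistics used to characterize
#' each functional type's fire-response envelope.
#'
#' `robust_persistence_threshold()` returns the smallest probability `p`
#' on the swept grid such that every probability strictly greater than `p`
#' is persistent at all swept scales (the last failing probability; the
#' grid minimum when nothing fails). `largest_persistent_prob()` and
#' `smallest_nonpersistent_prob()` read the corresponding extremes at one
#' scale.
#'
#' @param sw an `fc_sweep` containing the relevant single-species runs.
#' @param species species name.
#' @param scales scales to require (default: all swept scales).
#' @return a fire probability from the swept grid (or `NA` if undefined).
#' @rdname persistence_thresholds
#' @export
robust_persistence_threshold <- function(sw, species,
                                         scales = sw$meta$scales) {
  ag <- persistence_by_prob(sw, species, scales)
  probs <- sort(unique(ag$fire_prob))
  ok <- vapply(probs, function(p)
    all(ag$persistent[ag$fire_prob == p]), logical(1))
  if (all(ok)) return(probs[1])
  max(probs[!ok])
}

#' @rdname persistence_thresholds
#' @param scale single scale for the one-scale extremes.
#' @export
largest_persistent_prob <- function(sw, species, scale) {
  ag <- persistence_by_prob(sw, species, scale)
  if (!any(ag$persistent)) return(NA_real_)
  max(ag$fire_prob[ag$persistent])
}

#' @rdname persistence_thresholds
#' @export
smallest_nonpersistent_prob <- function(sw, species, scale) {
  ag <- persistence_by_prob(sw, species, scale)
  if (all(ag$persistent)) return(NA_real_)
  min(ag$fire_prob[!ag$persistent])
}

persistence_by_prob <- function(sw, species, scales) {
  ag <- summarize_sweep(sw)
  ag <- ag[ag$species == species & ag$scale %in% scales &
           startsWith(ag$configuration, "single:"), ]
  if (nrow(ag) == 0)
    stop("no single-species rows for '", species, "' at the requested scales")
  ag
}
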