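#' Fire regime description
#'
#' The fire process has three knobs. `fire_prob` is the per-generation
#' probability that an ignition block experiences a fire (the swept "fire
#' frequency" axis). `scale` is the edge length, in cells, of the square
#' ignition block: the grid is partitioned into aligned `scale` x `scale`
#' blocks, each of which ignites independently, so scale 16 on a 16 x 16
#' grid is a single fire across the whole landscape. `refractory` is the
#' conditional probability that an ignited cell actually burns when it
#' already burnt the previous generation (fuel has not re-accumulated);
#' cells not burnt the previous generation burn with conditional
#' probability 1.
#'
#' @param fire_prob per-generation block ignition probability in `[0, 1]`.
#' @param scale ignition block edge length (must divide the grid edge).
#' @param refractory fuel-memory modifier in `[0, 1]`, default 0.3.
#' @return An object of class `fc_regime`.
#' @export
fire_regime <- function(fire_prob, scale = 1L, refractory = 0.3) {
  stopifnot(fire_prob >= 0, fire_prob <= 1,
            refractory >= 0, refractory <= 1, scale >= 1)
  structure(list(fire_prob = fire_prob, scale = as.integer(scale),
                 refractory = refractory),
            class = "fc_regime")
}

#' @export
print.fc_regime <- function(x, ...) {
  cat("<fc_regime> p =", x$fire_prob, "| scale =", x$scale,
      "| refractory =", x$refractory, "\n")
  invisible(x)
}

## aligned block id (1-based) for each cell of an edge x edge grid,
## column-of-blocks major; cells are indexed i = (y-1)*edge + x
block_index <- function(edge, scale) {
  if (edge %% scale != 0)
    stop("fire scale ", scale, " does not divide the grid edge ", edge)
  x <- ((seq_len(edge * edge) - 1L) %% edge)
  y <- ((seq_len(edge * edge) - 1L) %/% edge)
  (x %/% scale) + (y %/% scale) * (edge %/% scale) + 1L
}

#' Draw one generation's burn mask
#'
#' The per-cell probability of fire is the product of two probabilities:
#' the block ignition probability and the fuel-conditional probability
#' (1 for cells unburnt in the previous generation, `refractory` for cells
#' that burnt). Within an ignited block every cell with fuel burns; cells
#' in non-ignited blocks never burn.
#'
#' @param ages per-cell time-since-fire (used only for its length / shape).
#' @param burnt_prev logical per cell: burnt in the previous generation.
#' @param regime an [fire_regime()].
#' @param edge grid edge length; defaults to `sqrt(length(burnt_prev))`.
#' @return logical vector: burnt this generation.
#' @export
sample_burn_mask <- function(ages, burnt_prev, regime,
                             edge = as.integer(round(sqrt(length(burnt_prev))))) {
  n <- length(burnt_prev)
  if (n != edge * edge) stop("burnt_prev length does not match grid edge")
  bi <- block_index(edge, regime$scale)
  nb <- max(bi)
  ignited <- stats::runif(nb) < regime$fire_prob
  p_fuel <- ifelse(burnt_prev, regime$refractory, 1)
  ignited[bi] & (stats::runif(n) < p_fuel)
}

#' Stationary burnt fraction of a single cell
#'
#' Closed form for the two-state fuel-memory chain at scale 1: a cell burns
#' with probability `f` when it did not burn last generation and `r * f`
#' when it did. The stationary per-generation burn probability solves
#' `pi = pi * r * f + (1 - pi) * f`, giving `pi = f / (1 + (1 - r) * f)`.
#'
#' @param regime an [fire_regime()].
#' @return the stationary burnt fraction.
#' @export
stationary_burn_fraction <- function(regime) {
  f <- regime$fire_prob
  r <- regime$refractory
  f / (1 + (1 - r) * f)
}

#' Stationary time-since-fire distribution of a single cell
#'
#' The fire-return process with fuel memory yields, at stationarity,
#' `P(age = 0) = pi` and `P(age = t) = pi * (1 - r f) * (1 - f)^(t-1)` for
#' `t >= 1` (a refractory-thinned geometric tail, the distribution the paper
#' of record for this landscape describes as negative-binomial-like).
#'
#' @param regime an [fire_regime()]; `fire_prob` must be positive.
#' @param max_age ages `0 .. max_age` are returned; the mass beyond
#'   `max_age` is aggregated into the last entry.
#' @return named probability vector over ages `0 .. max_age` (last entry is
#'   the aggregated open tail); sums to 1.
#' @export
age_distribution_analytic <- function(regime, max_age = 30L) {
  f <- regime$fire_prob
  r <- regime$refractory
  if (f <= 0) stop("no stationary age distribution when fire_prob = 0")
  pi0 <- stationary_burn_fraction(regime)
  ## exact mass at ages 0 .. max_age - 1, open tail aggregated in the last bin
  ages <- seq_len(max_age) - 1L
  p <- c(pi0, pi0 * (1 - r * f) * (1 - f)^(ages[-1] - 1))
  p <- c(p, max(0, 1 - sum(p)))
  names(p) <- c(ages, paste0(">=", max_age))
  p
}

#' Simulate the fire process alone
#'
#' Runs the burn-mask process on a grid with no demography, tracking
#' per-cell time-since-fire. Used for oracle cross-validation of
#' [stationary_burn_fraction()] / [age_distribution_analytic()] and for
#' fire-return-interval (patch age) analyses.
#'
#' @param regime an [fire_regime()].
#' @param generations number of generations to simulate.
#' @param edge grid edge length (default 16; use 1 for a single cell).
#' @param init_tsf initial time-since-fire for every cell.
#' @param record `"final"` returns only the final state; `"trace"`
#'   additionally records cell 1's age and the landscape burnt fraction at
#'   every generation.
#' @return list with `tsf` (final per-cell ages), `burnt_prev`, and when
#'   tracing, `age_trace` and `burnt_frac` (per-generation).
#' @export
simulate_fire_history <- function(regime, generations, edge = 16L,
                                  init_tsf = 1L,
                                  record = c("final", "trace")) {
  record <- match.arg(record)
  n <- edge * edge
  tsf <- rep(as.integer(init_tsf), n)
  burnt_prev <- rep(FALSE, n)
  trace_age <- if (record == "trace") integer(generations) else NULL
  trace_bf <- if (record == "trace") numeric(generations) else NULL
  for (g in seq_len(generations)) {
    mask <- sample_burn_mask(tsf, burnt_prev, regime, edge)
    tsf <- ifelse(mask, 0L, tsf + 1L)
    burnt_prev <- mask
    if (record == "trace") {
      trace_age[g] <- tsf[1L]
      trace_bf[g] <- mean(mask)
    }
  }
  out <- list(tsf = tsf, burnt_prev = burnt_prev)
  if (record == "trace") {
    out$age_trace <- trace_age
    out$burnt_frac <- trace_bf
  }
  out
}

#' Post-fire demographic response of one patch
#'
#' If the patch did not burn the stage vector is returned unchanged. In a
#' burnt patch: standing individuals survive according to the species'
#' per-stage fire-survival schedule (zero for the obligate seeder, the
#' resprouting survival for adults of the two resprouters, zero for
#' first-year seedlings); the seed pool of seed reproducers germinates into
#' the seedling stage (fraction `germination`); and surviving adults of the
#' obligate resprouter produce a post-fire ramet cohort.
#'
#' The germinating cohort is converted to an integer count by stochastic
#' rounding, so small populations can genuinely fail to recruit.
#'
#' @param v stage vector of one patch.
#' @param sp an `fc_species`.
#' @param burnt logical: did this patch burn.
#' @return the post-fire stage vector.
#' @export
apply_fire_response <- function(v, sp, burnt) {
  if (!burnt) return(v)
  drop(fire_response_pop(cbind(as.numeric(v)), sp, TRUE))
}

## vectorized fire response over a stage-by-patch matrix; mask is logical
## per patch
fire_response_pop <- function(pop, sp, mask) {
  if (!any(mask)) return(pop)
  idx <- which(mask)
  sub <- pop[, idx, drop = FALSE]
  germ <- numeric(length(idx))
  if (!is.na(sp$seedling_stage) && sp$fire_response != "obligate_resprouter") {
    germ <- stoch_round(sub[1L, ] * sp$germination)
    sub[1L, ] <- sub[1L, ] * (1 - sp$germination)
  }
  sub <- sub * sp$fire_survival
  if (!is.na(sp$seedling_stage))
    sub[sp$seedling_stage, ] <- sub[sp$seedling_stage, ] + germ
  if (sp$postfire_propagules > 0) {
    adults <- colSums(sub[sp$adult_stages, , drop = FALSE])
    sub[1L, ] <- sub[1L, ] + sp$postfire_propagules * adults
  }
  pop[, idx] <- sub
  pop
}
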