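#' Expectation-preserving stochastic rounding
#'
#' Converts real-valued expected counts to integers without drift:
#' `floor(x)` plus a Bernoulli draw on the fractional part, so
#' `E[stoch_round(x)] = x` exactly.
#'
#' @param x non-negative numeric vector.
#' @return integer-valued numeric vector of the same length.
#' @export
stoch_round <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  fl <- floor(x)
  fr <- x - fl
  fl + (stats::runif(length(x)) < fr)
}

#' Carrying-capacity survival lottery for one patch
#'
#' Competition for space acts on adults only. Expected adult counts per
#' (species, age-class) category are first converted to integers by
#' stochastic rounding. If the rounded total does not exceed the patch
#' carrying capacity the counts pass through unchanged; otherwise the
#' surviving adults are one multinomial draw of size `capacity` with
#' category probabilities proportional to the expected counts, so a
#' category with more expected recruits wins proportionally more of the
#' limited space.
#'
#' @param x non-negative numeric vector of expected adult counts, one entry
#'   per (species, age-class) category.
#' @param capacity integer patch carrying capacity (> 0).
#' @return integer-valued vector of realized adult counts; its total never
#'   exceeds `capacity` when the expected total does not round below it.
#' @export
lottery <- function(x, capacity) {
  if (any(x < 0)) stop("expected counts must be non-negative")
  if (capacity <= 0) stop("capacity must be positive")
  rounded <- stoch_round(x)
  if (sum(rounded) <= capacity) return(rounded)
  drop(stats::rmultinom(1L, size = capacity, prob = x))
}

## Landscape-level competition step. Builds the (species x adult-class) by
## patch matrix of expected adults, stochastically rounds everything, and
## redraws over-capacity patches from the multinomial lottery. Non-adult
## stages are untouched (the seed pool stays real-valued; seedling cohorts
## are already integerized at germination).
apply_competition <- function(l) {
  sp_names <- names(l$species)
  rows <- lapply(sp_names, function(nm)
    l$pop[[nm]][l$species[[nm]]$adult_stages, , drop = FALSE])
  E <- do.call(rbind, rows)
  R <- matrix(stoch_round(E), nrow = nrow(E))
  totals <- colSums(R)
  over <- which(totals > l$cell_capacity)
  for (cell in over)
    R[, cell] <- stats::rmultinom(1L, size = l$cell_capacity,
                                  prob = E[, cell])
  ## write the realized counts back per species
  offset <- 0L
  for (nm in sp_names) {
    st <- l$species[[nm]]$adult_stages
    l$pop[[nm]][st, ] <- R[offset + seq_along(st), , drop = FALSE]
    offset <- offset + length(st)
  }
  l
}
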