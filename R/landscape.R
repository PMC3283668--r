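#' Initialize the model landscape
#'
#' The landscape is an `edge` x `edge` lattice of 100 m x 100 m patches with
#' a shared total carrying capacity (default one million adults, i.e. 3906
#' adults per patch on the default 16 x 16 grid). Every patch is assigned to
#' exactly one species (the species form monospecific stands), uniformly at
#' random, and assigned patches start at the species' pre-fire adult
#' condition: the patch capacity spread evenly across the established adult
#' year classes.
#'
#' @param species a single `fc_species` or a list of 1-3 of them.
#' @param edge grid edge length in cells (default 16).
#' @param total_capacity landscape carrying capacity in adults (default
#'   `1e6`); the per-cell capacity is `floor(total_capacity / edge^2)`.
#' @param init_tsf initial per-cell time-since-fire (default 1, the
#'   pre-fire condition).
#' @return An object of class `fc_landscape`: per-species stage-by-patch
#'   abundance matrices plus per-cell fire history.
#' @export
init_landscape <- function(species, edge = 16L, total_capacity = 1e6,
                           init_tsf = 1L) {
  if (inherits(species, "fc_species")) species <- list(species)
  if (length(species) < 1) stop("at least one species is required")
  if (!all(vapply(species, inherits, logical(1), "fc_species")))
    stop("species must be fc_species objects")
  names(species) <- vapply(species, `[[`, character(1), "name")
  n <- as.integer(edge)^2
  K <- floor(total_capacity / n)
  assign <- sample.int(length(species), n, replace = TRUE)
  pop <- lapply(seq_along(species), function(k) {
    sp <- species[[k]]
    m <- matrix(0, nrow = length(sp$stages), ncol = n,
                dimnames = list(sp$stages, NULL))
    init <- which(assign == k)
    ## pre-fire adult condition: capacity split across established classes
    ## (the propagule pool starts empty)
    est <- setdiff(sp$adult_stages, 1L)
    m[est, init] <- K / length(est)
    m
  })
  names(pop) <- names(species)
  structure(list(edge = as.integer(edge), n_cells = n,
                 cell_capacity = K, total_capacity = total_capacity,
                 species = species, pop = pop,
                 tsf = rep(as.integer(init_tsf), n),
                 burnt_prev = rep(FALSE, n)),
            class = "fc_landscape")
}

#' @export
print.fc_landscape <- function(x, ...) {
  cat("<fc_landscape> ", x$edge, "x", x$edge, " patches, capacity ",
      x$cell_capacity, "/cell\n", sep = "")
  for (nm in names(x$species))
    cat(sprintf("  %-12s pop %10.0f  occupancy %.2f\n", nm,
                total_population(x, nm), occupancy(x, nm)))
  invisible(x)
}

adult_counts <- function(l, sp_name) {
  sp <- l$species[[sp_name]]
  colSums(l$pop[[sp_name]][sp$adult_stages, , drop = FALSE])
}

check_species <- function(l, sp_name) {
  if (!sp_name %in% names(l$species))
    stop("species '", sp_name, "' is not part of this landscape")
}

#' Patch occupancy of a species
#'
#' Fraction of patches holding at least `threshold` adult-equivalent
#' individuals of the species (1 = 100 % of patches).
#'
#' @param l an `fc_landscape`.
#' @param sp_name species name.
#' @param threshold minimum adult count for a patch to count as occupied.
#' @return proportion in `[0, 1]`.
#' @export
occupancy <- function(l, sp_name, threshold = 1) {
  check_species(l, sp_name)
  mean(adult_counts(l, sp_name) >= threshold)
}

#' Total landscape population of a species
#'
#' Sum of adult-equivalent individuals over all patches. Bounded by the
#' total carrying capacity after the competition step.
#'
#' @inheritParams occupancy
#' @return non-negative total.
#' @export
total_population <- function(l, sp_name) {
  check_species(l, sp_name)
  sum(adult_counts(l, sp_name))
}

#' Histogram of patch ages (time since last fire)
#'
#' Counts patches by time-since-fire; the final bin is open-ended.
#'
#' @param l an `fc_landscape` (or any object with a `tsf` field).
#' @param bins number of single-year bins; ages `>= bins` are pooled into
#'   the last, open-ended bin.
#' @return named integer vector of length `bins + 1`, summing to the number
#'   of patches.
#' @export
age_histogram <- function(l, bins = 20L) {
  tsf <- l$tsf
  cut_age <- pmin(tsf, bins)
  counts <- tabulate(cut_age + 1L, nbins = bins + 1L)
  names(counts) <- c(seq_len(bins) - 1L, paste0(">=", bins))
  counts
}

#' Export a landscape snapshot as a tidy data frame
#'
#' Long format, one row per (cell, species, stage): useful for debugging
#' and plotting.
#'
#' @param x an `fc_landscape`.
#' @param ... unused.
#' @return data.frame with cell coordinates, species, stage, count and
#'   time-since-fire.
#' @export
as.data.frame.fc_landscape <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$species), function(nm) {
    p <- x$pop[[nm]]
    data.frame(
      cell = rep(seq_len(x$n_cells), each = nrow(p)),
      species = nm,
      stage = rep(rownames(p), times = x$n_cells),
      count = as.vector(p))
  }))
  out$cell_x <- (out$cell - 1L) %% x$edge + 1L
  out$cell_y <- (out$cell - 1L) %/% x$edge + 1L
  out$time_since_fire <- x$tsf[out$cell]
  out[, c("cell", "cell_x", "cell_y", "species", "stage", "count",
          "time_since_fire")]
}
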