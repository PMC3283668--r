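#' Shannon-Wiener diversity index
#'
#' `H = -sum(p_i * log(p_i))` over species proportions, natural logarithm;
#' zero-count species contribute nothing. Maximal at `log(S)` under exact
#' equipartition of `S` species.
#'
#' @param counts non-negative species counts; at least one must be
#'   positive.
#' @return the index value.
#' @export
shannon_wiener <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("at least one count must be positive")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Diversity surface over the fire-regime grid
#'
#' For the full-community configuration of a sweep, computes in every
#' (fire probability, scale) grid cell the mean Shannon-Wiener index over
#' those patches in which all species are present (at least `threshold`
#' adults of each), averaged per patch first and then over replicates.
#' Grid cells without a single all-present patch in any replicate are
#' flagged undefined (`NA`), never zero-filled.
#'
#' @param sw an `fc_sweep` whose runs included the `"all"` configuration
#'   with per-patch counts retained.
#' @param threshold adult count for a species to count as present.
#' @return data.frame of class `fc_surface` with columns `fire_prob`,
#'   `scale`, `mean_H`, `sd_H`, `n_replicates_defined`,
#'   `n_cells_all_present` (mean over defined replicates).
#' @export
diversity_surface <- function(sw, threshold = 1) {
  keys <- names(sw$cell_counts)
  all_keys <- if (length(keys)) keys[startsWith(keys, "all|")] else character(0)
  if (length(all_keys) == 0)
    stop("sweep does not contain the 'all' species configuration ",
         "with per-patch counts")
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  fp <- as.numeric(parts[, 2])
  sc <- as.integer(parts[, 3])
  grid <- unique(data.frame(fire_prob = fp, scale = sc))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- which(fp == grid$fire_prob[i] & sc == grid$scale[i])
    per_rep <- vapply(sel, function(j) {
      cc <- sw$cell_counts[[all_keys[j]]]
      ok <- rowSums(cc >= threshold) == ncol(cc)
      if (!any(ok)) return(c(NA_real_, 0))
      H <- apply(cc[ok, , drop = FALSE], 1, shannon_wiener)
      c(mean(H), sum(ok))
    }, numeric(2))
    defined <- !is.na(per_rep[1, ])
    data.frame(
      fire_prob = grid$fire_prob[i], scale = grid$scale[i],
      mean_H = if (any(defined)) mean(per_rep[1, defined]) else NA_real_,
      sd_H = if (sum(defined) > 1) stats::sd(per_rep[1, defined]) else NA_real_,
      n_replicates_defined = sum(defined),
      n_cells_all_present = mean(per_rep[2, ]))
  }))
  out <- out[order(out$scale, out$fire_prob), ]
  rownames(out) <- NULL
  class(out) <- c("fc_surface", "data.frame")
  out
}

#' Locate the coexistence ridge of a diversity surface
#'
#' Pools the surface over scales (mean of the per-scale means, with regime
#' cells that hold no all-present patch contributing zero diversity — the
#' surface falls to the floor where coexistence is absent, as in a plotted
#' diversity surface) and reports the fire probability at which the pooled
#' mean diversity peaks, together with the per-scale peak positions and an
#' interquartile-style spread of each scale's diversity profile along the
#' fire-probability axis (the distance between the diversity-weighted 25 %
#' and 75 % quantiles).
#'
#' @param ds an `fc_surface` from [diversity_surface()].
#' @return list with `pooled_argmax`, `pooled` (data.frame of the pooled
#'   profile), and `per_scale` (data.frame with `scale`, `argmax`,
#'   `spread`).
#' @export
ridge_location <- function(ds) {
  if (all(is.na(ds$mean_H))) stop("diversity surface is undefined everywhere")
  probs <- sort(unique(ds$fire_prob))
  pooled <- vapply(probs, function(p) {
    h <- ds$mean_H[ds$fire_prob == p]
    if (all(is.na(h))) return(NA_real_)
    mean(ifelse(is.na(h), 0, h))     # no coexistence at a scale = no diversity
  }, numeric(1))
  pooled_argmax <- probs[which.max(pooled)]
  per_scale <- do.call(rbind, lapply(sort(unique(ds$scale)), function(s) {
    d <- ds[ds$scale == s, ]
    d <- d[order(d$fire_prob), ]
    if (all(is.na(d$mean_H)))
      return(data.frame(scale = s, argmax = NA_real_, spread = NA_real_))
    h <- ifelse(is.na(d$mean_H), 0, d$mean_H)
    data.frame(scale = s, argmax = d$fire_prob[which.max(h)],
               spread = weighted_iqr(d$fire_prob, h))
  }))
  list(pooled_argmax = pooled_argmax,
       pooled = data.frame(fire_prob = probs, mean_H = pooled),
       per_scale = per_scale)
}

## distance between the weighted 25% and 75% quantiles of x with weights w
weighted_iqr <- function(x, w) {
  if (sum(w) <= 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  q <- function(p) x[which(cw >= p)[1]]
  q(0.75) - q(0.25)
}
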