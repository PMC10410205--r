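## Stage 2: neighbour counts within fixed radii of each animal's centroid.
## No edge correction is applied (a known bias near colony edges,
## documented in the vignette); a centre exactly on the circle counts as
## inside (<=), pinned for determinism.

#' Neighbour counts within fixed radii
#'
#' For every animal and radius, counts the other animals whose centre
#' point (area centroid) lies within Euclidean distance `<= radius` of the
#' focal centre.
#'
#' @param site A [haulout_site()] (a single animal yields zero counts).
#' @param radii Strictly increasing positive radii in metres.
#' @return Data frame with `id`, `site_id`, `species`, `radius`, `count`.
#' @export
neighbour_counts <- function(site, radii = c(1, 3, 5, 10)) {
  stopifnot(inherits(site, "haulout_site"),
            length(radii) >= 1, all(radii > 0), !is.unsorted(radii, strictly = TRUE))
  ctr <- site_centres(site)
  n <- nrow(ctr)
  D <- as.matrix(dist(ctr))
  diag(D) <- Inf
  meta <- site_meta(site)
  out <- do.call(rbind, lapply(radii, function(r) {
    cbind(meta, radius = r,
          count = as.integer(rowSums(D <= r)))
  }))
  rownames(out) <- NULL
  out
}

#' Summarise neighbour counts per species and radius
#'
#' Mean, median and a normal-approximation 95% confidence interval for the
#' mean (mean +/- 1.96 * se); a percentile bootstrap interval is available
#' as an alternative.
#'
#' @param records Data frame from [neighbour_counts()] (concatenated over
#'   sites).
#' @param ci `"normal"` or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `ci = "bootstrap"`.
#' @return Data frame with `species`, `radius`, `n`, `mean`, `median`,
#'   `ci_lo`, `ci_hi`.
#' @export
summarize_density <- function(records, ci = c("normal", "bootstrap"),
                              boot_reps = 1000) {
  ci <- match.arg(ci)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be non-empty", call. = FALSE)
  groups <- split(records, list(records$species, records$radius), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g$count
    m <- mean(v)
    if (ci == "normal") {
      se <- sd(v) / sqrt(length(v))
      lo <- m - 1.96 * se; hi <- m + 1.96 * se
    } else {
      bm <- vapply(seq_len(boot_reps),
                   function(i) mean(sample(v, replace = TRUE)), 0)
      qs <- quantile(bm, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(species = g$species[1], radius = g$radius[1], n = length(v),
               mean = m, median = median(v), ci_lo = lo, ci_hi = hi)
  }))
  out <- out[order(out$radius, out$species), ]
  rownames(out) <- NULL
  out
}
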