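## Stage 1: edge-to-edge distance matrices and nearest-neighbour distances.
##
## Each animal contributes one NND (the minimum off-diagonal entry of its
## row), so mutual nearest-neighbour pairs are counted twice — each
## animal's position is treated as an independent placement decision.
## NNDs are computed within a site only, never across sites.

#' Pairwise edge-to-edge distance matrix for a site
#'
#' @param site A [haulout_site()] with at least two animals.
#' @return Symmetric n x n matrix (metres), zero diagonal, dimnames set to
#'   annotation ids. The diagonal is excluded from any minimum.
#' @export
distance_matrix <- function(site) {
  stopifnot(inherits(site, "haulout_site"))
  polys <- site_polygons(site)
  if (length(polys) < 2)
    stop("site '", site$site_id, "' has no neighbours (n < 2)", call. = FALSE)
  D <- cpp_dist_matrix(polys)
  ids <- vapply(site$annotations, `[[`, "", "id")
  dimnames(D) <- list(ids, ids)
  D
}

#' Per-animal nearest-neighbour distances
#'
#' @param site A [haulout_site()] with n >= 2 animals.
#' @return Data frame with columns `id`, `site_id`, `species`, `nnd`
#'   (metres); touching or overlapping neighbours give 0.
#' @export
nearest_neighbour_distances <- function(site) {
  D <- distance_matrix(site)
  diag(D) <- NA_real_
  out <- site_meta(site)
  out$nnd <- apply(D, 1, min, na.rm = TRUE)
  rownames(out) <- NULL
  out
}

#' Summarise NNDs by species or site
#'
#' Mean, median and quartiles (type-7 linear interpolation between order
#' statistics, pinned for bit-for-bit reproducibility) of the
#' nearest-neighbour distances per group.
#'
#' @param records Data frame from [nearest_neighbour_distances()] (rows
#'   from several sites may be concatenated).
#' @param group_by `"species"` or `"site"`.
#' @return Data frame with columns group, `n`, `mean`, `median`, `q25`,
#'   `q75`.
#' @export
summarize_nnd <- function(records, group_by = c("species", "site")) {
  group_by <- match.arg(group_by)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be non-empty", call. = FALSE)
  key <- if (group_by == "species") records$species else records$site_id
  out <- do.call(rbind, lapply(split(records$nnd, key), function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), mean = mean(v), median = q[2],
               q25 = q[1], q75 = q[3])
  }))
  out <- cbind(setNames(data.frame(rownames(out)), group_by), out)
  rownames(out) <- NULL
  out
}

#' Bin NNDs into fixed-width distance classes
#'
#' Left-closed, right-open bins `[0, w), [w, 2w), ...`; counts always sum
#' to the number of records.
#'
#' @param records NND data frame (or bare numeric vector of distances).
#' @param bin_width Bin width in metres.
#' @param max_m Upper edge of the last bin; defaults to the smallest
#'   multiple of `bin_width` strictly above the largest value.
#' @return Data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
bin_nnd <- function(records, bin_width = 0.25, max_m = NULL) {
  v <- if (is.data.frame(records)) records$nnd else records
  stopifnot(bin_width > 0, all(v >= 0))
  if (is.null(max_m)) max_m <- bin_width * (floor(max(v) / bin_width) + 1)
  edges <- seq(0, max_m, by = bin_width)
  if (edges[length(edges)] < max_m) edges <- c(edges, max_m)
  idx <- pmin(findInterval(v, edges), length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = counts)
}
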