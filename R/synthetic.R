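## Synthetic colonies: clustered, oriented body-ellipse polygons with a
## controllable hard-core (minimum edge-to-edge) gap, generated by
## sequential rejection ("dart throwing"). The generator gives every
## pipeline stage a ground truth: the hard-core gap plants a known
## avoidance signal, and the grey-like/harbour-like profile pair plants a
## known sign for the species contrasts.
##
## Body sizes are placeholders in the right ballpark for adult seals; they
## are NOT measured values, and no test derives a numeric claim from
## assumed biology — only from the configured truth.

#' Species profile for the synthetic generator
#'
#' @param name `"grey"`, `"harbour"` or `"custom"`.
#' @param body_length,body_width Ellipse axes in metres
#'   (`body_length >= body_width > 0`).
#' @param hardcore_gap Minimum edge-to-edge distance enforced between
#'   animals (metres, >= 0).
#' @param cluster_sd Gaussian spread of animals around their cluster
#'   parent (metres); `Inf` scatters animals uniformly over the window.
#' @param clusters_per_site Number of cluster parents.
#' @param orientation `"uniform"`, or a list
#'   `list(model = "common_heading", heading = degrees, sd = degrees)`.
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(name = "custom", body_length = 1.5,
                            body_width = 0.5, hardcore_gap = 0,
                            cluster_sd = 4, clusters_per_site = 3,
                            orientation = "uniform") {
  stopifnot(body_length >= body_width, body_width > 0, hardcore_gap >= 0,
            cluster_sd > 0, clusters_per_site >= 1)
  if (is.character(orientation)) orientation <- list(model = orientation)
  stopifnot(orientation$model %in% c("uniform", "common_heading"))
  structure(list(name = name, body_length = body_length,
                 body_width = body_width, hardcore_gap = hardcore_gap,
                 cluster_sd = cluster_sd,
                 clusters_per_site = as.integer(clusters_per_site),
                 orientation = orientation),
            class = "species_profile")
}

#' Default grey-like profile (dense, small hard-core gap)
#' @param ... Overrides passed to [species_profile()].
#' @return A `species_profile`.
#' @export
grey_profile <- function(...) {
  args <- list(name = "grey", body_length = 2.0, body_width = 0.6,
               hardcore_gap = 0.25, cluster_sd = 2.5, clusters_per_site = 4,
               orientation = list(model = "common_heading", heading = 0,
                                  sd = 15))
  do.call(species_profile, utils::modifyList(args, list(...)))
}

#' Default harbour-like profile (sparser, larger hard-core gap)
#' @param ... Overrides passed to [species_profile()].
#' @return A `species_profile`.
#' @export
harbour_profile <- function(...) {
  args <- list(name = "harbour", body_length = 1.5, body_width = 0.5,
               hardcore_gap = 0.40, cluster_sd = 3.5, clusters_per_site = 3,
               orientation = list(model = "common_heading", heading = 0,
                                  sd = 15))
  do.call(species_profile, utils::modifyList(args, list(...)))
}

## 24-vertex ellipse polygon
body_ellipse <- function(centre, length_m, width_m, heading_deg,
                         n_vertices = 24) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  p <- cbind(length_m / 2 * cos(th), width_m / 2 * sin(th))
  a <- heading_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(p %*% t(R), 2, centre, "+")
}

draw_heading <- function(orientation) {
  switch(orientation$model,
         uniform = runif(1, 0, 360),
         common_heading = rnorm(1, orientation$heading %||% 0,
                                orientation$sd %||% 10) %% 360)
}

#' Generate one synthetic colony
#'
#' Cluster parents are placed uniformly in the window; each animal's
#' centre is a Gaussian draw (sd = `cluster_sd`) around a random parent
#' (uniform over the window when `cluster_sd` is infinite), with its body
#' ellipse at an orientation from the profile's orientation model. A
#' candidate whose edge-to-edge distance to any accepted polygon is below
#' `hardcore_gap` (or that would leave the window) is rejected and
#' redrawn; generation fails once the retry budget is exhausted.
#'
#' @param profile A [species_profile()].
#' @param n Number of animals (>= 1).
#' @param window Window polygon; its area must be at least
#'   `10 * n * body_length * body_width`.
#' @param seed Integer seed; same `(profile, n, window, seed)` regenerates
#'   the identical site.
#' @param site_id Site identifier.
#' @param max_tries Total candidate budget (default `2000 * n`).
#' @return A [haulout_site()] with a `truth` attribute (class
#'   `synthetic_truth`: the profile, `n`, `seed` and window).
#' @export
generate_colony <- function(profile, n, window, seed, site_id = "synthetic",
                            max_tries = 2000 * n) {
  stopifnot(inherits(profile, "species_profile"), n >= 1)
  window <- validate_polygon(window, "window")
  if (abs(polygon_area(window)) <
      10 * n * profile$body_length * profile$body_width)
    stop("window too small: area must be >= 10 * n * body_length * ",
         "body_width", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  wb <- bbox(window)
  parents <- matrix(NA_real_, profile$clusters_per_site, 2)
  for (k in seq_len(profile$clusters_per_site)) {
    repeat {
      p <- c(runif(1, wb[1], wb[2]), runif(1, wb[3], wb[4]))
      if (point_in_polygon(p[1], p[2], window)) { parents[k, ] <- p; break }
    }
  }

  gap <- profile$hardcore_gap
  accepted <- vector("list", n)
  boxes <- matrix(NA_real_, n, 4) # cached bbox per accepted polygon
  n_acc <- 0L
  tries <- 0L
  while (n_acc < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("retry cap exceeded after ", n_acc, "/", n, " animals: ",
           "enlarge the window or reduce hardcore_gap", call. = FALSE)
    if (is.infinite(profile$cluster_sd)) {
      ctr <- c(runif(1, wb[1], wb[2]), runif(1, wb[3], wb[4]))
    } else {
      par <- parents[sample.int(nrow(parents), 1), ]
      ctr <- par + rnorm(2, sd = profile$cluster_sd)
    }
    if (!point_in_polygon(ctr[1], ctr[2], window)) next
    cand <- body_ellipse(ctr, profile$body_length, profile$body_width,
                         draw_heading(profile$orientation))
    if (!all(point_in_polygon(cand[, 1], cand[, 2], window))) next
    if (n_acc > 0L) {
      cb <- bbox(cand)
      near <- which(boxes[seq_len(n_acc), 1] <= cb[2] + gap &
                      boxes[seq_len(n_acc), 2] >= cb[1] - gap &
                      boxes[seq_len(n_acc), 3] <= cb[4] + gap &
                      boxes[seq_len(n_acc), 4] >= cb[3] - gap)
      ok <- TRUE
      for (j in near) {
        d <- cpp_edge_distance(cand, accepted[[j]])
        # even gap-0 colonies must stay overlap- and contact-free
        if (d < gap || d == 0) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    n_acc <- n_acc + 1L
    accepted[[n_acc]] <- cand
    boxes[n_acc, ] <- bbox(cand)
  }

  anns <- lapply(seq_len(n), function(i)
    seal_annotation(sprintf("%s_%04d", site_id, i), site_id,
                    if (profile$name %in% c("grey", "harbour"))
                      profile$name else "grey",
                    accepted[[i]]))
  site <- haulout_site(site_id, anns, window = window, crs = "EPSG:28992",
                       species = NULL)
  attr(site, "truth") <- structure(
    list(profile = profile, n = n, seed = as.integer(seed), window = window),
    class = "synthetic_truth")
  site
}

#' Generate a two-species synthetic study
#'
#' Independent colonies per site with per-site seeds derived from `seed`;
#' by default 2 grey-like and 5 harbour-like sites, with the grey-like
#' profile denser and with the smaller hard-core gap, so the species
#' contrasts computed by the pipeline have a known sign.
#'
#' @param profiles Named list with elements `grey` and `harbour`
#'   ([species_profile()] objects).
#' @param sites_per_species Named integer vector `c(grey =, harbour =)`.
#' @param n_per_site Named vector of animals per site by species.
#' @param window_side Side (metres) of the square generation window.
#' @param seed Integer seed.
#' @return List of `haulout_site` objects (each carrying its
#'   `synthetic_truth` attribute).
#' @export
generate_paired_study <- function(profiles = list(grey = grey_profile(),
                                                  harbour = harbour_profile()),
                                  sites_per_species = c(grey = 2, harbour = 5),
                                  n_per_site = c(grey = 200, harbour = 120),
                                  window_side = 60, seed = 1) {
  stopifnot(all(c("grey", "harbour") %in% names(profiles)))
  window <- cbind(c(0, window_side, window_side, 0),
                  c(0, 0, window_side, window_side))
  sites <- list()
  for (sp in c("grey", "harbour")) {
    for (k in seq_len(sites_per_species[[sp]])) {
      sid <- sprintf("%s_%02d", sp, k)
      sites[[sid]] <- generate_colony(profiles[[sp]], n_per_site[[sp]],
                                      window,
                                      seed = site_substream(seed, sid),
                                      site_id = sid)
    }
  }
  unname(sites)
}
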