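## Stage 3: the spatial-perturbation ("shuffle") null model.
##
## Each polygon is displaced to a new centre (Gaussian jitter with sd equal
## to the kernel bandwidth, or a draw from the fitted intensity surface),
## keeping its orientation. Polygons are then finalized one at a time in a
## seeded random order; a polygon overlapping an already-finalized one is
## rotated about its centroid in 1-degree increments and, failing that,
## stepped 10 cm at a time along a random direction until overlap-free.

#' Shuffle configuration
#'
#' @param seed Integer seed; fixes the whole shuffle reproducibly.
#' @param rotation_increment_deg Rotation step for overlap resolution.
#' @param translation_increment_m Translation step (metres).
#' @param mode `"jitter"` (per-polygon Gaussian displacement with sd =
#'   bandwidth; the default) or `"intensity"` (new centres drawn from the
#'   fitted intensity surface).
#' @param max_translation_steps Cap on translation steps per direction.
#' @param bandwidth_override Optional bandwidth in metres, bypassing
#'   cross-validation.
#' @return Object of class `shuffle_config`.
#' @export
shuffle_config <- function(seed = 1L, rotation_increment_deg = 1,
                           translation_increment_m = 0.10,
                           mode = c("jitter", "intensity"),
                           max_translation_steps = 1000,
                           bandwidth_override = NULL) {
  mode <- match.arg(mode)
  stopifnot(rotation_increment_deg > 0, translation_increment_m > 0,
            max_translation_steps >= 1)
  structure(list(seed = as.integer(seed),
                 rotation_increment_deg = rotation_increment_deg,
                 translation_increment_m = translation_increment_m,
                 mode = mode,
                 max_translation_steps = max_translation_steps,
                 bandwidth_override = bandwidth_override),
            class = "shuffle_config")
}

## deterministic per-site RNG substream: adding or reordering sites never
## perturbs another site's draws
site_substream <- function(seed, site_id) {
  h <- sum(utf8ToInt(site_id) * seq_along(utf8ToInt(site_id)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483597)
}

#' Propose perturbed centre positions
#'
#' Jitter mode adds an isotropic Gaussian displacement (sd = `model$sigma`
#' per axis) to each centre, rejection-resampled until the proposal falls
#' inside the window. Intensity mode draws each new centre from the fitted
#' intensity surface by rejection sampling. Orientation is untouched.
#'
#' @param site A [haulout_site()].
#' @param model A [fit_kernel()] model for this site.
#' @param cfg A [shuffle_config()].
#' @param max_tries Rejection cap per polygon.
#' @return n x 2 matrix of proposed centres, all inside the window.
#' @export
propose_positions <- function(site, model, cfg, max_tries = 10000) {
  centres <- site_centres(site)
  win <- site$window
  n <- nrow(centres)
  out <- matrix(NA_real_, n, 2)
  if (cfg$mode == "jitter") {
    for (i in seq_len(n)) {
      for (k in seq_len(max_tries)) {
        p <- centres[i, ] + rnorm(2, sd = model$sigma)
        if (point_in_polygon(p[1], p[2], win)) { out[i, ] <- p; break }
      }
      if (is.na(out[i, 1]))
        stop("window rejection exceeded ", max_tries, " tries for polygon ",
             site$annotations[[i]]$id, call. = FALSE)
    }
  } else {
    wb <- bbox(win)
    probe <- rbind(centres,
                   as.matrix(expand.grid(seq(wb[1], wb[2], length.out = 25),
                                         seq(wb[3], wb[4], length.out = 25))))
    lam_max <- 1.2 * max(model$intensity(probe[, 1], probe[, 2]))
    for (i in seq_len(n)) {
      for (k in seq_len(max_tries)) {
        p <- c(runif(1, wb[1], wb[2]), runif(1, wb[3], wb[4]))
        if (!point_in_polygon(p[1], p[2], win)) next
        if (runif(1) * lam_max <= model$intensity(p[1], p[2])) {
          out[i, ] <- p; break
        }
      }
      if (is.na(out[i, 1]))
        stop("intensity rejection exceeded ", max_tries,
             " tries for polygon ", site$annotations[[i]]$id, call. = FALSE)
    }
  }
  out
}

#' Resolve polygon overlaps by rotation, then translation
#'
#' Polygons are finalized sequentially in a random order; each is tested
#' against all already-finalized polygons. An overlapping polygon is first
#' rotated about its centroid in `rotation_increment_deg` steps through
#' 359 degrees; if no rotation frees it, rotation is reset and the polygon
#' is stepped along a random unit direction in
#' `translation_increment_m` increments until overlap-free. A direction
#' whose path would carry the centroid outside `window` is abandoned and a
#' fresh direction drawn (up to `max_directions`), which keeps every
#' placement inside the window.
#'
#' @param annotations List of [seal_annotation()] objects at their proposed
#'   poses.
#' @param cfg A [shuffle_config()] (its `seed` is *not* applied here; seed
#'   externally or via [shuffle_site()]).
#' @param window Optional window polygon constraining translation.
#' @param max_directions Directions tried before giving up.
#' @return Object of class `shuffle_result` (without NND records; see
#'   [shuffle_site()]): `placed`, `resolution_log`,
#'   `initial_overlap_fraction`.
#' @export
resolve_overlaps <- function(annotations, cfg = shuffle_config(),
                             window = NULL, max_directions = 25) {
  n <- length(annotations)
  polys <- lapply(annotations, `[[`, "polygon")
  ids <- vapply(annotations, `[[`, "", "id")
  boxes <- t(vapply(polys, bbox, numeric(4)))

  ## pairwise overlap state of the raw proposals, before any resolution
  init_olap <- logical(n)
  for (i in seq_len(n)) {
    if (init_olap[i]) next
    for (j in seq_len(n)) {
      if (j == i) next
      if (!bbox_overlap(boxes[i, ], boxes[j, ])) next
      if (overlaps(polys[[i]], polys[[j]])) {
        init_olap[i] <- TRUE
        init_olap[j] <- TRUE
        break
      }
    }
  }

  hits <- function(p, pb, done_idx) {
    for (j in done_idx) {
      if (!bbox_overlap(pb, boxes[j, ])) next
      if (overlaps(p, polys[[j]])) return(TRUE)
    }
    FALSE
  }

  ord <- sample.int(n)
  done <- integer(0)
  deg <- numeric(n); trans <- numeric(n); resolved <- rep(TRUE, n)
  for (i in ord) {
    p <- polys[[i]]
    if (!hits(p, boxes[i, ], done)) { done <- c(done, i); next }
    ctr <- centre_point(p)
    freed <- FALSE
    k <- cfg$rotation_increment_deg
    while (k < 360) {
      cand <- rotate_about(p, k, ctr)
      cb <- bbox(cand)
      if (!hits(cand, cb, done)) {
        polys[[i]] <- cand; boxes[i, ] <- cb
        deg[i] <- k; freed <- TRUE
        break
      }
      k <- k + cfg$rotation_increment_deg
    }
    if (!freed) {
      ## rotation reset; step along a random direction held fixed
      for (dtry in seq_len(max_directions)) {
        th <- runif(1, 0, 2 * pi)
        ux <- cos(th); uy <- sin(th)
        for (s in seq_len(cfg$max_translation_steps)) {
          d <- s * cfg$translation_increment_m
          if (!is.null(window) &&
              !point_in_polygon(ctr[1] + d * ux, ctr[2] + d * uy, window))
            break
          cand <- translate_poly(p, d * ux, d * uy)
          cb <- bbox(cand)
          if (!hits(cand, cb, done)) {
            polys[[i]] <- cand; boxes[i, ] <- cb
            trans[i] <- d; freed <- TRUE
            break
          }
        }
        if (freed) break
      }
      if (!freed)
        stop("could not resolve overlap for polygon '", ids[i],
             "' within ", cfg$max_translation_steps, " steps x ",
             max_directions, " directions (seed ", cfg$seed, ")",
             call. = FALSE)
    }
    done <- c(done, i)
  }

  placed <- annotations
  for (i in seq_len(n)) placed[[i]]$polygon <- polys[[i]]
  structure(list(
    placed = placed,
    resolution_log = data.frame(id = ids,
                                initially_overlapping = init_olap,
                                degrees_rotated = deg,
                                metres_translated = trans),
    initial_overlap_fraction = mean(init_olap)),
    class = "shuffle_result")
}

#' Shuffle one haul-out site
#'
#' Orchestrates the full perturbation: bandwidth (override or
#' cross-validated), kernel fit, centre proposals, overlap resolution, and
#' nearest-neighbour distances of the placed polygons. Fully reproducible
#' for a fixed `cfg$seed`; each site uses its own RNG substream derived
#' from `(seed, site_id)`.
#'
#' @param site A [haulout_site()] with >= 2 animals.
#' @param cfg A [shuffle_config()].
#' @return Object of class `shuffle_result`: `placed` (annotations at new
#'   poses), `resolution_log`, `initial_overlap_fraction`, `nnd` (data
#'   frame as from [nearest_neighbour_distances()]), `bandwidth`, `seed`.
#' @export
shuffle_site <- function(site, cfg = shuffle_config()) {
  stopifnot(inherits(site, "haulout_site"))
  if (length(site$annotations) < 2)
    stop("site '", site$site_id, "' has < 2 animals", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(site_substream(cfg$seed, site$site_id))

  sigma <- cfg$bandwidth_override %||%
    cv_bandwidth(site_centres(site), site$window)
  model <- fit_kernel(site, sigma)
  prop <- propose_positions(site, model, cfg)

  centres <- site_centres(site)
  moved <- site$annotations
  for (i in seq_along(moved))
    moved[[i]]$polygon <- translate_poly(moved[[i]]$polygon,
                                         prop[i, 1] - centres[i, 1],
                                         prop[i, 2] - centres[i, 2])
  res <- resolve_overlaps(moved, cfg, window = site$window)

  D <- cpp_dist_matrix(lapply(res$placed, `[[`, "polygon"))
  diag(D) <- NA_real_
  nnd <- site_meta(site)
  nnd$nnd <- apply(D, 1, min, na.rm = TRUE)
  res$nnd <- nnd
  res$bandwidth <- sigma
  res$seed <- cfg$seed
  res
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat("<shuffle_result> ", length(x$placed), " polygons, ",
      round(100 * x$initial_overlap_fraction), "% initially overlapping",
      if (!is.null(x$bandwidth)) paste0(", bandwidth ",
                                        signif(x$bandwidth, 3), " m"),
      "\n", sep = "")
  invisible(x)
}

#' Per-species averaged cross-validated bandwidths
#'
#' Computes the cross-validated bandwidth per site and averages it across
#' sites of the same species; the species mean is the bandwidth actually
#' applied to each of that species' sites during shuffling.
#'
#' @param sites List of `haulout_site` objects.
#' @param method Passed to [cv_bandwidth()].
#' @return Data frame with `site_id`, `species`, `bandwidth` (per-site CV
#'   value) and `bandwidth_used` (species average).
#' @export
species_average_bandwidths <- function(sites, method = "lscv") {
  per_site <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, species = s$species,
               bandwidth = cv_bandwidth(site_centres(s), s$window,
                                        method = method))
  }))
  avg <- tapply(per_site$bandwidth, per_site$species, mean)
  per_site$bandwidth_used <- as.numeric(avg[per_site$species])
  per_site
}
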