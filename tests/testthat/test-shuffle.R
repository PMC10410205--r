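# The spatial-perturbation null model: proposals, overlap resolution and
# whole-site shuffles.

jitter_site <- function(n = 40, side = 25, seed = 81, gap = 0) {
  set.seed(seed)
  generate_colony(species_profile("custom", 1.2, 0.4, hardcore_gap = gap,
                                  cluster_sd = Inf),
                  n, unit_window(side), seed = seed, site_id = "js")
}

test_that("proposals reduce to the originals in the zero-noise limit", {
  s <- jitter_site(20)
  m <- fit_kernel(s, sigma = 1e-6)
  set.seed(1)
  prop <- propose_positions(s, m, shuffle_config())
  ctr <- t(sapply(s$annotations, function(a) centre_point(a$polygon)))
  expect_lt(max(abs(prop - ctr)), 1e-4)
})

test_that("all proposals fall inside the window, in both modes", {
  s <- jitter_site(30)
  for (mode in c("jitter", "intensity")) {
    m <- fit_kernel(s, sigma = 3)
    set.seed(2)
    prop <- propose_positions(s, m, shuffle_config(mode = mode))
    expect_true(all(sealspacing:::point_in_polygon(prop[, 1], prop[, 2],
                                                   s$window)))
  }
})

test_that("jitter displacements follow the Rayleigh radial law", {
  # isotropic Gaussian jitter with sd sigma per axis has mean radial
  # displacement sigma * sqrt(pi / 2)
  side <- 2000 # window so large that rejection never bites
  polys <- lapply(1:3000, function(i)
    square_poly(runif(1, 900, 1100), runif(1, 900, 1100), 0.1))
  s <- make_site(polys, window = unit_window(side))
  m <- fit_kernel(s, sigma = 2)
  set.seed(3)
  prop <- propose_positions(s, m, shuffle_config())
  ctr <- t(sapply(s$annotations, function(a) centre_point(a$polygon)))
  r <- sqrt(rowSums((prop - ctr)^2))
  expect_equal(mean(r), 2 * sqrt(pi / 2), tolerance = 0.03)
})

test_that("overlap-free proposals pass through resolution untouched", {
  polys <- lapply(0:3, function(i) square_poly(3 * i, 0))
  anns <- lapply(seq_along(polys), function(i)
    seal_annotation(paste0("a", i), "s", "grey", polys[[i]]))
  set.seed(4)
  res <- resolve_overlaps(anns, shuffle_config())
  expect_identical(lapply(res$placed, `[[`, "polygon"), polys)
  expect_equal(res$resolution_log$degrees_rotated, rep(0, 4))
  expect_equal(res$resolution_log$metres_translated, rep(0, 4))
  expect_equal(res$initial_overlap_fraction, 0)
})

test_that("coincident congruent footprints are resolved by translation", {
  # rotation alone can never separate two identical squares on one spot
  anns <- list(seal_annotation("a", "s", "grey", square_poly(5, 5)),
               seal_annotation("b", "s", "grey", square_poly(5, 5)))
  set.seed(5)
  res <- resolve_overlaps(anns, shuffle_config(), window = unit_window(20))
  expect_equal(res$initial_overlap_fraction, 1)
  expect_gt(max(res$resolution_log$metres_translated), 0)
  expect_true(no_pair_overlaps(lapply(res$placed, `[[`, "polygon")))
})

test_that("a fixed seed reproduces a shuffle bit for bit", {
  s <- jitter_site(30)
  cfg <- shuffle_config(seed = 99, bandwidth_override = 1.5)
  r1 <- shuffle_site(s, cfg)
  r2 <- shuffle_site(s, cfg)
  expect_identical(r1, r2)
  # a different seed gives a different configuration
  r3 <- shuffle_site(s, shuffle_config(seed = 100, bandwidth_override = 1.5))
  expect_false(identical(r1$nnd$nnd, r3$nnd$nnd))
})

test_that("shuffles preserve shapes and orientations outside the resolver", {
  s <- jitter_site(60, side = 20)
  res <- shuffle_site(s, shuffle_config(seed = 7, bandwidth_override = 1))
  polys0 <- lapply(s$annotations, `[[`, "polygon")
  polys1 <- lapply(res$placed, `[[`, "polygon")
  for (i in seq_along(polys0)) {
    expect_equal(polygon_area(polys1[[i]]), polygon_area(polys0[[i]]),
                 tolerance = 1e-9)
    expect_equal(polygon_perimeter(polys1[[i]]),
                 polygon_perimeter(polys0[[i]]), tolerance = 1e-9)
    expect_identical(nrow(polys1[[i]]), nrow(polys0[[i]]))
  }
  # orientation is preserved exactly unless the resolver rotated a polygon
  log <- res$resolution_log
  for (i in which(log$degrees_rotated == 0)) {
    a <- sweep(polys0[[i]], 2, centre_point(polys0[[i]]))
    b <- sweep(polys1[[i]], 2, centre_point(polys1[[i]]))
    expect_equal(b, a, tolerance = 1e-9)
  }
  expect_gt(sum(log$degrees_rotated == 0), 0)
  expect_true(no_pair_overlaps(polys1))
})

test_that("shuffling a hard-core colony floods the small-NND bins", {
  # observed hard-core gap 0.5 m means no NND below 0.25 m; the jittered
  # null has no such inhibition
  hits <- 0L
  for (seed in 1:5) {
    s <- generate_colony(species_profile("custom", 1.2, 0.4,
                                         hardcore_gap = 0.5,
                                         cluster_sd = 2,
                                         clusters_per_site = 2),
                         60, unit_window(25), seed = 200 + seed,
                         site_id = "hc")
    obs <- nearest_neighbour_distances(s)
    expect_identical(sum(obs$nnd < 0.25), 0L)
    res <- shuffle_site(s, shuffle_config(seed = seed,
                                          bandwidth_override = 1.5))
    if (mean(res$nnd$nnd < 0.25) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("shuffling a no-inhibition pattern does not shift the small-NND rate", {
  # observed = one jitter+resolve application to a uniform gap-0 colony,
  # shuffled = a further application to the observed configuration; the
  # mean change in the proportion of NNDs < 0.25 m should vanish
  prof <- species_profile("custom", 0.8, 0.3, hardcore_gap = 0,
                          cluster_sd = Inf)
  w <- unit_window(12)
  diffs <- vapply(1:100, function(seed) {
    base <- generate_colony(prof, 40, w, seed = seed, site_id = "nb")
    base$window <- convex_hull_window(w, 3) # keep jitter truncation tiny
    obs <- shuffle_site(base, shuffle_config(seed = seed * 7 + 1,
                                             bandwidth_override = 0.5))
    obs_site <- base
    obs_site$annotations <- obs$placed
    shf <- shuffle_site(obs_site, shuffle_config(seed = seed * 7 + 2,
                                                 bandwidth_override = 0.5))
    mean(shf$nnd$nnd < 0.25) - mean(obs$nnd$nnd < 0.25)
  }, 0)
  ci <- mean(diffs) + c(-1.96, 1.96) * sd(diffs) / 10
  expect_true(ci[1] < 0 && 0 < ci[2])
})

test_that("the refitted intensity correlates with the original surface", {
  # clustered colonies: the shuffle must keep the heterogeneous density
  rs <- vapply(1:6, function(seed) {
    s <- generate_colony(species_profile("custom", 1.2, 0.4,
                                         cluster_sd = 2.5,
                                         clusters_per_site = 2),
                         80, unit_window(30), seed = 300 + seed,
                         site_id = "cl")
    sigma <- 1.5
    res <- shuffle_site(s, shuffle_config(seed = seed,
                                          bandwidth_override = sigma))
    m0 <- fit_kernel(s, sigma)
    ctr1 <- t(sapply(res$placed, function(a) centre_point(a$polygon)))
    m1 <- fit_kernel(ctr1, sigma, window = s$window)
    g <- expand.grid(x = seq(1, 29, 1.5), y = seq(1, 29, 1.5))
    cor(m0$intensity(g$x, g$y), m1$intensity(g$x, g$y))
  }, 0)
  expect_gt(mean(rs), 0.8)
})
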