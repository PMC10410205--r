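# GeoJSON IO, CRS contract, site filtering and table plumbing.

write_fixture_geojson <- function(path, features, crs = "EPSG:28992") {
  obj <- list(type = "FeatureCollection", features = features)
  if (!is.null(crs))
    obj$crs <- list(type = "name", properties = list(name = crs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

feat <- function(id, site, species, poly, type = "Polygon") {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  coords <- list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
  if (type == "MultiPolygon") coords <- list(coords)
  list(type = "Feature",
       properties = list(id = id, site = site, species = species),
       geometry = list(type = type, coordinates = coords))
}

test_that("a valid GeoJSON file round-trips through read and write", {
  polys <- list(square_poly(0, 0), square_poly(3, 0), square_poly(6, 2))
  f <- tempfile(fileext = ".geojson")
  write_fixture_geojson(f, lapply(1:3, function(i)
    feat(paste0("a", i), "s1", "grey", polys[[i]])))
  sites <- read_annotations(f)
  expect_length(sites, 1)
  s <- sites[[1]]
  expect_s3_class(s, "haulout_site")
  expect_length(s$annotations, 3)
  expect_identical(s$species, "grey")
  # write then re-read: coordinates identical to 1e-9, attributes kept
  f2 <- tempfile(fileext = ".geojson")
  write_annotations(sites, f2)
  back <- read_annotations(f2)[[1]]
  for (i in 1:3) {
    expect_equal(back$annotations[[i]]$polygon, s$annotations[[i]]$polygon,
                 tolerance = 1e-9)
    expect_identical(back$annotations[[i]]$id, s$annotations[[i]]$id)
    expect_identical(back$annotations[[i]]$species,
                     s$annotations[[i]]$species)
  }
})

test_that("geographic or missing CRS is a hard error naming the CRS", {
  f <- tempfile(fileext = ".geojson")
  write_fixture_geojson(f, list(feat("a1", "s1", "grey", square_poly())),
                        crs = "EPSG:4326")
  expect_error(read_annotations(f), "projected metric CRS required")
  write_fixture_geojson(f, list(feat("a1", "s1", "grey", square_poly())),
                        crs = NULL)
  expect_error(read_annotations(f), "projected metric CRS required")
  # but a supplied projected CRS rescues a CRS-less file
  expect_length(read_annotations(f, crs = "EPSG:28992"), 1)
})

test_that("invalid geometry and unknown species are rejected with ids", {
  f <- tempfile(fileext = ".geojson")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  write_fixture_geojson(f, list(feat("bad1", "s1", "grey", bowtie)))
  expect_error(read_annotations(f), "bad1")
  write_fixture_geojson(f, list(feat("a1", "s1", "walrus", square_poly())))
  expect_error(read_annotations(f), "unknown species value 'walrus'")
})

test_that("multipolygons are rejected by default, largest part kept on request", {
  f <- tempfile(fileext = ".geojson")
  write_fixture_geojson(f, list(
    feat("m1", "s1", "grey", square_poly(0, 0, 2), type = "MultiPolygon"),
    feat("a2", "s1", "grey", square_poly(5, 0))))
  expect_error(read_annotations(f), "MultiPolygon")
  sites <- read_annotations(f, split_multipolygons = TRUE)
  expect_length(sites[[1]]$annotations, 2)
})

test_that("default window is a buffered hull containing every polygon", {
  s <- make_site(list(square_poly(0, 0), square_poly(8, 4)))
  verts <- do.call(rbind, lapply(s$annotations, `[[`, "polygon"))
  expect_true(all(sealspacing:::point_in_polygon(verts[, 1], verts[, 2],
                                                 s$window)))
  # buffered by ~10 m beyond the hull
  expect_gte(min(verts[, 1]) - min(s$window[, 1]), 9.5)
})

test_that("filter_sites drops mixed and pupping sites with a logged reason", {
  mk <- function(id, species) {
    if (species == "mixed")
      make_site(list(square_poly(0, 0), square_poly(2, 0)), id,
                species = c("grey", "harbour"))
    else make_site(list(square_poly(0, 0), square_poly(2, 0)), id, species)
  }
  sites <- c(lapply(1:2, function(i) mk(paste0("g", i), "grey")),
             lapply(1:6, function(i) mk(paste0("h", i), "harbour")),
             lapply(1:3, function(i) mk(paste0("m", i), "mixed")))
  kept <- suppressMessages(filter_sites(sites, pupping_sites = "h6"))
  expect_length(kept, 7) # 2 grey + 5 harbour survive out of 11
  excl <- attr(kept, "exclusions")
  expect_identical(sort(excl$site_id), c("h6", "m1", "m2", "m3"))
  expect_true(any(grepl("pupping", excl$reason)))
  # stated rule on a minimal list, and the empty case
  expect_length(suppressMessages(
    filter_sites(list(mk("a", "grey"), mk("b", "mixed"),
                      mk("c", "harbour")))), 2)
  expect_length(filter_sites(list()), 0)
})

test_that("write_table is sorted, round-trips and rejects empty input", {
  rec <- data.frame(id = c("b", "a", "c"), site_id = c("s2", "s1", "s1"),
                    nnd = c(exp(1), pi, sqrt(2)))
  f <- tempfile(fileext = ".csv")
  write_table(rec, f)
  back <- read.csv(f, colClasses = c("character", "character", "numeric"))
  expect_identical(back$site_id, c("s1", "s1", "s2")) # site then id order
  expect_identical(back$id, c("a", "c", "b"))
  expect_identical(back$nnd, c(pi, sqrt(2), exp(1))) # full float precision
  expect_error(write_table(rec[0, ], f), "non-empty")
})

test_that("sites enforce the annotation contract", {
  a <- seal_annotation("x1", "s1", "grey", square_poly())
  expect_error(haulout_site("s2", list(a)), "site_id")
  expect_error(haulout_site("s1", list(a, a)), "duplicate")
  expect_error(haulout_site("s1", list(a), crs = "EPSG:4326"),
               "projected metric CRS")
  expect_error(seal_annotation("x", "s", "grey",
                               cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))))
})
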