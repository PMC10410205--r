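## Reading, validating and writing georeferenced seal annotations.
##
## One annotation = one animal = one simple polygon in a projected metric
## CRS. Annotations are grouped into haul-out sites; each site carries a
## species label (grey, harbour, or mixed when its animals disagree), an
## analysis window and CRS metadata.

SPECIES_LEVELS <- c("grey", "harbour", "mixed")

## EPSG codes / identifiers that are geographic (degree units) and
## therefore rejected; the analysis requires planar metre coordinates.
GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4258", "EPSG:4269", "EPSG:4277",
                    "OGC:CRS84", "CRS84", "WGS84", "EPSG:4979")

#' Construct a single seal annotation
#'
#' @param id Unique annotation id (string).
#' @param site_id Site the animal belongs to.
#' @param species `"grey"` or `"harbour"`.
#' @param polygon Simple polygon matrix (see [validate_polygon()]),
#'   coordinates in metres.
#' @return Object of class `seal_annotation`.
#' @export
seal_annotation <- function(id, site_id, species, polygon) {
  species <- match.arg(species, c("grey", "harbour"))
  polygon <- unclass(validate_polygon(polygon, paste0("polygon of '", id, "'")))
  structure(list(id = as.character(id), site_id = as.character(site_id),
                 species = species, polygon = polygon),
            class = "seal_annotation")
}

#' Construct a haul-out site
#'
#' @param site_id Site identifier.
#' @param annotations List of [seal_annotation()] objects carrying this
#'   `site_id`.
#' @param window Analysis-region polygon in the same CRS; defaults to the
#'   convex hull of all annotation vertices buffered by 10 m.
#' @param crs Projected CRS identifier (e.g. `"EPSG:28992"`); degree-unit
#'   systems are rejected.
#' @param species Site-level species; derived from the annotations when
#'   omitted (`"mixed"` when they disagree).
#' @param date Optional ISO date string.
#' @param resolution_cm Optional image resolution (cm/pixel).
#' @return Object of class `haulout_site`.
#' @export
haulout_site <- function(site_id, annotations, window = NULL,
                         crs = "EPSG:28992", species = NULL,
                         date = NULL, resolution_cm = NULL) {
  validate_crs(crs)
  stopifnot(length(annotations) >= 1)
  for (a in annotations) {
    if (!inherits(a, "seal_annotation"))
      stop("annotations must be seal_annotation objects", call. = FALSE)
    if (a$site_id != site_id)
      stop("annotation '", a$id, "' carries site_id '", a$site_id,
           "', not '", site_id, "'", call. = FALSE)
  }
  ids <- vapply(annotations, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate annotation ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sp <- unique(vapply(annotations, `[[`, "", "species"))
  if (is.null(species)) species <- if (length(sp) == 1) sp else "mixed"
  species <- match.arg(species, SPECIES_LEVELS)
  verts <- do.call(rbind, lapply(annotations, `[[`, "polygon"))
  if (is.null(window)) window <- convex_hull_window(verts, buffer = 10)
  window <- validate_polygon(window, "window")
  if (!all(point_in_polygon(verts[, 1], verts[, 2], window)))
    stop("window does not contain every annotation polygon", call. = FALSE)
  structure(list(site_id = as.character(site_id), species = species,
                 annotations = annotations, window = window, crs = crs,
                 date = date, resolution_cm = resolution_cm),
            class = "haulout_site")
}

#' @export
print.haulout_site <- function(x, ...) {
  cat("<haulout_site> ", x$site_id, ": ", length(x$annotations), " ",
      x$species, " seal(s), CRS ", x$crs, "\n", sep = "")
  invisible(x)
}

validate_crs <- function(crs) {
  if (is.null(crs) || is.na(crs) || !nzchar(crs))
    stop("projected metric CRS required, but no CRS is given", call. = FALSE)
  key <- toupper(gsub(".*EPSG:?:?", "EPSG:", toupper(crs)))
  if (toupper(crs) %in% GEOGRAPHIC_CRS || key %in% GEOGRAPHIC_CRS ||
      grepl("LONGLAT|4326|CRS84", toupper(crs)))
    stop("projected metric CRS required (got geographic CRS '", crs, "')",
         call. = FALSE)
  invisible(crs)
}

site_polygons <- function(site) lapply(site$annotations, `[[`, "polygon")

site_centres <- function(site) {
  t(vapply(site$annotations, function(a) centre_point(a$polygon), c(0, 0)))
}

site_meta <- function(site) {
  data.frame(id = vapply(site$annotations, `[[`, "", "id"),
             site_id = site$site_id,
             species = vapply(site$annotations, `[[`, "", "species"),
             stringsAsFactors = FALSE)
}

#' Read polygon annotations from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of polygon features (one feature per
#' animal) into one [haulout_site()] per distinct site value. The GeoJSON
#' must be in a projected metric CRS, declared either via a legacy `crs`
#' member or the `crs` argument; geographic (degree) systems are rejected.
#'
#' @param path GeoJSON file.
#' @param species_field,site_field Property names holding the species and
#'   site labels.
#' @param id_field Property holding the annotation id; feature order is
#'   used when absent.
#' @param crs CRS identifier overriding / replacing the file's `crs` member.
#' @param split_multipolygons MultiPolygon features are rejected by default
#'   (one animal, one polygon); `TRUE` keeps the largest part instead.
#' @param window Optional named list of window polygons (by site id).
#' @return List of `haulout_site` objects, sorted by site id.
#' @export
read_annotations <- function(path, species_field = "species",
                             site_field = "site", id_field = "id",
                             crs = NULL, split_multipolygons = FALSE,
                             window = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  if (is.null(crs)) {
    crs <- gj$crs$properties$name
    if (is.null(crs))
      stop("projected metric CRS required, but '", path,
           "' declares no CRS and none was supplied", call. = FALSE)
  }
  validate_crs(crs)
  feats <- gj$features
  if (length(feats) == 0) stop("no features in ", path, call. = FALSE)

  rows <- vector("list", length(feats))
  bad <- character()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    fid <- as.character(props[[id_field]] %||% k)
    geom <- f$geometry
    poly <- tryCatch(
      geojson_polygon(geom, fid, split_multipolygons),
      error = function(e) { bad <<- c(bad, conditionMessage(e)); NULL })
    if (is.null(poly)) next
    sp <- props[[species_field]]
    if (is.null(sp) || !(sp %in% c("grey", "harbour")))
      stop("unknown species value '", sp %||% "<missing>",
           "' on feature '", fid, "' (expected grey/harbour)", call. = FALSE)
    sid <- props[[site_field]]
    if (is.null(sid)) stop("feature '", fid, "' lacks site field '",
                           site_field, "'", call. = FALSE)
    rows[[k]] <- list(id = fid, site_id = as.character(sid),
                      species = sp, polygon = poly)
  }
  if (length(bad) > 0)
    stop("invalid geometry in ", path, ": ", paste(bad, collapse = "; "),
         call. = FALSE)

  rows <- Filter(Negate(is.null), rows)
  site_ids <- sort(unique(vapply(rows, `[[`, "", "site_id")))
  lapply(site_ids, function(sid) {
    anns <- lapply(Filter(function(r) r$site_id == sid, rows), function(r)
      seal_annotation(r$id, r$site_id, r$species, r$polygon))
    haulout_site(sid, anns, window = window[[sid]], crs = crs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

geojson_polygon <- function(geom, fid, split_multipolygons) {
  type <- geom$type %||% "<none>"
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    validate_polygon(m, paste0("feature '", fid, "'"))
  }
  if (type == "Polygon") {
    if (length(geom$coordinates) > 1)
      stop("feature '", fid, "' has interior rings (holes)")
    return(ring_to_matrix(geom$coordinates[[1]]))
  }
  if (type == "MultiPolygon") {
    if (!split_multipolygons)
      stop("feature '", fid, "' is a MultiPolygon ",
           "(use split_multipolygons = TRUE to keep the largest part)")
    parts <- lapply(geom$coordinates, function(pp) ring_to_matrix(pp[[1]]))
    areas <- vapply(parts, function(p) abs(polygon_area(p)), 0)
    return(parts[[which.max(areas)]])
  }
  stop("feature '", fid, "' has unsupported geometry type '", type, "'")
}

#' Write sites (or shuffled placements) as GeoJSON
#'
#' @param sites List of `haulout_site` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(sites, path) {
  if (inherits(sites, "haulout_site")) sites <- list(sites)
  stopifnot(length(sites) >= 1)
  crs <- sites[[1]]$crs
  features <- list()
  for (s in sites) {
    for (a in s$annotations) {
      ring <- rbind(a$polygon, a$polygon[1, , drop = FALSE])
      coords <- list(lapply(seq_len(nrow(ring)),
                            function(i) as.numeric(ring[i, ])))
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(id = a$id, site = a$site_id, species = a$species),
        geometry = list(type = "Polygon", coordinates = coords))
    }
  }
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name", properties = list(name = crs)),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Filter sites for the species comparison
#'
#' Drops mixed-species sites and sites flagged as pupping-season surveys.
#' Each exclusion is logged (via `message()`) and recorded in the
#' `"exclusions"` attribute of the result.
#'
#' @param sites List of `haulout_site` objects.
#' @param pupping_sites Character vector of site ids surveyed during the
#'   pupping season.
#' @param quiet Suppress exclusion messages.
#' @return Filtered list with an `exclusions` attribute (data frame of
#'   site_id / reason).
#' @export
filter_sites <- function(sites, pupping_sites = character(), quiet = FALSE) {
  keep <- logical(length(sites))
  excl <- list()
  for (k in seq_along(sites)) {
    s <- sites[[k]]
    if (s$species == "mixed") {
      excl[[length(excl) + 1]] <- data.frame(site_id = s$site_id,
                                             reason = "mixed-species site")
    } else if (s$site_id %in% pupping_sites) {
      excl[[length(excl) + 1]] <- data.frame(site_id = s$site_id,
                                             reason = "pupping-season survey")
    } else keep[k] <- TRUE
  }
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(site_id = character(), reason = character())
  if (!quiet) for (i in seq_len(nrow(excl)))
    message("excluding site '", excl$site_id[i], "': ", excl$reason[i])
  structure(sites[keep], exclusions = excl)
}

#' Write a results table as CSV
#'
#' UTF-8, `.` decimal separator, deterministic row order (sorted by
#' `site_id` then `id` when those columns are present).
#'
#' @param records Non-empty data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data frame", call. = FALSE)
  ord <- intersect(c("site_id", "id"), names(records))
  if (length(ord) > 0)
    records <- records[do.call(order, records[ord]), , drop = FALSE]
  keep_quoted <- which(!vapply(records, is.double, TRUE))
  for (nm in names(records)) # doubles at full precision for exact re-reads
    if (is.double(records[[nm]]))
      records[[nm]] <- ifelse(is.na(records[[nm]]), NA,
                              sprintf("%.17g", records[[nm]]))
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8",
            quote = keep_quoted)
  invisible(path)
}
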