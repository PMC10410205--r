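## Orchestration: annotations -> NND -> density -> shuffle -> inference,
## with a provenance copy of the configuration and a seeded, per-site
## reproducible shuffle.

#' Pipeline configuration
#'
#' @param radii Radii (metres) for the density analysis.
#' @param bin_width Histogram bin width for NND distributions (metres).
#' @param threshold Proximity threshold for the social-distancing test.
#' @param shuffle A [shuffle_config()].
#' @param replicates Number of shuffle replicates (1 reproduces the
#'   single-configuration protocol; more give a Monte-Carlo interval on
#'   the shuffled proportion).
#' @param pupping_sites Site ids flagged as pupping-season surveys
#'   (excluded, with the mixed-species sites, before any analysis).
#' @param bandwidth_method [cv_bandwidth()] method.
#' @param bandwidth_scope `"species_average"` (per-site CV bandwidths
#'   averaged within species; the default), `"per_site"`, or `"override"`
#'   (use `shuffle$bandwidth_override` everywhere).
#' @param out_dir Output directory for the CSV/GeoJSON/JSON bundle
#'   (nothing is written when `NULL`).
#' @param quiet Suppress progress messages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(radii = c(1, 3, 5, 10), bin_width = 0.25,
                            threshold = 0.25, shuffle = shuffle_config(),
                            replicates = 1, pupping_sites = character(),
                            bandwidth_method = "lscv",
                            bandwidth_scope = c("species_average",
                                                "per_site", "override"),
                            out_dir = NULL, quiet = FALSE) {
  bandwidth_scope <- match.arg(bandwidth_scope)
  if (bandwidth_scope == "override" && is.null(shuffle$bandwidth_override))
    stop("bandwidth_scope = 'override' needs shuffle$bandwidth_override",
         call. = FALSE)
  structure(list(radii = radii, bin_width = bin_width,
                 threshold = threshold, shuffle = shuffle,
                 replicates = as.integer(replicates),
                 pupping_sites = pupping_sites,
                 bandwidth_method = bandwidth_method,
                 bandwidth_scope = bandwidth_scope,
                 out_dir = out_dir, quiet = quiet),
            class = "pipeline_config")
}

## internal: rebuild a site around placed annotations without re-deriving
## or re-checking the window (shuffled polygons may graze the boundary)
site_from_placed <- function(template, annotations) {
  out <- template
  out$annotations <- annotations
  out
}

#' Run the full analysis pipeline
#'
#' Filters sites, computes per-animal NNDs and neighbour counts with
#' their per-species summaries, shuffles every site against the
#' kernel-perturbation null, and runs the three statistical comparisons.
#' When `config$out_dir` is set, writes the CSV tables, the shuffled
#' configuration as GeoJSON, a JSON shuffle report and a verbatim copy of
#' the configuration.
#'
#' @param sites List of [haulout_site()] objects (e.g. from
#'   [read_annotations()] or [generate_paired_study()]).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list bundle: records, summaries, bandwidths,
#'   shuffle results, test table and histograms.
#' @export
run_pipeline <- function(sites, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(...)

  sites <- filter_sites(sites, config$pupping_sites, quiet = config$quiet)
  exclusions <- attr(sites, "exclusions")
  small <- vapply(sites, function(s) length(s$annotations) < 2, TRUE)
  for (s in sites[small])
    say("skipping site '", s$site_id, "': fewer than 2 animals")
  sites <- sites[!small]
  if (length(sites) == 0) stop("no analysable sites remain", call. = FALSE)
  say(length(sites), " site(s) analysed")

  ## stage 1: nearest-neighbour distances
  nnd_records <- do.call(rbind, lapply(sites, nearest_neighbour_distances))
  nnd_species <- summarize_nnd(nnd_records, "species")
  nnd_site <- summarize_nnd(nnd_records, "site")

  ## stage 2: neighbourhood densities
  density_records <- do.call(rbind, lapply(sites, neighbour_counts,
                                           radii = config$radii))
  density_summary <- summarize_density(density_records)

  ## stage 3: bandwidths and shuffling
  bandwidths <- pipeline_bandwidths(sites, config)
  for (i in seq_len(nrow(bandwidths)))
    say("site '", bandwidths$site_id[i], "': bandwidth ",
        signif(bandwidths$bandwidth_used[i], 4), " m")
  shuffles <- list()
  shuffle_nnd <- list()
  for (r in seq_len(config$replicates)) {
    for (k in seq_along(sites)) {
      s <- sites[[k]]
      cfg <- config$shuffle
      cfg$seed <- cfg$seed + (r - 1L)
      cfg$bandwidth_override <-
        bandwidths$bandwidth_used[bandwidths$site_id == s$site_id]
      res <- shuffle_site(s, cfg)
      if (r == 1L) shuffles[[s$site_id]] <- res
      rec <- res$nnd
      rec$replicate <- r
      shuffle_nnd[[length(shuffle_nnd) + 1]] <- rec
    }
  }
  shuffle_nnd <- do.call(rbind, shuffle_nnd)

  ## stage 4: inference
  tests <- list()
  add_test <- function(name, expr) {
    tests[[name]] <<- tryCatch(expr, error = function(e) {
      say("test '", name, "' not computed: ", conditionMessage(e))
      NULL
    })
  }
  two_species <- length(unique(nnd_records$species)) == 2
  if (two_species) {
    add_test("median", median_difference_test(nnd_records))
    add_test("q25", quantile_difference_test(nnd_records, q = 0.25))
    for (r in config$radii)
      add_test(paste0("density_r", r), density_glm(density_records, r))
  } else say("single species: skipping between-species tests")
  for (sp in unique(nnd_records$species)) {
    tests[[paste0("proximity_", sp)]] <- cbind(
      species = sp,
      proximity_proportion_test(
        nnd_records[nnd_records$species == sp, ],
        shuffle_nnd[shuffle_nnd$species == sp, ],
        threshold = config$threshold))
  }
  tests <- Filter(Negate(is.null), tests)
  tests <- do.call(rbind, lapply(tests, function(d) {
    for (nm in c("species", "q", "method", "radius", "theta", "threshold",
                 "prop_observed", "prop_shuffled"))
      if (is.null(d[[nm]])) d[[nm]] <- NA
    d[c("model", "species", "estimate", "statistic", "p_value", "n", "q",
        "method", "radius", "theta", "threshold", "prop_observed",
        "prop_shuffled")]
  }))
  rownames(tests) <- NULL

  ## observed-vs-shuffled histograms per species
  max_m <- config$bin_width *
    ceiling(max(nnd_records$nnd, shuffle_nnd$nnd) / config$bin_width + 1)
  histograms <- do.call(rbind, lapply(unique(nnd_records$species),
                                      function(sp) {
    rbind(cbind(species = sp, condition = "observed",
                bin_nnd(nnd_records[nnd_records$species == sp, ],
                        config$bin_width, max_m)),
          cbind(species = sp, condition = "shuffled",
                bin_nnd(shuffle_nnd[shuffle_nnd$species == sp, ],
                        config$bin_width, max_m)))
  }))

  bundle <- list(sites = sites, exclusions = exclusions,
                 nnd_records = nnd_records,
                 nnd_summary_species = nnd_species,
                 nnd_summary_site = nnd_site,
                 density_records = density_records,
                 density_summary = density_summary,
                 bandwidths = bandwidths, shuffles = shuffles,
                 shuffle_nnd = shuffle_nnd, tests = tests,
                 histograms = histograms, config = config)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

pipeline_bandwidths <- function(sites, config) {
  meta <- data.frame(
    site_id = vapply(sites, `[[`, "", "site_id"),
    species = vapply(sites, `[[`, "", "species"),
    n = vapply(sites, function(s) length(s$annotations), 0L))
  if (config$bandwidth_scope == "override") {
    meta$bandwidth <- NA_real_
    meta$bandwidth_used <- config$shuffle$bandwidth_override
    return(meta)
  }
  meta$bandwidth <- vapply(seq_along(sites), function(k) {
    if (meta$n[k] < 10) return(NA_real_)
    cv_bandwidth(site_centres(sites[[k]]), sites[[k]]$window,
                 method = config$bandwidth_method)
  }, 0)
  if (config$bandwidth_scope == "per_site") {
    meta$bandwidth_used <- meta$bandwidth
  } else {
    avg <- tapply(meta$bandwidth, meta$species, mean, na.rm = TRUE)
    meta$bandwidth_used <- as.numeric(avg[meta$species])
  }
  if (any(is.na(meta$bandwidth_used)))
    stop("no cross-validated bandwidth available for site(s) ",
         paste(meta$site_id[is.na(meta$bandwidth_used)], collapse = ", "),
         "; supply shuffle$bandwidth_override", call. = FALSE)
  meta
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_table(bundle$nnd_records, p("nnd_records.csv"))
  write_table(bundle$nnd_summary_species, p("nnd_summary.csv"))
  write_table(bundle$nnd_summary_site, p("nnd_summary_site.csv"))
  write_table(bundle$density_records, p("density_records.csv"))
  write_table(bundle$density_summary, p("density_summary.csv"))
  write_table(bundle$shuffle_nnd, p("shuffle_nnd_records.csv"))
  write_table(bundle$tests, p("tests.csv"))
  write_table(bundle$histograms, p("histograms.csv"))
  write_table(bundle$bandwidths, p("bandwidths.csv"))
  if (nrow(bundle$exclusions) > 0)
    write_table(bundle$exclusions, p("exclusions.csv"))
  placed_sites <- lapply(names(bundle$shuffles), function(sid)
    site_from_placed(bundle$sites[[match(sid, vapply(bundle$sites, `[[`,
                                                     "", "site_id"))]],
                     bundle$shuffles[[sid]]$placed))
  write_annotations(placed_sites, p("shuffled_annotations.geojson"))
  report <- list(
    seed = bundle$config$shuffle$seed,
    threshold_m = bundle$config$threshold,
    replicates = bundle$config$replicates,
    bandwidths = bundle$bandwidths,
    sites = lapply(bundle$shuffles, function(r)
      list(initial_overlap_fraction = r$initial_overlap_fraction,
           bandwidth_m = r$bandwidth,
           resolution_log = r$resolution_log)))
  jsonlite::write_json(report, p("shuffle_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- bundle$config
  cfg$shuffle <- unclass(cfg$shuffle)
  jsonlite::write_json(unclass(cfg), p("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Observed-vs-shuffled NND histogram
#'
#' Side-by-side barplot of the binned observed and shuffled NND
#' distributions for one species, mirroring the pipeline's histogram
#' table.
#'
#' @param histograms The `histograms` element of a [run_pipeline()]
#'   bundle.
#' @param species Species to plot.
#' @param max_m Truncate the x axis at this distance.
#' @return Invisibly, the plotted matrix of counts.
#' @export
plot_nnd_histogram <- function(histograms, species = "grey", max_m = 5) {
  h <- histograms[histograms$species == species & histograms$bin_lo < max_m, ]
  obs <- h$count[h$condition == "observed"]
  shf <- h$count[h$condition == "shuffled"]
  lab <- h$bin_lo[h$condition == "observed"]
  m <- rbind(observed = obs, shuffled = shf)
  graphics::barplot(m, beside = TRUE, names.arg = sprintf("%.2f", lab),
                    col = c("grey25", "grey75"), las = 2,
                    xlab = "NND bin lower edge (m)", ylab = "count",
                    main = paste("NND distribution:", species))
  graphics::legend("topright", c("observed", "shuffled"),
                   fill = c("grey25", "grey75"), bty = "n")
  invisible(m)
}
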