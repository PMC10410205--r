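## Stage 4: the three statistical comparisons.
##
## 1. Species difference in median (and 25%-quantile) NND — quantile
##    regression on a species factor.
## 2. Species difference in neighbour counts per radius — negative
##    binomial GLM (log link), dispersion by maximum likelihood.
## 3. Observed-vs-shuffled proportion of NNDs below a proximity
##    threshold — binomial GLM (logit link) on aggregated counts.

test_result <- function(model, estimate, statistic, p_value, n, ...) {
  out <- data.frame(model = model, estimate = estimate,
                    statistic = statistic, p_value = p_value, n = n,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Species difference in a NND quantile (quantile regression)
#'
#' Fits `nnd ~ species` at quantile `q` with [quantreg::rq()]. The
#' coefficient on the species indicator estimates the between-species
#' difference in the `q`-quantile; the t statistic and p-value use the
#' asymptotic sparsity ("nid") standard error, flagged in `method`.
#'
#' @param records NND data frame with both species present (>= 10 records
#'   each).
#' @param q Quantile level (0.5 = median regression).
#' @return One-row data frame: `model`, `estimate` (quantile difference,
#'   second species level minus first), `statistic`, `p_value`, `n`,
#'   `q`, `method`.
#' @export
median_difference_test <- function(records, q = 0.5) {
  quantile_difference_test(records, q = q)
}

#' @rdname median_difference_test
#' @export
quantile_difference_test <- function(records, q = 0.25) {
  stopifnot(is.data.frame(records), q > 0, q < 1)
  records$species <- factor(records$species)
  tab <- table(records$species)
  if (length(tab) < 2)
    stop("both species must be present (got only ",
         paste(names(tab), collapse = ", "), ")", call. = FALSE)
  if (any(tab < 10))
    stop("each species needs >= 10 records", call. = FALSE)
  fit <- suppressWarnings(quantreg::rq(nnd ~ species, tau = q,
                                       data = records))
  sm <- suppressWarnings(summary(fit, se = "nid"))
  co <- sm$coefficients
  test_result(model = "quantile_regression",
              estimate = co[2, 1], statistic = co[2, 3],
              p_value = co[2, 4], n = nrow(records),
              q = q, method = "rq-nid")
}

#' Species difference in neighbour counts (negative-binomial GLM)
#'
#' Fits `count ~ species` at one radius with [MASS::glm.nb()] (log link,
#' dispersion estimated by maximum likelihood). The coefficient is the
#' log rate ratio between species.
#'
#' @param records Data frame from [neighbour_counts()].
#' @param radius Radius (metres) to test; must appear in `records`.
#' @return One-row data frame with `estimate` (log rate ratio), Wald `z`
#'   statistic, `p_value`, `n`, `radius`.
#' @export
density_glm <- function(records, radius) {
  stopifnot(is.data.frame(records))
  d <- records[records$radius == radius, ]
  if (nrow(d) == 0) stop("no records at radius ", radius, call. = FALSE)
  d$species <- factor(d$species)
  if (nlevels(d$species) < 2)
    stop("both species must be present at radius ", radius, call. = FALSE)
  zero <- tapply(d$count, d$species, function(v) all(v == 0))
  if (any(zero))
    stop("all counts are zero for species ",
         paste(names(zero)[zero], collapse = ", "),
         "; a log-link rate model is unidentified (consider an exact or ",
         "penalized comparison)", call. = FALSE)
  fit <- suppressWarnings(MASS::glm.nb(count ~ species, data = d))
  co <- summary(fit)$coefficients
  test_result(model = "negbin_glm",
              estimate = co[2, 1], statistic = co[2, 3],
              p_value = co[2, 4], n = nrow(d),
              radius = radius, theta = fit$theta)
}

#' Observed-vs-shuffled proximity proportion (binomial GLM)
#'
#' Counts NNDs below `threshold` ("successes") and at or above it
#' ("failures") in the observed and the shuffled records, then fits a
#' binomial GLM (logit link) on the observed/shuffled factor. The
#' estimate is the log-odds difference (shuffled minus observed). The
#' p-value is the likelihood-ratio test of the factor, which remains
#' defined when one condition has zero successes (where the Wald z
#' degenerates); the Wald z is reported as the statistic.
#'
#' @param observed,shuffled NND data frames (same species).
#' @param threshold Proximity threshold in metres; a distance exactly
#'   equal to the threshold counts as a failure.
#' @return One-row data frame with `estimate`, `statistic` (Wald z),
#'   `p_value` (LR test), `n`, `threshold`, `prop_observed`,
#'   `prop_shuffled`.
#' @export
proximity_proportion_test <- function(observed, shuffled, threshold = 0.25) {
  obs <- if (is.data.frame(observed)) observed$nnd else observed
  shf <- if (is.data.frame(shuffled)) shuffled$nnd else shuffled
  if (length(obs) == 0 || length(shf) == 0)
    stop("both conditions need at least one NND", call. = FALSE)
  counts <- data.frame(
    condition = factor(c("observed", "shuffled"),
                       levels = c("observed", "shuffled")),
    succ = c(sum(obs < threshold), sum(shf < threshold)),
    fail = c(sum(obs >= threshold), sum(shf >= threshold)))
  fit <- glm(cbind(succ, fail) ~ condition, family = binomial(),
             data = counts)
  co <- summary(fit)$coefficients
  lr <- anova(fit, test = "Chisq")
  test_result(model = "binomial_glm",
              estimate = co[2, 1], statistic = co[2, 3],
              p_value = lr$`Pr(>Chi)`[2],
              n = length(obs) + length(shf),
              threshold = threshold,
              prop_observed = counts$succ[1] / length(obs),
              prop_shuffled = counts$succ[2] / length(shf))
}
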