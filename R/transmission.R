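## Symbiont/host rate ratios, comparison against cladogenic calibrations,
## acquisition-mode classification, and divergence-to-time conversion.

#' Ratio of two substitution rates at fixed precision
#'
#' @param numerator,denominator Non-negative rates; denominator > 0.
#' @param digits Significant figures (default 2, the table convention).
#' @return `signif(numerator / denominator, digits)`.
#' @export
substitution_rate_ratio <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  signif(numerator / denominator, digits)
}

#' Symbiont/host silent-site ratio
#'
#' @param symbiont_ks,host_ks Silent-site divergences.
#' @return The ratio at 2 significant figures.
#' @export
ks_ratio <- function(symbiont_ks, host_ks) {
  substitution_rate_ratio(symbiont_ks, host_ks)
}

#' Bundled Wolbachia/host calibration table
#'
#' Published synonymous (k_s) and nonsynonymous (k_a) divergences for
#' Wolbachia and their hosts: the focal wRi-like Drosophila pair, one
#' Nasonia wasp pair (Raychoudhury et al. 2009) and six Nomada bee pairs
#' (Gerth & Bleidorn 2017). The `cladogenic` column flags the rows that
#' serve as codivergence calibrations; the focal Drosophila row does not.
#'
#' @param path TSV path; defaults to the copy shipped with the package.
#' @return Data frame with columns `source`, `species_1`, `species_2`,
#'   `host_ks`, `host_ka`, `symbiont_ks`, `symbiont_ka`, `ratio`,
#'   `cladogenic`.
#' @export
wolbachia_calibrations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "wolbachia_calibrations.tsv",
                        package = "codiverge", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "species_1", "species_2", "host_ks", "host_ka",
            "symbiont_ks", "symbiont_ka", "ratio", "cladogenic")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("calibration table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' Fold differences of an observed ratio against calibrations
#'
#' @param observed_ratio Observed symbiont/host k_s ratio (> 0).
#' @param calibrations Calibration data frame (rows with a `ratio`
#'   column); by default the cladogenic rows of
#'   [wolbachia_calibrations()].
#' @return Object of class `calibration_comparison`: per-entry fold
#'   differences (`calibration ratio / observed`) plus min, max and the
#'   order-of-magnitude range.
#' @export
compare_to_calibrations <- function(observed_ratio, calibrations = NULL) {
  if (observed_ratio <= 0) stop("observed_ratio must be positive")
  if (is.null(calibrations)) {
    calibrations <- wolbachia_calibrations()
    calibrations <- calibrations[calibrations$cladogenic, , drop = FALSE]
  }
  if (nrow(calibrations) == 0L) stop("empty calibration list")
  fold <- calibrations$ratio / observed_ratio
  tab <- data.frame(source = calibrations$source,
                    ratio = calibrations$ratio, fold = fold,
                    stringsAsFactors = FALSE)
  structure(list(observed = observed_ratio, folds = tab,
                 min_fold = min(fold), max_fold = max(fold),
                 orders_of_magnitude = range(log10(fold))),
            class = "calibration_comparison")
}

#' @export
print.calibration_comparison <- function(x, ...) {
  cat(sprintf("<calibration_comparison> observed ratio %.3g\n", x$observed))
  print(x$folds, row.names = FALSE, digits = 3)
  cat(sprintf("  fold range %.3g - %.3g (%.1f - %.1f orders of magnitude)\n",
              x$min_fold, x$max_fold, x$orders_of_magnitude[1],
              x$orders_of_magnitude[2]))
  invisible(x)
}

#' Classify the mode of symbiont acquisition
#'
#' Compares the observed symbiont/host-nuclear divergence ratio with the
#' range of ratios observed under cladogenic codivergence. The call is
#' `cladogenic_plausible` when the observed ratio falls within a factor
#' `concordance_factor` of the calibration range; cladogenic transmission
#' is rejected when the observed ratio is more than `rejection_factor`
#' below the smallest calibration. After rejection, a mitochondrial
#' divergence (on the host-nuclear scale) separates introgression
#' (mitochondrion concordant with the time-scaled symbiont divergence,
#' both far below nuclear) from horizontal transfer (symbiont younger
#' than the mitochondrion); without a mitochondrial estimate the call
#' degrades to `noncladogenic_transfer`.
#'
#' All rules are ratio-based, so multiplying every divergence by a
#' constant leaves the call unchanged.
#'
#' @param nuclear_div Host nuclear silent-site divergence (> 0).
#' @param symbiont_div Symbiont silent-site divergence (> 0).
#' @param mito_div Optional mitochondrial divergence rescaled to the host
#'   nuclear silent scale.
#' @param calibrations Calibration table; cladogenic rows are used.
#' @param concordance_factor Concordance tolerance T1 (default 2: under
#'   codivergence the chronograms should agree within about a factor of
#'   two).
#' @param rejection_factor Rejection threshold T2 (default 10).
#' @return Object of class `transmission_call`: `mode`, the observed
#'   ratio, the symbiont divergence rescaled by the calibration median,
#'   fold differences versus every calibration, and a rationale string.
#' @export
classify_transmission <- function(nuclear_div, symbiont_div,
                                  mito_div = NULL, calibrations = NULL,
                                  concordance_factor = 2,
                                  rejection_factor = 10) {
  if (is.null(calibrations)) calibrations <- wolbachia_calibrations()
  if (!nrow(calibrations)) stop("missing calibrations")
  if ("cladogenic" %in% names(calibrations))
    calibrations <- calibrations[calibrations$cladogenic, , drop = FALSE]
  if (!nrow(calibrations)) stop("no cladogenic calibration rows")
  if (nuclear_div <= 0 || symbiont_div <= 0)
    stop("divergences must be positive")
  if (!is.null(mito_div) && mito_div <= 0)
    stop("mito divergence must be positive")
  T1 <- concordance_factor; T2 <- rejection_factor

  obs <- symbiont_div / nuclear_div
  cmp <- compare_to_calibrations(obs, calibrations)
  lo <- min(calibrations$ratio); hi <- max(calibrations$ratio)
  scaled_symb <- symbiont_div / median(calibrations$ratio)

  if (obs >= lo / T1 && obs <= hi * T1) {
    mode <- "cladogenic_plausible"
    why <- sprintf(paste0("observed ratio %.3g lies within a factor %g of ",
                          "the cladogenic calibration range [%.3g, %.3g]"),
                   obs, T1, lo, hi)
  } else if (obs < lo / T2) {
    if (is.null(mito_div)) {
      mode <- "noncladogenic_transfer"
      why <- sprintf(paste0("observed ratio %.3g is %.3g-fold below the ",
                            "smallest cladogenic calibration (%.3g); ",
                            "without a mitochondrial estimate, ",
                            "introgression vs horizontal is indeterminate"),
                     obs, lo / obs, lo)
    } else if (mito_div <= scaled_symb * T1 && mito_div >= scaled_symb / T1 &&
               nuclear_div > mito_div * T1) {
      mode <- "introgression"
      why <- sprintf(paste0("mitochondrial divergence %.3g is concordant ",
                            "with the rescaled symbiont divergence %.3g and ",
                            "both are far below nuclear %.3g"),
                     mito_div, scaled_symb, nuclear_div)
    } else if (mito_div > scaled_symb * T1) {
      mode <- "horizontal"
      why <- sprintf(paste0("symbiont divergence (rescaled %.3g) is younger ",
                            "than the mitochondrial divergence %.3g"),
                     scaled_symb, mito_div)
    } else {
      mode <- "indeterminate"
      why <- "divergence pattern fits no acquisition mode cleanly"
    }
  } else {
    mode <- "indeterminate"
    why <- sprintf(paste0("observed ratio %.3g falls between the cladogenic ",
                          "range and the rejection threshold %.3g"),
                   obs, lo / T2)
  }
  structure(list(mode = mode, observed_ratio = obs,
                 scaled_symbiont_div = scaled_symb,
                 nuclear_div = nuclear_div, symbiont_div = symbiont_div,
                 mito_div = mito_div, folds = cmp$folds,
                 min_fold = cmp$min_fold,
                 thresholds = c(concordance = T1, rejection = T2),
                 rationale = why),
            class = "transmission_call")
}

#' @export
print.transmission_call <- function(x, ...) {
  cat(sprintf("<transmission_call> %s\n", x$mode))
  cat(sprintf("  symbiont/nuclear ratio %.3g (calibration folds %.3g - %.3g)\n",
              x$observed_ratio, min(x$folds$fold), max(x$folds$fold)))
  cat("  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Convert a divergence to calendar time
#'
#' Two explicit rate conventions, never inferred: `"per_lineage"` treats
#' the rate as substitutions per site per lineage, so for a pairwise
#' divergence d the time is `d / (2 * rate * g)`; `"pairwise_divergence"`
#' treats the rate as accumulating along the pair jointly, so
#' `t = d / (rate * g)`. `g` is generations per year when the rate is per
#' generation (leave at 1 for per-year rates). Interval endpoints come
#' from evaluating at the rate interval's endpoints (the slow rate gives
#' the upper time bound). Reported values are rounded to 2 significant
#' figures; the raw values are kept.
#'
#' @param divergence Substitutions per site (>= 0).
#' @param rate Point rate (per site per year, or per site per generation).
#' @param rate_interval Optional `c(lower, upper)` rate interval.
#' @param convention `"per_lineage"` or `"pairwise_divergence"`.
#' @param generations_per_year Generations per year (1 for per-year
#'   rates). Note: for temperate hosts an assumed 10/yr may overestimate
#'   by about a factor of two, inflating ages accordingly.
#' @return Object of class `time_estimate` with `years`, `years_rounded`
#'   and, given a rate interval, `interval` / `interval_rounded`.
#' @export
calibrate_time <- function(divergence, rate, rate_interval = NULL,
                           convention = c("per_lineage",
                                          "pairwise_divergence"),
                           generations_per_year = 1) {
  convention <- match.arg(convention)
  if (divergence < 0) stop("divergence must be non-negative")
  if (rate <= 0) stop("rate must be positive")
  if (generations_per_year <= 0) stop("generations_per_year must be positive")
  to_years <- function(r) {
    denom <- switch(convention,
                    per_lineage = 2 * r * generations_per_year,
                    pairwise_divergence = r * generations_per_year)
    divergence / denom
  }
  years <- to_years(rate)
  interval <- NULL
  if (!is.null(rate_interval)) {
    stopifnot(length(rate_interval) == 2L, all(rate_interval > 0),
              rate_interval[1] <= rate_interval[2])
    interval <- c(lower = to_years(rate_interval[2]),
                  upper = to_years(rate_interval[1]))
  }
  structure(list(years = years, years_rounded = signif(years, 2),
                 interval = interval,
                 interval_rounded = if (!is.null(interval))
                   signif(interval, 2),
                 divergence = divergence, rate = rate,
                 rate_interval = rate_interval, convention = convention,
                 generations_per_year = generations_per_year),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("<time_estimate> %s years (d = %.3g, %s convention)\n",
              format(x$years_rounded, big.mark = ","), x$divergence,
              x$convention))
  if (!is.null(x$interval))
    cat(sprintf("  interval: %s - %s years\n",
                format(x$interval_rounded[["lower"]], big.mark = ","),
                format(x$interval_rounded[["upper"]], big.mark = ",")))
  invisible(x)
}
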