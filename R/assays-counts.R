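#' Genetic linkage degree and screening filter
#'
#' The linkage degree between a phenotype-causing mutation and the reporter
#' construct is estimated by transforming wild-type cells with the mutant's
#' genomic DNA and plating: `linkage_pct = 100 * n_mutant_phenotype /
#' n_reporter_phenotype`. With this (field-printed) normalisation the value
#' can exceed 100%; a `"total"` mode dividing by the sum of both classes is
#' provided as an alternative.
#'
#' @param n_mutant_phenotype colonies showing the mutant blue/white
#'   phenotype.
#' @param n_reporter_phenotype colonies showing the unmutagenized reporter
#'   phenotype.
#' @param denominator `"reporter"` (printed formula, default) or `"total"`.
#' @return A list of class `linkage_result`: the two counts, `linkage_pct`
#'   (NA with `undefined = TRUE` when the denominator is 0) and the mode.
#' @export
linkage_degree <- function(n_mutant_phenotype, n_reporter_phenotype,
                           denominator = c("reporter", "total")) {
  denominator <- match.arg(denominator)
  if (n_mutant_phenotype < 0 || n_reporter_phenotype < 0) {
    stop("colony counts must be non-negative")
  }
  den <- switch(denominator,
                reporter = n_reporter_phenotype,
                total = n_mutant_phenotype + n_reporter_phenotype)
  pct <- if (den > 0) 100 * n_mutant_phenotype / den else NA_real_
  structure(list(n_mutant_phenotype = n_mutant_phenotype,
                 n_reporter_phenotype = n_reporter_phenotype,
                 linkage_pct = pct, undefined = den == 0,
                 denominator = denominator),
            class = "linkage_result")
}

#' @rdname linkage_degree
#' @param results list of `linkage_result` objects (or a data.frame with a
#'   `linkage_pct` column).
#' @param threshold_pct keep entries with linkage strictly below this
#'   percentage (default 3, the screen's unlinked-mutant criterion);
#'   undefined degrees are never kept.
#' @return `linkage_filter`: the kept subset.
#' @export
linkage_filter <- function(results, threshold_pct = 3) {
  if (is.data.frame(results)) {
    keep <- !is.na(results$linkage_pct) & results$linkage_pct < threshold_pct
    return(results[keep, , drop = FALSE])
  }
  keep <- vapply(results, function(r) {
    !r$undefined && r$linkage_pct < threshold_pct
  }, logical(1))
  results[keep]
}

#' Plate counts for one transformation reaction
#'
#' @param transformant_colonies colonies on the selective plate.
#' @param transformant_volume_ml volume plated on the selective plate (mL).
#' @param viable_colonies colonies on the viable-count plate.
#' @param viable_volume_ml volume plated on the viable-count plate (mL).
#' @param viable_dilution dilution factor of the viable-count plating
#'   (e.g. `1e6` for a 10^-6 dilution).
#' @param no_dna_revertant_colonies colonies in the no-DNA control (same
#'   plating volume as the transformant plate); sets the assay's detection
#'   limit via the spontaneous reversion rate.
#' @return A list of class `plate_counts`.
#' @export
plate_counts <- function(transformant_colonies, transformant_volume_ml,
                         viable_colonies, viable_volume_ml, viable_dilution,
                         no_dna_revertant_colonies = 0) {
  counts <- c(transformant_colonies, viable_colonies,
              no_dna_revertant_colonies)
  if (any(counts < 0)) stop("colony counts must be non-negative")
  stopifnot(transformant_volume_ml > 0, viable_volume_ml > 0,
            viable_dilution >= 1, viable_colonies > 0)
  structure(list(transformant_colonies = transformant_colonies,
                 transformant_volume_ml = transformant_volume_ml,
                 viable_colonies = viable_colonies,
                 viable_volume_ml = viable_volume_ml,
                 viable_dilution = viable_dilution,
                 no_dna_revertant_colonies = no_dna_revertant_colonies),
            class = "plate_counts")
}

#' Transformation frequency with detection-limit semantics
#'
#' Frequency = transformant CFU/mL divided by viable CFU/mL (volume- and
#' dilution-corrected). The detection limit is the spontaneous reversion
#' frequency from the no-DNA control; reactions with zero transformant
#' colonies are censored (`below_detection`), with the frequency reported as
#' `< detection_limit`. When the control itself has zero revertants, the
#' limit corresponds to < 1 colony on the control plate.
#'
#' @param x a [plate_counts()] or a list of them (replicates of one strain).
#' @param reference_frequency mean frequency of the reference strain, for
#'   `rel_log10 = log10(frequency / reference)`; optional.
#' @return An object of class `transformation_result`: per-replicate
#'   `frequency`, `detection_limit`, `below_detection`, plus `mean_frequency`
#'   (over uncensored replicates) and `rel_log10` when a reference is given.
#' @export
transformation_frequency <- function(x, reference_frequency = NULL) {
  reps <- if (inherits(x, "plate_counts")) list(x) else x
  stopifnot(all(vapply(reps, inherits, logical(1), "plate_counts")))
  per <- lapply(reps, function(p) {
    transformant_cfu_ml <- p$transformant_colonies / p$transformant_volume_ml
    viable_cfu_ml <- p$viable_colonies / p$viable_volume_ml * p$viable_dilution
    rev_col <- max(p$no_dna_revertant_colonies, 1)  # < 1 colony convention
    detection_limit <- (rev_col / p$transformant_volume_ml) / viable_cfu_ml
    below <- p$transformant_colonies == 0
    freq <- transformant_cfu_ml / viable_cfu_ml
    list(frequency = freq, detection_limit = detection_limit,
         below_detection = below)
  })
  freq <- vapply(per, `[[`, numeric(1), "frequency")
  lim <- vapply(per, `[[`, numeric(1), "detection_limit")
  below <- vapply(per, `[[`, logical(1), "below_detection")
  mean_freq <- if (all(below)) NA_real_ else mean(freq[!below])
  out <- list(frequency = freq, detection_limit = lim,
              below_detection = below, mean_frequency = mean_freq,
              n_replicates = length(per))
  if (!is.null(reference_frequency)) {
    out$rel_log10 <- if (is.na(mean_freq)) NA_real_ else {
      log10(mean_freq / reference_frequency)
    }
  }
  structure(out, class = "transformation_result")
}

#' @export
print.transformation_result <- function(x, ...) {
  if (all(x$below_detection)) {
    cat(sprintf("transformation frequency: < %.3g (below detection, n=%d)\n",
                max(x$detection_limit), x$n_replicates))
  } else {
    cat(sprintf("transformation frequency: %.3g (n=%d%s)\n",
                x$mean_frequency, x$n_replicates,
                if (any(x$below_detection)) {
                  sprintf(", %d censored", sum(x$below_detection))
                } else ""))
  }
  if (!is.null(x$rel_log10)) {
    cat(sprintf("rel_log10 vs reference: %.3f\n", x$rel_log10))
  }
  invisible(x)
}

#' One-way ANOVA of transformation frequencies across strains
#'
#' Ordinary fixed-effects one-way ANOVA on log10-transformed frequencies.
#' Below-detection (censored) replicates must be excluded by the caller or
#' passed as `NA`; they are dropped with a message.
#'
#' @param frequencies numeric vector of per-replicate frequencies (> 0).
#' @param strain factor/character of the same length.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_across_strains <- function(frequencies, strain) {
  stopifnot(length(frequencies) == length(strain))
  keep <- !is.na(frequencies) & frequencies > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " censored/invalid replicate(s)")
  }
  y <- log10(frequencies[keep])
  g <- factor(strain[keep])
  if (nlevels(g) < 2L) stop("need at least two strains")
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1])
}
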