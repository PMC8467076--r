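#' Classify a nucleotide substitution
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine exchanges
#' ({A,G} or {C,T}); everything else is a transversion. The EMS signature
#' class is the G:C->A:T transition, which on the reference strand reads as
#' either G->A or C->T; the classification is therefore invariant under
#' complementing both bases.
#'
#' @param ref,alt reference and alternate bases (vectors recycle).
#' @return A `data.frame` with columns `ref`, `alt`, `class`
#'   (`"transition"`/`"transversion"`) and `ems_signature` (logical).
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (any(!(ref %in% VALID_BASES)) || any(!(alt %in% VALID_BASES))) {
    stop("invalid nucleotide")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  transition <- (ref %in% purine) == (alt %in% purine)
  ems <- (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
  data.frame(ref = ref, alt = alt,
             class = ifelse(transition, "transition", "transversion"),
             ems_signature = ems, stringsAsFactors = FALSE)
}

#' Summarize the mutation spectrum of a screen
#'
#' Counts transitions, transversions and EMS-signature (G:C->A:T) changes
#' across all records, tabulates the per-mutant mutation burden, and derives
#' the genome-wide mutation rate as the average per-mutant SNP count divided
#' by the genome length. Mutants listed in the set but carrying no record
#' count as zero burden.
#'
#' @param x a [mutant_set()].
#' @param average `"mean"` (default) or `"median"` for the per-mutant burden
#'   used in `rate_per_bp`.
#' @return An object of class `spectrum_summary`: counts, `per_mutant_counts`
#'   (named integer vector over all mutants), `mean_per_mutant` and
#'   `rate_per_bp`.
#' @export
summarize_spectrum <- function(x, average = c("mean", "median")) {
  stopifnot(inherits(x, "mutant_set"))
  average <- match.arg(average)
  rec <- x$records
  counts <- stats::setNames(integer(length(x$mutant_ids)), x$mutant_ids)
  if (nrow(rec) > 0L) {
    tab <- table(factor(rec$mutant_id, levels = x$mutant_ids))
    counts[] <- as.integer(tab)
    cls <- classify_substitution(rec$ref_base, rec$alt_base)
    n_transitions <- sum(cls$class == "transition")
    n_ems <- sum(cls$ems_signature)
  } else {
    n_transitions <- 0L
    n_ems <- 0L
  }
  avg <- if (length(counts) == 0L) 0 else {
    if (average == "mean") mean(counts) else stats::median(counts)
  }
  structure(
    list(
      n_records = nrow(rec),
      n_transitions = n_transitions,
      n_transversions = nrow(rec) - n_transitions,
      n_ems_signature = n_ems,
      per_mutant_counts = counts,
      mean_per_mutant = avg,
      rate_per_bp = avg / x$genome_length,
      average = average
    ),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum: %d records | %d transitions, %d transversions\n",
              x$n_records, x$n_transitions, x$n_transversions))
  cat(sprintf("G:C->A:T signature: %d (%.1f%%)\n", x$n_ems_signature,
              if (x$n_records > 0) 100 * x$n_ems_signature / x$n_records else 0))
  cat(sprintf("%s burden: %.2f SNPs/genome (rate %.3g per bp)\n",
              x$average, x$mean_per_mutant, x$rate_per_bp))
  invisible(x)
}

#' Write a spectrum summary as TSV
#' @param x a `spectrum_summary`.
#' @param path output path.
#' @export
write_spectrum_tsv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_summary"))
  df <- data.frame(
    metric = c("n_records", "n_transitions", "n_transversions",
               "n_ems_signature", "burden_per_genome", "rate_per_bp"),
    value = c(x$n_records, x$n_transitions, x$n_transversions,
              x$n_ems_signature, x$mean_per_mutant, x$rate_per_bp)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mutagenesis efficiency from resistance plating
#'
#' The efficiency of chemical mutagenesis is monitored as the frequency of
#' rifampicin-resistant colonies in treated versus untreated cultures. When
#' the untreated control yields zero resistant colonies, the fold change is
#' reported as a lower bound using the control's detection limit of one
#' colony.
#'
#' @param treated_resistant_cfu resistant CFU/mL after mutagen treatment.
#' @param control_resistant_cfu resistant CFU/mL in the untreated control.
#' @param total_cfu total viable CFU/mL.
#' @return An object of class `efficiency_result`: `treated_freq`,
#'   `control_freq`, `fold_change`, `fold_is_lower_bound`.
#' @export
mutagenesis_efficiency <- function(treated_resistant_cfu,
                                   control_resistant_cfu, total_cfu) {
  if (treated_resistant_cfu < 0 || control_resistant_cfu < 0) {
    stop("colony counts must be non-negative")
  }
  stopifnot(total_cfu > 0)
  treated_freq <- treated_resistant_cfu / total_cfu
  control_freq <- control_resistant_cfu / total_cfu
  if (control_resistant_cfu > 0) {
    fold <- treated_freq / control_freq
    bound <- FALSE
  } else {
    # detection limit: < 1 resistant colony in the control
    fold <- treated_freq / (1 / total_cfu)
    bound <- TRUE
  }
  structure(list(treated_freq = treated_freq, control_freq = control_freq,
                 fold_change = fold, fold_is_lower_bound = bound),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("mutagenesis efficiency: treated %.3g, control %.3g, %s%.1f-fold\n",
              x$treated_freq, x$control_freq,
              if (x$fold_is_lower_bound) ">= " else "", x$fold_change))
  invisible(x)
}
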