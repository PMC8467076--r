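#' SNP record tables and mutant sets
#'
#' The central data structure of the pipeline is the *mutant set*: the merged
#' table of single-nucleotide substitution calls across all sequenced mutant
#' genomes of a screen, against one haploid reference. Each row of the record
#' table is one substitution observed in one mutant.
#'
#' @name snp-data
#' @keywords internal
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' Build a table of SNP records
#'
#' @param mutant_id character vector of mutant labels (e.g. `"M27"`).
#' @param position 1-based genomic coordinates (bp).
#' @param ref_base,alt_base reference and alternate nucleotides (`A`/`C`/`G`/`T`).
#' @param locus_tag optional gene identifier, `""` for intergenic.
#' @param note optional free-text annotation.
#' @return A `data.frame` with columns `mutant_id`, `position`, `ref_base`,
#'   `alt_base`, `locus_tag`, `note`, validated and ready for [mutant_set()].
#' @export
snp_records <- function(mutant_id, position, ref_base, alt_base,
                        locus_tag = "", note = "") {
  if (length(mutant_id) == 0L) {
    locus_tag <- character(0)
    note <- character(0)
  }
  df <- data.frame(
    mutant_id = as.character(mutant_id),
    position = as.integer(position),
    ref_base = toupper(as.character(ref_base)),
    alt_base = toupper(as.character(alt_base)),
    locus_tag = as.character(locus_tag),
    note = as.character(note),
    stringsAsFactors = FALSE
  )
  validate_snp_records(df)
  df
}

validate_snp_records <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("mutant_id", "position", "ref_base", "alt_base")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("SNP record table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$position)) || any(df$position < 1L)) {
    stop("SNP positions must be integers >= 1")
  }
  bad <- !(df$ref_base %in% VALID_BASES) | !(df$alt_base %in% VALID_BASES)
  if (any(bad)) {
    stop("invalid nucleotide in record(s) at position(s): ",
         paste(utils::head(df$position[bad], 5), collapse = ", "))
  }
  same <- df$ref_base == df$alt_base
  if (any(same)) {
    stop("ref_base equals alt_base at position(s): ",
         paste(utils::head(df$position[same], 5), collapse = ", "))
  }
  invisible(df)
}

#' Construct a mutant set
#'
#' A mutant set bundles the merged SNP record table of a screen with the
#' reference name and genome length. Records are stored sorted by
#' (position, mutant_id); exact duplicate (mutant, position) calls collapse
#' to one record.
#'
#' @param records a SNP record table as built by [snp_records()].
#' @param reference_name name of the reference replicon.
#' @param genome_length reference length in bp.
#' @param mutant_ids optional ordered character vector of all mutants in the
#'   screen (defaults to those present in `records`); mutants with zero
#'   records are legal and matter for per-mutant burden statistics.
#' @return An object of class `mutant_set`.
#' @export
mutant_set <- function(records, reference_name, genome_length,
                       mutant_ids = NULL) {
  if (missing(records) || is.null(records)) {
    records <- snp_records(character(), integer(), character(), character())
  }
  validate_snp_records(records)
  genome_length <- as.numeric(genome_length)
  stopifnot(length(genome_length) == 1L, genome_length >= 1)
  if (nrow(records) > 0L && any(records$position > genome_length)) {
    stop("record position(s) exceed genome_length")
  }
  if (is.null(mutant_ids)) {
    mutant_ids <- unique(records$mutant_id)
  } else {
    mutant_ids <- as.character(mutant_ids)
    extra <- setdiff(records$mutant_id, mutant_ids)
    if (length(extra) > 0L) {
      stop("records carry mutant id(s) absent from mutant_ids: ",
           paste(extra, collapse = ", "))
    }
  }
  if (anyDuplicated(mutant_ids)) stop("mutant_ids must be unique")
  records <- records[!duplicated(records[c("mutant_id", "position")]), ,
                     drop = FALSE]
  records <- records[order(records$position, records$mutant_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(
      reference_name = as.character(reference_name),
      genome_length = genome_length,
      records = records,
      mutant_ids = mutant_ids
    ),
    class = "mutant_set"
  )
}

#' @export
print.mutant_set <- function(x, ...) {
  cat(sprintf(
    "mutant_set: %d record(s) at %d position(s) in %d mutant(s)\n",
    nrow(x$records), length(unique(x$records$position)), length(x$mutant_ids)
  ))
  cat(sprintf("reference: %s (%s bp)\n", x$reference_name,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Number of records in a mutant set
#' @param x a `mutant_set`.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "mutant_set"))
  nrow(x$records)
}

#' Write / read the package's mutant-set TSV dialect
#'
#' Round-trip safe plain-text serialisation: a header line of the form
#' `#reference <name> <length>` followed by the tab-separated record table.
#'
#' @param x a `mutant_set`.
#' @param path output / input file path.
#' @return `write_mutant_set` returns `path` invisibly; `read_mutant_set`
#'   returns the reconstructed `mutant_set`.
#' @export
write_mutant_set <- function(x, path) {
  stopifnot(inherits(x, "mutant_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#reference\t%s\t%s", x$reference_name,
                     format(x$genome_length, scientific = FALSE)), con)
  writeLines(sprintf("#mutants\t%s", paste(x$mutant_ids, collapse = ",")), con)
  utils::write.table(x$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutant_set
#' @export
read_mutant_set <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#reference\t")) {
    stop("not a mutant-set file: ", path)
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  mut <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  ids <- if (length(mut) >= 2L) strsplit(mut[2], ",", fixed = TRUE)[[1]] else character()
  body <- lines[-(1:2)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character")
  df$position <- as.integer(df$position)
  if (nrow(df) == 0L) {
    df <- snp_records(character(), integer(), character(), character())
  }
  mutant_set(df, reference_name = hdr[2], genome_length = as.numeric(hdr[3]),
             mutant_ids = ids)
}
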