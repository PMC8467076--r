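#' Read a Snippy-style per-mutant variant table
#'
#' Consumes the tab-separated output of haploid read-mapping variant callers
#' (columns `CHROM`, `POS`, `TYPE`, `REF`, `ALT`, optionally `LOCUS_TAG`,
#' `EFFECT`, ...). Only single-nucleotide substitutions (`TYPE == "snp"`)
#' are retained; indel/complex/mnp records are skipped and their count is
#' reported via a message and the `"n_skipped"` attribute.
#'
#' @param path path to the TSV file (header required).
#' @param mutant_id label to assign to every record in the file.
#' @param reference_name if given, rows whose `CHROM` differs raise an error.
#' @return A SNP record table (see [snp_records()]) with attribute
#'   `n_skipped`.
#' @export
read_snp_table <- function(path, mutant_id, reference_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("CHROM", "POS", "TYPE", "REF", "ALT")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    out <- snp_records(character(), integer(), character(), character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (!is.null(reference_name)) {
    bad <- which(df$CHROM != reference_name)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: unknown reference name '%s' (expected '%s')",
                   bad[1] + 1L, df$CHROM[bad[1]], reference_name))
    }
  }
  pos <- suppressWarnings(as.integer(df$POS))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: malformed POS '%s'", bad[1] + 1L, df$POS[bad[1]]))
  }
  is_snp <- df$TYPE == "snp"
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0L) {
    message(sprintf("%s: skipped %d non-SNP record(s)", basename(path),
                    n_skipped))
  }
  keep <- which(is_snp)
  snp <- df[keep, , drop = FALSE]
  bad <- which(!(toupper(snp$REF) %in% VALID_BASES) |
                 !(toupper(snp$ALT) %in% VALID_BASES))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: malformed snp alleles '%s>%s'",
                 keep[bad[1]] + 1L, snp$REF[bad[1]], snp$ALT[bad[1]]))
  }
  out <- snp_records(
    mutant_id = rep(mutant_id, length(keep)),
    position = pos[keep],
    ref_base = snp$REF,
    alt_base = snp$ALT,
    locus_tag = if ("LOCUS_TAG" %in% names(snp)) snp$LOCUS_TAG else "",
    note = if ("PRODUCT" %in% names(snp)) snp$PRODUCT else ""
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read SNP records from a VCF file
#'
#' Alternate input dialect with the same contract as [read_snp_table()]:
#' multi-allelic records are split into one record per alternate allele and
#' non-SNP alleles (indels, symbolic, spanning deletions) are skipped.
#'
#' @inheritParams read_snp_table
#' @return A SNP record table with attribute `n_skipped` (count of skipped
#'   non-SNP alternate alleles).
#' @export
read_vcf <- function(path, mutant_id, reference_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) {  # single-record VCFs come back as a bare vector
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  }
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- snp_records(character(), integer(), character(), character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  if (!is.null(reference_name) && any(fix$CHROM != reference_name)) {
    stop("VCF contains records on an unknown reference: ",
         unique(fix$CHROM[fix$CHROM != reference_name])[1])
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  pos <- rep(as.integer(fix$POS), n_alt)
  ref <- toupper(rep(fix$REF, n_alt))
  alt <- toupper(unlist(alts))
  ok <- nchar(ref) == 1L & ref %in% VALID_BASES &
    nchar(alt) == 1L & alt %in% VALID_BASES & ref != alt
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    message(sprintf("%s: skipped %d non-SNP allele(s)", basename(path),
                    n_skipped))
  }
  out <- snp_records(mutant_id = rep(mutant_id, sum(ok)), position = pos[ok],
                     ref_base = ref[ok], alt_base = alt[ok])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Load the packaged M. luteus screen fixtures
#'
#' The package ships the curated main-cluster SNP tables of the published
#' *Micrococcus luteus* trpE16 EMS screen: the M-mutants (com promoter
#' up-regulated on rich medium) and the R-mutants (repressed on minimal
#' medium). Each table row lists one genomic position with the mutants
#' carrying the substitution; loading expands it to one record per
#' (position, mutant). The tables' own cluster labels are kept as provenance
#' in the `"fixture_table"` attribute and are never consulted by the
#' clustering algorithm.
#'
#' @param which `"M"` or `"R"`.
#' @return A [mutant_set()] on the single M. luteus chromosome
#'   (2,501,097 bp).
#' @export
load_screen_fixture <- function(which = c("M", "R")) {
  which <- match.arg(which)
  fname <- if (which == "M") "m_mutant_snps.tsv" else "r_mutant_snps.tsv"
  path <- system.file("extdata", fname, package = "emscreen", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  tab$position <- as.integer(tab$position)
  muts <- strsplit(tab$mutants, ",", fixed = TRUE)
  n <- lengths(muts)
  rec <- snp_records(
    mutant_id = unlist(muts),
    position = rep(tab$position, n),
    ref_base = rep(tab$ref, n),
    alt_base = rep(tab$alt, n),
    locus_tag = rep(tab$locus_tag, n),
    note = rep(tab$product, n)
  )
  ms <- mutant_set(rec, reference_name = "Mluteus_trpE16",
                   genome_length = 2501097)
  attr(ms, "fixture_table") <- tab
  ms
}

#' Construct a gene model table
#'
#' @param locus_tag gene identifiers (unique).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param product free-text annotation.
#' @return A `data.frame` sorted by `start` with class `gene_models`.
#' @export
gene_models <- function(locus_tag, start, end, strand, product = "") {
  if (length(locus_tag) == 0L) product <- character(0)
  df <- data.frame(
    locus_tag = as.character(locus_tag),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    product = as.character(product),
    stringsAsFactors = FALSE
  )
  if (nrow(df) > 0L) {
    stopifnot(all(df$start >= 1L), all(df$start <= df$end),
              all(df$strand %in% c("+", "-")))
    if (anyDuplicated(df$locus_tag)) {
      stop("duplicated locus_tag(s): ",
           paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
    }
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from a GFF3 file
#'
#' `gene` and `CDS` features become gene models (1-based inclusive
#' coordinates preserved). When a locus has both a `gene` and a `CDS` line,
#' the `CDS` coordinates win (they carry the reading frame used for codon
#' translation).
#'
#' @param path path to the GFF3 file.
#' @return A [gene_models()] table.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- ape::read.gff(path)
  g <- g[g$type %in% c("gene", "CDS"), , drop = FALSE]
  if (nrow(g) == 0L) {
    return(gene_models(character(), integer(), integer(), character()))
  }
  attr_field <- function(attr, keys) {
    out <- rep(NA_character_, length(attr))
    for (k in keys) {
      m <- regmatches(attr, regexec(paste0("(?:^|;)", k, "=([^;]+)"), attr))
      hit <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                    character(1))
      out[is.na(out)] <- hit[is.na(out)]
      if (all(!is.na(out))) break
    }
    out
  }
  tag <- attr_field(as.character(g$attributes), c("locus_tag", "ID", "Name"))
  if (any(is.na(tag))) stop("GFF feature without locus_tag/ID attribute")
  prod <- attr_field(as.character(g$attributes), "product")
  prod[is.na(prod)] <- ""
  df <- data.frame(locus_tag = tag, start = g$start, end = g$end,
                   strand = as.character(g$strand), product = prod,
                   type = as.character(g$type), stringsAsFactors = FALSE)
  pick <- lapply(split(df, df$locus_tag), function(d) {
    cds <- d[d$type == "CDS", , drop = FALSE]
    d <- if (nrow(cds) > 0L) cds else d
    d <- d[!duplicated(d[c("start", "end", "strand")]), , drop = FALSE]
    if (nrow(d) > 1L) {
      stop("conflicting features share locus_tag: ", d$locus_tag[1])
    }
    d
  })
  df <- do.call(rbind, pick)
  gene_models(df$locus_tag, df$start, df$end, df$strand, df$product)
}

#' Construct / read a reference genome
#'
#' Single-replicon pipeline: a genome is one upper-case A/C/G/T sequence.
#' Multi-contig FASTA inputs are rejected rather than silently concatenated.
#'
#' @param id sequence identifier.
#' @param sequence nucleotide string.
#' @return An object of class `genome` (list with `id`, `sequence`,
#'   `length`).
#' @export
genome <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence contains characters outside A/C/G/T")
  }
  structure(list(id = as.character(id), sequence = sequence,
                 length = nchar(sequence)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome %s: %s bp\n", x$id, format(x$length, big.mark = ",")))
  invisible(x)
}

#' @rdname genome
#' @param path path to a FASTA file with exactly one sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) {
    stop("single-reference pipeline: FASTA must contain exactly one sequence, found ",
         length(seqs))
  }
  genome(names(seqs)[1], as.character(seqs[[1]]))
}

#' @rdname genome
#' @param x a `genome`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "genome"))
  dna <- Biostrings::DNAStringSet(x$sequence)
  names(dna) <- x$id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write gene models as GFF3
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @param seqid sequence identifier for column 1.
#' @export
write_gff <- function(genes, path, seqid = "chr") {
  lines <- c("##gff-version 3",
             sprintf("%s\temscreen\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s;product=%s",
                     seqid, genes$start, genes$end, genes$strand,
                     genes$locus_tag, genes$locus_tag, genes$product))
  writeLines(lines, path)
  invisible(path)
}
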