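#' Place a genomic position relative to gene models
#'
#' A position is genic when `start <= position <= end` for some gene
#' (boundaries inclusive). If several genes overlap the position, the first
#' by start coordinate is the primary assignment and a warning lists the
#' others. Otherwise the position is intergenic, flanked by the nearest gene
#' ending before it and the nearest gene starting after it (either may be
#' absent near the replicon ends).
#'
#' @param position 1-based genomic coordinate.
#' @param genes a [gene_models()] table.
#' @return A list: `placement` (`"genic"`/`"intergenic"`), `locus_tag` (genic
#'   only), `left_tag`/`right_tag` (intergenic only, `""` when absent), and a
#'   compact `label` (`"tag"` or `"intergenic(left,right)"`).
#' @export
locate_position <- function(position, genes) {
  stopifnot(length(position) == 1L, position >= 1)
  hit <- which(genes$start <= position & genes$end >= position)
  if (length(hit) > 0L) {
    if (length(hit) > 1L) {
      warning(sprintf("position %d overlaps %d genes; primary = %s",
                      position, length(hit), genes$locus_tag[hit[1]]))
    }
    tag <- genes$locus_tag[hit[1]]
    return(list(placement = "genic", locus_tag = tag,
                all_locus_tags = genes$locus_tag[hit], label = tag))
  }
  left <- which(genes$end < position)
  right <- which(genes$start > position)
  left_tag <- if (length(left) > 0L) {
    genes$locus_tag[left[which.max(genes$end[left])]]
  } else ""
  right_tag <- if (length(right) > 0L) {
    genes$locus_tag[right[which.min(genes$start[right])]]
  } else ""
  list(placement = "intergenic", left_tag = left_tag, right_tag = right_tag,
       label = sprintf("intergenic(%s,%s)", left_tag, right_tag))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# bacterial genetic code (translation table 11); codons identical to the
# standard code, alternative initiators handled at codon 1 only
translate_codon <- function(codon, first_codon = FALSE) {
  if (first_codon && codon %in% c("ATG", "GTG", "TTG")) return("M")
  as.character(Biostrings::GENETIC_CODE[codon])
}

#' Codon change and amino-acid effect of a SNP
#'
#' Computes the codon-level consequence of a single-nucleotide substitution
#' inside a protein-coding gene, strand-aware: for a `-`-strand gene the
#' coding sequence is read from `end` towards `start` and every base is the
#' complement of the reference strand. Translation uses the bacterial code
#' (table 11); the alternative initiators GTG and TTG are rendered as M at
#' codon 1.
#'
#' @param gnm a [genome()].
#' @param gene one row of a [gene_models()] table (length divisible by 3).
#' @param position 1-based position of the substitution (inside the gene).
#' @param ref_base,alt_base reference-strand alleles; `ref_base` must match
#'   the genome sequence at `position`.
#' @return An object of class `effect_call`: `position`, `locus_tag`,
#'   `strand`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `klass` (`synonymous`/`missense`/`nonsense`/`start_lost`) and, for
#'   missense calls, the compact `label` `"X<index>Y"`.
#' @export
codon_change <- function(gnm, gene, position, ref_base, alt_base) {
  stopifnot(inherits(gnm, "genome"))
  gene <- as.list(gene)
  len <- gene$end - gene$start + 1L
  if (len %% 3L != 0L) {
    stop("gene ", gene$locus_tag, " length not divisible by 3")
  }
  if (position < gene$start || position > gene$end) {
    stop(sprintf("position %d outside gene %s [%d, %d]",
                 position, gene$locus_tag, gene$start, gene$end))
  }
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  genome_base <- substr(gnm$sequence, position, position)
  if (genome_base != ref_base) {
    stop(sprintf("reference mismatch at position %d: genome has %s, record says %s",
                 position, genome_base, ref_base))
  }
  if (gene$strand == "+") {
    offset <- position - gene$start
    coding_ref <- ref_base
    coding_alt <- alt_base
  } else {
    offset <- gene$end - position
    coding_ref <- unname(COMPLEMENT[ref_base])
    coding_alt <- unname(COMPLEMENT[alt_base])
  }
  codon_index <- offset %/% 3L + 1L
  within <- offset %% 3L  # 0-based offset inside the codon
  codon_start_off <- offset - within
  codon_pos <- if (gene$strand == "+") {
    gene$start + codon_start_off + 0:2
  } else {
    gene$end - codon_start_off - 0:2
  }
  bases <- strsplit(substr(gnm$sequence, min(codon_pos), max(codon_pos)),
                    "")[[1]]
  if (gene$strand == "-") bases <- unname(COMPLEMENT[rev(bases)])
  ref_codon <- paste(bases, collapse = "")
  alt_bases <- bases
  alt_bases[within + 1L] <- coding_alt
  alt_codon <- paste(alt_bases, collapse = "")
  first <- codon_index == 1L
  ref_aa <- translate_codon(ref_codon, first)
  alt_aa <- translate_codon(alt_codon, first)
  klass <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "nonsense"
  } else if (first && ref_aa == "M" && !(alt_codon %in% c("ATG", "GTG", "TTG"))) {
    "start_lost"
  } else {
    "missense"
  }
  label <- if (klass == "missense") {
    sprintf("%s%d%s", ref_aa, codon_index, alt_aa)
  } else NA_character_
  structure(list(position = position, locus_tag = gene$locus_tag,
                 strand = gene$strand, codon_index = codon_index,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa, klass = klass,
                 label = label),
            class = "effect_call")
}

#' @export
print.effect_call <- function(x, ...) {
  cat(sprintf("%s%d%s %s (%s): codon %d %s->%s, %s%s\n",
              x$ref_codon, x$position, x$alt_codon, x$locus_tag, x$strand,
              x$codon_index, x$ref_aa, x$alt_aa, x$klass,
              if (!is.na(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Annotate every SNP of a mutant set
#'
#' Places each record against the gene models and, where the record falls
#' inside a gene whose length is divisible by 3, computes the codon change.
#'
#' @param x a [mutant_set()].
#' @param gnm a [genome()] (needed for codon changes; may be `NULL` for
#'   placement-only annotation).
#' @param genes a [gene_models()] table.
#' @return A `data.frame`, one row per record, with placement and effect
#'   columns (`placement`, `label`, `klass`, `aa_change`).
#' @export
annotate_effects <- function(x, genes, gnm = NULL) {
  stopifnot(inherits(x, "mutant_set"))
  rec <- x$records
  out <- rec
  out$placement <- NA_character_
  out$effect_label <- NA_character_
  out$klass <- NA_character_
  out$aa_change <- NA_character_
  for (i in seq_len(nrow(rec))) {
    loc <- locate_position(rec$position[i], genes)
    out$placement[i] <- loc$label
    if (loc$placement == "intergenic") {
      out$klass[i] <- "intergenic"
      next
    }
    gene <- genes[genes$locus_tag == loc$locus_tag, , drop = FALSE][1, ]
    len <- gene$end - gene$start + 1L
    if (!is.null(gnm) && len %% 3L == 0L) {
      eff <- codon_change(gnm, gene, rec$position[i], rec$ref_base[i],
                          rec$alt_base[i])
      out$klass[i] <- eff$klass
      out$aa_change[i] <- paste0(eff$ref_aa, eff$codon_index, eff$alt_aa)
      out$effect_label[i] <- eff$label
    } else {
      out$klass[i] <- "genic"
    }
  }
  out
}

#' Parse and compare amino-acid substitution labels
#'
#' Substitution labels follow the compact field convention `"X<index>Y"`
#' (e.g. `"G27D"`): reference residue, 1-based residue index, alternate
#' residue, with residues drawn from the 20-letter amino-acid alphabet
#' plus `*`.
#'
#' @param text a label such as `"V31I"`.
#' @return `parse_label`: list with `ref_aa`, `residue_index`, `alt_aa`.
#' @export
parse_label <- function(text) {
  m <- regexec("^([A-Z*])([0-9]+)([A-Z*])$", text)[[1]]
  if (m[1] == -1L) stop("malformed substitution label: ", text)
  parts <- regmatches(text, regexec("^([A-Z*])([0-9]+)([A-Z*])$", text))[[1]]
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  if (!(parts[2] %in% aa) || !(parts[4] %in% aa)) {
    stop("invalid amino acid in label: ", text)
  }
  idx <- as.integer(parts[3])
  if (idx < 1L) stop("residue index must be >= 1: ", text)
  list(ref_aa = parts[2], residue_index = idx, alt_aa = parts[4])
}

#' @rdname parse_label
#' @param a,b labels (or parsed labels) to compare.
#' @return `residue_distance`: the absolute difference of the residue
#'   indices.
#' @export
residue_distance <- function(a, b) {
  if (is.character(a)) a <- parse_label(a)
  if (is.character(b)) b <- parse_label(b)
  abs(a$residue_index - b$residue_index)
}
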