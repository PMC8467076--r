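# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# A toy mutant set: positions/mutants given as parallel vectors.
toy_mutant_set <- function(position, mutant_id, ref = "G", alt = "A",
                           genome_length = 1e5, mutant_ids = NULL) {
  rec <- snp_records(mutant_id = mutant_id, position = position,
                     ref_base = ref, alt_base = alt)
  mutant_set(rec, reference_name = "toy", genome_length = genome_length,
             mutant_ids = mutant_ids)
}

# Write a Snippy-style TSV; rows is a data.frame with POS/TYPE/REF/ALT.
write_snippy_fixture <- function(rows, path = tempfile(fileext = ".tsv"),
                                 chrom = "chr") {
  df <- data.frame(CHROM = rep(chrom, nrow(rows)), POS = rows$POS,
                   TYPE = rows$TYPE, REF = rows$REF, ALT = rows$ALT)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal VCF 4.2 writer.
write_vcf_fixture <- function(pos, ref, alt, path = tempfile(fileext = ".vcf"),
                              chrom = "chr") {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s>", chrom),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos, ref, alt))
  writeLines(lines, path)
  path
}

# Build a genome containing one protein-coding gene from explicit codons.
# For strand "-" the reference is the reverse complement of the coding
# sequence; flank pads both sides so the gene does not start at position 1.
gene_construct <- function(codons, strand = "+", flank = 30, seed = 42) {
  set.seed(seed)
  coding <- paste(codons, collapse = "")
  ref_gene <- if (strand == "+") coding else revcomp(coding)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  left <- pad(flank)
  right <- pad(flank)
  seqn <- paste0(left, ref_gene, right)
  list(
    genome = genome("construct", seqn),
    gene = list(locus_tag = "g1", start = flank + 1,
                end = flank + nchar(coding), strand = strand),
    coding = coding
  )
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Independent effect oracle: extract the full CDS from the genome, apply the
# substitution in transcript coordinates, translate the whole protein with
# Biostrings, and diff the two proteins.
effect_oracle <- function(gnm, gene, position, alt_base) {
  cds <- substr(gnm$sequence, gene$start, gene$end)
  offset_genomic <- position - gene$start  # 0-based on reference strand
  if (gene$strand == "-") {
    cds <- revcomp(cds)
    offset <- (gene$end - gene$start) - offset_genomic
    alt <- chartr("ACGT", "TGCA", alt_base)
  } else {
    offset <- offset_genomic
    alt <- alt_base
  }
  mutated <- cds
  substr(mutated, offset + 1, offset + 1) <- alt
  tr <- function(s) {
    p <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    # table-11 alternative initiators read as M
    if (substr(s, 1, 3) %in% c("ATG", "GTG", "TTG")) {
      p <- paste0("M", substr(p, 2, nchar(p)))
    }
    p
  }
  p_ref <- tr(cds)
  p_alt <- tr(mutated)
  diff <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  list(
    codon_index = offset %/% 3 + 1,
    ref_aa = substr(p_ref, offset %/% 3 + 1, offset %/% 3 + 1),
    alt_aa = substr(p_alt, offset %/% 3 + 1, offset %/% 3 + 1),
    n_changed = length(diff)
  )
}

# Brute-force pairwise window score oracle (independent double loop).
brute_window_score <- function(positions, W) {
  k <- length(positions)
  if (k <= 1) return(0)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- s + (1 - abs(positions[i] - positions[j]) / W)
    }
  }
  s
}
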