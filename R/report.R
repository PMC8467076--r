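#' Track and table exports
#'
#' Machine-readable equivalents of the screen's genome-track figure:
#' clusters as BED (0-based half-open) and TSV (1-based, full fields), the
#' window score as bedGraph, per-position mutant counts as TSV, and a JSON
#' ranking summary. Coordinates are 1-based inclusive everywhere inside the
#' package; only the BED/bedGraph writers convert to 0-based half-open at
#' the boundary.
#'
#' @name exports
#' @keywords internal
NULL

#' @rdname exports
#' @param clusters a [call_clusters()] result.
#' @param path output path.
#' @param chrom chromosome name for column 1.
#' @export
write_clusters_bed <- function(clusters, path, chrom = "chr") {
  lines <- sprintf("%s\t%d\t%d\tcluster_%d\t%.4f", chrom,
                   clusters$start - 1L, clusters$end, clusters$cluster_id,
                   clusters$peak_score)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname exports
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- as.data.frame(clusters)
  df$positions <- vapply(df$positions, paste, character(1), collapse = ",")
  df$mutant_ids <- vapply(df$mutant_ids, paste, character(1), collapse = ",")
  if (!is.null(df$loci)) {
    df$loci <- vapply(df$loci, paste, character(1), collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @param track a [score_track()].
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  lines <- c("track type=bedGraph",
             sprintf("%s\t%d\t%d\t%.6f", chrom, track$window_start - 1L,
                     track$window_end, track$score))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname exports
#' @param counts a [per_position_counts()] table.
#' @export
write_position_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-mutant variant table in the Snippy-style dialect
#' @param x a [mutant_set()].
#' @param dir output directory (one TSV per mutant).
#' @export
write_snippy_tables <- function(x, dir) {
  stopifnot(inherits(x, "mutant_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (id in x$mutant_ids) {
    rec <- x$records[x$records$mutant_id == id, , drop = FALSE]
    df <- data.frame(CHROM = rep(x$reference_name, nrow(rec)),
                     POS = rec$position,
                     TYPE = rep("snp", nrow(rec)),
                     REF = rec$ref_base, ALT = rec$alt_base,
                     LOCUS_TAG = rec$locus_tag, PRODUCT = rec$note)
    p <- file.path(dir, paste0(id, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_manifest <- function(outdir, inputs, parameters, files, seed = NULL) {
  root <- paste0(normalizePath(outdir), .Platform$file.sep)
  rel <- sub(root, "", normalizePath(files), fixed = TRUE)
  manifest <- list(
    inputs = inputs,
    parameters = parameters,
    seed = seed,
    files = rel,
    package_version = as.character(utils::packageVersion("emscreen")),
    r_version = R.version.string
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the hotspot stage end to end
#'
#' Scores the genome, calls and (optionally) annotates clusters, and writes
#' the full track bundle: cluster TSV + BED, score bedGraph, per-position
#' counts TSV, JSON ranking summary, and a JSON run manifest.
#'
#' @param x a [mutant_set()].
#' @param outdir output directory (created).
#' @param genes optional [gene_models()] for cluster annotation.
#' @inheritParams call_clusters
#' @return The (annotated) cluster table, invisibly; files on disk.
#' @export
run_hotspot_analysis <- function(x, outdir, W = 5000, s = 500, max_gap = W,
                                 mode = c("occurrence", "unique"),
                                 genes = NULL) {
  mode <- match.arg(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  track <- score_track(x, W = W, s = s, mode = mode)
  clusters <- call_clusters(x, max_gap = max_gap, W = W, s = s, mode = mode,
                            track = track)
  if (!is.null(genes)) clusters <- annotate_clusters(clusters, genes)
  counts <- per_position_counts(x)
  chrom <- x$reference_name
  files <- c(
    write_clusters_tsv(clusters, file.path(outdir, "clusters.tsv")),
    write_clusters_bed(clusters, file.path(outdir, "clusters.bed"), chrom),
    write_bedgraph(track, file.path(outdir, "score.bedgraph"), chrom),
    write_position_counts_tsv(counts, file.path(outdir, "position_counts.tsv"))
  )
  summary_json <- file.path(outdir, "cluster_summary.json")
  jsonlite::write_json(
    lapply(seq_len(nrow(clusters)), function(i) {
      list(cluster_id = clusters$cluster_id[i], start = clusters$start[i],
           end = clusters$end[i], span_bp = clusters$span_bp[i],
           n_positions = clusters$n_positions[i],
           n_mutants = clusters$n_mutants[i],
           peak_score = clusters$peak_score[i])
    }),
    summary_json, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, summary_json)
  write_manifest(outdir,
                 inputs = list(reference = chrom,
                               n_records = nrow(x$records)),
                 parameters = list(W = W, s = s, max_gap = max_gap,
                                   mode = mode),
                 files = files)
  invisible(clusters)
}

#' Run the spectrum stage and write its report
#' @param x a [mutant_set()].
#' @param outdir output directory.
#' @return The `spectrum_summary`, invisibly.
#' @export
run_spectrum_analysis <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sm <- summarize_spectrum(x)
  cls <- classify_substitution(x$records$ref_base, x$records$alt_base)
  classified <- cbind(x$records, cls[c("class", "ems_signature")])
  files <- c(
    write_spectrum_tsv(sm, file.path(outdir, "spectrum_summary.tsv")),
    {
      p <- file.path(outdir, "classified_records.tsv")
      utils::write.table(classified, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    }
  )
  write_manifest(outdir,
                 inputs = list(reference = x$reference_name,
                               n_records = nrow(x$records)),
                 parameters = list(), files = files)
  invisible(sm)
}

#' Generate a complete ready-to-analyze simulated screen directory
#'
#' Writes reference FASTA, gene-model GFF3, per-mutant Snippy-style TSVs,
#' the merged mutant-set table, and a run manifest.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @return List with the simulated `genome`, `genes` and `mutant_set`,
#'   invisibly.
#' @export
run_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  ms <- simulate_ems_mutants(sim$genome, config)
  files <- c(
    write_fasta(sim$genome, file.path(outdir, "reference.fasta")),
    write_gff(sim$genes, file.path(outdir, "genes.gff3"),
              seqid = sim$genome$id),
    write_mutant_set(ms, file.path(outdir, "mutant_set.tsv")),
    write_snippy_tables(ms, file.path(outdir, "snippy"))
  )
  write_manifest(outdir,
                 inputs = list(),
                 parameters = unclass(config)[
                   setdiff(names(unclass(config)), "hotspots")],
                 files = files, seed = config$seed)
  invisible(list(genome = sim$genome, genes = sim$genes, mutant_set = ms))
}
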