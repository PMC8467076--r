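#' Simulation configuration for a synthetic EMS screen
#'
#' Defaults emulate the study conditions of an EMS screen in a high-GC
#' bacterium: a ~2.5 Mb chromosome at GC fraction 0.73, 22 sequenced mutant
#' genomes, a background of about one stable transition per 3e5 bp per
#' mutant (Binomial counts, mean ~8.3 SNPs/genome), and a mutation spectrum
#' dominated (95%) by the G:C->A:T EMS signature. Hotspots are planted as
#' intervals each mutant hits independently with a given probability.
#'
#' @param genome_length chromosome length L in bp.
#' @param gc_fraction genomic GC content in (0, 1).
#' @param n_mutants number of mutant genomes.
#' @param mutation_rate expected mutations per bp per mutant.
#' @param p_ems_signature fraction of background mutations that are
#'   G:C->A:T.
#' @param hotspots `data.frame` with columns `start`, `end`,
#'   `hit_probability` (per-mutant), or `NULL`.
#' @param n_genes,mean_gene_length gene-model generation for annotation.
#' @param seed integer seed; every generator in the package is
#'   deterministic under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2.5e6, gc_fraction = 0.73,
                       n_mutants = 22, mutation_rate = 1 / 3e5,
                       p_ems_signature = 0.95, hotspots = NULL,
                       n_genes = 0, mean_gene_length = 900, seed = 1L) {
  stopifnot(genome_length >= 1, gc_fraction > 0, gc_fraction < 1,
            n_mutants >= 1, mutation_rate >= 0,
            p_ems_signature >= 0, p_ems_signature <= 1)
  if (!is.null(hotspots)) {
    stopifnot(is.data.frame(hotspots),
              all(c("start", "end", "hit_probability") %in% names(hotspots)),
              all(hotspots$start >= 1), all(hotspots$end <= genome_length),
              all(hotspots$start <= hotspots$end),
              all(hotspots$hit_probability >= 0),
              all(hotspots$hit_probability <= 1))
  }
  structure(list(genome_length = genome_length, gc_fraction = gc_fraction,
                 n_mutants = n_mutants, mutation_rate = mutation_rate,
                 p_ems_signature = p_ems_signature, hotspots = hotspots,
                 n_genes = n_genes, mean_gene_length = mean_gene_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a reference genome and gene models
#'
#' Bases are i.i.d. at the configured GC fraction. Genes are non-overlapping
#' intervals with length divisible by 3 (roughly `mean_gene_length`, +/-30%)
#' on random strands.
#'
#' @param config a [sim_config()].
#' @return List with `genome` (a [genome()]) and `genes` (a
#'   [gene_models()] table, empty if `n_genes = 0`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_fraction
  bases <- sample(c("G", "C", "A", "T"), L, replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  gnm <- genome("sim_chr", paste(bases, collapse = ""))
  genes <- gene_models(character(), integer(), integer(), character())
  if (config$n_genes > 0) {
    lens <- 3 * pmax(round(stats::runif(config$n_genes,
                                        0.7 * config$mean_gene_length,
                                        1.3 * config$mean_gene_length) / 3), 30)
    if (sum(lens) > L) stop("requested genes exceed genome capacity")
    # place genes left to right with random gaps from the slack
    slack <- L - sum(lens)
    gaps <- stats::rmultinom(1, slack, rep(1, config$n_genes + 1))[, 1]
    starts <- cumsum(c(1 + gaps[1], utils::head(lens, -1) +
                         gaps[seq_len(config$n_genes - 1) + 1]))
    genes <- gene_models(
      locus_tag = sprintf("sim_%04d", seq_len(config$n_genes)),
      start = starts, end = starts + lens - 1,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
      product = "simulated CDS"
    )
  }
  list(genome = gnm, genes = genes)
}

#' Simulate per-mutant EMS SNP calls
#'
#' Per mutant, the background mutation count is Binomial(L, rate). A
#' fraction `p_ems_signature` of background mutations are EMS-signature
#' changes placed at G/C sites (G->A on a G, C->T on a C, reference
#' strand); the remainder are other substitutions at uniformly random sites.
#' Each configured hotspot is additionally hit by each mutant independently
#' with its `hit_probability`, the hit landing on a G/C site uniform within
#' the interval (EMS-signature change). All reference bases match the
#' genome; duplicate (mutant, position) draws collapse.
#'
#' @param gnm a [genome()].
#' @param config a [sim_config()].
#' @return A [mutant_set()] with mutants `sim_M1` ... `sim_M<n>`.
#' @export
simulate_ems_mutants <- function(gnm, config) {
  stopifnot(inherits(gnm, "genome"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- gnm$length
  raw <- charToRaw(gnm$sequence)
  gc_sites <- which(raw == charToRaw("G") | raw == charToRaw("C"))
  if (length(gc_sites) == 0L && config$mutation_rate > 0 &&
      config$p_ems_signature > 0) {
    stop("no G/C sites available for EMS-signature mutations")
  }
  base_at <- function(pos) rawToChar(raw[pos], multiple = TRUE)
  ems_alt <- function(ref) ifelse(ref == "G", "A", "T")
  other_alt <- function(ref) {
    # any substitution except the EMS pair at that base
    vapply(ref, function(b) {
      choices <- setdiff(VALID_BASES, b)
      if (b == "G") choices <- setdiff(choices, "A")
      if (b == "C") choices <- setdiff(choices, "T")
      sample(choices, 1)
    }, character(1))
  }

  ids <- sprintf("sim_M%d", seq_len(config$n_mutants))
  recs <- vector("list", config$n_mutants)
  for (i in seq_len(config$n_mutants)) {
    n <- stats::rbinom(1, L, config$mutation_rate)
    n_sig <- stats::rbinom(1, n, config$p_ems_signature)
    pos_sig <- if (n_sig > 0) {
      sample(gc_sites, min(n_sig, length(gc_sites)))
    } else integer()
    pos_oth <- if (n - n_sig > 0) sample.int(L, n - n_sig) else integer()
    pos <- c(pos_sig, pos_oth)
    ref <- base_at(pos)
    alt <- c(ems_alt(base_at(pos_sig)),
             if (length(pos_oth) > 0) other_alt(base_at(pos_oth)) else character())
    if (!is.null(config$hotspots)) {
      for (h in seq_len(nrow(config$hotspots))) {
        if (stats::runif(1) < config$hotspots$hit_probability[h]) {
          in_h <- gc_sites[gc_sites >= config$hotspots$start[h] &
                             gc_sites <= config$hotspots$end[h]]
          if (length(in_h) > 0L) {
            hp <- if (length(in_h) == 1L) in_h else sample(in_h, 1)
            pos <- c(pos, hp)
            ref <- c(ref, base_at(hp))
            alt <- c(alt, ems_alt(base_at(hp)))
          }
        }
      }
    }
    if (length(pos) > 0L) {
      recs[[i]] <- data.frame(mutant_id = ids[i], position = as.integer(pos),
                              ref_base = ref, alt_base = alt,
                              locus_tag = "", note = "",
                              stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, recs)
  if (is.null(rec)) {
    rec <- snp_records(character(), integer(), character(), character())
  }
  mutant_set(rec, reference_name = gnm$id, genome_length = L,
             mutant_ids = ids)
}

#' Simulate replicate reporter kinetic curves
#'
#' Signal = 4PL(truth) + Gaussian(0, `noise_sd`) on a plate-reader grid
#' (default: every 10 min over 10 h, 61 points).
#'
#' @param truth a [four_pl()] of true parameters.
#' @param noise_sd additive Gaussian noise SD (RFU), >= 0.
#' @param times measurement grid (min).
#' @param n_replicates replicate curves to draw.
#' @param seed integer seed.
#' @param strain strain label stamped on the output.
#' @return Long-format `data.frame`: `strain`, `replicate`, `time_min`,
#'   `rfu`.
#' @export
simulate_kinetics <- function(truth, noise_sd, times = seq(0, 600, by = 10),
                              n_replicates = 3, seed = 1L,
                              strain = "sim_strain") {
  stopifnot(inherits(truth, "four_pl"), noise_sd >= 0)
  set.seed(seed)
  mu <- predict_four_pl(truth, times)
  do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(strain = strain, replicate = r, time_min = times,
               rfu = mu + stats::rnorm(length(times), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate transformation-assay plate counts
#'
#' Standard Poisson plating model: transformant colonies ~
#' Poisson(frequency x viable CFU/mL x plated volume), revertant colonies in
#' the no-DNA control ~ Poisson(reversion rate x viable x volume); the
#' viable-count plate receives a diluted aliquot.
#'
#' @param true_frequency transformants per viable CFU.
#' @param viable_cfu_per_ml viable cell density.
#' @param reversion_rate spontaneous revertants per viable CFU.
#' @param n_replicates biological replicates.
#' @param volume_ml volume plated on selective plates (mL).
#' @param viable_dilution dilution factor of the viable-count plating.
#' @param seed integer seed.
#' @return List of [plate_counts()], one per replicate.
#' @export
simulate_plate_counts <- function(true_frequency, viable_cfu_per_ml,
                                  reversion_rate = 0, n_replicates = 3,
                                  volume_ml = 0.1, viable_dilution = 1e6,
                                  seed = 1L) {
  stopifnot(true_frequency >= 0, viable_cfu_per_ml > 0, reversion_rate >= 0)
  set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    plate_counts(
      transformant_colonies = stats::rpois(
        1, true_frequency * viable_cfu_per_ml * volume_ml),
      transformant_volume_ml = volume_ml,
      viable_colonies = max(1L, stats::rpois(
        1, viable_cfu_per_ml * volume_ml / viable_dilution)),
      viable_volume_ml = volume_ml,
      viable_dilution = viable_dilution,
      no_dna_revertant_colonies = stats::rpois(
        1, reversion_rate * viable_cfu_per_ml * volume_ml)
    )
  })
}
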