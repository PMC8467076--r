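#' Proximity-weighted window score
#'
#' The clustering score of a window is a pairwise proximity statistic over
#' the SNP occurrences it contains: with occurrences at sorted positions
#' \eqn{q_1 \le \dots \le q_k} and window length \eqn{W},
#' \deqn{score = \sum_{i<j} \left(1 - |q_i - q_j| / W\right).}
#' It grows with the number of occurrences and, at fixed count, grows as the
#' occurrences pack more tightly; a window with at most one occurrence
#' scores 0. An exponential-decay kernel \eqn{\sum_{i<j} e^{-|q_i-q_j|/\lambda}}
#' is available as an alternative.
#'
#' @param positions occurrence positions (one entry per (mutant, position)
#'   occurrence; a position recurrent in several mutants appears once per
#'   mutant). All must lie within one window of length `W`.
#' @param W window length (bp), > 0.
#' @param kernel `"linear"` (default, `1 - d/W`) or `"exponential"`
#'   (`exp(-d/lambda)`).
#' @param lambda decay length for the exponential kernel (default `W/5`).
#' @return Non-negative numeric score.
#' @export
window_score <- function(positions, W, kernel = c("linear", "exponential"),
                         lambda = W / 5) {
  kernel <- match.arg(kernel)
  stopifnot(W > 0)
  k <- length(positions)
  if (k <= 1L) return(0)
  positions <- sort(as.numeric(positions))
  if (positions[k] - positions[1] > W) {
    stop("occurrence positions span more than one window length")
  }
  if (kernel == "linear") {
    # sum of pairwise distances of a sorted vector, O(k)
    d_sum <- sum((2 * seq_len(k) - k - 1) * positions)
    choose(k, 2) - d_sum / W
  } else {
    sum(exp(-stats::dist(positions) / lambda))
  }
}

# Occurrence vectors for a mutant set: one (position, mutant) pair per
# occurrence, or unique positions only.
occurrences <- function(x, mode = c("occurrence", "unique")) {
  mode <- match.arg(mode)
  rec <- x$records
  if (mode == "unique") {
    pos <- sort(unique(rec$position))
    list(position = pos, mutant = rep(NA_character_, length(pos)))
  } else {
    ord <- order(rec$position)
    list(position = rec$position[ord], mutant = rec$mutant_id[ord])
  }
}

#' Sliding-window clustering score along the genome
#'
#' Slides a window of length `W` along the reference in steps of `s` and
#' computes the proximity-weighted [window_score()] of each window, together
#' with its occurrence, position and mutant counts. Window starts are
#' 1, 1+s, 2s+1, ...; the terminal window may be shorter than `W` but is
#' scored with the same `W` in the denominator so scores stay comparable.
#'
#' @param x a [mutant_set()].
#' @param W window length in bp (default 5000).
#' @param s step between window starts in bp (default 500).
#' @param mode `"occurrence"` (default; a position mutated in m mutants
#'   contributes m occurrences) or `"unique"` (distinct positions only).
#' @inheritParams window_score
#' @return A `data.frame` of class `score_track` with columns
#'   `window_start`, `window_end`, `score`, `n_occurrences`, `n_positions`,
#'   `n_mutants`; attributes `W`, `s`, `genome_length`, `mode`.
#' @export
score_track <- function(x, W = 5000, s = 500,
                        mode = c("occurrence", "unique"),
                        kernel = c("linear", "exponential"), lambda = W / 5) {
  stopifnot(inherits(x, "mutant_set"))
  if (W <= 0 || s <= 0) stop("W and s must be positive")
  if (x$genome_length < W) stop("genome_length must be >= W")
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  L <- x$genome_length
  n_win <- ceiling((L - W) / s) + 1
  starts <- 1 + s * (seq_len(n_win) - 1)
  ends <- pmin(starts + W - 1, L)

  occ <- occurrences(x, mode)
  p <- occ$position
  m <- occ$mutant
  csum <- c(0, cumsum(p))

  score <- numeric(n_win)
  n_occ <- integer(n_win)
  n_pos <- integer(n_win)
  n_mut <- integer(n_win)
  lo <- findInterval(starts - 1, p) + 1L
  hi <- findInterval(ends, p)
  for (i in seq_len(n_win)) {
    if (hi[i] < lo[i]) next
    idx <- lo[i]:hi[i]
    k <- length(idx)
    n_occ[i] <- k
    n_pos[i] <- length(unique(p[idx]))
    n_mut[i] <- if (mode == "unique") NA_integer_ else length(unique(m[idx]))
    if (k <= 1L) next
    q <- p[idx]
    if (kernel == "linear") {
      d_sum <- sum((2 * seq_len(k) - k - 1) * q)
      score[i] <- choose(k, 2) - d_sum / W
    } else {
      score[i] <- sum(exp(-stats::dist(q) / lambda))
    }
  }
  out <- data.frame(window_start = starts, window_end = ends, score = score,
                    n_occurrences = n_occ, n_positions = n_pos,
                    n_mutants = n_mut)
  attr(out, "W") <- W
  attr(out, "s") <- s
  attr(out, "genome_length") <- L
  attr(out, "mode") <- mode
  class(out) <- c("score_track", "data.frame")
  out
}

#' Per-position mutant counts
#'
#' For every distinct mutated position, the number of distinct mutants
#' carrying a substitution at exactly that position (the recurrence track of
#' a screen).
#'
#' @param x a [mutant_set()].
#' @return A `data.frame` with columns `position`, `n_mutants`, sorted by
#'   position.
#' @export
per_position_counts <- function(x) {
  stopifnot(inherits(x, "mutant_set"))
  rec <- x$records
  if (nrow(rec) == 0L) {
    return(data.frame(position = integer(), n_mutants = integer()))
  }
  key <- paste(rec$position, rec$mutant_id)
  rec <- rec[!duplicated(key), , drop = FALSE]
  tab <- table(rec$position)
  data.frame(position = as.integer(names(tab)),
             n_mutants = as.integer(tab), row.names = NULL)
}

#' Call mutation hotspot clusters
#'
#' Groups the distinct mutated positions by single linkage: two positions
#' belong to the same cluster when their gap is at most `max_gap` (default:
#' the window length). Every position belongs to exactly one cluster; the
#' clusters partition the positions and are pairwise separated by gaps
#' larger than `max_gap`. Clusters are ranked by the peak window score
#' overlapping them (descending), ties broken by occurrence count then by
#' leftmost start. Cluster calling is deliberately decoupled from any score
#' threshold: a lone recurrent position is still a (low-ranked) cluster.
#'
#' @param x a [mutant_set()].
#' @param max_gap maximal intra-cluster gap between neighbouring member
#'   positions (bp); defaults to `W`.
#' @param track optional precomputed [score_track()]; computed on the fly
#'   otherwise.
#' @inheritParams score_track
#' @return A `data.frame` of class `cluster_set`, one row per cluster,
#'   ranked; columns `cluster_id`, `start`, `end`, `span_bp`, `n_positions`,
#'   `n_occurrences`, `n_mutants`, `peak_score`, plus list-columns
#'   `positions` and `mutant_ids`.
#' @export
call_clusters <- function(x, max_gap = W, W = 5000, s = 500,
                          mode = c("occurrence", "unique"), track = NULL) {
  stopifnot(inherits(x, "mutant_set"))
  mode <- match.arg(mode)
  if (is.null(track)) track <- score_track(x, W = W, s = s, mode = mode)
  rec <- x$records
  pos <- sort(unique(rec$position))
  if (length(pos) == 0L) {
    out <- data.frame(cluster_id = integer(), start = integer(),
                      end = integer(), span_bp = integer(),
                      n_positions = integer(), n_occurrences = integer(),
                      n_mutants = integer(), peak_score = numeric())
    out$positions <- list()
    out$mutant_ids <- list()
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  grp <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
  pieces <- split(pos, grp)
  rows <- lapply(pieces, function(pp) {
    members <- rec[rec$position %in% pp, , drop = FALSE]
    mut <- unique(members$mutant_id)
    start <- min(pp)
    end <- max(pp)
    overlap <- track$window_end >= start & track$window_start <= end
    peak <- if (any(overlap)) max(track$score[overlap]) else 0
    df <- data.frame(start = start, end = end, span_bp = end - start,
                     n_positions = length(pp), n_occurrences = nrow(members),
                     n_mutants = length(mut), peak_score = peak)
    df$positions <- list(pp)
    df$mutant_ids <- list(mut)
    df
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$peak_score, -out$n_occurrences, out$start)
  out <- out[ord, , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "max_gap") <- max_gap
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("%d hotspot cluster(s), ranked by peak score\n", nrow(x)))
  show <- as.data.frame(x)[, c("cluster_id", "start", "end", "span_bp",
                               "n_positions", "n_occurrences", "n_mutants",
                               "peak_score")]
  print(utils::head(show, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Annotate cluster member positions against gene models
#'
#' Labels every member position of every cluster with the enclosing gene's
#' locus tag, or `intergenic(left,right)` with the flanking tags when it
#' falls inside no gene. Adds list-column `loci` plus counts `n_genic`,
#' `n_intergenic` per cluster.
#'
#' @param clusters a [call_clusters()] result.
#' @param genes a [gene_models()] table on the same reference.
#' @return The cluster table with annotation columns filled.
#' @export
annotate_clusters <- function(clusters, genes) {
  stopifnot(inherits(clusters, "cluster_set"))
  loci <- lapply(clusters$positions, function(pp) {
    vapply(pp, function(p) locate_position(p, genes)$label, character(1))
  })
  clusters$loci <- loci
  clusters$n_intergenic <- vapply(loci, function(l) {
    sum(startsWith(l, "intergenic("))
  }, integer(1))
  clusters$n_genic <- clusters$n_positions - clusters$n_intergenic
  clusters
}
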