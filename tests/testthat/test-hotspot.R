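test_that("window score follows the pairwise proximity formula", {
  # k co-located occurrences: every pair at distance 0
  expect_equal(window_score(rep(1000, 5), 5000), choose(5, 2))
  # single pair at distance 500 in a 5 kb window
  expect_equal(window_score(c(100, 600), 5000), 0.9)
  # same count, tighter packing scores higher
  loose <- window_score(c(0, 1000, 2000) + 1, 5000)
  tight <- window_score(c(0, 100, 200) + 1, 5000)
  expect_equal(loose, 2.2)
  expect_equal(tight, 2.92)
  expect_gt(tight, loose)
  # degenerate windows
  expect_equal(window_score(integer(), 5000), 0)
  expect_equal(window_score(123, 5000), 0)
  expect_error(window_score(c(1, 6000), 5000), "span")
})

test_that("window score equals the brute-force pairwise oracle", {
  set.seed(11)
  for (i in 1:60) {
    W <- sample(c(1000, 5000, 20000), 1)
    k <- sample(2:200, 1)
    q <- sort(sample.int(W, k, replace = TRUE))
    expect_equal(window_score(q, W), brute_window_score(q, W),
                 tolerance = 1e-12)
  }
})

test_that("window score is monotone in occurrences and proximity", {
  set.seed(12)
  W <- 5000
  for (i in 1:25) {
    q <- sort(sample.int(W, sample(2:30, 1), replace = TRUE))
    base <- window_score(q, W)
    # adding any occurrence strictly increases the score
    extra <- sample.int(W, 1)
    expect_gt(window_score(c(q, extra), W), base)
    # growing one pairwise distance (moving the max outward) decreases it
    if (max(q) < W - 10 && max(q) > min(q)) {
      stretched <- c(q[-length(q)], max(q) + 10)
      expect_lt(window_score(stretched, W), base)
    }
  }
})

test_that("score track geometry and degenerate inputs behave", {
  empty <- mutant_set(NULL, "toy", 20000)
  tr <- score_track(empty, W = 5000, s = 500)
  expect_true(all(tr$score == 0))
  expect_true(all(diff(tr$window_start) == 500))
  widths <- tr$window_end - tr$window_start + 1
  expect_true(all(widths[-length(widths)] == 5000))
  expect_equal(max(tr$window_end), 20000)

  lone <- toy_mutant_set(7777L, "m1", genome_length = 20000)
  expect_true(all(score_track(lone, 5000, 500)$score == 0))
  # a lone SNP never scores, but is still counted
  tr1 <- score_track(lone, 5000, 500)
  expect_true(any(tr1$n_occurrences == 1))

  expect_error(score_track(empty, W = 0), "positive")
  expect_error(score_track(empty, s = -5), "positive")
  expect_error(score_track(toy_mutant_set(10L, "m", genome_length = 100),
                           W = 5000), ">= W")
})

test_that("track scores are invariant under translation of all positions", {
  set.seed(13)
  # keep positions well inside so every covering window exists before and
  # after the shift (no truncation at the replicon start)
  pos <- sort(sample(20000:60000, 40))
  ids <- sample(paste0("m", 1:6), 40, replace = TRUE)
  ms1 <- toy_mutant_set(pos, ids, genome_length = 2e5)
  shift <- 37000L
  ms2 <- toy_mutant_set(pos + shift, ids, genome_length = 2e5)
  s1 <- score_track(ms1, 5000, 500)
  s2 <- score_track(ms2, 5000, 500)
  # the non-zero score profile is the same, shifted
  expect_equal(sort(s1$score[s1$score > 0]), sort(s2$score[s2$score > 0]),
               tolerance = 1e-9)
  expect_equal(max(s1$score), max(s2$score), tolerance = 1e-9)
})

test_that("the fixture's score peak sits on the dense promoter-region cluster", {
  m <- load_screen_fixture("M")
  tr <- score_track(m)
  best <- tr[which.max(tr$score), ]
  expect_lte(best$window_start, 1606810)
  expect_gte(best$window_end, 1607314)
})

test_that("per-position counts tally distinct mutants", {
  m <- load_screen_fixture("M")
  pc <- per_position_counts(m)
  expect_equal(pc$n_mutants[pc$position == 1607261], 10L)
  expect_equal(pc$n_mutants[pc$position == 1607117], 1L)
  expect_equal(sum(pc$n_mutants), n_records(m))

  # duplicate (mutant, position) records count once
  dup <- toy_mutant_set(c(10L, 10L, 10L), c("a", "a", "b"))
  expect_equal(per_position_counts(dup)$n_mutants, 2L)
})

test_that("cluster calling partitions positions by single linkage", {
  # boundary: exactly max_gap joins, max_gap + 1 splits
  joined <- call_clusters(toy_mutant_set(c(1000L, 6000L), c("a", "b")),
                          max_gap = 5000)
  expect_equal(nrow(joined), 1L)
  split2 <- call_clusters(toy_mutant_set(c(1000L, 6001L), c("a", "b")),
                          max_gap = 5000)
  expect_equal(nrow(split2), 2L)
  expect_true(all(split2$n_positions == 1L))

  # partition property on random sets
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    pos <- sort(sample.int(9e4, n))
    ms <- toy_mutant_set(pos, sample(paste0("m", 1:8), n, TRUE),
                         genome_length = 1e5)
    cl <- call_clusters(ms, max_gap = 3000, W = 5000, s = 1000)
    got <- sort(unlist(cl$positions))
    expect_equal(got, sort(unique(pos)))  # union = all distinct positions
    # pairwise separation between clusters > max_gap
    bounds <- cl[order(cl$start), c("start", "end")]
    if (nrow(bounds) > 1) {
      gaps <- bounds$start[-1] - bounds$end[-nrow(bounds)]
      expect_true(all(gaps > 3000))
    }
  }
})

test_that("fixture clusters reproduce the curated grouping without reading it", {
  m <- load_screen_fixture("M")
  cl <- call_clusters(m, max_gap = 5000)
  tab <- attr(m, "fixture_table")  # provenance labels, algorithm never sees them
  expected <- split(tab$position, tab$cluster)
  got <- lapply(cl$positions, sort)
  # same partition of the 21 positions, irrespective of ranking order
  key <- function(part) sort(unname(vapply(part, function(p)
    paste(sort(p), collapse = ","), character(1))))
  expect_equal(key(got), key(expected))

  r <- load_screen_fixture("R")
  clr <- call_clusters(r, max_gap = 5000)
  tad <- clr[vapply(clr$positions, function(p) 810889 %in% p, logical(1)), ]
  expect_equal(tad$n_positions, 4L)
  expect_setequal(tad$positions[[1]], c(810889, 812767, 812940, 816694))
})

test_that("cluster annotation separates genic from intergenic members", {
  m <- load_screen_fixture("M")
  cl <- call_clusters(m, max_gap = 5000)
  # gene model consistent with the curated table: the pilus-assembly gene
  # ends before 1607081 and the DNA-binding gene starts after 1607117
  genes <- gene_models(
    locus_tag = c("Mlut_14650", "Mlut_14660"),
    start = c(1605900, 1607150),
    end = c(1607000, 1607500),
    strand = c("-", "+")
  )
  ann <- annotate_clusters(cl, genes)
  top <- ann[1, ]
  expect_equal(top$n_intergenic, 2L)
  expect_equal(top$n_genic, 4L)
  expect_true(all(grepl("^intergenic\\(Mlut_14650,Mlut_14660\\)$",
                        top$loci[[1]][top$positions[[1]] %in%
                                        c(1607081, 1607117)])))

  # minus-strand genes label their members like any other
  ms <- toy_mutant_set(c(150L, 160L), c("a", "b"))
  g <- gene_models("neg", 100, 399, "-")
  a2 <- annotate_clusters(call_clusters(ms, max_gap = 100, W = 5000,
                                        track = score_track(ms, 5000, 500)),
                          g)
  expect_equal(a2$loci[[1]], c("neg", "neg"))
})
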