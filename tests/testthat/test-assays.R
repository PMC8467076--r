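test_that("4PL fitting recovers parameters from clean and noisy curves", {
  truth <- four_pl(a = 50, d = 5000, c = 180, b = 3)
  clean <- simulate_kinetics(truth, 0, n_replicates = 1, seed = 1)
  fp <- fit_4pl(clean$time_min, clean$rfu)
  rel <- abs(c(fp$a - 50, fp$d - 5000, fp$c - 180, fp$b - 3)) /
    c(50, 5000, 180, 3)
  expect_true(all(rel < 1e-6))
  expect_true(fp$converged)

  # decreasing curve: the model is symmetric, d < a
  falling <- four_pl(a = 5000, d = 50, c = 180, b = 3)
  dn <- simulate_kinetics(falling, 0, n_replicates = 1, seed = 2)
  fd <- fit_4pl(dn$time_min, dn$rfu)
  expect_lt(fd$d, fd$a)
  expect_equal(attr(max_slope(fd), "sign"), -1)
  expect_gt(as.numeric(max_slope(fd)), 0)

  expect_error(fit_4pl(seq(0, 70, 10), rep(5, 8)), "constant")
})

test_that("maximal slope matches numeric maximization and scales linearly", {
  fp <- four_pl(a = 0, d = 100, c = 60, b = 2)
  tg <- seq(1e-3, 600, by = 1e-3)
  numeric_max <- max(diff(predict_four_pl(fp, tg)) / 1e-3)
  expect_equal(as.numeric(max_slope(fp)), numeric_max, tolerance = 1e-6)

  # flat curve
  expect_equal(as.numeric(max_slope(four_pl(100, 100, 60, 2))), 0)

  # doubling the amplitude doubles the slope
  s1 <- as.numeric(max_slope(four_pl(0, 100, 60, 2)))
  s2 <- as.numeric(max_slope(four_pl(0, 200, 60, 2)))
  expect_equal(s2, 2 * s1, tolerance = 1e-12)

  # b <= 1: supremum at t -> 0, evaluated at the observed range start
  shallow <- four_pl(0, 100, 60, 0.8)
  expect_error(max_slope(shallow), "t_range")
  s <- max_slope(shallow, t_range = c(10, 600))
  expect_equal(attr(s, "t_max"), 10)
})

test_that("relative activity flags repressed strains with a strict threshold", {
  truth <- four_pl(50, 5000, 180, 3)
  ref <- simulate_kinetics(truth, 0, n_replicates = 3, seed = 1,
                           strain = "ref")
  scale_curve <- function(f) {
    d <- simulate_kinetics(four_pl(50, 50 + f * 4950, 180, 3), 0,
                           n_replicates = 3, seed = 1, strain = "mut")
    d
  }
  # identical strain: relative activity 1, not flagged
  same <- ref
  same$strain <- "mut"
  act <- relative_activity(rbind(ref, same), reference = "ref")
  expect_equal(act$relative_activity[act$strain == "mut"], 1,
               tolerance = 1e-9)
  expect_false(act$flag_low[act$strain == "mut"])

  # 0.4x amplitude: flagged
  act4 <- relative_activity(rbind(ref, scale_curve(0.4)), reference = "ref")
  expect_true(act4$flag_low[act4$strain == "mut"])
  expect_equal(act4$relative_activity[act4$strain == "mut"], 0.4,
               tolerance = 1e-6)

  # exactly half: strictly-less-than rule keeps it
  act5 <- relative_activity(rbind(ref, scale_curve(0.5)), reference = "ref")
  expect_false(act5$flag_low[act5$strain == "mut"])

  # scale invariance: multiplying every curve by a constant changes nothing
  both <- rbind(ref, scale_curve(0.4))
  scaled <- both
  scaled$rfu <- scaled$rfu * 7.3
  a1 <- relative_activity(both, "ref")
  a2 <- relative_activity(scaled, "ref")
  expect_equal(a1$relative_activity, a2$relative_activity, tolerance = 1e-9)

  expect_error(relative_activity(ref, reference = "absent"), "not found")
})

test_that("group comparison follows the classical t / F machinery", {
  expect_equal(compare_activity(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_activity(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(compare_activity(c(5, 5, 5), c(5, 5, 5))$p, 1)

  shifted <- compare_activity(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.001)

  # two-group ANOVA F equals the square of the pooled t statistic
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1), 10, 2)
    y <- rnorm(sample(3:8, 1), 12, 2)
    tt <- compare_activity(x, y, var_equal = TRUE)
    av <- anova_across_strains(10^c(x, y),
                               rep(c("a", "b"), c(length(x), length(y))))
    expect_equal(av$F, tt$t^2, tolerance = 1e-9)
    expect_equal(av$p, tt$p, tolerance = 1e-9)
  }
})

test_that("t-test p agrees with a permutation oracle on normal data", {
  set.seed(32)
  x <- rnorm(8, 10, 1)
  y <- rnorm(8, 11, 1)
  t_obs <- abs(compare_activity(x, y)$t)
  pool <- c(x, y)
  n_perm <- 20000
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(16, 8)
    tp <- abs(compare_activity(pool[idx], pool[-idx])$t)
    if (tp >= t_obs - 1e-12) hits <- hits + 1
  }
  p_perm <- hits / n_perm
  p_t <- compare_activity(x, y)$p
  expect_lt(abs(p_perm - p_t), 3 * sqrt(p_t * (1 - p_t) / n_perm) + 0.01)
})

test_that("linkage degree and filter implement the plated-colony formula", {
  l1 <- linkage_degree(5, 100)
  expect_equal(l1$linkage_pct, 5)
  l2 <- linkage_degree(0, 100)
  expect_equal(l2$linkage_pct, 0)
  l3 <- linkage_degree(2, 80)
  expect_equal(l3$linkage_pct, 2.5)
  l0 <- linkage_degree(4, 0)
  expect_true(l0$undefined)

  kept <- linkage_filter(list(l1, l2, l3, l0), threshold_pct = 3)
  expect_equal(length(kept), 2L)
  expect_equal(vapply(kept, `[[`, numeric(1), "linkage_pct"), c(0, 2.5))

  # alternative normalisation divides by the total
  lt <- linkage_degree(20, 80, denominator = "total")
  expect_equal(lt$linkage_pct, 20)
})

test_that("transformation frequency handles exact arithmetic and censoring", {
  # 50 transformant CFU/mL against 1e8 viable CFU/mL
  pc <- plate_counts(transformant_colonies = 50, transformant_volume_ml = 1,
                     viable_colonies = 100, viable_volume_ml = 1,
                     viable_dilution = 1e6, no_dna_revertant_colonies = 0)
  tf <- transformation_frequency(pc)
  expect_equal(tf$frequency, 5e-7)  # exact rational arithmetic

  # 100-fold drop is rel_log10 = -2
  low <- plate_counts(1, 2, 100, 1, 1e6)  # 0.5 CFU/mL -> 5e-9
  tf_low <- transformation_frequency(low, reference_frequency = 5e-7)
  expect_equal(tf_low$rel_log10, -2)

  # zero transformants: censored at the revertant-derived detection limit
  cen <- plate_counts(0, 1, 100, 1, 1e6, no_dna_revertant_colonies = 2)
  tf_cen <- transformation_frequency(cen)
  expect_true(all(tf_cen$below_detection))
  expect_equal(tf_cen$detection_limit, 2e-8)
  expect_true(is.na(tf_cen$mean_frequency))

  # censored replicates are excluded from the ANOVA with a message
  expect_message(
    av <- anova_across_strains(c(1e-6, 2e-6, NA, 3e-7, 4e-7, 5e-7),
                               rep(c("a", "b"), each = 3)),
    "censored"
  )
  expect_true(av$p < 1)

  expect_error(plate_counts(-1, 1, 100, 1, 1e6), "non-negative")
})
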