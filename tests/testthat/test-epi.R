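# characterization statistics and pattern naming

test_that("chi_square_test agrees with an independent implementation", {
  set.seed(13)
  for (r in 1:50) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 25) + 1, nrow = nr)
    ours <- chi_square_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # proportional rows give exactly 0
  expect_equal(chi_square_test(rbind(c(10, 20), c(20, 40)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(chi_square_test(matrix(1:3, 1)), "2 x 2")
})

test_that("anova raw and summary entry points agree; F = t^2 for 2 groups", {
  set.seed(14)
  x <- rnorm(90, mean = rep(c(0, 0.5, 1), each = 30))
  g <- rep(letters[1:3], each = 30)
  raw <- anova_oneway(x, g)
  s <- data.frame(n = as.numeric(table(g)),
                  mean = as.numeric(tapply(x, g, mean)),
                  sd = as.numeric(tapply(x, g, sd)))
  via_summary <- anova_oneway(summaries = s)
  expect_equal(raw$F, via_summary$F, tolerance = 1e-9)
  expect_equal(raw$p_value, via_summary$p_value, tolerance = 1e-9)
  ref <- summary(stats::aov(x ~ g))[[1]]
  expect_equal(raw$F, ref$`F value`[1], tolerance = 1e-9)

  x2 <- rnorm(40); g2 <- rep(c("u", "v"), each = 20)
  tt <- stats::t.test(x2 ~ g2, var.equal = TRUE)
  expect_equal(anova_oneway(x2, g2)$F, unname(tt$statistic)^2,
               tolerance = 1e-9)

  # identical group means -> F = 0
  expect_equal(anova_oneway(rep(c(1, 2), 10), rep(c("a", "b"), each = 10))$F,
               0, tolerance = 1e-12)
  expect_error(anova_oneway(rep(1, 10), rep(c("a", "b"), each = 5)),
               "undefined")
})

test_that("bonferroni_pairwise multiplies by the pair count and caps at 1", {
  set.seed(15)
  x <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  adj <- bonferroni_pairwise(x, g)
  expect_equal(adj["a", "b"], attr(adj, "raw")["a", "b"])  # m = 1
  x4 <- rnorm(80); g4 <- rep(letters[1:4], each = 20)
  adj4 <- bonferroni_pairwise(x4, g4)
  raw4 <- attr(adj4, "raw")
  expect_equal(attr(adj4, "n_comparisons"), 6)
  expect_equal(adj4[upper.tri(adj4)],
               pmin(1, 6 * raw4[upper.tri(raw4)]), tolerance = 1e-12)
  expect_warning(bonferroni_pairwise(c(x4, 0), c(g4, "tiny")), "n < 2")
})

test_that("one shifted group lights up exactly its three pairs", {
  hits <- matrix(0, 4, 4)
  for (s in 1:20) {
    set.seed(400 + s)
    g <- rep(letters[1:4], each = 40)
    x <- rnorm(160) + ifelse(g == "c", 1.2, 0)
    adj <- bonferroni_pairwise(x, g)
    hits <- hits + (adj < 0.05)
  }
  involved <- c(hits["c", "a"], hits["c", "b"], hits["c", "d"])
  others <- c(hits["a", "b"], hits["a", "d"], hits["b", "d"])
  expect_true(all(involved >= 19))
  expect_true(all(others <= 2))
})

test_that("prevalence_table counts and shares are exact", {
  co <- generate_cohort(synth_config(n_patients = 200, seed = 6))
  lab <- co$planted_group
  pt <- prevalence_table(co, lab)
  expect_equal(sum(pt$pattern_sizes), nrow(co))
  expect_equal(sum(pt$shares), 1, tolerance = 1e-12)
  for (g in unique(lab)) {
    expect_equal(pt$counts["ckd", as.character(g)],
                 sum(co$ckd[lab == g]))
  }
  # all records in one community, all diseased -> prevalence 1
  co2 <- co[1:10, ]
  co2[, c("hypertension", "dyslipidemia", "diabetes", "ckd",
          "hyperuricemia")] <- TRUE
  pt2 <- prevalence_table(co2, rep(1, 10))
  expect_true(all(pt2$prevalence == 1))
})

test_that("planted prevalences are recovered within binomial error", {
  cfg <- synth_config(n_patients = 5000, seed = 17)
  co <- generate_cohort(cfg)
  pt <- prevalence_table(co, co$planted_group)
  for (g in 1:4) {
    n_g <- pt$pattern_sizes[g]
    tol <- 4 * sqrt(cfg$disease_prev[g, ] * (1 - cfg$disease_prev[g, ]) / n_g)
    expect_true(all(abs(pt$prevalence[, g] - cfg$disease_prev[g, ]) < tol))
  }
})

test_that("name_patterns reproduces the published mapping and handles ties", {
  # published Table 1 prevalences with sizes 471/127/1463/245
  counts <- do.call(rbind, published_disease_counts)
  prev <- structure(list(
    counts = counts,
    prevalence = sweep(counts, 2, published_sizes, "/"),
    pattern_sizes = published_sizes,
    pattern_labels = c("1", "2", "3", "4"),
    shares = published_sizes / sum(published_sizes)),
    class = "cmm_prevalence")
  nm <- name_patterns(prev)
  expect_equal(unname(nm), c("HPG", "UADCG", "MDHG", "KDLG"))

  # permuted community labels keep the same member-to-name mapping
  perm <- c(3, 1, 4, 2)
  prev_p <- prev
  prev_p$counts <- prev$counts[, perm]
  prev_p$prevalence <- prev$prevalence[, perm]
  prev_p$pattern_sizes <- prev$pattern_sizes[perm]
  nm_p <- name_patterns(prev_p)
  expect_equal(unname(nm_p), unname(nm)[perm])

  # identical prevalences -> generic fallback
  prev_t <- prev
  prev_t$prevalence[] <- 0.5
  prev_t$counts[] <- 50
  expect_message(nm_t <- name_patterns(prev_t), "fell back")
  expect_true(all(grepl("^Pattern-", nm_t)))
})

test_that("pattern_profile assembles tests for a planted cohort", {
  co <- filter_cmm(generate_cohort(recovery_config(n = 400, seed = 19)))
  prof <- pattern_profile(co, co$planted_group,
                          continuous = c("age", "bmi", "choline"),
                          categorical = c("gender", "smoking_100"))
  expect_s3_class(prof, "cmm_profile")
  expect_length(prof$disease_tests, 5)
  expect_true(all(sapply(prof$continuous_tests, function(x) x$anova$df1) == 3))
  path <- file.path(tempdir(), "profile_test")
  report_profile(prof, path)
  expect_true(file.exists(paste0(path, ".json")))
  expect_true(file.exists(paste0(path, ".md")))
  unlink(paste0(path, c(".json", ".md")))
})
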