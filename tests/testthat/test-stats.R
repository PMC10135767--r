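test_that("identical groups give t = 0, p = 1", {
  a <- suppressWarnings(group_sample("a", c(1, 2, 3)))
  b <- suppressWarnings(group_sample("b", c(1, 2, 3)))
  res <- compare_two(a, b)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")
  expect_false(res$degenerate)
})

test_that("pooled t matches its closed form on a shifted pair", {
  ## +10 shift with tiny within-group variance
  x <- c(1, 1.01, 1.02); y <- x + 10
  res <- compare_two(suppressWarnings(group_sample("a", x)),
                     suppressWarnings(group_sample("b", y)))
  ## equal group variances: pooled variance = var(x), SE = sd * sqrt(2/3)
  t_manual <- (mean(x) - mean(y)) / (sd(x) * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_manual, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$df, 4)
})

test_that("degenerate zero-variance groups are flagged with the p = 1 convention", {
  a <- suppressWarnings(group_sample("a", c(5, 5, 5)))
  b <- suppressWarnings(group_sample("b", c(5, 5, 5)))
  res <- compare_two(a, b)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(compare_two(suppressWarnings(group_sample("a", 1)), a),
               class = "caflow_parameter_error")
})

test_that("one-way ANOVA F matches pencil-and-paper arithmetic", {
  ## groups {1,2,3}, {2,3,4}, {6,7,8}: SSB = 42 (df 2), SSW = 6 (df 6),
  ## F = 21 exactly
  gs <- lapply(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)),
               function(v) suppressWarnings(group_sample("g", v)))
  gs <- Map(function(g, nm) { g$condition <- nm; g }, gs, c("a", "b", "c"))
  res <- compare_many(gs)
  expect_equal(res$statistic, 21, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  ## Tukey covers all unordered pairs, and only pairs involving the shifted
  ## group are significant
  expect_equal(nrow(res$pairwise), 3L)
  sig <- res$pairwise$p_adj < 0.05
  involves_c <- res$pairwise$group_1 == "c" | res$pairwise$group_2 == "c"
  expect_identical(sig, involves_c)
})

test_that("three identical groups give F ~ 0 and all adjusted p ~ 1", {
  v <- c(4, 5, 6, 7)
  gs <- lapply(c("x", "y", "z"), function(nm)
    suppressWarnings(group_sample(nm, v)))
  res <- compare_many(gs)
  expect_lt(res$statistic, 1e-20)
  expect_gt(min(res$pairwise$p_adj), 0.999)
})

test_that("compare_many validates group sizes and names the offender", {
  gs <- list(suppressWarnings(group_sample("ok1", 1:5)),
             suppressWarnings(group_sample("ok2", 2:6)),
             suppressWarnings(group_sample("tiny", 7)))
  err <- tryCatch(compare_many(gs), error = function(e) e)
  expect_s3_class(err, "caflow_parameter_error")
  expect_match(conditionMessage(err), "tiny")
  expect_error(compare_many(gs[1:2]), class = "caflow_parameter_error")
})

test_that("five-number summary follows the documented interpolation rule", {
  s <- summarize_group(suppressWarnings(group_sample("g", c(1, 2, 3, 4, 5))))
  expect_equal(unlist(s[c("min", "median", "max")], use.names = FALSE),
               c(1, 3, 5))
  ## {1..8}: linear interpolation between order statistics gives
  ## Q1 = x_(2) + 0.75 * (x_(3) - x_(2)) = 2.75 and Q3 = 6.25
  s8 <- summarize_group(suppressWarnings(group_sample("g", 1:8)))
  expect_equal(s8$q1, 2.75)
  expect_equal(s8$q3, 6.25)
  expect_equal(s8$sem, sd(1:8) / sqrt(8))
  ## degenerate single value
  s1 <- summarize_group(suppressWarnings(group_sample("g", 7)))
  expect_true(all(unlist(s1[c("min", "q1", "median", "q3", "max", "mean")]) == 7))
  expect_equal(s1$sem, 0)
  expect_true(s1$degenerate)
})

test_that("the collection rule warns below 15 events per group", {
  expect_warning(group_sample("small", 1:10), "15")
  expect_silent(group_sample("ok", 1:15))
})

test_that("star notation matches the figure convention", {
  expect_equal(caflow:::p_stars(c(0.2, 0.05, 0.04, 0.009, 9e-4, 9e-5)),
               c("ns", "ns", "*", "**", "***", "****"))
})

test_that("group_statistics ties features to conditions end to end", {
  co <- generate_cohort(cohort_design_knockdown(), n_per_condition = 20,
                        mode = "traces", snr = 10, seed = 8)
  ft <- quantify_traces(co$traces)
  gs <- suppressWarnings(group_statistics(ft))
  expect_setequal(gs$tests$feature, c("T_D_s", "T_P_s", "I_P"))
  expect_true(all(gs$tests$p_value >= 0 & gs$tests$p_value <= 1))
  expect_equal(nrow(gs$summaries), 6L)  # 3 features x 2 conditions
  ## knockdown lengthens the delay: the mean difference has the right sign
  sm <- gs$summaries[gs$summaries$feature == "T_D_s", ]
  expect_gt(sm$median[sm$condition == "shKindlin3"],
            sm$median[sm$condition == "WT"])
})
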