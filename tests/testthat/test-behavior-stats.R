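test_that("level classification follows the half-open SPL bins", {
  expect_equal(classify_level(216.4), "very_high")
  expect_equal(classify_level(93), "background")
  expect_equal(classify_level(165), "high")      # the 165-170 gap is 'high'
  expect_equal(classify_level(c(119.99, 120, 139.99, 140, 149.99, 150,
                                169.99, 170)),
               c("background", "low", "low", "medium", "medium", "high",
                 "high", "very_high"))
  expect_error(classify_level(NaN), "finite")
})

test_that("Levene's test: shifted copies give W = 0, hand oracle agrees", {
  x <- c(1, 3, 7, 2, 9)
  vals <- c(x, x + 10, x - 4)
  grp <- rep(c("a", "b", "c"), each = 5)
  lv <- levene_test(vals, grp)
  expect_equal(lv$W, 0)
  expect_equal(lv$p, 1)
  # 2x3 toy: W equals a one-way ANOVA on |x - group mean| done by hand
  v <- c(1, 2, 6, 4, 4, 10)
  g <- rep(c("a", "b"), each = 3)
  z <- abs(v - ave(v, g))
  fit <- anova(lm(z ~ g))
  lv2 <- levene_test(v, g)
  expect_equal(lv2$W, fit$`F value`[1])
  expect_equal(lv2$p, fit$`Pr(>F)`[1])
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "single value.*b")
  # variance 1 vs 100, n = 20: detected
  set.seed(31)
  vals <- c(rnorm(20, sd = 1), rnorm(20, sd = 10))
  expect_lt(levene_test(vals, rep(c("a", "b"), each = 20))$p, 0.05)
})

test_that("two-way ANOVA equals the design-matrix oracle (balanced and unbalanced)", {
  set.seed(17)
  for (rep in 1:8) {
    nA <- sample(2:3, 1); nB <- sample(2:4, 1)
    n <- sample(c(2, 3), 1)
    d <- expand.grid(A = letters[1:nA], B = LETTERS[1:nB])
    d <- d[rep(seq_len(nrow(d)), n), ]
    if (rep > 4) d <- rbind(d, d[sample(nrow(d), 3), ])   # unbalance, no empty cells
    y <- rnorm(nrow(d)) + as.integer(d$A) + 0.5 * as.integer(d$B)
    got <- two_way_anova(y, d$A, d$B)
    want <- oracle_type3(y, d$A, d$B)
    expect_equal(got$sum_sq[1:3], want$ss, tolerance = 1e-8)
    expect_equal(got$sum_sq[4], want$rss)
    expect_equal(got$df[4], want$df_res)
  }
})

test_that("ANOVA degenerate and closed-form cases behave", {
  # balanced 2x2 with identical cell means: all F = 0, p = 1
  d <- expand.grid(A = c("a", "b"), B = c("x", "y"), r = 1:3)
  y <- c(1, -1, 0)[d$r]   # same within-cell values everywhere, cell means 0
  res <- two_way_anova(y, d$A, d$B)
  expect_equal(res$F[1:3], rep(0, 3), tolerance = 1e-6)
  expect_equal(res$p[1:3], rep(1, 3), tolerance = 1e-6)
  # one-way, two groups: F equals the squared pooled-variance t statistic
  set.seed(23)
  y <- c(rnorm(8, 0), rnorm(11, 1))
  g <- rep(c("a", "b"), c(8, 11))
  res1 <- two_way_anova(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res1$F[1], unname(tt$statistic)^2)
  expect_equal(res1$p[1], tt$p.value)
  # relabeling levels and adding constants change nothing
  y2 <- y + 100
  g2 <- ifelse(g == "a", "zebra", "ant")
  res2 <- two_way_anova(y2, g2)
  expect_equal(res2$F, res1$F)
  expect_equal(res2$p, res1$p)
  # missing cells reduce the interaction df instead of crashing
  d <- expand.grid(A = c("a", "b", "c"), B = c("x", "y"), r = 1:3)
  d <- d[!(d$A == "c" & d$B == "y"), ]
  set.seed(5)
  res3 <- two_way_anova(rnorm(nrow(d)), d$A, d$B)
  expect_equal(res3$df[res3$effect == "interaction"], 1)  # not (3-1)*(2-1)=2
  expect_error(two_way_anova(rnorm(4), rep("a", 4)), ">= 2 levels")
})

test_that("Tukey-Kramer homogeneous subsets match pairwise brute force", {
  # identical group means: one subset with all groups
  set.seed(11)
  noise <- rnorm(10, sd = 0.5)
  vals <- c(noise, noise + 0.01, noise - 0.01)
  g <- rep(c("a", "b", "c"), each = 10)
  tk <- tukey_subsets(vals, g)
  expect_length(tk$subsets, 1)
  expect_setequal(tk$subsets[[1]], c("a", "b", "c"))
  # two groups 10 pooled SDs apart: singleton subsets
  v2 <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  tk2 <- tukey_subsets(v2, rep(c("lo", "hi"), each = 10))
  expect_length(tk2$subsets, 2)
  # three groups (A ~ B) << C -> {A,B},{C}; verify p-values pairwise
  v3 <- c(rnorm(12, 0), rnorm(12, 0.2), rnorm(12, 8))
  g3 <- rep(c("A", "B", "C"), each = 12)
  tk3 <- tukey_subsets(v3, g3)
  expect_length(tk3$subsets, 2)
  expect_setequal(tk3$subsets[[1]], c("A", "B"))
  expect_equal(tk3$subsets[[2]], "C")
  # brute-force check of the q statistics against ptukey via TukeyHSD
  th <- TukeyHSD(aov(v3 ~ g3))$g3
  got <- tk3$pairwise
  for (i in seq_len(nrow(got))) {
    key <- paste0(got$group2[i], "-", got$group1[i])
    key2 <- paste0(got$group1[i], "-", got$group2[i])
    row <- if (key %in% rownames(th)) th[key, ] else th[key2, ]
    expect_equal(got$p[i], unname(row["p adj"]), tolerance = 1e-6)
  }
  expect_error(tukey_subsets(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("composite score separates responders and classifies monotonically", {
  set.seed(41)
  n_null <- 30
  rec <- data.frame(
    event_id = sprintf("e%02d", 1:(n_null + 5)),
    source_type = "tone",
    level_class = c(rep("background", n_null), rep("very_high", 5)),
    spl_db = c(rep(100, n_null), rep(180, 5)),
    d_com = c(rnorm(n_null, 0, 0.3), rnorm(5, -3.3, 0.3)),
    d_extent = c(rnorm(n_null, 0, 0.5), rnorm(5, -6, 0.5)),
    d_length = c(rnorm(n_null, 0, 1), rnorm(5, -8, 1)),
    d_tilt = c(rnorm(n_null, 0, 0.02), rnorm(5, 0.1, 0.02)))
  sc <- composite_score(rec)
  expect_length(sc, n_null + 5)
  resp <- abs(sc[(n_null + 1):(n_null + 5)])
  expect_true(all(resp > quantile(abs(sc[1:n_null]), 0.95)))
  cls <- classify_behavior(sc)
  expect_true(all(cls[(n_null + 1):(n_null + 5)] == "B2"))
  # monotone in |score|
  expect_equal(classify_behavior(c(0, 0.49, 0.5, 1.9, 2, -3)),
               c("B0", "B0", "B1", "B1", "B2", "B2"))
  # all events identical to baseline -> degenerate: zero-variance vars error
  same <- rec; same[c("d_com", "d_extent", "d_length", "d_tilt")] <- 0
  expect_error(suppressWarnings(composite_score(same)), "zero variance")
  # one informative variable: score proportional to its z-value
  one <- rec
  one[c("d_extent", "d_length", "d_tilt")] <- 0
  sc1 <- suppressWarnings(composite_score(one))
  expect_equal(abs(cor(sc1, one$d_com)), 1, tolerance = 1e-9)
  expect_error(composite_score(rec[1:2, ]), ">= 3 complete")
})

test_that("build_event_table joins envelope and trace aggregates per event", {
  # synthetic envelope: constant com 12 before events, 9 during event windows
  pt <- seq(0, 2000, by = 1)
  sched <- event_schedule(data.frame(
    event_id = c("a", "b", "c"), start_time = c(500, 1000, 2500),
    duration_s = c(100, 100, 100), source_type = c("tone", "lupara", "tone"),
    nominal_frequency_hz = c(50, NA, 100), spl_db = c(165, 216.4, 130)))
  in_ev <- (pt >= 500 & pt < 600) | (pt >= 1000 & pt < 1100)
  env <- data.frame(ping_time = pt, com_range = ifelse(in_ev, 9, 12),
                    lower_range = ifelse(in_ev, 6, 4),
                    upper_range = ifelse(in_ev, 12, 23), valid = TRUE)
  tab <- build_event_table(sched, env, list())
  expect_equal(nrow(tab), 2)                       # event c outside data span
  expect_equal(attr(tab, "skipped"), "c")
  expect_equal(tab$d_com, c(-3, -3))
  expect_equal(tab$d_extent, c(-13, -13))          # 19 -> 6
  expect_equal(tab$level_class, c("high", "very_high"))
  # empty trace table: trace variables missing, no crash
  expect_true(all(is.na(tab$avg_trace_length)))
  expect_true(all(is.na(tab$d_tilt)))
})

test_that("simulated level effect is detected, absent type effect is not (power)", {
  p_level <- numeric(20); p_type <- numeric(20)
  for (i in 1:20) {
    tab <- simulate_event_table(seed = 1000 + i)
    res <- two_way_anova(tab$d_com, tab$source_type, tab$level_class)
    p_level[i] <- res$p[res$effect == "source_level"]
    p_type[i] <- res$p[res$effect == "source_type"]
  }
  expect_gte(mean(p_level < 0.05), 0.8)
  expect_lte(mean(p_type < 0.05), 0.1)
})
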