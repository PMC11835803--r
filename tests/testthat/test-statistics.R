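toy_table <- function(values, electrodes, subject = "s1", group = "H") {
  data.frame(subject = subject, group = group, state = "task",
             measure = "sampen_beta", condition = "1T",
             electrode = electrodes, value = values)
}

test_that("region averaging means electrodes and skips undefined values", {
  map <- list(frontal = c("F1", "F3", "F5"), occipital = "O1")
  tab <- entropy_table(toy_table(c(1, 2, 3, 9), c("F1", "F3", "F5", "O1")))
  out <- region_average(tab, map)
  expect_equal(out$value[out$electrode == "frontal"], 2)
  expect_equal(out$value[out$electrode == "occipital"], 9)

  tab$value[2] <- NA_real_
  out2 <- region_average(entropy_table(tab), map)
  expect_equal(out2$value[out2$electrode == "frontal"], 2)

  expect_error(region_average(tab, list(parietal = "P3")), "no measured")
})

test_that("Levene check flags variance heterogeneity and not its absence", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- levene_check(g)
  expect_equal(res$p, 1, tolerance = 1e-12)

  set.seed(21)
  hits <- 0L
  for (i in 1:20) {
    r <- levene_check(list(rnorm(100), rnorm(100, sd = 3)))
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits, 19L)  # near-certain detection at this variance ratio

  expect_error(levene_check(list(1:3)), "at least 2 groups")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  res <- one_way_anova(list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(5, 6, 7)))
  # SS_between = 26, SS_within = 6, df = (2, 6)
  expect_equal(res$statistic, 13)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p, pf(13, 2, 6, lower.tail = FALSE))
  expect_equal(res$effect_size, 26 / 32)

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
})

test_that("with two groups the one-way F equals the squared t", {
  set.seed(31)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  a <- one_way_anova(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
})

test_that("Bonferroni pairwise tests scale p and report pooled-SD d", {
  set.seed(41)
  gl <- list(A = rnorm(10), B = rnorm(12, 1), C = rnorm(9, 2))
  res <- bonferroni_pairwise(gl)
  expect_identical(nrow(res), 3L)
  raw <- t.test(gl$A, gl$B, var.equal = TRUE)$p.value
  expect_equal(res$p[res$effect == "A vs B"], min(1, raw * 3))
  expect_true(all(res$p <= 1))
  d_manual <- (mean(gl$A) - mean(gl$B)) /
    sqrt((9 * var(gl$A) + 11 * var(gl$B)) / 20)
  expect_equal(res$effect_size[res$effect == "A vs B"], d_manual)
  expect_true(all(res$p_adjusted))
})

test_that("split-plot ANOVA matches sums of squares computed from definitions", {
  d <- data.frame(
    subject = rep(paste0("s", 1:8), each = 2),
    group = rep(c("a", "b"), each = 8),
    condition = rep(c("c1", "c2"), 8),
    value = c(3, 5, 4, 7, 2, 6, 5, 5, 8, 9, 7, 11, 9, 8, 10, 12))
  res <- mixed_two_way_anova(d)
  o <- oracle_split_plot(data.frame(y = d$value, subject = d$subject,
                                    group = d$group, condition = d$condition))
  f_group <- (o$group / 1) / (o$subj_within / 6)
  f_cond <- (o$cond / 1) / (o$resid / 6)
  f_int <- (o$interaction / 1) / (o$resid / 6)
  expect_equal(res$statistic[res$effect == "group"], f_group)
  expect_equal(res$statistic[res$effect == "condition"], f_cond)
  expect_equal(res$statistic[res$effect == "group:condition"], f_int)
  expect_equal(res$effect_size[res$effect == "group"],
               o$group / (o$group + o$subj_within))
  expect_equal(res$df2[res$effect == "group"], 6)
  expect_equal(res$df2[res$effect == "condition"], 6)

  # duplicated values per subject: condition carries no sum of squares
  d2 <- d; d2$value <- rep(c(3, 4, 2, 5, 8, 7, 9, 10), each = 2)
  res2 <- mixed_two_way_anova(d2)
  expect_lt(res2$statistic[res2$effect == "condition"], 0.01)
  expect_gt(res2$p[res2$effect == "condition"], 0.9)

  d3 <- d[-1, ]
  expect_error(mixed_two_way_anova(d3), "exactly one measurement")
})

test_that("entropy-behavior correlation recovers exact and null relations", {
  subj <- paste0("s", 1:10)
  x <- 1:10
  tab <- entropy_table(data.frame(
    subject = subj, group = "H", state = "task", measure = "sampen_alpha",
    condition = "1T", electrode = "Cz", value = x))
  beh <- data.frame(subject = subj, group = "H", condition = "1T",
                    performance = 2 * x)
  res <- entropy_behavior_correlation(tab, beh, scope = "summary")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_identical(res$n, 10L)

  # affine invariance and symmetry of the correlation
  beh2 <- beh; beh2$performance <- -3 * x + 7
  expect_equal(entropy_behavior_correlation(tab, beh2, "summary")$r, -1,
               tolerance = 1e-12)

  # zero-variance input is flagged, not propagated
  tab0 <- tab; tab0$value <- 1
  res0 <- entropy_behavior_correlation(entropy_table(tab0), beh, "summary")
  expect_true(is.na(res0$r))
  expect_identical(res0$flag, "zero_variance")

  # undefined entropy rows are dropped pairwise
  tabna <- tab; tabna$value[3] <- NA_real_
  resna <- entropy_behavior_correlation(entropy_table(tabna), beh, "summary")
  expect_identical(resna$n, 9L)
  expect_equal(resna$r, 1, tolerance = 1e-12)
})

test_that("electrode scope returns one correlation per electrode", {
  subj <- rep(paste0("s", 1:8), each = 2)
  set.seed(51)
  tab <- entropy_table(data.frame(
    subject = subj, group = "H", state = "task", measure = "sampen_beta",
    condition = "1T", electrode = rep(c("Cz", "Pz"), 8),
    value = rnorm(16)))
  beh <- data.frame(subject = paste0("s", 1:8), group = "H",
                    condition = "1T", performance = rnorm(8))
  res <- entropy_behavior_correlation(tab, beh, scope = "electrode")
  expect_identical(sort(unique(res$electrode)), c("Cz", "Pz"))
  expect_identical(nrow(res), 2L)
  manual <- cor(tab$value[tab$electrode == "Cz"][order(subj[tab$electrode == "Cz"])],
                beh$performance[order(beh$subject)])
  expect_equal(res$r[res$electrode == "Cz"], manual, tolerance = 1e-12)
})
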