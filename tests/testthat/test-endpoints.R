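test_that("group summaries follow the median/IQR conventions", {
  s <- summarize_group(c(1, 2, 3, 4, 5), "odd")
  expect_equal(s$median, 3)
  s <- summarize_group(c(1, 2, 3, 4), "even")
  expect_equal(s$median, 2.5)
  expect_true(s$iqr_low <= s$median && s$median <= s$iqr_high)
  # invariant to input order
  set.seed(3)
  x <- rnorm(20)
  a <- summarize_group(x); b <- summarize_group(sample(x))
  expect_equal(a[c("median", "iqr_low", "iqr_high")],
               b[c("median", "iqr_low", "iqr_high")])
  # large-sample median concentrates at the distribution median
  set.seed(4)
  expect_lt(abs(summarize_group(runif(1000))$median - 0.5), 0.05)
  expect_error(summarize_group(numeric(0)), class = "bbbmap_data_error")
})

test_that("group comparison delegates to the rank test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
  # agrees with the enumeration oracle at small n
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    expect_equal(compare_groups(a, b)$p_two_sided,
                 mwu_oracle(a, b)$p_two_sided, tolerance = 1e-12)
  }
  # a 3-SD location shift at n = 8 is detected nearly always
  set.seed(6)
  hits <- mean(vapply(1:400, function(i) {
    compare_groups(rnorm(8), rnorm(8) + 3)$p_two_sided < 0.05
  }, logical(1)))
  expect_gte(hits, 0.95)
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  tab <- survival_table(paste0("s", 1:5), "g", c(2, 4, 6, 8, 10), rep(1, 5))
  km <- km_estimate(tab, "g")
  expect_equal(km$steps$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$steps$time, c(2, 4, 6, 8, 10))
  expect_true(km$median_defined)
  expect_equal(km$median, 6)

  one <- km_estimate(survival_table("s1", "g", 5, 1), "g")
  expect_equal(one$steps$surv, 0)
  expect_equal(one$median, 5)

  cens <- km_estimate(survival_table(paste0("s", 1:4), "g", c(3, 5, 7, 9),
                                     rep(0, 4)), "g")
  expect_true(all(cens$steps$surv == 1))
  expect_false(cens$median_defined)
  expect_true(is.na(cens$median))
})

test_that("KM is a non-increasing step function equal to the ECDF complement without censoring", {
  set.seed(8)
  times <- sample(1:40, 12)
  tab <- survival_table(paste0("s", 1:12), "g", times, rep(1, 12))
  km <- km_estimate(tab, "g")
  expect_true(all(diff(km$steps$surv) <= 0))
  expect_lte(max(km$steps$surv), 1)
  emp <- vapply(km$steps$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$steps$surv, emp)
})

test_that("log-rank statistic matches an independent observed/expected computation", {
  # hand-rolled Mantel-Cox oracle over pooled event times
  logrank_oracle <- function(time, event, grp) {
    g <- unique(grp); stopifnot(length(g) == 2)
    o_minus_e <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      n <- sum(at_risk); n1 <- sum(at_risk & grp == g[1])
      d <- sum(event == 1 & time == t)
      d1 <- sum(event == 1 & time == t & grp == g[1])
      o_minus_e <- o_minus_e + d1 - d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / v
  }
  time <- c(1:10, 11:20)
  event <- rep(1, 20)
  grp <- rep(c("A", "B"), each = 10)
  tab <- survival_table(paste0("s", 1:20), grp, time, event)
  got <- logrank_test(tab)
  expect_equal(got$chisq, logrank_oracle(time, event, grp), tolerance = 1e-10)
  expect_equal(got$df, 1)

  # with censoring mixed in
  set.seed(9)
  time2 <- sample(1:30, 16); event2 <- rbinom(16, 1, 0.7)
  event2[1] <- 1
  grp2 <- rep(c("A", "B"), each = 8)
  tab2 <- survival_table(paste0("s", 1:16), grp2, time2, event2)
  expect_equal(logrank_test(tab2)$chisq,
               logrank_oracle(time2, event2, grp2), tolerance = 1e-10)
})

test_that("log-rank degenerate cases follow the contracts", {
  # two identical groups: statistic 0, p = 1
  tab <- survival_table(paste0("s", 1:10), rep(c("A", "B"), each = 5),
                        rep(c(2, 4, 6, 8, 10), 2), rep(1, 10))
  got <- logrank_test(tab)
  expect_equal(got$chisq, 0, tolerance = 1e-10)
  expect_equal(got$p, 1, tolerance = 1e-10)
  # one group or zero events: refused
  expect_error(logrank_test(survival_table("s1", "A", 3, 1)),
               class = "bbbmap_data_error")
  expect_error(logrank_test(survival_table(paste0("s", 1:4),
                                           rep(c("A", "B"), 2),
                                           1:4, rep(0, 4))),
               class = "bbbmap_data_error")
})

test_that("log-rank is invariant to monotone time transforms", {
  set.seed(10)
  time <- sample(1:50, 14); event <- rbinom(14, 1, 0.8); event[1] <- 1
  grp <- rep(c("A", "B"), 7)
  t1 <- logrank_test(survival_table(paste0("s", 1:14), grp, time, event))
  t2 <- logrank_test(survival_table(paste0("s", 1:14), grp, time^3, event))
  expect_equal(t1$chisq, t2$chisq, tolerance = 1e-12)
})

test_that("endpoint value tables validate bounds and integrality on load", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "nss.csv")
  write.csv(data.frame(subject_id = c("a", "b"), group = c("g1", "g2"),
                       nss = c(18, 12)), f, row.names = FALSE)
  got <- read_endpoint_values(f, "nss", bounds = c(0, 18),
                              integer_valued = TRUE)
  expect_equal(got$value, c(18, 12))
  write.csv(data.frame(subject_id = "a", group = "g1", nss = 19), f,
            row.names = FALSE)
  expect_error(read_endpoint_values(f, "nss", bounds = c(0, 18)),
               class = "bbbmap_data_error")
  write.csv(data.frame(subject_id = "a", group = "g1", nss = 2.5), f,
            row.names = FALSE)
  expect_error(read_endpoint_values(f, "nss", integer_valued = TRUE),
               class = "bbbmap_data_error")
})

test_that("survival tables validate on construction and from CSV", {
  expect_error(survival_table("a", "g", -1, 1), class = "bbbmap_data_error")
  expect_error(survival_table("a", "g", 3, 2), class = "bbbmap_data_error")
  dir <- withr::local_tempdir()
  f <- file.path(dir, "surv.csv")
  write.csv(data.frame(subject_id = c("a", "b"), group = c("g1", "g2"),
                       time = c(3, 5), event = c(1, 0)), f, row.names = FALSE)
  tab <- read_survival_table(f)
  expect_s3_class(tab, "survival_table")
  expect_equal(tab$group_label, c("g1", "g2"))
})
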