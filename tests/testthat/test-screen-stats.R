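test_that("Wilcoxon against controls matches exact enumeration", {
  expect_equal(wilcoxon_vs_controls(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # five guides all above ten controls: one-sided 1/C(15,5), doubled
  expect_equal(wilcoxon_vs_controls(11:15, 1:10), 2 / 3003)
  # identical groups are symmetric
  p_sym <- wilcoxon_vs_controls(c(1, 9, 5), c(5, 1, 9))
  expect_equal(as.numeric(p_sym), 1)
  # degenerate all-tied input
  p_tied <- wilcoxon_vs_controls(c(2, 2), c(2, 2, 2))
  expect_equal(as.numeric(p_tied), 1)
  expect_true(attr(p_tied, "tied"))
  expect_error(wilcoxon_vs_controls(numeric(), 1:3), "non-empty")

  # property: agreement with full enumeration for all n + m <= 12
  set.seed(17)
  for (k in 1:40) {
    n <- sample(1:5, 1); m <- sample((n + 1):(12 - n), 1)
    x <- sample(100, n + m)  # tie-free
    expect_equal(wilcoxon_vs_controls(x[1:n], x[(n + 1):(n + m)]),
                 oracle_wilcoxon(x[1:n], x[(n + 1):(n + m)]),
                 tolerance = 1e-12, info = sprintf("case %d (n=%d m=%d)", k, n, m))
  }
})

test_that("BH adjustment matches the step-up formula and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(18)
  for (k in 1:20) {
    p <- runif(sample(3:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # monotone in the ranks
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("combined score calibrates at the published anchor and is monotone", {
  expect_equal(combined_score(2, 0.01), 4)
  expect_equal(combined_score(5, 1), 0)
  expect_equal(combined_score(-1.5, 0.001), 4.5)
  expect_warning(s0 <- combined_score(1, 0), "p_floor")
  expect_equal(s0, 300)
  # monotone increasing in |F|, decreasing in p_adj
  expect_true(all(diff(combined_score(seq(0, 5, 0.5), 0.01)) > 0))
  expect_true(all(diff(combined_score(2, c(0.5, 0.1, 0.01, 0.001))) > 0))
})

test_that("class summaries count any-condition significance with 2-decimal percentages", {
  mk_calls <- function(n, n_sig, cls) {
    ids <- sprintf("%s%04d", cls, seq_len(n))
    # two conditions; significant targets exceed threshold in exactly one
    data.frame(target_id = rep(ids, 2L),
               condition_id = rep(c("c1", "c2"), each = n),
               S = c(ifelse(seq_len(n) <= n_sig, 5, 1), rep(0.5, n)))
  }
  calls <- rbind(mk_calls(912, 18, "a"), mk_calls(529, 61, "i"),
                 mk_calls(245, 27, "s"))
  classes <- c(setNames(rep("asRNA", 912), sprintf("a%04d", 1:912)),
               setNames(rep("iTSS", 529), sprintf("i%04d", 1:529)),
               setNames(rep("sRNA", 245), sprintf("s%04d", 1:245)))
  out <- class_summary(calls, classes, threshold = 4)
  out <- out[match(c("asRNA", "iTSS", "sRNA"), out$class), ]
  expect_equal(out$n_targets, c(912L, 529L, 245L))
  expect_equal(out$n_significant, c(18L, 61L, 27L))
  expect_equal(out$percent, c(1.97, 11.53, 11.02))
  # zero significant -> 0.00
  z <- class_summary(mk_calls(10, 0, "z"),
                     setNames(rep("zcls", 10), sprintf("z%04d", 1:10)))
  expect_equal(z$percent, 0)
  expect_error(class_summary(calls, classes[-1]), "without class")
})

test_that("condition regression recovers planted effects and the OLS solution", {
  design <- data.frame(condition_id = sprintf("c%d", 1:8),
                       co2 = rep(c("high", "low"), 4L),
                       light = rep(c(60, 150, 1000, 150), 2L),
                       fluctuating_light = c(0, 0, 1, 0, 1, 0, 0, 0),
                       glucose = c(0, 1, 0, 0, 0, 1, 0, 1),
                       DCMU = c(0, 0, 0, 1, 0, 0, 1, 0),
                       N_limitation = 0,
                       generation_time_h = 20)
  terms <- c("co2_high", "light", "glucose")
  co2 <- as.numeric(design$co2 == "high")
  # planted: fitness = 2 * co2_high exactly
  F_mat <- rbind(tgA = 2 * co2, tgZero = rep(0, 8))
  colnames(F_mat) <- design$condition_id
  # the planted fit is exact, so summary.lm warns about a perfect fit
  out <- suppressWarnings(condition_regression(F_mat, design, terms = terms))
  a <- out[out$target_id == "tgA", ]
  expect_equal(a$estimate[a$term == "co2_high"], 2, tolerance = 1e-10)
  expect_equal(a$estimate[a$term == "light"], 0, tolerance = 1e-10)
  z <- out[out$target_id == "tgZero", ]
  expect_equal(z$estimate, rep(0, 4L), tolerance = 1e-12)

  # random response: equals the normal-equations solution
  set.seed(19)
  y <- rnorm(8)
  X <- cbind(1, co2, design$light, design$glucose)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  got <- condition_regression(matrix(y, 1, dimnames = list("t", design$condition_id)),
                              design, terms = terms)
  expect_equal(got$estimate, as.numeric(beta), tolerance = 1e-10)

  # aliased factor errors with its name
  design2 <- design; design2$DCMU <- design2$glucose
  expect_error(condition_regression(F_mat, design2,
                                    terms = c("glucose", "DCMU")),
               "aliased.*DCMU")
})

test_that("paired fitness correlation matches the textbook formula", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(paired_fitness_correlation(a, a)$R, 1)
  b <- c(0.8, 2.4, 2.9, 3.6, 5.4)
  got <- paired_fitness_correlation(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$R, r_hand, tolerance = 1e-12)
  expect_equal(got$p, cor.test(a, b)$p.value)
  # independent large samples give near-zero correlation
  set.seed(20)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(abs(paired_fitness_correlation(x, y)$R), 0.1)
  deg <- paired_fitness_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(deg$R))
  expect_true(attr(deg, "degenerate"))
})

test_that("pathway medians equal a sort-based oracle", {
  tt <- data.frame(target_id = rep(sprintf("g%d", 1:6), 2L),
                   condition_id = rep(c("c1", "c2"), each = 6L),
                   F_wmean = c(-2, 0, 4, 1, -1, 3, 5, 2, -3, 0, 0, 1))
  pw <- setNames(c("P1", "P1", "P1", "P2", "P2", "PX"),
                 sprintf("g%d", 1:6))
  out <- pathway_median_fitness(tt, pw)
  expect_equal(out$median_F[out$pathway == "P1" & out$condition_id == "c1"], 0)
  expect_equal(out$median_F[out$pathway == "PX" & out$condition_id == "c2"], 1)
  # random grouping vs sort-based oracle
  set.seed(22)
  tt2 <- data.frame(target_id = sprintf("g%02d", 1:40), condition_id = "c",
                    F_wmean = rnorm(40))
  pw2 <- setNames(sample(c("A", "B", "C"), 40, replace = TRUE),
                  tt2$target_id)
  out2 <- pathway_median_fitness(tt2, pw2)
  for (g in c("A", "B", "C")) {
    vals <- sort(tt2$F_wmean[pw2[tt2$target_id] == g])
    n <- length(vals)
    med <- if (n %% 2 == 1) vals[(n + 1) / 2] else
      (vals[n / 2] + vals[n / 2 + 1]) / 2
    expect_equal(out2$median_F[out2$pathway == g], med)
  }
})
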