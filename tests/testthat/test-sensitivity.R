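test_that("flux grouping: cutoff semantics and degenerate cases", {
  fl <- c(a = 0, b = 0.01, c = 0.05, d = 0.3)
  gr <- bimodal_grouping(fl)
  expect_equal(unname(gr), c("low", "low", "high", "high"),
               ignore_attr = TRUE)  # 0.05 -> high
  expect_equal(attr(gr, "sizes"), c(low = 2L, high = 2L))
  expect_warning(bimodal_grouping(c(a = 0, b = 0)), "one group")
})

test_that("planted flux mixture is recovered exactly and robust to cutoff", {
  set.seed(17)
  fl <- c(stats::setNames(abs(stats::rnorm(20, 0, 1e-4)), paste0("lo", 1:20)),
          stats::setNames(stats::rnorm(20, 0.3, 0.05), paste0("hi", 1:20)))
  truth <- rep(c("low", "high"), each = 20)
  for (cutoff in c(0.02, 0.05, 0.1)) {
    gr <- bimodal_grouping(fl, cutoff)
    expect_equal(unname(gr), truth, ignore_attr = TRUE,
                 info = paste("cutoff", cutoff))
  }
})

test_that("group comparison matches the closed-form Welch t statistic", {
  vals <- c(l1 = 10, l2 = 12, l3 = 11, h1 = 7, h2 = 8, h3 = 6)
  grp <- c(l1 = "low", l2 = "low", l3 = "low",
           h1 = "high", h2 = "high", h3 = "high")
  st <- compare_groups(grp, vals)
  hi <- vals[4:6]; lo <- vals[1:3]
  t_manual <- (mean(hi) - mean(lo)) /
    sqrt(stats::var(hi) / 3 + stats::var(lo) / 3)
  expect_equal(st$statistic, t_manual, tolerance = 1e-12)
  expect_equal(st$direction, -1)
  expect_lt(st$p_value, 0.05)
  expect_error(compare_groups(grp[c(1, 4, 5)], vals), ">= 2")
})

test_that("identical group distributions give t near 0 and p near 1", {
  vals <- stats::setNames(rep(c(5, 6), 10), paste0("l", 1:20))
  grp <- stats::setNames(rep(c("low", "high"), each = 10), paste0("l", 1:20))
  st <- compare_groups(grp, vals)
  expect_equal(st$statistic, 0, tolerance = 1e-9)
  expect_equal(st$p_value, 1, tolerance = 1e-9)
})

test_that("t-test is symmetric under swapping the group labels", {
  set.seed(23)
  vals <- stats::setNames(stats::rnorm(30), paste0("c", 1:30))
  grp <- stats::setNames(rep(c("low", "high"), 15), paste0("c", 1:30))
  swapped <- stats::setNames(ifelse(grp == "low", "high", "low"), names(grp))
  a <- compare_groups(grp, vals)
  b <- compare_groups(swapped, vals)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("planted AUC shift is detected at scale (power check)", {
  set.seed(31)
  hits <- 0
  for (i in 1:20) {
    lo <- stats::rnorm(400, 10, 1.5)
    hi <- stats::rnorm(400, 10 - 2.6, 1.5)
    vals <- stats::setNames(c(lo, hi), paste0("c", 1:800))
    grp <- stats::setNames(rep(c("low", "high"), each = 400), names(vals))
    if (compare_groups(grp, vals)$p_value < 1e-5) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("correlation matches the textbook formula on a hand table", {
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 5, 4, 9)
  st <- correlate(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(st$statistic, r_manual, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$statistic, -1, tolerance = 1e-12)
  expect_error(correlate(x, rep(1, 5)), "variance")
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("negative flux-response association is recovered under noise", {
  set.seed(37)
  rs <- numeric(50)
  for (i in 1:50) {
    flux <- stats::runif(16, 0, 10)
    auc <- 12 - 0.5 * flux + stats::rnorm(16, 0, 1)
    rs[i] <- correlate(flux, auc)$statistic
  }
  expect_true(all(rs < 0))
  # analytic expectation: r ~ -b*sd(x)/sqrt(b^2 var(x) + sigma^2)
  r_exp <- -0.5 * sqrt(100 / 12) / sqrt(0.25 * 100 / 12 + 1)
  expect_equal(mean(rs), r_exp, tolerance = 0.1)
})

test_that("median normalization: zeros, arithmetic, shift invariance", {
  auc <- rbind(line1 = c(10, 10, 10, 10),
               line2 = c(10, 12, 14, 16))
  colnames(auc) <- paste0("d", 1:4)
  sc <- median_normalize_scores(auc)
  expect_equal(unname(sc["line1", ]), c(0, 0, 0, 0))
  expect_equal(unname(sc["line2", ]), c(-3, -1, 1, 3))
  shifted <- auc; shifted["line2", ] <- shifted["line2", ] + 7
  expect_equal(median_normalize_scores(shifted)["line2", ], sc["line2", ])
  with_na <- rbind(auc, line3 = c(5, NA, NA, NA))
  expect_warning(sc2 <- median_normalize_scores(with_na), "excluded")
  expect_false("line3" %in% rownames(sc2))
})

test_that("delta-difference grouping: all-equal deltas give one class", {
  deltas <- matrix(1, 5, 4, dimnames = list(paste0("l", 1:5), paste0("d", 1:4)))
  scores <- matrix(0, 5, 4, dimnames = dimnames(deltas))
  expect_warning(out <- group_by_delta_difference(deltas, scores, 0.1),
                 "one class")
  expect_true(all(out$classes == "no_difference"))
})

test_that("delta-difference classes are invariant to drug order and detect
           planted drug-specific sensitivity", {
  set.seed(41)
  n <- 40
  lines <- paste0("l", 1:n)
  drugs <- paste0("d", 1:4)
  deltas <- matrix(0.1, n, 4, dimnames = list(lines, drugs))
  special <- sample(seq_len(n), 15)
  deltas[cbind(special, sample(1:4, 15, replace = TRUE))] <- 3
  auc <- 10 - 1 * deltas + matrix(stats::rnorm(n * 4, 0, 0.5), n)
  scores <- median_normalize_scores(auc)
  out <- group_by_delta_difference(deltas, scores, threshold = 1)
  expect_equal(sum(out$classes == "large_difference"), 15)
  expect_lt(out$mean_scores[["large_difference"]],
            out$mean_scores[["no_difference"]])
  expect_lt(out$test$p_value, 0.01)
  perm <- c(3, 1, 4, 2)
  out2 <- group_by_delta_difference(deltas[, perm], scores[, perm], 1)
  expect_equal(out2$classes[, drugs[perm]], out$classes[, drugs[perm]])
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  universe <- paste0("g", 1:10)
  A <- universe[1:5]
  B <- universe[c(1, 2, 3, 4)]
  st <- hypergeometric_overlap(A, B, universe)
  # enumerate all C(10,4) draws of |B| genes; count overlap >= 4
  draws <- utils::combn(universe, 4, simplify = FALSE)
  p_enum <- mean(vapply(draws, function(d) length(intersect(d, A)) >= 4,
                        logical(1)))
  expect_equal(st$p_value, p_enum, tolerance = 1e-12)
  expect_equal(st$statistic, 4)
  # zero overlap with small lists: p close to 1
  st2 <- hypergeometric_overlap(universe[1:2], universe[9:10], universe)
  expect_gt(st2$p_value, 0.9)
  # maximal overlap is the most extreme attainable for the fixed sizes
  st3 <- hypergeometric_overlap(A, A[1:4], universe)
  for (d in draws) {
    p_other <- hypergeometric_overlap(A, d, universe)$p_value
    expect_gte(p_other, st3$p_value - 1e-12)
  }
  expect_error(hypergeometric_overlap(A, B, character()), "universe")
  expect_error(hypergeometric_overlap(c(A, "zzz"), B, universe), "subsets")
})

test_that("selectivity metric equals direct group-mean subtraction and the
           planted KDAC effect is detected", {
  set.seed(43)
  n <- 60
  lines <- paste0("l", 1:n)
  flux <- stats::setNames(c(rep(0, 30), rep(10, 30)), lines)
  gr <- bimodal_grouping(flux)
  kdacs <- paste0("kdac", 1:4)
  others <- paste0("cmpd", 1:8)
  auc <- matrix(10, n, 12, dimnames = list(lines, c(kdacs, others)))
  auc[, kdacs] <- auc[, kdacs] - 0.26 * flux
  auc <- auc + matrix(stats::rnorm(n * 12, 0, 0.8), n)
  out <- selectivity_screen(gr, auc, kdacs)
  for (cm in colnames(auc)) {
    direct <- mean(auc[gr == "high", cm]) - mean(auc[gr == "low", cm])
    expect_equal(out$selectivity[[cm]], direct, tolerance = 1e-12)
  }
  expect_lt(out$test$p_value, 0.05)
  expect_equal(out$test$direction, -1)
})

test_that("uniform selectivity across compounds is not called significant", {
  set.seed(47)
  n <- 40
  lines <- paste0("l", 1:n)
  flux <- stats::setNames(c(rep(0, 20), rep(10, 20)), lines)
  gr <- bimodal_grouping(flux)
  ps <- replicate(20, {
    auc <- matrix(stats::rnorm(n * 10, 10, 1), n,
                  dimnames = list(lines, paste0("c", 1:10)))
    selectivity_screen(gr, auc, paste0("c", 1:4))$test$p_value
  })
  expect_gt(mean(ps), 0.2)  # p roughly uniform under the null
})
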