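test_that("normality and homoscedasticity screens behave under known generators", {
  # under the null (normal data) Lilliefors rarely rejects
  set.seed(100)
  p_norm <- replicate(100, lilliefors_test(rnorm(1000))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  # under a skewed alternative it essentially always rejects
  set.seed(101)
  p_exp <- replicate(100, lilliefors_test(rexp(1000))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.99)
  expect_error(lilliefors_test(rep(1, 10)), "constant")
  expect_error(lilliefors_test(c(1, 2, 3, 4)), "at least 5")

  # a pure location shift does not trigger Levene
  set.seed(102)
  base <- rnorm(60)
  lv <- levene_test(list(base, base + 5))
  expect_gt(lv$p_value, 0.05)
  # a genuine scale difference does
  lv2 <- levene_test(list(base, 6 * rnorm(60)))
  expect_lt(lv2$p_value, 0.01)
})

test_that("Kruskal-Wallis matches hand rank arithmetic and rank invariances", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 12 / 42 * (2 * 4 + 0 + 2 * 4), tolerance = 1e-12)
  # identical groups: H = 0, p = 1
  g <- c(1, 2, 3)
  r0 <- kruskal_wallis(list(g, g, g))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # adding a constant leaves H unchanged
  set.seed(5)
  xs <- list(rnorm(8), rnorm(8), rnorm(8))
  shifted <- lapply(xs, function(v) v + 17.3)
  expect_equal(kruskal_wallis(xs)$statistic,
               kruskal_wallis(shifted)$statistic, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 2))), "2 groups")
})

test_that("Mann-Whitney p-values and Cliff's delta match first principles", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), c(1)), "empty")

  # delta stays in [-1, 1] under ties and duplicates
  set.seed(6)
  for (i in 1:50) {
    x <- sample(0:3, sample(2:9, 1), replace = TRUE)
    y <- sample(0:3, sample(2:9, 1), replace = TRUE)
    d <- cliffs_delta(x, y)
    expect_gte(d, -1); expect_lte(d, 1)
    expect_equal(d, mean(outer(x, y, ">")) - mean(outer(x, y, "<")),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test and rank-biserial match their definitions", {
  x <- rnorm(8)
  r <- wilcoxon_signed_rank(x + 1, x)   # all differences positive
  expect_equal(r$effect_size, 1)
  r2 <- wilcoxon_signed_rank(x, x + 1)
  expect_equal(r2$effect_size, -1)
  # symmetric construction gives r = 0
  a <- c(1, 2, 3, 4); b <- a + c(0.5, -0.5, 1.5, -1.5)
  expect_equal(rank_biserial(a, b), 0)
  # n = 5 strictly increasing differences: exact p = 2/2^5
  r3 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5) + c(10, 20, 30, 40, 50),
                             c(10, 20, 30, 40, 50))
  expect_equal(r3$p_value, 0.0625, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(a, a), "zero")

  set.seed(7)
  for (i in 1:30) {
    x <- sample(-2:2, 8, replace = TRUE)
    y <- sample(-2:2, 8, replace = TRUE)
    if (all(x == y)) next
    rb <- rank_biserial(x, y)
    expect_gte(rb, -1); expect_lte(rb, 1)
  }
})

test_that("exact enumeration oracles agree with the rank tests for all n <= 8", {
  set.seed(8)
  for (n1 in 3:8) for (n2 in n1:8) {
    x <- rnorm(n1); y <- rnorm(n2)         # continuous -> no ties
    expect_equal(mann_whitney_u(x, y)$p_value, enum_mann_whitney_p(x, y),
                 tolerance = 1e-12, label = paste("MW", n1, n2))
  }
  for (n in 4:8) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, enum_signed_rank_p(x, y),
                 tolerance = 1e-12, label = paste("SR", n))
  }
})

test_that("chi-square independence matches direct computation", {
  # proportional rows: X^2 = 0, p = 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  r <- chi_square_independence(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  # diagonal 2x2: all expected 5, X^2 = 20, df = 1
  r2 <- suppressWarnings(chi_square_independence(rbind(c(10, 0), c(0, 10))))
  expect_equal(r2$statistic, 20, tolerance = 1e-12)
  expect_equal(unname(attr(r2, "expected")[1, 1]), 5)
  expect_error(chi_square_independence(rbind(c(1, 0), c(2, 0))), "marginal")
  expect_error(chi_square_independence(matrix(1:3, 1)), "2x2")
})

test_that("the full group analysis emits the expected battery of tests", {
  set.seed(12)
  mk_rows <- function(g, n, shift) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(subject_id = paste0(g, i), group = g,
                 channel = c("C3", "Cz", "C4", "C3", "Cz", "C4"),
                 band = rep(c("alpha", "beta"), each = 3),
                 eri_db = rnorm(6, shift))
    }))
  }
  eri <- rbind(mk_rows("healthy", 8, -2), mk_rows("control", 8, -1),
               mk_rows("dysphagic", 8, -0.3))
  li <- do.call(rbind, lapply(unique(eri$subject_id), function(s) {
    data.frame(subject_id = s, group = eri$group[eri$subject_id == s][1],
               band = c("alpha", "beta"), li = rnorm(2, 0, 0.2),
               denominator_flag = FALSE)
  }))
  rep <- run_group_analysis(list(eri = eri, li = li))
  expect_equal(nrow(rep$omnibus), 6)        # 3 channels x 2 bands
  expect_equal(nrow(rep$pairwise), 18)      # 3 pairs x 6
  expect_equal(nrow(rep$paired_c3_c4), 6)   # 3 groups x 2 bands
  expect_equal(nrow(rep$li_omnibus), 2)
  expect_equal(nrow(rep$li_pairwise), 6)
  expect_true(all(rep$pairwise$p_value >= 0 & rep$pairwise$p_value <= 1))

  # single-group input: no between-group tests
  rep1 <- run_group_analysis(list(eri = mk_rows("healthy", 8, -2), li = NULL))
  expect_null(rep1$omnibus)
  expect_null(rep1$pairwise)
  expect_equal(nrow(rep1$paired_c3_c4), 2)

  # optional multiplicity correction is exposed
  rep2 <- run_group_analysis(list(eri = eri, li = li), correction = "holm")
  expect_true(all(rep2$pairwise$p_adjusted >= rep2$pairwise$p_value - 1e-15))

  # demographics contingency tables ride along
  demo <- list(gender = rbind(c(11, 10), c(17, 15), c(33, 17)))
  rep3 <- run_group_analysis(list(eri = eri, li = li), demographics = demo)
  expect_equal(rep3$demographics$test, "chi_square_gender")
})
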