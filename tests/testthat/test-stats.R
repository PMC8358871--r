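# Mann-Whitney U and Spearman correlation against enumeration oracles.

test_that("fully separated small samples give U = 0 and exact p = 0.1", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)   # 2 of the 20 rank splits are as extreme
})

test_that("identical samples give p = 1 under symmetric tie handling", {
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$u1, r$u2)
  expect_equal(r$method, "normal_approx")   # ties force the approximation
  expect_equal(r$p_value, 1.0)
})

test_that("U and exact p match the full-enumeration oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1000, n1 + n2)   # tie-free
    a <- x[seq_len(n1)]
    b <- x[-seq_len(n1)]
    got <- mann_whitney_u(a, b)
    want <- oracle_mwu(a, b)
    expect_equal(got$u1, want$u1)
    expect_equal(got$u2, want$u2)
    expect_equal(got$u_statistic, min(want$u1, want$u2))
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("the test is symmetric in its arguments", {
  set.seed(11)
  a <- rnorm(5)
  b <- rnorm(7) + 1
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$u1, r2$u2)
  expect_equal(r1$u2, r2$u1)
  expect_equal(r1$u_statistic, r2$u_statistic)
  expect_error(mann_whitney_u(numeric(0), b), "non-empty")
})

test_that("exact and normal-approximation p agree for n1 = n2 = 6", {
  set.seed(19)
  for (rep in 1:100) {
    x <- sample(10000, 12)
    a <- x[1:6]
    b <- x[7:12]
    pe <- mann_whitney_u(a, b, method = "exact")$p_value
    pn <- mann_whitney_u(a, b, method = "normal_approx")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("Spearman rho matches the rank-difference formula and cor.test", {
  expect_equal(spearman_correlation(1:4, c(2, 1, 4, 3))$rho, 0.6)
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    x <- sample(1000, n)
    y <- sample(1000, n)
    got <- spearman_correlation(x, y)
    expect_equal(got$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(got$r_squared, got$rho^2)
    expect_equal(got$rho,
                 unname(suppressWarnings(
                   cor.test(x, y, method = "spearman")$estimate)),
                 tolerance = 1e-12)
  }
})

test_that("perfect monotone relations report the permutation bound", {
  r <- spearman_correlation(1:6, c(60, 50, 40, 30, 20, 10))
  expect_equal(r$rho, -1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$p_value, 2 / factorial(6))
  # the bound is the exact permutation tail: rho = +/-1 occurs twice in n!
  perms <- do.call(rbind, combinat_perms(4))
  rhos <- apply(perms, 1, function(p) oracle_spearman_rho(1:4, p))
  expect_equal(mean(abs(rhos) >= 1 - 1e-12),
               spearman_correlation(1:4, 4:1)$p_value)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(29)
  x <- runif(12)
  y <- runif(12)
  base <- spearman_correlation(x, y)
  expect_equal(spearman_correlation(exp(3 * x), y)$rho, base$rho)
  expect_equal(spearman_correlation(x, y^3 + 10)$rho, base$rho)
  expect_equal(spearman_correlation(-1 / (x + 1), y)$rho, base$rho)
  expect_error(spearman_correlation(rep(1, 5), y[1:5]), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "n >= 3")
})

test_that("type-I error of the Spearman test is near nominal", {
  set.seed(37)
  rejections <- 0L
  n_rep <- 1000L
  for (i in seq_len(n_rep)) {
    x <- rnorm(20)
    y <- rnorm(20)
    if (spearman_correlation(x, y)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.03)
  expect_lte(rejections / n_rep, 0.07)
})

test_that("cohort analysis wires contrasts and pooling correctly", {
  tab <- data.frame(
    sample_id = sprintf("s%02d", 1:9),
    group = rep(c("control", "MCD", "FSGS"), each = 3),
    mean_ratio = c(0.2, 0.25, 0.3, 0.9, 1.0, 1.1, 0.8, 0.85, 0.95),
    mean_fsd_per_um = c(2.0, 1.9, 1.8, 0.8, 0.7, 0.6, 0.9, 0.85, 0.75),
    stringsAsFactors = FALSE)
  rep_ <- cohort_analysis(tab, contrasts = list("control:MCD",
                                                "control:MCD+FSGS"))
  expect_equal(nrow(rep_$contrasts), 4L)
  pooled <- rep_$contrasts[rep_$contrasts$group_b == "MCD+FSGS", ]
  expect_equal(unique(pooled$n2), 6L)
  expect_lt(rep_$correlation$rho, 0)
  expect_equal(rep_$correlation$n, 9L)
  expect_error(cohort_analysis(tab, contrasts = list("control:nope")),
               "unknown group")
  # single group, no contrasts: correlation only
  solo <- cohort_analysis(tab[tab$group == "MCD", ], contrasts = list())
  expect_equal(nrow(solo$contrasts), 0L)
  expect_false(is.null(solo$correlation))
})
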