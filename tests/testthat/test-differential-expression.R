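test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  # hand evaluation: ranks 1..6, R = (3, 7, 11), no ties:
  # H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 4.571429
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 4.571429, tolerance = 1e-3)

  # independent brute-force evaluation with ties, including the correction
  set.seed(8)
  for (rep in 1:20) {
    groups <- lapply(c(5, 7, 6), function(n) sample(1:8, n, replace = TRUE))
    x <- unlist(groups); N <- length(x); r <- rank(x)
    Ri <- tapply(r, rep(1:3, lengths(groups)), sum)
    H_raw <- 12 / (N * (N + 1)) * sum(Ri^2 / lengths(groups)) - 3 * (N + 1)
    tie <- table(x)
    H_oracle <- H_raw / (1 - sum(tie^3 - tie) / (N^3 - N))
    expect_equal(kruskal_wallis(groups)$H, H_oracle, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid group inputs are handled", {
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5))),
               list(H = 0, p = 1))
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
  expect_error(kruskal_wallis(list(1, 1)), "N >= 3")
})

test_that("two-group H equals the squared standardized rank-sum statistic", {
  set.seed(42)
  for (rep in 1:20) {
    a <- rnorm(6); b <- rnorm(9)
    r <- rank(c(a, b)); n1 <- 6; n2 <- 9; N <- n1 + n2
    z <- (sum(r[1:6]) - n1 * (N + 1) / 2) /
      sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kruskal_wallis(list(a, b))$H, z^2, tolerance = 1e-9)
  }
})

test_that("chi-square p agrees with exhaustive permutation at N = 8", {
  perm_p <- function(a, b) {
    x <- c(a, b)
    idx <- combn(8, length(a))
    H_obs <- kruskal_wallis(list(a, b))$H
    H_all <- apply(idx, 2, function(i)
      kruskal_wallis(list(x[i], x[-i]))$H)
    mean(H_all >= H_obs - 1e-12)
  }
  set.seed(3)
  for (rep in 1:5) {
    x <- sample(100, 8)  # no ties
    a <- x[1:4]; b <- x[5:8]
    p_exact <- perm_p(a, b)
    p_chisq <- kruskal_wallis(list(a, b))$p
    # the chi-square reference is asymptotic and the exact distribution at
    # N = 8 is a step function (jumps of 1/35): agreement is loose in the
    # middle of the range, tight where decisions are made
    expect_lt(abs(p_chisq - p_exact), 0.15)
    if (p_exact <= 0.1) expect_lt(abs(p_chisq - p_exact), 0.05)
  }
})

test_that("Dunn z matches a brute-force rank-mean computation", {
  set.seed(9)
  groups <- list(g1 = c(3.2, 1.1, 7.4), g2 = c(0.5, 2.2, 9.9),
                 g3 = c(4.4, 4.4, 6.1))  # N = 9 with a tie
  dn <- dunns_test(groups)
  x <- unlist(groups); N <- 9; r <- rank(x)
  rbar <- tapply(r, rep(1:3, each = 3), mean)
  tie <- table(x); Tt <- sum(tie^3 - tie)
  v <- N * (N + 1) / 12 - Tt / (12 * (N - 1))
  for (k in 1:3) {
    pair <- list(c(1, 2), c(1, 3), c(2, 3))[[k]]
    z_oracle <- (rbar[pair[1]] - rbar[pair[2]]) / sqrt(v * (2 / 3))
    expect_equal(dn$z[k], unname(z_oracle), tolerance = 1e-9)
    expect_equal(dn$p[k], unname(2 * pnorm(-abs(z_oracle))), tolerance = 1e-9)
  }
  expect_equal(dn$p_adj, pmin(1, dn$p * 3))

  # antisymmetry: swapping the groups negates z, keeps p
  dn_swap <- dunns_test(list(g1 = groups$g2, g2 = groups$g1, g3 = groups$g3))
  expect_equal(dn_swap$z[1], -dn$z[1])
  expect_equal(dn_swap$p[1], dn$p[1])

  # the extreme pair has the largest |z|
  sep <- dunns_test(list(a = c(1, 2, 3), b = c(10, 20, 30),
                         c = c(100, 200, 300)))
  expect_equal(which.max(abs(sep$z)), 2L)  # pair (a, c)
})

test_that("fold differences follow the median/pseudocount closed form", {
  expect_equal(fold_difference(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(fold_difference(c(31, 31), c(7, 7)), 2)  # log2(32/8)
  expect_error(fold_difference(numeric(0), 1:3), "nonempty")
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(adjust_pvalues(0.02), 0.02)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(50)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_equal(order(q[order(p)]), 1:50)  # order-preserving
})

test_that("rank tests are invariant under strictly monotone transforms", {
  co <- default_cohort(seed = 51)
  small <- co$norm
  small$values <- small$values[1:10, ]
  de1 <- run_de(small, co$group)
  small$values <- exp(small$values / max(small$values))
  de2 <- run_de(small, co$group)
  expect_equal(de1$p_kw, de2$p_kw)
  expect_equal(de1$z_fi_vs_nofi, de2$z_fi_vs_nofi)
})

test_that("DE table is structurally complete with valid probabilities", {
  co <- default_cohort(seed = 61)
  de <- run_de(co$norm, co$group)
  expect_equal(nrow(de), 74)
  expect_true(all(de$H >= 0))
  for (col in grep("^(p|q)", names(de), value = TRUE))
    expect_true(all(de[[col]] >= 0 & de[[col]] <= 1))
  expect_true(all(de$q_fi_vs_nofi >= de$p_fi_vs_nofi))
})

test_that("type-I error is controlled on null simulations", {
  # no planted effect: fraction of genes with p < 0.05 near alpha
  empty <- setNames(numeric(0), character(0))
  pvals <- unlist(lapply(1:20, function(s) {
    cfg <- sim_config(eoe_effect = empty, fi_effect = empty, seed = 7000 + s)
    sim <- simulate_counts(cfg)
    norm <- normalize_lanes(sim$counts)
    run_de(norm, factor(sim$truth$group,
                        levels = c("Control", "EoE_no_FI", "EoE_FI")))$p_kw
  }))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
})

test_that("planted FI genes dominate the FI contrast ranking", {
  planted <- names(default_fi_effect())
  hits <- vapply(1:20, function(s) {
    co <- default_cohort(seed = 8000 + s)
    de <- run_de(co$norm, co$group)
    top12 <- de$gene[order(-abs(de$z_fi_vs_nofi))][1:12]
    all(planted %in% top12)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted fold difference is recovered at large n", {
  cfg <- sim_config(n_control = 4, n_eoe_nofi = 100, n_eoe_fi = 100,
                    lane_scale_sd = 0, seed = 77)
  sim <- simulate_counts(cfg)
  norm <- normalize_lanes(sim$counts)
  grp <- factor(sim$truth$group, levels = c("Control", "EoE_no_FI", "EoE_FI"))
  fd <- fold_difference(norm$values["CPA3", grp == "EoE_FI"],
                        norm$values["CPA3", grp == "EoE_no_FI"])
  expect_lt(abs(fd - log2(0.3)), 0.25)
})
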