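fake_de <- function(genes, fd, q) {
  structure(data.frame(gene = genes, log2fd_fi_vs_nofi = fd,
                       q_fi_vs_nofi = q, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

test_that("transcript weights follow the fold x significance product", {
  # gene failing the alpha gate gets weight zero
  de <- fake_de(c("A", "B"), c(2, -1), c(0.2, 0.01))
  w <- compute_transcript_weights(de, alpha = 0.05)
  expect_equal(unname(w$weights["A"]), 0)
  # single passing gene: raw weight -1 * (-log10 0.01) = -2, L1-normalized -1
  expect_equal(unname(w$weights["B"]), -1)
  expect_equal(w$norm_const, 2)

  # L1 normalization with signs preserved
  de2 <- fake_de(c("A", "B", "C"), c(1, -2, 0.5), c(0.01, 0.001, 0.2))
  w2 <- compute_transcript_weights(de2)$weights
  expect_equal(sum(abs(w2)), 1)
  expect_true(w2[["A"]] > 0 && w2[["B"]] < 0 && w2[["C"]] == 0)

  expect_error(compute_transcript_weights(fake_de("A", 1, 0.9)),
               "empty signature")
})

test_that("raw score is the weighted sum of cohort z-scores", {
  co <- default_cohort(seed = 71)
  fi <- fi_signature(co$norm, co$group)
  cohort <- names(fi$raw)
  expr <- log_expression(co$norm)[, cohort]
  w <- fi$weights$weights

  # direct recomputation
  z <- t(apply(expr, 1, function(v) (v - mean(v)) / ifelse(sd(v) == 0, 1, sd(v))))
  expect_equal(unname(colSums(w[rownames(z)] * z)), unname(fi$raw),
               tolerance = 1e-12)

  # linearity: two patients differing only in one weighted gene
  g <- names(which(w != 0))[1]
  norm3 <- co$norm
  twin <- co$norm$values[, cohort[1]]
  twin[g] <- co$norm$values[g, cohort[2]]
  norm3$values <- cbind(co$norm$values[, cohort], TWIN = twin)
  sc3 <- compute_raw_fi_score(norm3, fi$weights, c(cohort, "TWIN"))
  z3 <- t(apply(log_expression(norm3), 1,
                function(v) (v - mean(v)) / sd(v)))
  expect_equal(unname(sc3[["TWIN"]] - sc3[[cohort[1]]]),
               unname(w[g] * (z3[g, "TWIN"] - z3[g, cohort[1]])),
               tolerance = 1e-12)

  # a patient at every gene's cohort mean scores zero
  mu_patient <- rowMeans(expr)
  norm2 <- co$norm
  norm2$values <- cbind(co$norm$values, AVG = 2^mu_patient - 1)
  sc <- compute_raw_fi_score(norm2, fi$weights, c(cohort, "AVG"))
  # the augmented cohort mean equals the old mean, so z = 0 exactly
  expect_equal(sc[["AVG"]], 0, tolerance = 1e-9)

  expect_error(compute_raw_fi_score(co$norm, fi$weights, cohort[1:2]),
               ">= 3")
})

test_that("all-zero weights give all-zero scores", {
  co <- default_cohort(seed = 72)
  w <- structure(list(weights = setNames(rep(0, 74),
                                         rownames(co$norm$values)),
                      alpha = 0.05, norm_const = 0),
                 class = "transcript_weights")
  cohort <- colnames(co$norm$values)[co$group != "Control"]
  expect_equal(unname(compute_raw_fi_score(co$norm, w, cohort)),
               rep(0, length(cohort)))
})

test_that("standardization is exact, affine-invariant, and guarded", {
  s <- standardize_scores(c(-1, 0, 1))
  expect_equal(s, c(-1, 0, 1))  # sd(ddof=1) of {-1,0,1} is 1
  set.seed(2)
  x <- rnorm(20)
  expect_equal(standardize_scores(3 * x + 7), standardize_scores(x))
  out <- standardize_scores(x)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sd(out), 1, tolerance = 1e-12)
  expect_error(standardize_scores(c(1, 1, 1)), "degenerate")
  expect_error(standardize_scores(c(1, 2)), ">= 3")
})

test_that("calls threshold at >= cutoff and respect the sign symmetry", {
  expect_true(call_fi(0.04, 0.03))
  expect_true(call_fi(0.03, 0.03))   # boundary is positive
  expect_false(call_fi(0.029, 0.03))
  expect_error(call_fi(1, Inf), "finite")

  co <- default_cohort(seed = 73)
  fi <- fi_signature(co$norm, co$group)
  flipped <- call_fi(-fi$standardized, -fi$cutoff)
  # score equal to the cutoff maps to positive on both sides; exclude ties
  ties <- fi$standardized == fi$cutoff
  expect_equal(flipped[!ties], !fi$calls[!ties])
})

test_that("score is invariant to per-gene affine rescaling of expression", {
  co <- default_cohort(seed = 74)
  fi1 <- fi_signature(co$norm, co$group)
  norm2 <- co$norm
  # rescale each gene's log-expression: absorbed by per-gene standardization
  expr <- log_expression(co$norm)
  scaled <- 2^(sweep(sweep(expr, 1, runif(nrow(expr), 1, 2), `*`),
                     1, runif(nrow(expr), 0, 3), `+`)) - 1
  norm2$values <- scaled
  sc2 <- compute_raw_fi_score(norm2, fi1$weights, names(fi1$raw))
  # weights fixed; z-scores unchanged by the per-gene affine map
  expect_equal(standardize_scores(sc2), standardize_scores(fi1$raw),
               tolerance = 1e-9)
})

test_that("in-sample discrimination is high on planted cohorts", {
  res <- vapply(1:50, function(s) {
    co <- default_cohort(seed = 9000 + s)
    fi <- tryCatch(fi_signature(co$norm, co$group),
                   error = function(e) NULL)
    if (is.null(fi)) return(c(auc = NA_real_, neg = NA_real_))
    planted <- names(default_fi_effect())
    c(auc = fi$roc$auc,
      neg = as.numeric(all(fi$weights$weights[planted] < 0)))
  }, numeric(2))
  expect_gte(mean(res["auc", ] >= 0.90, na.rm = FALSE), 0.9)
  expect_gte(mean(res["neg", ]), 0.9)
})

test_that("permuting FI labels destroys discrimination", {
  co <- default_cohort(seed = 75)
  set.seed(99)
  aucs <- vapply(1:50, function(i) {
    grp <- co$group
    eoe <- grp != "Control"
    grp[eoe] <- sample(grp[eoe])  # permute FI status within EoE
    tryCatch(fi_signature(co$norm, grp)$roc$auc,
             # no surviving signature means no classifier: chance level
             error = function(e) 0.5)
  }, numeric(1))
  expect_gte(median(aucs), 0.35)
  expect_lte(median(aucs), 0.65)
})

test_that("leave-one-out discrimination does not exceed in-sample", {
  aucs <- vapply(1:5, function(s) {
    co <- default_cohort(seed = 9500 + s)
    c(loo_fi_scores(co$norm, co$group)$auc,
      fi_signature(co$norm, co$group)$roc$auc)
  }, numeric(2))
  expect_lte(mean(aucs[1, ]), mean(aucs[2, ]) + 1e-9)
})
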