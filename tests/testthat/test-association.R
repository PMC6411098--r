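test_that("rank-sum comparison matches exact small-sample p-values", {
  r <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)  # 2/choose(6,3) per tail
  expect_equal(rank_sum_compare(c(4, 5, 6), c(1, 2, 3))$p, 0.1)  # symmetry
  expect_equal(rank_sum_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(rank_sum_compare(numeric(), 1:3), "at least one")
})

test_that("spearman correlation equals rank-then-Pearson with t p-value", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  r <- spearman_corr(x, y)
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(r$rho, rho_oracle)
  t_oracle <- rho_oracle * sqrt((6 - 2) / (1 - rho_oracle^2))
  expect_equal(r$p, 2 * pt(abs(t_oracle), 4, lower.tail = FALSE))
  # rho and the t-approximation p also match cor.test's asymptotic branch
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(r$rho, unname(ct$estimate))

  expect_equal(spearman_corr(1:10, exp(1:10))$rho, 1)   # monotone transform
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  expect_error(spearman_corr(1:3, 3:1), "4 complete pairs")
  expect_error(spearman_corr(1:5, rep(2, 5)), "zero variance")
  # incomplete pairs dropped
  expect_equal(spearman_corr(c(1:5, NA), c(5:1, 3))$n, 5L)
})

test_that("the Williams dependent-correlation test follows its formula", {
  # equal correlations: no evidence either way
  r0 <- dependent_correlation_test(0.4, 0.4, 0.2, 50)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # antisymmetry under swapping the two compared correlations
  a <- dependent_correlation_test(0.5, 0.2, 0.3, 103)
  b <- dependent_correlation_test(0.2, 0.5, 0.3, 103)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # frozen value of the closed form at (0.5, 0.2, 0.3, 103)
  expect_equal(a$t, 2.889640757, tolerance = 1e-8)
  expect_equal(a$p, 0.004729834285, tolerance = 1e-8)
  expect_error(dependent_correlation_test(1, 0.2, 0.3, 50), "strictly")
  expect_error(dependent_correlation_test(0.9, -0.9, 0.9, 50), "inconsistent")
})

test_that("linear model fits match the normal-equations solution", {
  set.seed(11)
  d <- data.frame(x1 = rnorm(20), x2 = runif(20))
  d$y <- 2 + 1.5 * d$x1 - 3 * d$x2 + rnorm(20, 0, 0.3)
  fit <- fit_linear_model(d, "y", c(x1 = "numeric", x2 = "numeric"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(fit$estimate, beta[2:3, 1], ignore_attr = TRUE)
  expect_equal(attr(fit, "n_used"), 20L)
  # permuting rows changes nothing
  fit2 <- fit_linear_model(d[sample(20), ], "y",
                           c(x1 = "numeric", x2 = "numeric"))
  expect_equal(fit2$estimate, fit$estimate)
  # exact linear response recovers the slope with zero residual
  d2 <- data.frame(x = 1:10, y = 3 * (1:10) - 1)
  f2 <- suppressWarnings(fit_linear_model(d2, "y", c(x = "numeric")))
  expect_equal(f2$estimate, 3)
  # z-scored covariate rescales the coefficient by sd(x)
  f3 <- suppressWarnings(fit_linear_model(d2, "y", c(x = "z_scored_numeric")))
  expect_equal(f3$estimate, 3 * sd(d2$x))
  # rank deficiency errors and names the offender
  d$x3 <- d$x1
  expect_error(fit_linear_model(d, "y", c(x1 = "numeric", x3 = "numeric")),
               "x3")
  expect_error(fit_linear_model(d, "y", c(y = "numeric")), "response")
})

test_that("variance inflation follows 1/(1-R^2)", {
  set.seed(12)
  z1 <- scale(rnorm(50))[, 1]
  z2 <- scale(resid(lm(rnorm(50) ~ z1)))[, 1]
  d <- data.frame(a = z1, b = 0.6 * z1 + sqrt(1 - 0.36) * z2)
  v <- variance_inflation(d, c("a", "b"))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2))  # = 1.5625
  # orthogonal covariates: VIF 1; duplicated covariate: infinite
  d2 <- data.frame(a = z1, b = z2)
  expect_equal(unname(variance_inflation(d2, c("a", "b"))), c(1, 1))
  d3 <- data.frame(a = z1, b = z1)
  expect_true(all(is.infinite(suppressWarnings(
    variance_inflation(d3, c("a", "b"))))))
  if (requireNamespace("car", quietly = TRUE)) {
    d4 <- data.frame(a = z1, b = d$b, c = runif(50))
    d4$y <- rnorm(50)
    expect_equal(unname(variance_inflation(d4, c("a", "b", "c"))),
                 unname(car::vif(lm(y ~ a + b + c, data = d4))),
                 tolerance = 1e-8)
  }
})

test_that("feature scan filters, adjusts and matches rank-sum direction", {
  set.seed(13)
  n <- 60
  score <- setNames(rnorm(n), sprintf("s%d", 1:n))
  feats <- rbind(on = rep(1L, n),                      # constant: dropped
                 rare = c(rep(1L, 3), rep(0L, n - 3)), # below filter
                 real = rbinom(n, 1, 0.5))
  colnames(feats) <- names(score)
  score <- score + 1.2 * feats["real", ]
  res <- feature_scan(score, feats, min_positive = 10)
  expect_equal(res$feature, "real")
  expect_true(res$estimate > 0 && res$p < 0.01)
  expect_equal(attr(res, "filter"), "min 10 positive samples")
  # unadjusted scan direction agrees with the rank-sum comparison
  rs <- rank_sum_compare(score[feats["real", ] == 1],
                         score[feats["real", ] == 0])
  expect_true(rs$p < 0.05)
  expect_warning(empty <- feature_scan(score, feats, min_positive = n + 1),
                 "no feature")
  expect_equal(nrow(empty), 0L)
  expect_error(feature_scan(score, feats, min_positive = 0), ">= 1")
})

test_that("arm scan labels direction by where the high scores sit", {
  set.seed(14)
  n <- 120
  ids <- sprintf("s%d", 1:n)
  z <- rnorm(n)
  del_prob <- plogis(-1 + 1.5 * z)
  calls_pos <- rbind(armA = ifelse(runif(n) < del_prob, -1L,
                                   ifelse(runif(n) < 0.1, 1L, 0L)))
  colnames(calls_pos) <- ids
  score <- setNames(2 * z + rnorm(n, 0, 0.5), ids)
  res <- arm_scan(score, calls_pos)
  expect_equal(res$direction_label, "deletion-high")
  expect_true(res$p < 0.01)
  # flipped coupling: deleted samples now carry LOW scores
  res2 <- arm_scan(-score, calls_pos)
  expect_equal(res2$direction_label, "amplification-high")
  # single-level arm is skipped with a warning
  calls1 <- rbind(flat = rep(0L, n)); colnames(calls1) <- ids
  expect_warning(r1 <- arm_scan(score, calls1), "single call level")
  expect_equal(nrow(r1), 0L)
})

test_that("matched-normal arm test rejects contaminated normals and groups", {
  set.seed(15)
  nn <- 40
  ids <- sprintf("n%d", 1:nn)
  scores <- setNames(rnorm(nn), ids)
  own <- matrix(0L, 1, nn, dimnames = list("5q", ids))
  tum <- matrix(rep(c(-1L, 0L), each = nn / 2), 1, nn,
                dimnames = list("5q", ids))
  res <- matched_normal_arm_test(scores, own, tum)
  expect_equal(res$arm, "5q")
  expect_equal(res$n_deleted, nn / 2)
  expect_true(res$p >= 0 && res$p <= 1)
  own2 <- own; own2[1, 1] <- -1L
  expect_error(matched_normal_arm_test(scores, own2, tum), "excluded")
  tum_small <- tum; tum_small[1, 3:nn] <- 0L
  expect_warning(r2 <- matched_normal_arm_test(scores, own, tum_small),
                 "fewer than 3")
  expect_true(is.na(r2$p))
})

test_that("auxiliary tests behave on degenerate and balanced inputs", {
  set.seed(16)
  # balanced amplification/deletion counts give a direction-free zero
  expect_equal(amplification_deletion_balance(10, 10), 0)
  expect_true(amplification_deletion_balance(30, 5) > 0)
  expect_true(amplification_deletion_balance(5, 30) < 0)
  expect_error(amplification_deletion_balance(0, 0), "no alterations")
  # fligner on equal-variance groups: non-degenerate p
  v <- rnorm(60); g <- rep(c("a", "b", "c"), 20)
  expect_true(fligner_variance_test(v, g)$p > 0)
  expect_error(fligner_variance_test(v[1:3], c("a", "a", "b")), "two or more")
  # two-way anova interaction p on a no-interaction design
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:10)
  y <- rnorm(nrow(d)) + as.numeric(d$a == "x")
  expect_true(interaction_anova(y, d$a, d$b) > 0)
  expect_error(interaction_anova(y, rep("x", nrow(d)), d$b), "two levels")
})

test_that("signature contribution scan adjusts for instability covariates", {
  set.seed(17)
  n <- 150
  ids <- sprintf("s%d", 1:n)
  z <- rnorm(n)
  score <- setNames(2 * z + rnorm(n, 0, 0.5), ids)
  inst <- data.frame(aneuploidy = z + rnorm(n), burden = z + rnorm(n),
                     cna = z + rnorm(n), clones = z + rnorm(n),
                     row.names = ids)
  contrib <- rbind(coupled = plogis(z + rnorm(n, 0, 0.5)),
                   noise = runif(n),
                   flat = rep(0.2, n))
  colnames(contrib) <- ids
  res <- signature_contribution_scan(score, contrib, inst)
  expect_setequal(res$feature, c("coupled", "noise"))  # flat skipped
  expect_true(res$estimate[res$feature == "coupled"] > 0)
  expect_equal(res$q, bh_adjust(res$p))
})

test_that("association-profile clustering is deterministic and exact on 3 rows", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(3, 4, 0))
  cl <- cluster_association_profiles(m)
  # identical rows merge first at height zero
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(sort(cl$hclust$labels[-cl$hclust$merge[1, ]]), c("a", "b"))
  # complete linkage height of the final merge = max pairwise distance
  expect_equal(cl$hclust$height[2], 5)
  # row permutation leaves topology and leaf order unchanged
  cl2 <- cluster_association_profiles(m[c(3, 1, 2), ])
  expect_equal(cl2$order, cl$order)
  expect_equal(cl2$hclust$height, cl$hclust$height)
  expect_error(cluster_association_profiles(m[1, , drop = FALSE]), "2 rows")
  expect_error(cluster_association_profiles(rbind(a = c(1, Inf), b = c(0, 0))),
               "finite")
})
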