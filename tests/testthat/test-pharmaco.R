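test_that("compound filtering uses a strict missingness threshold", {
  auc <- matrix(rnorm(50), 5, 10,
                dimnames = list(sprintf("c%d", 1:5), sprintf("l%d", 1:10)))
  auc[1, 1:3] <- NA   # 30% missing: dropped
  auc[2, 1:2] <- NA   # exactly 20%: retained
  filt <- filter_compounds(auc)
  expect_setequal(rownames(filt), c("c2", "c3", "c4", "c5"))
  expect_equal(attr(filt, "removed"), "c1")
  expect_error(filter_compounds(auc[1, , drop = FALSE]), "every compound")
})

test_that("sensitivity scan finds planted compounds with negative rho", {
  p <- generate_cellline_panel(n_cell_lines = 120, n_compounds = 12,
                               n_perturbations = 12,
                               sensitive_compounds = 1:3, delta = 1,
                               seed = 41)
  res <- sensitivity_scan(p$cellline_scores, p$auc)
  hit <- res[res$feature %in% p$sensitive_compounds, ]
  expect_true(all(hit$estimate < 0 & hit$q < 0.05))
  expect_equal(res$q, bh_adjust(res$p))
  # rho is antisymmetric under an AUC sign flip
  res2 <- sensitivity_scan(p$cellline_scores, -p$auc)
  expect_equal(res2$estimate, -res$estimate)
  expect_equal(res2$p, res$p)
  # compounds with too few complete pairs are skipped with a warning
  auc3 <- p$auc; auc3[1, -(1:3)] <- NA
  expect_warning(res3 <- sensitivity_scan(p$cellline_scores, auc3),
                 "complete pairs")
  expect_false(p$id_map$compound[1] %in% res3$feature)
})

test_that("permutation Q-Q envelope is seeded, monotone and covers the null", {
  p <- generate_cellline_panel(n_cell_lines = 60, n_compounds = 40,
                               n_perturbations = 10, delta = 0, seed = 42)
  qq <- permutation_qq(p$cellline_scores, p$auc, n_perm = 100, seed = 9)
  expect_equal(qq, permutation_qq(p$cellline_scores, p$auc, n_perm = 100,
                                  seed = 9))  # bit-identical rerun
  expect_false(is.unsorted(qq$expected))
  expect_false(is.unsorted(qq$observed))
  # null observed quantiles track the permutation expectation (the formal
  # slope criterion is checked at full panel size in the acceptance suite)
  expect_gt(cor(qq$observed, qq$expected), 0.9)
  expect_lt(abs(median(qq$observed - qq$expected)), 0.2)
  expect_error(permutation_qq(p$cellline_scores, p$auc, n_perm = 1, seed = 1),
               "at least 2")
  # missing-data path agrees with the complete-panel fast path in structure
  auc_na <- p$auc; auc_na[1, 1:5] <- NA
  qq_na <- permutation_qq(p$cellline_scores, auc_na, n_perm = 20, seed = 3)
  expect_equal(nrow(qq_na), nrow(p$auc))
})

test_that("connectivity averaging is the arithmetic mean over profiled lines", {
  conn <- rbind(allneg = rep(-100, 9),
                mixed = c(100, -100, rep(NA, 7)),
                nine = c(12, -40, 7, 88, -2, 0, -66, 30, 5))
  colnames(conn) <- sprintf("cl%d", 1:9)
  avg <- average_connectivity(conn)
  expect_equal(avg$average_score,
               c(-100, 0, sum(c(12, -40, 7, 88, -2, 0, -66, 30, 5)) / 9))
  expect_equal(avg$n_cell_lines, c(9L, 2L, 9L))
  conn2 <- rbind(conn, empty = rep(NA_real_, 9))
  expect_error(average_connectivity(conn2), "empty")
  expect_error(average_connectivity(conn * 2), "\\[-100, 100\\]")
})

test_that("integration joins datasets and applies the candidate rule", {
  sens <- association_table(c("c1", "c2", "c3", "c4"),
                            c(-0.5, -0.4, 0.1, 0.3),
                            c(0.001, 0.002, 0.9, 0.4), rep(100L, 4))
  avg <- data.frame(perturbation = c("p1", "p2", "p3", "p4"),
                    average_score = c(-95, -50, -99, 20))
  map <- data.frame(compound = c("c1", "c2", "c3", "c4"),
                    perturbation = c("p1", "p2", "p3", "p4"))
  res <- integrate_ctrp_cmap(sens, avg, map)
  expect_equal(res$n, 4L)
  tab <- res$table
  expect_true(tab$candidate[tab$compound == "c1"])    # q<0.05 & score<-90
  expect_false(tab$candidate[tab$compound == "c2"])   # score too high
  expect_false(tab$candidate[tab$compound == "c3"])   # not significant
  # the rule is a pure function of (q, average_score)
  expect_equal(tab$candidate,
               tab$q < 0.05 & tab$average_score < -90)
  expect_error(integrate_ctrp_cmap(sens, avg,
                                   data.frame(compound = "zz",
                                              perturbation = "pz")),
               "no compound shared")
})

test_that("planted compounds drive sensitivity and connectivity jointly", {
  p <- generate_cellline_panel(n_cell_lines = 150, n_compounds = 20,
                               n_perturbations = 20,
                               sensitive_compounds = 1:5, delta = 1,
                               seed = 44)
  sens <- sensitivity_scan(p$cellline_scores, p$auc)
  avg <- average_connectivity(p$connectivity)
  res <- integrate_ctrp_cmap(sens, avg, p$id_map)
  expect_true(res$rho > 0)   # both analyses rank the same compounds low
  expect_setequal(res$table$compound[res$table$candidate],
                  p$sensitive_compounds)
})

test_that("target-proliferation associations recover planted coupling", {
  set.seed(45)
  n <- 100
  ids <- sprintf("s%d", 1:n)
  prolif <- setNames(runif(n, 0.01, 0.05), ids)
  cohort <- setNames(rep(c("A", "B"), n / 2), ids)
  expr <- rbind(coupled = 50 * prolif + rnorm(n, 0, 0.2),
                flat = rnorm(n))
  colnames(expr) <- ids
  map <- data.frame(compound = c("d1", "d2", "d3"),
                    target = c("coupled", "flat", NA))
  res <- target_proliferation_assoc(expr, prolif, cohort, map)
  expect_equal(res$compound, c("d1", "d2", "d3"))
  r1 <- res[res$compound == "d1", ]
  expect_true(r1$estimate > 0 && r1$p < 0.01)
  expect_true(res$p[res$compound == "d2"] > 0.01)
  expect_true(is.na(res$estimate[res$compound == "d3"]))
})
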