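test_that("threshold eligibility uses a closed boundary and validates names", {
  st <- random_score_table(50, c("muscle", "goblet"), seed = 2)
  st$auc[1, "muscle"] <- 0.42
  thr <- c(muscle = 0.42, goblet = 0.9)
  elig <- apply_thresholds(st, thr)
  expect_true(elig[1, "muscle"])  # exactly at threshold -> eligible
  expect_identical(elig, st$auc >= rep(thr[colnames(st$auc)],
                                       each = nrow(st$auc)))
  # impossible thresholds exclude everyone (validated to [0,1])
  expect_error(apply_thresholds(st, c(muscle = 1.01, goblet = 1.01)), "0, 1|\\[0, 1\\]")
  none <- apply_thresholds(st, c(muscle = 1, goblet = 1))
  expect_true(sum(none) <= sum(st$auc == 1))
  expect_error(apply_thresholds(st, c(muscle = 0.5)), "goblet")
  expect_warning(apply_thresholds(st, c(muscle = .5, goblet = .5, x = .5)),
                 "unscored")
})

test_that("disambiguation picks the highest quantile, then z, then lexical order", {
  # constructed 100-cell table: cell 1 at quantile 0.99 for muscle, 0.80 goblet
  n <- 100
  auc <- cbind(muscle = seq(0, 0.98, length.out = n),
               goblet = seq(0, 0.98, length.out = n))
  auc[1, "muscle"] <- 0.995   # above all but none -> quantile 0.99
  auc[1, "goblet"] <- auc[order(auc[, "goblet"])[81], "goblet"] - 1e-9
  rownames(auc) <- sprintf("c%03d", 1:n)
  st <- structure(list(auc = auc, z = NULL, top_fraction = 0.05,
                       n_genes = 100L, n_s = c(muscle = 5L, goblet = 5L),
                       tie_seed = 1L), class = "score_table")
  st <- standardize_scores(st)
  elig <- matrix(FALSE, n, 2, dimnames = dimnames(auc))
  elig[1, ] <- TRUE
  res <- disambiguate_calls(st, elig)
  expect_identical(res$calls$label[1], "muscle")
  expect_identical(unique(res$calls$label[-1]), "unassigned")

  # equal quantiles -> larger z wins
  set.seed(17)
  auc2 <- cbind(hi_z = c(0.9, runif(8, 0.1, 0.5), 0.05),
                lo_z = c(0.9, runif(8, 0.80, 0.89), 0.05))
  rownames(auc2) <- sprintf("c%02d", 1:10)
  st2 <- structure(list(auc = auc2, z = NULL, top_fraction = 0.05,
                        n_genes = 100L, n_s = c(hi_z = 5L, lo_z = 5L),
                        tie_seed = 1L), class = "score_table")
  st2 <- standardize_scores(st2)
  stopifnot(st2$z[1, "hi_z"] > st2$z[1, "lo_z"])
  elig2 <- matrix(FALSE, 10, 2, dimnames = dimnames(auc2))
  elig2[1, ] <- TRUE
  expect_identical(disambiguate_calls(st2, elig2)$calls$label[1], "hi_z")

  # exact ties on both criteria fall back to lexical order, with a warning
  auc3 <- cbind(b_sig = c(0.5, 0.1), a_sig = c(0.5, 0.1))
  rownames(auc3) <- c("c1", "c2")
  st3 <- structure(list(auc = auc3, z = NULL, top_fraction = 0.05,
                        n_genes = 100L, n_s = c(b_sig = 5L, a_sig = 5L),
                        tie_seed = 1L), class = "score_table")
  st3 <- standardize_scores(st3)
  elig3 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2,
                  dimnames = dimnames(auc3))
  expect_warning(res3 <- disambiguate_calls(st3, elig3), "lexical")
  expect_identical(res3$calls$label[1], "a_sig")
})

test_that("eligibility agrees with an elementwise comparison oracle on random tables", {
  set.seed(31)
  for (rep in 1:5) {
    st <- random_score_table(40, c("s1", "s2", "s3"), seed = rep)
    thr <- setNames(runif(3), c("s1", "s2", "s3"))
    elig <- apply_thresholds(st, thr)
    for (s in colnames(st$auc))
      expect_identical(unname(elig[, s]), unname(st$auc[, s] >= thr[s]))
    res <- disambiguate_calls(st, elig)
    expect_identical(nrow(res$calls), 40L)
    expect_true(all(res$calls$label %in% c(colnames(st$auc), "unassigned")))
    # every cell gets exactly one label; unassigned iff no eligibility
    expect_identical(res$calls$label == "unassigned",
                     unname(rowSums(elig) == 0))
  }
})

test_that("merging collapses groups, conserves counts, and rejects overlap", {
  st <- random_score_table(60, c("Tuft1", "Tuft2", "Skin_basal"), seed = 4)
  elig <- apply_thresholds(st, c(Tuft1 = 0.5, Tuft2 = 0.5, Skin_basal = 0.5))
  res <- disambiguate_calls(st, elig)
  merged <- merge_signatures(res, list(Tuft = c("Tuft1", "Tuft2")))
  expect_false(any(merged$calls$label %in% c("Tuft1", "Tuft2")))
  expect_identical(sum(merged$calls$label == "Tuft"),
                   sum(res$calls$label %in% c("Tuft1", "Tuft2")))
  expect_identical(nrow(merged$calls), nrow(res$calls))
  expect_identical(merge_signatures(res, list()), res)
  expect_error(merge_signatures(res, list(A = "Tuft1", B = "Tuft1")),
               "overlap")
})

test_that("detectable-expression proportion carries a Wilson interval", {
  cnt <- matrix(c(rep(1, 7), rep(0, 3)), 10, 1,
                dimnames = list(paste0("c", 1:10), "Foxn1"))
  out <- expression_proportion(cnt, paste0("c", 1:10), "Foxn1")
  expect_equal(out$proportion, 0.7)
  expect_equal(out$lower, 0.3968, tolerance = 1e-3)
  expect_equal(out$upper, 0.8922, tolerance = 1e-3)
  zero <- expression_proportion(cnt, paste0("c", 8:10), "Foxn1")
  expect_equal(zero$proportion, 0)
  expect_equal(zero$lower, 0)
  expect_error(expression_proportion(cnt, character(0), "Foxn1"), "empty")
  expect_error(expression_proportion(cnt, "c1", "Aire"), "not in matrix")
})
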