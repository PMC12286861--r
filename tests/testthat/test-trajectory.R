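# path-graph connectivity matrix with unit edge weights
path_graph <- function(n) {
  C <- matrix(0, n, n, dimnames = list(as.character(1:n), as.character(1:n)))
  for (i in seq_len(n - 1)) { C[i, i + 1] <- 1; C[i + 1, i] <- 1 }
  as_neighbor_graph(C)
}

test_that("diffusion pseudotime is zero at the root and ordered along a path", {
  g <- path_graph(30)
  pt <- diffusion_pseudotime(g, root = "1", n_comps = 29)
  expect_equal(unname(pt$t["1"]), 0)
  expect_true(all(diff(pt$t) > 0))  # strictly increasing along the path
  # symmetric roots give mirrored pseudotimes
  pt_a <- diffusion_pseudotime(g, root = "1", n_comps = 29)
  pt_b <- diffusion_pseudotime(g, root = "30", n_comps = 29)
  expect_equal(unname(pt_a$t), unname(rev(pt_b$t)), tolerance = 1e-8)
  # disconnected graphs are rejected with the unreachable cells named
  C <- matrix(0, 4, 4); C[1, 2] <- C[2, 1] <- 1; C[3, 4] <- C[4, 3] <- 1
  expect_error(diffusion_pseudotime(as_neighbor_graph(C), root = 1),
               "unreachable")
})

test_that("combined kernel mixes pseudotime direction with connectivity", {
  g <- path_graph(10)
  t <- setNames(as.numeric(1:10), as.character(1:10))
  # lambda = 0 reduces to the row-normalized connectivity kernel
  k0 <- build_combined_kernel(g, t, lambda_ = 0)
  P_conn <- g$c / rowSums(g$c)
  expect_equal(unname(k0$P), unname(P_conn), tolerance = 1e-12)
  # rows always sum to 1
  for (lam in c(0, 0.5, 0.8, 1)) {
    k <- build_combined_kernel(g, t, lambda_ = lam)
    expect_lt(max(abs(rowSums(k$P) - 1)), 1e-9)
    expect_true(all(k$P >= 0))
  }
  # kappa -> infinity: backward mass vanishes, forward dominates moves
  kinf <- build_combined_kernel(g, t, lambda_ = 1, kappa = 1e3)
  expect_lt(kinf$P["5", "4"], 1e-6)           # backward -> 0
  expect_gt(kinf$P["5", "6"], kinf$P["5", "4"])  # forward dominant
  # auto kappa is recorded and positive
  ka <- build_combined_kernel(g, t)
  expect_gt(ka$kappa, 0)
  expect_equal(ka$lambda, 0.8)
  # random-graph rows also sum to 1
  set.seed(8)
  emb <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(sprintf("c%02d", 1:60), NULL))
  gr <- knn_graph(emb, k = 6)
  tr <- setNames(runif(60), rownames(emb))
  kr <- build_combined_kernel(gr, tr)
  expect_lt(max(abs(rowSums(kr$P) - 1)), 1e-9)
})

test_that("terminal selection takes the top-AUC cells and rejects overlap", {
  st <- random_score_table(100, c("muscle", "goblet"), seed = 6)
  sel <- select_terminal_cells(st, c("muscle", "goblet"), n_per = 5)
  expect_identical(nrow(sel), 10L)
  for (p in c("muscle", "goblet")) {
    picked <- sel$cell[sel$population == p]
    expect_setequal(picked,
                    rownames(st$auc)[order(st$auc[, p],
                                           decreasing = TRUE)[1:5]])
  }
  # n_per = 1 picks the argmax cell
  sel1 <- select_terminal_cells(st, c("muscle",  "goblet"), n_per = 1)
  expect_identical(sel1$cell[1], rownames(st$auc)[which.max(st$auc[, "muscle"])])
  # shared top cell across populations is an error
  st2 <- st
  st2$auc[, "goblet"] <- st2$auc[, "muscle"]
  expect_error(select_terminal_cells(st2, c("muscle", "goblet"), n_per = 5),
               "overlap")
})

test_that("absorption probabilities reproduce the gambler's-ruin closed form", {
  # symmetric walk on 11 nodes with absorbing ends: P(right | i) = i/10
  C <- matrix(0, 11, 11, dimnames = list(as.character(0:10), as.character(0:10)))
  for (i in 1:10) { C[i, i + 1] <- 1; C[i + 1, i] <- 1 }
  P <- C / rowSums(C)
  kern <- structure(list(P = P, lambda = 0, kappa = 1),
                    class = "transition_kernel")
  terms <- data.frame(cell = c("0", "10"), population = c("left", "right"))
  fate <- absorption_probabilities(kern, terms)
  expect_lt(max(abs(fate[, "right"] - (0:10) / 10)), 1e-8)
  expect_lt(max(abs(rowSums(fate) - 1)), 1e-6)
  # a terminal population's own cells have probability 1 for it
  expect_equal(unname(fate["10", "right"]), 1)
  # random kernels: rows sum to one whenever absorption is certain
  set.seed(12)
  emb <- matrix(rnorm(50 * 2), 50, 2,
                dimnames = list(sprintf("c%02d", 1:50), NULL))
  g <- knn_graph(emb, k = 5)
  tr <- setNames(runif(50), rownames(emb))
  k <- build_combined_kernel(g, tr)
  tcells <- data.frame(cell = rownames(emb)[1:6],
                       population = rep(c("a", "b"), 3))
  f2 <- absorption_probabilities(k, tcells)
  expect_lt(max(abs(rowSums(f2) - 1)), 1e-6)
})

test_that("fate overlap follows Jaccard set arithmetic", {
  F <- cbind(a = c(0.9, 0.8, 0.1, 0), b = c(0.1, 0.8, 0.9, 0))
  rownames(F) <- paste0("c", 1:4)
  # threshold 0.5: A = {c1, c2}, B = {c2, c3} -> J = 1/3
  J <- fate_overlap_jaccard(F, threshold = 0.5)
  expect_equal(J["a", "b"], 1 / 3)
  expect_equal(diag(J), c(a = 1, b = 1))
  # identical columns duplicate to J = 1
  F2 <- cbind(a = c(0.9, 0.1), b = c(0.9, 0.1)); rownames(F2) <- c("c1", "c2")
  expect_equal(fate_overlap_jaccard(F2, 0.5)["a", "b"], 1)
  # threshold above 0.5 on a row-stochastic matrix: off-diagonal is 0
  F3 <- cbind(a = c(0.7, 0.2), b = c(0.3, 0.8)); rownames(F3) <- c("c1", "c2")
  expect_equal(fate_overlap_jaccard(F3, 0.6)["a", "b"], 0)
})
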