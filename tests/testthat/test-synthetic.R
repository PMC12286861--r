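test_that("single-cell generator is deterministic and respects invariants", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  expect_identical(sort(unique(unname(a$truth$cell_labels))),
                   c("bulkpop", "rarepop"))
  expect_length(a$truth$cell_labels, cfg$n_cells)
})

test_that("planted marker effects are realized at the requested size", {
  pops <- list(
    population_spec("big", 0.5, sprintf("gene_%04d", 1:20), marker_log2fc = 2),
    population_spec("other", 0.5, sprintf("gene_%04d", 21:40),
                    marker_log2fc = 0))
  cfg <- sim_config(3000, 100, seed = 5, populations = pops)
  sim <- simulate_single_cell(cfg)
  idx <- sim$truth$cell_labels == "big"
  m_in <- colMeans(sim$counts[idx, sprintf("gene_%04d", 1:20)])
  m_out <- colMeans(sim$counts[!idx, sprintf("gene_%04d", 1:20)])
  realized <- log2(mean(m_in) / mean(m_out))
  expect_lt(abs(realized - 2), 0.3)
  # null population: no elevation of its own markers
  idx2 <- sim$truth$cell_labels == "other"
  r2 <- log2(mean(colMeans(sim$counts[idx2, sprintf("gene_%04d", 21:40)])) /
             mean(colMeans(sim$counts[!idx2, sprintf("gene_%04d", 21:40)])))
  expect_lt(abs(r2), 0.3)
})

test_that("impossible population frequencies are rejected by name", {
  pops <- list(
    population_spec("common", 0.9995, "gene_0001"),
    population_spec("ghost", 0.0005, "gene_0002"))
  cfg <- sim_config(100, 10, seed = 1, populations = pops)
  expect_error(simulate_single_cell(cfg), "ghost")
  expect_error(sim_config(100, 10, populations = list(
    population_spec("a", 0.5, "g1"))), "sum to 1")
})

test_that("bulk generator scales signature genes by the planted shift", {
  cfg <- tiny_config(n_genes = 300, seed = 3)
  sigs <- list(up50 = sprintf("gene_%04d", 101:150))
  shifts <- data.frame(signature = "up50", condition = "B", log2fc = 1)
  bulk <- simulate_bulk(cfg, c("A", "B"), sigs, shifts, n_replicates = 4)
  expect_identical(dim(bulk$counts), c(300L, 8L))
  isB <- bulk$samples$condition == "B"
  cpmA <- sweep(bulk$counts[, !isB], 2, colSums(bulk$counts[, !isB]) / 1e6, "/")
  cpmB <- sweep(bulk$counts[, isB], 2, colSums(bulk$counts[, isB]) / 1e6, "/")
  ratio <- log2(rowMeans(cpmB)[101:150] / rowMeans(cpmA)[101:150])
  expect_lt(abs(mean(ratio) - 1), 0.3)
  # unknown gene errors
  expect_error(simulate_bulk(cfg, c("A", "B"), list(bad = "nope"),
                             data.frame(signature = "bad", condition = "B",
                                        log2fc = 1)), "absent")
  # empty shifts give a valid null dataset
  null <- simulate_bulk(cfg, c("A", "B"), n_replicates = 2)
  expect_true(all(null$counts >= 0))
})

test_that("barcodes are clonal and thinned at the detection rate", {
  cfg <- tiny_config(n_cells = 2000, seed = 9)
  sim <- simulate_single_cell(cfg)
  bc1 <- simulate_barcodes(sim$truth, 3, list(c("bulkpop", "rarepop")),
                           detection_rate = 1, seed = 4)
  expect_true(all(bc1 == 1))  # one clone spanning all populations
  bc2 <- simulate_barcodes(sim$truth, 1, list("rarepop"),
                           detection_rate = 1, seed = 4)
  in_pop <- sim$truth$cell_labels == "rarepop"
  expect_true(all(bc2[!in_pop, ] == 0))
  expect_true(all(bc2[in_pop, ] == 1))
  # thinning: observed fraction within binomial 99% bounds of 0.3
  bc3 <- simulate_barcodes(sim$truth, 1, list(c("bulkpop", "rarepop")),
                           detection_rate = 0.3, seed = 4)
  n <- nrow(bc3)
  obs <- mean(bc3)
  bound <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(obs - 0.3), bound)
  expect_error(simulate_barcodes(sim$truth, 1, list("unknown_pop")),
               "unknown population")
})

test_that("time course has its minimum at the planted nadir", {
  tc <- simulate_timecourse(21, n_mice = 40, noise_sd = 0, seed = 2)
  expect_true(all(tc$age >= 0 & tc$age <= 56))
  expect_equal(tc$age[which.min(tc$ratio)], 21, tolerance = 2)
  expect_error(simulate_timecourse(21, n_mice = 5), ">= 10")
  expect_error(simulate_timecourse(60, n_mice = 20, age_range = c(0, 56)),
               "inside")
  # determinism
  expect_identical(simulate_timecourse(21, 30, 0.3, seed = 8),
                   simulate_timecourse(21, 30, 0.3, seed = 8))
})
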