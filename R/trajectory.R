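#' Symmetric k-nearest-neighbour connectivity graph
#'
#' Builds a union-kNN graph over a cell embedding with Gaussian-kernel
#' connectivities `c_ij = exp(-d_ij^2 / (2 sigma^2))`, `sigma` the median
#' kNN distance, symmetrized by the elementwise maximum. No self loops.
#'
#' @param embedding cells x dims numeric matrix.
#' @param k neighbours per cell.
#' @return object of class `neighbor_graph`: list with `c` (dense
#'   symmetric connectivity matrix) and `k`.
#' @export
knn_graph <- function(embedding, k = 15L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  assert_count(k, "k")
  if (k >= n) stop2("'k' must be < number of cells")
  D <- as.matrix(dist(embedding))
  adj <- matrix(FALSE, n, n)
  knn_d <- numeric(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
    knn_d <- c(knn_d, D[i, nb])
  }
  adj <- adj | t(adj)
  sigma <- median(knn_d)
  C <- exp(-D^2 / (2 * sigma^2)) * adj
  diag(C) <- 0
  dimnames(C) <- list(rownames(embedding), rownames(embedding))
  structure(list(c = C, k = as.integer(k)), class = "neighbor_graph")
}

#' Wrap a precomputed connectivity matrix as a neighbour graph
#'
#' @param C symmetric non-negative connectivity matrix with zero diagonal.
#' @return a `neighbor_graph`.
#' @export
as_neighbor_graph <- function(C) {
  C <- as.matrix(C)
  if (!isSymmetric(unname(C), tol = 1e-9)) stop2("connectivities must be symmetric")
  if (any(C < 0)) stop2("connectivities must be non-negative")
  diag(C) <- 0
  structure(list(c = C, k = NA_integer_), class = "neighbor_graph")
}

# BFS reachability over positive connectivities
reachable_from <- function(C, start) {
  n <- nrow(C)
  seen <- logical(n); seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(C[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Diffusion pseudotime from a root cell
#'
#' Eigendecomposes the symmetrized random-walk operator
#' `S = D^{-1/2} C D^{-1/2}` of the connectivity matrix; with the
#' nontrivial eigenpairs `(lambda_l, psi_l)` (right eigenvectors of the
#' walk, `psi_l = D^{-1/2} v_l`), the pseudotime of cell `i` is
#' `sqrt(sum_l (lambda_l / (1 - lambda_l))^2 (psi_l(i) - psi_l(root))^2)`,
#' which is 0 at the root by construction. The root is typically the cell
#' with the highest early-progenitor signature AUC.
#'
#' @param graph a `neighbor_graph`.
#' @param root root cell (index or name).
#' @param n_comps number of nontrivial diffusion components retained
#'   (dense eigendecomposition; suited to graphs up to a few thousand
#'   cells).
#' @return object of class `pseudotime`: list with `t` (named vector),
#'   `root`.
#' @export
diffusion_pseudotime <- function(graph, root, n_comps = 15L) {
  stopifnot(inherits(graph, "neighbor_graph"))
  C <- graph$c
  n <- nrow(C)
  if (is.character(root)) root <- match(root, rownames(C))
  if (is.na(root) || root < 1 || root > n) stop2("invalid root cell")
  deg <- rowSums(C)
  if (any(deg <= 0)) stop2("isolated cell(s): ",
                           paste(head(which(deg <= 0), 5), collapse = ", "))
  seen <- reachable_from(C, root)
  if (!all(seen))
    stop2("cell(s) unreachable from root: ",
          paste(head(which(!seen), 10), collapse = ", "))
  dhalf <- 1 / sqrt(deg)
  S <- C * outer(dhalf, dhalf)
  eig <- eigen(S, symmetric = TRUE)
  keep <- seq(2L, min(n_comps + 1L, n))
  lam <- eig$values[keep]
  lam <- pmin(lam, 1 - 1e-12)
  psi <- dhalf * eig$vectors[, keep, drop = FALSE]
  w <- lam / (1 - lam)
  diffc <- sweep(psi, 2, psi[root, ])
  t <- sqrt(rowSums(sweep(diffc, 2, w, "*")^2))
  t <- t - t[root]
  names(t) <- rownames(C)
  structure(list(t = t, root = root), class = "pseudotime")
}

#' Combine pseudotime-directed and connectivity kernels
#'
#' The pseudotime kernel biases the walk towards increasing pseudotime:
#' `P_pt(i, j) = c_ij logistic(kappa (t_j - t_i)) / sum_j c_ij` for
#' neighbours `j != i`, with the complementary (against-time) mass kept as
#' the probability of staying at `i`, so rows sum to 1 without discarding
#' directional information. The connectivity kernel is the row-normalized
#' connectivity matrix. The combined kernel is the mixture
#' `P = lambda * P_pt + (1 - lambda) * P_conn`.
#'
#' @param graph a `neighbor_graph`.
#' @param t a `pseudotime` (or named numeric vector).
#' @param lambda_ mixture weight on the pseudotime kernel, default 0.8.
#' @param kappa directional softness; `NULL` (auto) uses 1 / the raw
#'   median absolute deviation of neighbour pseudotime differences.
#' @return object of class `transition_kernel`: list with `P`
#'   (row-stochastic matrix), `lambda`, `kappa`.
#' @export
build_combined_kernel <- function(graph, t, lambda_ = 0.8, kappa = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (inherits(t, "pseudotime")) t <- t$t
  assert_fraction(lambda_, "lambda_")
  C <- graph$c
  n <- nrow(C)
  if (any(!is.finite(t))) stop2("pseudotime must be finite")
  deg <- rowSums(C)
  if (any(deg <= 0)) stop2("isolated cell(s) have no neighbours")
  if (is.null(kappa)) {
    edges <- which(C > 0, arr.ind = TRUE)
    dt <- t[edges[, 2]] - t[edges[, 1]]
    m <- median(abs(dt - median(dt)))
    if (m <= 0) m <- median(abs(dt))
    if (m <= 0) m <- 1
    kappa <- 1 / m
  }
  if (kappa <= 0) stop2("'kappa' must be > 0")
  dtmat <- outer(t, t, function(a, b) b - a)
  W <- C * plogis(kappa * dtmat)
  P_pt <- W / deg
  diag(P_pt) <- 1 - rowSums(P_pt)
  P_conn <- C / deg
  P <- lambda_ * P_pt + (1 - lambda_) * P_conn
  dimnames(P) <- dimnames(C)
  structure(list(P = P, lambda = lambda_, kappa = kappa),
            class = "transition_kernel")
}

#' Select terminal cells by highest signature AUC
#'
#' For each terminal population, picks the `n_per` cells with the highest
#' AUC for the signature of the same name. Populations claiming the same
#' cell indicate non-separable signatures and raise an error.
#'
#' @param scores a `score_table`.
#' @param populations character vector of signature/population names.
#' @param n_per representatives per population, default 30.
#' @return data frame with columns `cell`, `population`.
#' @export
select_terminal_cells <- function(scores, populations, n_per = 30L) {
  stopifnot(inherits(scores, "score_table"))
  assert_count(n_per, "n_per")
  miss <- setdiff(populations, colnames(scores$auc))
  if (length(miss)) stop2("unscored population(s): ", paste(miss, collapse = ", "))
  if (nrow(scores$auc) < n_per * 1L)
    stop2("fewer cells than n_per")
  picks <- lapply(populations, function(p) {
    ord <- order(scores$auc[, p], decreasing = TRUE)[seq_len(n_per)]
    rownames(scores$auc)[ord]
  })
  names(picks) <- populations
  all_cells <- unlist(picks)
  if (anyDuplicated(all_cells)) {
    dup <- all_cells[duplicated(all_cells)]
    who <- populations[vapply(picks, function(p) any(p %in% dup), logical(1))]
    stop2("terminal selections overlap between populations: ",
          paste(who, collapse = ", "))
  }
  data.frame(cell = all_cells,
             population = rep(populations, each = n_per), row.names = NULL)
}

#' Absorption fate probabilities
#'
#' Makes the terminal cells absorbing and solves the absorbing-chain
#' linear system: with transient block `Q` and transient-to-absorbing
#' block `R`, the per-cell fate matrix is `F = (I - Q)^{-1} R`, columns
#' aggregated by terminal population. Rows sum to 1 when every transient
#' cell can reach a terminal cell; terminal cells are assigned their own
#' population with probability 1.
#'
#' @param kernel a `transition_kernel`.
#' @param terminals data frame with columns `cell`, `population` (see
#'   [select_terminal_cells()]).
#' @return object of class `fate_matrix`: cells x terminal-populations
#'   probability matrix (all cells, terminal rows one-hot).
#' @export
absorption_probabilities <- function(kernel, terminals) {
  stopifnot(inherits(kernel, "transition_kernel"))
  P <- kernel$P
  n <- nrow(P)
  cells <- rownames(P) %||% as.character(seq_len(n))
  rownames(P) <- colnames(P) <- cells
  if (!all(terminals$cell %in% cells)) stop2("unknown terminal cell(s)")
  term_idx <- match(terminals$cell, cells)
  trans_idx <- setdiff(seq_len(n), term_idx)
  pops <- unique(terminals$population)
  Q <- P[trans_idx, trans_idx, drop = FALSE]
  R <- P[trans_idx, term_idx, drop = FALSE]
  Fi <- tryCatch(solve(diag(nrow(Q)) - Q, R), error = function(e)
    stop2("absorbing system is singular; some transient cells cannot ",
          "reach any terminal cell"))
  agg <- vapply(pops, function(p)
    rowSums(Fi[, terminals$population == p, drop = FALSE]),
    numeric(length(trans_idx)))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = length(trans_idx),
                                       dimnames = list(NULL, pops))
  bad <- abs(rowSums(agg) - 1) > 1e-6
  if (any(bad))
    stop2("transient cell(s) with no path to any terminal cell: ",
          paste(head(cells[trans_idx][bad], 10), collapse = ", "))
  out <- matrix(0, n, length(pops), dimnames = list(cells, pops))
  out[trans_idx, ] <- agg
  out[cbind(term_idx, match(terminals$population, pops))] <- 1
  structure(out, class = c("fate_matrix", class(out)))
}

#' Jaccard overlap of high-fate-probability cell sets
#'
#' For each pair of terminal populations, the Jaccard index of the cell
#' sets whose fate probability exceeds `threshold`.
#'
#' @param F a `fate_matrix` (or plain probability matrix).
#' @param threshold fate-probability cutoff in `(0, 1)`, default 0.5.
#' @return populations x populations symmetric matrix.
#' @export
fate_overlap_jaccard <- function(F, threshold = 0.5) {
  assert_fraction(threshold, "threshold", open0 = TRUE, open1 = TRUE)
  Fm <- unclass(F)
  sets <- lapply(seq_len(ncol(Fm)), function(j) which(Fm[, j] > threshold))
  p <- ncol(Fm)
  J <- matrix(0, p, p, dimnames = list(colnames(Fm), colnames(Fm)))
  for (a in seq_len(p)) for (b in seq_len(p)) {
    u <- length(union(sets[[a]], sets[[b]]))
    if (u == 0) {
      J[a, b] <- 0
      if (a == b) message("population '", colnames(Fm)[a],
                          "' has no cell above the fate threshold")
    } else J[a, b] <- length(intersect(sets[[a]], sets[[b]])) / u
  }
  J
}
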