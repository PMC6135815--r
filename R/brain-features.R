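# Functional connectivity features: ROI correlation matrices, Fisher z,
# Louvain consensus communities over an agreement matrix, edgewise
# permutation statistics with FDR, and the subcortical asymmetry ratio.

#' Pearson connectivity matrix from ROI time series
#'
#' @param ts samples x nodes numeric matrix (>= 3 samples); column names are
#'   node ids.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
connectivity_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L)
    stop("need at least 3 samples to correlate", call. = FALSE)
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant signal in node(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  r <- cor(ts)
  diag(r) <- 1
  r
}

#' Fisher z transform of a correlation matrix
#'
#' Applies `z = atanh(r)` elementwise off-diagonal; the diagonal is set to 0
#' by convention. Off-diagonal entries at `|r| = 1` (or beyond, from
#' numerical noise) are clipped to `1 - 1e-7` with a warning.
#'
#' @param r correlation matrix (r-space).
#' @return matrix in z-space.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1)) {
    warning("off-diagonal |r| >= 1 clipped to 1 - 1e-7")
    r[off & abs(r) >= 1] <- sign(r[off & abs(r) >= 1]) * (1 - 1e-7)
  }
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Inverse Fisher transform
#'
#' @param z matrix in z-space.
#' @return correlation matrix, diagonal restored to 1.
#' @export
fisher_r <- function(z) {
  r <- tanh(as.matrix(z))
  diag(r) <- 1
  r
}

#' Restrict a connectivity matrix to a node mask
#'
#' @param mat square matrix with node ids as dimnames.
#' @param node_mask character vector of node ids to keep.
#' @return the submatrix on the masked nodes; its `k` nodes carry
#'   `k*(k-1)/2` unique edges.
#' @export
restrict_to_nodes <- function(mat, node_mask) {
  mat <- as.matrix(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- colnames(mat)
  if (is.null(ids))
    stop("matrix must carry node ids as dimnames", call. = FALSE)
  node_mask <- as.character(node_mask)
  unknown <- setdiff(node_mask, ids)
  if (length(unknown))
    stop(sprintf("unknown node(s) in mask: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  mat[node_mask, node_mask, drop = FALSE]
}

#' Louvain consensus community detection over an agreement matrix
#'
#' Runs the Louvain algorithm `reps_per_subject` times on every subject's
#' connectivity matrix (node order shuffled per repetition so repetitions
#' differ), accumulates the node-pair co-assignment frequency into an
#' agreement matrix over all `subjects x reps` partitions, thresholds the
#' agreement at `agree_threshold`, and returns the connected components of
#' the thresholded agreement graph as the final modules.
#'
#' Louvain modularity requires nonnegative weights; negative entries are
#' dropped (set to 0) for the partitioning step only, and the count of
#' dropped entries is recorded on the result.
#'
#' @param matrices list of symmetric connectivity matrices sharing node ids
#'   (one per subject, r- or z-space).
#' @param reps_per_subject Louvain repetitions per subject (default 100).
#' @param agree_threshold agreement threshold (default 0.5).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed.
#' @return list of class `consensus_partition`: `membership` (named integer
#'   vector, contiguous labels), `agreement` (node x node co-assignment
#'   frequency), `n_partitions` (= subjects x reps), `n_modules`.
#' @export
louvain_consensus <- function(matrices, reps_per_subject = 100,
                              agree_threshold = 0.5, resolution = 1,
                              seed = 1L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  reps_per_subject <- stopifnot_count(reps_per_subject, "reps_per_subject", 1L)
  ids <- rownames(matrices[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(nrow(matrices[[1]])))
  n <- length(ids)
  for (m in matrices)
    if (!identical(dim(m), c(n, n)))
      stop("all matrices must share the same nodes", call. = FALSE)

  agree <- matrix(0, n, n, dimnames = list(ids, ids))
  mats <- lapply(matrices, function(m) {
    w <- as.matrix(m)
    dimnames(w) <- list(ids, ids)
    diag(w) <- 0
    w[w < 0] <- 0
    w
  })
  n_neg <- sum(vapply(matrices, function(m) sum(m < 0), numeric(1))) / 2
  with_seed(seed, {
    for (w in mats) {
      for (r in seq_len(reps_per_subject)) {
        ord <- sample.int(n)
        g <- igraph::graph_from_adjacency_matrix(
          w[ord, ord], mode = "undirected", weighted = TRUE, diag = FALSE)
        memb <- igraph::membership(igraph::cluster_louvain(
          g, resolution = resolution))
        memb <- memb[order(ord)]            # back to canonical node order
        agree <- agree + outer(memb, memb, "==")
      }
    }
  })
  n_partitions <- length(matrices) * reps_per_subject
  agree <- agree / n_partitions
  diag(agree) <- 1

  adj <- (agree >= agree_threshold) * 1
  g2 <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(g2)
  membership <- setNames(as.integer(comp$membership), ids)
  if (any(comp$csize == 1L))
    message(sprintf("louvain_consensus: %d singleton module(s) after thresholding",
                    sum(comp$csize == 1L)))
  structure(list(membership = membership, agreement = agree,
                 n_partitions = n_partitions,
                 n_modules = comp$no),
            negative_weights = n_neg,
            class = "consensus_partition")
}

#' Edgewise two-sample permutation test with FDR control
#'
#' For every unique edge of the (Fisher z) connectivity matrices, a pooled
#' two-sample t statistic between groups; the permutation null is generated
#' by reshuffling group labels, with the *same* shuffles applied to every
#' edge so that cross-edge dependence is preserved. Per-edge p values carry
#' the add-one correction; Benjamini-Hochberg is applied across all edges.
#'
#' @param group_a,group_b lists of symmetric matrices (same node ids),
#'   >= 2 subjects each; z-space values are expected.
#' @param n_perm number of label shuffles (default 5000; below 100 a
#'   warning about unstable p values is emitted).
#' @param fdr_alpha FDR level for the significance flag (default 0.05).
#' @param seed integer seed.
#' @return data frame of class `edge_test_result` with one row per edge:
#'   `node_i`, `node_j`, `t`, `p`, `q`, `flag`; attributes `n_perm`,
#'   `n_edges`.
#' @export
edgewise_permutation_test <- function(group_a, group_b, n_perm = 5000,
                                      fdr_alpha = 0.05, seed = 1L) {
  stopifnot(is.list(group_a), is.list(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  n_perm <- stopifnot_count(n_perm, "n_perm", 1L)
  if (n_perm < 100L)
    warning("n_perm < 100: permutation p values will be unstable")

  ids <- rownames(group_a[[1]])
  n_nodes <- nrow(group_a[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(n_nodes))
  pairs <- upper_tri_pairs(n_nodes)
  ut <- upper.tri(diag(n_nodes))
  edge_vec <- function(m) as.matrix(m)[ut]
  X <- rbind(t(vapply(group_a, edge_vec, numeric(sum(ut)))),
             t(vapply(group_b, edge_vec, numeric(sum(ut)))))
  na <- length(group_a); nb <- length(group_b); n <- na + nb

  t_stat <- function(in_a) {
    xa <- X[in_a, , drop = FALSE]; xb <- X[!in_a, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- col_vars(xa); vb <- col_vars(xb)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    tt[!is.finite(tt)] <- 0
    tt
  }
  in_a_obs <- c(rep(TRUE, na), rep(FALSE, nb))
  t_obs <- t_stat(in_a_obs)

  exceed <- integer(length(t_obs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      in_a <- logical(n)
      in_a[sample.int(n, na)] <- TRUE
      exceed <- exceed + (abs(t_stat(in_a)) >= abs(t_obs))
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(node_i = ids[pairs[, "row"]],
                    node_j = ids[pairs[, "col"]],
                    t = t_obs, p = p, q = q, flag = q < fdr_alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "n_edges") <- nrow(out)
  class(out) <- c("edge_test_result", class(out))
  out
}

#' Subcortical limbic volume asymmetry ratio
#'
#' Right-hemisphere volumes of the nucleus accumbens, amygdala and
#' hippocampus are summed and divided by the summed left-hemisphere
#' volumes: 1 indicates perfect symmetry, values above (below) 1 a
#' rightward (leftward) bias.
#'
#' @param right,left numeric vectors of the structures' volumes (mm^3),
#'   strictly positive.
#' @return scalar ratio `sum(right) / sum(left)`.
#' @examples
#' asymmetry_ratio(c(550, 1750, 4300), c(500, 1700, 4200))
#' @export
asymmetry_ratio <- function(right, left) {
  right <- as.numeric(right); left <- as.numeric(left)
  if (any(right <= 0) || any(left <= 0))
    stop("volumes must be strictly positive", call. = FALSE)
  sum(right) / sum(left)
}

#' Residualize a measurement on covariates
#'
#' Covariate adjustment used before group contrasts on anatomical measures
#' (e.g. asymmetry ratio adjusted for peripheral gray matter volume, age
#' and sex): returns the residuals of a linear regression of `y` on the
#' covariates, plus the grand mean.
#'
#' @param y numeric response.
#' @param covariates data frame or matrix of covariates.
#' @return numeric vector, same length as `y`.
#' @export
adjust_covariates <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y))
  fit <- lm(y ~ ., data = cbind(y = y, covariates))
  residuals(fit) + mean(y)
}
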