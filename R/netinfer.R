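#' Pairwise mutual information between metabolites
#'
#' Estimates the metabolite x metabolite mutual-information matrix from one
#' condition slice (metabolites x individuals, log2 intensities). Two
#' estimators are offered:
#' \describe{
#'   \item{`gaussian_spearman`}{Gaussian-copula MI: the Spearman correlation
#'     `r_s` (Pearson on ranks) is first converted to the implied Gaussian
#'     correlation `r = 2*sin(pi*r_s/6)` (the Spearman correlation of a
#'     bivariate normal with correlation `r` is `(6/pi)*asin(r/2)`, so this
#'     back-transform makes the estimator consistent), then
#'     `MI = -1/2 * log(1 - r^2)`. This is the defensible choice at very
#'     small sample sizes; `r^2` is clamped at `1 - 1e-12` so perfectly
#'     correlated pairs stay finite.}
#'   \item{`binned_empirical`}{Plug-in MI on equal-frequency bins
#'     (`ceiling(sqrt(n))` bins per variable). Noisy at small n; retained for
#'     comparability with discretising toolkits.}
#' }
#' Both are invariant under strictly monotone transforms of each variable.
#' Units are nats. Constant metabolites get MI 0 against everything, with a
#' warning. The diagonal is zero.
#'
#' @param slice Metabolites x individuals numeric matrix.
#' @param estimator `"gaussian_spearman"` (default) or `"binned_empirical"`.
#' @return Symmetric non-negative matrix of class `mi_matrix`.
#' @export
pairwise_mi <- function(slice, estimator = c("gaussian_spearman",
                                             "binned_empirical")) {
  estimator <- match.arg(estimator)
  x <- as.matrix(slice)
  n <- ncol(x)
  if (n < 4) design_error("need >= 4 individuals to estimate mutual information")
  const <- apply(x, 1, function(v) max(v) == min(v))
  if (any(const))
    warning(sprintf("%d constant metabolite(s): MI set to 0", sum(const)))

  if (estimator == "gaussian_spearman") {
    rs <- suppressWarnings(stats::cor(t(x), method = "spearman"))
    rs[!is.finite(rs)] <- 0
    r <- 2 * sin(pi * rs / 6)
    r2 <- pmin(r^2, 1 - 1e-12)
    mi <- -0.5 * log(1 - r2)
  } else {
    nb <- ceiling(sqrt(n))
    bins <- t(apply(x, 1, function(v) {
      br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nb + 1)))
      if (length(br) < 2) return(rep(1L, n))
      as.integer(cut(v, breaks = br, include.lowest = TRUE))
    }))
    G <- nrow(x)
    mi <- matrix(0, G, G)
    for (i in seq_len(G)) {
      for (j in seq_len(G)) {
        if (j <= i) next
        joint <- base::table(bins[i, ], bins[j, ]) / n
        pi_ <- rowSums(joint); pj <- colSums(joint)
        nz <- joint > 0
        val <- sum(joint[nz] * log(joint[nz] /
                                     outer(pi_, pj)[nz]))
        mi[i, j] <- mi[j, i] <- max(val, 0)
      }
    }
  }
  mi[const, ] <- 0
  mi[, const] <- 0
  diag(mi) <- 0
  mi[mi < 0] <- 0
  dimnames(mi) <- list(rownames(x), rownames(x))
  class(mi) <- c("mi_matrix", class(mi))
  mi
}

#' ARACNE-style pruning by the data-processing inequality
#'
#' For every triple (i, j, k), the edge (i, j) is removed when
#' `MI(i,j) < min(MI(i,k), MI(j,k)) - eps`, i.e. when it is the weakest edge
#' of a triangle and therefore consistent with an indirect interaction. All
#' decisions are taken against the original MI matrix simultaneously, so the
#' result does not depend on node order. Edges with weight `<= weight_floor`
#' are then dropped.
#'
#' @param mi An `mi_matrix` (or symmetric non-negative matrix).
#' @param eps Tolerance of the DPI rule (default 0; must be >= 0).
#' @param weight_floor Minimum retained edge weight (default 0: zero-MI
#'   pairs never form edges).
#' @param condition Optional condition label stored on the network.
#' @return An igraph weighted undirected graph of class
#'   `c("mi_network", "igraph")`, with the MI weight on each edge.
#' @export
dpi_prune <- function(mi, eps = 0, weight_floor = 0, condition = NULL) {
  if (eps < 0) value_error("eps must be >= 0")
  m <- unclass(as.matrix(mi))
  if (!isSymmetric(unname(m), tol = 1e-12))
    value_error("MI matrix must be symmetric")
  diag(m) <- 0
  G <- nrow(m)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("V", seq_len(G))

  # indirect[i,j] = max_k min(m[i,k], m[k,j]); the zero diagonal makes the
  # k = i and k = j terms vanish automatically
  indirect <- matrix(0, G, G)
  for (k in seq_len(G)) {
    col <- m[, k]
    cand <- pmin(matrix(col, G, G), matrix(col, G, G, byrow = TRUE))
    upd <- cand > indirect
    indirect[upd] <- cand[upd]
  }
  keep <- m >= indirect - eps & m > weight_floor
  adj <- ifelse(keep, m, 0)
  diag(adj) <- 0

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g$condition <- condition
  class(g) <- c("mi_network", class(g))
  g
}

#' Infer one condition's MI network from a tensor
#'
#' Convenience wrapper: extracts the condition's log2 slice, estimates
#' pairwise MI and applies DPI pruning.
#'
#' @param tensor An [intensity_tensor()].
#' @param condition Condition label.
#' @param estimator,eps,weight_floor Passed to [pairwise_mi()] and
#'   [dpi_prune()].
#' @return An `mi_network`.
#' @export
infer_network <- function(tensor, condition,
                          estimator = "gaussian_spearman",
                          eps = 0, weight_floor = 0) {
  cond <- normalize_condition(condition)
  slice <- condition_slice(tensor, cond, log2 = TRUE)
  mi <- pairwise_mi(slice, estimator)
  dpi_prune(mi, eps = eps, weight_floor = weight_floor, condition = cond)
}

#' Basic size/weight summary of an MI network
#'
#' @param net An `mi_network` (any igraph graph).
#' @return List with `n_nodes`, `n_edges`, `density` (edges over `n(n-1)/2`)
#'   and a five-number `weight_summary`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  w <- if (e > 0) igraph::E(net)$weight else numeric(0)
  list(n_nodes = n, n_edges = e,
       density = if (n > 1) e / (n * (n - 1) / 2) else 0,
       weight_summary = if (e > 0) summary(w) else NULL)
}

#' Write a network as GraphML and as a TSV edge list
#'
#' @param net An `mi_network`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.graphml` and `<prefix>_edges.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_network <- function(net, path_prefix) {
  gml <- paste0(path_prefix, ".graphml")
  tsv <- paste0(path_prefix, "_edges.tsv")
  igraph::write_graph(net, gml, format = "graphml")
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  names(el)[names(el) == "weight"] <- "mi_weight"
  utils::write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gml, edges = tsv))
}
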