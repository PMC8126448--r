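# Weighted adjacency matrix of an igraph graph, with vertex names.
graph_adjacency <- function(net, weighted = TRUE) {
  w <- if (weighted && !is.null(igraph::E(net)$weight)) "weight" else NULL
  m <- igraph::as_adjacency_matrix(net, attr = w, sparse = FALSE)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("V", seq_len(nrow(m)))
  m
}

# Leading (largest-eigenvalue) eigenvector of a symmetric matrix with the
# sign fixed so the first nonzero entry is positive.
leading_eigvec <- function(B) {
  e <- eigen(B, symmetric = TRUE)
  v <- e$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  list(value = e$values[1], vector = v)
}

#' Leading-eigenvector modularity partition
#'
#' Partitions a weighted undirected network into topological modules by
#' recursive spectral bisection of the (generalised) modularity matrix
#' `B = W - k k' / 2m`: each group is split by the sign of the leading
#' eigenvector of its generalised modularity matrix, zero entries joining
#' the positive side, and a split is accepted only if it increases the
#' global modularity Q. Isolated nodes become singleton modules. Module
#' labels are contiguous from 1, in order of first node appearance.
#'
#' @param net An `mi_network` (any igraph undirected graph).
#' @param weighted Use edge weights (default TRUE).
#' @return An object of class `module_partition`: `assignment` (named
#'   integer vector), `Q`, `q_contrib` (per-module contributions summing to
#'   Q), `n_modules`, `condition`.
#' @export
leading_eigenvector_partition <- function(net, weighted = TRUE) {
  W <- graph_adjacency(net, weighted)
  n <- nrow(W)
  if (n == 0)
    return(structure(list(assignment = integer(0), Q = 0,
                          q_contrib = numeric(0), n_modules = 0L,
                          condition = net$condition %||% NA_character_),
                     class = "module_partition"))
  k <- rowSums(W)
  two_m <- sum(k)
  groups <- list()

  isolated <- which(k == 0)
  connected <- setdiff(seq_len(n), isolated)

  if (two_m == 0 || length(connected) == 0) {
    groups <- as.list(seq_len(n))
  } else {
    B <- W - outer(k, k) / two_m
    recurse <- function(idx) {
      if (length(idx) == 1L) return(list(idx))
      Bg <- B[idx, idx, drop = FALSE]
      diag(Bg) <- diag(Bg) - rowSums(Bg)
      le <- leading_eigvec(Bg)
      s <- ifelse(le$vector >= 0, 1, -1)   # zeros join the positive group
      if (all(s == s[1])) return(list(idx))
      dQ <- drop(t(s) %*% Bg %*% s) / (2 * two_m)
      if (dQ <= 1e-12) return(list(idx))
      c(recurse(idx[s > 0]), recurse(idx[s < 0]))
    }
    # start from connected components: modularity never merges across them
    comp <- igraph::components(net)$membership[connected]
    groups <- unlist(lapply(split(connected, comp), recurse),
                     recursive = FALSE)
    groups <- c(groups, as.list(isolated))
  }

  assignment <- integer(n)
  ord <- order(vapply(groups, min, numeric(1)))
  for (lab in seq_along(ord)) assignment[groups[[ord[lab]]]] <- lab
  names(assignment) <- rownames(W)

  qc <- modularity_contributions(W, assignment)
  structure(list(assignment = assignment, Q = sum(qc), q_contrib = qc,
                 n_modules = length(groups),
                 condition = net$condition %||% NA_character_),
            class = "module_partition")
}

# Per-module contribution to Q: e_mm - a_m^2, with e_mm the within-module
# weight fraction and a_m the module's strength fraction.
modularity_contributions <- function(W, assignment) {
  two_m <- sum(W)
  labs <- sort(unique(assignment))
  if (two_m == 0) return(setNames(rep(0, length(labs)), labs))
  qc <- vapply(labs, function(l) {
    idx <- which(assignment == l)
    e_mm <- sum(W[idx, idx]) / two_m
    a_m <- sum(W[idx, ]) / two_m
    e_mm - a_m^2
  }, numeric(1))
  setNames(qc, labs)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition (%s): %d modules, Q = %.4f\n",
              x$condition, x$n_modules, x$Q))
  print(base::table(x$assignment))
  invisible(x)
}

#' Eigenvector centrality of a weighted network
#'
#' Node importance from the dominant eigenvector of the (weighted)
#' adjacency matrix. Each connected component with at least one edge is
#' analysed separately and its Perron vector is normalised so the
#' component's maximum centrality is 1; isolated nodes get centrality 0.
#' The returned vector therefore lies in `[0, 1]` with at least one 1 per
#' analysed component.
#'
#' @param net An igraph undirected graph.
#' @param weighted Use edge weights (default TRUE).
#' @param tol Residual tolerance for verifying `A c = lambda c`.
#' @return Named numeric vector of centralities.
#' @export
eigenvector_centrality <- function(net, weighted = TRUE, tol = 1e-10) {
  W <- graph_adjacency(net, weighted)
  n <- nrow(W)
  cent <- setNames(numeric(n), rownames(W))
  if (n == 0) return(cent)
  comp <- igraph::components(net)$membership
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L || sum(W[idx, idx]) == 0) next
    A <- W[idx, idx, drop = FALSE]
    e <- eigen(A, symmetric = TRUE)
    lam <- e$values[1]
    v <- abs(e$vectors[, 1])          # Perron vector is non-negative
    if (max(abs(A %*% v - lam * v)) > tol * max(1, abs(lam)))
      mdnm_error("eigenvector centrality failed the residual check",
                 "mdnm_numerical_error")
    cent[idx] <- v / max(v)
  }
  cent
}

#' Per-condition centralities and paired change
#'
#' @param net_post,net_fasted Networks on the same metabolite set.
#' @param weighted Use edge weights.
#' @return data.frame `metabolite_id`, `centrality_post`,
#'   `centrality_fasted`, `delta_centrality`.
#' @export
centrality_table <- function(net_post, net_fasted, weighted = TRUE) {
  cp <- eigenvector_centrality(net_post, weighted)
  cf <- eigenvector_centrality(net_fasted, weighted)
  if (!setequal(names(cp), names(cf)))
    align_error("the two networks have different metabolite sets")
  cf <- cf[names(cp)]
  data.frame(metabolite_id = names(cp),
             centrality_post = unname(cp),
             centrality_fasted = unname(cf),
             delta_centrality = unname(cf - cp),
             stringsAsFactors = FALSE)
}

#' Match fasted modules to post-absorptive modules by Jaccard overlap
#'
#' Maps each fasted-state module to the baseline module with which it shares
#' the largest Jaccard overlap (ties broken by the smaller baseline label)
#' and flags, per metabolite, whether its baseline module differs from the
#' baseline image of its fasted module.
#'
#' @param p_post,p_fast `module_partition` objects on the same metabolites.
#' @return List with `mapping` (data.frame: fasted module, matched post
#'   module, jaccard) and `membership_change` (named logical per metabolite).
#' @export
match_modules <- function(p_post, p_fast) {
  a_post <- p_post$assignment
  a_fast <- p_fast$assignment
  if (!setequal(names(a_post), names(a_fast)))
    align_error("partitions cover different metabolite sets")
  a_post <- a_post[names(a_fast)]
  fl <- sort(unique(a_fast)); pl <- sort(unique(a_post))
  jac <- matrix(0, length(fl), length(pl), dimnames = list(fl, pl))
  for (i in seq_along(fl)) {
    fi <- names(a_fast)[a_fast == fl[i]]
    for (j in seq_along(pl)) {
      pj <- names(a_post)[a_post == pl[j]]
      jac[i, j] <- length(intersect(fi, pj)) / length(union(fi, pj))
    }
  }
  best <- apply(jac, 1, function(r) which(r == max(r))[1])  # first = smallest label
  mapping <- data.frame(fasted_module = fl,
                        post_module = pl[best],
                        jaccard = jac[cbind(seq_along(fl), best)])
  mapped_post <- setNames(pl[best], fl)
  change <- a_post != mapped_post[as.character(a_fast)]
  list(mapping = mapping, membership_change = change, jaccard_matrix = jac)
}
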