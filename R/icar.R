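# Adjacency graphs and the intrinsic CAR (ICAR) prior: structure
# matrices, connected components, constrained sampling.

#' Build a validated adjacency object
#'
#' Symmetrises the edge list, rejects self-loops, and records connected
#' components (the ICAR sum-to-zero constraint applies per component).
#'
#' @param from,to vectors of node ids (edge endpoints).
#' @param ids optional complete node id vector (isolated nodes allowed);
#'   defaults to the ids seen in the edges.
#' @return list of class `adjacency`: `ids`, `edges` (2-column integer
#'   matrix, `from < to`), `nbs` (neighbour index list), `n_neigh`,
#'   `component` (integer label per node), `n_components`.
#' @export
make_adjacency <- function(from, to, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(from, to)))
  i <- match(from, ids); j <- match(to, ids)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node id set")
  if (any(i == j)) stop("self-loops are not allowed")
  e <- cbind(pmin(i, j), pmax(i, j))
  e <- unique(e)
  n <- length(ids)
  nbs <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    nbs[[e[k, 1]]] <- c(nbs[[e[k, 1]]], e[k, 2])
    nbs[[e[k, 2]]] <- c(nbs[[e[k, 2]]], e[k, 1])
  }
  nbs <- lapply(nbs, function(x) sort(unique(x)))
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, nbs[[v]][comp[nbs[[v]]] == 0L])
    }
  }
  structure(list(ids = ids, edges = e, nbs = nbs,
                 n_neigh = vapply(nbs, length, integer(1)),
                 component = comp, n_components = cur),
            class = "adjacency")
}

#' ICAR structure (precision) matrix
#'
#' Returns the graph Laplacian `Q` with `Q[k,k]` = number of neighbours
#' and `Q[k,l] = -1` for neighbouring pairs; the ICAR prior is
#' `p(u) propto exp(-tau/2 * u'Qu)`, improper with rank deficiency equal
#' to the number of connected components.
#'
#' @param adj adjacency object.
#' @return dense symmetric matrix.
#' @export
icar_precision <- function(adj) {
  n <- length(adj$ids)
  Q <- matrix(0, n, n)
  for (k in seq_len(nrow(adj$edges))) {
    i <- adj$edges[k, 1]; j <- adj$edges[k, 2]
    Q[i, j] <- Q[i, j] - 1
    Q[j, i] <- Q[j, i] - 1
  }
  diag(Q) <- adj$n_neigh
  Q
}

# quadratic form u'Qu computed edge-wise: sum over edges of (u_i - u_j)^2
icar_quadform <- function(adj, u) {
  d <- u[adj$edges[, 1]] - u[adj$edges[, 2]]
  sum(d * d)
}

# centre a vector to mean zero within each graph component
center_by_component <- function(u, component) {
  u - stats::ave(u, component)
}

#' Sample from the ICAR prior under per-component sum-to-zero
#'
#' Draws `u ~ N(0, (tau * Q)^-)` restricted to the subspace orthogonal to
#' each component's constant vector, via the eigendecomposition of `Q`.
#' Isolated nodes (degree 0) get exact zeros.
#'
#' @param adj adjacency object.
#' @param tau precision (> 0).
#' @return numeric vector, mean-zero within each component (to 1e-8).
#' @export
icar_sample <- function(adj, tau) {
  stopifnot(tau > 0)
  n <- length(adj$ids)
  if (n == 1L) stop("ICAR is undefined on a single node")
  Q <- icar_precision(adj)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  if (!any(pos)) stop("ICAR undefined: graph has no edges")
  z <- stats::rnorm(sum(pos), sd = 1 / sqrt(tau * eg$values[pos]))
  u <- as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  center_by_component(u, adj$component)
}

# RW1 structure matrix (second-difference Laplacian of a path of length T)
rw1_precision <- function(T) {
  if (T < 2) return(matrix(0, T, T))
  Q <- matrix(0, T, T)
  for (t in seq_len(T - 1)) {
    Q[t, t] <- Q[t, t] + 1
    Q[t + 1, t + 1] <- Q[t + 1, t + 1] + 1
    Q[t, t + 1] <- Q[t, t + 1] - 1
    Q[t + 1, t] <- Q[t + 1, t] - 1
  }
  Q
}
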