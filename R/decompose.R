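#' Decompose a network into its colored biadjacency matrices
#'
#' Splits the ternary status matrix into three binary indicator matrices:
#' `a_plus` (active pairs), `a_minus` (inactive pairs) and `a_star`
#' (unknown pairs). The three matrices partition the drug x target pairs,
#' so they sum elementwise to the all-ones matrix. Row sums of `a_plus` are
#' the polypharmacology degrees; column sums are the polyspecificity
#' degrees.
#'
#' @param network A `dtnet` object.
#' @return An object of class `dt_subnetworks`: a named list of the three
#'   n x m binary matrices `a_plus`, `a_minus`, `a_star`, with drug/target
#'   dimnames.
#' @export
#' @examples
#' sub <- decompose_network(load_worked_example())
#' rowSums(sub$a_plus) # polypharmacology degrees
decompose_network <- function(network) {
  check_dtnet(network)
  s <- network$status
  ind <- function(level) {
    m <- (s == level) + 0L
    dimnames(m) <- dimnames(s)
    m
  }
  structure(
    list(a_plus = ind("active"), a_minus = ind("inactive"),
         a_star = ind("unknown")),
    class = "dt_subnetworks"
  )
}

#' @export
print.dt_subnetworks <- function(x, ...) {
  cat(sprintf(
    "<dt_subnetworks> %d x %d: |A+| = %d, |A-| = %d, |A*| = %d\n",
    nrow(x$a_plus), ncol(x$a_plus),
    sum(x$a_plus), sum(x$a_minus), sum(x$a_star)
  ))
  invisible(x)
}

#' Long-format view of a colored decomposition
#'
#' @param x A `dt_subnetworks` object.
#' @param ... Unused.
#' @return A tibble with columns `drug`, `target`, `a_plus`, `a_minus`,
#'   `a_star` (one row per pair; the three indicators sum to 1).
#' @method tidy dt_subnetworks
#' @export
tidy.dt_subnetworks <- function(x, ...) {
  d <- rownames(x$a_plus); tg <- colnames(x$a_plus)
  tibble::tibble(
    drug = rep(d, each = length(tg)),
    target = rep(tg, times = length(d)),
    a_plus = as.integer(t(x$a_plus)),
    a_minus = as.integer(t(x$a_minus)),
    a_star = as.integer(t(x$a_star))
  )
}

#' Assemble the full adjacency matrix of a bipartite graph
#'
#' Expands an n x m binary biadjacency matrix A into the full
#' (n+m) x (n+m) adjacency matrix of the bipartite graph,
#' `[[0, A], [A', 0]]`: drugs index the first n rows/columns, targets the
#' last m, the diagonal blocks are zero (edges only link nodes between the
#' two sets) and the result is symmetric.
#'
#' @param biadjacency Binary (0/1) matrix, e.g. one component of
#'   [decompose_network()].
#' @return A symmetric (n+m) x (n+m) binary matrix; dimnames concatenate the
#'   row and column names of the input when present.
#' @export
full_adjacency <- function(biadjacency) {
  if (!is.matrix(biadjacency) || !is.numeric(biadjacency) ||
      !all(biadjacency %in% c(0, 1))) {
    abort_invalid("`biadjacency` must be a binary 0/1 matrix")
  }
  n <- nrow(biadjacency); m <- ncol(biadjacency)
  adj <- matrix(0L, n + m, n + m)
  adj[seq_len(n), n + seq_len(m)] <- biadjacency
  adj[n + seq_len(m), seq_len(n)] <- t(biadjacency)
  labels <- c(rownames(biadjacency), colnames(biadjacency))
  if (length(labels) == n + m) dimnames(adj) <- list(labels, labels)
  adj
}
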