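#' Shortest-path verification oracle for the age bounds
#'
#' Independent re-derivation of [compute_age_bounds()] used for testing.
#' Node ages are encoded as a difference-constraint system (a simple
#' temporal network): for each branch with duration interval `[lb, ub]`,
#' `lb <= age(parent) - age(child) <= ub`; every tip equals a reference
#' variable fixed at 0; each calibration bounds a node against the
#' reference.  All-pairs shortest paths (Floyd–Warshall) then give, for
#' every node, the tightest feasible age interval; a negative cycle means
#' the constraints are jointly infeasible.
#'
#' Cubic in the number of nodes; intended for trees up to a few hundred
#' nodes.
#'
#' @inheritParams upward_pass
#' @return A `"node_age_bounds"` object, or an error of class
#'   `"chronobounds_infeasible"` if a negative cycle is detected.
#' @export
stp_oracle_bounds <- function(tree, rates, calibrations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  cal <- calibration_vectors(tree, calibrations)
  n_tip <- Ntip(tree)
  n_all <- n_tip + Nnode(tree)
  ref <- n_all + 1L

  D <- matrix(Inf, ref, ref)
  diag(D) <- 0
  iv <- branch_interval(tree$edge.length, rates)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    D[ch, p] <- min(D[ch, p], iv$ub[k])   # age(p) - age(c) <= ub
    D[p, ch] <- min(D[p, ch], -iv$lb[k])  # age(c) - age(p) <= -lb
  }
  tips <- seq_len(n_tip)
  D[ref, tips] <- pmin(D[ref, tips], 0)   # age(t) <= 0
  D[tips, ref] <- pmin(D[tips, ref], 0)   # age(t) >= 0
  for (v in which(cal$min > 0))
    D[v, ref] <- min(D[v, ref], -cal$min[v])
  for (v in which(is.finite(cal$max) & cal$max > 0))
    D[ref, v] <- min(D[ref, v], cal$max[v])

  for (k in seq_len(ref))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))

  neg <- which(diag(D) < -1e-9)
  if (length(neg)) {
    cand <- neg[neg <= n_all]
    node <- if (any(cand > n_tip)) cand[cand > n_tip][1]
            else if (length(cand)) cand[1] else root_node(tree)
    stop_infeasible(tree, node, -D[node, ref], D[ref, node],
                    "negative cycle in the difference-constraint graph")
  }
  structure(list(L = -D[seq_len(n_all), ref], U = D[ref, seq_len(n_all)],
                 tree = tree), class = "node_age_bounds")
}
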