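#' Conceivable substitution-rate interval
#'
#' The central assumption of the method: a single interval
#' \eqn{[r_{min}, r_{max}]} of substitution rates (substitutions per site per
#' time unit) assumed to contain the true rate of every branch.  `r_min` must
#' be strictly positive, because `r_min = 0` makes every maximum age
#' infinite; to bound ages from above, supply a positive `r_min` together
#' with a maximum age calibration at the root.
#'
#' @param r_min,r_max Positive finite rates with `r_min <= r_max`.
#' @return An object of class `"rate_bounds"`.
#' @examples
#' rate_bounds(0.5, 2.0)
#' @export
rate_bounds <- function(r_min, r_max) {
  if (!is_scalar_number(r_min) || !is_scalar_number(r_max))
    stop("r_min and r_max must be single finite numbers", call. = FALSE)
  if (r_min <= 0)
    stop(paste("r_min must be > 0: a zero minimum rate makes all maximum",
               "ages infinite; use a positive r_min plus a root maximum-age",
               "calibration to bound ages"), call. = FALSE)
  if (r_min > r_max)
    stop("r_min must not exceed r_max", call. = FALSE)
  structure(list(r_min = r_min, r_max = r_max), class = "rate_bounds")
}

#' @export
print.rate_bounds <- function(x, ...) {
  cat(sprintf("rate bounds: [%.6g, %.6g] substitutions/site/time\n",
              x$r_min, x$r_max))
  invisible(x)
}

#' Feasible time-duration interval of a branch
#'
#' A branch carrying `s` expected substitutions per site, evolved at some
#' rate within `[r_min, r_max]`, must have lasted between `s / r_max` and
#' `s / r_min` time units.  This is the only place the rate assumption
#' enters the method.
#'
#' @param substitutions Non-negative molecular branch length(s),
#'   substitutions per site.  Vectorised.
#' @param rates A [rate_bounds()] object.
#' @return A list with numeric vectors `lb` and `ub` (time units).
#' @examples
#' branch_interval(1.0, rate_bounds(0.5, 2.0))  # [0.5, 2.0]
#' @export
branch_interval <- function(substitutions, rates) {
  stopifnot(inherits(rates, "rate_bounds"), is.numeric(substitutions))
  if (any(!is.finite(substitutions) | substitutions < 0))
    stop("substitutions must be finite and >= 0", call. = FALSE)
  list(lb = substitutions / rates$r_max, ub = substitutions / rates$r_min)
}

# Expand a calibration_set into per-node min/max vectors.
calibration_vectors <- function(tree, calibrations) {
  n_all <- Ntip(tree) + Nnode(tree)
  cal_min <- rep(0, n_all)
  cal_max <- rep(Inf, n_all)
  if (!is.null(calibrations) && nrow(calibrations)) {
    stopifnot(inherits(calibrations, "calibration_set"))
    if (any(calibrations$node > n_all))
      stop("calibration refers to a node outside the tree", call. = FALSE)
    sel <- !is.na(calibrations$min_age)
    cal_min[calibrations$node[sel]] <- calibrations$min_age[sel]
    sel <- !is.na(calibrations$max_age)
    cal_max[calibrations$node[sel]] <- calibrations$max_age[sel]
  }
  # tips are extant: pinned to age 0
  tips <- seq_len(Ntip(tree))
  bad <- tips[cal_min[tips] > 0]
  if (length(bad))
    stop(sprintf("tip %s is pinned at age 0 but has min_age %g",
                 tree$tip.label[bad[1]], cal_min[bad[1]]), call. = FALSE)
  cal_min[tips] <- 0
  cal_max[tips] <- pmin(cal_max[tips], 0)
  list(min = cal_min, max = cal_max)
}

#' Upward (postorder) propagation of age constraints
#'
#' Computes, for every node, the tightest bounds implied by the node's own
#' descendants and calibrations at or below it: tips get `[0, 0]`; an
#' internal node `n` with children `c` whose branch duration intervals are
#' `[lb_c, ub_c]` gets
#' \deqn{L_{up}(n) = \max(cal_{min}(n), \max_c(L_{up}(c) + lb_c))}
#' \deqn{U_{up}(n) = \min(cal_{max}(n), \min_c(U_{up}(c) + ub_c))}
#' Infeasibility (`L_up > U_up` beyond floating-point tolerance) is raised
#' as a condition of class `"chronobounds_infeasible"` naming the node.
#'
#' @param tree A `"phylo"` with molecular branch lengths.
#' @param rates A [rate_bounds()] object.
#' @param calibrations A `"calibration_set"` (or `NULL` for none).
#' @return List with numeric vectors `L_up`, `U_up` indexed by node.
#' @export
upward_pass <- function(tree, rates, calibrations = NULL) {
  cal <- calibration_vectors(tree, calibrations)
  n_tip <- Ntip(tree)
  n_all <- n_tip + Nnode(tree)
  po <- reorder.phylo(tree, "postorder")
  iv <- branch_interval(po$edge.length, rates)

  L <- cal$min
  U <- cal$max
  L[seq_len(n_tip)] <- 0
  U[seq_len(n_tip)] <- 0
  done <- c(rep(TRUE, n_tip), rep(FALSE, n_all - n_tip))

  edge <- po$edge
  parents_po <- unique(edge[, 1])  # postorder over internal nodes
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    # child is final by postorder; check it once when first folded
    if (!done[ch] && L[ch] > U[ch] + feas_tol(L[ch], U[ch]))
      stop_infeasible(tree, ch, L[ch], U[ch],
                      "conflict between descendant branch lengths and calibrations")
    done[ch] <- TRUE
    L[p] <- max(L[p], L[ch] + iv$lb[k])
    U[p] <- min(U[p], U[ch] + iv$ub[k])
  }
  r <- root_node(tree)
  if (L[r] > U[r] + feas_tol(L[r], U[r]))
    stop_infeasible(tree, r, L[r], U[r],
                    "conflict between descendant branch lengths and calibrations")
  list(L_up = L, U_up = U)
}

#' Downward (preorder) propagation of age constraints
#'
#' Refines the upward bounds with information flowing from ancestors: the
#' root keeps its upward bounds; a child `c` of parent `p` with duration
#' interval `[lb_c, ub_c]` gets
#' \deqn{U(c) = \min(U_{up}(c),\; U(p) - lb_c)}
#' \deqn{L(c) = \max(L_{up}(c),\; L(p) - ub_c)}
#' The result is exact for this constraint structure: at every node `L` and
#' `U` equal the minimum and maximum of the node's age over all chronograms
#' whose branch durations lie in their intervals and that satisfy all
#' calibrations.
#'
#' @inheritParams upward_pass
#' @param up The result of [upward_pass()].
#' @return A `"node_age_bounds"` object: list with vectors `L` and `U`
#'   (time before present, indexed by node) and the `tree`.
#' @export
downward_pass <- function(tree, rates, calibrations = NULL, up) {
  po <- reorder.phylo(tree, "postorder")
  iv <- branch_interval(po$edge.length, rates)
  L <- up$L_up
  U <- up$U_up
  edge <- po$edge
  for (k in rev(seq_len(nrow(edge)))) {  # preorder: parents before children
    p <- edge[k, 1]; ch <- edge[k, 2]
    U[ch] <- min(U[ch], U[p] - iv$lb[k])
    L[ch] <- max(L[ch], L[p] - iv$ub[k])
    if (L[ch] > U[ch] + feas_tol(L[ch], U[ch]))
      stop_infeasible(tree, ch, L[ch], U[ch],
                      "an ancestral maximum age conflicts with a minimum age below")
  }
  structure(list(L = L, U = U, tree = tree), class = "node_age_bounds")
}

#' Feasible age interval of every node
#'
#' The core of the method.  Given a phylogeny with molecular branch lengths,
#' a conceivable substitution-rate interval, and optional node-age
#' calibrations, computes for every node the youngest (`L`) and oldest (`U`)
#' age consistent with those assumptions, by exact interval-constraint
#' propagation: branch durations constrained to `[s/r_max, s/r_min]`, tips
#' pinned at age 0, calibrations as per-node bounds; one postorder pass
#' ([upward_pass()]) then one preorder pass ([downward_pass()]).
#'
#' No single "best" age is reported, by design: the method's output is the
#' full feasible range, and picking a point inside it would require exactly
#' the kind of rate or age model the method refuses to assume.
#'
#' @inheritParams upward_pass
#' @return A `"node_age_bounds"` object with vectors `L`, `U` and the `tree`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' b <- compute_age_bounds(tr, rate_bounds(0.5, 2))
#' b$L[5]; b$U[5]  # MRCA(A,B): [0.5, 2]
#' @export
compute_age_bounds <- function(tree, rates, calibrations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (Ntip(tree) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  up <- upward_pass(tree, rates, calibrations)
  downward_pass(tree, rates, calibrations, up)
}

#' @export
print.node_age_bounds <- function(x, ...) {
  cat(sprintf("feasible node ages for %d nodes (%d tips)\n",
              length(x$L), Ntip(x$tree)))
  r <- root_node(x$tree)
  cat(sprintf("root age in [%.6g, %s]\n", x$L[r],
              if (is.finite(x$U[r])) sprintf("%.6g", x$U[r]) else "Inf"))
  invisible(x)
}

#' Build the two extreme chronograms
#'
#' `tree_min` assigns every node its youngest feasible age `L`; `tree_max`
#' assigns every node its oldest feasible age `U`.  Both are valid
#' chronograms — the earliest- and latest-solution property of
#' difference-constraint systems guarantees that taking all lower (or all
#' upper) bounds simultaneously satisfies every branch-duration interval and
#' calibration.
#'
#' @param bounds A feasible `"node_age_bounds"` object.
#' @param tree The `"phylo"` the bounds were computed for.
#' @return List with components `tree_min` and `tree_max`, both
#'   `"chronogram"` objects.
#' @export
build_extreme_chronograms <- function(bounds, tree) {
  stopifnot(inherits(bounds, "node_age_bounds"))
  if (any(!is.finite(bounds$U)))
    stop(paste("some maximum ages are infinite; add a root maximum-age",
               "calibration (or a positive r_min) before building tree_max"),
         call. = FALSE)
  list(tree_min = chronogram(tree, bounds$L),
       tree_max = chronogram(tree, bounds$U))
}

#' Implied per-branch substitution rates of a chronogram
#'
#' Audit utility: divides each branch's molecular length (substitutions per
#' site, from `tree`) by its time duration in `chronogram`.  On `tree_min`
#' every defined rate equals `r_max`; on `tree_max` every defined rate
#' equals `r_min` — only the extreme rates can realise the extreme ages.
#'
#' @param chronogram A `"chronogram"` sharing `tree`'s topology.
#' @param tree The source `"phylo"` with molecular branch lengths.
#' @return Numeric vector of per-edge rates aligned with `tree$edge` rows;
#'   `NA` flags a zero-substitutions, zero-duration branch (rate undefined).
#' @export
implied_branch_rates <- function(chronogram, tree) {
  stopifnot(inherits(chronogram, "chronogram"))
  if (!identical(dim(chronogram$tree$edge), dim(tree$edge)) ||
      !all(chronogram$tree$edge == tree$edge))
    stop("chronogram and tree do not share a topology", call. = FALSE)
  dur <- chronogram$ages[tree$edge[, 1]] - chronogram$ages[tree$edge[, 2]]
  subs <- tree$edge.length
  zero_dur <- dur <= 0
  if (any(zero_dur & subs > 0)) {
    k <- which(zero_dur & subs > 0)[1]
    stop(sprintf(
      "branch above %s has %g substitutions but zero duration (infinite rate)",
      node_label(tree, tree$edge[k, 2]), subs[k]), call. = FALSE)
  }
  out <- subs / dur
  out[zero_dur & subs == 0] <- NA_real_
  out
}
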