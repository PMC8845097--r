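# Shared fixtures and random-instance generators (all built in code).

# the three-taxon worked example used throughout: ((A:1,B:1):1,C:2)
worked_tree <- function() read_tree("((A:1,B:1):1,C:2);")
worked_rates <- function() rate_bounds(0.5, 2)

# a conflicting cherry: lower bound via A (4/2 = 2) exceeds upper via B
# (0.5/0.5 = 1) at MRCA(A,B)
infeasible_tree <- function() read_tree("((A:4,B:0.5):1,C:2);")

mrca_ab <- function(tree) ape::getMRCA(tree, c("A", "B"))

# random rooted tree with branch lengths in (0, 5]
random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 1e-3, 5)
  tr
}

# random rate bounds with r_max / r_min in [1, 100]
random_rates <- function() {
  r_min <- stats::runif(1, 0.05, 2)
  rate_bounds(r_min, r_min * stats::runif(1, 1, 100))
}

# 0..3 random calibrations on distinct internal nodes; ages drawn on the
# scale of the tree's feasible root ages so that both feasible and
# infeasible instances arise
random_calibrations <- function(tree, rates, n_cal = sample(0:3, 1)) {
  if (n_cal == 0) return(NULL)
  n_tip <- ape::Ntip(tree)
  internals <- (n_tip + 1):(n_tip + ape::Nnode(tree))
  nodes <- sample(internals, min(n_cal, length(internals)))
  depth <- max(ape::node.depth.edgelength(tree))
  scale <- depth / rates$r_min
  mins <- maxs <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    kind <- sample(1:3, 1)  # 1 = min only, 2 = max only, 3 = both
    if (kind != 2) mins[i] <- stats::runif(1, 0, scale)
    if (kind != 1) {
      lo <- if (is.na(mins[i])) 0 else mins[i]
      maxs[i] <- lo + stats::runif(1, 1e-6, scale)
    }
  }
  chronobounds:::make_calibration_set(tree, nodes, mins, maxs)
}

# run both the propagation engine and the shortest-path oracle; return a
# comparable summary (verdict plus bounds)
bounds_both_ways <- function(tree, rates, calibrations = NULL) {
  run <- function(f) tryCatch(
    list(feasible = TRUE, bounds = f(tree, rates, calibrations)),
    chronobounds_infeasible = function(e) list(feasible = FALSE, bounds = NULL))
  list(engine = run(compute_age_bounds), oracle = run(stp_oracle_bounds))
}

expect_bounds_agree <- function(both, tol = 1e-9) {
  expect_identical(both$engine$feasible, both$oracle$feasible)
  if (both$engine$feasible) {
    e <- both$engine$bounds; o <- both$oracle$bounds
    scale <- pmax(1, abs(o$L), abs(o$U[is.finite(o$U)][1]))
    expect_lt(max(abs(e$L - o$L) / pmax(1, abs(o$L))), tol)
    fin <- is.finite(o$U)
    expect_identical(fin, is.finite(e$U))
    expect_lt(max(abs(e$U[fin] - o$U[fin]) / pmax(1, abs(o$U[fin]))), tol)
  }
  invisible(both)
}

# validity checks for an extreme chronogram pair against its inputs
expect_valid_extremes <- function(tree, rates, bounds, rate_tol = 1e-6) {
  ch <- build_extreme_chronograms(bounds, tree)
  for (cg in ch) {
    expect_true(all(abs(cg$ages[seq_len(ape::Ntip(tree))]) < 1e-12))
    dur <- cg$ages[tree$edge[, 1]] - cg$ages[tree$edge[, 2]]
    expect_true(all(dur >= -1e-9 * pmax(1, abs(cg$ages[tree$edge[, 1]]))))
    r <- implied_branch_rates(cg, tree)
    r <- r[!is.na(r)]
    expect_true(all(r >= rates$r_min - rate_tol * rates$r_max))
    expect_true(all(r <= rates$r_max * (1 + rate_tol)))
  }
  invisible(ch)
}
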