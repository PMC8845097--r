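# Internal helpers shared across modules.

#' @importFrom ape Ntip Nnode reorder.phylo read.tree write.tree getMRCA
#'   node.depth.edgelength
NULL

# Root node index of a phylo object (does not assume Ntip + 1).
root_node <- function(tree) {
  parents <- unique(tree$edge[, 1])
  r <- setdiff(parents, tree$edge[, 2])
  if (length(r) != 1L) stop("tree does not have exactly one root", call. = FALSE)
  r
}

# For every node, the two lexicographically smallest tip labels of its clade
# (a tip gives its own label twice).  Used to name nodes in tables and errors.
defining_tips <- function(tree) {
  n_tip <- Ntip(tree)
  n_all <- n_tip + Nnode(tree)
  best <- vector("list", n_all)
  for (i in seq_len(n_tip)) best[[i]] <- c(tree$tip.label[i], tree$tip.label[i])
  edge <- reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    cand <- sort(unique(c(best[[p]], best[[ch]])))
    best[[p]] <- cand[seq_len(min(2L, length(cand)))]
  }
  vapply(best, function(x) paste(x[c(1L, min(2L, length(x)))], collapse = ";"),
         character(1))
}

# Label for one node, e.g. "MRCA(A,B)" or "tip A".
node_label <- function(tree, node) {
  if (node <= Ntip(tree)) return(sprintf("tip %s", tree$tip.label[node]))
  dt <- strsplit(defining_tips(tree)[node], ";", fixed = TRUE)[[1]]
  sprintf("MRCA(%s,%s)", dt[1], dt[2])
}

# Relative-or-absolute floating point guard used in every feasibility
# comparison: tol = eps * max(1, |a|, |b|).
feas_tol <- function(a, b, eps = 1e-9) eps * pmax(1, abs(a), abs(b))

# Signal an infeasibility condition naming the offending node.
stop_infeasible <- function(tree, node, lower, upper, context) {
  msg <- sprintf(
    "infeasible constraints at %s: youngest feasible age %.12g exceeds oldest feasible age %.12g (%s)",
    node_label(tree, node), lower, upper, context)
  cond <- structure(
    class = c("chronobounds_infeasible", "error", "condition"),
    list(message = msg, call = sys.call(-1),
         node = node, lower = lower, upper = upper))
  stop(cond)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
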