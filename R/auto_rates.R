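#' Terminal sister-branch length ratios
#'
#' For every cherry (an internal node whose two children are both tips) with
#' terminal molecular lengths `b1 >= b2 > 0`, the ratio `b1 / b2` is
#' reported.  Sister terminal branches span exactly the same amount of time,
#' so their molecular-length ratio is a direct substitution-rate ratio —
#' the only model-free glimpse of rate variation the tree itself offers.
#' Cherries with a zero-length member are skipped with a warning.
#'
#' @param tree A `"phylo"` with molecular branch lengths.
#' @return Numeric vector of ratios, each `>= 1`, one per usable cherry.
#' @examples
#' cherry_ratios(read_tree("((A:2.0,B:0.5):0.5,C:2.0);"))  # 4
#' @export
cherry_ratios <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- Ntip(tree)
  edge <- tree$edge
  is_tip_child <- edge[, 2] <= n_tip
  parents <- edge[is_tip_child, 1]
  tab <- table(parents)
  kids_per_parent <- table(edge[, 1])
  cherries <- as.integer(names(tab))[
    tab == 2L & kids_per_parent[names(tab)] == 2L]
  if (!length(cherries))
    stop(paste("no cherries (terminal sister pairs) in the tree;",
               "supply rate bounds manually"), call. = FALSE)
  ratios <- numeric(0)
  skipped <- 0L
  for (p in cherries) {
    lens <- edge.lengths_of(tree, p)
    if (min(lens) <= 0) { skipped <- skipped + 1L; next }
    ratios <- c(ratios, max(lens) / min(lens))
  }
  if (skipped)
    warning(sprintf("%d cherr%s with a zero-length terminal branch skipped",
                    skipped, if (skipped == 1L) "y" else "ies"),
            call. = FALSE)
  if (!length(ratios))
    stop(paste("every cherry has a zero-length terminal branch;",
               "supply rate bounds manually"), call. = FALSE)
  ratios
}

edge.lengths_of <- function(tree, parent) {
  tree$edge.length[tree$edge[, 1] == parent]
}

#' Derive a deliberately wide rate interval from the tree itself
#'
#' Heuristic for choosing `[r_min, r_max]` when no external rate knowledge
#' is available.  A central rate is anchored in absolute time,
#' `r_mid = mean molecular root-to-tip length / root_age_anchor` (absolute
#' rates are unidentifiable from a molecular tree alone, so some age anchor
#' is required — typically a believed root age).  The spread comes from the
#' most extreme terminal sister-pair ratio `rho = max(cherry_ratios(tree))`:
#' \deqn{r_{max} = r_{mid} \sqrt{\rho} \cdot inflate, \qquad
#'       r_{min} = r_{mid} / (\sqrt{\rho} \cdot inflate)}
#' so that `r_min * r_max = r_mid^2` (symmetric on the log scale).  The
#' maximum ratio, rather than an average, matches the method's philosophy of
#' bounding rather than estimating; `inflate` (default 2) widens further,
#' following the general advice to favour wider rate intervals unless there
#' is an explicit reason not to.
#'
#' @param tree A `"phylo"` with molecular branch lengths.
#' @param root_age_anchor Positive believed root age (time before present).
#' @param inflate Multiplicative widening factor, `>= 1`; applied
#'   symmetrically on the log scale.
#' @return A [rate_bounds()] object, with attributes `r_mid` and `rho`
#'   recording the intermediate statistics.
#' @examples
#' set_auto_rates(read_tree("((A:2.0,B:0.5):0.5,C:2.0);"),
#'                root_age_anchor = 2, inflate = 1)
#' @export
set_auto_rates <- function(tree, root_age_anchor, inflate = 2) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_scalar_number(root_age_anchor) || root_age_anchor <= 0)
    stop("root_age_anchor must be a single positive number", call. = FALSE)
  if (!is_scalar_number(inflate) || inflate < 1)
    stop("inflate must be a single number >= 1", call. = FALSE)
  rho <- max(cherry_ratios(tree))
  depths <- node.depth.edgelength(tree)[seq_len(Ntip(tree))]
  mean_depth <- mean(depths)
  if (mean_depth <= 0)
    stop("mean molecular root-to-tip length is zero; cannot anchor a rate",
         call. = FALSE)
  r_mid <- mean_depth / root_age_anchor
  spread <- sqrt(rho) * inflate
  out <- rate_bounds(r_mid / spread, r_mid * spread)
  attr(out, "r_mid") <- r_mid
  attr(out, "rho") <- rho
  attr(out, "inflate") <- inflate
  out
}
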