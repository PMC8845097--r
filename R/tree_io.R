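#' Read a rooted phylogeny with molecular branch lengths
#'
#' Parses a single newick statement into an [ape][ape::read.tree] `"phylo"`
#' object and validates it for use by the bounds engine: at least two tips,
#' unique non-empty tip labels, and a finite non-negative branch length on
#' every non-root edge.  Branch lengths are interpreted as expected
#' substitutions per site.
#'
#' Lines starting with `#` and bracketed comment lines (as written by
#' [cli_run()] output headers) are ignored.  A basal polytomy (e.g. an
#' unrooted tree written with a trifurcation at its base) is accepted and
#' treated as a rooted polytomy at the root, with a warning, because the
#' placement of the root affects the age bounds.
#'
#' @param newick_text Character scalar: one newick statement terminated by
#'   `;`, with branch lengths on all non-root edges.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_tree("((A:1.0,B:1.0):1.0,C:2.0);")
#' @export
read_tree <- function(newick_text) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  lines <- strsplit(newick_text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*(#|\\[)", lines) & nzchar(trimws(lines))]
  text <- paste(trimws(lines), collapse = "")
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: no terminating ';' found", call. = FALSE)
  if (grepl(";.*\\S", text))
    stop("newick parse error: text continues after the terminating ';'",
         call. = FALSE)

  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop(sprintf("newick parse error: unmatched ')' at position %d",
                 which(depth < 0)[1]), call. = FALSE)
  if (depth[length(depth)] != 0)
    stop(sprintf(
      "newick parse error: %d unmatched '(' (first opened at position %d)",
      depth[length(depth)], which(depth == depth[length(depth)])[1]),
      call. = FALSE)

  tree <- tryCatch(read.tree(text = text),
                   error = function(e) stop(sprintf(
                     "newick parse error: %s", conditionMessage(e)),
                     call. = FALSE))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: input did not yield a tree", call. = FALSE)
  validate_tree(tree)
}

# Invariant checks shared by read_tree() and the simulator output.
validate_tree <- function(tree) {
  if (Ntip(tree) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty tip label", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop(sprintf("duplicate tip label(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; molecular branch lengths are required",
         call. = FALSE)
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length < 0)
  if (length(bad)) {
    child <- tree$edge[bad[1], 2]
    stop(sprintf(
      "missing, non-finite or negative branch length on the edge above %s",
      node_label_safe(tree, child)), call. = FALSE)
  }
  root <- root_node(tree)
  if (sum(tree$edge[, 1] == root) > 2L)
    warning(paste("basal polytomy: treating the input as a rooted polytomy",
                  "at the root; root placement affects the age bounds"),
            call. = FALSE)
  tree
}

# node_label() needs valid lengths for defining_tips(); during validation use
# a length-free fallback.
node_label_safe <- function(tree, node) {
  if (node <= Ntip(tree)) sprintf("tip %s", tree$tip.label[node])
  else sprintf("internal node %d", node)
}

#' Parse a calibration table into clade-resolved age constraints
#'
#' Reads a TSV with columns `tips`, `min_age` and `max_age` (header
#' required).  `tips` is a semicolon-separated set of tip labels; each row is
#' resolved to the most recent common ancestor (MRCA) of its tip set on
#' `tree`.  Ages are in time before present; use the literal `NA` for an
#' absent bound.  A row with a single tip label addresses that tip, which is
#' pinned at age 0, so such a row must be compatible with age 0.
#'
#' @param table_text Character scalar holding the TSV text (or a vector of
#'   lines).
#' @param tree A `"phylo"` object the constraints refer to.
#' @return A `"calibration_set"`: a data frame with one row per calibrated
#'   node and columns `node` (index in `tree`), `tips` (the input tip set),
#'   `min_age`, `max_age`, sorted by `node`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' parse_calibrations("tips\tmin_age\tmax_age\nA;B\t1.5\tNA\n", tr)
#' @export
parse_calibrations <- function(table_text, tree) {
  stopifnot(is.character(table_text))
  text <- paste(table_text, collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_calibration_set())
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          colClasses = c("character", "character", "character"),
                          na.strings = character(0), strip.white = TRUE)
  req <- c("tips", "min_age", "max_age")
  if (!identical(names(df)[seq_along(req)], req))
    stop(sprintf("calibration table must have header '%s'",
                 paste(req, collapse = "\t")), call. = FALSE)
  parse_age <- function(x, row, field) {
    if (toupper(x) == "NA") return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) || !is.finite(v))
      stop(sprintf("calibration row %d: %s '%s' is not a number or NA",
                   row, field, x), call. = FALSE)
    v
  }
  out <- data.frame(node = integer(0), tips = character(0),
                    min_age = numeric(0), max_age = numeric(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    labels <- trimws(strsplit(df$tips[i], ";", fixed = TRUE)[[1]])
    labels <- labels[nzchar(labels)]
    if (!length(labels))
      stop(sprintf("calibration row %d: empty tip set", i), call. = FALSE)
    unknown <- setdiff(labels, tree$tip.label)
    if (length(unknown))
      stop(sprintf("calibration row %d: unknown tip label(s): %s",
                   i, paste(unknown, collapse = ", ")), call. = FALSE)
    mn <- parse_age(df$min_age[i], i, "min_age")
    mx <- parse_age(df$max_age[i], i, "max_age")
    if (is.na(mn) && is.na(mx))
      stop(sprintf("calibration row %d: both min_age and max_age are NA", i),
           call. = FALSE)
    if (!is.na(mn) && mn < 0)
      stop(sprintf("calibration row %d: min_age must be >= 0", i),
           call. = FALSE)
    if (!is.na(mx) && mx <= 0)
      stop(sprintf("calibration row %d: max_age must be > 0", i),
           call. = FALSE)
    if (!is.na(mn) && !is.na(mx) && mn > mx)
      stop(sprintf("calibration row %d: min_age %g > max_age %g", i, mn, mx),
           call. = FALSE)
    node <- if (length(labels) == 1L) {
      which(tree$tip.label == labels)
    } else {
      getMRCA(tree, unique(labels))
    }
    if (node <= Ntip(tree) && !is.na(mn) && mn > 0)
      stop(sprintf(
        "calibration row %d: tip %s is extant (age 0); a positive min_age is not satisfiable",
        i, labels[1]), call. = FALSE)
    if (node %in% out$node)
      stop(sprintf(
        "calibration row %d: a previous row already calibrates %s",
        i, node_label(tree, node)), call. = FALSE)
    out <- rbind(out, data.frame(node = node, tips = df$tips[i],
                                 min_age = mn, max_age = mx,
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calibration_set", "data.frame")
  out
}

empty_calibration_set <- function() {
  out <- data.frame(node = integer(0), tips = character(0),
                    min_age = numeric(0), max_age = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Construct a chronogram (time-calibrated tree) from node ages
#'
#' A chronogram pairs a tree topology with an age (time before present) for
#' every node.  Extant tips must sit at age 0 and every parent must be at
#' least as old as each of its children.
#'
#' @param tree A `"phylo"` object supplying the topology.
#' @param ages Numeric vector of node ages indexed like the nodes of `tree`
#'   (tips `1..Ntip`, then internal nodes).
#' @return An object of class `"chronogram"`: a list with elements `tree` (a
#'   `"phylo"` whose branch lengths are time durations) and `ages`.
#' @export
chronogram <- function(tree, ages) {
  n_all <- Ntip(tree) + Nnode(tree)
  stopifnot(is.numeric(ages), length(ages) == n_all, all(is.finite(ages)))
  tips <- seq_len(Ntip(tree))
  if (any(abs(ages[tips]) > 1e-12))
    stop("chronogram invariant violated: all tip ages must be 0",
         call. = FALSE)
  durations <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  bad <- which(durations < -feas_tol(ages[tree$edge[, 1]], ages[tree$edge[, 2]]))
  if (length(bad))
    stop(sprintf(
      "chronogram invariant violated: %s is older than its parent",
      node_label(tree, tree$edge[bad[1], 2])), call. = FALSE)
  out <- tree
  out$edge.length <- pmax(durations, 0)
  structure(list(tree = out, ages = ages), class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, root age %.6g\n",
              Ntip(x$tree), x$ages[root_node(x$tree)]))
  invisible(x)
}

#' Write a chronogram as newick text
#'
#' Branch lengths in the output are time durations (parent age minus child
#' age), printed with up to 12 significant digits, so re-reading the text and
#' recomputing node ages from the root height reproduces the ages.
#'
#' @param chronogram An object of class `"chronogram"`.
#' @return Character scalar: a newick statement.
#' @export
write_chronogram <- function(chronogram) {
  stopifnot(inherits(chronogram, "chronogram"))
  # re-validate before writing: parent >= child, tips at 0
  chronogram <- chronogram(chronogram$tree, chronogram$ages)
  write.tree(chronogram$tree, digits = 12)
}

#' Recompute node ages of a chronogram read back from newick
#'
#' Inverse of [write_chronogram()]: takes a tree whose branch lengths are
#' time durations and returns ages measured from the present, taking the
#' deepest tip as the present.
#'
#' @param tree A `"phylo"` with branch lengths in time units.
#' @return A `"chronogram"`.
#' @export
as_chronogram <- function(tree) {
  depth <- node.depth.edgelength(tree)
  ages <- max(depth[seq_len(Ntip(tree))]) - depth
  ages[seq_len(Ntip(tree))][abs(ages[seq_len(Ntip(tree))]) < 1e-9 * max(1, max(depth))] <- 0
  chronogram(tree, ages)
}

#' Write per-node age bounds as a TSV table
#'
#' One row per node in postorder, with columns `node_id` (index in the
#' tree), `defining_tips` (the two lexicographically smallest tip labels of
#' the node's clade, `label;label`; a tip repeats its own label), `min_age`
#' (the youngest feasible age L) and `max_age` (the oldest feasible age U).
#' The output is byte-identical across calls on equal inputs.
#'
#' @param bounds A `"node_age_bounds"` object from [compute_age_bounds()].
#' @param tree The `"phylo"` the bounds were computed for.
#' @return Character scalar: TSV text including the header line.
#' @export
write_bounds_table <- function(bounds, tree) {
  stopifnot(inherits(bounds, "node_age_bounds"))
  edge <- reorder.phylo(tree, "postorder")$edge
  nodes <- c(edge[, 2], root_node(tree))  # postorder, root last
  dt <- defining_tips(tree)
  rows <- sprintf("%d\t%s\t%s\t%s", nodes, dt[nodes],
                  format_age(bounds$L[nodes]), format_age(bounds$U[nodes]))
  paste(c("node_id\tdefining_tips\tmin_age\tmax_age", rows, ""),
        collapse = "\n")
}

format_age <- function(x) {
  ifelse(is.finite(x), sprintf("%.12g", x), "Inf")
}
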