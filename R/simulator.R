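#' Simulation configuration
#'
#' Bundles the parameters of the simulation study design: a pure-birth
#' (Yule) branching process over `n_taxa` extant taxa, optionally with a
#' speciation-rate increase confined to one clade, independent lognormal
#' branch substitution rates, and molecular branch lengths observed either
#' exactly or with finite-site substitution-count noise.
#'
#' Defaults reproduce the reference design: 24 taxa, extinction 0, a 10-fold
#' clade speciation increase available via `shift_factor`, branch rates
#' lognormal with real-space mean 0.05 and variance 0.00025 substitutions
#' per site per time unit, and 50,000 sites.
#'
#' @param n_taxa Number of extant taxa, `>= 3`.
#' @param lambda0 Background speciation rate, `> 0`.
#' @param extinction Extinction rate; only `0` is supported (the design this
#'   simulator implements uses a pure-birth process), any other value errors.
#' @param shift_factor Multiplier applied to the speciation rate of the
#'   shifted clade, `>= 1`; `1` disables the shift.
#' @param shift_trigger_lineages Extant lineage count at which the shifted
#'   clade is seeded (one extant lineage is then marked uniformly at
#'   random), `>= 2`.
#' @param rate_mean Real-space mean of the lognormal branch-rate
#'   distribution (substitutions/site/time).
#' @param rate_var Real-space variance of the branch-rate distribution,
#'   `>= 0`; `0` gives a strict clock at `rate_mean`.
#' @param sites Alignment length in sites, used by the `"poisson"` noise
#'   model.
#' @param noise `"none"` for exact molecular lengths (`rate * duration`) or
#'   `"poisson"` for substitution-count sampling over `sites` sites.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 24L, lambda0 = 1, extinction = 0,
                       shift_factor = 1, shift_trigger_lineages = 4L,
                       rate_mean = 0.05, rate_var = 0.00025,
                       sites = 50000L, noise = c("none", "poisson"),
                       seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is_scalar_number(n_taxa), n_taxa >= 3,
            is_scalar_number(lambda0), lambda0 > 0,
            is_scalar_number(shift_factor), shift_factor >= 1,
            is_scalar_number(shift_trigger_lineages),
            shift_trigger_lineages >= 2,
            is_scalar_number(rate_mean), rate_mean > 0,
            is_scalar_number(rate_var), rate_var >= 0,
            is_scalar_number(sites), sites >= 1)
  if (!is_scalar_number(extinction) || extinction != 0)
    stop(paste("extinction > 0 is not supported: the simulation design is a",
               "pure-birth (Yule) process"), call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa), lambda0 = lambda0,
                 extinction = 0, shift_factor = shift_factor,
                 shift_trigger_lineages = as.integer(shift_trigger_lineages),
                 rate_mean = rate_mean, rate_var = rate_var,
                 sites = as.integer(sites), noise = noise, seed = seed),
            class = "sim_config")
}

#' Simulate a Yule tree with an optional clade speciation-rate shift
#'
#' Forward-time pure-birth simulation starting from two lineages at the
#' root.  Every extant lineage speciates at rate `lambda0`; when the extant
#' lineage count first reaches `shift_trigger_lineages` (and
#' `shift_factor > 1`), one extant lineage chosen uniformly at random is
#' marked, and it and all its descendants thereafter speciate at
#' `lambda0 * shift_factor`.  Births accumulate until `n_taxa` lineages are
#' extant; the tree is then extended by one further exponential waiting
#' time (the time to the next, unobserved birth), so terminal branches have
#' positive length, and returned with all tips at age 0.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.  `NULL` uses the
#'   current RNG state (so a caller can drive many replicates from one
#'   seed).
#' @return A `"time_tree"`: list with `tree` (a `"phylo"` with branch
#'   lengths in time units), `ages` (true node ages, time before present),
#'   `shift_crown` (node index of the crown of the shifted clade, or `NA`
#'   if no shift or the marked lineage never split), and `config`.
#' @export
simulate_yule_shift <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_taxa
  # internal node records (ids 1..n-1; 1 is the root at time 0)
  node_time <- numeric(n - 1L)
  node_parent <- rep(NA_integer_, n - 1L)
  next_internal <- 2L
  # extant lineages: the internal node each hangs from, and shift marking
  lin_parent <- c(1L, 1L)
  lin_marked <- c(FALSE, FALSE)
  shift_pending <- config$shift_factor > 1
  shift_crown_internal <- NA_integer_
  t <- 0

  repeat {
    k <- length(lin_parent)
    if (shift_pending && k >= config$shift_trigger_lineages) {
      lin_marked[sample.int(k, 1L)] <- TRUE
      shift_pending <- FALSE
    }
    lrates <- ifelse(lin_marked, config$lambda0 * config$shift_factor,
                     config$lambda0)
    dt <- stats::rexp(1L, sum(lrates))
    t <- t + dt
    if (k == n) break  # stop just before the (n+1)-th birth
    j <- sample.int(k, 1L, prob = lrates)
    id <- next_internal
    node_time[id] <- t
    node_parent[id] <- lin_parent[j]
    if (lin_marked[j] && is.na(shift_crown_internal))
      shift_crown_internal <- id
    lin_parent[j] <- id
    lin_parent <- c(lin_parent, id)
    lin_marked <- c(lin_marked, lin_marked[j])
    next_internal <- next_internal + 1L
  }

  # assemble the phylo object: tips 1..n, internal id i -> n + i
  edge <- matrix(0L, 2L * n - 2L, 2L)
  edge_len <- numeric(2L * n - 2L)
  for (i in seq_len(n)) {
    edge[i, ] <- c(n + lin_parent[i], i)
    edge_len[i] <- t - node_time[lin_parent[i]]
  }
  for (id in 2:(n - 1L)) {
    edge[n + id - 1L, ] <- c(n + node_parent[id], n + id)
    edge_len[n + id - 1L] <- node_time[id] - node_time[node_parent[id]]
  }
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         Nnode = n - 1L,
                         tip.label = paste0("t", seq_len(n))),
                    class = "phylo")
  tree <- reorder.phylo(tree, "cladewise")
  ages <- c(rep(0, n), t - node_time)
  structure(list(tree = tree, ages = ages,
                 shift_crown = if (is.na(shift_crown_internal)) NA_integer_
                               else n + shift_crown_internal,
                 config = config),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time tree: %d tips, root age %.6g%s\n", Ntip(x$tree),
              x$ages[root_node(x$tree)],
              if (!is.na(x$shift_crown))
                sprintf(", shifted clade crown at node %d", x$shift_crown)
              else ""))
  invisible(x)
}

#' Draw independent lognormal substitution rates for every branch
#'
#' Each branch receives an independent draw from a lognormal distribution
#' parameterised by its real-space mean `m` and variance `v`: in log space,
#' `sigma^2 = log(1 + v / m^2)` and `mu = log(m) - sigma^2 / 2`.  `v = 0`
#' gives the strict-clock degenerate case, a constant rate `m`.
#'
#' @param time_tree A `"time_tree"` from [simulate_yule_shift()].
#' @param m Real-space mean rate, `> 0`.
#' @param v Real-space rate variance, `>= 0`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return The `"time_tree"` with a `rates` element: per-edge rates aligned
#'   with `tree$edge` rows.
#' @export
draw_branch_rates <- function(time_tree, m, v, seed = NULL) {
  stopifnot(inherits(time_tree, "time_tree"),
            is_scalar_number(m), m > 0, is_scalar_number(v), v >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_edge <- nrow(time_tree$tree$edge)
  time_tree$rates <- lognormal_mv(n_edge, m, v)
  time_tree
}

# lognormal draws parameterised by real-space mean and variance
lognormal_mv <- function(n, m, v) {
  if (v == 0) return(rep(m, n))
  sigma2 <- log(1 + v / m^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Transform a time tree with rates into a molecular tree
#'
#' Converts branch durations into molecular branch lengths (expected
#' substitutions per site).  With `noise = "none"` each branch gets exactly
#' `rate * duration`.  With `noise = "poisson"` the substitution count over
#' `sites` sites is drawn as `Poisson(rate * duration * sites)` and the
#' branch length is `count / sites`, emulating the sampling error of
#' branch-length estimation from a finite alignment at low divergence
#' (multiple hits are negligible there).
#'
#' @param time_tree A `"time_tree"` with rates assigned by
#'   [draw_branch_rates()].
#' @param sites Alignment length, `>= 1` (used only under `"poisson"`).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `"phylo"` with molecular branch lengths, same topology and tip
#'   labels as the input.
#' @export
molecularize <- function(time_tree, sites = 50000L,
                         noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(time_tree, "time_tree"))
  if (is.null(time_tree$rates))
    stop("assign branch rates with draw_branch_rates() first", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  expected <- time_tree$rates * time_tree$tree$edge.length
  out <- time_tree$tree
  out$edge.length <- switch(noise,
    none = expected,
    poisson = {
      stopifnot(sites >= 1)
      stats::rpois(length(expected), expected * sites) / sites
    })
  out
}

# Build a calibration_set programmatically from node indices.
make_calibration_set <- function(tree, node, min_age = NA_real_,
                                 max_age = NA_real_) {
  dt <- defining_tips(tree)
  out <- data.frame(node = as.integer(node), tips = dt[node],
                    min_age = as.numeric(min_age),
                    max_age = as.numeric(max_age),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Run a coverage experiment over simulated replicates
#'
#' For each replicate: simulate a (possibly rate-shifted) Yule time tree,
#' draw lognormal branch rates, produce the molecular tree, choose rate
#' bounds, apply calibrations, compute feasible age intervals with
#' [compute_age_bounds()], and record whether each internal node's true age
#' falls inside its interval.
#'
#' Rate bounds: `"true_envelope"` uses the exact range of the replicate's
#' true branch rates (the idealised best case — under noiseless molecular
#' lengths, coverage of every true node age is then guaranteed);
#' `"autorates"` derives bounds with [set_auto_rates()], anchored at the
#' true root age.
#'
#' Calibrations: the root age is always treated as known (root minimum and
#' maximum both set to the true root age).  With
#' `calibration_mode = "min_at_shift_crown"` a minimum age constraint equal
#' to 90% of the true crown age of the shifted clade is added at that crown
#' node.
#'
#' @param config A [sim_config()]; its `seed` drives all replicates.
#' @param reps Number of replicates, `>= 1`.
#' @param rate_bounds_mode `"true_envelope"` or `"autorates"`.
#' @param calibration_mode `"none"` or `"min_at_shift_crown"` (requires
#'   `config$shift_factor > 1`).
#' @param inflate Widening factor passed to [set_auto_rates()] in
#'   `"autorates"` mode.
#' @return A `"coverage_report"`: list with `per_node` (data frame: `rep`,
#'   `node`, `defining_tips`, `true_age`, `L`, `U`, `covered`),
#'   `calibrated` (data frame of the calibrated shift-crown node per
#'   replicate, if any), `coverage` (proportion of true internal-node ages
#'   inside their interval), `mean_rel_width` (mean of `(U - L) / true_age`
#'   over internal nodes with positive true age), `n_reps`, and
#'   `n_infeasible` (replicates whose constraints were infeasible; these
#'   contribute no covered nodes and are reported, never dropped silently).
#' @export
run_coverage_experiment <- function(config, reps,
                                    rate_bounds_mode = c("true_envelope",
                                                         "autorates"),
                                    calibration_mode = c("none",
                                                         "min_at_shift_crown"),
                                    inflate = 2) {
  stopifnot(inherits(config, "sim_config"))
  rate_bounds_mode <- match.arg(rate_bounds_mode)
  calibration_mode <- match.arg(calibration_mode)
  if (!is_scalar_number(reps) || reps < 1)
    stop("reps must be >= 1", call. = FALSE)
  if (calibration_mode == "min_at_shift_crown" && config$shift_factor <= 1)
    stop("calibration_mode = 'min_at_shift_crown' requires shift_factor > 1",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  loop_config <- config
  loop_config$seed <- NULL

  per_node <- vector("list", reps)
  calibrated <- vector("list", reps)
  n_infeasible <- 0L
  for (r in seq_len(reps)) {
    tt <- simulate_yule_shift(loop_config, seed = NULL)
    tt <- draw_branch_rates(tt, config$rate_mean, config$rate_var)
    mol <- molecularize(tt, config$sites, config$noise)
    rb <- switch(rate_bounds_mode,
      true_envelope = rate_bounds(min(tt$rates), max(tt$rates)),
      autorates = set_auto_rates(mol, root_age_anchor =
                                   tt$ages[root_node(tt$tree)],
                                 inflate = inflate))
    root <- root_node(tt$tree)
    root_age <- tt$ages[root]
    cal_nodes <- root
    cal_min <- root_age
    cal_max <- root_age
    if (calibration_mode == "min_at_shift_crown" && !is.na(tt$shift_crown)) {
      cal_nodes <- c(cal_nodes, tt$shift_crown)
      cal_min <- c(cal_min, 0.9 * tt$ages[tt$shift_crown])
      cal_max <- c(cal_max, NA_real_)
    }
    cal <- make_calibration_set(mol, cal_nodes, cal_min, cal_max)

    bounds <- tryCatch(compute_age_bounds(mol, rb, cal),
                       chronobounds_infeasible = function(e) NULL)
    if (is.null(bounds)) { n_infeasible <- n_infeasible + 1L; next }

    internals <- (Ntip(mol) + 1L):(Ntip(mol) + Nnode(mol))
    age <- tt$ages[internals]
    L <- bounds$L[internals]
    U <- bounds$U[internals]
    tol <- feas_tol(age, age)
    per_node[[r]] <- data.frame(
      rep = r, node = internals, defining_tips = defining_tips(mol)[internals],
      true_age = age, L = L, U = U,
      covered = (L - tol <= age) & (age <= U + tol),
      stringsAsFactors = FALSE)
    if (calibration_mode == "min_at_shift_crown" && !is.na(tt$shift_crown))
      calibrated[[r]] <- data.frame(
        rep = r, node = tt$shift_crown,
        true_age = tt$ages[tt$shift_crown],
        L = bounds$L[tt$shift_crown], U = bounds$U[tt$shift_crown])
  }
  per_node <- do.call(rbind, per_node)
  calibrated <- do.call(rbind, calibrated)
  pos <- per_node$true_age > 0 & is.finite(per_node$U)
  structure(list(
    per_node = per_node,
    calibrated = calibrated,
    coverage = mean(per_node$covered),
    mean_rel_width = mean((per_node$U[pos] - per_node$L[pos]) /
                            per_node$true_age[pos]),
    n_reps = reps, n_infeasible = n_infeasible,
    rate_bounds_mode = rate_bounds_mode,
    calibration_mode = calibration_mode),
    class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage experiment: %d replicates (%s rate bounds, calibration %s)\n",
    x$n_reps, x$rate_bounds_mode, x$calibration_mode))
  cat(sprintf("  true internal-node ages covered: %.1f%% (%d/%d nodes)\n",
              100 * x$coverage, sum(x$per_node$covered), nrow(x$per_node)))
  cat(sprintf("  mean relative interval width (U - L) / true age: %.3g\n",
              x$mean_rel_width))
  if (x$n_infeasible)
    cat(sprintf("  infeasible replicates: %d\n", x$n_infeasible))
  invisible(x)
}
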