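test_that("branch_interval applies the rate bounds in the right direction", {
  rb <- rate_bounds(0.5, 2)
  iv <- branch_interval(1.0, rb)
  expect_equal(iv$lb, 0.5)
  expect_equal(iv$ub, 2.0)
  expect_equal(branch_interval(0, rb), list(lb = 0, ub = 0))
  strict <- branch_interval(2, rate_bounds(1, 1))
  expect_equal(strict$lb, 2)
  expect_equal(strict$ub, 2)
  expect_error(branch_interval(-1, rb), ">= 0")
})

test_that("rate_bounds rejects degenerate rate intervals", {
  expect_error(rate_bounds(0, 1), "r_min must be > 0")
  expect_error(rate_bounds(2, 1), "must not exceed")
  expect_error(rate_bounds(1, Inf), "finite")
})

test_that("the worked example yields the expected feasible intervals", {
  tr <- worked_tree()
  cal <- parse_calibrations("tips\tmin_age\tmax_age\nA;B;C\tNA\t10\n", tr)
  up <- upward_pass(tr, worked_rates(), cal)
  ab <- mrca_ab(tr); root <- 4
  expect_equal(up$L_up[ab], 0.5)
  expect_equal(up$U_up[ab], 2.0)
  expect_equal(up$L_up[root], 1.0)
  expect_equal(up$U_up[root], 4.0)
  b <- compute_age_bounds(tr, worked_rates(), cal)
  expect_equal(b$L[c(ab, root)], c(0.5, 1.0))
  expect_equal(b$U[c(ab, root)], c(2.0, 4.0))
  expect_equal(b$L[1:3], c(0, 0, 0))
  expect_equal(b$U[1:3], c(0, 0, 0))
})

test_that("a minimum age calibration propagates upward to ancestors", {
  tr <- worked_tree()
  cal <- parse_calibrations("tips\tmin_age\tmax_age\nA;B\t1.5\tNA\n", tr)
  b <- compute_age_bounds(tr, worked_rates(), cal)
  expect_equal(b$L[mrca_ab(tr)], 1.5)
  expect_equal(b$U[mrca_ab(tr)], 2.0)
  expect_equal(b$L[4], 2.0)  # L(root) = max(1.5 + 0.5, 1.0)
  expect_equal(b$U[4], 4.0)
})

test_that("a root maximum age calibration propagates down to descendants", {
  tr <- worked_tree()
  cal <- parse_calibrations("tips\tmin_age\tmax_age\nA;B;C\tNA\t2.5\n", tr)
  b <- compute_age_bounds(tr, worked_rates(), cal)
  expect_equal(b$U[mrca_ab(tr)], 2.0)  # min(2.0, 2.5 - 0.5)
  expect_equal(b$L[4], 1.0)
  expect_equal(b$U[4], 2.5)
})

test_that("a known root age pins the root and tightens descendants", {
  tr <- worked_tree()
  cal <- parse_calibrations("tips\tmin_age\tmax_age\nA;B;C\t2\t2\n", tr)
  b <- compute_age_bounds(tr, worked_rates(), cal)
  expect_equal(b$L[4], 2)
  expect_equal(b$U[4], 2)
  expect_equal(b$L[mrca_ab(tr)], 0.5)
  expect_equal(b$U[mrca_ab(tr)], 1.5)  # min(2.0, 2 - 0.5)
})

test_that("conflicting branch lengths raise infeasibility naming the node", {
  err <- tryCatch(compute_age_bounds(infeasible_tree(), worked_rates()),
                  chronobounds_infeasible = function(e) e)
  expect_s3_class(err, "chronobounds_infeasible")
  expect_match(conditionMessage(err), "MRCA(A,B)", fixed = TRUE)
  expect_match(conditionMessage(err), "2.*exceeds.*1")
})

test_that("a max-age below a propagated min-age is caught downward", {
  # min 3 at MRCA(A,B) forces the root to >= 3.5, allowed (root max 10);
  # but max 0.8 at MRCA(A,B) with min 3 at root: root min pushes AB to
  # L = 3 - 2 = 1 > 0.8
  tr <- worked_tree()
  cal <- parse_calibrations(
    "tips\tmin_age\tmax_age\nA;B\tNA\t0.8\nA;B;C\t3\tNA\n", tr)
  err <- tryCatch(compute_age_bounds(tr, worked_rates(), cal),
                  chronobounds_infeasible = function(e) e)
  expect_s3_class(err, "chronobounds_infeasible")
  expect_match(conditionMessage(err), "MRCA(A,B)", fixed = TRUE)
})

test_that("strict clock on an ultrametric tree gives point ages depth/r", {
  tr <- read_tree("((A:1,B:1):1,C:2);")
  b <- compute_age_bounds(tr, rate_bounds(1, 1))
  expect_equal(b$L, b$U)
  expect_equal(b$L[4:5], c(2, 1))
})

test_that("extreme chronograms take all-L and all-U ages and extreme rates", {
  tr <- worked_tree()
  cal <- parse_calibrations("tips\tmin_age\tmax_age\nA;B;C\tNA\t10\n", tr)
  b <- compute_age_bounds(tr, worked_rates(), cal)
  ch <- build_extreme_chronograms(b, tr)
  expect_equal(ch$tree_min$ages[4:5], c(1, 0.5))
  expect_equal(ch$tree_max$ages[4:5], c(4, 2))
  expect_equal(write_chronogram(ch$tree_min), "((A:0.5,B:0.5):0.5,C:1);")
  # on tree_min every branch ran at r_max; on tree_max at r_min
  expect_equal(unique(implied_branch_rates(ch$tree_min, tr)), 2)
  expect_equal(unique(implied_branch_rates(ch$tree_max, tr)), 0.5)
})

test_that("zero-length terminal branches pin their parent at age 0", {
  tr <- read_tree("((A:0,B:0):1,C:2);")
  b <- compute_age_bounds(tr, worked_rates())
  expect_equal(b$L[5], 0)
  expect_equal(b$U[5], 0)
  expect_true(all(is.finite(b$U)))  # r_min > 0 bounds every age
})

test_that("implied_branch_rates flags undefined and impossible rates", {
  tr <- read_tree("((A:0,B:0):1,C:2);")
  cg <- chronogram(tr, c(0, 0, 0, 2, 0))  # zero-subs cherry collapsed to 0
  r <- implied_branch_rates(cg, tr)
  expect_true(all(is.na(r[tr$edge[, 2] <= 2])))  # 0 subs / 0 time: undefined
  cg2 <- chronogram(worked_tree(), c(0, 0, 0, 2, 0))
  expect_error(implied_branch_rates(cg2, worked_tree()), "zero duration")
})

test_that("widening rates or dropping calibrations never tightens bounds", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:20) {
    tr <- random_tree(sample(5:20, 1))
    r1 <- random_rates()
    r2 <- rate_bounds(r1$r_min / 2, r1$r_max * 2)
    # a random non-clock tree can be infeasible under narrow rates; the
    # monotonicity property is about feasible baselines
    b1 <- tryCatch(compute_age_bounds(tr, r1),
                   chronobounds_infeasible = function(e) NULL)
    if (is.null(b1)) next
    n_checked <- n_checked + 1L
    b2 <- compute_age_bounds(tr, r2)
    tol <- 1e-9 * pmax(1, abs(b1$L))
    expect_true(all(b2$L <= b1$L + tol))
    expect_true(all(b2$U >= b1$U - tol))
    # adding a consistent calibration never widens
    root <- chronobounds:::root_node(tr)
    cal <- chronobounds:::make_calibration_set(
      tr, root, min_age = b1$L[root], max_age = b1$U[root])
    b3 <- compute_age_bounds(tr, r1, cal)
    expect_true(all(b3$L >= b1$L - tol))
    expect_true(all(b3$U <= b1$U + tol))
  }
  expect_gt(n_checked, 5)
})

test_that("polytomies and zero-length branches are handled", {
  tr <- read_tree("((A:1,B:1,C:1):0,D:1);")
  b <- compute_age_bounds(tr, rate_bounds(1, 1))
  # zero-length internal edge collapses root and MRCA(A,B,C) to equal age
  expect_equal(b$L[5], b$L[6])
  expect_equal(b$U[5], b$U[6])
  both <- bounds_both_ways(tr, worked_rates())
  expect_bounds_agree(both)
})
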