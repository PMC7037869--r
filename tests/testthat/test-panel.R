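test_that("assessment validation enforces the 0-4 integer scale and zero diagonal", {
  labs3 <- paste0("D", 1:3)
  expect_silent(validate_assessment(named_square(rep(0, 9)), labs3))

  labs2 <- paste0("D", 1:2)
  expect_error(validate_assessment(named_square(c(0, 5, 1, 0)), labs2),
               "\\(1,2\\)=5")
  expect_error(validate_assessment(named_square(c(1, 2, 3, 0)), labs2),
               "diagonal \\(1,1\\)")
  expect_error(validate_assessment(named_square(c(0, 2.5, 1, 0)), labs2),
               "0-4 integer")
  expect_error(validate_assessment(named_square(rep(0, 9)), labs2),
               "3x3.*2 departments")
  expect_error(influence_assessment("e", matrix(0, 1, 1,
                                                dimnames = list("D1", "D1"))),
               "at least 2")
})

test_that("rank-weighted aggregation matches hand arithmetic", {
  p <- two_expert_panel(c(2, 1))
  m1 <- influence_assessment("e1", named_square(c(0, 4, 2, 0)))
  m2 <- influence_assessment("e2", named_square(c(0, 1, 2, 0)))
  z <- aggregate_influence(list(m1, m2), p)
  # (2*4 + 1*1)/3 = 3 ; (2*2 + 1*2)/3 = 2
  expect_equal(unclass(z)[1, 2], 3)
  expect_equal(unclass(z)[2, 1], 2)
  expect_equal(diag(unclass(z)), c(D1 = 0, D2 = 0))
})

test_that("single expert and identical matrices pass through unchanged", {
  p <- expert_panel("solo", "infection", 1)
  m <- named_square(c(0, 3, 1, 0))
  z1 <- aggregate_influence(list(influence_assessment("solo", m)), p)
  expect_equal(unclass(z1), m, ignore_attr = TRUE)

  p3 <- expert_panel(c("a", "b", "c"), rep("infection", 3), c(1, 1, 1))
  same <- lapply(c("a", "b", "c"), influence_assessment, matrix = m)
  expect_equal(unclass(aggregate_influence(same, p3)), m, ignore_attr = TRUE)
})

test_that("aggregation is permutation-invariant, convex and rank-scale invariant", {
  set.seed(7)
  labs <- paste0("D", 1:4)
  p <- expert_panel(c("a", "b", "c"), rep("infection", 3), c(3, 2, 1))
  mats <- replicate(3, {
    m <- matrix(sample(0:4, 16, TRUE), 4, 4, dimnames = list(labs, labs))
    diag(m) <- 0
    m
  }, simplify = FALSE)
  as <- Map(influence_assessment, c("a", "b", "c"), mats)
  z <- aggregate_influence(as, p)
  z_rev <- aggregate_influence(rev(as), p)
  expect_equal(unclass(z), unclass(z_rev))

  lo <- Reduce(pmin, mats)
  hi <- Reduce(pmax, mats)
  expect_true(all(unclass(z) >= lo - 1e-12 & unclass(z) <= hi + 1e-12))

  p5 <- expert_panel(c("a", "b", "c"), rep("infection", 3), 5 * c(3, 2, 1))
  expect_equal(unclass(aggregate_influence(as, p5)), unclass(z), ignore_attr = TRUE)

  p_eq <- expert_panel(c("a", "b", "c"), rep("infection", 3), c(2, 2, 2))
  expect_equal(unclass(aggregate_influence(as, p_eq)),
               Reduce(`+`, mats) / 3, ignore_attr = TRUE)
})

test_that("aggregation aligns departments by label, not position", {
  labs <- c("D1", "D2", "D3")
  m1 <- matrix(c(0, 1, 2, 3, 0, 4, 1, 2, 0), 3, 3, byrow = TRUE,
               dimnames = list(labs, labs))
  perm <- c("D3", "D1", "D2")
  m2 <- m1[perm, perm]
  p <- two_expert_panel(c(1, 1))
  z <- aggregate_influence(list(influence_assessment("e1", m1),
                                influence_assessment("e2", m2)), p)
  expect_equal(unclass(z), m1, ignore_attr = TRUE)
  expect_equal(attr(z, "departments"), labs)
})

test_that("aggregation rejects unknown experts, empty panels, label mismatches", {
  p <- two_expert_panel()
  m <- influence_assessment("ghost", named_square(c(0, 1, 1, 0)))
  expect_error(aggregate_influence(list(m), p), "unknown expert")
  expect_error(aggregate_influence(list(), p), "at least one")
  other <- influence_assessment("e2", named_square(c(0, 1, 1, 0), c("X", "Y")))
  ok <- influence_assessment("e1", named_square(c(0, 1, 1, 0)))
  expect_error(aggregate_influence(list(ok, other), p),
               "inconsistent department")
  expect_error(expert_panel(c("a", "a"), rep("infection", 2), c(1, 1)),
               "duplicate")
  expect_error(expert_panel("a", "infection", 0), "positive integer")
})

test_that("decision-value aggregation is a bounded rank-weighted mean", {
  p <- two_expert_panel(c(3, 1), cluster = "managerial")
  t1 <- matrix(100, 1, 1, dimnames = list("MR1", "ED1"))
  t2 <- matrix(0, 1, 1, dimnames = list("MR1", "ED1"))
  out <- aggregate_decision_values(list(e1 = t1, e2 = t2), p)
  expect_equal(out[1, 1], 75)  # (3*100 + 1*0)/4

  solo <- expert_panel("e1", "managerial", 2)
  expect_equal(aggregate_decision_values(list(e1 = t1), solo), t1)

  t50 <- matrix(50, 2, 3, dimnames = list(c("MR1", "MR2"), paste0("ED", 1:3)))
  out50 <- aggregate_decision_values(list(e1 = t50, e2 = t50), p)
  expect_true(all(out50 == 50))

  bad <- matrix(120, 1, 1, dimnames = list("MR1", "ED1"))
  expect_error(aggregate_decision_values(list(e1 = t1, e2 = bad), p),
               "\\[0, 100\\]")
  wrong <- matrix(1, 2, 1, dimnames = list(c("MR1", "MR2"), "ED1"))
  expect_error(aggregate_decision_values(list(e1 = t1, e2 = wrong), p),
               "same shape")
})
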