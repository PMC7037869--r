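test_that("risk mapping rescales |R-C| onto 0-100 as specified", {
  profile <- list(relation = c(A = 0, B = -1, C = 2),
                  departments = c("A", "B", "C"))
  sc <- dematel_to_risk_scores(profile, "abs_minmax")
  expect_equal(as.vector(sc), c(0, 50, 100))

  degenerate <- list(relation = c(A = 1, B = -1), departments = c("A", "B"))
  expect_warning(sc50 <- dematel_to_risk_scores(degenerate, "abs_minmax"),
                 "degenerate")
  expect_equal(as.vector(sc50), c(50, 50))

  rb <- dematel_to_risk_scores(profile, "rank_based")
  expect_equal(as.vector(rb), c(0, 50, 100))

  manual <- dematel_to_risk_scores(profile, "manual",
                                   overrides = c(C = 10, A = 20, B = 30))
  expect_equal(as.vector(manual), c(20, 30, 10))  # reordered to departments
  expect_error(dematel_to_risk_scores(profile, "manual",
                                      overrides = c(A = 1)), "missing")
  expect_error(dematel_to_risk_scores(profile, "manual",
                                      overrides = c(A = 1, B = 2, C = 101)),
               "\\[0, 100\\]")
})

test_that("injecting the risk criterion renormalises weights jointly", {
  V <- matrix(c(10, 20, 30, 40), 2, 2,
              dimnames = list(c("m1", "m2"), c("A", "B")))
  w <- criterion_set(c("m1", "m2"), c(50, 50))
  risk <- c(A = 80, B = 20)
  merged <- inject_risk_criterion(V, w, risk, risk_weight = 100)
  expect_equal(dim(merged$values), c(3, 2))
  expect_equal(unname(merged$weights$normalized_weights), c(0.25, 0.25, 0.5))
  expect_equal(merged$values["infection_risk", ], risk)

  # zero-weight risk criterion leaves the ranking untouched
  merged0 <- inject_risk_criterion(V, w, risk, risk_weight = 0)
  expect_equal(wsm(merged0$weights, merged0$values)$totals,
               wsm(w, V)$totals)

  expect_error(inject_risk_criterion(V, w, c(A = 1)), "missing")
})

test_that("the pipeline runs end to end on synthetic panels and conserves R-C", {
  case <- generate_case(synth_config(n_departments = 8, seed = 3))
  res <- run_pipeline(list(panel = case$panel,
                           assessments = case$assessments,
                           weights_tables = case$weights_tables,
                           values_tables = case$values_tables,
                           top_k = 3))
  expect_s3_class(res, "hybrid_ranking")
  expect_lt(abs(sum(res$dematel$relation)), 1e-9)
  expect_equal(nrow(res$shortlist), 3)
  expect_true(all(res$shortlist$alternative %in% case$departments))
  expect_output(print(res), "shortlist")
  s <- summary(res)
  expect_equal(nrow(s), 8)
  expect_equal(sum(s$shortlisted), 3)
})

test_that("extreme weight settings collapse the hybrid to its parts", {
  case <- generate_case(synth_config(n_departments = 6, seed = 5))
  cfg <- list(panel = case$panel, assessments = case$assessments,
              weights_tables = case$weights_tables,
              values_tables = case$values_tables, top_k = 6)
  res0 <- run_pipeline(c(cfg, list(risk_weight = 0)))
  # managerial-only reference
  vals <- aggregate_decision_values(case$values_tables, case$panel)
  tabs <- lapply(case$weights_tables, function(w)
    matrix(w, ncol = 1, dimnames = list(names(w), "weight")))
  raw_w <- drop(aggregate_decision_values(tabs, case$panel))
  ref <- wsm(criterion_set(rownames(vals), raw_w[rownames(vals)]), vals)
  expect_equal(res0$shortlist$alternative, ref$ranking)

  # all managerial weights zero: ranking ordered by risk scores alone
  zero_w <- lapply(case$weights_tables, function(w) 0 * w)
  res_risk <- run_pipeline(list(panel = case$panel,
                                assessments = case$assessments,
                                weights_tables = zero_w,
                                values_tables = case$values_tables,
                                top_k = 6))
  risk_order <- names(sort(res_risk$risk_scores, decreasing = TRUE))
  expect_equal(res_risk$shortlist$alternative, risk_order)
})

test_that("pipeline reruns are deterministic and stage errors are labelled", {
  case <- generate_case(synth_config(n_departments = 5, seed = 9))
  cfg <- list(panel = case$panel, assessments = case$assessments,
              weights_tables = case$weights_tables,
              values_tables = case$values_tables)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_equal(r1$wsm$totals, r2$wsm$totals)
  expect_equal(r1$shortlist, r2$shortlist)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_pipeline_artifacts(r1, d1)
  write_pipeline_artifacts(r2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))

  bad <- cfg
  bad$assessments <- cfg$assessments[1]  # drop the rest: panel still larger, fine
  bad$assessments[[1]]$matrix[1, 2] <- 9
  expect_error(run_pipeline(bad), "^\\[aggregation\\]")
  bad2 <- cfg
  bad2$risk_mode <- "manual"
  expect_error(run_pipeline(bad2), "^\\[risk_mapping\\]")
})

test_that("the case-study fixtures drive the documented shortlist", {
  f3 <- load_fixture("bahonar_table3")
  totals <- colSums(f3$weighted_cells)
  ord <- names(sort(totals, decreasing = TRUE))
  expect_equal(ord[1:4], c("ED10", "ED17", "ED18", "ED11"))
})
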