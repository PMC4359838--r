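test_that("two-manifest data yields the unique single-latent topology", {
  set.seed(6)
  X <- matrix(rbinom(400, 1, 0.5), 200, dimnames = list(NULL, c("a", "b")))
  X[, "b"] <- ifelse(runif(200) < 0.8, X[, "a"], X[, "b"])
  sr <- search_structure(symptom_matrix(X),
                         search_config(seed = 4, init_restarts = 2))
  expect_length(latent_vars(sr$model), 1L)
  expect_setequal(unname(leaf_partition(sr$model)), latent_vars(sr$model))
})

test_that("search separates two strongly planted blocks", {
  spec <- planted_spec(list(
    planted_block("A", paste0("a", 1:4), loading = 0.85),
    planted_block("B", paste0("b", 1:4), loading = 0.85)),
    n_records = 2000, seed = 31)
  sim <- simulate_cohort(spec)
  sr <- search_structure(sim$data, search_config(seed = 8))
  expect_gte(length(latent_vars(sr$model)), 2L)
  expect_equal(ari(leaf_partition(sr$model), sim$partition), 1.0)
  # the trace records the accepted trajectory with strictly increasing BIC
  acc <- sr$trace[sr$trace$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$bic_after > acc$bic_before))
  # every intermediate structure is valid: the final model certainly is
  validate_ltm(sr$model)
})

test_that("i.i.d. coin columns collapse to a simple model", {
  set.seed(13)
  X <- matrix(rbinom(2000 * 5, 1, 0.5), 2000,
              dimnames = list(NULL, paste0("c", 1:5)))
  sr <- search_structure(symptom_matrix(X), search_config(seed = 3))
  expect_length(latent_vars(sr$model), 1L)
  expect_lte(sr$model$card[[latent_vars(sr$model)]], 2L)
  # the selected model's BIC beats every multi-latent candidate tried
  tried <- sr$trace[sr$trace$operator == "node_introduction", ]
  if (nrow(tried) > 0) expect_true(all(sr$bic >= tried$bic_after - 1e-6))
})

test_that("node introduction requires siblings and respects max_latents", {
  set.seed(40)
  m <- random_ltm(1, 4)
  cand <- operator_node_introduction(m, c("x1", "x3"))
  expect_true("L1" %in% latent_vars(cand))
  expect_equal(cand$parent[["x1"]], "L1")
  expect_equal(cand$parent[["L1"]], "H1")
  expect_error(operator_node_introduction(m, c("x1", "L9")),
               class = "lantree_schema_error")
  # d changes by the new node's parameters plus the re-parented pair's
  # CPTs shrinking from card(H1) to 2 rows
  d0 <- lantree:::n_free_params(m)
  ch1 <- m$card[["H1"]]
  expect_equal(lantree:::n_free_params(cand),
               d0 + (2 - 1) * ch1 + 2 * (2 - ch1))
})

test_that("introduction then deletion restores BIC within EM noise", {
  spec <- planted_spec(list(planted_block("A", paste0("a", 1:5), loading = 0.7)),
                       n_records = 800, seed = 2)
  sim <- simulate_cohort(spec)
  str <- flat_structure(paste0("a", 1:5), name = "R")
  f0 <- fit_em(str, sim$data, restarts = 3, seed = 5)
  b0 <- bic_score(f0$model, sim$data, loglik = f0$loglik)
  cand <- operator_node_introduction(f0$model, c("a1", "a2"))
  f1 <- fit_em(cand, sim$data, restarts = 2, seed = 6, init = "current")
  back <- lantree:::delete_latent(f1$model, "L1")
  f2 <- fit_em(back, sim$data, restarts = 2, seed = 7, init = "current")
  b2 <- bic_score(f2$model, sim$data, loglik = f2$loglik)
  expect_lt(abs(b2 - b0), 5)
})

test_that("state adjustment respects bounds and round-trips", {
  set.seed(21)
  m <- random_ltm(1, 5, max_card = 2)
  expect_error(operator_state_adjustment(m, "H1", -1, 2, 5),
               class = "lantree_bound_error")
  up <- operator_state_adjustment(m, "H1", +1, 2, 5)
  expect_equal(up$card[["H1"]], 3L)
  validate_ltm(up)
  down <- operator_state_adjustment(up, "H1", -1, 2, 5)
  expect_equal(down$card[["H1"]], 2L)
  validate_ltm(down)
})

test_that("relocation is identity to the same parent and rejects cycles", {
  set.seed(30)
  m <- random_ltm(2, 4)
  expect_identical(operator_relocation(m, "x1", m$parent[["x1"]]), m)
  expect_error(operator_relocation(m, "H1", "H2"),
               class = "lantree_schema_error")  # H2 sits under H1: cycle
  moved <- operator_relocation(m, "x1", "H2")
  expect_equal(moved$parent[["x1"]], "H2")
  expect_null(moved$cpts[["x1"]])
})

test_that("a mis-attached manifest is relocated on strong-signal data", {
  spec <- planted_spec(list(
    planted_block("A", paste0("a", 1:4), loading = 0.85),
    planted_block("B", paste0("b", 1:4), loading = 0.85)),
    n_records = 2000, seed = 77)
  sim <- simulate_cohort(spec)
  sr <- search_structure(sim$data, search_config(seed = 10))
  part <- leaf_partition(sr$model)
  expect_equal(part[["a4"]], part[["a1"]])
  expect_false(part[["a4"]] == part[["b1"]])
})
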