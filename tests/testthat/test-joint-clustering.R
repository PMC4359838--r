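# Joint clustering fixtures are built at reduced scale: a base model is
# learned (or planted) over a handful of blocks and factors pool subsets of
# the block latents.

test_that("exclusions are a pure order-preserving set difference", {
  z1 <- c("stomach bloating", "chills", "hypochondriac pain", "stomachache",
          "dizziness", "chest distress", "abdominal distension")
  out <- apply_exclusions(z1, c("chills", "dizziness"))
  expect_equal(out, c("stomach bloating", "hypochondriac pain", "stomachache",
                      "chest distress", "abdominal distension"))
  expect_length(out, 5L)
  expect_identical(apply_exclusions(z1, character(0)), z1)
  expect_message(apply_exclusions(c("a", "b"), "zz"), "ignored")
  expect_warning(apply_exclusions(c("a", "b"), c("a", "b")), "empty")
})

test_that("cardinality selection recovers planted mixture sizes", {
  cfg <- search_config(seed = 6)
  # 3-state planted latent over 6 well-separated columns
  spec3 <- planted_spec(list(
    planted_block("Z", paste0("v", 1:6), cardinality = 3, loading = 0.85)),
    n_records = 5000, seed = 41)
  sim3 <- simulate_cohort(spec3)
  c3 <- choose_cardinality(sim3$data, bounds = c(2L, 5L), cfg = cfg)
  expect_equal(as.integer(c3), 3L)

  # 2-state planted latent
  spec2 <- planted_spec(list(
    planted_block("Z", paste0("v", 1:6), cardinality = 2, loading = 0.85)),
    n_records = 5000, seed = 42)
  sim2 <- simulate_cohort(spec2)
  c2 <- choose_cardinality(sim2$data, bounds = c(2L, 5L), cfg = cfg)
  expect_equal(as.integer(c2), 2L)

  # pure noise: lower bound wins and the BIC gap is reported
  set.seed(43)
  noise <- matrix(rbinom(5000 * 4, 1, 0.5), 5000,
                  dimnames = list(NULL, paste0("n", 1:4)))
  cn <- choose_cardinality(symptom_matrix(noise), bounds = c(2L, 4L), cfg = cfg)
  expect_equal(as.integer(cn), 2L)
  bics <- attr(cn, "bic")
  expect_length(bics, 3L)
  expect_true(all(bics["2"] >= bics[-1]))
})

make_two_block_base <- function(seed = 51, n = 2500) {
  spec <- planted_spec(list(
    planted_block("A", paste0("a", 1:3), loading = 0.8),
    planted_block("B", paste0("b", 1:3), loading = 0.8),
    planted_block("C", paste0("c", 1:3), loading = 0.8)),
    n_records = n, seed = seed)
  sim <- simulate_cohort(spec)
  list(sim = sim, model = sim$model)
}

test_that("single-member factors reduce to the latent's own significant list", {
  tb <- make_two_block_base()
  map <- syndrome_factor_map(list(fA = list(latents = "A")))
  j <- build_jcm(tb$model, tb$sim$data, "fA", map, cfg = search_config(seed = 2),
                 scope = "children")
  cv <- information_curve(tb$model, "A", scope = "children")
  expect_setequal(j$pooled_manifests, select_significant(cv, 95))
  expect_setequal(j$selected, j$pooled_manifests)
  expect_s3_class(j$curve, "information_curve")
})

test_that("pooling is monotone in the member set and exclusions apply", {
  tb <- make_two_block_base()
  map <- syndrome_factor_map(list(
    one = list(latents = "A"),
    two = list(latents = c("A", "B")),
    twox = list(latents = c("A", "B"), exclusions = c("b1", "a2"))))
  cfg <- search_config(seed = 3)
  j1 <- build_jcm(tb$model, tb$sim$data, "one", map, cfg, scope = "children")
  j2 <- build_jcm(tb$model, tb$sim$data, "two", map, cfg, scope = "children")
  expect_true(all(j1$pooled_manifests %in% j2$pooled_manifests))
  jx <- build_jcm(tb$model, tb$sim$data, "twox", map, cfg, scope = "children")
  expect_false(any(c("b1", "a2") %in% jx$selected))
  expect_equal(setdiff(j2$selected, c("b1", "a2")), jx$selected)
})

test_that("planted-factor recovery: Z's selection matches the planted set", {
  # two factors over distinct block pairs; Jaccard of the recovered set
  scores <- vapply(1:10, function(s) {
    spec <- planted_spec(list(
      planted_block("A", paste0("a", 1:3), loading = 0.8),
      planted_block("B", paste0("b", 1:3), loading = 0.8),
      planted_block("C", paste0("c", 1:3), loading = 0.8)),
      n_records = 1500, seed = 100 + s)
    sim <- simulate_cohort(spec)
    map <- syndrome_factor_map(list(f = list(latents = c("A", "B"))))
    j <- build_jcm(sim$model, sim$data, "f", map,
                   cfg = search_config(seed = s), scope = "children")
    planted <- paste0(rep(c("a", "b"), each = 3), 1:3)
    length(intersect(j$selected, planted)) / length(union(j$selected, planted))
  }, 0)
  expect_gte(mean(scores >= 0.8), 0.8)
})

test_that("subdivision splits a planted 3-state factor into its two blocks", {
  # baseline state + block A + block B, the canonical 3-condition pattern
  spec <- planted_spec(
    list(planted_block("Z", c(paste0("p", 1:3), paste0("q", 1:3)),
                       cardinality = 3, loading = 0.8,
                       active_state = rep(c(2L, 3L), each = 3))),
    n_records = 5000, seed = 71)
  sim <- simulate_cohort(spec)
  map <- syndrome_factor_map(list(f = list(latents = "Z")))
  cfg <- search_config(seed = 4)
  j <- build_jcm(sim$model, sim$data, "f", map, cfg, scope = "children")
  expect_equal(j$cardinality, 3L)
  j <- subdivide(j, sim$data, cfg)
  expect_length(j$subsyndromes, 2L)
  parts <- lapply(j$subsyndromes, `[[`, "manifests")
  # sub-syndrome order follows arbitrary latent state labels: compare as sets
  keys <- unname(sort(vapply(parts, function(p) paste(sort(p), collapse = ","), "")))
  expect_equal(keys, c(paste(paste0("p", 1:3), collapse = ","),
                       paste(paste0("q", 1:3), collapse = ",")))
  # disjoint and inside the pooled set
  expect_length(intersect(parts[[1]], parts[[2]]), 0L)
  expect_true(all(unlist(parts) %in% j$pooled_manifests))

  # binary JCM: no-op with a notice
  j2 <- j
  j2$cardinality <- 2L
  j2$subsyndromes <- NULL
  expect_message(out <- subdivide(j2, sim$data, cfg), "nothing to subdivide")
  expect_null(out$subsyndromes)

  # label-invariance: permuting Z's states yields the same partition
  jp <- j
  perm <- c(2L, 3L, 1L)
  jp$model$cpts$Z <- j$model$cpts$Z[perm]
  for (m in jp$pooled_manifests)
    jp$model$cpts[[m]] <- j$model$cpts[[m]][perm, , drop = FALSE]
  jp$subsyndromes <- NULL
  jp <- subdivide(jp, sim$data, cfg)
  pparts <- lapply(jp$subsyndromes, `[[`, "manifests")
  pkeys <- unname(sort(vapply(pparts, function(p) paste(sort(p), collapse = ","), "")))
  expect_equal(pkeys, keys)
})

test_that("factor-map JSON fixture loads and resolves against a model", {
  f <- system.file("extdata", "syndrome_factors.json", package = "lantree")
  map <- read_factor_map(f)
  expect_setequal(names(map$factors),
                  c("qi_stagnation", "dampness", "blood_stasis", "heat",
                    "deficiency"))
  expect_equal(map$factors$qi_stagnation$latents, c("Y0", "Y1", "Y9"))
  expect_equal(map$factors$blood_stasis$exclusions,
               c("slippery pulse", "plump tongue"))
  expect_equal(map$factors$deficiency$sub_exclusions, "bitter taste")
  # anchors resolve references against a model with different latent names
  m <- make_planted_model(plc_cohort_preset(seed = 1))
  res <- lantree:::resolve_latents(c("Y0", "Y8"), m, map)
  expect_equal(unname(res), c("Y0", "Y8"))
})
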