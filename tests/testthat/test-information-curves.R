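test_that("pairwise MI matches closed forms and the enumeration oracle", {
  # independent pair -> 0; deterministic copy of a uniform latent -> 1 bit
  m <- flat_structure(c("x", "y"))
  m$cpts <- setNames(list(c(0.5, 0.5), matrix(0.5, 2, 2),
                          matrix(c(1, 0, 0, 1), 2)), c("H", "x", "y"))
  expect_equal(pairwise_mi(m, "H", "x"), 0, tolerance = 1e-12)
  expect_equal(pairwise_mi(m, "H", "y"), 1, tolerance = 1e-12)

  set.seed(202)
  for (i in 1:20) {
    rm <- random_ltm(sample(1:3, 1), sample(3:6, 1))
    lat <- sample(latent_vars(rm), 1)
    man <- sample(manifest_vars(rm), 1)
    expect_equal(pairwise_mi(rm, lat, man), oracle_mi(rm, lat, man),
                 tolerance = 1e-9)
    # between two latents too (used by the data-processing check)
    l2 <- sample(latent_vars(rm), 1)
    expect_equal(pairwise_mi(rm, lat, l2), oracle_mi(rm, lat, l2),
                 tolerance = 1e-9)
  }
})

test_that("cumulative MI is exact, definitional at k = 1, and monotone", {
  set.seed(303)
  for (i in 1:10) {
    m <- random_ltm(2, 5)
    mans <- sample(manifest_vars(m))
    lat <- sample(latent_vars(m), 1)
    expect_equal(as.numeric(cumulative_mi(m, lat, mans[1])),
                 pairwise_mi(m, lat, mans[1]), tolerance = 1e-9)
    vals <- vapply(seq_along(mans), function(k)
      as.numeric(cumulative_mi(m, lat, mans[1:k])), 0)
    expect_true(all(diff(vals) >= -1e-9))
    expect_equal(vals[length(mans)],
                 oracle_joint_mi(m, lat, mans), tolerance = 1e-9)
  }
  expect_error(cumulative_mi(random_ltm(1, 3), "H1", character(0)),
               class = "lantree_domain_error")
})

test_that("Monte-Carlo cumulative MI agrees with exact within 3 SEs", {
  set.seed(99)
  m <- random_ltm(2, 10)
  lat <- "H1"
  mans <- manifest_vars(m)
  exact <- as.numeric(cumulative_mi(m, lat, mans))
  mc <- cumulative_mi(m, lat, mans, limit = 2, mc_samples = 1e5, seed = 17)
  expect_equal(attr(mc, "method"), "monte-carlo")
  expect_lt(abs(as.numeric(mc) - exact), 3 * max(attr(mc, "se"), 1e-4))
})

test_that("information curve invariants hold on random models", {
  set.seed(404)
  for (i in 1:8) {
    m <- random_ltm(sample(1:2, 1), sample(4:7, 1))
    lat <- sample(latent_vars(m), 1)
    cv <- tryCatch(information_curve(m, lat),
                   lantree_degenerate_latent = function(e) NULL)
    if (is.null(cv)) next
    expect_true(all(cv$pairwise_mi >= 0))
    expect_true(all(diff(cv$pairwise_mi) <= 1e-12))          # sorted descending
    expect_true(all(diff(cv$cumulative_mi) >= -1e-9))
    expect_true(all(diff(cv$coverage) >= -1e-9))
    expect_equal(cv$coverage[nrow(cv)], 100, tolerance = 1e-6)
    # deterministic recomputation gives an identical ordering
    cv2 <- information_curve(m, lat)
    expect_identical(cv$manifest, cv2$manifest)
  }
})

test_that("coverage is invariant to the MI scale (log-base change)", {
  set.seed(19)
  m <- random_ltm(2, 5)
  cv <- information_curve(m, "H1")
  nats <- cv$cumulative_mi * log(2)       # same curve in different units
  expect_equal(100 * nats / nats[length(nats)], cv$coverage, tolerance = 1e-9)
})

test_that("data-processing inequality holds along the tree", {
  # manifest outside a latent's subtree: MI bounded by MI with the separator
  set.seed(55)
  for (i in 1:8) {
    m <- random_ltm(2, 6)
    lat <- "H2"
    outside <- setdiff(manifest_vars(m),
                       lantree:::manifest_descendants(m, lat))
    for (x in outside) {
      sep <- m$parent[[x]]                # separator on the path lat .. x
      expect_lte(pairwise_mi(m, lat, x), pairwise_mi(m, lat, sep) + 1e-9)
    }
  }
})

test_that("95% rule selects the shortest qualifying prefix", {
  # two deterministic copies: the first entry already covers everything
  m <- flat_structure(c("a", "b"))
  m$cpts <- setNames(list(c(0.5, 0.5), matrix(c(1, 0, 0, 1), 2),
                          matrix(c(1, 0, 0, 1), 2)), c("H", "a", "b"))
  cv <- information_curve(m, "H")
  expect_equal(cv$coverage[1], 100, tolerance = 1e-9)
  expect_equal(select_significant(cv, 95), "a")

  # strong pair + weak tail behaves like the fever-block reading: two
  # manifests suffice at the 95% rule
  spec <- planted_spec(list(
    planted_block("Y8", c("fever", "hectic fever", "rapid pulse", "ascites",
                          "pale lips and nails"),
                  loading = c(0.9, 0.9, 0.12, 0.12, 0.12))),
    n_records = 100, seed = 1)
  my8 <- make_planted_model(spec)
  cv8 <- information_curve(my8, "Y8")
  expect_equal(cv8$manifest[1:2], c("fever", "hectic fever"))
  expect_gte(cv8$coverage[2], 95)
  expect_equal(select_significant(cv8, 95), c("fever", "hectic fever"))

  # boundary conventions
  expect_equal(select_significant(cv8, 100), cv8$manifest)
  expect_equal(select_significant(cv8, 0), cv8$manifest[1])

  # synthetic coverage sequence: shortest prefix >= 95 has length 2
  fake <- cv8[1:4, ]
  fake$coverage <- c(60, 96, 99, 100)
  class(fake) <- class(cv8)
  expect_length(select_significant(fake, 95), 2L)
})

test_that("degenerate latent (no information) is an error", {
  m <- flat_structure(c("x", "y"))
  m$cpts <- setNames(list(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
                     c("H", "x", "y"))
  expect_error(information_curve(m, "H"),
               class = "lantree_degenerate_latent")
})

test_that("curve TSV export writes the documented columns", {
  set.seed(23)
  m <- random_ltm(1, 4)
  cv <- information_curve(m, "H1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curve_tsv(cv, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("manifest", "pairwise_mi_bits",
                             "cumulative_mi_bits", "coverage_pct"))
  expect_equal(nrow(tab), 4L)
})
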