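test_that("model construction enforces tree and CPT invariants", {
  vars <- list(variable_spec("H", "latent", 2),
               variable_spec("x", "manifest"), variable_spec("y", "manifest"))
  m <- ltm_model(vars, rbind(c("H", "x"), c("H", "y")))
  expect_s3_class(m, "ltm")
  expect_equal(m$root, "H")
  expect_error(validate_ltm(m), class = "lantree_schema_error")  # no CPTs yet

  m$cpts <- list(H = c(0.3, 0.7), x = matrix(c(0.9, 0.2, 0.1, 0.8), 2),
                 y = matrix(c(0.5, 0.5, 0.5, 0.5), 2))
  names(m$cpts) <- c("H", "x", "y")
  expect_true(validate_ltm(m))
  bad <- m
  bad$cpts$x[1, ] <- c(0.9, 0.2)
  expect_error(validate_ltm(bad), class = "lantree_schema_error")

  # manifest node with children is rejected
  expect_error(
    ltm_model(vars, rbind(c("H", "x"), c("x", "y"))),
    class = "lantree_schema_error")
  # two roots / disconnection is rejected
  expect_error(ltm_model(vars, rbind(c("H", "x"))),
               class = "lantree_schema_error")
})

test_that("independent Bernoulli(0.5) model gives -M ln 2 per record", {
  M <- 6
  man <- paste0("x", 1:M)
  m <- flat_structure(man, card = 2)
  m$cpts$H <- c(0.5, 0.5)
  for (v in man) m$cpts[[v]] <- matrix(0.5, 2, 2)
  X <- matrix(rbinom(M, 1, 0.5), 1, dimnames = list(NULL, man))
  expect_equal(loglikelihood(m, X), -M * log(2), tolerance = 1e-12)
  # additivity: duplicating every record doubles the log-likelihood
  m2 <- random_ltm(2, 5)
  set.seed(5)
  X2 <- matrix(rbinom(40, 1, 0.5), 8, dimnames = list(NULL, paste0("x", 1:5)))
  expect_equal(loglikelihood(m2, rbind(X2, X2)), 2 * loglikelihood(m2, X2),
               tolerance = 1e-12)
})

test_that("message passing matches the enumeration oracle on random models", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_ltm(sample(1:3, 1), sample(3:6, 1))
    X <- matrix(rbinom(5 * length(manifest_vars(m)), 1, 0.5), 5,
                dimnames = list(NULL, manifest_vars(m)))
    expect_equal(loglikelihood(m, X), oracle_loglik(m, X), tolerance = 1e-9)

    lat <- sample(latent_vars(m), 1)
    rec <- setNames(X[1, ], colnames(X))
    expect_equal(unname(posterior(m, rec, lat)),
                 unname(oracle_posterior(m, rec, lat)), tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to latent-state relabeling", {
  set.seed(77)
  m <- random_ltm(2, 5)
  lat <- latent_vars(m)[2]
  perm <- rev(seq_len(m$card[[lat]]))
  m2 <- m
  m2$cpts[[lat]] <- m$cpts[[lat]][, perm, drop = FALSE]
  for (ch in m$children[[lat]])
    m2$cpts[[ch]] <- m$cpts[[ch]][perm, , drop = FALSE]
  X <- matrix(rbinom(50, 1, 0.5), 10, dimnames = list(NULL, paste0("x", 1:5)))
  expect_equal(loglikelihood(m, X), loglikelihood(m2, X), tolerance = 1e-10)
})

test_that("single-parent closed form equals the engine likelihood", {
  set.seed(31)
  m <- flat_structure(paste0("x", 1:4))
  m$cpts$H <- c(0.4, 0.6)
  for (v in paste0("x", 1:4))
    m$cpts[[v]] <- cbind(p0 <- runif(2), 1 - p0)
  x <- c(x1 = 1, x2 = 0, x3 = 1, x4 = 1)
  byhand <- sum(vapply(1:2, function(s)
    m$cpts$H[s] * prod(vapply(names(x), function(v)
      m$cpts[[v]][s, x[[v]] + 1], 0)), 0))
  X <- matrix(x, 1, dimnames = list(NULL, names(x)))
  expect_equal(loglikelihood(m, X), log(byhand), tolerance = 1e-12)
})

test_that("enumerate_joint marginal consistency and factorization", {
  set.seed(11)
  m <- random_ltm(2, 4)
  # root marginal
  jr <- enumerate_joint(m, m$root)
  expect_equal(jr$prob, unname(m$cpts[[m$root]]), tolerance = 1e-12)
  # summing out a variable matches the smaller marginal
  jab <- enumerate_joint(m, c("x1", "x2"))
  ja <- enumerate_joint(m, "x1")
  agg <- tapply(jab$prob, jab$x1, sum)
  expect_equal(as.vector(agg), ja$prob, tolerance = 1e-12)
  expect_equal(sum(jab$prob), 1, tolerance = 1e-9)
  # 2-node chain: joint = prior * CPT
  ch <- ltm_model(list(variable_spec("H", "latent", 2),
                       variable_spec("x", "manifest")), cbind("H", "x"))
  ch$cpts <- setNames(list(c(0.3, 0.7), matrix(c(0.8, 0.1, 0.2, 0.9), 2)),
                      c("H", "x"))
  j <- enumerate_joint(ch, c("H", "x"))
  expect_equal(j$prob, as.vector(c(0.3, 0.7) * ch$cpts$x),
               tolerance = 1e-12)
  # capacity guard
  expect_error(enumerate_joint(m, manifest_vars(m), limit = 2),
               class = "lantree_capacity_error")
})

test_that("posterior handles independence, determinism and zero evidence", {
  # latent independent of the observed manifest: posterior equals prior
  m <- flat_structure(c("x", "y"))
  m$cpts <- setNames(list(c(0.25, 0.75), matrix(0.5, 2, 2),
                          matrix(c(0.9, 0.2, 0.1, 0.8), 2)), c("H", "x", "y"))
  expect_equal(unname(posterior(m, c(x = 1), "H")), c(0.25, 0.75),
               tolerance = 1e-12)
  # deterministic copy leaf pins the posterior
  m$cpts$x <- matrix(c(1, 0, 0, 1), 2)
  p <- posterior(m, c(x = 1), "H")
  expect_equal(unname(p), c(0, 1), tolerance = 1e-9)
  # zero-probability evidence
  m$cpts$H <- c(1, 0)
  m$cpts$y <- matrix(c(1, 1, 0, 0), 2)
  expect_error(posterior(m, c(y = 1), "H", p_floor = 0),
               class = "lantree_numeric_error")
})

test_that("model JSON round trip and DOT export work", {
  set.seed(9)
  m <- random_ltm(2, 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(back$parent, m$parent)
  expect_equal(back$card, m$card)
  for (v in m$var_names)
    expect_equal(back$cpts[[v]], m$cpts[[v]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  d <- withr::local_tempfile(fileext = ".dot")
  export_dot(m, d)
  txt <- readLines(d)
  expect_true(any(grepl("penwidth", txt)))
  expect_equal(sum(grepl(" -- ", txt)), length(m$var_names) - 1L)
})
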