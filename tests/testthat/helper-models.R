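# Shared fixtures: random latent tree models, oracle computations from the
# enumeration joint, and small planted cohorts. All randomness is seeded by
# the caller.

# random rooted latent tree: latent backbone chain, manifests attached
# round-robin; random Dirichlet CPTs
random_ltm <- function(n_latent = 2, n_manifest = 5, max_card = 3) {
  lat <- paste0("H", seq_len(n_latent))
  man <- paste0("x", seq_len(n_manifest))
  cards <- sample.int(max_card - 1L, n_latent, replace = TRUE) + 1L
  vars <- c(mapply(function(l, cc) variable_spec(l, "latent", cc),
                   lat, cards, SIMPLIFY = FALSE),
            lapply(man, variable_spec, kind = "manifest"))
  edges <- NULL
  if (n_latent > 1)
    edges <- cbind(lat[-n_latent], lat[-1])
  edges <- rbind(edges, cbind(lat[(seq_len(n_manifest) - 1) %% n_latent + 1], man))
  m <- ltm_model(vars, edges)
  for (v in m$var_names) {
    cv <- m$card[[v]]
    if (v == m$root) {
      g <- rgamma(cv, 1)
      m$cpts[[v]] <- g / sum(g)
    } else {
      pu <- m$card[[m$parent[[v]]]]
      g <- matrix(rgamma(pu * cv, 1), pu, cv)
      m$cpts[[v]] <- g / rowSums(g)
    }
  }
  validate_ltm(m)
  m
}

# oracle: marginal probability of full manifest records from the enumerated
# joint (independent of the message-passing path)
oracle_loglik <- function(model, X) {
  j <- enumerate_joint(model, manifest_vars(model))
  jk <- apply(as.matrix(j[manifest_vars(model)]), 1, paste, collapse = "-")
  key <- apply(X[, manifest_vars(model), drop = FALSE] + 1L, 1, paste,
               collapse = "-")
  sum(log(j$prob[match(key, jk)]))
}

# oracle: posterior of a latent given a full manifest record
oracle_posterior <- function(model, record, latent) {
  j <- enumerate_joint(model, c(latent, names(record)))
  sel <- rep(TRUE, nrow(j))
  for (v in names(record)) sel <- sel & j[[v]] == record[[v]] + 1L
  p <- vapply(seq_len(model$card[[latent]]), function(s)
    sum(j$prob[sel & j[[latent]] == s]), 0)
  p / sum(p)
}

# oracle: MI in bits between two variables from the enumerated joint
oracle_mi <- function(model, a, b) {
  j <- enumerate_joint(model, c(a, b))
  tab <- matrix(0, model$card[[a]], model$card[[b]])
  for (r in seq_len(nrow(j)))
    tab[j[[a]][r], j[[b]][r]] <- tab[j[[a]][r], j[[b]][r]] + j$prob[r]
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (k in seq_along(pb))
    if (tab[i, k] > 0) s <- s + tab[i, k] * log2(tab[i, k] / (pa[i] * pb[k]))
  s
}

# oracle: joint MI I(latent; manifests) from the enumerated joint
oracle_joint_mi <- function(model, latent, manifests) {
  j <- enumerate_joint(model, c(latent, manifests))
  key <- apply(as.matrix(j[manifests]), 1, paste, collapse = "-")
  py <- tapply(j$prob, j[[latent]], sum)
  px <- tapply(j$prob, key, sum)
  s <- 0
  for (r in seq_len(nrow(j))) {
    p <- j$prob[r]
    if (p > 0) s <- s + p * log2(p / (py[[j[[latent]][r]]] * px[[key[r]]]))
  }
  s
}

# align the states of a single-latent fit to reference CPTs by the best
# state permutation (likelihood is invariant to latent relabeling)
align_single_latent <- function(fitted, reference, latent) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; bestd <- Inf
  mans <- manifest_vars(fitted)
  for (p in perms(seq_len(fitted$card[[latent]]))) {
    d <- sum(abs(fitted$cpts[[latent]][p] - reference$cpts[[latent]]))
    for (m in mans)
      d <- d + sum(abs(fitted$cpts[[m]][p, , drop = FALSE] - reference$cpts[[m]]))
    if (d < bestd) { bestd <- d; best <- p }
  }
  out <- fitted
  out$cpts[[latent]] <- fitted$cpts[[latent]][best]
  for (m in mans) out$cpts[[m]] <- fitted$cpts[[m]][best, , drop = FALSE]
  out
}

# flat single-latent structure over given manifest names
flat_structure <- function(manifests, card = 2, name = "H") {
  vars <- c(list(variable_spec(name, "latent", card)),
            lapply(manifests, variable_spec, kind = "manifest"))
  ltm_model(vars, cbind(name, manifests))
}

# adjusted Rand index between two partitions given as named vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b[names(a)])
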