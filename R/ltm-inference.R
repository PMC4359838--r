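# Exact inference on latent tree models by upward/downward message passing,
# vectorized over records. Evidence is an N x k matrix of 0/1/NA values whose
# column names are manifest variables; NA means unobserved.

# coerce user data (symptom_matrix / matrix / data.frame) to an evidence matrix
ltm_evidence <- function(model, data, strict_columns = TRUE) {
  X <- if (inherits(data, "symptom_matrix")) data$values else as.matrix(data)
  if (is.null(colnames(X)))
    stop_lantree("evidence must have column names", "lantree_schema_error")
  unknown <- setdiff(colnames(X), manifest_vars(model))
  if (length(unknown)) {
    if (strict_columns)
      stop_lantree(sprintf("unknown manifest column(s): %s",
                           paste(unknown, collapse = ", ")),
                   "lantree_schema_error")
    X <- X[, setdiff(colnames(X), unknown), drop = FALSE]
  }
  storage.mode(X) <- "integer"
  bad <- which(!(is.na(X) | X == 0L | X == 1L), arr.ind = TRUE)
  if (nrow(bad))
    stop_lantree(sprintf("non-binary value at row %d, column '%s'",
                         bad[1L, 1L], colnames(X)[bad[1L, 2L]]),
                 "lantree_coding_error")
  X
}

# Core message-passing engine.
#   post_nodes: nodes whose marginal posteriors are needed
#   need_edge:  compute expected sufficient statistics for every edge (EM)
#   weights:    per-row record multiplicities (compressed data); scales the
#               total log-likelihood and the expected counts
# Returns list(loglik_record, loglik, post, root_counts, edge_counts).
ltm_infer <- function(model, X, post_nodes = character(0), need_edge = FALSE,
                      p_floor = 1e-12, weights = NULL) {
  N <- nrow(X)
  floor_cpt <- function(cpt) {            # avoid pmax allocation when moot
    if (any(cpt < p_floor)) pmax(cpt, p_floor) else cpt
  }
  kind <- model$kind; card <- model$card
  parent <- model$parent; children <- model$children
  root <- model$root
  beta <- vector("list", length(model$var_names)); names(beta) <- model$var_names
  msg <- beta
  logscale <- numeric(N)
  xcols <- colnames(X)

  for (v in rev(model$topo)) {
    if (kind[[v]] == "manifest") {
      # observed leaf: the upward message is a row lookup into t(CPT);
      # unobserved cells send a flat message
      if (!is.na(parent[[v]])) {
        tc <- t(floor_cpt(model$cpts[[v]]))
        x <- if (v %in% xcols) X[, v] else rep(NA_integer_, N)
        idx <- x + 1L
        nas <- is.na(idx)
        if (any(nas)) idx[nas] <- 1L
        m <- tc[idx, , drop = FALSE]
        if (any(nas)) m[nas, ] <- 1
        msg[[v]] <- m
      }
      next
    }
    b <- matrix(1, N, card[[v]])
    for (w in children[[v]]) b <- b * msg[[w]]
    s <- .rowSums(b, N, card[[v]])
    zero <- s <= 0
    if (any(zero)) s[zero] <- 1       # impossible records keep likelihood 0
    b <- b / s
    logscale <- logscale + log(s)
    beta[[v]] <- b
    if (!is.na(parent[[v]]))
      msg[[v]] <- b %*% t(floor_cpt(model$cpts[[v]]))
  }

  prior <- floor_cpt(model$cpts[[root]])
  lik <- as.vector(beta[[root]] %*% prior)
  llr <- ifelse(lik > 0, log(lik) + logscale, -Inf)

  out <- list(loglik_record = llr,
              loglik = if (is.null(weights)) sum(llr) else sum(weights * llr))

  need_post <- length(post_nodes) > 0L || need_edge
  if (!need_post) return(out)

  # downward pass restricted to required nodes (ancestors of post_nodes,
  # or every node when edge statistics are requested)
  if (need_edge) {
    needed <- model$var_names
  } else {
    needed <- character(0)
    for (v in post_nodes) {
      while (!is.na(v)) {
        needed <- c(needed, v)
        v <- parent[[v]]
      }
    }
    needed <- unique(needed)
  }

  post <- list()
  pr <- beta[[root]] * rep(prior, each = N)
  post[[root]] <- row_normalize(pr)
  cr <- card[[root]]
  root_counts <- if (is.null(weights)) .colSums(post[[root]], N, cr)
                 else .colSums(post[[root]] * weights, N, cr)
  edge_counts <- list()

  for (v in model$topo) {
    u <- parent[[v]]
    if (is.na(u) || !(v %in% needed)) next
    cu <- card[[u]]; cv <- card[[v]]
    if (kind[[v]] == "manifest") {
      # observed leaves are handled in bulk after this loop; compute a
      # posterior here only if explicitly requested
      if (v %in% post_nodes) {
        x <- if (v %in% xcols) X[, v] else rep(NA_integer_, N)
        obs <- !is.na(x)
        pv <- matrix(0, N, cv)
        if (any(obs)) pv[cbind(which(obs), x[obs] + 1L)] <- 1
        if (any(!obs))
          pv[!obs, ] <- post[[u]][!obs, , drop = FALSE] %*%
            floor_cpt(model$cpts[[v]])
        post[[v]] <- pv
      }
      next
    }
    cpt <- floor_cpt(model$cpts[[v]])
    mv <- msg[[v]]
    if (any(mv < 1e-300)) mv <- pmax(mv, 1e-300)
    piuv <- post[[u]] / mv
    bv <- beta[[v]]
    parts <- vector("list", cu)
    Z <- numeric(N)
    for (a in seq_len(cu)) {
      m <- piuv[, a] * bv * rep(cpt[a, ], each = N)
      parts[[a]] <- m
      Z <- Z + .rowSums(m, N, cv)
    }
    Z[Z <= 0] <- 1
    pv <- matrix(0, N, cv)
    ec <- matrix(0, cu, cv)
    for (a in seq_len(cu)) {
      m <- parts[[a]] / Z
      if (need_edge)
        ec[a, ] <- if (is.null(weights)) .colSums(m, N, cv)
                   else .colSums(m * weights, N, cv)
      pv <- pv + m
    }
    post[[v]] <- pv
    if (need_edge) edge_counts[[v]] <- ec
  }

  if (need_edge) {
    # expected edge counts for every leaf child of each latent, in bulk:
    # for an observed leaf v, P(u = a, v = x_i | record i) = post_u[i, a],
    # so counts are cross-products of the leaf columns with the parent
    # posterior
    for (u in model$topo) {
      if (kind[[u]] != "latent") next
      kids <- children[[u]]
      kids <- kids[kind[kids] == "manifest"]
      if (!length(kids)) next
      cu <- card[[u]]
      pu <- if (is.null(weights)) post[[u]] else post[[u]] * weights
      tots <- .colSums(pu, N, cu)
      xs <- lapply(kids, function(v)
        if (v %in% xcols) X[, v] else rep(NA_integer_, N))
      clean <- !vapply(xs, anyNA, TRUE)
      if (any(clean)) {
        Xk <- matrix(unlist(xs[clean]), N)
        S <- crossprod(Xk, pu)                       # [k x cu]
        for (j in seq_len(sum(clean)))
          edge_counts[[kids[clean][[j]]]] <- cbind(tots - S[j, ], S[j, ])
      }
      for (j in which(!clean)) {
        x <- xs[[j]]
        obs <- !is.na(x)
        ec <- matrix(0, cu, 2L)
        if (any(obs)) {
          agg <- rowsum(pu[obs, , drop = FALSE], group = x[obs])
          ec[, as.integer(rownames(agg)) + 1L] <- t(agg)
        }
        if (any(!obs)) {
          tot <- .colSums(pu[!obs, , drop = FALSE], sum(!obs), cu)
          ec <- ec + tot * floor_cpt(model$cpts[[kids[[j]]]])
        }
        edge_counts[[kids[[j]]]] <- ec
      }
    }
  }

  out$post <- post[intersect(unique(c(post_nodes, if (need_edge) model$var_names)),
                             names(post))]
  out$root_counts <- root_counts
  out$edge_counts <- edge_counts
  out
}

#' Log-likelihood of binary records under a latent tree model
#'
#' Computes the sum over records of the log marginal probability of the
#' observed manifest configuration, by an upward message-passing sweep of the
#' tree (exact inference). Probabilities are floored at `p_floor` so that
#' estimated-zero CPT cells cannot produce `log(0)` for attainable records.
#'
#' @param model A fitted `ltm`.
#' @param data A [symptom_matrix()], or a matrix/data.frame of 0/1 values with
#'   column names; columns must be a subset of the model's manifest variables
#'   (absent columns are treated as unobserved).
#' @param p_floor Probability floor applied to CPT cells during inference.
#' @return Log-likelihood in nats. `-Inf` (with a warning) if some record has
#'   probability zero.
#' @export
loglikelihood <- function(model, data, p_floor = 1e-12) {
  validate_ltm(model)
  X <- ltm_evidence(model, data)
  r <- ltm_infer(model, X, p_floor = p_floor)
  if (any(!is.finite(r$loglik_record)))
    warning("some records have probability zero under the model")
  r$loglik
}

#' Posterior distribution of a latent variable given observed manifestations
#'
#' @param model A fitted `ltm`.
#' @param record Named vector (or single-row data.frame) of 0/1 values for a
#'   subset of the manifest variables.
#' @param latent Name of a latent variable in the model.
#' @param p_floor Probability floor used during inference.
#' @return Named numeric vector over the latent states, summing to 1.
#' @export
posterior <- function(model, record, latent, p_floor = 1e-12) {
  validate_ltm(model)
  if (!latent %in% latent_vars(model))
    stop_lantree(sprintf("'%s' is not a latent variable of the model", latent),
                 "lantree_schema_error")
  if (is.data.frame(record)) record <- unlist(record[1L, , drop = TRUE])
  X <- matrix(as.integer(record), nrow = 1L,
              dimnames = list(NULL, names(record)))
  X <- ltm_evidence(model, X)
  r <- ltm_infer(model, X, post_nodes = latent, p_floor = p_floor)
  if (!is.finite(r$loglik_record[1L]))
    stop_lantree("evidence has probability zero: posterior undefined",
                 "lantree_numeric_error")
  stats::setNames(as.vector(r$post[[latent]][1L, ]),
                  paste0("state", seq_len(model$card[[latent]])))
}

#' Exact joint distribution over a subset of model variables
#'
#' Brute-force enumeration oracle: sums the fully factored joint over all
#' configurations of all variables, then marginalizes to `subset`. Intended
#' for testing and for exact mutual-information computations on small models.
#'
#' @param model A fitted `ltm`.
#' @param subset Character vector of variable names (latent and/or manifest).
#' @param limit Maximum number of cells in the returned joint (default
#'   `2^20`); exceeding it signals a capacity error suggesting the
#'   Monte-Carlo path used by [cumulative_mi()].
#' @return A data.frame of class `ltm_joint` with one column per subset
#'   variable (state indices `1..cardinality`; for manifest variables state 1
#'   codes 0 and state 2 codes 1) and a `prob` column summing to 1.
#' @export
enumerate_joint <- function(model, subset, limit = 2^20) {
  validate_ltm(model)
  if (!all(subset %in% model$var_names))
    stop_lantree("subset contains unknown variables", "lantree_schema_error")
  cells <- prod(model$card[subset])
  if (cells > limit)
    stop_lantree(sprintf(
      "joint over subset has %.0f cells (> limit %.0f); use the Monte-Carlo estimator",
      cells, limit), "lantree_capacity_error")
  full <- prod(model$card)
  if (full > 2^24)
    stop_lantree("full joint too large to enumerate", "lantree_capacity_error")

  ord <- model$topo
  grid <- as.matrix(expand.grid(lapply(model$card[ord], seq_len),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- ord
  p <- model$cpts[[model$root]][grid[, model$root]]
  for (v in ord) {
    if (v == model$root) next
    p <- p * model$cpts[[v]][cbind(grid[, model$parent[[v]]], grid[, v])]
  }

  sub <- grid[, subset, drop = FALSE]
  mult <- cumprod(c(1, model$card[subset]))[seq_along(subset)]
  key <- as.vector((sub - 1L) %*% mult) + 1L
  agg <- rowsum(p, key)
  out <- as.data.frame(as.matrix(expand.grid(lapply(model$card[subset], seq_len),
                                             KEEP.OUT.ATTRS = FALSE)))
  names(out) <- subset
  out$prob <- 0
  out$prob[as.integer(rownames(agg))] <- agg[, 1L]
  structure(out, class = c("ltm_joint", "data.frame"),
            variables = subset, cards = model$card[subset])
}

# marginal distribution of every node, by a downward sweep of the CPTs
node_marginals <- function(model) {
  marg <- stats::setNames(vector("list", length(model$var_names)), model$var_names)
  marg[[model$root]] <- as.vector(model$cpts[[model$root]])
  for (v in model$topo) {
    if (v == model$root) next
    marg[[v]] <- as.vector(marg[[model$parent[[v]]]] %*% model$cpts[[v]])
  }
  marg
}

# ancestral sampling: returns integer state matrix (1..card) over all nodes
ltm_sample_states <- function(model, n, seed) {
  validate_ltm(model)
  set.seed(seed)
  S <- matrix(0L, n, length(model$var_names),
              dimnames = list(NULL, model$var_names))
  S[, model$root] <- sample.int(model$card[[model$root]], n, replace = TRUE,
                                prob = model$cpts[[model$root]])
  for (v in model$topo) {
    if (v == model$root) next
    u <- model$parent[[v]]
    cpt <- model$cpts[[v]]
    for (a in seq_len(model$card[[u]])) {
      idx <- which(S[, u] == a)
      if (length(idx))
        S[idx, v] <- sample.int(model$card[[v]], length(idx), replace = TRUE,
                                prob = cpt[a, ])
    }
  }
  S
}
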