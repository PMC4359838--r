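# Parameter learning for a fixed tree structure.

# collapse duplicate 0/1 rows into unique rows + multiplicities; the EM
# sufficient statistics are identical and the E-step cost drops accordingly
compress_rows <- function(X) {
  n <- ncol(X)
  grp <- split(seq_len(n), ceiling(seq_len(n) / 25))
  parts <- lapply(grp, function(g)
    as.vector(X[, g, drop = FALSE] %*% 2^(seq_along(g) - 1)))
  key <- do.call(paste, c(parts, sep = "-"))
  first <- !duplicated(key)
  f <- match(key, key[first])
  list(X = X[first, , drop = FALSE], w = tabulate(f, sum(first)))
}

# random row-stochastic CPTs from a symmetric Dirichlet(1)
random_cpts <- function(model) {
  cpts <- model$cpts
  for (v in model$var_names) {
    cv <- model$card[[v]]
    if (v == model$root) {
      g <- stats::rgamma(cv, 1)
      cpts[[v]] <- g / sum(g)
    } else {
      pu <- model$card[[model$parent[[v]]]]
      g <- matrix(stats::rgamma(pu * cv, 1), pu, cv)
      cpts[[v]] <- row_normalize(g)
    }
  }
  cpts
}

# smoothing prior term: smooth * sum(log theta) over all CPT cells
smooth_logprior <- function(model, smooth, p_floor = 1e-12) {
  if (smooth <= 0) return(0)
  s <- 0
  for (v in model$var_names) s <- s + sum(log(pmax(model$cpts[[v]], p_floor)))
  smooth * s
}

#' Fit latent tree model parameters by expectation-maximization
#'
#' Maximum a posteriori EM for a fixed tree structure: the E-step runs exact
#' message passing on the tree, the M-step sets each CPT row to the
#' expected-count ratio with `smooth` pseudo-counts added per cell
#' (a Dirichlet(1 + smooth) prior; `smooth = 0` gives plain maximum
#' likelihood). Several restarts from random Dirichlet(1) parameter draws are
#' fitted and the best final objective wins; with `init = "current"` the first
#' restart warm-starts from the CPTs already present in `structure` (missing
#' or dimension-mismatched CPTs are drawn randomly).
#'
#' @param structure An `ltm` (skeleton or fitted) defining the tree.
#' @param data A [symptom_matrix()] (or 0/1 matrix) covering the model's
#'   manifest variables.
#' @param tol Convergence threshold on the relative change of the monitored
#'   objective.
#' @param max_iter Maximum EM iterations per restart (0 evaluates the current
#'   parameters without updating them).
#' @param restarts Number of restarts (>= 1).
#' @param seed Integer seed; all restart initializations derive from it.
#' @param smooth Pseudo-count added to every CPT cell in the M-step.
#' @param init `"random"` or `"current"` (warm start, see above).
#' @return An object of class `ltm_em`: list with `model` (fitted `ltm`),
#'   `loglik_trace` (per-iteration monitored objective: data log-likelihood
#'   plus the smoothing prior term, non-decreasing up to numerical tolerance),
#'   `loglik` (final data log-likelihood), `converged`, `restarts_used`,
#'   `seed`.
#' @export
fit_em <- function(structure, data, tol = 1e-6, max_iter = 500L, restarts = 8L,
                   seed = 1L, smooth = 0.01, init = c("random", "current")) {
  init <- match.arg(init)
  stopifnot(tol > 0, restarts >= 1L, max_iter >= 0L)
  validate_ltm(structure, require_cpts = FALSE)
  X <- ltm_evidence(structure, data, strict_columns = FALSE)
  miss <- setdiff(manifest_vars(structure), colnames(X))
  if (length(miss))
    stop_lantree(sprintf("data lacks manifest column(s): %s",
                         paste(miss, collapse = ", ")),
                 "lantree_schema_error")
  w <- NULL
  if (!anyNA(X)) {
    cw <- compress_rows(X)
    if (nrow(cw$X) < nrow(X)) {
      X <- cw$X
      w <- cw$w
    }
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("em-restart-", r)))
    model <- structure
    if (init == "current" && r == 1L) {
      rand <- random_cpts(model)
      for (v in model$var_names)
        if (is.null(model$cpts[[v]])) model$cpts[[v]] <- rand[[v]]
    } else {
      model$cpts <- random_cpts(model)
    }

    trace <- numeric(0)
    converged <- FALSE
    ll <- NA_real_
    iter <- 0L
    repeat {
      inf <- ltm_infer(model, X, need_edge = TRUE, weights = w)
      ll <- inf$loglik
      obj <- ll + smooth_logprior(model, smooth)
      trace <- c(trace, obj)
      n_tr <- length(trace)
      if (n_tr > 1L) {
        rel <- (trace[n_tr] - trace[n_tr - 1L]) / max(abs(trace[n_tr - 1L]), 1)
        if (abs(rel) < tol) { converged <- TRUE; break }
      }
      if (iter >= max_iter) { converged <- max_iter == 0L; break }
      iter <- iter + 1L
      # M-step
      model$cpts[[model$root]] <- {
        c0 <- inf$root_counts + smooth
        c0 / sum(c0)
      }
      for (v in model$var_names) {
        if (v == model$root) next
        model$cpts[[v]] <- row_normalize(inf$edge_counts[[v]] + smooth)
      }
    }

    fit <- list(model = model, loglik_trace = trace, loglik = ll,
                converged = converged, restart = r)
    if (is.null(best) || trace[length(trace)] > best$loglik_trace[length(best$loglik_trace)])
      best <- fit
  }

  res <- list(model = best$model, loglik_trace = best$loglik_trace,
              loglik = best$loglik, converged = best$converged,
              restarts_used = restarts, best_restart = best$restart,
              seed = seed, smooth = smooth)
  class(res) <- "ltm_em"
  res
}

#' @export
print.ltm_em <- function(x, ...) {
  cat(sprintf("EM fit: loglik %.4f after %d iteration(s), %s (restart %d of %d)\n",
              x$loglik, length(x$loglik_trace) - 1L,
              if (x$converged) "converged" else "not converged",
              x$best_restart, x$restarts_used))
  invisible(x)
}

#' Bayesian information criterion of a fitted latent tree model
#'
#' `BIC = loglik - (d / 2) * ln(N)` where `d` is the number of free CPT
#' parameters, `d = sum over nodes of (cardinality - 1) * cardinality(parent)`
#' with `cardinality(parent) = 1` for the root. Higher is better; this is the
#' score driving structure search.
#'
#' @param model A fitted `ltm`.
#' @param data A [symptom_matrix()] or 0/1 matrix.
#' @param loglik Optional precomputed log-likelihood of `model` on `data`.
#' @return BIC score (nats).
#' @export
bic_score <- function(model, data, loglik = NULL) {
  X <- if (inherits(data, "symptom_matrix")) data$values else data
  N <- nrow(X)
  ll <- loglik %||% loglikelihood(model, data)
  ll - n_free_params(model) / 2 * log(N)
}
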