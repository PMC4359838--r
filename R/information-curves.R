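# Mutual-information curves: the interpretation device for latent variables.
# MI is computed from the fitted model distribution (not raw cell counts):
# pairwise MI exactly via transfer matrices along the tree path, cumulative
# MI exactly by enumeration when small enough, otherwise by a seeded
# Monte-Carlo estimator based on E_x[ KL(p(y|x) || p(y)) ].

# exact joint of two model variables via the path between them
pairwise_joint <- function(model, a, b) {
  marg <- node_marginals(model)
  if (a == b) {
    p <- marg[[a]]
    return(diag(p, nrow = length(p)))
  }
  # path a -> root, b -> root, splice at the lowest common ancestor
  path_up <- function(v) {
    out <- v
    while (!is.na(model$parent[[v]])) { v <- model$parent[[v]]; out <- c(out, v) }
    out
  }
  pa <- path_up(a); pb <- path_up(b)
  lca <- pa[pa %in% pb][1L]
  path <- c(pa[seq_len(match(lca, pa))], rev(pb[seq_len(match(lca, pb) - 1L)]))

  M <- diag(1, model$card[[a]])
  for (i in seq_len(length(path) - 1L)) {
    from <- path[[i]]; to <- path[[i + 1L]]
    if (identical(model$parent[[from]], to)) {        # upward: reverse the CPT
      cpt <- model$cpts[[from]]                        # [card(to) x card(from)]
      rev_m <- t(cpt * marg[[to]])                     # [card(from) x card(to)]
      den <- marg[[from]]
      den[den <= 0] <- 1
      M <- M %*% (rev_m / den[row(rev_m)])
    } else {                                           # downward: forward CPT
      M <- M %*% model$cpts[[to]]
    }
  }
  marg[[a]] * M                                        # joint, rows = states of a
}

mi_bits_from_joint <- function(j) {
  pa <- rowSums(j); pb <- colSums(j)
  den <- outer(pa, pb)
  pos <- j > 0 & den > 0
  sum(j[pos] * log2(j[pos] / den[pos]))
}

#' Pairwise mutual information between two model variables
#'
#' `I(A; B) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` in bits, computed from
#' the model's exact pairwise marginal (transfer matrices along the tree path
#' connecting the two variables).
#'
#' @param model A fitted `ltm`.
#' @param a,b Variable names (typically a latent and a manifest variable).
#' @return Mutual information in bits (>= 0).
#' @export
pairwise_mi <- function(model, a, b) {
  if (!all(c(a, b) %in% model$var_names))
    stop_lantree("unknown variable in pairwise_mi", "lantree_schema_error")
  max(0, mi_bits_from_joint(pairwise_joint(model, a, b)))
}

# cumulative MI of a latent with each prefix of an ordered manifest list.
# Returns list(values, se, method). Shared machinery for cumulative_mi()
# and information_curve().
cum_mi_prefixes <- function(model, latent, manifests, limit = 2^20,
                            mc_samples = 20000L, seed = 1L) {
  K <- length(manifests)
  cy <- model$card[[latent]]
  prior <- node_marginals(model)[[latent]]
  lp <- log2(pmax(prior, 1e-300))

  kl_terms <- function(post) {
    # per-record KL(p(y | x) || p(y)) in bits
    t <- xlog2x(post) - post * rep(lp, each = nrow(post))
    rowSums(t)
  }

  exact_one <- function(k) {
    grid <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
    colnames(grid) <- manifests[seq_len(k)]
    inf <- ltm_infer(model, grid, post_nodes = latent)
    px <- exp(inf$loglik_record)
    sum(px * kl_terms(inf$post[[latent]]))
  }

  if (cy * 2^K <= limit) {
    vals <- vapply(seq_len(K), exact_one, 0)
    return(list(values = vals, se = rep(0, K), method = "exact"))
  }

  # seeded Monte-Carlo with one shared sample across prefixes
  S <- ltm_sample_states(model, mc_samples, derive_seed(seed, paste0("cummi-", latent)))
  Xs <- S[, manifests, drop = FALSE] - 1L
  vals <- numeric(K); se <- numeric(K)
  for (k in seq_len(K)) {
    if (cy * 2^k <= limit && k <= 16L) {
      vals[k] <- exact_one(k)
      se[k] <- 0
    } else {
      inf <- ltm_infer(model, Xs[, seq_len(k), drop = FALSE], post_nodes = latent)
      terms <- kl_terms(inf$post[[latent]])
      vals[k] <- mean(terms)
      se[k] <- stats::sd(terms) / sqrt(mc_samples)
    }
  }
  list(values = vals, se = se, method = "monte-carlo")
}

#' Cumulative (joint) mutual information of a latent variable with a set of
#' manifest variables
#'
#' `I(Y; X1..Xk)` in bits under the model joint. Exact by enumeration over
#' manifest configurations when `cardinality(Y) * 2^k <= limit`; otherwise a
#' seeded Monte-Carlo estimate of `E_x[KL(p(y|x) || p(y))]` with its standard
#' error attached as attribute `"se"` (attribute `"method"` records which
#' path was used).
#'
#' @param model A fitted `ltm`.
#' @param latent Latent variable name.
#' @param manifests Nonempty character vector of manifest variable names.
#' @param limit Cell limit for exact enumeration (default `2^20`).
#' @param mc_samples Monte-Carlo sample size.
#' @param seed Integer seed for the Monte-Carlo path.
#' @return Mutual information in bits with attributes `se` and `method`.
#' @export
cumulative_mi <- function(model, latent, manifests, limit = 2^20,
                          mc_samples = 20000L, seed = 1L) {
  if (length(manifests) < 1L)
    stop_lantree("manifests must be nonempty", "lantree_domain_error")
  if (!latent %in% latent_vars(model))
    stop_lantree(sprintf("'%s' is not a latent variable", latent),
                 "lantree_schema_error")
  if (!all(manifests %in% manifest_vars(model)))
    stop_lantree("unknown manifest variable in cumulative_mi", "lantree_schema_error")
  r <- cum_mi_prefixes(model, latent, manifests, limit, mc_samples, seed)
  k <- length(manifests)
  structure(r$values[k], se = r$se[k], method = r$method)
}

#' Information curve of a latent variable
#'
#' Orders the manifest variables in `scope` by decreasing pairwise mutual
#' information with the latent variable (ties broken alphabetically), then
#' accumulates joint mutual information along that order. The information
#' coverage of the first `k` variables is
#' `100 * I(Y; X_(1..k)) / I(Y; all of scope)`; reading the curve off at a
#' coverage threshold (conventionally 95%) yields the latent variable's
#' significant manifestations.
#'
#' When the cumulative values come from the Monte-Carlo estimator they are
#' made non-decreasing by a running maximum (joint MI is monotone in the
#' variable set; the raw draws are kept in attribute `"raw_cumulative"`).
#'
#' @param model A fitted `ltm`.
#' @param latent Latent variable name.
#' @param scope Manifest variables over which coverage is normalized.
#'   Default: all manifest variables in the model. `scope = "children"`
#'   restricts to the latent variable's own manifest descendants.
#' @param limit,mc_samples,seed Passed to the cumulative-MI machinery.
#' @return A data.frame of class `information_curve` with columns `manifest`,
#'   `pairwise_mi`, `cumulative_mi` (bits) and `coverage` (percent);
#'   attributes `latent`, `scope`, `method`, `se`.
#' @export
information_curve <- function(model, latent, scope = NULL, limit = 2^20,
                              mc_samples = 20000L, seed = 1L) {
  if (!latent %in% latent_vars(model))
    stop_lantree(sprintf("'%s' is not a latent variable", latent),
                 "lantree_schema_error")
  if (identical(scope, "children")) scope <- manifest_descendants(model, latent)
  scope <- scope %||% manifest_vars(model)
  if (length(scope) < 1L)
    stop_lantree("scope must be nonempty", "lantree_domain_error")
  if (!all(scope %in% manifest_vars(model)))
    stop_lantree("scope contains unknown manifest variables", "lantree_schema_error")

  pm <- vapply(scope, function(m) pairwise_mi(model, latent, m), 0)
  ord <- order(-pm, scope)
  scope <- scope[ord]; pm <- pm[ord]

  r <- cum_mi_prefixes(model, latent, scope, limit, mc_samples, seed)
  raw <- r$values
  cum <- if (r$method == "monte-carlo") cummax(raw) else raw
  total <- cum[length(cum)]
  if (total <= 1e-12)
    stop_lantree(sprintf("latent '%s' carries no information about the scope",
                         latent), "lantree_degenerate_latent")

  out <- data.frame(manifest = scope, pairwise_mi = unname(pm),
                    cumulative_mi = cum, coverage = 100 * cum / total,
                    row.names = NULL)
  structure(out, class = c("information_curve", "data.frame"),
            latent = latent, scope = scope, method = r$method, se = r$se,
            raw_cumulative = raw)
}

#' Select a latent variable's significant manifestations by information
#' coverage
#'
#' Returns the shortest prefix of the curve whose coverage reaches
#' `threshold` percent, preserving curve order. `threshold = 100` selects all
#' entries; `threshold = 0` selects the first entry (the selection is never
#' empty, by convention).
#'
#' @param curve An [information_curve()].
#' @param threshold Coverage threshold in percent (default 95).
#' @return Character vector of manifest names.
#' @export
select_significant <- function(curve, threshold = 95) {
  stopifnot(inherits(curve, "information_curve"))
  k <- which(curve$coverage >= threshold)
  k <- if (length(k)) max(1L, k[1L]) else nrow(curve)
  curve$manifest[seq_len(k)]
}

#' Plot an information curve
#'
#' Two-curve layout: pairwise mutual information (lower curve) and cumulative
#' mutual information (upper curve) against the ordered manifest variables,
#' with information coverage on the right axis.
#'
#' @param x An [information_curve()].
#' @param threshold Coverage threshold drawn as a reference line.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.information_curve <- function(x, threshold = 95, ...) {
  op <- graphics::par(mar = c(9, 4, 3, 4))
  on.exit(graphics::par(op))
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$cumulative_mi, type = "b", pch = 19, xaxt = "n",
                 xlab = "", ylab = "mutual information (bits)",
                 ylim = c(0, max(x$cumulative_mi) * 1.05),
                 main = sprintf("Information curve of %s", attr(x, "latent")), ...)
  graphics::lines(idx, x$pairwise_mi, type = "b", pch = 1, lty = 2)
  graphics::axis(1, at = idx, labels = x$manifest, las = 2, cex.axis = 0.7)
  usr <- graphics::par("usr")
  sc <- usr[4] / 100
  graphics::lines(idx, x$coverage * sc, col = "grey40", lty = 3)
  graphics::abline(h = threshold * sc, col = "grey70")
  graphics::axis(4, at = c(0, 25, 50, 75, 100) * sc,
                 labels = c(0, 25, 50, 75, 100))
  graphics::mtext("coverage (%)", side = 4, line = 2.5)
  invisible(x)
}

#' Export an information curve as TSV
#'
#' Columns: manifest, pairwise_mi_bits, cumulative_mi_bits, coverage_pct
#' (coverage rounded to 2 decimals for reporting; computations keep full
#' precision).
#'
#' @param curve An [information_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- data.frame(manifest = curve$manifest,
                   pairwise_mi_bits = curve$pairwise_mi,
                   cumulative_mi_bits = curve$cumulative_mi,
                   coverage_pct = round(curve$coverage, 2))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
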