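# Joint clustering: for each syndrome factor, pool the evidence of the
# latent variables carrying that factor, fit one new latent class variable Z
# over the pooled manifest columns, read Z's information curve, apply the
# declarative expert exclusions, and split Z into sub-syndromes when it has
# more than two states.

#' Construct / validate a syndrome-factor map
#'
#' Maps factor names to the latent variables that carry the factor, with
#' optional declarative exclusion lists (the software never auto-excludes;
#' exclusions encode expert judgment). An optional `anchors` table maps
#' referenced latent names to representative manifest lists so a map written
#' against one model (e.g. planted ground truth) can be resolved against a
#' learned model whose latent variables have different names (maximum
#' Jaccard overlap of leaf sets).
#'
#' @param factors Named list: each element
#'   `list(latents =, exclusions =, sub_exclusions =)` (the last two
#'   optional).
#' @param anchors Optional named list: latent reference name -> character
#'   vector of manifest names.
#' @return A `syndrome_factor_map`.
#' @export
syndrome_factor_map <- function(factors, anchors = NULL) {
  stopifnot(is.list(factors), !is.null(names(factors)))
  factors <- lapply(factors, function(f) {
    list(latents = as.character(f$latents),
         exclusions = as.character(f$exclusions %||% character(0)),
         sub_exclusions = as.character(f$sub_exclusions %||% character(0)))
  })
  structure(list(factors = factors, anchors = anchors),
            class = "syndrome_factor_map")
}

#' Read a syndrome-factor map from JSON
#'
#' @param path JSON file with fields `factors` (and optionally `anchors`).
#' @return A [syndrome_factor_map()].
#' @export
read_factor_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  syndrome_factor_map(lapply(j$factors, as.list), anchors = j$anchors)
}

# resolve latent references against a model: exact name, else anchor overlap
resolve_latents <- function(refs, model, map) {
  lats <- latent_vars(model)
  part <- leaf_partition(model)
  vapply(refs, function(r) {
    if (r %in% lats) return(r)
    anchor <- map$anchors[[r]]
    if (is.null(anchor))
      stop_lantree(sprintf("latent '%s' not in model and no anchor given", r),
                   "lantree_config_error")
    jac <- vapply(lats, function(l) {
      leaves <- manifest_descendants(model, l)
      length(intersect(leaves, anchor)) / length(union(leaves, anchor))
    }, 0)
    lats[which.max(jac)]
  }, "")
}

#' Remove expert-excluded manifestations from a selection
#'
#' Set difference preserving order. Exclusions absent from the input are
#' ignored with a message.
#'
#' @param selected Character vector of manifest names (curve order).
#' @param exclusions Character vector of manifest names to drop.
#' @return `selected` without `exclusions`, order preserved.
#' @export
apply_exclusions <- function(selected, exclusions) {
  missing <- setdiff(exclusions, selected)
  if (length(missing))
    message(sprintf("exclusion(s) not in selection (ignored): %s",
                    paste(missing, collapse = ", ")))
  out <- selected[!selected %in% exclusions]
  if (!length(out))
    warning("all manifestations excluded: empty selection")
  out
}

#' Choose the cardinality of a latent class variable by BIC
#'
#' Fits a flat latent class model (a single latent over the given binary
#' columns) at each cardinality within `bounds` and returns the BIC-maximizer
#' (deterministic given the configuration seed).
#'
#' @param data A [symptom_matrix()] or 0/1 matrix (the pooled columns).
#' @param bounds Integer vector `c(lower, upper)`, within 2..5 by default.
#' @param cfg A [search_config()] supplying the EM budget and seed.
#' @return Integer cardinality, with attributes `bic` (named vector of scores
#'   per candidate cardinality) and `fits` (the [fit_em()] results).
#' @export
choose_cardinality <- function(data, bounds = c(2L, 5L), cfg = search_config()) {
  X <- if (inherits(data, "symptom_matrix")) data$values else as.matrix(data)
  cards <- seq.int(bounds[[1L]], bounds[[2L]])
  fits <- lapply(cards, function(cc) {
    str <- latent_class_structure(colnames(X), cc, name = "Z")
    fit_em(str, X, tol = cfg$full_em$tol, max_iter = cfg$full_em$max_iter,
           restarts = max(cfg$init_restarts, 2L),
           seed = derive_seed(cfg$seed, paste0("card-", cc)),
           smooth = cfg$smooth)
  })
  bics <- vapply(seq_along(cards), function(i)
    bic_score(fits[[i]]$model, X, loglik = fits[[i]]$loglik), 0)
  names(bics) <- cards
  best <- which.max(bics)
  structure(cards[[best]], bic = bics, fits = fits)
}

#' Build the joint clustering model (JCM) of a syndrome factor
#'
#' Pools the significant manifestations (by each member latent variable's
#' information curve at `threshold`) of the latent variables carrying the
#' factor, fits a new latent class variable Z over the pooled columns with
#' BIC-selected cardinality, computes Z's information curve over the pooled
#' scope, and applies the factor's declarative exclusions to the selection.
#'
#' @param base The fitted base `ltm` (the full latent structural model).
#' @param data The [symptom_matrix()] the base model was fitted on.
#' @param factor Factor name present in `map`.
#' @param map A [syndrome_factor_map()].
#' @param cfg A [search_config()] (EM budget, bounds, seed).
#' @param threshold Information-coverage threshold in percent (default 95).
#' @param scope Scope mode for the member latent curves: `"model"` (all
#'   manifest variables, the default) or `"children"` (each latent's own
#'   manifest descendants).
#' @param z_name Name given to the new latent variable.
#' @param mc_samples,limit Passed to the information-curve machinery.
#' @return An object of class `jcm`: list with `factor`, `z_name`,
#'   `cardinality`, `members` (resolved latent names), `pooled_manifests`,
#'   `model` (the fitted flat latent class model), `curve`, `selected`
#'   (post-exclusion, curve order), `exclusions`, `bic` (per-cardinality
#'   scores) and `subsyndromes` (`NULL` until [subdivide()] is called).
#' @export
build_jcm <- function(base, data, factor, map, cfg = search_config(),
                      threshold = 95, scope = c("model", "children"),
                      z_name = "Z", mc_samples = 20000L, limit = 2^20) {
  scope <- match.arg(scope)
  if (!factor %in% names(map$factors))
    stop_lantree(sprintf("factor '%s' not in map", factor), "lantree_config_error")
  fac <- map$factors[[factor]]
  if (length(fac$latents) < 1L)
    stop_lantree("factor has no member latents", "lantree_config_error")
  members <- resolve_latents(fac$latents, base, map)

  pooled <- character(0)
  for (y in unique(members)) {
    sc <- if (scope == "children") "children" else NULL
    curve <- information_curve(base, y, scope = sc, limit = limit,
                               mc_samples = mc_samples,
                               seed = derive_seed(cfg$seed, paste0("curve-", y)))
    pooled <- union(pooled, select_significant(curve, threshold))
  }
  if (!length(pooled))
    stop_lantree("pooled manifest set is empty", "lantree_config_error")
  X <- if (inherits(data, "symptom_matrix")) data$values else as.matrix(data)
  pooled <- intersect(colnames(X), pooled)   # data column order

  card <- choose_cardinality(X[, pooled, drop = FALSE],
                             bounds = c(cfg$card_min, cfg$card_max), cfg = cfg)
  fit <- attr(card, "fits")[[match(as.integer(card), as.integer(names(attr(card, "bic"))))]]
  zmodel <- fit$model
  # rename the class variable to the requested Z name
  names(zmodel$var_names) <- NULL
  zmodel <- local({
    vars <- c(list(variable_spec(z_name, "latent", zmodel$card[["Z"]])),
              lapply(pooled, variable_spec, kind = "manifest"))
    m2 <- ltm_model(vars, cbind(z_name, pooled))
    m2$cpts[[z_name]] <- zmodel$cpts[["Z"]]
    for (p in pooled) m2$cpts[[p]] <- zmodel$cpts[[p]]
    m2
  })

  curve <- information_curve(zmodel, z_name, scope = pooled, limit = limit,
                             mc_samples = mc_samples,
                             seed = derive_seed(cfg$seed, paste0("curve-", z_name)))
  selected <- apply_exclusions(select_significant(curve, threshold),
                               fac$exclusions)

  structure(list(factor = factor, z_name = z_name,
                 cardinality = as.integer(card), members = unname(members),
                 pooled_manifests = pooled, model = zmodel, curve = curve,
                 selected = selected, exclusions = fac$exclusions,
                 sub_exclusions = fac$sub_exclusions,
                 bic = attr(card, "bic"), subsyndromes = NULL),
            class = "jcm")
}

#' @export
print.jcm <- function(x, ...) {
  cat(sprintf("JCM '%s' (factor: %s): %d states over %d pooled manifestations\n",
              x$z_name, x$factor, x$cardinality, length(x$pooled_manifests)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$subsyndromes))
    cat(sprintf("  %d sub-syndrome(s)\n", length(x$subsyndromes)))
  invisible(x)
}

#' Split a joint clustering model into sub-syndromes
#'
#' When the factor's latent class variable Z has three or more states, the
#' factor decomposes: one sub-syndrome per non-baseline state. The baseline
#' state is the state with the lowest mean manifestation probability; each
#' pooled manifest is assigned to the state maximizing its lift
#' `P(m = 1 | z = s) / P(m = 1)` (only lifts > 1 count; ties go to the
#' earlier state index), and manifests assigned to the baseline state belong
#' to no sub-syndrome. Each sub-syndrome is re-fitted as its own flat latent
#' class model over its manifests and its information curve emitted; the
#' factor's `sub_exclusions` are applied to every sub-selection.
#'
#' @param jcm A [build_jcm()] result.
#' @param data The [symptom_matrix()] used to build it.
#' @param cfg A [search_config()].
#' @param threshold Coverage threshold for sub-curves.
#' @param mc_samples,limit Information-curve controls.
#' @return The `jcm` with `subsyndromes` filled: a list (one element per
#'   non-baseline state with assigned manifests) of lists with `state`,
#'   `name` (e.g. `Z5a`), `manifests`, `cardinality`, `model`, `curve`,
#'   `selected`. If Z is binary the input is returned unchanged with a
#'   notice.
#' @export
subdivide <- function(jcm, data, cfg = search_config(), threshold = 95,
                      mc_samples = 20000L, limit = 2^20) {
  stopifnot(inherits(jcm, "jcm"))
  if (jcm$cardinality < 3L) {
    message(sprintf("JCM '%s' has only %d states: nothing to subdivide",
                    jcm$z_name, jcm$cardinality))
    return(jcm)
  }
  z <- jcm$z_name
  model <- jcm$model
  prior <- model$cpts[[z]]
  p1 <- vapply(jcm$pooled_manifests, function(m) model$cpts[[m]][, 2L],
               numeric(jcm$cardinality))     # [state x manifest]
  p1 <- matrix(p1, nrow = jcm$cardinality,
               dimnames = list(NULL, jcm$pooled_manifests))
  baseline <- which.min(rowMeans(p1))
  marg1 <- as.vector(prior %*% p1)
  lift <- p1 / rep(pmax(marg1, 1e-12), each = jcm$cardinality)

  assign_state <- vapply(seq_along(jcm$pooled_manifests), function(j) {
    lifts <- lift[, j]
    s <- which.max(lifts)                   # ties: earlier state (which.max)
    if (lifts[s] <= 1) return(NA_integer_)
    as.integer(s)
  }, 0L)

  X <- if (inherits(data, "symptom_matrix")) data$values else as.matrix(data)
  subs <- list()
  k <- 0L
  for (s in setdiff(seq_len(jcm$cardinality), baseline)) {
    mans <- jcm$pooled_manifests[!is.na(assign_state) & assign_state == s]
    if (!length(mans)) next
    k <- k + 1L
    nm <- paste0(z, letters[[k]])
    if (length(mans) >= 2L) {
      card <- choose_cardinality(X[, mans, drop = FALSE],
                                 bounds = c(cfg$card_min,
                                            min(cfg$card_max, max(2L, length(mans)))),
                                 cfg = cfg)
      fit <- attr(card, "fits")[[match(as.integer(card),
                                       as.integer(names(attr(card, "bic"))))]]
      sm <- fit$model
      curve <- information_curve(sm, "Z", scope = mans, limit = limit,
                                 mc_samples = mc_samples,
                                 seed = derive_seed(cfg$seed, paste0("curve-", nm)))
      sel <- apply_exclusions(select_significant(curve, threshold),
                              jcm$sub_exclusions)
      subs[[nm]] <- list(state = s, name = nm, manifests = mans,
                         cardinality = as.integer(card), model = sm,
                         curve = curve, selected = sel)
    } else {
      subs[[nm]] <- list(state = s, name = nm, manifests = mans,
                         cardinality = NA_integer_, model = NULL, curve = NULL,
                         selected = apply_exclusions(mans, jcm$sub_exclusions))
    }
  }
  jcm$baseline_state <- as.integer(baseline)
  jcm$assignment <- stats::setNames(assign_state, jcm$pooled_manifests)
  jcm$subsyndromes <- subs
  jcm
}
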