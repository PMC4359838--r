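#' Declare a model variable
#'
#' A latent tree model is built from variable specifications: observed
#' (manifest) clinical manifestations, which are strictly binary, and
#' unobserved (latent) discrete variables whose cardinality is chosen by
#' model selection.
#'
#' @param name Nonempty character scalar, unique within a model.
#' @param kind `"manifest"` or `"latent"`.
#' @param cardinality Number of states. Manifest variables must have 2 states
#'   (coded 0/1). Latent variables may have 1 state (the degenerate
#'   independence model) up to any finite number; structure search bounds
#'   them to 2..5 by default.
#' @return A `variable_spec` object.
#' @export
variable_spec <- function(name, kind = c("manifest", "latent"), cardinality = 2L) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_lantree("variable name must be a nonempty string", "lantree_schema_error")
  cardinality <- as.integer(cardinality)
  if (kind == "manifest" && cardinality != 2L)
    stop_lantree(sprintf("manifest variable '%s' must be binary", name),
                 "lantree_schema_error")
  if (kind == "latent" && cardinality < 1L)
    stop_lantree(sprintf("latent variable '%s' needs cardinality >= 1", name),
                 "lantree_schema_error")
  structure(list(name = name, kind = kind, cardinality = cardinality),
            class = "variable_spec")
}

#' Construct a latent tree model
#'
#' A rooted tree whose internal nodes are discrete latent variables and whose
#' leaves are binary manifest variables. The root carries a marginal
#' distribution over its states; every other node carries a conditional
#' probability table (CPT) of its states given each parent state, stored as a
#' row-stochastic matrix with one row per parent state.
#'
#' @param variables List of [variable_spec()] objects (or a single one).
#' @param edges Two-column matrix or data.frame of `parent`, `child` names
#'   forming a rooted tree that spans all variables.
#' @param cpts Named list: for the root a numeric vector of length
#'   `cardinality`; for node `v` a matrix with `cardinality(parent)` rows and
#'   `cardinality(v)` columns. May be `NULL` (or partially `NULL`) for a
#'   structure-only skeleton to be fitted with [fit_em()].
#' @return An object of class `ltm`.
#' @seealso [validate_ltm()], [loglikelihood()], [fit_em()]
#' @export
ltm_model <- function(variables, edges, cpts = NULL) {
  if (inherits(variables, "variable_spec")) variables <- list(variables)
  nm <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop_lantree("duplicate variable names in model", "lantree_schema_error")
  kind <- stats::setNames(vapply(variables, `[[`, "", "kind"), nm)
  card <- stats::setNames(vapply(variables, `[[`, 0L, "cardinality"), nm)

  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), 0, 2)
  if (ncol(edges) != 2L)
    stop_lantree("edges must have two columns (parent, child)", "lantree_schema_error")
  parent <- stats::setNames(rep(NA_character_, length(nm)), nm)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]; ch <- edges[i, 2L]
    if (!p %in% nm || !ch %in% nm)
      stop_lantree(sprintf("edge (%s -> %s) references unknown variable", p, ch),
                   "lantree_schema_error")
    if (!is.na(parent[[ch]]))
      stop_lantree(sprintf("variable '%s' has two parents", ch), "lantree_schema_error")
    parent[[ch]] <- p
  }
  roots <- nm[is.na(parent)]
  if (length(roots) != 1L)
    stop_lantree(sprintf("model must have exactly one root (found %d)", length(roots)),
                 "lantree_schema_error")
  root <- roots[[1L]]
  if (kind[[root]] != "latent" && length(nm) > 1L)
    stop_lantree("root must be a latent variable", "lantree_schema_error")

  children <- split(unname(edges[, 2L]), factor(edges[, 1L], levels = nm))
  children <- lapply(children, as.character)

  # breadth-first topological order, root first; also detects disconnection
  topo <- character(0)
  frontier <- root
  while (length(frontier)) {
    topo <- c(topo, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
  }
  if (length(topo) != length(nm))
    stop_lantree("edges do not form a single connected rooted tree", "lantree_schema_error")

  leafless <- nm[kind == "manifest" & lengths(children[nm]) > 0L]
  if (length(leafless))
    stop_lantree(sprintf("manifest variable '%s' must be a leaf", leafless[[1L]]),
                 "lantree_schema_error")

  model <- structure(list(
    var_names = nm, kind = kind, card = card,
    parent = parent, children = children, root = root, topo = topo,
    cpts = cpts %||% stats::setNames(vector("list", length(nm)), nm)
  ), class = "ltm")
  if (!is.null(cpts)) validate_ltm(model)
  model
}

#' Validate latent tree model invariants
#'
#' Checks tree-ness, leaf status of manifest variables, CPT dimensions,
#' nonnegativity, and that every distribution row sums to 1 within `tol`.
#'
#' @param model An `ltm` object.
#' @param tol Row-sum tolerance.
#' @param require_cpts If `FALSE`, a skeleton with missing CPTs passes.
#' @return `TRUE` invisibly; signals an error on violation.
#' @export
validate_ltm <- function(model, tol = 1e-9, require_cpts = TRUE) {
  stopifnot(inherits(model, "ltm"))
  for (v in model$var_names) {
    cpt <- model$cpts[[v]]
    if (is.null(cpt)) {
      if (require_cpts)
        stop_lantree(sprintf("missing CPT for variable '%s'", v), "lantree_schema_error")
      next
    }
    cv <- model$card[[v]]
    if (v == model$root) {
      if (length(cpt) != cv)
        stop_lantree(sprintf("root marginal for '%s' has wrong length", v),
                     "lantree_schema_error")
      rows <- matrix(cpt, nrow = 1L)
    } else {
      pu <- model$parent[[v]]
      if (!is.matrix(cpt) || nrow(cpt) != model$card[[pu]] || ncol(cpt) != cv)
        stop_lantree(sprintf("CPT for '%s' must be %d x %d", v, model$card[[pu]], cv),
                     "lantree_schema_error")
      rows <- cpt
    }
    if (any(rows < -tol) || any(rows > 1 + tol))
      stop_lantree(sprintf("probabilities for '%s' outside [0, 1]", v),
                   "lantree_schema_error")
    if (any(abs(rowSums(rows) - 1) > tol))
      stop_lantree(sprintf("distribution rows for '%s' do not sum to 1", v),
                   "lantree_schema_error")
  }
  invisible(TRUE)
}

#' @export
print.ltm <- function(x, ...) {
  cat(sprintf("Latent tree model: %d latent, %d manifest variables (root: %s)\n",
              length(latent_vars(x)), length(manifest_vars(x)), x$root))
  fitted <- !any(vapply(x$cpts, is.null, TRUE))
  cat(if (fitted) "  parameters: fitted\n" else "  parameters: skeleton (unfitted)\n")
  invisible(x)
}

#' Manifest (observed) variable names of a model
#' @param model An `ltm` object.
#' @return Character vector in model order.
#' @export
manifest_vars <- function(model) unname(model$var_names[model$kind == "manifest"])

#' Latent variable names of a model
#' @param model An `ltm` object.
#' @return Character vector in model order.
#' @export
latent_vars <- function(model) unname(model$var_names[model$kind == "latent"])

#' Grouping of manifest leaves by their parent latent variable
#'
#' The manifest partition induced by latent adjacency: used to compare a
#' learned tree against planted block structure (e.g. with an adjusted Rand
#' index).
#'
#' @param model An `ltm` object.
#' @return Named character vector mapping each manifest variable to the name
#'   of its parent latent variable.
#' @export
leaf_partition <- function(model) {
  m <- manifest_vars(model)
  stats::setNames(unname(model$parent[m]), m)
}

# number of free parameters: sum over nodes of (card - 1) * card(parent),
# card(parent) = 1 for the root
n_free_params <- function(model) {
  d <- 0L
  for (v in model$var_names) {
    pc <- if (v == model$root) 1L else model$card[[model$parent[[v]]]]
    d <- d + (model$card[[v]] - 1L) * pc
  }
  d
}

# descendant manifest variables of a node (itself if manifest)
manifest_descendants <- function(model, node) {
  if (model$kind[[node]] == "manifest") return(node)
  out <- character(0)
  frontier <- model$children[[node]]
  while (length(frontier)) {
    mm <- frontier[model$kind[frontier] == "manifest"]
    out <- c(out, mm)
    frontier <- unlist(model$children[frontier[model$kind[frontier] == "latent"]],
                       use.names = FALSE)
  }
  out
}

# rebuild an ltm after structure surgery, keeping CPTs whose dimensions
# still match (others are reset to NULL for re-initialization by EM)
rebuild_ltm <- function(model, parent, card = NULL, drop = character(0)) {
  keep <- setdiff(model$var_names, drop)
  card <- card %||% model$card
  vars <- lapply(keep, function(v)
    variable_spec(v, model$kind[[v]], card[[v]]))
  eg <- cbind(unname(parent[keep][!is.na(parent[keep])]),
              keep[!is.na(parent[keep])])
  new <- ltm_model(vars, eg, cpts = NULL)
  for (v in keep) {
    cpt <- model$cpts[[v]]
    if (is.null(cpt)) next
    ok <- if (v == new$root) {
      is.null(dim(cpt)) && length(cpt) == new$card[[v]]
    } else {
      is.matrix(cpt) && !is.na(new$parent[[v]]) &&
        nrow(cpt) == new$card[[new$parent[[v]]]] && ncol(cpt) == new$card[[v]] &&
        identical(new$parent[[v]], model$parent[[v]])
    }
    if (ok) new$cpts[[v]] <- cpt
  }
  new
}
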