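# Model serialization: JSON with explicit nodes/edges/CPTs, and DOT export
# with edge line-width proportional to pairwise mutual information.

#' Write a latent tree model to JSON
#'
#' Schema: `nodes` (name, kind, cardinality, states), `edges`
#' (parent, child), `cpts` (root marginal as a vector, other nodes as
#' row-major matrices with one row per parent state).
#'
#' @param model An `ltm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_ltm(model, require_cpts = FALSE)
  nodes <- lapply(model$var_names, function(v) list(
    name = v, kind = model$kind[[v]], cardinality = model$card[[v]],
    states = if (model$kind[[v]] == "manifest") c("0", "1")
             else paste0("state", seq_len(model$card[[v]]))))
  ch <- model$var_names[!is.na(model$parent)]
  edges <- lapply(ch, function(v) list(parent = model$parent[[v]], child = v))
  cpts <- lapply(model$var_names, function(v) {
    cpt <- model$cpts[[v]]
    if (is.null(cpt)) NULL
    else if (v == model$root) as.vector(cpt)
    else lapply(seq_len(nrow(cpt)), function(i) as.vector(cpt[i, ]))
  })
  names(cpts) <- model$var_names
  jsonlite::write_json(list(nodes = nodes, edges = edges, cpts = cpts),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a latent tree model from JSON
#'
#' @param path A file written by [write_model_json()].
#' @return An `ltm`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- lapply(j$nodes, function(n)
    variable_spec(n$name, n$kind, n$cardinality))
  edges <- do.call(rbind, lapply(j$edges, function(e) c(e$parent, e$child)))
  model <- ltm_model(vars, edges)
  for (v in names(j$cpts)) {
    cpt <- j$cpts[[v]]
    if (is.null(cpt)) next
    model$cpts[[v]] <- if (v == model$root) unlist(cpt)
      else do.call(rbind, lapply(cpt, unlist))
  }
  validate_ltm(model, require_cpts = FALSE)
  model
}

#' Export a latent tree model as a DOT graph
#'
#' Latent variables are drawn as ellipses, manifest variables as boxes, and
#' each edge's line width is proportional to the pairwise mutual information
#' between its endpoints (the convention used to draw latent structural
#' models, where correlation strength is shown as line width).
#'
#' @param model A fitted `ltm`.
#' @param path Output path (`.dot`).
#' @param max_penwidth Line width given to the strongest edge.
#' @return `path`, invisibly.
#' @export
export_dot <- function(model, path, max_penwidth = 5) {
  validate_ltm(model)
  ch <- model$var_names[!is.na(model$parent)]
  mi <- vapply(ch, function(v) pairwise_mi(model, model$parent[[v]], v), 0)
  w <- if (max(mi) > 0) 0.3 + (max_penwidth - 0.3) * mi / max(mi) else rep(1, length(mi))
  lines <- c("graph ltm {", "  rankdir=TB;")
  for (v in model$var_names) {
    shape <- if (model$kind[[v]] == "latent") "ellipse" else "box"
    lines <- c(lines, sprintf('  "%s" [shape=%s];', v, shape))
  }
  for (i in seq_along(ch))
    lines <- c(lines, sprintf('  "%s" -- "%s" [penwidth=%.2f];',
                              model$parent[[ch[[i]]]], ch[[i]], w[[i]]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export an EM trace as TSV
#'
#' @param fit An [fit_em()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(fit, path) {
  utils::write.table(
    data.frame(iteration = seq_along(fit$loglik_trace) - 1L,
               objective = fit$loglik_trace),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an EM fit to JSON
#'
#' Writes the fitted model (inline, same schema as [write_model_json()])
#' together with the optimization record: trace, convergence flag, restarts
#' and seed.
#'
#' @param fit An [fit_em()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_em_json <- function(fit, path) {
  stopifnot(inherits(fit, "ltm_em"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_model_json(fit$model, tmp)
  model <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  jsonlite::write_json(
    list(model = model, loglik = fit$loglik,
         loglik_trace = fit$loglik_trace, converged = fit$converged,
         restarts_used = fit$restarts_used, best_restart = fit$best_restart,
         seed = fit$seed, smooth = fit$smooth),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
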