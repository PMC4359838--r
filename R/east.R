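# Greedy, BIC-guided structure search for latent tree models, in the style
# of the expansion / adjustment / simplification search family:
#   expansion      - introduce a new 2-state latent over a sibling pair, or
#                    add a state to an existing latent
#   adjustment     - relocate nodes to better-fitting latent parents
#   simplification - delete latent nodes or states
# Phases cycle until no operator improves BIC. Candidates are scored with a
# short warm-started EM; the accepted winner is re-fitted with the full
# budget. All randomness derives from the configuration seed.

#' Structure-search configuration
#'
#' @param max_latents Maximum number of latent variables.
#' @param card_min,card_max Bounds on latent cardinality (defaults 2 and 5).
#' @param short_em EM budget for scoring expansion/simplification
#'   candidates: `list(tol, max_iter, restarts)`; candidates warm-start from
#'   the current parameters.
#' @param reloc_em Tighter EM budget for scoring relocation candidates
#'   (only the moved edge must adapt, so a short warm run ranks reliably).
#' @param full_em EM budget for re-fitting accepted candidates.
#' @param init_restarts Random restarts for the initial flat model.
#' @param k_intro Number of top-scoring sibling pairs considered per
#'   expansion step.
#' @param k_parents Candidate new parents considered per node during
#'   adjustment.
#' @param max_cycles Safety cap on expansion/adjustment/simplification cycles.
#' @param smooth M-step pseudo-count (see [fit_em()]).
#' @param seed Master seed; every candidate evaluation derives its own seed
#'   from it.
#' @return A `search_config` list.
#' @export
search_config <- function(max_latents = 25L, card_min = 2L, card_max = 5L,
                          short_em = list(tol = 1e-4, max_iter = 100L, restarts = 1L),
                          reloc_em = list(tol = 1e-4, max_iter = 40L, restarts = 1L),
                          full_em = list(tol = 1e-5, max_iter = 200L, restarts = 1L),
                          init_restarts = 4L, k_intro = 8L, k_parents = 3L,
                          max_cycles = 8L, smooth = 0.01, seed = 1L) {
  stopifnot(card_min >= 2L, card_max >= card_min, max_latents >= 1L)
  structure(list(max_latents = as.integer(max_latents),
                 card_min = as.integer(card_min), card_max = as.integer(card_max),
                 short_em = short_em, reloc_em = reloc_em, full_em = full_em,
                 init_restarts = as.integer(init_restarts),
                 k_intro = as.integer(k_intro), k_parents = as.integer(k_parents),
                 max_cycles = as.integer(max_cycles), smooth = smooth,
                 seed = as.integer(seed)),
            class = "search_config")
}

# flat latent class structure: one latent over all manifest columns
latent_class_structure <- function(manifests, card = 2L, name = "L1") {
  vars <- c(list(variable_spec(name, "latent", card)),
            lapply(manifests, variable_spec, kind = "manifest"))
  ltm_model(vars, cbind(name, manifests))
}

#' Introduce a latent variable over a sibling pair
#'
#' Expansion operator: inserts a new 2-state latent variable between a parent
#' and two of its children; the pair becomes children of the new node.
#' Returns an unfitted candidate (CPTs of the affected edges are reset and
#' re-estimated by EM during scoring).
#'
#' @param model An `ltm`.
#' @param pair Character vector of two sibling node names.
#' @param name Name for the new latent (default: next free `L<k>`).
#' @param card Cardinality of the new latent (default 2).
#' @return Candidate `ltm` skeleton.
#' @export
operator_node_introduction <- function(model, pair, name = NULL, card = 2L) {
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% model$var_names))
    stop_lantree("pair contains unknown variables", "lantree_schema_error")
  p1 <- model$parent[[pair[[1L]]]]
  if (is.na(p1) || !identical(p1, model$parent[[pair[[2L]]]]))
    stop_lantree("pair must share a parent", "lantree_schema_error")
  name <- name %||% next_latent_name(model)
  parent <- model$parent
  parent[pair] <- name
  new <- rebuild_with_extra(model, parent, extra = list(
    variable_spec(name, "latent", card)), extra_parent = stats::setNames(p1, name))
  new
}

#' Adjust the number of states of a latent variable
#'
#' Expansion/simplification operator: returns a candidate with the latent's
#' cardinality changed by `delta` (+1 or -1). State addition seeds the new
#' state from a perturbed copy of existing rows; state deletion removes the
#' state with the smallest marginal mass. Bound violations signal an error.
#'
#' @param model A fitted `ltm`.
#' @param latent Latent variable name.
#' @param delta +1 or -1.
#' @param card_min,card_max Cardinality bounds.
#' @return Candidate `ltm` (warm-started CPTs).
#' @export
operator_state_adjustment <- function(model, latent, delta,
                                      card_min = 2L, card_max = 5L) {
  stopifnot(delta %in% c(-1L, 1L))
  cv <- model$card[[latent]]
  newc <- cv + delta
  if (newc < card_min || newc > card_max)
    stop_lantree(sprintf("cardinality %d outside bounds [%d, %d]",
                         newc, card_min, card_max), "lantree_bound_error")
  card <- model$card
  card[[latent]] <- newc
  new <- rebuild_ltm(model, model$parent, card = card)

  own <- model$cpts[[latent]]
  kids <- model$children[[latent]]
  if (delta == 1L) {
    eps <- 0.1
    if (latent == model$root) {
      new$cpts[[latent]] <- c(own * (1 - eps), eps)
    } else if (!is.null(own)) {
      new$cpts[[latent]] <- cbind(own * (1 - eps), eps)
    }
    for (i in seq_along(kids)) {
      ck <- model$cpts[[kids[[i]]]]
      if (is.null(ck)) next
      w <- 0.75 + 0.05 * (i %% 4)           # deterministic asymmetric seeding
      newrow <- w * ck[1L, ] + (1 - w) / ncol(ck)
      new$cpts[[kids[[i]]]] <- rbind(ck, newrow / sum(newrow))
    }
  } else {
    marg <- node_marginals(model)[[latent]]
    drop <- which.min(marg)
    if (latent == model$root) {
      pr <- own[-drop]
      new$cpts[[latent]] <- pr / sum(pr)
    } else if (!is.null(own)) {
      new$cpts[[latent]] <- row_normalize(own[, -drop, drop = FALSE])
    }
    for (k in kids) {
      ck <- model$cpts[[k]]
      if (!is.null(ck)) new$cpts[[k]] <- ck[-drop, , drop = FALSE]
    }
  }
  new
}

#' Relocate a node to a new latent parent
#'
#' Adjustment operator: re-attaches `node` (a manifest leaf or a latent
#' subtree) under `new_parent`, preserving tree-ness. Relocating to the
#' current parent is the identity; moves that would create a cycle (a latent
#' moved into its own subtree) are rejected.
#'
#' @param model An `ltm`.
#' @param node Node to move (not the root).
#' @param new_parent A latent variable.
#' @return Candidate `ltm` (the moved edge's CPT is re-initialized).
#' @export
operator_relocation <- function(model, node, new_parent) {
  if (identical(model$parent[[node]], new_parent)) return(model)
  if (is.na(model$parent[[node]]))
    stop_lantree("cannot relocate the root", "lantree_schema_error")
  if (model$kind[[new_parent]] != "latent")
    stop_lantree("new parent must be latent", "lantree_schema_error")
  if (model$kind[[node]] == "latent") {
    sub <- c(node, manifest_descendants(model, node))
    anc <- new_parent
    while (!is.na(anc)) {
      if (anc == node)
        stop_lantree("relocation would create a cycle", "lantree_schema_error")
      anc <- model$parent[[anc]]
    }
  }
  parent <- model$parent
  parent[[node]] <- new_parent
  new <- rebuild_ltm(model, parent)
  new$cpts[[node]] <- NULL
  new
}

next_latent_name <- function(model) {
  k <- 1L
  repeat {
    nm <- paste0("L", k)
    if (!nm %in% model$var_names) return(nm)
    k <- k + 1L
  }
}

# rebuild with additional variables appended
rebuild_with_extra <- function(model, parent, extra, extra_parent) {
  vars <- c(lapply(model$var_names, function(v)
    variable_spec(v, model$kind[[v]], model$card[[v]])), extra)
  parent <- c(parent, extra_parent)
  nm <- vapply(vars, `[[`, "", "name")
  eg <- cbind(unname(parent[nm][!is.na(parent[nm])]), nm[!is.na(parent[nm])])
  new <- ltm_model(vars, eg)
  for (v in model$var_names) {
    cpt <- model$cpts[[v]]
    if (is.null(cpt)) next
    ok <- if (v == new$root) {
      is.null(dim(cpt)) && length(cpt) == new$card[[v]]
    } else {
      is.matrix(cpt) && !is.na(new$parent[[v]]) &&
        identical(new$parent[[v]], model$parent[[v]]) &&
        nrow(cpt) == new$card[[new$parent[[v]]]] && ncol(cpt) == new$card[[v]]
    }
    if (ok) new$cpts[[v]] <- cpt
  }
  new
}

# delete a non-root latent; its children re-attach to its parent
delete_latent <- function(model, z) {
  stopifnot(model$kind[[z]] == "latent", z != model$root)
  parent <- model$parent
  parent[model$children[[z]]] <- parent[[z]]
  parent <- parent[names(parent) != z]
  rebuild_ltm(model, parent, drop = z)
}

# empirical-MI affinity between two nodes: mean pairwise MI over the cross
# product of their manifest descendants
node_affinity <- function(model, emp, a, b) {
  da <- manifest_descendants(model, a)
  db <- manifest_descendants(model, b)
  if (!length(da) || !length(db)) return(0)
  mean(emp[da, db, drop = FALSE])
}

#' Learn a latent tree structure from binary data
#'
#' Greedy hill-climbing over latent tree structures, scored by BIC. Starting
#' from a single latent class variable over all manifest columns, the search
#' cycles through an expansion phase (node introduction over high-affinity
#' sibling pairs, state addition), an adjustment phase (node relocation) and
#' a simplification phase (state and node deletion) until no candidate
#' improves BIC. Candidate moves are scored with a short warm-started EM and
#' each accepted move is re-fitted with the full budget; ties are broken
#' lexicographically by (operator, description) so the search is
#' deterministic given the seed.
#'
#' @param data A [symptom_matrix()] or 0/1 matrix with >= 2 columns.
#' @param cfg A [search_config()].
#' @param verbose Print accepted moves.
#' @return List with elements `model` (the fitted `ltm`), `bic`, `fit` (the
#'   final [fit_em()] result) and `trace` (data.frame of all evaluated moves:
#'   phase, operator, description, bic_before, bic_after, accepted).
#' @export
search_structure <- function(data, cfg = search_config(), verbose = FALSE) {
  X <- if (inherits(data, "symptom_matrix")) data$values else as.matrix(data)
  M <- ncol(X)
  if (M < 2L)
    stop_lantree("need at least two manifest columns", "lantree_schema_error")
  emp <- empirical_mi_matrix(X)
  counter <- 0L
  nseed <- function(tag) {
    counter <<- counter + 1L
    derive_seed(cfg$seed, paste0(tag, "-", counter))
  }
  trace <- list()
  note <- function(phase, op, desc, b0, b1, acc) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, operator = op, description = desc,
      bic_before = b0, bic_after = b1, accepted = acc)
  }

  short_fit <- function(m, budget = cfg$short_em) {
    fit_em(m, X, tol = budget$tol, max_iter = budget$max_iter,
           restarts = budget$restarts, seed = nseed("short"),
           smooth = cfg$smooth, init = "current")
  }
  full_fit <- function(m, restarts = cfg$full_em$restarts) {
    fit_em(m, X, tol = cfg$full_em$tol, max_iter = cfg$full_em$max_iter,
           restarts = restarts, seed = nseed("full"),
           smooth = cfg$smooth, init = "current")
  }

  model <- latent_class_structure(colnames(X), cfg$card_min)
  fit <- fit_em(model, X, tol = cfg$full_em$tol, max_iter = cfg$full_em$max_iter,
                restarts = cfg$init_restarts, seed = derive_seed(cfg$seed, "init"),
                smooth = cfg$smooth)
  model <- fit$model
  bic <- bic_score(model, X, loglik = fit$loglik)
  eps <- 1e-6

  # ---- candidate generation -------------------------------------------------

  expansion_candidates <- function(model) {
    cands <- list()
    n_lat <- length(latent_vars(model))
    if (n_lat < cfg$max_latents) {
      pairs <- list()
      for (p in latent_vars(model)) {
        kids <- model$children[[p]]
        if (length(kids) < 3L) next        # pair under a 2-child parent is equivalent
        if (length(kids) > 12L) {
          # keep the strongest-affinity children to bound the pair set
          aff <- vapply(kids, function(k) {
            d <- manifest_descendants(model, k)
            if (!length(d)) 0 else max(emp[d, , drop = FALSE])
          }, 0)
          kids <- kids[order(-aff)][seq_len(12L)]
        }
        cmb <- utils::combn(sort(kids), 2L)
        for (j in seq_len(ncol(cmb)))
          pairs[[length(pairs) + 1L]] <- list(parent = p, pair = cmb[, j])
      }
      if (length(pairs)) {
        sc <- vapply(pairs, function(pp)
          node_affinity(model, emp, pp$pair[[1L]], pp$pair[[2L]]), 0)
        pairs <- pairs[order(-sc)][seq_len(min(cfg$k_intro, length(pairs)))]
        for (pp in pairs) {
          cands[[length(cands) + 1L]] <- list(
            op = "node_introduction",
            desc = paste0(pp$pair[[1L]], "+", pp$pair[[2L]]),
            build = local({
              pr <- pp
              function(m) operator_node_introduction(m, pr$pair)
            }))
          # compound variant: when the parent has surplus states, the new
          # node can take over one of them; plain introduction cannot beat
          # an inflated parent, so the swap is offered as its own candidate
          if (model$card[[pp$parent]] > cfg$card_min) {
            cands[[length(cands) + 1L]] <- list(
              op = "node_introduction_state_swap",
              desc = paste0(pp$pair[[1L]], "+", pp$pair[[2L]], "-",
                            pp$parent),
              build = local({
                pr <- pp
                function(m) {
                  m2 <- operator_state_adjustment(m, pr$parent, -1L,
                                                  cfg$card_min, cfg$card_max)
                  operator_node_introduction(m2, pr$pair)
                }
              }))
          }
        }
      }
    }
    for (z in sort(latent_vars(model))) {
      if (model$card[[z]] < cfg$card_max) {
        cands[[length(cands) + 1L]] <- list(
          op = "state_addition", desc = z,
          build = local({
            zz <- z
            function(m) operator_state_adjustment(m, zz, +1L,
                                                  cfg$card_min, cfg$card_max)
          }))
      }
    }
    cands
  }

  relocation_candidates <- function(model) {
    lats <- latent_vars(model)
    if (length(lats) < 2L) return(list())
    cands <- list()
    movable <- c(manifest_vars(model), setdiff(lats, model$root))
    for (v in movable) {
      p <- model$parent[[v]]
      if (is.na(p)) next
      targets <- setdiff(lats, c(v, p))
      if (model$kind[[v]] == "latent") {
        targets <- Filter(function(q) {     # reject moves into v's own subtree
          anc <- q
          while (!is.na(anc)) {
            if (anc == v) return(FALSE)
            anc <- model$parent[[anc]]
          }
          TRUE
        }, targets)
      }
      if (!length(targets)) next
      aff <- vapply(targets, function(q) node_affinity(model, emp, v, q), 0)
      keep <- order(-aff)[seq_len(min(cfg$k_parents, length(targets)))]
      for (q in targets[keep]) {
        cands[[length(cands) + 1L]] <- list(
          op = "relocation", desc = paste0(v, "->", q),
          move = list(node = v, to = q),
          build = local({
            vv <- v; qq <- q
            function(m) operator_relocation(m, vv, qq)
          }))
      }
    }
    cands
  }

  simplification_candidates <- function(model) {
    cands <- list()
    for (z in sort(latent_vars(model))) {
      if (model$card[[z]] > cfg$card_min) {
        cands[[length(cands) + 1L]] <- list(
          op = "state_deletion", desc = z,
          build = local({
            zz <- z
            function(m) operator_state_adjustment(m, zz, -1L,
                                                  cfg$card_min, cfg$card_max)
          }))
      }
      if (z != model$root) {
        cands[[length(cands) + 1L]] <- list(
          op = "node_deletion", desc = z,
          build = local({
            zz <- z
            function(m) delete_latent(m, zz)
          }))
      }
    }
    cands
  }

  # ---- candidate evaluation -------------------------------------------------

  eval_cands <- function(model, cands, budget = cfg$short_em) {
    res <- lapply(cands, function(cd) {
      cand <- tryCatch(cd$build(model), lantree_error = function(e) NULL)
      if (is.null(cand)) return(NULL)
      f <- short_fit(cand, budget)
      list(cd = cd, model = f$model, bic = bic_score(f$model, X, loglik = f$loglik))
    })
    Filter(Negate(is.null), res)
  }

  # stable ordering for deterministic tie-breaks; expansion candidates are
  # ranked by cost-effectiveness (BIC improvement per added free parameter)
  # so that cheap node introductions are preferred over parameter-hungry
  # state additions when both improve the score
  order_res <- function(res, model = NULL, bic = NULL) {
    key <- vapply(res, function(r) paste(r$cd$op, r$cd$desc), "")
    bics <- vapply(res, `[[`, 0, "bic")
    if (!is.null(model)) {
      d0 <- n_free_params(model)
      eff <- vapply(res, function(r)
        (r$bic - bic) / max(n_free_params(r$model) - d0, 1L), 0)
      return(res[order(-eff, key)])
    }
    res[order(-bics, key)]
  }

  accept_best <- function(phase, model, bic, cands) {
    if (!length(cands)) return(list(model = model, bic = bic, accepted = FALSE))
    res <- eval_cands(model, cands)
    res <- if (phase == "expansion") {
      res <- Filter(function(r) r$bic > bic + eps, res)
      order_res(res, model, bic)
    } else order_res(res)
    if (!length(res)) return(list(model = model, bic = bic, accepted = FALSE))
    best <- res[[1L]]
    if (best$bic <= bic + eps) {
      note(phase, best$cd$op, best$cd$desc, bic, best$bic, FALSE)
      return(list(model = model, bic = bic, accepted = FALSE))
    }
    f <- full_fit(best$model)
    nb <- bic_score(f$model, X, loglik = f$loglik)
    if (nb <= bic + eps) {
      note(phase, best$cd$op, best$cd$desc, bic, nb, FALSE)
      return(list(model = model, bic = bic, accepted = FALSE))
    }
    note(phase, best$cd$op, best$cd$desc, bic, nb, TRUE)
    if (verbose)
      message(sprintf("[%s] %s %s: BIC %.2f -> %.2f", phase, best$cd$op,
                      best$cd$desc, bic, nb))
    list(model = f$model, bic = nb, accepted = TRUE)
  }

  # batched adjustment sweep: score every relocation in isolation, apply all
  # improving moves together, keep the batch only if the re-fitted BIC
  # improves, otherwise fall back to the single best move
  adjustment_sweep <- function(model, bic) {
    cands <- relocation_candidates(model)
    if (!length(cands)) return(list(model = model, bic = bic, accepted = FALSE))
    res <- order_res(eval_cands(model, cands, cfg$reloc_em %||% cfg$short_em))
    imp <- Filter(function(r) r$bic > bic + eps, res)
    if (!length(imp)) return(list(model = model, bic = bic, accepted = FALSE))
    if (length(imp) > 1L) {
      cand <- model
      applied <- list()
      moved <- character(0)
      for (r in imp) {
        mv <- r$cd$move
        if (mv$node %in% moved || !mv$to %in% latent_vars(cand)) next
        ok <- tryCatch({
          cand <- operator_relocation(cand, mv$node, mv$to)
          TRUE
        }, lantree_error = function(e) FALSE)
        if (ok) { applied[[length(applied) + 1L]] <- r; moved <- c(moved, mv$node) }
      }
      f <- full_fit(cand)
      nb <- bic_score(f$model, X, loglik = f$loglik)
      if (nb > bic + eps) {
        for (r in applied) note("adjustment", "relocation", r$cd$desc, bic, nb, TRUE)
        if (verbose)
          message(sprintf("[adjustment] batch of %d relocations: BIC %.2f -> %.2f",
                          length(applied), bic, nb))
        return(list(model = f$model, bic = nb, accepted = TRUE))
      }
    }
    # single best move
    best <- imp[[1L]]
    f <- full_fit(best$model)
    nb <- bic_score(f$model, X, loglik = f$loglik)
    if (nb <= bic + eps) {
      note("adjustment", "relocation", best$cd$desc, bic, nb, FALSE)
      return(list(model = model, bic = bic, accepted = FALSE))
    }
    note("adjustment", "relocation", best$cd$desc, bic, nb, TRUE)
    if (verbose)
      message(sprintf("[adjustment] relocation %s: BIC %.2f -> %.2f",
                      best$cd$desc, bic, nb))
    list(model = f$model, bic = nb, accepted = TRUE)
  }

  # ---- main loop ------------------------------------------------------------

  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    any_accept <- FALSE
    repeat {   # expansion
      st <- accept_best("expansion", model, bic, expansion_candidates(model))
      model <- st$model; bic <- st$bic
      if (!st$accepted) break
      any_accept <- TRUE
    }
    sweeps <- 0L
    repeat {   # adjustment
      sweeps <- sweeps + 1L
      st <- adjustment_sweep(model, bic)
      model <- st$model; bic <- st$bic
      if (!st$accepted || sweeps >= 6L) break
      any_accept <- TRUE
    }
    repeat {   # simplification
      st <- accept_best("simplification", model, bic, simplification_candidates(model))
      model <- st$model; bic <- st$bic
      if (!st$accepted) break
      any_accept <- TRUE
    }
    if (!any_accept || cycles >= cfg$max_cycles) break
  }

  # final polish: warm refit at full budget (EM is monotone, so BIC can only
  # stay or improve up to convergence tolerance)
  fit <- full_fit(model, restarts = 1L)
  final_bic <- bic_score(fit$model, X, loglik = fit$loglik)
  if (final_bic >= bic - 1e-6) {
    model <- fit$model
    bic <- max(bic, final_bic)
  } else {
    fit$model <- model
  }

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = character(), operator = character(),
               description = character(), bic_before = numeric(),
               bic_after = numeric(), accepted = logical())
  list(model = model, bic = bic, fit = fit, trace = trace_df)
}
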