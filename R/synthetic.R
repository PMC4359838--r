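# Synthetic binary cohorts with planted latent tree structure. The generator
# is the test bed for the whole pipeline: every block of manifest variables
# is driven by one planted latent variable, blocks are tied together by a
# weakly coupled latent backbone, and a preset emulates the shape of a
# 559-record, 57-symptom clinical cohort grouped into 14 latent blocks.

#' Declare a planted block
#'
#' One latent variable and the manifest variables it drives. A member with
#' loading strength `s` has `P(present | active state) = 0.5 + s/2` and
#' `P(present | other states) = 0.5 - s/2`, so the between-state contrast is
#' exactly `s` (`s = 1` gives deterministic CPTs).
#'
#' @param latent Latent variable name.
#' @param members Character vector of manifest variable names.
#' @param cardinality Number of latent states (default 2).
#' @param loading Loading strength in (0, 1]; scalar or one value per member.
#' @param active_state For each member, the state in which it is likely
#'   present (default: states `2..cardinality` in round-robin).
#' @return A `planted_block` list.
#' @export
planted_block <- function(latent, members, cardinality = 2L, loading = 0.6,
                          active_state = NULL) {
  stopifnot(length(members) >= 1L, cardinality >= 2L)
  loading <- rep_len(loading, length(members))
  if (any(loading <= 0 | loading > 1))
    stop_lantree("loading strength must be in (0, 1]", "lantree_spec_error")
  active_state <- active_state %||%
    (2L + (seq_along(members) - 1L) %% (cardinality - 1L))
  active_state <- rep_len(as.integer(active_state), length(members))
  if (any(active_state < 1L | active_state > cardinality))
    stop_lantree("active_state outside latent cardinality", "lantree_spec_error")
  structure(list(latent = latent, members = members,
                 cardinality = as.integer(cardinality),
                 loading = loading, active_state = active_state),
            class = "planted_block")
}

#' Declare a planted cohort specification
#'
#' @param blocks List of [planted_block()]s; manifest names must be unique
#'   across blocks.
#' @param backbone Optional data.frame with columns `parent`, `child` and
#'   `coupling` describing latent-latent edges. A scalar coupling `e` mixes a
#'   uniform distribution with a state-following component
#'   (`P(child = j | parent = i) = (1-e)/c + e * [j == 1 + (i-1) mod c]`).
#'   `coupling` may instead hold a list-column of explicit row-stochastic
#'   matrices. Default: a chain over the blocks in order with coupling 0.1.
#' @param hubs Optional list of latent-only variables:
#'   `list(name =, cardinality =, marginal =)`; a hub used as a root supplies
#'   its own marginal.
#' @param n_records Number of records to sample.
#' @param seed Master seed for sampling.
#' @param tags Optional named list of categorical tag columns:
#'   `list(sex = c(male = 482/559, ...))`; tags are sampled independently of
#'   the symptom model and are not used in fitting.
#' @return A `planted_spec` list.
#' @export
planted_spec <- function(blocks, backbone = NULL, hubs = NULL, n_records,
                         seed = 1L, tags = NULL) {
  if (inherits(blocks, "planted_block")) blocks <- list(blocks)
  members <- unlist(lapply(blocks, `[[`, "members"))
  if (anyDuplicated(members))
    stop_lantree(sprintf("manifest '%s' appears in more than one block",
                         members[duplicated(members)][1L]), "lantree_spec_error")
  if (n_records < 1L)
    stop_lantree("n_records must be >= 1", "lantree_spec_error")
  lat <- vapply(blocks, `[[`, "", "latent")
  if (is.null(backbone) && length(lat) > 1L)
    backbone <- data.frame(parent = lat[-length(lat)], child = lat[-1L],
                           coupling = 0.1)
  structure(list(blocks = blocks, backbone = backbone, hubs = hubs,
                 n_records = as.integer(n_records), seed = as.integer(seed),
                 tags = tags),
            class = "planted_spec")
}

coupling_cpt <- function(coupling, cu, cv) {
  if (is.matrix(coupling)) {
    stopifnot(nrow(coupling) == cu, ncol(coupling) == cv)
    return(row_normalize(coupling))
  }
  e <- as.numeric(coupling)
  m <- matrix((1 - e) / cv, cu, cv)
  for (i in seq_len(cu)) {
    j <- 1L + (i - 1L) %% cv
    m[i, j] <- m[i, j] + e
  }
  m
}

#' Build the ground-truth latent tree model of a planted specification
#'
#' @param spec A [planted_spec()].
#' @return A fitted `ltm` whose leaves are the block members and whose
#'   internal nodes are the block latents (plus any hubs).
#' @export
make_planted_model <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  vars <- list()
  edges <- NULL
  cpts <- list()
  lat_card <- integer(0)

  for (h in spec$hubs %||% list()) {
    vars[[length(vars) + 1L]] <- variable_spec(h$name, "latent", h$cardinality)
    lat_card[[h$name]] <- as.integer(h$cardinality)
    if (!is.null(h$marginal)) cpts[[h$name]] <- h$marginal / sum(h$marginal)
  }
  for (b in spec$blocks) {
    vars[[length(vars) + 1L]] <- variable_spec(b$latent, "latent", b$cardinality)
    lat_card[[b$latent]] <- b$cardinality
    for (i in seq_along(b$members)) {
      m <- b$members[[i]]
      vars[[length(vars) + 1L]] <- variable_spec(m, "manifest")
      edges <- rbind(edges, c(b$latent, m))
      hi <- 0.5 + b$loading[[i]] / 2
      lo <- 0.5 - b$loading[[i]] / 2
      cpt <- matrix(c(1 - lo, lo), b$cardinality, 2L, byrow = TRUE)
      cpt[b$active_state[[i]], ] <- c(1 - hi, hi)
      cpts[[m]] <- cpt
    }
  }
  bb <- spec$backbone
  if (!is.null(bb)) {
    for (i in seq_len(nrow(bb))) {
      p <- bb$parent[[i]]; ch <- bb$child[[i]]
      edges <- rbind(edges, c(p, ch))
      cp <- if (is.list(bb$coupling)) bb$coupling[[i]] else bb$coupling[[i]]
      cpts[[ch]] <- coupling_cpt(cp, lat_card[[p]], lat_card[[ch]])
    }
  }
  model <- ltm_model(vars, edges)
  # root marginal: uniform unless supplied by a hub
  if (is.null(cpts[[model$root]]))
    cpts[[model$root]] <- rep(1 / model$card[[model$root]],
                              model$card[[model$root]])
  model$cpts <- cpts[model$var_names]
  names(model$cpts) <- model$var_names
  validate_ltm(model)
  model
}

#' Sample a binary cohort from a latent tree model
#'
#' Draws `n` i.i.d. records by ancestral sampling down the tree,
#' reproducibly for a given seed.
#'
#' @param model A fitted `ltm`.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @return A [symptom_matrix()] with one 0/1 column per manifest variable, in
#'   model order.
#' @export
sample_cohort <- function(model, n, seed = 1L) {
  if (n < 1L)
    stop_lantree("n must be >= 1", "lantree_spec_error")
  S <- ltm_sample_states(model, n, derive_seed(seed, "cohort"))
  m <- manifest_vars(model)
  symptom_matrix(S[, m, drop = FALSE] - 1L)
}

#' Simulate a full planted cohort
#'
#' Convenience wrapper: builds the ground-truth model, samples the cohort and
#' any demographic tag columns, and returns the planted leaf partition for
#' recovery scoring.
#'
#' @param spec A [planted_spec()].
#' @return List with `model`, `data` (a [symptom_matrix()]), `tags`
#'   (data.frame or `NULL`) and `partition` (named manifest -> latent map).
#' @export
simulate_cohort <- function(spec) {
  model <- make_planted_model(spec)
  data <- sample_cohort(model, spec$n_records, spec$seed)
  tags <- NULL
  if (!is.null(spec$tags)) {
    set.seed(derive_seed(spec$seed, "tags"))
    tags <- as.data.frame(lapply(spec$tags, function(p)
      sample(names(p), spec$n_records, replace = TRUE, prob = p)))
  }
  list(model = model, data = data, tags = tags,
       partition = leaf_partition(model))
}

#' Preset emulating the shape of the clinical liver-cancer cohort
#'
#' A 559-record, 57-symptom specification whose columns group into 14 latent
#' blocks (Y0..Y13). Block memberships follow the per-latent symptom
#' groupings reported in liver-cancer syndrome-differentiation work where
#' those are stated; the remaining symptoms are
#' assigned to clinically plausible blocks and the assignment is synthetic,
#' not an estimate. Three additional weak members sit under the fever block
#' (rapid pulse, ascites, pale lips and nails) with loading 0.25, mirroring
#' the thin edges drawn for that latent. The five deficiency-related blocks
#' (Y2, Y3, Y10, Y11, Y12) hang off a 3-state hub `DEF` (baseline /
#' spleen-kidney / liver-kidney patterns, with Y10 active in both
#' non-baseline states), so that joint clustering of the deficiency factor
#' genuinely exhibits three conditions; the other nine blocks form a chain
#' with coupling 0.1. Demographic tags (sex 482:77, six clinical stages
#' 66/72/92/171/139/19) are generated but excluded from model fitting.
#'
#' @param n_records Number of records (default 559).
#' @param loading Default loading strength (0.6).
#' @param seed Master seed.
#' @return A [planted_spec()].
#' @export
plc_cohort_preset <- function(n_records = 559L, loading = 0.6, seed = 1L) {
  blocks <- list(
    planted_block("Y0", c("hypochondriac pain", "chest pain"), loading = loading),
    planted_block("Y1", c("stomach bloating", "chills", "chest distress",
                          "stomachache", "dizziness", "abdominal distension",
                          "shoulder and back pain", "depression"),
                  loading = loading),
    planted_block("Y2", c("anorexia", "hypochondrium block",
                          "nausea and vomiting"), loading = loading),
    planted_block("Y3", c("dim complexion", "night sweating", "loose stool",
                          "tinnitus", "sallow complexion", "pale complexion",
                          "spontaneous sweating"), loading = loading),
    planted_block("Y4", c("purplish tongue", "plump tongue",
                          "sublingual vein varicose", "petechiae tongue"),
                  loading = loading),
    planted_block("Y5", c("greasy tongue coating", "yellow tongue coating",
                          "white tongue coating", "heavy head and body"),
                  loading = loading),
    planted_block("Y6", "red tongue", loading = loading),
    planted_block("Y7", c("cyanotic lips and nails",
                          "liver palms and spider nevus"), loading = loading),
    planted_block("Y8", c("fever", "hectic fever", "rapid pulse", "ascites",
                          "pale lips and nails"),
                  loading = c(loading, loading, 0.25, 0.25, 0.25)),
    planted_block("Y9", c("taut pulse", "slippery pulse", "unsmooth pulse"),
                  loading = loading),
    planted_block("Y10", c("thready pulse", "weak pulse"), loading = loading),
    planted_block("Y11", c("fatigue", "lumbar genu aching and limp", "insomnia",
                           "night urination"), loading = loading),
    planted_block("Y12", c("dry mouth and throat", "bitter taste",
                           "heat in palms and soles", "thirst", "dry stool"),
                  loading = loading),
    planted_block("Y13", c("yellow urine", "hiccup", "jaundice",
                           "edema in feet and legs", "bad breath",
                           "hydrothorax", "oliguria"), loading = loading)
  )
  act <- function(p) matrix(c(1 - p, p), ncol = 2)   # rows: DEF states
  backbone <- data.frame(
    parent = c("Y0", "Y1", "Y4", "Y5", "Y6", "Y7", "Y8", "Y9",
               "Y0", "DEF", "DEF", "DEF", "DEF", "DEF"),
    child = c("Y1", "Y4", "Y5", "Y6", "Y7", "Y8", "Y9", "Y13",
              "DEF", "Y2", "Y3", "Y10", "Y11", "Y12"))
  # hub-to-block activation is nearly deterministic (0.97) so the three
  # planted conditions, not block-level noise, dominate the pooled columns
  backbone$coupling <- list(
    0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
    act(c(0.03, 0.97, 0.03)),    # Y2 active under the spleen-kidney state
    act(c(0.03, 0.97, 0.03)),    # Y3
    act(c(0.03, 0.97, 0.97)),    # Y10 active under both deficiency states
    act(c(0.03, 0.03, 0.97)),    # Y11 active under the liver-kidney state
    act(c(0.03, 0.03, 0.97)))    # Y12
  hubs <- list(list(name = "DEF", cardinality = 3L,
                    marginal = c(0.4, 0.3, 0.3)))
  tags <- list(sex = c(male = 482, female = 77) / 559,
               stage = c(Ia = 66, Ib = 72, IIa = 92, IIb = 171,
                         IIIa = 139, IIIb = 19) / 559)
  planted_spec(blocks, backbone = backbone, hubs = hubs,
               n_records = n_records, seed = seed, tags = tags)
}

#' Write a planted specification to JSON
#'
#' @param spec A [planted_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_spec <- function(spec, path) {
  stopifnot(inherits(spec, "planted_spec"))
  bb <- spec$backbone
  jsonlite::write_json(list(
    blocks = lapply(spec$blocks, function(b)
      list(latent = b$latent, members = b$members,
           cardinality = b$cardinality, loading = b$loading,
           active_state = b$active_state)),
    backbone = if (!is.null(bb)) lapply(seq_len(nrow(bb)), function(i)
      list(parent = bb$parent[[i]], child = bb$child[[i]],
           coupling = bb$coupling[[i]])),
    hubs = spec$hubs, n_records = spec$n_records, seed = spec$seed,
    tags = spec$tags), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a planted specification from JSON
#'
#' @param path A file written by [write_planted_spec()].
#' @return A [planted_spec()].
#' @export
read_planted_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  blocks <- lapply(j$blocks, function(b)
    planted_block(b$latent, unlist(b$members), b$cardinality,
                  unlist(b$loading), unlist(b$active_state)))
  backbone <- NULL
  if (length(j$backbone)) {
    backbone <- data.frame(
      parent = vapply(j$backbone, `[[`, "", "parent"),
      child = vapply(j$backbone, `[[`, "", "child"))
    backbone$coupling <- lapply(j$backbone, function(e) {
      cp <- e$coupling
      if (is.list(cp)) do.call(rbind, lapply(cp, unlist)) else as.numeric(cp)
    })
  }
  hubs <- lapply(j$hubs, function(h)
    list(name = h$name, cardinality = h$cardinality,
         marginal = unlist(h$marginal)))
  tags <- lapply(j$tags, function(tt) unlist(tt))
  planted_spec(blocks, backbone = backbone,
               hubs = if (length(hubs)) hubs,
               n_records = j$n_records, seed = j$seed,
               tags = if (length(tags)) tags)
}
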