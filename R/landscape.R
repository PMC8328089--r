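# Attractor landscape: random-restart discovery, functional classification
# of attractors by progesterone response, basin assignment.
#
# An attractor's identity under fixed dynamics (model + clamps) is the
# smallest packed state of its cycle: that state belongs to exactly one
# cycle, so the key is unique and reproducible across runs and platforms.

#' Default simulation protocol for the AR model
#'
#' Input-node settings representing capacitating medium: physiological
#' external calcium and bicarbonate present, no ionophore, progesterone per
#' protocol. Passed as a clamp set; inputs hold their value, so for input
#' nodes the clamp only fixes the sampled level.
#'
#' @param Pg progesterone input level (0 = absent, 1 = present).
#' @param ... further node levels overriding the defaults.
#' @return a [clamp_set()].
#' @export
ar_protocol <- function(Pg = 0, ...) {
  base <- list(Ca_o = 1L, HCO3_o = 1L, A23187 = 0L, Pg = as.integer(Pg))
  clamp_set(modifyList(base, list(...)), label = sprintf("Pg=%d", Pg))
}

# split a clamp set into input-node assignments (sampling-time fixes; inputs
# hold their value anyway) and dynamic clamps on non-input nodes
split_clamps <- function(model, clamps) {
  a <- clamps$assignments
  roles <- model$nodes$role[match(names(a), node_names(model))]
  list(inputs = a[roles == "input"],
       dynamic = clamp_set(as.list(a[roles != "input"]),
                           label = clamps$label))
}

fixed_levels_vector <- function(model, assignments) {
  fl <- rep(-1L, n_nodes(model))
  if (length(assignments))
    fl[match(names(assignments), node_names(model))] <-
      as.integer(assignments)
  fl
}

#' Discover the attractor landscape by random restart
#'
#' Draws uniform random valid states (nodes fixed by `clamps` are held at
#' their clamped level, including input-node protocol settings), runs each to
#' its attractor, canonicalizes and deduplicates. Stops once `n_confirm`
#' consecutive samples yield no new attractor; if `n_samples` is exhausted
#' first the landscape is returned flagged `converged = FALSE`, never
#' silently.
#'
#' @param model an `acrodyn_network`.
#' @param clamps a [clamp_set()]: input protocol plus any experimental
#'   clamps, e.g. `ar_protocol(Pg = 0)`.
#' @param n_samples maximum number of restart samples.
#' @param n_confirm consecutive non-novel samples required to declare
#'   convergence (default 1e5).
#' @param seed RNG seed; identical seeds yield identical landscapes.
#' @param max_steps trajectory step bound.
#' @param constraints named levels fixed in every sampled restart state.
#'   Defaults to the fusion-machinery-off restriction (`Fusion`, `Swell`,
#'   `SNARE` at 0, silently dropped for models lacking those nodes): because
#'   exocytosis is modeled as irreversible, states born fused are
#'   biologically unreasonable starting points and would flood the landscape
#'   with trivially fused attractors. Pass `NULL` for unrestricted sampling.
#' @return an `acrodyn_landscape`: attractor list (canonical cycles), keys,
#'   discovery log and convergence flag. Classes are filled by
#'   [classify_landscape()].
#' @export
discover_attractors <- function(model, clamps = NULL, n_samples = 1e6,
                                n_confirm = 1e5, seed = 1L,
                                max_steps = 10000L,
                                constraints = DEFAULT_CONSTRAINTS) {
  clamps <- check_clamps(model, clamps)
  model <- precompile(model)
  sp <- split_clamps(model, clamps)
  if (identical(constraints, DEFAULT_CONSTRAINTS))
    constraints <- constraints[names(constraints) %in% node_names(model)]
  fl <- fixed_levels_vector(model, c(constraints, clamps$assignments))
  cv <- clamp_vectors(model, sp$dynamic)
  set.seed(seed)
  res <- cpp_discover(compile_model(model), fl, cv$node, cv$lev,
                      n_samples, n_confirm, max_steps)
  attractors <- lapply(res$key, function(k)
    run_to_attractor(model, unpack_states(model, k)[1, ], sp$dynamic,
                     max_steps))
  names(attractors) <- format_key(res$key)
  structure(list(
    attractors = attractors,
    key = res$key,
    classes = setNames(rep(NA_character_, length(res$key)),
                       format_key(res$key)),
    class_log = NULL,
    context = clamps,
    discovery = list(n_drawn = res$n_drawn, first_seen = res$first_seen,
                     n_confirm = n_confirm, seed = seed,
                     constraints = constraints,
                     converged = res$converged),
    model_name = model$name), class = "acrodyn_landscape")
}

format_key <- function(key) sprintf("%.0f", key)

#' @export
print.acrodyn_landscape <- function(x, ...) {
  cat(sprintf("<acrodyn_landscape> %s [%s]: %d attractors (%s, %s samples)\n",
              x$model_name, x$context$label, length(x$attractors),
              if (x$discovery$converged) "converged" else "NOT converged",
              format(x$discovery$n_drawn, big.mark = ",")))
  if (!all(is.na(x$classes)))
    print(table(factor(x$classes,
                       c("Spontaneous", "Inducible", "Negative"))))
  invisible(x)
}

node_active <- function(model, states, node) {
  M <- model$nodes$max_level[match(node, node_names(model))]
  states[, node] > M / 2
}

#' Classify one attractor by its progesterone response
#'
#' Implements the three functional classes of progesterone-free attractors:
#' Spontaneous if any cycle state shows membrane fusion (`Fusion = 1`);
#' otherwise the progesterone input is switched on from every phase of the
#' cycle and the resulting target attractors inspected — Inducible if any
#' target reaches fusion, Negative if none does. Phase disagreement (only
#' some phases leading to fusion) is recorded, not hidden.
#'
#' @param model an `acrodyn_network`.
#' @param attractor result of [run_to_attractor()] (or a landscape entry)
#'   computed under `Pg = 0`.
#' @param clamps the dynamic (non-input) clamps the attractor was computed
#'   under; kept active during the progesterone switch.
#' @param pg_node,fusion_node node names of the progesterone input and the
#'   fusion reporter.
#' @param max_steps trajectory step bound.
#' @return a list: `class` (`"Spontaneous"`, `"Inducible"`, `"Negative"`),
#'   `phase_agreement` (FALSE if phases disagree about inducibility),
#'   `targets` (keys of target attractors after the switch, or NULL).
#' @export
classify_attractor <- function(model, attractor, clamps = NULL,
                               pg_node = "Pg", fusion_node = "Fusion",
                               max_steps = 10000L) {
  cyc <- attractor$cycle
  if (any(cyc[, pg_node] != 0))
    stop("attractor was computed under ", pg_node,
         " = 1; classification requires a progesterone-free attractor")
  if (any(node_active(model, cyc, fusion_node)))
    return(list(class = "Spontaneous", phase_agreement = TRUE,
                targets = NULL))
  clamps <- check_clamps(model, clamps)
  fused <- logical(nrow(cyc))
  targets <- numeric(nrow(cyc))
  for (i in seq_len(nrow(cyc))) {
    st <- cyc[i, ]
    st[pg_node] <- 1L
    tgt <- run_to_attractor(model, st, clamps, max_steps)
    fused[i] <- any(node_active(model, tgt$cycle, fusion_node))
    targets[i] <- tgt$key
  }
  list(class = if (any(fused)) "Inducible" else "Negative",
       phase_agreement = length(unique(fused)) == 1L,
       targets = targets)
}

#' Classify every attractor of a landscape
#'
#' @param model an `acrodyn_network`.
#' @param landscape an `acrodyn_landscape` discovered under `Pg = 0`.
#' @param ... passed to [classify_attractor()].
#' @return the landscape with `classes` filled and a `class_log` recording
#'   phase agreement and progesterone-switch targets per attractor.
#' @export
classify_landscape <- function(model, landscape, ...) {
  sp <- split_clamps(model, landscape$context)
  res <- lapply(landscape$attractors, function(a)
    classify_attractor(model, a, clamps = sp$dynamic, ...))
  landscape$classes <- setNames(vapply(res, `[[`, "", "class"),
                                names(landscape$attractors))
  landscape$class_log <- res
  landscape
}

#' Assign a state to its basin of attraction
#'
#' Runs the state to its attractor under the landscape's context and returns
#' the attractor key. If the attractor is not yet part of the landscape it
#' is added and the landscape's convergence flag cleared.
#'
#' @param model an `acrodyn_network`.
#' @param state an initial state.
#' @param landscape an `acrodyn_landscape`.
#' @param max_steps trajectory step bound.
#' @return a list: `key` (attractor key as character), `transient`, and the
#'   possibly extended `landscape`.
#' @export
assign_basin <- function(model, state, landscape, max_steps = 10000L) {
  sp <- split_clamps(model, landscape$context)
  res <- run_to_attractor(model, state, sp$dynamic, max_steps)
  kc <- format_key(res$key)
  if (!kc %in% names(landscape$attractors)) {
    landscape$attractors[[kc]] <- res
    landscape$key <- c(landscape$key, res$key)
    landscape$classes[kc] <- NA_character_
    landscape$discovery$converged <- FALSE
  }
  list(key = kc, transient = res$transient, landscape = landscape)
}

# batch: run many states to attractors, return factor of class per state;
# states whose attractor is unknown get NA unless extend = TRUE, in which
# case new attractors are classified on the fly and the landscape grows
basin_classes <- function(model, states, landscape, extend = TRUE,
                          max_steps = 10000L) {
  sp <- split_clamps(model, landscape$context)
  cv <- clamp_vectors(model, sp$dynamic)
  tr <- cpp_trajectories(compile_model(model), states, cv$node, cv$lev,
                         max_steps)
  kc <- format_key(tr$key)
  unknown <- setdiff(unique(kc), names(landscape$attractors))
  if (length(unknown) && extend) {
    for (k in unknown) {
      a <- run_to_attractor(model,
                            unpack_states(model, as.numeric(k))[1, ],
                            sp$dynamic, max_steps)
      landscape$attractors[[k]] <- a
      landscape$key <- c(landscape$key, a$key)
      cl <- classify_attractor(model, a, clamps = sp$dynamic,
                               max_steps = max_steps)
      landscape$classes[k] <- cl$class
      landscape$class_log[[k]] <- cl
      landscape$discovery$converged <- FALSE
    }
  }
  list(class = landscape$classes[kc], key = kc, landscape = landscape)
}

#' Summarize a landscape as a data frame
#'
#' One row per attractor: key, cycle length, functional class, phase
#' agreement of the classification.
#'
#' @param landscape a classified `acrodyn_landscape`.
#' @return a data.frame.
#' @export
landscape_summary <- function(landscape) {
  data.frame(
    key = names(landscape$attractors),
    length = vapply(landscape$attractors, `[[`, 0L, "length"),
    class = unname(landscape$classes[names(landscape$attractors)]),
    phase_agreement = vapply(seq_along(landscape$attractors), function(i) {
      lg <- landscape$class_log[[i]]
      if (is.null(lg)) NA else lg$phase_agreement
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a landscape report to JSON
#'
#' Machine-readable report: context, discovery log, and per attractor the
#' canonical cycle, length and class. Deterministic output (sorted keys).
#'
#' @param landscape a classified `acrodyn_landscape`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  ord <- order(landscape$key)
  out <- list(
    model = landscape$model_name,
    context = as.list(landscape$context$assignments),
    discovery = landscape$discovery[c("n_drawn", "n_confirm", "seed",
                                      "converged")],
    attractors = lapply(ord, function(i) {
      a <- landscape$attractors[[i]]
      list(key = names(landscape$attractors)[i], length = a$length,
           class = unname(landscape$classes[i]),
           cycle = unname(apply(a$cycle, 1, as.integer, simplify = FALSE)))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
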