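# Clamping experiments on the acrosomal-pH node, single-node transient
# state perturbations, and truth-table row perturbations.

#' Landscape under a global node clamp
#'
#' Rediscovers and reclassifies the attractor landscape with `node` held at
#' `level` during ALL dynamics — discovery and the progesterone switch used
#' for classification. Models a sustained pharmacological condition applied
#' to the entire state space (for the acrosomal pH node: acidic pH_a = 5.5
#' maps to level 0, alkaline pH_a = 6.7 to level 1).
#'
#' @param model an `acrodyn_network`.
#' @param node clamped node name.
#' @param level clamped level.
#' @param protocol input protocol, default [ar_protocol()] with `Pg = 0`.
#' @param n_samples,n_confirm,seed discovery parameters, see
#'   [discover_attractors()].
#' @return a list of class `acrodyn_clamp_experiment`: mode, clamp, the
#'   clamped classified landscape, attractor count and class distribution.
#' @export
clamp_global <- function(model, node, level, protocol = NULL,
                         n_samples = 1e6, n_confirm = 1e5, seed = 1L) {
  if (is.null(protocol)) protocol <- ar_protocol(Pg = 0)
  clamps <- clamp_set(modifyList(as.list(protocol$assignments),
                                 setNames(list(as.integer(level)), node)),
                      label = sprintf("%s|%s=%d", protocol$label, node,
                                      level))
  clamps <- check_clamps(model, clamps)
  ls <- discover_attractors(model, clamps, n_samples, n_confirm, seed)
  ls <- classify_landscape(model, ls)
  structure(list(mode = "global_state_space", node = node, level = level,
                 landscape = ls, n_attractors = length(ls$attractors),
                 class_distribution = table(factor(ls$classes,
                   c("Spontaneous", "Inducible", "Negative"))),
                 converged = ls$discovery$converged),
            class = "acrodyn_clamp_experiment")
}

#' @export
print.acrodyn_clamp_experiment <- function(x, ...) {
  cat(sprintf("<clamp experiment> %s, %s = %d: %d attractors\n", x$mode,
              x$node, x$level, x$n_attractors))
  print(x$class_distribution)
  invisible(x)
}

#' Clamp a node only on the attractor states
#'
#' The milder intervention: instead of constraining the whole state space,
#' `node` is set to `level` in the states of each already-reached attractor
#' (altering the condition once the cell has settled), and the dynamics run
#' on with the clamp held persistently from that point. Each source
#' attractor maps to a target attractor whose class is computed under the
#' clamp; the source attractor count is preserved as the unit of accounting.
#'
#' @param model an `acrodyn_network`.
#' @param landscape the classified unclamped `Pg = 0` landscape.
#' @param node clamped node name.
#' @param level clamped level.
#' @param one_shot if TRUE the node is edited once and the dynamics relax
#'   freely (sensitivity variant); default FALSE holds the clamp.
#' @return an `acrodyn_clamp_experiment` with a per-source fate table.
#' @export
clamp_attractor_states <- function(model, landscape, node, level,
                                   one_shot = FALSE) {
  if (any(is.na(landscape$classes)))
    stop("landscape must be classified first")
  sp <- split_clamps(model, landscape$context)
  hold <- if (one_shot) sp$dynamic else
    clamp_set(modifyList(as.list(sp$dynamic$assignments),
                         setNames(list(as.integer(level)), node)),
              label = sprintf("%s=%d", node, level))
  hold <- check_clamps(model, hold)
  fate <- lapply(names(landscape$attractors), function(k) {
    a <- landscape$attractors[[k]]
    # representative phase: canonical first state; all phases logged
    per_phase <- lapply(seq_len(a$length), function(i) {
      st <- a$cycle[i, ]
      st[node] <- as.integer(level)
      tgt <- run_to_attractor(model, st, hold)
      cls <- classify_attractor(model, tgt, clamps = hold)
      list(target = format_key(tgt$key), class = cls$class)
    })
    cls <- vapply(per_phase, `[[`, "", "class")
    list(source = k, source_class = unname(landscape$classes[k]),
         target = per_phase[[1]]$target, class = cls[1],
         phase_classes = cls)
  })
  cls <- vapply(fate, `[[`, "", "class")
  structure(list(mode = "attractor_states_only", node = node, level = level,
                 one_shot = one_shot, fate = fate,
                 n_attractors = length(fate),
                 source_distribution = table(factor(landscape$classes,
                   c("Spontaneous", "Inducible", "Negative"))),
                 class_distribution = table(factor(cls,
                   c("Spontaneous", "Inducible", "Negative"))),
                 converged = TRUE),
            class = "acrodyn_clamp_experiment")
}

#' Single-node transient perturbation screen (one cell)
#'
#' Samples `n` random states from the basins of attraction of the given
#' source class, applies a one-time edit of a single node (binary nodes are
#' inverted; multi-level nodes get a uniformly drawn DIFFERENT level), runs
#' the free dynamics to the resulting attractor and classifies it. The
#' truth tables are never modified and no clamp is applied. For Spontaneous
#' sources the candidate states are restricted to those with the fusion
#' machinery off (`Swell`, `SNARE`, `SYT`, `Fusion` all 0), since membrane
#' fusion is irreversible.
#'
#' @param model an `acrodyn_network`.
#' @param landscape classified `Pg = 0` landscape.
#' @param source_class `"Spontaneous"`, `"Inducible"` or `"Negative"`.
#' @param node node to perturb.
#' @param n number of sampled basin states.
#' @param seed RNG seed.
#' @return a list: `changed` (fraction of perturbations that changed the
#'   functional class), `destination` (named fractions by destination
#'   class, summing to `changed`), `n`, `seed`.
#' @export
perturb_states <- function(model, landscape, source_class, node, n = 1e4,
                           seed = 1L) {
  states <- sample_basin_states(model, landscape, source_class, n, seed)
  perturbed <- apply_perturbation(model, states, node,
                                  seed = seed + 1L)
  bc <- basin_classes(model, perturbed, landscape)
  dest <- factor(bc$class, c("Spontaneous", "Inducible", "Negative"))
  changed <- dest != source_class
  breakdown <- c(table(dest[changed]) / length(dest))
  list(source_class = source_class, node = node,
       changed = mean(changed),
       destination = breakdown[names(breakdown) != source_class],
       n = n, seed = seed)
}

# rejection-sample n states lying in basins of the given class
sample_basin_states <- function(model, landscape, source_class, n, seed,
                                max_tries = 2000) {
  constraints <- if (source_class == "Spontaneous")
    c(Swell = 0L, SNARE = 0L, SYT = 0L, Fusion = 0L) else integer(0)
  constraints <- constraints[names(constraints) %in% node_names(model)]
  fixed <- gather_fixed(model, constraints,
                        landscape$context$assignments)
  fl <- fixed_levels_vector(model, fixed)
  model <- precompile(model)
  set.seed(seed)
  out <- NULL; drawn <- 0; batch <- max(1000, 2 * n)
  while (is.null(out) || nrow(out) < n) {
    if (drawn > max_tries * n)
      stop("no eligible states found in basins of class ", source_class)
    states <- cpp_sample_states(compile_model(model), fl, batch)
    colnames(states) <- node_names(model)
    drawn <- drawn + batch
    bc <- basin_classes(model, states, landscape)
    landscape <- bc$landscape
    hit <- which(!is.na(bc$class) & bc$class == source_class)
    if (length(hit))
      out <- rbind(out, states[hit, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# one-node transient edit: invert binary nodes, redraw multi-level nodes
# uniformly among the OTHER levels (never a no-op)
apply_perturbation <- function(model, states, node, seed = 1L) {
  j <- match(node, node_names(model))
  if (is.na(j)) stop("unknown node ", node)
  M <- model$nodes$max_level[j]
  cur <- states[, j]
  if (M == 1L) {
    states[, j] <- 1L - cur
  } else {
    set.seed(seed)
    shift <- sample.int(M, nrow(states), replace = TRUE) # 1..M
    states[, j] <- (cur + shift) %% (M + 1L)
  }
  states
}

#' Full transient-perturbation matrix
#'
#' Runs [perturb_states()] for every (source class, node) combination and
#' returns the tidy matrix behind the sensitivity ranking: which nodes,
#' when transiently flipped, most often push a cell into a different
#' functional class.
#'
#' @param model an `acrodyn_network`.
#' @param landscape classified `Pg = 0` landscape.
#' @param nodes nodes to perturb (default: all non-input nodes).
#' @param classes source classes to cover.
#' @param n states per cell.
#' @param seed RNG seed.
#' @return data.frame: source_class, node, changed fraction, destination
#'   fractions (`to_Spontaneous`, `to_Inducible`, `to_Negative`), n, seed.
#' @export
perturbation_matrix <- function(model, landscape,
                                nodes = NULL,
                                classes = c("Spontaneous", "Inducible",
                                            "Negative"),
                                n = 1e4, seed = 1L) {
  if (is.null(nodes))
    nodes <- node_names(model)[model$nodes$role != "input"]
  classes <- intersect(classes, unique(stats::na.omit(landscape$classes)))
  rows <- list()
  for (cls in classes) {
    # share one basin sample per class across all perturbed nodes
    states <- sample_basin_states(model, landscape, cls, n, seed)
    for (nd in nodes) {
      perturbed <- apply_perturbation(model, states, nd, seed = seed + 1L)
      bc <- basin_classes(model, perturbed, landscape)
      dest <- factor(bc$class, c("Spontaneous", "Inducible", "Negative"))
      changed <- dest != cls
      frac <- function(to) mean(dest == to & changed)
      rows[[length(rows) + 1L]] <- data.frame(
        source_class = cls, node = nd, changed = mean(changed),
        to_Spontaneous = frac("Spontaneous"),
        to_Inducible = frac("Inducible"),
        to_Negative = frac("Negative"), n = n, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Perturb one truth-table row
#'
#' Builds a modified model in which a single row of `node`'s truth table is
#' changed to `new_output`, re-runs the fates of a baseline ensemble under
#' the modified regulatory logic, and reports the shift in the functional
#' class proportions. The original model is untouched.
#'
#' @param model an `acrodyn_network`.
#' @param node target node whose function is edited.
#' @param row 1-based row index into the node's truth table (rows ordered
#'   with the first regulator most significant; see [function_rows()]).
#' @param new_output replacement output level (must differ from the current
#'   one and lie in the node's range).
#' @param baseline_sample an `acrodyn_population` whose fates are compared.
#' @param landscape classified landscape of the unmodified model, used for
#'   the baseline proportions.
#' @return a list: `before` and `after` named class-proportion vectors,
#'   `delta`, and the modified model in `model`.
#' @export
perturb_truth_table_row <- function(model, node, row, new_output,
                                    baseline_sample, landscape) {
  f <- model$functions[[node]]
  if (is.null(f)) stop("node ", node, " has no regulatory function")
  if (row < 1 || row > length(f$table)) stop("row index out of range")
  M <- model$nodes$max_level[match(node, node_names(model))]
  if (new_output < 0 || new_output > M)
    stop("output level out of range for ", node)
  if (new_output == f$table[row])
    stop("new_output equals the current output; not a perturbation")
  modified <- model
  modified$functions[[node]]$table[row] <- as.integer(new_output)
  modified$functions[[node]]$rule <- NULL # rule no longer describes table
  modified$edges <- derive_edges(modified)
  attr(modified, "compiled") <- NULL
  modified <- precompile(modified)

  before <- class_proportions(model, landscape, baseline_sample)
  ls2 <- discover_from_sample(modified, landscape$context,
                              baseline_sample$states)
  after <- class_proportions(modified, ls2, baseline_sample)
  list(node = node, row = row, new_output = new_output,
       before = before, after = after, delta = after - before,
       model = modified)
}

# class proportions of an ensemble's fates under a model/landscape
class_proportions <- function(model, landscape, sample) {
  bc <- basin_classes(model, sample$states, landscape)
  pr <- prop.table(table(factor(bc$class, c("Spontaneous", "Inducible",
                                            "Negative"))))
  c(pr)
}

# minimal landscape seeded from an ensemble (used for modified models where
# the attractor registry must be rebuilt)
discover_from_sample <- function(model, context, states) {
  ls <- structure(list(attractors = list(), key = numeric(0),
                       classes = character(0), class_log = list(),
                       context = context,
                       discovery = list(n_drawn = 0, first_seen = numeric(0),
                                        n_confirm = 0, seed = NA,
                                        converged = FALSE),
                       model_name = model$name),
                  class = "acrodyn_landscape")
  basin_classes(model, states, ls)$landscape
}

#' Enumerate the rows of a node's truth table
#'
#' Returns the regulator tuples in table-row order, with the current output
#' level — the addressing used by [perturb_truth_table_row()].
#'
#' @param model an `acrodyn_network`.
#' @param node node name.
#' @return data.frame of regulator levels plus `output`.
#' @export
function_rows <- function(model, node) {
  f <- model$functions[[node]]
  if (is.null(f)) stop("node ", node, " has no regulatory function")
  lev <- node_levels(model)[f$regulators]
  rows <- as.data.frame(enumerate_rows(lev))
  rows$output <- f$table
  rows
}
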