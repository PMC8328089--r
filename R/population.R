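# Initial-state ensembles representing physiological heterogeneity, and the
# per-node activation statistics computed on them.
#
# Activation of a node x with maximum level M is defined as x > M/2: for
# binary nodes that is x = 1; for the four multi-level nodes it selects
# Em in {2,3}, CatSper = 2, Ca_i = 2, pH_i = 2.

DEFAULT_CONSTRAINTS <- c(Fusion = 0L, Swell = 0L, SNARE = 0L)

#' Sample uniform random initial states under constraints
#'
#' Each unconstrained node level is drawn independently and uniformly over
#' its range; constrained nodes (by default the fusion-machinery reporters
#' `Fusion`, `Swell`, `SNARE`, all 0: states that have already fused are
#' biologically unreasonable starting points) and protocol inputs are fixed.
#'
#' @param model an `acrodyn_network`.
#' @param n number of states.
#' @param constraints named levels fixed in every state.
#' @param inputs protocol input settings (a [clamp_set()] or named levels),
#'   default [ar_protocol()] values when the nodes exist, else none.
#' @param seed RNG seed.
#' @return an `acrodyn_population`: `states` matrix plus bookkeeping.
#' @export
sample_uniform_constrained <- function(model, n,
                                       constraints = DEFAULT_CONSTRAINTS,
                                       inputs = NULL, seed = 1L) {
  stopifnot(n >= 1)
  if (missing(constraints)) # defaults only bind where the nodes exist
    constraints <- constraints[names(constraints) %in% node_names(model)]
  fixed <- gather_fixed(model, constraints, inputs)
  set.seed(seed)
  states <- cpp_sample_states(compile_model(model),
                              fixed_levels_vector(model, fixed), n)
  colnames(states) <- node_names(model)
  structure(list(states = states, strata = NULL, constraints = fixed,
                 seed = seed, n = n, weights = NULL),
            class = "acrodyn_population")
}

gather_fixed <- function(model, constraints, inputs) {
  if (inherits(inputs, "acrodyn_clamps")) inputs <- inputs$assignments
  if (is.null(inputs)) {
    proto <- c(Ca_o = 1L, HCO3_o = 1L, A23187 = 0L, Pg = 0L)
    inputs <- proto[names(proto) %in% node_names(model)]
  }
  fixed <- c(as.integer(constraints), as.integer(inputs))
  names(fixed) <- c(names(constraints), names(inputs))
  if (anyDuplicated(names(fixed))) {
    dup <- names(fixed)[duplicated(names(fixed))]
    vals <- split(unname(fixed), names(fixed))
    bad <- vapply(vals, function(v) length(unique(v)) > 1L, logical(1))
    if (any(bad)) stop("contradictory constraints on node ",
                       names(vals)[bad][1])
    fixed <- fixed[!duplicated(names(fixed))]
  }
  unknown <- setdiff(names(fixed), node_names(model))
  if (length(unknown)) stop("constraint on unknown node ", unknown[1])
  fixed
}

#' @export
print.acrodyn_population <- function(x, ...) {
  cat(sprintf("<acrodyn_population> %d states, %d fixed nodes (%s)\n",
              nrow(x$states), length(x$constraints),
              paste(names(x$constraints), x$constraints, sep = "=",
                    collapse = ", ")))
  if (!is.null(x$strata)) print(table(x$strata))
  invisible(x)
}

#' Stratified initial-state ensemble at observed AR proportions
#'
#' Rejection-samples constrained uniform states, assigns each to the
#' functional class of its basin of attraction, and accepts states so that
#' the realized class proportions match the normalized `class_weights` —
#' the selection cancels any effect of the relative basin sizes. The
#' physiologically observed proportions are 15% spontaneous, 30%
#' progesterone-inducible and 65% unreactive; since these sum to 110%, the
#' default normalizes them to fractions (0.136/0.273/0.591); mode
#' `"rescale_negative"` instead keeps 15/30 and lowers the negative share
#' to 55 so the stated spontaneous/inducible percentages are exact.
#'
#' @param model an `acrodyn_network`.
#' @param landscape a classified `acrodyn_landscape` (context defines the
#'   dynamics used for basin assignment).
#' @param n ensemble size.
#' @param class_weights positive weights named Spontaneous / Inducible /
#'   Negative.
#' @param mode weight normalization mode (see above).
#' @param constraints named levels fixed in every state.
#' @param seed RNG seed.
#' @param max_tries sampling-budget multiplier before giving up.
#' @return an `acrodyn_population` with `strata` (class factor per state)
#'   and the realized acceptance probabilities in `acceptance`.
#' @export
sample_stratified <- function(model, landscape, n,
                              class_weights = c(Spontaneous = 15,
                                                Inducible = 30,
                                                Negative = 65),
                              mode = c("normalize", "rescale_negative"),
                              constraints = DEFAULT_CONSTRAINTS,
                              seed = 1L, max_tries = 500) {
  mode <- match.arg(mode)
  if (missing(constraints))
    constraints <- constraints[names(constraints) %in% node_names(model)]
  if (any(class_weights < 0)) stop("class weights must be non-negative")
  if (mode == "rescale_negative" &&
      setequal(names(class_weights), c("Spontaneous", "Inducible",
                                       "Negative")))
    class_weights["Negative"] <-
      100 - sum(class_weights[c("Spontaneous", "Inducible")])
  w <- class_weights / sum(class_weights)
  quota <- diff(round(cumsum(c(0, w * n))))
  names(quota) <- names(w)
  fixed <- gather_fixed(model, constraints,
                        landscape$context$assignments)
  fl <- fixed_levels_vector(model, fixed)
  model <- precompile(model)
  set.seed(seed)
  taken <- lapply(quota, function(q) vector("list", 0))
  got <- setNames(numeric(length(quota)), names(quota))
  drawn <- 0; batch <- max(1000, 2 * n)
  while (any(got < quota)) {
    if (drawn > max_tries * n)
      stop("stratified sampling budget exhausted; empty or tiny basin for ",
           paste(names(quota)[got < quota], collapse = ", "))
    states <- cpp_sample_states(compile_model(model), fl, batch)
    colnames(states) <- node_names(model)
    drawn <- drawn + batch
    bc <- basin_classes(model, states, landscape)
    landscape <- bc$landscape
    for (cls in names(quota)) {
      need <- quota[cls] - got[cls]
      if (need <= 0) next
      idx <- which(!is.na(bc$class) & bc$class == cls)
      if (!length(idx)) next
      take <- idx[seq_len(min(need, length(idx)))]
      taken[[cls]] <- c(taken[[cls]], list(states[take, , drop = FALSE]))
      got[cls] <- got[cls] + length(take)
    }
    # classes absent from the discovered landscape can never fill a quota
    absent <- setdiff(names(quota)[quota > 0], unique(landscape$classes))
    if (length(absent) && drawn >= 10 * batch)
      stop("no discovered basin for requested class ",
           paste(absent, collapse = ", "))
  }
  states <- do.call(rbind, unlist(taken, recursive = FALSE))
  strata <- factor(rep(names(quota), times = got),
                   levels = c("Spontaneous", "Inducible", "Negative"))
  ord <- sample.int(nrow(states)) # shuffle so strata are interleaved
  structure(list(states = states[ord, , drop = FALSE],
                 strata = strata[ord], constraints = fixed, seed = seed,
                 n = n, weights = w, mode = mode,
                 acceptance = sum(quota) / drawn,
                 landscape = landscape),
            class = "acrodyn_population")
}

#' Per-node activation statistics of a state ensemble
#'
#' Activation probability P(x) = P(x > M_x/2) per node with its binomial
#' standard error, plus the full level distribution for multi-level nodes.
#'
#' @param model an `acrodyn_network`.
#' @param sample an `acrodyn_population` or a plain state matrix.
#' @param include_inputs include input nodes (external medium components)?
#' @return a list: `stats` data.frame (node, P, SE, n) and `levels`
#'   data.frame (node, level, P) for nodes with more than two levels.
#' @export
activation_stats <- function(model, sample, include_inputs = FALSE) {
  states <- if (inherits(sample, "acrodyn_population")) sample$states
            else sample
  if (is.null(dim(states)) || nrow(states) == 0)
    stop("empty sample")
  nd <- model$nodes
  keep <- if (include_inputs) seq_len(nrow(nd)) else which(nd$role != "input")
  n <- nrow(states)
  P <- vapply(keep, function(i) mean(states[, i] > nd$max_level[i] / 2),
              numeric(1))
  stats <- data.frame(node = nd$name[keep], P = P,
                      SE = sqrt(P * (1 - P) / n), n = n,
                      stringsAsFactors = FALSE)
  multi <- keep[nd$max_level[keep] > 1L]
  levels <- do.call(rbind, lapply(multi, function(i) {
    lv <- 0:nd$max_level[i]
    data.frame(node = nd$name[i], level = lv,
               P = vapply(lv, function(v) mean(states[, i] == v),
                          numeric(1)),
               stringsAsFactors = FALSE)
  }))
  list(stats = stats, levels = levels, n = n)
}

#' Activation statistics per functional class
#'
#' Computes [activation_stats()] separately for the Spontaneous, Inducible
#' and Negative classes, either over sampled basin states (`scope =
#' "basin_states"`, requires a stratified sample) or over the states
#' composing the attractors themselves (`scope = "attractor_states"`).
#'
#' @param model an `acrodyn_network`.
#' @param landscape a classified `acrodyn_landscape`.
#' @param sample an `acrodyn_population` with strata; only used for
#'   `basin_states`.
#' @param scope which states to aggregate.
#' @param include_inputs include input nodes?
#' @return named list of [activation_stats()] results, one per non-empty
#'   class; empty classes are flagged with `NULL`.
#' @export
per_class_stats <- function(model, landscape, sample = NULL,
                            scope = c("basin_states", "attractor_states"),
                            include_inputs = FALSE) {
  scope <- match.arg(scope)
  classes <- c("Spontaneous", "Inducible", "Negative")
  out <- setNames(vector("list", length(classes)), classes)
  if (scope == "basin_states") {
    if (is.null(sample$strata))
      stop("basin_states scope needs a stratified sample")
    for (cls in classes) {
      sel <- sample$strata == cls
      if (any(sel))
        out[[cls]] <- activation_stats(model,
                                       sample$states[sel, , drop = FALSE],
                                       include_inputs)
    }
  } else {
    for (cls in classes) {
      keys <- names(landscape$classes)[!is.na(landscape$classes) &
                                         landscape$classes == cls]
      if (!length(keys)) next
      states <- do.call(rbind, lapply(landscape$attractors[keys],
                                      `[[`, "cycle"))
      out[[cls]] <- activation_stats(model, states, include_inputs)
    }
  }
  out
}

#' Tidy per-class activation table
#'
#' Flattens [per_class_stats()] into one tidy data.frame (node, class,
#' scope, P, SE, n) suitable for CSV export and bar-chart regeneration.
#'
#' @inheritParams per_class_stats
#' @return a data.frame.
#' @export
class_stats_table <- function(model, landscape, sample = NULL,
                              scope = "basin_states",
                              include_inputs = FALSE) {
  res <- per_class_stats(model, landscape, sample, scope, include_inputs)
  do.call(rbind, lapply(names(res), function(cls) {
    if (is.null(res[[cls]])) return(NULL)
    cbind(res[[cls]]$stats, class = cls, scope = scope)
  }))
}
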