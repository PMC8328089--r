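# Core types: multi-valued logical network, states, clamps.
#
# A network is a list with
#   nodes:     data.frame(name, max_level, compartment, role)
#   labels:    named list of level-label character vectors (length max_level+1)
#   functions: named list, one entry per non-input node:
#              list(regulators = character(), table = integer(), rule = NULL)
#              table rows are ordered with the FIRST regulator as the most
#              significant mixed-radix digit.
#   edges:     data.frame(from, to, sign) with sign in
#              c("positive", "negative", "dual")
#   name, metadata: free-form provenance.
# States are integer vectors (or row-matrices) in declared node order.

VALID_COMPARTMENTS <- c("i", "a", "o", "f", "ns", "none")
VALID_ROLES <- c("input", "internal", "reporter")
VALID_SIGNS <- c("positive", "negative", "dual")

#' Construct a multi-valued logical network
#'
#' Builds and validates a synchronous, deterministic multi-valued logical
#' network. Every non-input node carries a complete truth table over its
#' regulators; input nodes have no function and hold their value under the
#' dynamics.
#'
#' @param nodes data.frame with columns `name`, `max_level` and optionally
#'   `compartment` (one of `"i"`, `"a"`, `"o"`, `"f"`, `"ns"`, `"none"`) and
#'   `role` (`"input"`, `"internal"`, `"reporter"`).
#' @param functions named list (one entry per non-input node) of
#'   `list(regulators = <character>, table = <integer>)`. The table must have
#'   one entry per regulator-level combination; rows are ordered with the
#'   first regulator as the most significant mixed-radix digit.
#' @param edges optional data.frame `from`, `to`, `sign`. When omitted, the
#'   edge list is derived from the regulator lists with signs inferred from
#'   table monotonicity.
#' @param labels optional named list of level-label character vectors.
#' @param name,metadata free-form provenance strings.
#' @return an object of class `acrodyn_network`.
#' @examples
#' toy <- logical_network(
#'   nodes = data.frame(name = c("A", "B"), max_level = c(1L, 1L)),
#'   functions = list(
#'     A = list(regulators = "B", table = c(1L, 0L)),  # A <- NOT B
#'     B = list(regulators = "A", table = c(0L, 1L))   # B <- A
#'   )
#' )
#' run_to_attractor(toy, c(A = 0L, B = 0L))$length  # the 4-cycle
#' @export
logical_network <- function(nodes, functions, edges = NULL, labels = NULL,
                            name = "network", metadata = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$compartment)) nodes$compartment <- "none"
  if (is.null(nodes$role)) nodes$role <- "internal"
  nodes$max_level <- as.integer(nodes$max_level)
  model <- structure(
    list(nodes = nodes, labels = labels, functions = functions,
         edges = NULL, name = name, metadata = metadata),
    class = "acrodyn_network")
  model$edges <- if (is.null(edges)) derive_edges(model) else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges
  }
  validate_network(model)
}

node_names <- function(model) model$nodes$name
n_nodes <- function(model) nrow(model$nodes)
node_levels <- function(model) setNames(model$nodes$max_level + 1L,
                                        model$nodes$name)

#' @export
print.acrodyn_network <- function(x, ...) {
  cat(sprintf("<acrodyn_network> %s: %d nodes, %d edges\n", x$name,
              nrow(x$nodes), nrow(x$edges)))
  ml <- x$nodes$max_level
  cat(sprintf("  inputs: %s\n",
              paste(x$nodes$name[x$nodes$role == "input"], collapse = ", ")))
  cat(sprintf("  multi-level: %s\n",
              paste(sprintf("%s (0..%d)", x$nodes$name[ml > 1], ml[ml > 1]),
                    collapse = ", ")))
  cat(sprintf("  state space: %.4g states\n", prod(as.numeric(ml + 1))))
  invisible(x)
}

#' Validate a logical network
#'
#' Checks the structural invariants: unique node names, level ranges,
#' complete duplicate-free truth tables with in-range outputs, one function
#' per non-input node and none for inputs, and regulator/edge-list
#' consistency. Hard failures stop with the offending node named.
#'
#' @param model an `acrodyn_network`.
#' @return the model, invisibly, on success.
#' @export
validate_network <- function(model) {
  nd <- model$nodes
  if (anyDuplicated(nd$name))
    stop("duplicate node name: ", nd$name[duplicated(nd$name)][1])
  if (any(nd$max_level < 1L))
    stop("max_level must be >= 1 for node ",
         nd$name[which(nd$max_level < 1L)[1]])
  if (!all(nd$compartment %in% VALID_COMPARTMENTS))
    stop("invalid compartment for node ",
         nd$name[which(!nd$compartment %in% VALID_COMPARTMENTS)[1]])
  if (!all(nd$role %in% VALID_ROLES))
    stop("invalid role for node ", nd$name[which(!nd$role %in% VALID_ROLES)[1]])
  if (!is.null(model$labels)) {
    for (nm in names(model$labels)) {
      ml <- nd$max_level[match(nm, nd$name)]
      if (is.na(ml)) stop("level labels for unknown node ", nm)
      if (length(model$labels[[nm]]) != ml + 1L)
        stop("node ", nm, " needs ", ml + 1L, " level labels")
    }
  }
  internal <- nd$name[nd$role != "input"]
  missing_fun <- setdiff(internal, names(model$functions))
  if (length(missing_fun))
    stop("non-input node without regulatory function: ", missing_fun[1])
  extra_fun <- setdiff(names(model$functions), internal)
  if (length(extra_fun))
    stop("function given for input or unknown node: ", extra_fun[1])
  lev <- node_levels(model)
  for (nm in names(model$functions)) {
    f <- model$functions[[nm]]
    if (anyDuplicated(f$regulators))
      stop("duplicate regulator in function of ", nm)
    unknown <- setdiff(f$regulators, nd$name)
    if (length(unknown))
      stop("unknown regulator '", unknown[1], "' in function of ", nm)
    n_rows <- prod(lev[f$regulators])
    if (length(f$table) != n_rows)
      stop("incomplete truth table for ", nm, ": ", length(f$table),
           " rows, expected ", n_rows)
    if (any(f$table < 0L | f$table > nd$max_level[match(nm, nd$name)]))
      stop("out-of-range output level in truth table of ", nm)
  }
  ed <- model$edges
  if (!all(ed$sign %in% VALID_SIGNS))
    stop("invalid edge sign: ", ed$sign[which(!ed$sign %in% VALID_SIGNS)[1]])
  declared <- if (nrow(ed)) paste(ed$from, ed$to) else character(0)
  derived <- unlist(lapply(names(model$functions), function(nm) {
    regs <- model$functions[[nm]]$regulators
    if (length(regs)) paste(regs, nm) else character(0)
  }))
  if (is.null(derived)) derived <- character(0)
  if (!setequal(declared, derived) || anyDuplicated(declared))
    stop("edge list and regulator lists are inconsistent (",
         length(declared), " edges declared, ", length(unique(derived)),
         " regulator pairs derived)")
  invisible(model)
}

# edge list derived from the regulator lists; sign from table monotonicity
derive_edges <- function(model) {
  rows <- lapply(names(model$functions), function(nm) {
    f <- model$functions[[nm]]
    if (!length(f$regulators)) return(NULL)
    sg <- vapply(f$regulators, function(r)
      table_monotonicity(model, nm, r), character(1))
    sg[sg == "constant"] <- "positive" # inert regulator: any sign is consistent
    data.frame(from = f$regulators, to = nm, sign = sg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      sign = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# direction of a table in one regulator with the others held fixed:
# "positive" (non-decreasing), "negative" (non-increasing), "dual" (neither)
table_monotonicity <- function(model, target, regulator) {
  f <- model$functions[[target]]
  lev <- node_levels(model)[f$regulators]
  j <- match(regulator, f$regulators)
  rows <- enumerate_rows(lev)
  up <- down <- FALSE
  for (v in seq_len(lev[j] - 1L)) {
    sel <- rows[, j] == v - 1L
    lo <- f$table[row_index(lev, rows[sel, , drop = FALSE])]
    hi_rows <- rows[sel, , drop = FALSE]
    hi_rows[, j] <- v
    hi <- f$table[row_index(lev, hi_rows)]
    if (any(hi > lo)) up <- TRUE
    if (any(hi < lo)) down <- TRUE
  }
  if (up && down) "dual" else if (down) "negative"
  else if (up) "positive" else "constant"
}

# all regulator tuples in table-row order (first regulator most significant)
enumerate_rows <- function(lev) {
  k <- length(lev)
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  # expand.grid varies its first factor fastest; the table wants the LAST
  # regulator fastest, so feed reversed levels and reverse columns back
  grids <- lapply(rev(lev), function(L) 0:(L - 1L))
  rows <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  rows <- rows[, rev(seq_len(k)), drop = FALSE]
  colnames(rows) <- names(lev)
  storage.mode(rows) <- "integer"
  rows
}

# 1-based row index of regulator tuples (matrix, columns in regulator order)
row_index <- function(lev, tuples) {
  if (!is.matrix(tuples)) tuples <- matrix(tuples, nrow = 1L)
  idx <- rep(0, nrow(tuples))
  for (j in seq_along(lev)) idx <- idx * lev[j] + tuples[, j]
  as.integer(idx + 1L)
}

#' Evaluate one regulatory function
#'
#' Looks up the output level of a node's truth table for the regulator
#' levels in `state`. Pure and deterministic.
#'
#' @param model an `acrodyn_network`.
#' @param target name of the regulated node.
#' @param state full network state (integer vector in node order, or named).
#' @return the output level, an integer.
#' @export
evaluate_function <- function(model, target, state) {
  f <- model$functions[[target]]
  if (is.null(f)) stop("no regulatory function for node ", target)
  state <- as_state(model, state)
  lev <- node_levels(model)[f$regulators]
  tuple <- state[match(f$regulators, node_names(model))]
  f$table[row_index(lev, matrix(tuple, nrow = 1L))]
}

#' Define a clamp set (in-silico intervention)
#'
#' A clamp holds nodes at fixed levels during every update, representing a
#' pharmacological block or constitutive activation. Input-node settings are
#' expressed the same way; inputs hold their value anyway, so clamping them
#' simply fixes the protocol.
#'
#' @param ... named levels, e.g. `clamp_set(pH_a = 1)`, or a single named
#'   vector/list.
#' @param label optional condition label.
#' @return an object of class `acrodyn_clamps`.
#' @export
clamp_set <- function(..., label = NULL) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || length(dots[[1]]) > 1L || !is.null(names(dots[[1]]))))
    dots <- as.list(dots[[1]])
  if (length(dots) && is.null(names(dots)))
    stop("clamp levels must be named by node")
  lv <- vapply(dots, function(x) as.integer(x), integer(1))
  structure(list(assignments = lv,
                 label = if (is.null(label)) "" else label),
            class = "acrodyn_clamps")
}

empty_clamps <- function() clamp_set()

check_clamps <- function(model, clamps) {
  if (is.null(clamps)) clamps <- empty_clamps()
  if (!inherits(clamps, "acrodyn_clamps")) clamps <- clamp_set(clamps)
  a <- clamps$assignments
  if (!length(a)) return(clamps)
  unknown <- setdiff(names(a), node_names(model))
  if (length(unknown)) stop("clamp on unknown node ", unknown[1])
  ml <- model$nodes$max_level[match(names(a), node_names(model))]
  bad <- a < 0L | a > ml
  if (any(bad)) stop("clamp level out of range for node ", names(a)[bad][1])
  clamps
}

as_state <- function(model, state) {
  nm <- node_names(model)
  if (!is.null(names(state))) {
    missing <- setdiff(nm, names(state))
    if (length(missing)) stop("state is missing node ", missing[1])
    state <- state[nm]
  }
  if (length(state) != length(nm)) stop("state has wrong length")
  state <- as.integer(state)
  if (any(state < 0L | state > model$nodes$max_level))
    stop("state level out of range for node ",
         nm[which(state < 0L | state > model$nodes$max_level)[1]])
  setNames(state, nm)
}

# flat-array engine form, cached on the model environment-free via attribute
compile_model <- function(model) {
  cached <- attr(model, "compiled")
  if (!is.null(cached)) return(cached)
  nm <- node_names(model)
  is_input <- as.integer(model$nodes$role == "input")
  reg_idx <- integer(0); tab_val <- integer(0)
  reg_off <- integer(nrow(model$nodes) + 1L)
  tab_off <- integer(nrow(model$nodes) + 1L)
  for (i in seq_along(nm)) {
    reg_off[i] <- length(reg_idx)
    tab_off[i] <- length(tab_val)
    if (!is_input[i]) {
      f <- model$functions[[nm[i]]]
      reg_idx <- c(reg_idx, match(f$regulators, nm) - 1L)
      tab_val <- c(tab_val, as.integer(f$table))
    }
  }
  reg_off[length(reg_off)] <- length(reg_idx)
  tab_off[length(tab_off)] <- length(tab_val)
  list(n = length(nm), max_level = model$nodes$max_level,
       is_input = is_input, reg_off = reg_off, reg_idx = reg_idx,
       tab_off = tab_off, tab_val = tab_val)
}

#' Precompile a network for repeated simulation
#'
#' Attaches the flat-array engine form to the model so repeated calls skip
#' recompilation. Purely an optimization; all functions accept either form.
#'
#' @param model an `acrodyn_network`.
#' @return the model with a cached compiled form.
#' @export
precompile <- function(model) {
  attr(model, "compiled") <- compile_model(model)
  model
}

clamp_vectors <- function(model, clamps) {
  a <- clamps$assignments
  list(node = match(names(a), node_names(model)),
       lev = as.integer(unname(a)))
}

#' One synchronous update step
#'
#' All non-input, non-clamped nodes simultaneously take the value of their
#' regulatory function evaluated on the current state; input nodes hold
#' their value; clamped nodes take the clamped level.
#'
#' @param model an `acrodyn_network`.
#' @param state integer state vector (named or in node order).
#' @param clamps optional [clamp_set()].
#' @return the successor state, named integer vector.
#' @export
step <- function(model, state, clamps = NULL) {
  clamps <- check_clamps(model, clamps)
  state <- as_state(model, state)
  cm <- compile_model(model)
  cv <- clamp_vectors(model, clamps)
  setNames(cpp_step(cm, state, cv$node, cv$lev), node_names(model))
}

#' Run a trajectory to its attractor
#'
#' Iterates the synchronous update from `state` until a state repeats,
#' recording every visited state; the first revisited state marks the cycle
#' entry, so the transient length falls out of the visited record. The cycle
#' is returned in canonical rotation (smallest packed state first).
#'
#' @param model an `acrodyn_network`.
#' @param state initial state.
#' @param clamps optional [clamp_set()] held during the whole run.
#' @param max_steps abort (with an error) if no state repeats within this
#'   many steps; finite deterministic systems must cycle, so exceeding a
#'   generous bound signals a bug. Default 10000.
#' @return a list with `transient` (steps before entering the cycle),
#'   `length`, `key` (packed canonical first state, the attractor identity
#'   under these dynamics) and `cycle` (matrix, one row per state).
#' @export
run_to_attractor <- function(model, state, clamps = NULL, max_steps = 10000L) {
  clamps <- check_clamps(model, clamps)
  state <- as_state(model, state)
  cm <- compile_model(model)
  cv <- clamp_vectors(model, clamps)
  res <- cpp_run_to_attractor(cm, state, cv$node, cv$lev, max_steps)
  colnames(res$cycle) <- node_names(model)
  res$context <- clamps$label
  res
}

#' Canonicalize a cycle
#'
#' Rotates a closed simple cycle of states so that it begins at the state
#' with the smallest packed (mixed-radix) index. Two discoveries of the same
#' cycle entered at different phases canonicalize identically.
#'
#' @param model an `acrodyn_network`.
#' @param cycle matrix of states, one row per state, in dynamical order.
#' @param clamps clamps under which the cycle must be closed.
#' @return the rotated cycle matrix with attribute `key`.
#' @export
canonicalize <- function(model, cycle, clamps = NULL) {
  if (!is.matrix(cycle)) cycle <- matrix(cycle, nrow = 1L)
  cm <- compile_model(model)
  keys <- cpp_pack(cm, cycle)
  if (anyDuplicated(keys)) stop("cycle is not simple: repeated state")
  n <- nrow(cycle)
  nxt <- rbind(cycle[-1, , drop = FALSE], cycle[1, , drop = FALSE])
  for (i in seq_len(n)) {
    succ <- step(model, cycle[i, ], clamps)
    if (!all(succ == nxt[i, ])) stop("cycle is not closed under step()")
  }
  rot <- which.min(keys)
  out <- cycle[c(seq(rot, n), if (rot > 1) seq_len(rot - 1L)), , drop = FALSE]
  colnames(out) <- node_names(model)
  attr(out, "key") <- min(keys)
  out
}

#' Pack and unpack states
#'
#' Bijection between valid level vectors and `[0, prod(max_level + 1))`
#' via mixed-radix encoding, first declared node most significant. Packed
#' keys are exact doubles (state spaces are validated below 2^53).
#'
#' @param model an `acrodyn_network`.
#' @param states matrix of states (one row each) or a single state vector.
#' @return numeric vector of packed indices.
#' @export
pack_states <- function(model, states) {
  if (!is.matrix(states)) states <- matrix(as_state(model, states), nrow = 1L)
  cpp_pack(compile_model(model), states)
}

#' @rdname pack_states
#' @param keys numeric vector of packed indices.
#' @return for `unpack_states`, a matrix of states with node-name columns.
#' @export
unpack_states <- function(model, keys) {
  out <- cpp_unpack(compile_model(model), as.numeric(keys))
  colnames(out) <- node_names(model)
  out
}
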