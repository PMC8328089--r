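# Synthetic random multi-valued networks and the exhaustive brute-force
# oracle used to validate the sampling-based machinery.

#' Generate a random multi-valued logical network
#'
#' Test-support generator. Three table schemes: `uniform_random` draws every
#' table row independently; `monotone_random` assigns each regulator a random
#' sign and builds a quantized weighted-threshold table, which is guaranteed
#' monotone in every regulator with the assigned sign (used to exercise the
#' sign-consistency validator); `constant` makes every function constant,
#' so the network has exactly one attractor.
#'
#' @param n_nodes number of nodes.
#' @param max_levels scalar or per-node vector of maximum levels.
#' @param k number of regulators per node (scalar, or length-2 range sampled
#'   per node). Capped at `n_nodes`.
#' @param scheme table generation scheme.
#' @param n_inputs number of input nodes (placed first, hold their value).
#' @param seed RNG seed; the same seed yields an identical model.
#' @return an `acrodyn_network`.
#' @export
random_network <- function(n_nodes, max_levels = 1L, k = 2L,
                           scheme = c("uniform_random", "monotone_random",
                                      "constant"),
                           n_inputs = 0L, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  max_levels <- rep_len(as.integer(max_levels), n_nodes)
  nm <- sprintf("n%02d", seq_len(n_nodes))
  nodes <- data.frame(name = nm, max_level = max_levels,
                      compartment = "none",
                      role = c(rep("input", n_inputs),
                               rep("internal", n_nodes - n_inputs)),
                      stringsAsFactors = FALSE)
  functions <- list()
  edges <- NULL
  for (i in seq_len(n_nodes)) {
    if (nodes$role[i] == "input") next
    ki <- if (length(k) == 2L) sample(k[1]:k[2], 1L) else k
    ki <- min(ki, n_nodes)
    regs <- sample(nm, ki)
    lev <- max_levels[match(regs, nm)] + 1L
    n_rows <- prod(lev)
    M <- max_levels[i]
    if (scheme == "constant") {
      tab <- rep(sample(0:M, 1L), n_rows)
      sg <- rep("positive", ki)
    } else if (scheme == "uniform_random") {
      tab <- sample(0:M, n_rows, replace = TRUE)
      functions[[nm[i]]] <- list(regulators = regs, table = as.integer(tab))
      next # edges derived from monotonicity afterwards
    } else {
      sg <- sample(c("positive", "negative"), ki, replace = TRUE)
      w <- runif(ki, 0.5, 1.5)
      rows <- enumerate_rows(setNames(lev, regs))
      signed <- rows
      for (j in seq_len(ki))
        if (sg[j] == "negative") signed[, j] <- (lev[j] - 1L) - rows[, j]
      score <- as.numeric(signed %*% w)
      smax <- sum(w * (lev - 1L))
      tab <- pmin(M, as.integer(floor(score / max(smax, 1e-9) *
                                        (M + 1L) * 0.999999)))
    }
    functions[[nm[i]]] <- list(regulators = regs, table = as.integer(tab))
    if (scheme != "uniform_random")
      edges <- rbind(edges, data.frame(from = regs, to = nm[i], sign = sg,
                                       stringsAsFactors = FALSE))
  }
  logical_network(nodes, functions, edges = edges,
                  name = sprintf("random_%s_seed%d", scheme, seed),
                  metadata = list(scheme = scheme, seed = seed))
}

#' Exhaustive attractor landscape by full state enumeration
#'
#' Enumerates every network state, follows successors with memoized
#' attractor labels and returns the exact attractor set and basin partition.
#' Serves as the independent oracle for the sampling-based discovery. Errors
#' (never silently samples) if the state space exceeds `budget`.
#'
#' @param model an `acrodyn_network`.
#' @param clamps optional [clamp_set()] applied during all dynamics.
#' @param budget maximum admissible number of states (default `2^20`).
#' @return a list with `attractors` (list of cycle matrices in canonical
#'   rotation), `key`, `length`, `basin_size` (per attractor, summing to the
#'   state-space size), `basin` (attractor index per packed state, in packed
#'   order) and `total_states`.
#' @export
brute_force_landscape <- function(model, clamps = NULL, budget = 2^20) {
  clamps <- check_clamps(model, clamps)
  cm <- compile_model(model)
  cv <- clamp_vectors(model, clamps)
  res <- cpp_brute_force(cm, cv$node, cv$lev, budget)
  cycles <- lapply(res$key, function(k) {
    run_to_attractor(model, unpack_states(model, k)[1, ], clamps)$cycle
  })
  list(attractors = cycles, key = res$key, length = res$length,
       basin_size = as.numeric(tabulate(res$basin, nbins = length(res$key))),
       basin = res$basin, total_states = res$total_states,
       context = clamps$label)
}
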