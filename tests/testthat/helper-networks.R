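# Small fixture networks built in code.

# A <- NOT B, B <- A: the canonical 4-cycle (0,0)->(1,0)->(1,1)->(0,1)->
negation_loop <- function() {
  logical_network(
    nodes = data.frame(name = c("A", "B"), max_level = c(1L, 1L)),
    functions = list(
      A = list(regulators = "B", table = c(1L, 0L)),
      B = list(regulators = "A", table = c(0L, 1L))),
    name = "negation_loop")
}

# every function constant: a unique fixed point
constant_net <- function(n = 3L, value = 1L) {
  nm <- paste0("n", seq_len(n))
  logical_network(
    nodes = data.frame(name = nm, max_level = 1L),
    functions = setNames(lapply(nm, function(x)
      list(regulators = character(0), table = value)), nm),
    name = "constant_net")
}

# two binary regulators, AND logic on node C; A and B hold themselves
and_gate <- function() {
  logical_network(
    nodes = data.frame(name = c("A", "B", "C"), max_level = 1L,
                       role = c("input", "input", "internal")),
    functions = list(
      C = list(regulators = c("A", "B"), table = c(0L, 0L, 0L, 1L))),
    name = "and_gate")
}

# toy with a progesterone-like input driving a fusion-like reporter:
# Fusion(t+1) = Pg, one internal relay to give a non-trivial transient
pg_toy <- function() {
  logical_network(
    nodes = data.frame(name = c("Pg", "Relay", "Fusion"), max_level = 1L,
                       role = c("input", "internal", "reporter")),
    functions = list(
      Relay = list(regulators = "Pg", table = c(0L, 1L)),
      Fusion = list(regulators = "Relay", table = c(0L, 1L))),
    name = "pg_toy")
}

# exhaustively enumerate all states of a small model (rows = states)
all_states <- function(model) {
  lev <- model$nodes$max_level + 1L
  S <- prod(lev)
  unpack_states(model, 0:(S - 1))
}
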