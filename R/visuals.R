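# Small presentation helpers: state-transition-graph export and activation
# bar plots.

#' Export a state-transition graph
#'
#' Enumerates every state of a (small) model, draws one directed edge per
#' synchronous transition, and writes the graph as Graphviz DOT or GraphML.
#' Attractor states are marked. Only feasible for enumerable models; errors
#' beyond `budget` states.
#'
#' @param model an `acrodyn_network`.
#' @param path output path.
#' @param clamps optional [clamp_set()] applied during the dynamics.
#' @param format `"dot"` or `"graphml"` (default from the file extension).
#' @param budget maximum number of states (default `2^16`).
#' @return `path`, invisibly.
#' @export
export_stg <- function(model, path, clamps = NULL, format = NULL,
                       budget = 2^16) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path)) "graphml" else "dot"
  bf <- brute_force_landscape(model, clamps, budget = budget)
  S <- bf$total_states
  clamps <- check_clamps(model, clamps)
  cm <- compile_model(model)
  cv <- clamp_vectors(model, clamps)
  succ <- cpp_successors(cm, cv$node, cv$lev, budget)
  on_cycle <- logical(S)
  for (cyc in bf$attractors)
    on_cycle[pack_states(model, cyc) + 1] <- TRUE
  if (format == "dot") {
    lines <- c(sprintf("digraph \"%s_stg\" {", model$name),
               "  node [shape=point];",
               sprintf("  s%.0f [color=%s];", 0:(S - 1),
                       ifelse(on_cycle, "black", "gray")),
               sprintf("  s%.0f -> s%.0f;", 0:(S - 1), succ),
               "}")
    writeLines(lines, path)
  } else {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    xml2::xml_add_child(doc, "key", id = "d_attr", `for` = "node",
                        attr.name = "attractor", attr.type = "boolean")
    g <- xml2::xml_add_child(doc, "graph", id = paste0(model$name, "_stg"),
                             edgedefault = "directed")
    for (s in 0:(S - 1)) {
      n <- xml2::xml_add_child(g, "node", id = sprintf("s%.0f", s))
      d <- xml2::xml_add_child(n, "data", key = "d_attr")
      xml2::xml_text(d) <- tolower(as.character(on_cycle[s + 1]))
    }
    for (s in 0:(S - 1))
      xml2::xml_add_child(g, "edge", source = sprintf("s%.0f", s),
                          target = sprintf("s%.0f", succ[s + 1]))
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Bar plot of per-node activation probabilities
#'
#' Base-graphics rendering of [activation_stats()] (or one class of
#' [per_class_stats()]): one bar per node with +/- 1 SE whiskers.
#'
#' @param stats result of [activation_stats()].
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_activation <- function(stats, main = "Node activation probability",
                            ...) {
  s <- stats$stats
  mids <- graphics::barplot(s$P, names.arg = s$node, las = 2,
                            ylim = c(0, 1), ylab = "P(x > M/2)",
                            main = main, cex.names = 0.6, ...)
  has_se <- s$SE > 0
  if (any(has_se))
    graphics::arrows(mids[has_se], pmax(0, s$P - s$SE)[has_se],
                     mids[has_se], pmin(1, s$P + s$SE)[has_se],
                     angle = 90, code = 3, length = 0.02)
  invisible(mids)
}
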