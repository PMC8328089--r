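# JSON network-file format: reader, rule expansion, writer, graph exporters.
#
# Schema (one JSON document):
#   name, metadata        free-form
#   nodes                 [{name, max_level, compartment, role, labels}]
#   edges                 [{from, to, sign}]          (sign: positive/negative/dual)
#   functions             [{target, regulators, table | rule, provenance}]
# A "rule" is an R expression over regulator names, evaluated on every
# regulator-level combination and expanded to a full truth table at load;
# the engine only ever sees complete tables.

#' Load a logical network from a JSON file
#'
#' Parses the JSON dialect, expands any rule shorthand into complete truth
#' tables and returns a fully validated network. Fails hard (naming the
#' offending node) on unknown regulators, out-of-range levels, incomplete
#' tables or duplicate nodes.
#'
#' @param path path to the network JSON file.
#' @return an `acrodyn_network`.
#' @export
load_network <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- do.call(rbind, lapply(doc$nodes, function(n)
    data.frame(name = n$name, max_level = as.integer(n$max_level),
               compartment = n$compartment %||% "none",
               role = n$role %||% "internal", stringsAsFactors = FALSE)))
  labels <- Filter(Negate(is.null),
                   setNames(lapply(doc$nodes, function(n)
                     if (is.null(n$labels)) NULL else unlist(n$labels)),
                     vapply(doc$nodes, `[[`, "", "name")))
  if (!length(labels)) labels <- NULL
  lev <- setNames(nodes$max_level + 1L, nodes$name)
  functions <- list()
  for (f in doc$functions) {
    regs <- as.character(unlist(f$regulators))
    unknown <- setdiff(regs, nodes$name)
    if (length(unknown))
      stop("function for ", f$target, " names unknown regulator ", unknown[1])
    tab <- if (!is.null(f$table)) as.integer(unlist(f$table))
           else expand_rule(f$rule, regs, lev[regs])
    functions[[f$target]] <-
      list(regulators = regs, table = tab, rule = f$rule %||% NULL,
           provenance = f$provenance %||% NULL)
  }
  edges <- if (!is.null(doc$edges))
    do.call(rbind, lapply(doc$edges, function(e)
      data.frame(from = e$from, to = e$to, sign = e$sign,
                 stringsAsFactors = FALSE)))
  logical_network(nodes, functions, edges = edges, labels = labels,
                  name = doc$name %||% basename(path),
                  metadata = doc$metadata %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restricted evaluation environment for rule shorthand
rule_env <- function() {
  allowed <- c("+", "-", "*", "(", ">", "<", ">=", "<=", "==", "!=",
               "&", "|", "!", "ifelse", "pmin", "pmax", "as.integer",
               "abs", "c")
  e <- new.env(parent = emptyenv())
  for (fn in allowed) assign(fn, get(fn, baseenv()), envir = e)
  e
}

# evaluate a rule over every regulator tuple -> full table (integer vector)
expand_rule <- function(rule, regulators, lev) {
  rows <- enumerate_rows(lev)
  env <- as.list(as.data.frame(rows))
  if (!length(regulators)) env <- list()
  expr <- tryCatch(parse(text = rule)[[1]],
                   error = function(e) stop("unparsable rule: ", rule))
  val <- eval(expr, envir = env, enclos = rule_env())
  val <- as.integer(val)
  if (length(val) == 1L) val <- rep(val, nrow(rows))
  if (length(val) != nrow(rows))
    stop("rule does not evaluate to one output per table row: ", rule)
  val
}

#' Write a logical network to a JSON file
#'
#' Emits the schema read by [load_network()], always including the fully
#' expanded truth tables (rules, when present, are kept as provenance), so
#' a load/write/load round trip yields table-identical models.
#'
#' @param model an `acrodyn_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  nd <- model$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    out <- list(name = nd$name[i], max_level = nd$max_level[i],
                compartment = nd$compartment[i], role = nd$role[i])
    if (!is.null(model$labels[[nd$name[i]]]))
      out$labels <- model$labels[[nd$name[i]]]
    out
  })
  functions <- lapply(names(model$functions), function(nm) {
    f <- model$functions[[nm]]
    out <- list(target = nm, regulators = f$regulators, table = f$table)
    if (!is.null(f$rule)) out$rule <- f$rule
    if (!is.null(f$provenance)) out$provenance <- f$provenance
    out
  })
  edges <- lapply(seq_len(nrow(model$edges)), function(i)
    as.list(model$edges[i, c("from", "to", "sign")]))
  doc <- list(name = model$name, metadata = model$metadata,
              nodes = nodes, edges = edges, functions = functions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Check declared edge signs against truth-table monotonicity
#'
#' For every edge declared positive (negative) the target's truth table must
#' be non-decreasing (non-increasing) in that regulator with all other
#' regulators held fixed; dual edges are exempt.
#'
#' @param model an `acrodyn_network`.
#' @return data.frame with one row per edge: `from`, `to`, `sign`,
#'   `observed` (monotonicity actually found) and `consistent`.
#' @export
check_edge_signs <- function(model) {
  ed <- model$edges
  obs <- vapply(seq_len(nrow(ed)), function(i)
    table_monotonicity(model, ed$to[i], ed$from[i]), character(1))
  # a constant dependence is monotone both ways: consistent with either sign
  consistent <- ed$sign == "dual" | obs == "constant" |
    (ed$sign == "positive" & obs == "positive") |
    (ed$sign == "negative" & obs == "negative")
  cbind(ed, observed = obs, consistent = consistent)
}

#' Export the interaction graph in DOT format
#'
#' @param model an `acrodyn_network`.
#' @param path output path for the Graphviz DOT file.
#' @return `path`, invisibly.
#' @export
export_dot <- function(model, path) {
  col <- c(positive = "black", negative = "red", dual = "gold")
  lines <- c(sprintf("digraph \"%s\" {", model$name),
             sprintf("  \"%s\" [shape=%s];", model$nodes$name,
                     ifelse(model$nodes$role == "input", "box",
                            ifelse(model$nodes$role == "reporter",
                                   "doublecircle", "ellipse"))),
             sprintf("  \"%s\" -> \"%s\" [color=%s];", model$edges$from,
                     model$edges$to, col[model$edges$sign]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export the interaction graph as GraphML
#'
#' @param model an `acrodyn_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(model, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (spec in list(c("d_sign", "edge", "sign"), c("d_role", "node", "role")))
    xml2::xml_add_child(doc, "key", id = spec[1], `for` = spec[2],
                        attr.name = spec[3], attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = model$name,
                           edgedefault = "directed")
  for (i in seq_len(nrow(model$nodes))) {
    n <- xml2::xml_add_child(g, "node", id = model$nodes$name[i])
    d <- xml2::xml_add_child(n, "data", key = "d_role")
    xml2::xml_text(d) <- model$nodes$role[i]
  }
  for (i in seq_len(nrow(model$edges))) {
    e <- xml2::xml_add_child(g, "edge", source = model$edges$from[i],
                             target = model$edges$to[i])
    d <- xml2::xml_add_child(e, "data", key = "d_sign")
    xml2::xml_text(d) <- model$edges$sign[i]
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export the model as SBML-qual
#'
#' Writes an SBML Level 3 document using the qualitative-models package:
#' one qualitative species per node (with `maxLevel`) and one transition per
#' regulatory function, each truth-table row becoming a function term whose
#' condition is the conjunction of regulator-level equalities. Import is not
#' provided (multi-valued SBML-qual support varies between tools).
#'
#' @param model an `acrodyn_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sbml_qual <- function(model, path) {
  ns_qual <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:qual" = ns_qual, level = "3", version = "1",
    "qual:required" = "true")
  mdl <- xml2::xml_add_child(doc, "model", id = gsub("\\W", "_", model$name))
  lqs <- xml2::xml_add_child(mdl, "qual:listOfQualitativeSpecies")
  for (i in seq_len(nrow(model$nodes)))
    xml2::xml_add_child(lqs, "qual:qualitativeSpecies",
                        "qual:id" = model$nodes$name[i],
                        "qual:maxLevel" = as.character(model$nodes$max_level[i]),
                        "qual:constant" = if (model$nodes$role[i] == "input")
                          "true" else "false")
  lot <- xml2::xml_add_child(mdl, "qual:listOfTransitions")
  mathml <- "http://www.w3.org/1998/Math/MathML"
  for (nm in names(model$functions)) {
    f <- model$functions[[nm]]
    tr <- xml2::xml_add_child(lot, "qual:transition",
                              "qual:id" = paste0("tr_", nm))
    if (length(f$regulators)) {
      lin <- xml2::xml_add_child(tr, "qual:listOfInputs")
      for (r in f$regulators)
        xml2::xml_add_child(lin, "qual:input",
                            "qual:qualitativeSpecies" = r,
                            "qual:transitionEffect" = "none")
    }
    lo <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(lo, "qual:output", "qual:qualitativeSpecies" = nm,
                        "qual:transitionEffect" = "assignmentLevel")
    lft <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    lev <- node_levels(model)[f$regulators]
    rows <- enumerate_rows(lev)
    levels_used <- sort(unique(f$table))
    default <- levels_used[1]
    xml2::xml_add_child(lft, "qual:defaultTerm",
                        "qual:resultLevel" = as.character(default))
    for (v in setdiff(levels_used, default)) {
      ft <- xml2::xml_add_child(lft, "qual:functionTerm",
                                "qual:resultLevel" = as.character(v))
      math <- xml2::xml_add_child(ft, "math", xmlns = mathml)
      sel <- which(f$table == v)
      or_node <- if (length(sel) > 1) {
        ap <- xml2::xml_add_child(math, "apply")
        xml2::xml_add_child(ap, "or")
        ap
      } else math
      for (ri in sel) {
        ap <- if (length(f$regulators) > 1) {
          a <- xml2::xml_add_child(or_node, "apply")
          xml2::xml_add_child(a, "and")
          a
        } else or_node
        for (j in seq_along(f$regulators)) {
          eq <- xml2::xml_add_child(ap, "apply")
          xml2::xml_add_child(eq, "eq")
          ci <- xml2::xml_add_child(eq, "ci")
          xml2::xml_text(ci) <- f$regulators[j]
          cn <- xml2::xml_add_child(eq, "cn", type = "integer")
          xml2::xml_text(cn) <- as.character(rows[ri, j])
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
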