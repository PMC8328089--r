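# The bundled acrosome-reaction network and its domain-specific validator.

#' Load the bundled human-sperm AR network
#'
#' Returns the 38-node, 87-edge discrete regulatory network of the human
#' sperm acrosome reaction. Four input nodes represent external stimuli
#' (`A23187`, `Pg`, `Ca_o`, `HCO3_o`); the reporter node `Fusion` marks
#' completion of the AR. Four nodes are multi-level: `Em` (0..3), `CatSper`,
#' `Ca_i` and `pH_i` (0..2 each); all others are binary.
#'
#' The regulatory truth tables are reconstructed from the published
#' mechanistic description of the pathway and marked
#' `provenance = "reconstructed"` in the bundled file; see the package
#' vignette for what that implies for quantitative comparisons.
#'
#' @return an `acrodyn_network`, precompiled for simulation.
#' @examples
#' ar <- ar_network()
#' nrow(ar$nodes)   # 38
#' nrow(ar$edges)   # 87
#' @export
ar_network <- function() {
  path <- system.file("extdata", "ar_network.json", package = "acrodyn")
  precompile(load_network(path))
}

# common name variants -> canonical bundled node names
AR_SYNONYMS <- c(
  "[Ca2+]_i" = "Ca_i", "[Ca2+]_a" = "Ca_a", "Ca2+_i" = "Ca_i",
  "Ca2+_a" = "Ca_a", "Cai" = "Ca_i", "Caa" = "Ca_a",
  "pHi" = "pH_i", "pHa" = "pH_a", "Hv1" = "Hv",
  "V-ATPase" = "V_ATPase", "VATPase" = "V_ATPase",
  "NSF/aSNAP" = "NSF", "NSF/alphaSNAP" = "NSF", "aSNAP" = "NSF",
  "SNAREs" = "SNARE", "SNARE's" = "SNARE", "Swelling" = "Swell",
  "F" = "Fusion", "IP3R" = "IP3R_a", "HCO3o" = "HCO3_o", "Cao" = "Ca_o",
  "Progesterone" = "Pg", "IKSper" = "IKsper", "KSper" = "IKsper",
  "Slo3" = "IKsper", "HCO3i" = "HCO3_i")

#' Resolve a node name, accepting common synonyms
#'
#' @param model an `acrodyn_network`.
#' @param name a node name or a common variant (e.g. `"[Ca2+]_i"`,
#'   `"Hv1"`, `"Swelling"`, `"F"`).
#' @return the canonical node name; errors if unresolvable.
#' @export
resolve_node <- function(model, name) {
  if (name %in% node_names(model)) return(name)
  if (name %in% names(AR_SYNONYMS)) {
    cand <- unname(AR_SYNONYMS[name])
    if (cand %in% node_names(model)) return(cand)
  }
  stop("cannot resolve node name '", name, "'")
}

#' Validate the AR-specific model contract
#'
#' Checks the domain contract of the bundled AR network: 38 nodes, 87 drawn
#' edges matching the regulator-derived edge list, the four inputs, the
#' `Fusion` reporter, the exact multi-level node set (`Em` 0..3 with
#' hyperpolarized..fully depolarized labels, `CatSper` 0..2
#' closed/open/inactivated, `Ca_i` 0..2 basal/activator/inhibitor, `pH_i`
#' 0..2 acidic..fully alkaline), presence of the capacitation-control node
#' flags, and sign consistency of every truth table against its declared
#' edge signs. Soft failures never throw; the result is a structured
#' pass/fail report.
#'
#' @param model an `acrodyn_network` (typically [ar_network()]).
#' @return a data.frame of class `acrodyn_validation` with columns `check`,
#'   `ok`, `detail`, and attribute `passed` (all checks ok).
#' @export
validate_ar_model <- function(model) {
  checks <- list()
  add <- function(check, ok, detail)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  nd <- model$nodes
  add("node_count", nrow(nd) == 38L, sprintf("%d nodes", nrow(nd)))
  derived <- nrow(model$edges)
  drawn <- model$metadata$drawn_edge_count %||% derived
  add("edge_count", derived == 87L,
      sprintf("%d regulator-derived edges, %d drawn in the published figure",
              derived, drawn))
  inputs <- sort(nd$name[nd$role == "input"])
  add("inputs", identical(inputs, sort(c("A23187", "Pg", "Ca_o", "HCO3_o"))),
      paste(inputs, collapse = ", "))
  add("reporter", identical(nd$name[nd$role == "reporter"], "Fusion"),
      paste(nd$name[nd$role == "reporter"], collapse = ", "))
  want_ml <- c(Em = 3L, CatSper = 2L, Ca_i = 2L, pH_i = 2L)
  got_ml <- setNames(nd$max_level, nd$name)[nd$max_level > 1L]
  add("multi_level_nodes",
      length(got_ml) == 4L && all(names(want_ml) %in% names(got_ml)) &&
        all(got_ml[names(want_ml)] == want_ml),
      paste(names(got_ml), got_ml, sep = ":", collapse = ", "))
  em_labels <- model$labels[["Em"]]
  add("em_labels",
      !is.null(em_labels) && length(em_labels) == 4L &&
        grepl("hyperpolarized", em_labels[1], ignore.case = TRUE) &&
        grepl("depolarized", em_labels[4], ignore.case = TRUE),
      paste(em_labels, collapse = " / "))
  cs_labels <- model$labels[["CatSper"]]
  add("catsper_labels",
      !is.null(cs_labels) && length(cs_labels) == 3L &&
        grepl("closed", cs_labels[1], ignore.case = TRUE) &&
        grepl("inactivated", cs_labels[3], ignore.case = TRUE),
      paste(cs_labels, collapse = " / "))
  cap <- unlist(model$metadata$capacitation_nodes)
  add("capacitation_flags",
      length(cap) > 0 && all(cap %in% nd$name),
      paste(cap, collapse = ", "))
  signs <- tryCatch(check_edge_signs(model), error = function(e) NULL)
  add("sign_consistency", !is.null(signs) && all(signs$consistent),
      if (is.null(signs)) "edge/function structure too inconsistent to check"
      else sprintf("%d/%d edges consistent", sum(signs$consistent),
                   nrow(signs)))
  named <- c("NBC", "SLC", "sAC", "sNHE", "Hv", "V_ATPase", "HLeak_a",
             "pH_i", "pH_a", "Em", "CatSper", "IKsper", "SOC", "STIM",
             "IP3R_a", "IP3R_ns", "PLC", "IP3", "PMCA", "ACA", "cAMP",
             "PDE", "EPAC", "RAP", "Rab3A", "NSF", "SNARE", "SYT", "Swell",
             "Fusion", "Ca_i", "Ca_a", "A23187", "Pg", "Ca_o", "HCO3_o")
  add("named_components", all(named %in% nd$name),
      paste(setdiff(named, nd$name), collapse = ", "))
  out <- do.call(rbind, checks)
  attr(out, "passed") <- all(out$ok)
  class(out) <- c("acrodyn_validation", class(out))
  out
}

#' @export
print.acrodyn_validation <- function(x, ...) {
  cat(sprintf("AR model validation: %s\n",
              if (attr(x, "passed")) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-20s %s\n", if (x$ok[i]) "ok" else "FAIL",
                x$check[i], x$detail[i]))
  invisible(x)
}
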