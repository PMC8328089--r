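# In-silico experimental-condition harness: condition -> intervention
# mapping, population response metric, direction-agreement scoring.
#
# A condition is a named intervention: input-node settings (overriding the
# protocol levels in every initial state) and/or clamps on internal nodes
# (held during all dynamics). The battery config is data (bundled JSON), so
# the pharmacology-to-node mapping can be edited without code changes.

#' Load an experiment battery configuration
#'
#' The config is a JSON document with `conditions` (name -> intervention:
#' `inputs` and/or `clamps`, each a map node -> level) and `rows` (the
#' literature comparisons: `variable`, `readout` node, `condition` name or
#' name array for compound conditions, `baseline` — a condition name, array,
#' or `"control"` for the untouched capacitated population —, `reported`
#' direction `"up"`/`"down"`, `reported_magnitude` in percentage points when
#' printed, and a `reference` tag).
#'
#' @param path path to a battery JSON; default the bundled battery
#'   reproducing the 26 published comparisons.
#' @return a list with `conditions` and `rows`.
#' @export
load_battery <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ar_battery.json", package = "acrodyn")
  doc <- jsonlite::read_json(path)
  rows <- lapply(doc$rows, function(r) {
    r$condition <- as.character(unlist(r$condition))
    r$baseline <- as.character(unlist(r$baseline %||% "control"))
    r
  })
  list(conditions = doc$conditions, rows = rows,
       metric = doc$metric %||% "percentage_points",
       dead_band = doc$dead_band %||% 0.5)
}

# merge the interventions of one or more named conditions
resolve_intervention <- function(battery, names) {
  inputs <- list(); clamps <- list()
  for (nm in names) {
    if (identical(nm, "control")) next
    cond <- battery$conditions[[nm]]
    if (is.null(cond)) stop("unknown condition ", nm)
    inputs <- modifyList(inputs, as.list(cond$inputs %||% list()))
    clamps <- modifyList(clamps, as.list(cond$clamps %||% list()))
  }
  list(inputs = inputs, clamps = clamps)
}

# population mean activation (percent) of `readout` over attractor states
# reached from `states` under an intervention
arm_value <- function(model, states, intervention, readout,
                      max_steps = 10000L, cache = NULL) {
  key <- paste(readout,
               paste(names(intervention$inputs),
                     unlist(intervention$inputs), collapse = ","),
               paste(names(intervention$clamps),
                     unlist(intervention$clamps), collapse = ","),
               sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  nm <- node_names(model)
  for (nd in names(intervention$inputs))
    states[, nd] <- as.integer(intervention$inputs[[nd]])
  for (nd in names(intervention$clamps)) # clamp active from t = 0
    states[, nd] <- as.integer(intervention$clamps[[nd]])
  clamps <- check_clamps(model, clamp_set(intervention$clamps))
  cv <- clamp_vectors(model, clamps)
  tr <- cpp_trajectories(compile_model(model), states, cv$node, cv$lev,
                         max_steps)
  keys <- unique(tr$key)
  j <- match(readout, nm)
  if (is.na(j)) stop("unknown readout node ", readout)
  M <- model$nodes$max_level[j]
  per_attr <- vapply(keys, function(k) {
    cyc <- run_to_attractor(model, unpack_states(model, k)[1, ],
                            clamps, max_steps)$cycle
    mean(cyc[, j] > M / 2)
  }, numeric(1))
  val <- 100 * mean(per_attr[match(tr$key, keys)])
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Run one experimental condition on a population
#'
#' Every population member is run to its attractor under the baseline and
#' under the condition intervention; the readout is the population mean
#' activation of the readout node over attractor states, and the response is
#' the difference in percentage points.
#'
#' @param model an `acrodyn_network`.
#' @param condition condition name (or names, merged) from the battery.
#' @param population an `acrodyn_population` (the stratified physiological
#'   ensemble).
#' @param readout readout node name.
#' @param baseline baseline condition name(s), or `"control"`.
#' @param battery battery config from [load_battery()].
#' @return one-row data.frame: control value, condition value, delta (pp),
#'   direction, n.
#' @export
run_condition <- function(model, condition, population, readout,
                          baseline = "control", battery = load_battery()) {
  model <- precompile(model)
  ctrl <- arm_value(model, population$states,
                    resolve_intervention(battery, baseline), readout)
  cond <- arm_value(model, population$states,
                    resolve_intervention(battery, condition), readout)
  delta <- cond - ctrl
  data.frame(condition = paste(condition, collapse = " + "),
             baseline = paste(baseline, collapse = " + "),
             readout = readout, control = ctrl, value = cond,
             delta = delta,
             direction = direction_of(delta, battery$dead_band),
             n = nrow(population$states), stringsAsFactors = FALSE)
}

direction_of <- function(delta, dead_band = 0.5) {
  if (delta > dead_band) "up" else if (delta < -dead_band) "down" else "nc"
}

#' Run the full experiment battery
#'
#' Executes every battery row on the population, scores the direction
#' agreement of the modeled response against the reported one (with a
#' dead band below which a delta counts as "no change"), and returns the
#' per-row report plus the overall agreement rate.
#'
#' @param model an `acrodyn_network`.
#' @param population an `acrodyn_population`.
#' @param battery battery config from [load_battery()].
#' @param seed recorded in the report (the population fixes the randomness).
#' @return a list of class `acrodyn_battery_report`: `rows` data.frame
#'   (variable, condition, reported, delta, direction, agreement, ...) and
#'   `agreement_rate`.
#' @export
run_battery <- function(model, population, battery = load_battery(),
                        seed = NA_integer_) {
  model <- precompile(model)
  cache <- new.env(parent = emptyenv())
  out <- lapply(battery$rows, function(r) {
    ctrl <- arm_value(model, population$states,
                      resolve_intervention(battery, r$baseline), r$readout,
                      cache = cache)
    cond <- arm_value(model, population$states,
                      resolve_intervention(battery, r$condition), r$readout,
                      cache = cache)
    delta <- cond - ctrl
    dir <- direction_of(delta, battery$dead_band)
    data.frame(variable = r$variable,
               condition = paste(r$condition, collapse = " + "),
               baseline = paste(r$baseline, collapse = " + "),
               readout = r$readout, reference = r$reference %||% "",
               reported = r$reported,
               reported_magnitude = r$reported_magnitude %||% NA_real_,
               control = ctrl, value = cond, delta = delta,
               direction = dir, agreement = identical(dir, r$reported),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, out)
  structure(list(rows = rows,
                 agreement_rate = mean(rows$agreement),
                 n_agree = sum(rows$agreement), n_rows = nrow(rows),
                 n = nrow(population$states), seed = seed,
                 metric = battery$metric, dead_band = battery$dead_band),
            class = "acrodyn_battery_report")
}

#' @export
print.acrodyn_battery_report <- function(x, ...) {
  cat(sprintf(
    "<battery report> %d/%d rows agree (%.0f%%), n = %d, metric = %s\n",
    x$n_agree, x$n_rows, 100 * x$agreement_rate, x$n, x$metric))
  print(x$rows[, c("variable", "condition", "reported", "delta",
                   "direction", "agreement")], digits = 3)
  invisible(x)
}

#' Write a battery report to CSV
#'
#' @param report an `acrodyn_battery_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_battery <- function(report, path) {
  write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}
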