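# YAML/JSON configuration: transport cycles, gradient sets and run configs.
#
# Schema (YAML shown; JSON is isomorphic):
#
#   label: "VcINDY (3 Na+ : 1 succinate2-)"
#   cycle:
#     - {name: Na, valence: 1, stoichiometry: 3, role: coupling_ion}
#     - {name: succinate, valence: -2, stoichiometry: 1, role: substrate}
#   gradients:
#     Na:        {c_in: 25, c_out: 100, unit: mM}
#     succinate: {c_in: 1,  c_out: 0.1, unit: uM}
#   candidates: [[1, 1], [2, 1], [3, 1], [4, 1]]
#   substrate_valence: -2
#   voltages: [12, 48, 84]
#   timepoints: [0, 15, 30, 45, 60, 90, 120]
#   replicates: 3
#   seed: 1
#   params: {rate_scale: 5.0e-9, counting_efficiency: 0.3,
#            specific_activity: 60, leak_rate: 0, baseline_jitter_cv: 0}
#   analysis: {alpha: 0.05, tolerance_mV: 10, leak: false,
#              normalize: false, t_norm: 5}
#
# Concentrations take explicit unit suffixes (M, mM, uM) and are held
# internally in mol/L.

.unit_factor <- function(unit) {
  factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6)
  if (!unit %in% names(factors))
    stop(sprintf("unknown concentration unit '%s' (use M, mM or uM)", unit),
         call. = FALSE)
  factors[[unit]]
}

.cycle_from_list <- function(lst, label = "") {
  terms <- lapply(lst, function(t) {
    species_term(t$name, t$valence, t$stoichiometry,
                 role = if (is.null(t$role)) "coupling_ion" else t$role)
  })
  transport_cycle(terms, label = label)
}

.cycle_to_list <- function(cycle) {
  df <- cycle$terms
  lapply(seq_len(nrow(df)), function(i) {
    list(name = df$name[i], valence = df$valence[i],
         stoichiometry = df$stoichiometry[i], role = df$role[i])
  })
}

.gradients_from_list <- function(lst) {
  entries <- lapply(names(lst), function(nm) {
    g <- lst[[nm]]
    f <- .unit_factor(if (is.null(g$unit)) "M" else g$unit)
    c(g$c_in * f, g$c_out * f)
  })
  names(entries) <- names(lst)
  do.call(gradient_set, c(entries, list(unit = "M")))
}

.gradients_to_list <- function(gradients) {
  conc <- gradients$concentrations
  out <- lapply(seq_len(nrow(conc)), function(i) {
    list(c_in = conc$c_in[i], c_out = conc$c_out[i], unit = "M")
  })
  names(out) <- conc$name
  out
}

.read_config_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Read a run configuration (YAML or JSON)
#'
#' Parses the documented config schema into package objects: the transport
#' cycle, the gradient set (converted to mol/L), candidate stoichiometries,
#' clamp voltages, simulator parameters and analysis options. Any section may
#' be absent; the returned list then carries `NULL` for it.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A list with elements `cycle`, `gradients`, `candidates`,
#'   `substrate_valence`, `voltages`, `timepoints`, `replicates`, `params`
#'   (a [flux_params()]), `population`, `analysis`, `seed` and `md5` (hash of
#'   the config file, recorded in output manifests).
#' @export
read_run_config <- function(path) {
  cfg <- .read_config_file(path)
  out <- list(md5 = unname(tools::md5sum(path)))
  out$label <- if (is.null(cfg$label)) "" else cfg$label
  out$cycle <- if (!is.null(cfg$cycle)) .cycle_from_list(cfg$cycle, out$label)
  out$gradients <- if (!is.null(cfg$gradients)) .gradients_from_list(cfg$gradients)
  out$candidates <- if (!is.null(cfg$candidates)) {
    if (is.matrix(cfg$candidates)) {
      lapply(seq_len(nrow(cfg$candidates)), function(i) cfg$candidates[i, ])
    } else {
      lapply(cfg$candidates, unlist)
    }
  }
  out$substrate_valence <- if (is.null(cfg$substrate_valence)) -2
                           else cfg$substrate_valence
  out$voltages <- if (!is.null(cfg$voltages)) unlist(cfg$voltages)
  out$timepoints <- if (is.null(cfg$timepoints)) c(0, 15, 30, 45, 60, 90, 120)
                    else unlist(cfg$timepoints)
  out$replicates <- if (is.null(cfg$replicates)) 3L else as.integer(cfg$replicates)
  out$seed <- cfg$seed
  p <- if (is.null(cfg$params)) list() else cfg$params
  if (!is.null(out$seed)) p$seed <- out$seed
  out$params <- do.call(flux_params, p)
  pop <- if (is.null(cfg$population)) list() else cfg$population
  out$population <- do.call(vesicle_population, pop)
  out$analysis <- if (is.null(cfg$analysis)) list() else cfg$analysis
  out
}

#' Write a transport cycle and gradients to a config file
#'
#' Serializes to the same YAML/JSON schema that [read_run_config()] reads, so
#' cycle and gradient definitions round-trip.
#'
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param cycle A [transport_cycle()] (optional).
#' @param gradients A [gradient_set()] (optional).
#' @param extra Named list of additional top-level config entries
#'   (candidates, voltages, seed, ...).
#' @return `path`, invisibly.
#' @export
write_transport_config <- function(path, cycle = NULL, gradients = NULL,
                                   extra = list()) {
  cfg <- extra
  if (!is.null(cycle)) {
    cfg$label <- cycle$label
    cfg$cycle <- .cycle_to_list(cycle)
  }
  if (!is.null(gradients)) cfg$gradients <- .gradients_to_list(gradients)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path)
  else
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(path)
}
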