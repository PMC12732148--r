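#' Load and validate a full model parameter set
#'
#' Reads a structured parameter document (YAML, or JSON when the file
#' extension is `.json`) with sections `epidemiology`, `accuracy`,
#' `costs`, `transitions`, `economics` and `uncertainty`, and returns a
#' validated parameter set. The packaged baseline file
#' (`system.file("extdata", "baseline_parameters.yaml", package =
#' "nstagecea")`) holds the published base-case values for the three
#' staging strategies.
#'
#' Validation is exhaustive: every offending field is collected and
#' reported in a single error message rather than failing on the first.
#'
#' @param source Path to a YAML or JSON parameter file, or an
#'   already-parsed nested list with the same structure.
#' @return An object of class `nstage_params`: a nested list with
#'   elements `epidemiology`, `accuracy` (one `sensitivity`/`specificity`
#'   pair per strategy), `costs`, `transitions`, `economics` and
#'   `uncertainty` (a data frame of sampling specifications).
#' @seealso [baseline_parameters()], [write_parameter_set()],
#'   [validate_parameter_set()]
#' @export
load_parameter_set <- function(source) {
  if (is.character(source)) {
    if (!file.exists(source)) {
      stop("parameter file not found: ", source, call. = FALSE)
    }
    doc <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    doc <- source
  } else {
    stop("`source` must be a file path or a nested list", call. = FALSE)
  }
  params <- as_nstage_params(doc)
  validate_parameter_set(params)
  params
}

# Coerce a parsed document into the canonical in-memory layout.
as_nstage_params <- function(doc) {
  required <- c("epidemiology", "accuracy", "costs", "transitions", "economics")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    stop("parameter document is missing section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unc <- doc$uncertainty
  if (is.null(unc)) {
    unc <- data.frame(parameter_id = character(), family = character(),
                      mean = numeric(), lower = numeric(), upper = numeric(),
                      clerical = logical(), stringsAsFactors = FALSE)
  } else if (!is.data.frame(unc)) {
    unc <- do.call(rbind, lapply(unc, function(u) {
      data.frame(parameter_id = u$parameter_id,
                 family = u$family,
                 mean = as.numeric(u$mean),
                 lower = if (is.null(u$lower)) NA_real_ else as.numeric(u$lower),
                 upper = if (is.null(u$upper)) NA_real_ else as.numeric(u$upper),
                 clerical = isTRUE(u$clerical),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(unc) <- NULL
  structure(list(
    epidemiology = lapply(doc$epidemiology, as.numeric),
    accuracy = lapply(doc$accuracy, function(a) lapply(a, as.numeric)),
    costs = lapply(doc$costs, function(x) {
      if (is.list(x)) lapply(x, as.numeric) else as.numeric(x)
    }),
    transitions = lapply(doc$transitions, as.numeric),
    economics = list(
      discount_rate = as.numeric(doc$economics$discount_rate),
      horizon_years = as.integer(doc$economics$horizon_years),
      cycle_length_years = as.numeric(doc$economics$cycle_length_years),
      half_cycle_correction = isTRUE(doc$economics$half_cycle_correction)
    ),
    uncertainty = unc
  ), class = "nstage_params")
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter set: probabilities
#' in \[0, 1\], non-negative costs, prevalences summing to at most 1,
#' positive cohort size, unit cycle length, presence of all three
#' strategies, and that every uncertain parameter id resolves to a field
#' of the set. All violations are reported together.
#'
#' @param params An `nstage_params` object.
#' @return `params`, invisibly, if valid; otherwise an error listing
#'   every offending field.
#' @export
validate_parameter_set <- function(params) {
  bad <- character()
  note <- function(cond, field) if (cond) bad <<- c(bad, field)
  epi <- params$epidemiology
  note(!is.finite(epi$cohort_size) || epi$cohort_size <= 0, "cohort_size")
  note(!is.finite(epi$initial_age) || epi$initial_age < 0, "initial_age")
  for (p in c("prevalence_nodal", "prevalence_metastatic")) {
    note(!is.finite(epi[[p]]) || epi[[p]] < 0 || epi[[p]] > 1, p)
  }
  if (is.finite(epi$prevalence_nodal) && is.finite(epi$prevalence_metastatic) &&
      epi$prevalence_nodal + epi$prevalence_metastatic > 1) {
    bad <- c(bad, "prevalence_nodal+prevalence_metastatic")
  }
  missing_strat <- setdiff(.STRATEGIES, names(params$accuracy))
  if (length(missing_strat)) {
    bad <- c(bad, paste0("accuracy.", missing_strat))
  }
  for (s in intersect(.STRATEGIES, names(params$accuracy))) {
    for (m in c("sensitivity", "specificity")) {
      v <- params$accuracy[[s]][[m]]
      note(is.null(v) || !is.finite(v) || v < 0 || v > 1, paste0(m, "_", s))
    }
  }
  cost_fields <- c("elective_dissection", "radical_dissection",
                   "resection_nodal_chemo", "followup_annual",
                   "recurrence_annual", "metastatic_annual")
  for (f in cost_fields) {
    v <- params$costs[[f]]
    note(is.null(v) || !is.finite(v) || v < 0, f)
  }
  for (s in .STRATEGIES) {
    v <- params$costs$exam[[s]]
    note(is.null(v) || !is.finite(v) || v < 0, paste0("exam_", s))
  }
  for (f in c("p_recurrence_tn", "p_recurrence_fp", "p_recurrence_tp",
              "p_recurrence_fn", "p_death_nplus", "p_death_metastatic")) {
    v <- params$transitions[[f]]
    note(is.null(v) || !is.finite(v) || v < 0 || v > 1, f)
  }
  econ <- params$economics
  note(!is.finite(econ$discount_rate) || econ$discount_rate < 0 ||
         econ$discount_rate > 1, "discount_rate")
  note(is.na(econ$horizon_years) || econ$horizon_years < 0, "horizon_years")
  note(!isTRUE(all.equal(econ$cycle_length_years, 1)), "cycle_length_years")
  if (nrow(params$uncertainty)) {
    known <- names(param_paths())
    unknown <- setdiff(params$uncertainty$parameter_id, known)
    if (length(unknown)) bad <- c(bad, paste0("uncertainty:", unknown))
    fam_ok <- params$uncertainty$family %in%
      c("beta", "lognormal", "uniform", "fixed")
    if (any(!fam_ok)) {
      bad <- c(bad, paste0("uncertainty family:",
                           params$uncertainty$parameter_id[!fam_ok]))
    }
  }
  if (length(bad)) {
    stop("invalid parameter set; offending field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

#' Serialize a parameter set back to YAML or JSON
#'
#' The written document round-trips losslessly through
#' [load_parameter_set()] (field-by-field equality).
#'
#' @param params An `nstage_params` object.
#' @param path Output file; `.json` extension selects JSON, anything
#'   else YAML.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  doc <- unclass(params)
  doc$uncertainty <- lapply(seq_len(nrow(params$uncertainty)), function(i) {
    as.list(params$uncertainty[i, , drop = FALSE])
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 15)
  }
  invisible(path)
}

# Map of parameter ids (as used by the uncertainty table, the DSA and
# the PSA) to their location inside an nstage_params object.
param_paths <- function() {
  paths <- list(
    cohort_size = c("epidemiology", "cohort_size"),
    initial_age = c("epidemiology", "initial_age"),
    prevalence_nodal = c("epidemiology", "prevalence_nodal"),
    prevalence_metastatic = c("epidemiology", "prevalence_metastatic"),
    elective_dissection = c("costs", "elective_dissection"),
    radical_dissection = c("costs", "radical_dissection"),
    resection_nodal_chemo = c("costs", "resection_nodal_chemo"),
    followup_annual = c("costs", "followup_annual"),
    recurrence_annual = c("costs", "recurrence_annual"),
    metastatic_annual = c("costs", "metastatic_annual"),
    p_recurrence_tn = c("transitions", "p_recurrence_tn"),
    p_recurrence_fp = c("transitions", "p_recurrence_fp"),
    p_recurrence_tp = c("transitions", "p_recurrence_tp"),
    p_recurrence_fn = c("transitions", "p_recurrence_fn"),
    p_death_nplus = c("transitions", "p_death_nplus"),
    p_death_metastatic = c("transitions", "p_death_metastatic"),
    discount_rate = c("economics", "discount_rate"),
    horizon_years = c("economics", "horizon_years")
  )
  for (s in .STRATEGIES) {
    paths[[paste0("sensitivity_", s)]] <- c("accuracy", s, "sensitivity")
    paths[[paste0("specificity_", s)]] <- c("accuracy", s, "specificity")
    paths[[paste0("exam_", s)]] <- c("costs", "exam", s)
  }
  paths
}

#' Read or replace one parameter by id
#'
#' Parameter ids are flat names such as `"sensitivity_PETCT"`,
#' `"exam_CT"` or `"p_recurrence_tn"`, matching the `parameter_id`
#' column of the uncertainty table.
#'
#' @param params An `nstage_params` object.
#' @param id Parameter id.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the numeric value; `param_set` returns
#'   the modified parameter set.
#' @export
param_get <- function(params, id) {
  path <- param_paths()[[id]]
  if (is.null(path)) stop("unknown parameter id: ", id, call. = FALSE)
  params[[path]]
}

#' @rdname param_get
#' @export
param_set <- function(params, id, value) {
  path <- param_paths()[[id]]
  if (is.null(path)) stop("unknown parameter id: ", id, call. = FALSE)
  params[[path]] <- value
  params
}

#' @export
print.nstage_params <- function(x, ...) {
  epi <- x$epidemiology
  cat("<nstage_params>\n")
  cat(sprintf("  cohort: %g patients, initial age %g\n",
              epi$cohort_size, epi$initial_age))
  cat(sprintf("  prevalence: nodal %.1f%%, metastatic %.1f%%\n",
              100 * epi$prevalence_nodal, 100 * epi$prevalence_metastatic))
  for (s in .STRATEGIES) {
    cat(sprintf("  %-5s sens %.3f spec %.3f exam EUR %g\n", s,
                x$accuracy[[s]]$sensitivity, x$accuracy[[s]]$specificity,
                x$costs$exam[[s]]))
  }
  cat(sprintf("  economics: discount %.1f%%, horizon %d y, half-cycle %s\n",
              100 * x$economics$discount_rate, x$economics$horizon_years,
              if (x$economics$half_cycle_correction) "on" else "off"))
  cat(sprintf("  uncertainty: %d parameter(s) with distributions\n",
              sum(x$uncertainty$family != "fixed")))
  invisible(x)
}
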