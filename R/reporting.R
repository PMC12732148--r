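#' Run configuration for the command-line workflows
#'
#' @param params_file Path to a YAML/JSON parameter file; `NULL` uses
#'   the packaged baseline.
#' @param lifetable_file Path to a two-column life-table CSV; `NULL`
#'   uses the default synthetic Gompertz table.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed, recorded in every output.
#' @param n_draws PSA draw count.
#' @param half_cycle `"trapezoid"` (half-cycle correction on) or
#'   `"end"` (end-of-cycle accounting).
#' @param longterm_cost `"annual"` or `"oneoff"` long-term cost accrual.
#' @return A list of class `run_config`.
#' @export
run_config <- function(params_file = NULL, lifetable_file = NULL,
                       out_dir = "nstagecea-out", seed = 1L,
                       n_draws = 1000L,
                       half_cycle = c("trapezoid", "end"),
                       longterm_cost = c("annual", "oneoff")) {
  for (f in c(params_file, lifetable_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("file not found: ", f, call. = FALSE)
    }
  }
  structure(list(params_file = params_file,
                 lifetable_file = lifetable_file,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_draws = as.integer(n_draws),
                 half_cycle = match.arg(half_cycle),
                 longterm_cost = match.arg(longterm_cost)),
            class = "run_config")
}

resolve_inputs <- function(config) {
  params <- if (is.null(config$params_file)) {
    baseline_parameters()
  } else {
    load_parameter_set(config$params_file)
  }
  params$economics$half_cycle_correction <- config$half_cycle == "trapezoid"
  lifetable <- if (is.null(config$lifetable_file)) {
    default_lifetable()
  } else {
    read_lifetable(config$lifetable_file)
  }
  list(params = params, lifetable = lifetable)
}

provenance_header <- function(config) {
  c(paste0("nstagecea ",
           as.character(utils::packageVersion("nstagecea"))),
    paste0("seed=", config$seed,
           " half_cycle=", config$half_cycle,
           " longterm_cost=", config$longterm_cost))
}

write_csv_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Per-strategy results table (branch costs and life years)
#'
#' One row per strategy/branch with patient counts, discounted costs and
#' life years, a per-strategy total row, and the exam-cost add-on —
#' the layout of the published economic-evaluation results table.
#'
#' @param outcomes Named list of `strategy_outcome` objects.
#' @return A data frame.
#' @export
table2_report <- function(outcomes) {
  rows <- lapply(outcomes, function(o) {
    br <- lapply(.BRANCHES, function(b) {
      x <- o$branches[[b]]
      data.frame(strategy = o$strategy, row = b, n_patients = x$count,
                 percent = 100 * x$count / o$cohort_size,
                 cost = x$total_discounted_cost, ly = x$total_discounted_ly,
                 stringsAsFactors = FALSE)
    })
    br <- do.call(rbind, br)
    rbind(br,
          data.frame(strategy = o$strategy, row = "TOTAL",
                     n_patients = o$cohort_size, percent = 100,
                     cost = o$total_cost - o$exam_cost, ly = o$total_ly),
          data.frame(strategy = o$strategy, row = "EXAM_COST",
                     n_patients = NA, percent = NA, cost = o$exam_cost,
                     ly = NA),
          data.frame(strategy = o$strategy, row = "TOTAL_WITH_EXAM",
                     n_patients = o$cohort_size, percent = 100,
                     cost = o$total_cost, ly = o$total_ly))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Comparison report (costs, life years, increments, ICER/dominance)
#'
#' Thin wrapper over [comparison_table()] that puts the intervention
#' first.
#'
#' @param outcomes Named list of `strategy_outcome` objects.
#' @param intervention Strategy treated as the new technology.
#' @return A data frame.
#' @export
table3_report <- function(outcomes, intervention = "PETCT") {
  ord <- c(intervention, setdiff(names(outcomes), intervention))
  comparison_table(outcomes[ord])
}

markdown_comparison <- function(tab) {
  fmt <- function(x, d = 2) ifelse(is.na(x), "", formatC(x, format = "f",
                                                         digits = d,
                                                         big.mark = ","))
  lines <- c(
    "| Strategy | Costs (EUR 2024) | Life years | dCOST | dLY | ICER (EUR/LY) | Verdict |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(tab)), function(i) {
      r <- tab[i, ]
      sprintf("| %s | %s | %s | %s | %s | %s | %s |", r$strategy,
              fmt(r$total_cost), fmt(r$total_ly, 3), fmt(r$delta_cost),
              fmt(r$delta_ly, 4), fmt(r$icer),
              ifelse(is.na(r$verdict), "", r$verdict))
    }, "")
  )
  lines
}

#' Run the base-case analysis and write publication-shaped reports
#'
#' Evaluates all three strategies on the configured parameter set and
#' life table and writes, under `config$out_dir`: `allocation.csv`,
#' `table2.csv` (per-branch results), `table3.csv` / `table3.json` /
#' `table3.md` (comparison), one per-cycle trace CSV per
#' strategy/branch, and `run_info.json` recording the package version,
#' seed and resolved toggles. Deterministic: identical configurations
#' produce byte-identical outputs.
#'
#' @param config A `run_config`.
#' @return The comparison data frame, invisibly.
#' @export
cmd_run <- function(config) {
  inp <- resolve_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0) {
    stop("output directory not writable: ", config$out_dir, call. = FALSE)
  }
  hdr <- provenance_header(config)
  outcomes <- lapply(.STRATEGIES, function(s) {
    evaluate_strategy(inp$params, s, inp$lifetable,
                      longterm_cost = config$longterm_cost)
  })
  names(outcomes) <- .STRATEGIES
  write_csv_report(allocation_table(inp$params),
                   file.path(config$out_dir, "allocation.csv"), hdr)
  write_csv_report(table2_report(outcomes),
                   file.path(config$out_dir, "table2.csv"), hdr)
  tab3 <- table3_report(outcomes)
  write_csv_report(tab3, file.path(config$out_dir, "table3.csv"), hdr)
  jsonlite::write_json(list(provenance = hdr, comparison = tab3),
                       file.path(config$out_dir, "table3.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(c(paste0("<!-- ", hdr, " -->"), markdown_comparison(tab3)),
             file.path(config$out_dir, "table3.md"))
  for (s in .STRATEGIES) {
    for (b in .BRANCHES) {
      write_csv_report(outcomes[[s]]$branches[[b]]$trace,
                       file.path(config$out_dir,
                                 sprintf("trace_%s_%s.csv", s, b)), hdr)
    }
  }
  jsonlite::write_json(
    list(package = "nstagecea",
         version = as.character(utils::packageVersion("nstagecea")),
         seed = config$seed, half_cycle = config$half_cycle,
         longterm_cost = config$longterm_cost,
         params_file = if (is.null(config$params_file)) "packaged baseline"
                       else config$params_file,
         lifetable = if (is.null(config$lifetable_file))
           "synthetic Gompertz (default calibration)"
         else config$lifetable_file),
    file.path(config$out_dir, "run_info.json"), auto_unbox = TRUE)
  invisible(tab3)
}

#' Write tornado (one-way DSA) reports
#'
#' One CSV per comparison (intervention vs each other strategy), rows
#' sorted by descending spread.
#'
#' @param config A `run_config`.
#' @param intervention Strategy treated as the new technology.
#' @param wtp Willingness-to-pay used for the INMB ranking.
#' @return Named list of tornado data frames, invisibly.
#' @export
cmd_dsa <- function(config, intervention = "PETCT", wtp = 27117) {
  inp <- resolve_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  res <- list()
  for (cp in setdiff(.STRATEGIES, intervention)) {
    tor <- one_way_dsa(inp$params, inp$lifetable, intervention, cp,
                       wtp = wtp, longterm_cost = config$longterm_cost)
    write_csv_report(tor, file.path(config$out_dir,
                                    sprintf("tornado_%s_vs_%s.csv",
                                            intervention, cp)), hdr)
    res[[paste0(intervention, "_vs_", cp)]] <- tor
  }
  invisible(res)
}

#' Run the PSA and write draw cloud, CEAC and summary
#'
#' Writes `psa_draws.csv` (per-draw costs/LYs and incremental deltas),
#' `ceac.csv` and `psa_summary.json` (dominance and quadrant
#' probabilities, seed, draw count).
#'
#' @param config A `run_config`.
#' @param intervention Strategy compared against all others.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(config, intervention = "PETCT") {
  inp <- resolve_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  psa <- run_psa(inp$params, inp$lifetable, n_draws = config$n_draws,
                 seed = config$seed, intervention = intervention,
                 longterm_cost = config$longterm_cost)
  write_csv_report(psa$draws, file.path(config$out_dir, "psa_draws.csv"),
                   hdr)
  write_csv_report(psa$ceac, file.path(config$out_dir, "ceac.csv"), hdr)
  jsonlite::write_json(
    list(provenance = hdr, n_draws = psa$n_draws, seed = psa$seed,
         p_dominant = as.list(psa$p_dominant),
         quadrants = lapply(psa$quadrants, as.list)),
    file.path(config$out_dir, "psa_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(psa)
}

#' Write a synthetic Gompertz life table
#'
#' @param config A `run_config` (only `out_dir` and provenance fields
#'   are used).
#' @param target_le,at_age,b Calibration: see [calibrate_gompertz()].
#' @param path Output CSV path; default `lifetable.csv` in the output
#'   directory.
#' @return The path, invisibly.
#' @export
cmd_synth_lifetable <- function(config, target_le = 20, at_age = 63,
                                b = 0.09, path = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gp <- calibrate_gompertz(target_le, at_age, b)
  lt <- make_gompertz_lifetable(gp$a, gp$b, 0L, 120L)
  if (is.null(path)) path <- file.path(config$out_dir, "lifetable.csv")
  write_lifetable(lt, path,
                  header = c(provenance_header(config),
                             sprintf("gompertz a=%.8g b=%.4g (LE %.4g at age %g)",
                                     gp$a, gp$b, target_le, at_age)))
  invisible(path)
}
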