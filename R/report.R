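# Configuration, the end-to-end analysis driver, and the JSON report.

#' Analysis configuration
#'
#' Bundles every run setting so that the report can echo full provenance:
#' a rerun from the reported configuration reproduces the reported numbers.
#'
#' @param seed integer seed (required).
#' @param n_samples samples per coefficient index.
#' @param scale sampling box upper bound.
#' @param dual_mode `"all"` or `"paper"` (extended-matrix row selection).
#' @param max_i largest characteristic-polynomial coefficient index.
#' @param max_confirm cap on eigenvalue confirmations.
#' @param steady_tol,instability_tol,evec_tol tolerances for the steady
#'   state precondition, the instability band, and eigenvector asymmetry.
#' @param simulate logical: run the ODE confirmation ([detect_smsb()]) on
#'   each confirmed state.
#' @param epsilon,t_end,ee_threshold simulation settings (see
#'   [detect_smsb()]).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(seed, n_samples = 10000L, scale = 2,
                            dual_mode = "all", max_i = 5L, max_confirm = 25L,
                            steady_tol = 1e-8, instability_tol = 1e-9,
                            evec_tol = 1e-7, simulate = FALSE,
                            epsilon = 1e-10, t_end = 1e6,
                            ee_threshold = 0.1) {
  if (missing(seed)) stop("seed is required")
  stopifnot(steady_tol > 0, instability_tol > 0, evec_tol > 0,
            scale > 0, n_samples >= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 scale = scale, dual_mode = match.arg(dual_mode,
                                                      c("all", "paper")),
                 max_i = as.integer(max_i),
                 max_confirm = as.integer(max_confirm),
                 steady_tol = steady_tol, instability_tol = instability_tol,
                 evec_tol = evec_tol, simulate = isTRUE(simulate),
                 epsilon = epsilon, t_end = t_end,
                 ee_threshold = ee_threshold),
            class = "analysis_config")
}

report_schema_version <- "1.0"

#' Run the full analysis on a network file and write a report
#'
#' Parses the network, verifies pseudochirality, runs [sna_sampling()],
#' optionally confirms each sampled state by ODE simulation, and writes a
#' machine-readable JSON report (plus a human-readable summary to the
#' console).
#'
#' @param network_path path to a `.crn` file (or a `reaction_network`).
#' @param config an [analysis_config()].
#' @param report_path optional JSON output path.
#' @return the report, a list of class `analysis_report`, invisibly when
#'   written to file.
#' @export
run_analysis <- function(network_path, config, report_path = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  net <- if (inherits(network_path, "reaction_network")) network_path
         else read_network(network_path)
  chiral <- check_pseudochiral(net)
  rep0 <- sna_sampling(net, chiral, seed = config$seed,
                       n_samples = config$n_samples, scale = config$scale,
                       dual_mode = config$dual_mode, max_i = config$max_i,
                       max_confirm = config$max_confirm)
  sims <- NULL
  if (config$simulate && length(rep0$confirmed)) {
    sims <- lapply(rep0$confirmed, function(cs) {
      sm <- detect_smsb(net, chiral, cs$state, epsilon = config$epsilon,
                        t_end = config$t_end,
                        ee_threshold = config$ee_threshold)
      list(smsb = as.logical(sm),
           ee_plus = attr(sm, "ee_plus"), ee_minus = attr(sm, "ee_minus"))
    })
  }
  report <- structure(list(
    schema_version = report_schema_version,
    network = net$name,
    order = chiral$order,
    verdict = rep0$verdict,
    reason = rep0$reason,
    n_extreme_currents = rep0$cone$s,
    per_i = lapply(rep0$per_i, function(rec) list(
      i = rec$i,
      polynomial = format(as_cpoly(rec$polynomial)),
      status = rec$status,
      n_samples_found = nrow(rec$samples),
      n_tried = rec$n_tried)),
    confirmed_states = lapply(rep0$confirmed, function(cs) list(
      j = as.numeric(cs$j),
      concentrations = as.list(cs$state$concentrations),
      rate_constants = as.list(cs$state$rate_constants),
      lambda = if (!is.null(cs$lambda))
        list(re = Re(cs$lambda), im = Im(cs$lambda)) else NULL,
      max_re = cs$max_re)),
    simulations = sims,
    provenance = list(config = unclass(config),
                      package_version =
                        as.character(utils::packageVersion("chiralnet")))
  ), class = "analysis_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis of '", x$network, "' (pseudochiral order ", x$order, ")\n",
      sep = "")
  cat("  verdict:", x$verdict,
      if (!is.null(x$reason)) paste0("(", x$reason, ")") else "", "\n")
  cat("  extreme currents:", x$n_extreme_currents, "\n")
  for (rec in x$per_i)
    cat(sprintf("  i=%d: %s  [%s]\n", rec$i, rec$status, rec$polynomial))
  cat("  confirmed states:", length(x$confirmed_states), "\n")
  if (!is.null(x$simulations)) {
    ok <- vapply(x$simulations, function(s) isTRUE(s$smsb), TRUE)
    cat("  SMSB confirmed by simulation:", sum(ok), "of", length(ok), "\n")
  }
  invisible(x)
}

#' Minimal structural validation of a report
#' @param report an `analysis_report` or a list parsed from report JSON.
#' @return TRUE, or an error describing the first violated requirement.
#' @export
validate_report <- function(report) {
  req <- c("schema_version", "network", "order", "verdict", "per_i",
           "confirmed_states", "provenance")
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report lacks fields: ", paste(miss, collapse = ", "))
  if (!report$verdict %in% c("accept", "reject", "inconclusive"))
    stop("invalid verdict: ", report$verdict)
  if (is.null(report$provenance$config$seed))
    stop("report provenance lacks the seed")
  TRUE
}
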