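#' Write an exploration result to a report directory
#'
#' Serialises a `"solution_space"` object to `report.json` (configuration,
#' counts, posterior probabilities and intervals, per-trial trace,
#' termination, taxonomy label) plus one `solutions/P<i>.csv` partition file
#' per unique solution, so results are reproducible and consumable outside R.
#'
#' @param x A `"solution_space"` object.
#' @param dir Output directory (created if needed).
#' @param classification Optional `"space_classification"`; computed with
#'   default policy when omitted.
#' @return `dir`, invisibly.
#' @export
write_solution_space <- function(x, dir, classification = NULL) {
  stopifnot(inherits(x, "solution_space"))
  if (is.null(classification)) classification <- classify_space(x)
  dir.create(file.path(dir, "solutions"), recursive = TRUE,
             showWarnings = FALSE)
  post <- posterior(x$model)
  report <- list(
    package_version = as.character(utils::packageVersion("solspace")),
    config = x$config,
    model = model_state(x$model),
    posterior = list(mean = post$mean, lower = post$lower,
                     upper = post$upper),
    termination = list(cause = x$termination$cause,
                       dominant_index = x$termination$dominant_index),
    classification = list(label = classification$label,
                          n_valid = classification$n_valid,
                          rationale = as.list(classification$rationale)),
    validity = lapply(x$validity, function(v)
      list(is_valid = v$is_valid, is_degenerate = v$is_degenerate,
           reasons = as.list(v$reasons), k = v$k,
           intra_edges = v$intra_edges, inter_edges = v$inter_edges)),
    trace = x$trace
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  for (i in seq_along(x$solutions)) {
    write_partition(x$solutions[[i]],
                    file.path(dir, "solutions", paste0("P", i, ".csv")))
  }
  invisible(dir)
}

#' Read back a written exploration report
#'
#' Restores the model state, posterior, termination, classification label and
#' unique solutions from a directory written by [write_solution_space()].
#' The returned list is sufficient for classification and agreement analysis;
#' it is not a full `"solution_space"` object (the graph itself is not
#' stored).
#'
#' @param dir Report directory.
#' @export
read_solution_space <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop_input("no report.json under ", dir)
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  files <- sort(list.files(file.path(dir, "solutions"), pattern = "^P\\d+\\.csv$",
                           full.names = TRUE))
  ord <- order(as.integer(sub("^P(\\d+)\\.csv$", "\\1", basename(files))))
  report$solutions <- lapply(files[ord], read_partition)
  report$model <- model_from_state(report$model)
  report
}

#' One-line textual summary of an exploration
#'
#' Renders the five headline fields of a result — convergence cause, trials,
#' total solutions, valid solutions, solution-space type — as a named
#' character vector, the row format used for cross-algorithm comparison
#' tables.
#'
#' @param x A `"solution_space"` object.
#' @param classification Optional precomputed classification.
#' @export
render_summary_row <- function(x, classification = NULL) {
  stopifnot(inherits(x, "solution_space"))
  if (is.null(classification)) classification <- classify_space(x)
  cause <- c(STABILISATION = "Stabilisation", SEPARATION = "Separation",
             MAX_TRIALS = "max. trials", RUNNING = "running")[
               x$termination$cause]
  c(Algorithm = x$config$algorithm,
    Convergence = unname(cause),
    Trials = as.character(nrow(x$trace)),
    `Total solutions` = as.character(n_unique_solutions(x)),
    `Valid solutions` = as.character(classification$n_valid),
    `Type of solution space` = classification$label)
}
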