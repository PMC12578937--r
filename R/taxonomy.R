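#' Classify a solution space into the five-class taxonomy
#'
#' Assigns exactly one of five labels to an explored solution space, by a
#' decision cascade over the number of valid solutions, the termination cause
#' and the posterior:
#'
#' 1. **EMPTY** — no valid solutions remain (validity per
#'    [validate_partition()]; degenerate solutions count as invalid when
#'    `treat_degenerate_as_invalid = TRUE`, the default).
#' 2. **SINGLE** — exactly one valid solution and termination by
#'    stabilisation.
#' 3. **DOMINANT** — termination by separation with a valid dominant
#'    solution.
#' 4. **SPARSE** — novel valid solutions in at least `sparse_ratio` of
#'    trials (the "n_s close to t" regime of incoherent, low-probability
#'    partitions). A sparse run typically fails to converge and stops at
#'    `t_max`, but it can also terminate by stabilisation: with many
#'    near-equal small probabilities every credible interval shrinks below
#'    `delta`, so the novel-solution rate, not the termination cause, is the
#'    defining condition.
#' 5. **MULTIPLE** — otherwise: several solutions with overlapping credible
#'    intervals and no decisive separation.
#'
#' The boundary between MULTIPLE and SPARSE is a recognised grey area;
#' `sparse_ratio` makes the operational choice explicit and is echoed in the
#' rationale. Reaching `t_max` alone does not force SPARSE: a run stopped at
#' `t_max` with a handful of recurring solutions is MULTIPLE. The rationale
#' also reports whether `max_i p_i^l < 0.5` held, flagging a discrepancy when
#' the overlap-based decision disagrees with that secondary condition.
#'
#' @param x A `"solution_space"` object from [explore()].
#' @param treat_degenerate_as_invalid Should degenerate solutions (more
#'   inter- than intra-community edges) count as invalid, possibly demoting
#'   the space to EMPTY?
#' @param sparse_ratio Minimum fraction of trials that discovered a novel
#'   valid solution for the SPARSE label (default 0.8).
#' @return An object of class `"space_classification"`: list with `label`,
#'   `dominant_index` (or `NA`), `n_valid`, `n_solutions`, `rationale`
#'   (named logical vector of the predicates evaluated).
#' @export
classify_space <- function(x, treat_degenerate_as_invalid = TRUE,
                           sparse_ratio = 0.8) {
  stopifnot(inherits(x, "solution_space"))
  if (sparse_ratio <= 0 || sparse_ratio > 1)
    stop_input("`sparse_ratio` must be in (0, 1]")

  valid <- vapply(x$validity, function(v) {
    v$is_valid && !(treat_degenerate_as_invalid && v$is_degenerate)
  }, logical(1))
  n_valid <- sum(valid)
  n_s <- n_unique_solutions(x)
  trials <- nrow(x$trace)
  cause <- x$termination$cause
  dominant <- x$termination$dominant_index

  post <- if (x$model$t > 0) posterior(x$model) else NULL
  max_lower <- if (is.null(post)) NA_real_ else max(post$lower)
  novel_idx <- x$trace$solution[x$trace$novel]
  novel_idx <- novel_idx[!is.na(novel_idx)]
  novel_fraction <- if (trials > 0) sum(valid[novel_idx]) / trials else 0

  rationale <- c(
    no_valid_solutions = n_valid == 0L,
    single_valid_stabilised = n_valid == 1L && cause == "STABILISATION",
    separated = cause == "SEPARATION" && !is.na(dominant) &&
      dominant <= n_s && valid[dominant],
    reached_t_max = cause == "MAX_TRIALS",
    novel_fraction_ge_sparse_ratio = novel_fraction >= sparse_ratio,
    max_lower_bound_below_half = isTRUE(max_lower < 0.5)
  )

  label <-
    if (rationale[["no_valid_solutions"]]) "EMPTY"
    else if (rationale[["single_valid_stabilised"]]) "SINGLE"
    else if (rationale[["separated"]]) "DOMINANT"
    else if (rationale[["novel_fraction_ge_sparse_ratio"]]) "SPARSE"
    else "MULTIPLE"

  structure(list(
    label = label,
    dominant_index = if (label == "DOMINANT") dominant else NA_integer_,
    n_valid = n_valid,
    n_solutions = n_s,
    trials = trials,
    novel_fraction = novel_fraction,
    sparse_ratio = sparse_ratio,
    treat_degenerate_as_invalid = treat_degenerate_as_invalid,
    multiple_condition_discrepancy = label == "MULTIPLE" &&
      !rationale[["max_lower_bound_below_half"]],
    rationale = rationale
  ), class = "space_classification")
}

#' @export
print.space_classification <- function(x, ...) {
  cat("Solution space type:", x$label, "\n")
  if (!is.na(x$dominant_index))
    cat("  dominant solution: P", x$dominant_index, "\n", sep = "")
  cat("  solutions:", x$n_solutions, "(valid:", x$n_valid, ") over",
      x$trials, "trials\n")
  cat("  rationale:\n")
  for (nm in names(x$rationale))
    cat("    ", nm, ": ", x$rationale[[nm]], "\n", sep = "")
  if (isTRUE(x$multiple_condition_discrepancy))
    cat("  note: overlap-based MULTIPLE decision disagrees with the",
        "max-lower-bound < 0.5 condition\n")
  invisible(x)
}

#' Check consistency with a known k-fold symmetry
#'
#' When a graph admits `k_symmetric` symmetry-equivalent partitions, no single
#' solution is expected to exceed roughly `1/k` posterior probability. This
#' diagnostic reports whether the largest estimated probability is consistent
#' with `1/k`, judged by whether `1/k` lies inside that solution's credible
#' interval.
#'
#' @param x A `"solution_space"` object.
#' @param k_symmetric The number of symmetry-equivalent partitions (>= 2);
#'   symmetry detection is up to the user.
#' @return A list with `consistent` (logical), `expected` (1/k),
#'   `max_p_hat`, `interval`, and `message` (human-readable text).
#' @export
symmetry_note <- function(x, k_symmetric) {
  stopifnot(inherits(x, "solution_space"))
  if (!is.numeric(k_symmetric) || k_symmetric < 2)
    stop_input("`k_symmetric` must be >= 2")
  post <- posterior(x$model)
  i <- which.max(post$mean)
  expected <- 1 / k_symmetric
  consistent <- post$lower[i] <= expected && expected <= post$upper[i]
  msg <- if (consistent) {
    sprintf("max p_hat = %.3f: consistent with %d-fold symmetry (1/k = %.3f inside [%.3f, %.3f])",
            post$mean[i], k_symmetric, expected, post$lower[i], post$upper[i])
  } else {
    sprintf("max p_hat = %.3f: inconsistent with %d-fold symmetry (1/k = %.3f outside [%.3f, %.3f])",
            post$mean[i], k_symmetric, expected, post$lower[i], post$upper[i])
  }
  list(consistent = consistent, expected = expected,
       max_p_hat = post$mean[i],
       interval = c(lower = post$lower[i], upper = post$upper[i]),
       message = msg)
}
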