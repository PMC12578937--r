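#' Explore the solution space of a community-detection algorithm
#'
#' Repeatedly runs a community-detection algorithm on a graph, permuting the
#' input ordering independently at each trial, and models the probabilities
#' of the unique partitions discovered with a sequential Dirichlet-Multinomial
#' posterior. Each trial's partition is matched against the solutions found so
#' far by exact set-partition equality (equivalent to NMI = 1); a match
#' increments that solution's count, a novel partition expands the model.
#' Exploration stops at *stabilisation* (all credible intervals narrower than
#' `delta`), *separation* (one solution unambiguously dominant), or after
#' `t_max` trials.
#'
#' Permuting the input ordering at every trial (the default) makes the trials
#' exchangeable and counteracts input-ordering bias: with `permute = FALSE` an
#' order-sensitive deterministic algorithm returns the same partition every
#' trial and the solution space is undersampled.
#'
#' @param graph An undirected, named [igraph::igraph] (see [check_graph()]).
#' @param adapter A [community_adapter()], an algorithm code accepted by
#'   [builtin_adapter()] (`"eb"`, `"lv"`, `"ld"`, `"lp"`, `"im"`, `"wt"`), or
#'   a function `graph -> partition`.
#' @param delta Stabilisation tolerance on credible-interval widths
#'   (default 0.1).
#' @param t_max Maximum number of trials (default 50).
#' @param gamma0 Dirichlet prior count per solution (default 1).
#' @param level Credible level (default 0.95).
#' @param t_min Minimum trials before convergence can be declared
#'   (default 10).
#' @param seed Integer seed governing all randomness (per-trial permutation
#'   and algorithm stochasticity); per-trial seeds are pre-derived so each
#'   trial is individually reproducible.
#' @param permute Permute node and edge order before every trial?
#' @param validity_policy `"count_all"` (default): every returned partition
#'   is counted in the model and validity is assessed per solution for the
#'   taxonomy. `"drop_invalid"`: invalid partitions are recorded in the trace
#'   but not counted in the model.
#' @return An object of class `"solution_space"`: a list with
#'   \describe{
#'     \item{solutions}{unique partitions in discovery order}
#'     \item{model}{the fitted [dirichlet_model()]}
#'     \item{validity}{one [validate_partition()] report per solution}
#'     \item{trace}{data frame with one row per trial: `trial`, `solution`
#'       (matched index), `novel`, `cause`}
#'     \item{history}{per-trial posterior snapshots (mean/lower/upper)}
#'     \item{termination}{final `"convergence_status"`}
#'     \item{config}{the exploration settings, including the seed}
#'   }
#'   Methods: [print.solution_space()], [summary.solution_space()],
#'   [coef.solution_space()] (posterior means), [confint.solution_space()]
#'   (credible intervals), [plot.solution_space()] (posterior trajectories),
#'   [classify_space()] (taxonomy label).
#' @examples
#' g <- ring_of_cliques(4, 5, central = TRUE)
#' fit <- explore(g, "lp", seed = 1)
#' fit
#' coef(fit)
#' classify_space(fit)
#' @export
explore <- function(graph, adapter, delta = 0.1, t_max = 50, gamma0 = 1,
                    level = 0.95, t_min = 10, seed = NULL, permute = TRUE,
                    validity_policy = c("count_all", "drop_invalid")) {
  check_graph(graph)
  adapter <- as_adapter(adapter)
  validity_policy <- match.arg(validity_policy)
  if (t_max < 1) stop_input("`t_max` must be >= 1")

  trial_seeds <- derive_seeds(seed, t_max)
  model <- dirichlet_model(gamma0 = gamma0, level = level)

  solutions <- list()
  tokens <- character(0)
  validity <- list()
  trace <- data.frame(trial = integer(0), solution = integer(0),
                      novel = logical(0), cause = character(0),
                      stringsAsFactors = FALSE)
  history <- list()
  termination <- NULL

  for (t in seq_len(t_max)) {
    p <- with_seed(trial_seeds[t], {
      g_t <- if (permute) permute_graph(graph) else graph
      tryCatch(run_adapter(adapter, g_t),
               error = function(e)
                 stop_input("trial ", t, " failed: ", conditionMessage(e)))
    })

    token <- canonical_form(p)
    idx <- match(token, tokens)
    novel <- is.na(idx)
    counted <- TRUE
    if (novel) {
      report <- validate_partition(graph, p)
      if (validity_policy == "drop_invalid" && !report$is_valid) {
        counted <- FALSE
        idx <- NA_integer_
      } else {
        solutions[[length(solutions) + 1L]] <- p
        tokens <- c(tokens, token)
        validity[[length(validity) + 1L]] <- report
        idx <- length(solutions)
        model <- observe(model, NULL)
      }
    } else if (validity_policy == "drop_invalid" && !validity[[idx]]$is_valid) {
      counted <- FALSE
      idx <- NA_integer_
    } else {
      model <- observe(model, idx)
    }

    status <- check_convergence(model, delta = delta, t_max = t_max,
                                t_min = t_min)
    trace <- rbind(trace, data.frame(trial = t, solution = idx, novel = novel,
                                     cause = status$cause,
                                     stringsAsFactors = FALSE))
    history[t] <- list(if (model$t > 0) posterior(model))
    termination <- status
    if (status$converged) break
  }
  if (!termination$converged && termination$cause == "RUNNING") {
    # loop exhausted without convergence (can happen under drop_invalid when
    # the model saw fewer observations than trials)
    termination$cause <- "MAX_TRIALS"
  }

  structure(list(
    solutions = solutions,
    model = model,
    validity = validity,
    trace = trace,
    history = history,
    termination = termination,
    config = list(algorithm = adapter$name, params = adapter$params,
                  delta = delta, t_max = t_max, gamma0 = gamma0,
                  level = level, t_min = t_min, seed = seed,
                  permute = permute, validity_policy = validity_policy,
                  n_v = igraph::vcount(graph), n_e = igraph::ecount(graph)),
    call = match.call()
  ), class = "solution_space")
}

#' Number of unique solutions in a solution space
#' @param x A `"solution_space"` object.
#' @export
n_unique_solutions <- function(x) {
  stopifnot(inherits(x, "solution_space"))
  length(x$solutions)
}

#' @export
print.solution_space <- function(x, digits = 3, ...) {
  cat("Solution space exploration:", x$config$algorithm, "on",
      x$config$n_v, "nodes /", x$config$n_e, "edges\n")
  cat("  trials:", nrow(x$trace), "  unique solutions:",
      n_unique_solutions(x), "\n")
  cat("  termination:", x$termination$cause, "\n")
  if (x$model$t > 0) {
    post <- posterior(x$model)
    tab <- data.frame(
      count = x$model$counts,
      p_hat = round(post$mean, digits),
      lower = round(post$lower, digits),
      upper = round(post$upper, digits),
      k = vapply(x$solutions, n_communities, numeric(1)),
      valid = vapply(x$validity, `[[`, logical(1), "is_valid"),
      degenerate = vapply(x$validity, `[[`, logical(1), "is_degenerate"))
    rownames(tab) <- paste0("P", seq_len(nrow(tab)))
    print(tab)
  }
  invisible(x)
}

#' @export
summary.solution_space <- function(object, ...) {
  cls <- classify_space(object, ...)
  structure(list(space = object, classification = cls),
            class = "summary.solution_space")
}

#' @export
print.summary.solution_space <- function(x, ...) {
  print(x$space)
  cat("\n")
  print(x$classification)
  invisible(x)
}

#' Posterior solution probabilities
#'
#' @param object A `"solution_space"` object.
#' @param ... Unused.
#' @return Named vector of posterior means, one per unique solution.
#' @export
coef.solution_space <- function(object, ...) {
  post <- posterior(object$model)
  stats::setNames(post$mean, paste0("P", seq_along(post$mean)))
}

#' Credible intervals for solution probabilities
#'
#' @param object A `"solution_space"` object.
#' @param parm Solution indices (default all).
#' @param level Ignored; the level is fixed at model-fitting time.
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper`.
#' @export
confint.solution_space <- function(object, parm = NULL, level = NULL, ...) {
  if (!is.null(level) && level != object$model$level)
    warning("credible level is fixed at exploration time (",
            object$model$level, ")", call. = FALSE)
  post <- posterior(object$model)
  ci <- cbind(lower = post$lower, upper = post$upper)
  rownames(ci) <- paste0("P", seq_len(nrow(ci)))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Plot posterior trajectories of an exploration
#'
#' Draws the posterior probability of each unique solution as a function of
#' the trial number, with shaded credible intervals.
#'
#' @param x A `"solution_space"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.solution_space <- function(x, ...) {
  n_t <- length(x$history)
  k <- n_unique_solutions(x)
  if (n_t == 0 || k == 0) stop_input("nothing to plot")
  traj <- function(field, i) {
    vapply(x$history, function(h) {
      v <- h[[field]]
      if (i <= length(v)) v[i] else NA_real_
    }, numeric(1))
  }
  cols <- grDevices::hcl.colors(max(k, 2), "Dark 2")
  graphics::plot(NULL, xlim = c(1, n_t), ylim = c(0, 1),
                 xlab = "trial", ylab = expression(hat(p)[i]),
                 main = paste("Solution space:", x$config$algorithm), ...)
  for (i in seq_len(k)) {
    lo <- traj("lower", i); up <- traj("upper", i); mu <- traj("mean", i)
    ok <- which(!is.na(mu))
    graphics::polygon(c(ok, rev(ok)), c(lo[ok], rev(up[ok])),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(ok, mu[ok], col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = paste0("P", seq_len(k)),
                   col = cols[seq_len(k)], lwd = 2, bty = "n")
  invisible(x)
}
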