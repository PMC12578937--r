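#' Sequential Dirichlet-Multinomial model over unique solutions
#'
#' The exploration loop models the probability of each unique partition with
#' a Dirichlet-Multinomial posterior: after observing counts
#' `c = (c_1, ..., c_k)` over `k` unique solutions in `t = sum(c)` trials,
#'
#'   `p | c ~ Dirichlet(gamma0 + c_1, ..., gamma0 + c_k)`
#'
#' where `gamma0` is a weakly informative prior count assigned equally to all
#' solutions (default 1, the uniform prior). The model is initialised with a
#' single dimension, reflecting the belief that at least one solution exists,
#' and is expanded each time a novel solution appears. The posterior depends
#' on the counts only, so permuting the observation order leaves the model
#' state unchanged (exchangeability).
#'
#' @param gamma0 Prior count per solution (> 0).
#' @param level Credible level for the Beta marginal intervals, in (0, 1).
#' @return An object of class `"dirichlet_model"` with fields `gamma0`,
#'   `level`, `counts` (integer vector) and `t` (total observations).
#' @seealso [observe()], [posterior()], [check_convergence()]
#' @export
dirichlet_model <- function(gamma0 = 1, level = 0.95) {
  if (!is.numeric(gamma0) || gamma0 <= 0) stop_input("`gamma0` must be > 0")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_input("`level` must be in (0, 1)")
  structure(list(gamma0 = gamma0, level = level, counts = 0L, t = 0L),
            class = "dirichlet_model")
}

n_solutions <- function(m) length(m$counts)

#' Record one observation in the model
#'
#' When the trial's partition matched unique solution `index`, that count is
#' incremented. When it was novel (`index = NULL`), the model is expanded
#' with a new dimension starting at count 1 — except for the very first
#' observation, which fills the initial dimension.
#'
#' @param m A [dirichlet_model()].
#' @param index Matched solution index (1-based), or `NULL` for a novel
#'   solution.
#' @return The updated model.
#' @export
observe <- function(m, index = NULL) {
  stopifnot(inherits(m, "dirichlet_model"))
  k <- n_solutions(m)
  if (is.null(index)) {
    if (m$t == 0L && k == 1L) {
      m$counts[1L] <- 1L            # first observation fills the initial dimension
    } else {
      m$counts <- c(m$counts, 1L)
    }
  } else {
    if (!is.numeric(index) || index < 1L || index > k)
      stop_input("`index` out of range 1..", k)
    m$counts[index] <- m$counts[index] + 1L
  }
  m$t <- m$t + 1L
  m
}

#' Posterior means and credible intervals
#'
#' Posterior means are `(gamma0 + c_i) / (k * gamma0 + t)` and sum to one.
#' Equal-tailed credible intervals at the model's level come from the Beta
#' marginals `Beta(gamma0 + c_i, (k - 1) * gamma0 + t - c_i)`. With a single
#' known solution (`k = 1`) the second Beta parameter vanishes and the
#' posterior is a point mass: the mean is 1 with a zero-width interval.
#'
#' @param m A [dirichlet_model()] with at least one observation.
#' @return A list with `mean`, `lower`, `upper` (numeric vectors of length k).
#' @export
posterior <- function(m) {
  stopifnot(inherits(m, "dirichlet_model"))
  if (m$t < 1L) stop_input("posterior undefined before the first observation")
  k <- n_solutions(m)
  a <- m$gamma0 + m$counts
  total <- k * m$gamma0 + m$t
  mean <- a / total
  if (k == 1L) {
    return(list(mean = 1, lower = 1, upper = 1))
  }
  b <- total - a
  alpha <- (1 - m$level) / 2
  list(mean = mean,
       lower = stats::qbeta(alpha, a, b),
       upper = stats::qbeta(1 - alpha, a, b))
}

#' Convergence check for the exploration loop
#'
#' Exploration stops when the posterior makes the solution space statistically
#' unambiguous:
#'
#' * **Stabilisation** — every credible interval is narrower than `delta`:
#'   `max_i (p_i^u - p_i^l) <= delta`.
#' * **Separation** — one solution's lower bound exceeds every other
#'   solution's upper bound, making it unambiguously dominant.
#'
#' Stabilisation is evaluated first; if both hold, the cause is recorded as
#' stabilisation and the dominant index is still reported. Convergence is only
#' declared after `t_min` trials, guarding against premature termination when
#' few trials have run (with one known solution the interval has zero width
#' from the outset). If neither condition holds by `t_max` trials the status
#' is `MAX_TRIALS`.
#'
#' @param m A [dirichlet_model()].
#' @param delta Stabilisation tolerance on interval widths (> 0).
#' @param t_max Maximum number of trials (>= 1).
#' @param t_min Minimum trials before convergence can be declared.
#' @return An object of class `"convergence_status"`: list with `converged`,
#'   `cause` (`"STABILISATION"`, `"SEPARATION"`, `"MAX_TRIALS"`,
#'   `"RUNNING"`), `dominant_index` (or `NA`), `max_width`.
#' @export
check_convergence <- function(m, delta = 0.1, t_max = 50, t_min = 10) {
  stopifnot(inherits(m, "dirichlet_model"))
  if (!is.numeric(delta) || delta <= 0) stop_input("`delta` must be > 0")
  if (!is.numeric(t_max) || t_max < 1) stop_input("`t_max` must be >= 1")

  status <- function(cause, dominant = NA_integer_, width = NA_real_) {
    structure(list(converged = cause %in% c("STABILISATION", "SEPARATION"),
                   cause = cause, dominant_index = dominant,
                   max_width = width),
              class = "convergence_status")
  }

  if (m$t < 1L) return(status("RUNNING"))
  post <- posterior(m)
  widths <- post$upper - post$lower
  k <- n_solutions(m)

  # dominant solution, if any: lower bound above every other upper bound
  dominant <- NA_integer_
  if (k > 1L) {
    i_star <- which.max(post$mean)
    if (post$lower[i_star] > max(post$upper[-i_star])) dominant <- i_star
  }

  if (m$t >= t_min) {
    if (max(widths) <= delta)
      return(status("STABILISATION", dominant, max(widths)))
    if (!is.na(dominant))
      return(status("SEPARATION", dominant, max(widths)))
  }
  if (m$t >= t_max) return(status("MAX_TRIALS", dominant, max(widths)))
  status("RUNNING", dominant, max(widths))
}

#' @export
print.dirichlet_model <- function(x, digits = 3, ...) {
  cat("Dirichlet-Multinomial model: k =", n_solutions(x), "solutions, t =",
      x$t, "trials (gamma0 =", x$gamma0, ", level =", x$level, ")\n")
  if (x$t > 0) {
    post <- posterior(x)
    tab <- data.frame(count = x$counts,
                      p_hat = round(post$mean, digits),
                      lower = round(post$lower, digits),
                      upper = round(post$upper, digits))
    rownames(tab) <- paste0("P", seq_len(nrow(tab)))
    print(tab)
  }
  invisible(x)
}

#' @export
print.convergence_status <- function(x, ...) {
  cat("Convergence:", x$cause)
  if (!is.na(x$dominant_index)) cat(" (dominant solution:", x$dominant_index, ")")
  cat("\n")
  invisible(x)
}

# JSON-serialisable state, used by the report writers.
model_state <- function(m) {
  list(gamma0 = m$gamma0, level = m$level, counts = m$counts, t = m$t)
}

model_from_state <- function(s) {
  m <- dirichlet_model(gamma0 = s$gamma0, level = s$level)
  m$counts <- as.integer(s$counts)
  m$t <- as.integer(s$t)
  m
}
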