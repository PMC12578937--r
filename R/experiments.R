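#' Reference partitions of the ring-of-cliques-with-centre benchmark
#'
#' Constructs, by definition, the symmetric candidate partitions of a
#' ring of `n_cliques` cliques with a central hub: `P1..P<nc>` assign the hub
#' to clique 1..nc (each clique otherwise its own community), and
#' `P_singleton` isolates the hub as a single-node community. Without a
#' central node the single clique-per-community partition `P0` is returned.
#'
#' These analytic references let experiment code categorise algorithm output
#' exactly (via [canonical_form()]) regardless of the labels the algorithm
#' used.
#'
#' @inheritParams ring_of_cliques
#' @param central Include the central hub (default `TRUE`)?
#' @return Named list of partitions.
#' @export
rc_reference_partitions <- function(n_cliques, clique_size, central = TRUE) {
  nc <- as.integer(n_cliques); cs <- as.integer(clique_size)
  base <- stats::setNames(
    as.character(rep(seq_len(nc), each = cs)),
    paste0("c", rep(seq_len(nc), each = cs), "_n", rep(seq_len(cs), nc)))
  if (!central) return(list(P0 = base))
  refs <- lapply(seq_len(nc), function(i) c(base, centre = as.character(i)))
  names(refs) <- paste0("P", seq_len(nc))
  refs$P_singleton <- c(base, centre = as.character(nc + 1L))
  refs
}

# Match a partition against a named list of reference partitions; returns the
# reference name or "OTHER".
match_reference <- function(p, refs) {
  token <- canonical_form(p)
  ref_tokens <- vapply(refs, canonical_form, character(1))
  hit <- names(refs)[match(token, ref_tokens)]
  if (is.na(hit)) "OTHER" else hit
}

#' Input-ordering bias experiment
#'
#' Characterises an algorithm's sensitivity to input ordering on the
#' ring-of-cliques benchmark by running it `n_runs` times on the graph as
#' generated (fixed ordering) and `n_runs` times on a freshly permuted copy
#' per run. Each run's partition is matched exactly against the analytic
#' reference partitions ([rc_reference_partitions()]); anything else counts
#' as `OTHER`.
#'
#' Two tests summarise the tables:
#' * per condition, a chi-square goodness-of-fit of the frequencies over the
#'   symmetric hub-in-clique categories against uniformity (the graph's
#'   symmetry makes them equally likely for an unbiased algorithm);
#' * between conditions, a chi-square homogeneity test of the two frequency
#'   tables. An order-invariant algorithm is statistically indistinguishable
#'   across conditions (p above `alpha`); an order-sensitive deterministic
#'   one concentrates its fixed-order runs on a single category.
#'
#' This experiment deliberately bypasses the Bayesian stopping rule: it uses
#' a fixed number of runs because it characterises the algorithm, not the
#' posterior.
#'
#' @param adapter Adapter, algorithm code, or function (see [explore()]).
#' @param n_cliques,clique_size,central Benchmark parameters
#'   (see [ring_of_cliques()]).
#' @param n_runs Runs per condition (default 1000).
#' @param seed Integer seed governing all randomness.
#' @param alpha Significance level for the homogeneity verdict (default
#'   0.01).
#' @return An object of class `"bias_experiment"`: list with `algorithm`,
#'   `n_runs`, `categories`, `fixed` and `permuted` count tables,
#'   `gof` (per-condition chi-square GOF against uniformity over the
#'   symmetric categories), `homogeneity` (chi-square test between
#'   conditions), `order_sensitive` (verdict at `alpha`), and capability
#'   flags `saw_multiple` and `saw_singleton`.
#' @examples
#' \donttest{
#' be <- bias_experiment("lp", 4, 5, n_runs = 200, seed = 1)
#' be
#' }
#' @export
bias_experiment <- function(adapter, n_cliques, clique_size, central = TRUE,
                            n_runs = 1000, seed = NULL, alpha = 0.01) {
  adapter <- as_adapter(adapter)
  if (n_runs < 1) stop_input("`n_runs` must be >= 1")
  g <- ring_of_cliques(n_cliques, clique_size, central = central)
  refs <- rc_reference_partitions(n_cliques, clique_size, central = central)
  categories <- c(names(refs), "OTHER")
  symmetric <- if (central) paste0("P", seq_len(n_cliques)) else names(refs)

  seeds <- derive_seeds(seed, 2L * n_runs)
  run_one <- function(s, permuted) {
    with_seed(s, {
      g_run <- if (permuted) permute_graph(g) else g
      match_reference(run_adapter(adapter, g_run), refs)
    })
  }
  fixed_cats <- vapply(seeds[seq_len(n_runs)], run_one, character(1),
                       permuted = FALSE)
  perm_cats <- vapply(seeds[n_runs + seq_len(n_runs)], run_one, character(1),
                      permuted = TRUE)

  tab <- function(x) table(factor(x, levels = categories))
  fixed <- tab(fixed_cats); permuted <- tab(perm_cats)

  gof <- lapply(list(fixed = fixed, permuted = permuted), function(tt) {
    counts <- as.vector(tt[symmetric])
    if (sum(counts) == 0 || length(counts) < 2) return(NULL)
    suppressWarnings(stats::chisq.test(counts))
  })

  both <- rbind(fixed = as.vector(fixed), permuted = as.vector(permuted))
  keep <- colSums(both) > 0
  homogeneity <- if (sum(keep) >= 2) {
    suppressWarnings(stats::chisq.test(both[, keep, drop = FALSE]))
  } else NULL
  order_sensitive <- if (is.null(homogeneity)) NA else
    homogeneity$p.value < alpha

  structure(list(
    algorithm = adapter$name,
    n_runs = n_runs,
    categories = categories,
    symmetric_categories = symmetric,
    fixed = fixed,
    permuted = permuted,
    gof = gof,
    homogeneity = homogeneity,
    alpha = alpha,
    order_sensitive = order_sensitive,
    saw_multiple = length(unique(perm_cats)) > 1L,
    saw_singleton = central && "P_singleton" %in% c(fixed_cats, perm_cats)
  ), class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("Input-ordering bias experiment:", x$algorithm, "(", x$n_runs,
      "runs per condition )\n")
  tab <- rbind(fixed = as.vector(x$fixed), permuted = as.vector(x$permuted))
  colnames(tab) <- x$categories
  print(tab)
  if (!is.null(x$homogeneity))
    cat(sprintf("homogeneity chi-square p = %.4g -> %s (alpha = %g)\n",
                x$homogeneity$p.value,
                if (isTRUE(x$order_sensitive)) "order-sensitive"
                else "order-invariant", x$alpha))
  cat("multiple solutions observed:", x$saw_multiple,
      " singleton hub community observed:", x$saw_singleton, "\n")
  invisible(x)
}

#' Solution-space sweep over benchmark sizes
#'
#' Runs [explore()] followed by [classify_space()] for every combination of
#' algorithm, number of cliques and clique size on the ring-of-cliques-with-
#' centre benchmark, and tabulates the taxonomy label per cell. Per-cell
#' failures are recorded as `"ERROR"` and the sweep continues.
#'
#' @param adapters Character vector of algorithm codes and/or a (optionally
#'   named) list of adapters.
#' @param nc_values,cs_values Integer vectors of benchmark sizes.
#' @param central Include the central hub?
#' @param seed Master seed; every cell receives its own derived seed.
#' @param ... Further arguments for [explore()] (`delta`, `t_max`, ...).
#' @return An object of class `"space_sweep"`: list with `grid` (data frame
#'   `algorithm`, `n_cliques`, `clique_size`, `label`, `n_solutions`,
#'   `trials`) and `prevalent` (modal label per algorithm).
#' @export
sweep_solution_spaces <- function(adapters, nc_values, cs_values,
                                  central = TRUE, seed = NULL, ...) {
  if (length(nc_values) == 0 || length(cs_values) == 0)
    stop_input("`nc_values` and `cs_values` must be nonempty")
  if (!is.list(adapters)) adapters <- as.list(adapters)
  adapters <- lapply(adapters, as_adapter)
  names(adapters) <- vapply(adapters, `[[`, character(1), "name")

  cells <- expand.grid(algorithm = names(adapters), n_cliques = nc_values,
                       clique_size = cs_values, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    out <- tryCatch({
      g <- ring_of_cliques(cell$n_cliques, cell$clique_size, central = central)
      fit <- explore(g, adapters[[cell$algorithm]], seed = seeds[i], ...)
      cls <- classify_space(fit)
      data.frame(cell, label = cls$label, n_solutions = cls$n_solutions,
                 trials = cls$trials, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cell, label = "ERROR", n_solutions = NA_integer_,
                 trials = NA_integer_, stringsAsFactors = FALSE)
    })
    out
  })
  grid <- do.call(rbind, rows)
  prevalent <- vapply(split(grid$label[grid$label != "ERROR"],
                            grid$algorithm[grid$label != "ERROR"]),
                      function(l) names(sort(table(l), decreasing = TRUE))[1],
                      character(1))
  structure(list(grid = grid, prevalent = prevalent),
            class = "space_sweep")
}

#' @export
print.space_sweep <- function(x, ...) {
  cat("Solution-space sweep over", nrow(x$grid), "cells\n")
  cat("Prevalent type per algorithm:\n")
  for (a in names(x$prevalent)) cat("  ", a, ":", x$prevalent[[a]], "\n")
  print(utils::head(x$grid, 12))
  if (nrow(x$grid) > 12) cat("... (", nrow(x$grid) - 12, " more rows)\n", sep = "")
  invisible(x)
}
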