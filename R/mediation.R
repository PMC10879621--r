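# Coerce an effect+se pair: numeric c(beta, se), list(beta=, se=), or an
# mr_estimate.
.effect_se <- function(x, what) {
  if (inherits(x, "mr_estimate")) return(c(x$beta, x$se))
  if (is.list(x) && !is.null(x$beta) && !is.null(x$se)) return(c(x$beta, x$se))
  if (is.numeric(x) && length(x) == 2) return(unname(x))
  stop(what, " must be an effect/standard-error pair: c(beta, se), ",
       "list(beta=, se=), or an mr_estimate", call. = FALSE)
}

#' Two-step MR mediation decomposition
#'
#' Decomposes a total exposure-outcome effect `c` into the mediator-carried
#' indirect effect `a * b` and the direct effect `c' = c - a * b`, where `a`
#' is the exposure-mediator effect (MR step 1) and `b` the mediator-outcome
#' effect (MR step 2, instrumented by the mediator's own variants). All three
#' inputs must be on a common additive (log or SD) scale.
#'
#' Standard errors use the product-of-coefficients delta method,
#' `se(ab) = sqrt(b^2 se_a^2 + a^2 se_b^2)`, treating the two MR steps as
#' independent (non-overlapping source studies), and
#' `se(c') = sqrt(se_c^2 + se(ab)^2)`. The proportion mediated is
#' `ab / c` with delta-method standard error
#' `|ab/c| sqrt(se(ab)^2/(ab)^2 + se_c^2/c^2)` and a symmetric 95% interval;
#' a seeded simulation interval (draws of a, b, c from their sampling
#' normals) is available via `ci_method = "simulation"`.
#'
#' @param a,b,c Effect/standard-error pairs (numeric `c(beta, se)`,
#'   `list(beta=, se=)`, or [mr_estimate()] objects) for the
#'   exposure-mediator, mediator-outcome, and total exposure-outcome
#'   effects.
#' @param ci_method `"delta"` (default) or `"simulation"` for the
#'   proportion-mediated interval.
#' @param n_draws Simulation draws when `ci_method = "simulation"`.
#' @param seed Seed for the simulation interval (required then).
#' @return A list of class `mediation_result` with the three inputs, the
#'   indirect and direct effects with standard errors, and `proportion`,
#'   `proportion_se`, `proportion_ci`.
#' @export
#' @examples
#' two_step_mediation(a = c(0.5, 0.1), b = c(0.4, 0.1), c = c(1.0, 0.1))
two_step_mediation <- function(a, b, c, ci_method = c("delta", "simulation"),
                               n_draws = 10000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  a <- .effect_se(a, "a")
  b <- .effect_se(b, "b")
  c <- .effect_se(c, "c")
  if (any(c(a[2], b[2], c[2]) <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  if (c[1] == 0) {
    stop("proportion mediated undefined: total effect c is zero", call. = FALSE)
  }
  indirect <- a[1] * b[1]
  se_indirect <- sqrt(b[1]^2 * a[2]^2 + a[1]^2 * b[2]^2)
  c_prime <- c[1] - indirect
  se_c_prime <- sqrt(c[2]^2 + se_indirect^2)
  proportion <- indirect / c[1]
  proportion_se <- if (indirect == 0) {
    se_indirect / abs(c[1])
  } else {
    abs(proportion) * sqrt(se_indirect^2 / indirect^2 + c[2]^2 / c[1]^2)
  }
  proportion_ci <- if (ci_method == "delta") {
    proportion + c(-1.96, 1.96) * proportion_se
  } else {
    with_seed(seed, {
      draws <- rnorm(n_draws, a[1], a[2]) * rnorm(n_draws, b[1], b[2]) /
        rnorm(n_draws, c[1], c[2])
      unname(stats::quantile(draws, c(0.025, 0.975)))
    })
  }
  structure(list(a = a[1], se_a = a[2], b = b[1], se_b = b[2],
                 c = c[1], se_c = c[2],
                 indirect = indirect, se_indirect = se_indirect,
                 c_prime = c_prime, se_c_prime = se_c_prime,
                 proportion = proportion, proportion_se = proportion_se,
                 proportion_ci = proportion_ci, ci_method = ci_method),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation decomposition\n")
  cat(sprintf("  a (exposure -> mediator): %.6g (se %.6g)\n", x$a, x$se_a))
  cat(sprintf("  b (mediator -> outcome):  %.6g (se %.6g)\n", x$b, x$se_b))
  cat(sprintf("  c (total effect):         %.6g (se %.6g)\n", x$c, x$se_c))
  cat(sprintf("  indirect (a x b):         %.6g (se %.6g)\n", x$indirect, x$se_indirect))
  cat(sprintf("  direct (c' = c - a x b):  %.6g (se %.6g)\n", x$c_prime, x$se_c_prime))
  cat(sprintf("  proportion mediated:      %.1f%% [95%% CI %.1f%%, %.1f%%]\n",
              100 * x$proportion, 100 * x$proportion_ci[1],
              100 * x$proportion_ci[2]))
  invisible(x)
}

.run_methods <- function(table, methods, n_boot, seed) {
  fits <- list()
  for (m in methods) {
    fits[[m]] <- switch(m,
      ivw = mr_ivw(table),
      ivw_fixed = mr_ivw(table, model = "fixed"),
      egger = mr_egger(table),
      weighted_median = mr_weighted_median(table, n_boot = n_boot, seed = seed),
      simple_mode = mr_mode(table, weighted = FALSE, n_boot = n_boot, seed = seed + 1L),
      weighted_mode = mr_mode(table, weighted = TRUE, n_boot = n_boot, seed = seed + 2L),
      stop("unknown method: ", m, call. = FALSE))
  }
  fits
}

#' Bidirectional two-sample MR
#'
#' Assesses reciprocal causation between two traits: the forward direction
#' selects instruments from the first trait's summary statistics and
#' estimates its effect on the second; the reverse direction swaps the
#' roles, selecting instruments from the second trait's statistics.
#'
#' @param exposure_stats,outcome_stats Summary statistics for the two traits.
#' @param ld LD matrix covering the forward candidates.
#' @param config [selection_config()] for the forward direction.
#' @param ld_reverse LD matrix for the reverse candidates (default `ld`).
#' @param config_reverse Selection config for the reverse direction (default
#'   same as forward).
#' @param methods Estimators to run per direction (see [mr_ivw()] etc.).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Integer seed for all stochastic steps.
#' @return A list with `forward` and `reverse` elements, each holding the
#'   selected `instruments`, the harmonized `table`, and the `estimates`
#'   list.
#' @export
bidirectional_mr <- function(exposure_stats, outcome_stats, ld,
                             config = selection_config(), ld_reverse = ld,
                             config_reverse = config,
                             methods = c("ivw", "egger", "weighted_median"),
                             n_boot = 1000, seed = 1) {
  run_dir <- function(from, to, ld_m, cfg, seed_offset) {
    ins <- select_instruments(from, ld_m, cfg, verbose = FALSE)
    tab <- harmonize(ins, to)
    feasible <- methods[vapply(methods, function(m) {
      m %in% c("ivw", "ivw_fixed") || nrow(.retained(tab)) >= 3
    }, logical(1))]
    list(instruments = ins, table = tab,
         estimates = .run_methods(tab, feasible, n_boot, seed + seed_offset))
  }
  list(forward = run_dir(exposure_stats, outcome_stats, ld, config, 0L),
       reverse = run_dir(outcome_stats, exposure_stats, ld_reverse,
                         config_reverse, 10L))
}
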