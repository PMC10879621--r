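#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' fixed-effect IVW estimate, `Q = sum(w_j (r_j - beta_fixed)^2)`,
#' chi-square with `J - 1` degrees of freedom under homogeneity. The
#' Higgins I-squared, `max(0, (Q - df)/Q)`, is reported as a convenience
#' summary of the excess-dispersion fraction.
#'
#' @inheritParams mr_ivw
#' @return A list of class `mr_heterogeneity` with `q`, `df`, `pval`, `i2`.
#' @export
cochran_q <- function(table, order = "first") {
  t <- .require_snps(table, 2, "Cochran's Q")
  r <- .table_ratios(t, order = order)
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta)^2)
  df <- nrow(r) - 1
  structure(list(q = q, df = df,
                 pval = pchisq(q, df = df, lower.tail = FALSE),
                 i2 = if (q > 0) max(0, (q - df) / q) else 0),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.4g (I2 = %.1f%%)\n",
              x$q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the [mr_egger()] regression estimates the average
#' pleiotropic effect of the instruments; a non-zero intercept indicates
#' directional pleiotropy.
#'
#' @inheritParams mr_ivw
#' @return A list with `estimate`, `se`, `pval`.
#' @export
egger_intercept_test <- function(table) {
  fit <- mr_egger(table)
  list(estimate = fit$extra$intercept, se = fit$extra$intercept_se,
       pval = fit$extra$intercept_pval)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' statistic is `RSS = sum(w_j (beta_out_j - b_loo_j beta_exp_j)^2)` with
#' `b_loo_j` the leave-one-out fixed-effect IVW slope and `w_j = se_out^-2`.
#' Its null distribution is simulated parametrically: per replicate, exposure
#' and outcome effects are redrawn from normals centred on the observed
#' exposure effects and the leave-one-out predictions, and the RSS is
#' recomputed on the simulated table. The global p-value uses add-one
#' smoothing, `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`, so it is never exactly
#' zero; per-SNP outlier p-values compare each observed weighted residual
#' with its simulated distribution and are Bonferroni-multiplied by the
#' number of SNPs.
#'
#' @inheritParams mr_ivw
#' @param n_sim Number of null-simulation replicates (default 1000).
#' @param seed Integer seed (required).
#' @param outlier_alpha Significance level for flagging outliers after
#'   Bonferroni adjustment (default 0.05).
#' @return A list of class `mr_presso` with `global_rss`, `global_p`,
#'   `outlier_p` (named, adjusted), `outlier_ids`, `n_sim`, `seed`.
#' @export
mr_presso <- function(table, n_sim = 1000, seed, outlier_alpha = 0.05) {
  t <- .require_snps(table, 4, "MR-PRESSO")
  if (n_sim < 1) stop("n_sim must be at least 1", call. = FALSE)
  J <- nrow(t)
  bx <- t$beta_exp
  by <- t$beta_out
  w <- t$se_out^-2
  loo_slope <- function(bx, by) {
    s1 <- sum(w * bx * by)
    s2 <- sum(w * bx^2)
    (s1 - w * bx * by) / (s2 - w * bx^2)
  }
  b_loo <- loo_slope(bx, by)
  resid_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(resid_obs)

  sims <- with_seed(seed, {
    bx_star <- matrix(rnorm(J * n_sim, mean = bx, sd = t$se_exp), nrow = J)
    by_star <- matrix(rnorm(J * n_sim, mean = b_loo * bx, sd = t$se_out), nrow = J)
    s1 <- colSums(w * bx_star * by_star)
    s2 <- colSums(w * bx_star^2)
    num <- sweep(-(w * bx_star * by_star), 2, s1, "+")
    den <- sweep(-(w * bx_star^2), 2, s2, "+")
    b_loo_star <- num / den
    resid_star <- w * (by_star - b_loo_star * bx_star)^2
    list(rss = colSums(resid_star), resid = resid_star)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(sims$resid >= resid_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * J)
  names(p_adj) <- t$snp_id
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_p = p_adj,
                 outlier_ids = t$snp_id[p_adj < outlier_alpha],
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global RSS = %.4g, p = %.4g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator on the table with each SNP removed in turn; the
#' final row is the all-SNP estimate. Large shifts when a single SNP is
#' dropped indicate that SNP drives the pooled result.
#'
#' @inheritParams mr_ivw
#' @return A `data.frame` with columns `excluded`, `n_snps`, `beta`, `se`,
#'   `pval`; the last row has `excluded = "none"`.
#' @export
leave_one_out <- function(table, model = "multiplicative_random") {
  t <- .require_snps(table, 2, "leave-one-out analysis")
  J <- nrow(t)
  one <- function(tab, label) {
    fit <- mr_ivw(tab, model = model)
    data.frame(excluded = label, n_snps = fit$n_snps, beta = fit$beta,
               se = fit$se, pval = fit$pval, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(J), function(j) one(t[-j, , drop = FALSE], t$snp_id[j]))
  rows[[J + 1]] <- one(t, "none")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot-ready scatter and funnel tables
#'
#' The scatter table holds the per-SNP exposure and outcome effects with
#' their standard errors plus one fitted line per requested method; the
#' funnel table holds each Wald ratio against its precision `1/se_ratio`.
#'
#' @inheritParams mr_ivw
#' @param methods Character vector among `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_mode"`, `"weighted_mode"`; fitted lines
#'   use point estimates only. May be empty.
#' @return A list with `scatter`, `fits`, `funnel` data.frames.
#' @export
funnel_and_scatter_data <- function(table, methods = c("ivw", "egger")) {
  t <- .retained(table)
  if (nrow(t) == 0) stop("no instruments in harmonized table", call. = FALSE)
  r <- .table_ratios(t)
  scatter <- data.frame(snp_id = r$snp_id, beta_exp = t$beta_exp,
                        se_exp = t$se_exp, beta_out = t$beta_out,
                        se_out = t$se_out, stringsAsFactors = FALSE)
  funnel <- data.frame(snp_id = r$snp_id, ratio = r$ratio,
                       precision = 1 / r$se_ratio, stringsAsFactors = FALSE)
  fit_one <- function(method) {
    sl_int <- switch(method,
      ivw = c(sum(r$weight * r$ratio) / sum(r$weight), 0),
      egger = {
        fit <- mr_egger(t)
        c(fit$beta, fit$extra$intercept)
      },
      weighted_median = c(.weighted_median(r$ratio, r$weight), 0),
      simple_mode = c(.mode_point(r$ratio, rep(1, nrow(r)), 1), 0),
      weighted_mode = c(.mode_point(r$ratio, r$weight, 1), 0),
      stop("unknown method: ", method, call. = FALSE))
    data.frame(method = method, slope = sl_int[1], intercept = sl_int[2],
               stringsAsFactors = FALSE)
  }
  fits <- if (length(methods) > 0) {
    do.call(rbind, lapply(methods, fit_one))
  } else {
    data.frame(method = character(0), slope = numeric(0),
               intercept = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(fits) <- NULL
  list(scatter = scatter, fits = fits, funnel = funnel)
}
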