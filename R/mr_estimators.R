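#' Construct an MR estimate object
#'
#' Container for one method's causal-effect estimate on the additive
#' (log/SD) scale, with the exponentiated effect and its 95% interval
#' (`exp(beta +/- 1.96 se)`) attached for reporting.
#'
#' @param method Method name.
#' @param beta,se Estimate and standard error on the additive scale.
#' @param pval Two-sided p-value.
#' @param n_snps Number of instruments used.
#' @param extra Named list of method-specific fields.
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, pval, n_snps, extra = list()) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n_snps = as.integer(n_snps), extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP%s\n", x$method, x$n_snps,
              if (x$n_snps == 1) "" else "s"))
  cat(sprintf("  beta = %.6g (se %.6g), p = %.4g\n", x$beta, x$se, x$pval))
  cat(sprintf("  OR = %.4g, 95%% CI (%.4g, %.4g)\n", x$or_, x$ci_low, x$ci_high))
  if (!is.null(x$extra$intercept)) {
    cat(sprintf("  intercept = %.6g (se %.6g), p = %.4g\n",
                x$extra$intercept, x$extra$intercept_se, x$extra$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             pval = x$pval, or_ = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio of the SNP-outcome effect to the SNP-exposure effect. The
#' first-order standard error is `se_out / |beta_exp|`; the second-order
#' variant additionally propagates the exposure-side error,
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param beta_exp,se_exp,beta_out,se_out Per-SNP effects and standard errors
#'   (vectorized).
#' @param order `"first"` (default) or `"second"` standard error.
#' @param snp_id Optional identifiers carried through (used in error
#'   messages and the returned table).
#' @return A `data.frame` with columns `snp_id`, `ratio`, `se_ratio`, and
#'   inverse-variance `weight`.
#' @export
#' @examples
#' wald_ratio(0.1, 0.02, 0.2, 0.05)  # ratio 2, se 0.5
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       order = c("first", "second"), snp_id = NULL) {
  order <- match.arg(order)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_along(beta_exp))
  zero <- beta_exp == 0
  if (any(zero)) {
    stop("Wald ratio undefined for SNP(s) with zero exposure effect: ",
         paste(snp_id[zero], collapse = ", "), call. = FALSE)
  }
  ratio <- beta_out / beta_exp
  se_ratio <- if (order == "first") {
    se_out / abs(beta_exp)
  } else {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  data.frame(snp_id = snp_id, ratio = ratio, se_ratio = se_ratio,
             weight = se_ratio^-2, stringsAsFactors = FALSE)
}

# Ratio estimates from the retained rows of a harmonized table.
.table_ratios <- function(table, order = "first") {
  t <- .retained(table)
  if (nrow(t) == 0) stop("no instruments in harmonized table", call. = FALSE)
  wald_ratio(t$beta_exp, t$se_exp, t$beta_out, t$se_out, order = order,
             snp_id = if ("snp_id" %in% names(t)) t$snp_id else NULL)
}

.require_snps <- function(table, k, method) {
  t <- .retained(table)
  if (nrow(t) < k) {
    stop(sprintf("%s requires at least %d instruments (got %d)",
                 method, k, nrow(t)), call. = FALSE)
  }
  t
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect meta-analysis of the per-SNP Wald ratios,
#' `beta = sum(w_j r_j) / sum(w_j)` with `w_j = se_ratio_j^-2`, equivalent to
#' weighted least squares of `beta_out` on `beta_exp` through the origin with
#' weights `se_out^-2` (first-order ratio standard errors). Under the
#' multiplicative random-effects model (the default) the fixed-effect
#' standard error `(sum w_j)^-1/2` is scaled by
#' `max(1, sqrt(Q / (J - 1)))`, so homogeneous tables are never
#' down-weighted and overdispersed ones are inflated.
#'
#' @param table Harmonized instrument table (see [harmonize()]).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @param order Wald-ratio standard-error order, `"first"` or `"second"`.
#' @return An [mr_estimate()] with the Q statistic in `extra$q`.
#' @export
mr_ivw <- function(table, model = c("multiplicative_random", "fixed"),
                   order = "first") {
  model <- match.arg(model)
  r <- .table_ratios(table, order = order)
  J <- nrow(r)
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- if (J >= 2) sum(w * (r$ratio - beta)^2) else NA_real_
  scale <- if (model == "multiplicative_random" && J >= 2) {
    max(1, sqrt(q / (J - 1)))
  } else {
    1
  }
  se <- se_fixed * scale
  pval <- 2 * pnorm(-abs(beta / se))
  mr_estimate("ivw", beta, se, pval, J,
              extra = list(model = model, q = q, se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure effects
#' with an unconstrained intercept (weights `se_out^-2`), after orienting
#' every SNP so its exposure effect is non-negative (required for the
#' estimator's identifiability). The slope estimates the causal effect under
#' the InSIDE assumption; the intercept estimates average directional
#' pleiotropy. Standard errors from the weighted fit are scaled by
#' `max(1, sqrt(RSS_w / (J - 2)))` and p-values use a t distribution with
#' `J - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An [mr_estimate()] for the slope with `intercept`,
#'   `intercept_se`, `intercept_pval` in `extra`.
#' @export
mr_egger <- function(table) {
  t <- .require_snps(table, 3, "MR-Egger")
  J <- nrow(t)
  s <- ifelse(t$beta_exp < 0, -1, 1)
  bx <- t$beta_exp * s
  by <- t$beta_out * s
  w <- t$se_out^-2
  fit <- stats::lm.wfit(x = cbind(intercept = 1, slope = bx), y = by, w = w)
  coefs <- fit$coefficients
  rss_w <- sum(w * fit$residuals^2)
  sigma2 <- rss_w / (J - 2)
  xtwx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  ses <- sqrt(max(1, sigma2) * diag(xtwx_inv))
  pvals <- 2 * pt(-abs(coefs / ses), df = J - 2)
  mr_estimate("mr_egger", coefs[["slope"]], ses[2], pvals[2], J,
              extra = list(intercept = coefs[["intercept"]],
                           intercept_se = ses[1], intercept_pval = pvals[1],
                           rss_w = rss_w))
}

# Weighted-median point estimate: standardized inclusive cumulative weights
# p_j = (S_j - w_j/2) / sum(w); linear interpolation of the sorted ratios at
# p = 0.5.
.weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  approx(p, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Parametric bootstrap over the per-SNP effects shared by the median and
# mode estimators: redraw beta_exp and beta_out from normals centred on the
# observed values, recompute the point estimator, return the replicate SD.
.parametric_boot_se <- function(t, n_boot, seed, estimator) {
  J <- nrow(t)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(J, t$beta_exp, t$se_exp)
      by <- rnorm(J, t$beta_out, t$se_out)
      bx[bx == 0] <- .Machine$double.eps
      estimator(by / bx, (bx / t$se_out)^2)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP Wald ratios, consistent when valid
#' instruments carry more than half of the total weight. The standard error
#' comes from a seeded parametric bootstrap that redraws the per-SNP
#' exposure and outcome effects from their sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the standard error (default 1000).
#' @param seed Integer seed for the bootstrap (required; the estimator never
#'   reads the global RNG state implicitly).
#' @return An [mr_estimate()] with `n_boot` in `extra`.
#' @export
mr_weighted_median <- function(table, n_boot = 1000, seed) {
  t <- .require_snps(table, 3, "the weighted-median estimator")
  r <- .table_ratios(t)
  est <- .weighted_median(r$ratio, r$weight)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  se <- .parametric_boot_se(t, n_boot, seed, .weighted_median)
  se <- max(se, .Machine$double.eps)
  mr_estimate("weighted_median", est, se, 2 * pnorm(-abs(est / se)), nrow(t),
              extra = list(n_boot = n_boot, seed = seed))
}

# Mode point estimate: normal-kernel density over the ratios with a modified
# Silverman bandwidth, argmax on a 512-point grid spanning the ratio range
# +/- 3 bandwidths.
.mode_point <- function(ratio, w, bandwidth_factor) {
  J <- length(ratio)
  s <- sd(ratio)
  m <- mad(ratio)
  h0 <- 0.9 * min(s, if (m > 0) m else s) * J^(-1 / 5)
  if (!is.finite(h0) || h0 <= 0) h0 <- 1e-8 * max(1, max(abs(ratio)))
  h <- bandwidth_factor * h0
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
  dens <- colSums(dnorm(outer(ratio, grid, "-") / h) * (w / sum(w)))
  grid[which.max(dens)]
}

#' Mode-based estimators
#'
#' The argmax of a normal-kernel density over the per-SNP Wald ratios, with
#' unit weights (simple mode) or inverse-variance weights (weighted mode).
#' The bandwidth is the modified Silverman rule
#' `0.9 min(sd, mad) J^(-1/5)` times `bandwidth_factor`, the density is
#' evaluated on a 512-point grid spanning the ratio range plus three
#' bandwidths, and the standard error uses the same parametric bootstrap as
#' [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param weighted Use inverse-variance weights (`TRUE`) or unit weights
#'   (`FALSE`, the simple mode).
#' @param bandwidth_factor Multiplier on the Silverman bandwidth (default 1).
#' @return An [mr_estimate()] with the bandwidth in `extra`.
#' @export
mr_mode <- function(table, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed) {
  t <- .require_snps(table, 3, "the mode estimator")
  r <- .table_ratios(t)
  w <- if (weighted) r$weight else rep(1, nrow(r))
  est <- .mode_point(r$ratio, w, bandwidth_factor)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  se <- .parametric_boot_se(t, n_boot, seed, function(ratio, weight) {
    .mode_point(ratio, if (weighted) weight else rep(1, length(ratio)),
                bandwidth_factor)
  })
  se <- max(se, .Machine$double.eps)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              est, se, 2 * pnorm(-abs(est / se)), nrow(t),
              extra = list(bandwidth_factor = bandwidth_factor,
                           n_boot = n_boot, seed = seed))
}

.as_record <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop(what, " must be a single record", call. = FALSE)
    x <- as.list(x)
  }
  if (is.null(x$beta) || is.null(x$se)) {
    stop(what, " must carry beta and se fields", call. = FALSE)
  }
  x
}

#' Summary-data MR (SMR) for a gene-expression exposure
#'
#' Uses the top cis-eQTL as the single instrument for expression. The effect
#' of expression on the outcome is the ratio `b_xy = beta_gwas / beta_eqtl`;
#' the test statistic combines the two z-statistics as
#' `T = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)`, chi-square with 1 df,
#' and the standard error is the second-order ratio standard error
#' (equivalently `|b_xy| / sqrt(T)` whenever `T > 0`).
#'
#' @param top_eqtl SNP-expression association (single record or list with
#'   `beta`, `se`), alleles already harmonized to `gwas`.
#' @param gwas SNP-outcome association at the same SNP.
#' @return An [mr_estimate()] with `t_smr` in `extra`.
#' @export
mr_smr <- function(top_eqtl, gwas) {
  e <- .as_record(top_eqtl, "top_eqtl")
  g <- .as_record(gwas, "gwas")
  if (e$beta == 0) stop("SMR undefined for a zero eQTL effect", call. = FALSE)
  b_xy <- g$beta / e$beta
  se <- sqrt(g$se^2 / e$beta^2 + g$beta^2 * e$se^2 / e$beta^4)
  z2_g <- (g$beta / g$se)^2
  z2_e <- (e$beta / e$se)^2
  t_smr <- if (z2_g == 0) 0 else z2_g * z2_e / (z2_g + z2_e)
  pval <- pchisq(t_smr, df = 1, lower.tail = FALSE)
  mr_estimate("smr", b_xy, se, pval, 1, extra = list(t_smr = t_smr))
}
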