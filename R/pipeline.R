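#' Study configuration
#'
#' Bundles all inputs of a full two-step MR mediation study. Summary
#' statistics and LD matrices may be given as in-memory objects or as file
#' paths (read with [read_sumstats()] / [read_ld_matrix()]).
#'
#' @param exposure,outcome Summary statistics (or paths) for the exposure
#'   and outcome traits.
#' @param mediator Summary statistics (or path) for the mediator trait at
#'   the exposure instruments; `NULL` disables the mediation arms.
#' @param eqtl cis-eQTL summary statistics (or path) for the mediator gene;
#'   `NULL` disables the mediator-outcome arm.
#' @param ld LD matrix (or path) covering exposure and outcome candidates.
#' @param gene Mediator gene locus: list with `chrom`, `start`, `end`.
#' @param selection [selection_config()] for trait instruments.
#' @param selection_eqtl [selection_config()] for eQTL instruments.
#' @param methods Estimators run on every arm.
#' @param b_method Estimator feeding the mediator-outcome effect `b` into
#'   the mediation algebra: `"ivw"` (default) or `"smr"`.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param n_sim MR-PRESSO null-simulation replicates.
#' @param seed Integer seed consumed by every stochastic step.
#' @param alpha Significance level for the report (default 0.05).
#' @param output_dir Optional directory; when set, [run_study()] writes its
#'   tables there as TSV files as they are produced.
#' @return A list of class `study_config`.
#' @export
study_config <- function(exposure, outcome, mediator = NULL, eqtl = NULL,
                         ld, gene = NULL,
                         selection = selection_config(),
                         selection_eqtl = selection_config(),
                         methods = c("ivw", "egger", "weighted_median",
                                     "simple_mode", "weighted_mode"),
                         b_method = c("ivw", "smr"),
                         n_boot = 1000, n_sim = 1000, seed = 1,
                         alpha = 0.05, output_dir = NULL) {
  b_method <- match.arg(b_method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  load_stats <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (!file.exists(x)) stop("file not found for ", what, ": ", x, call. = FALSE)
      return(read_sumstats(x))
    }
    validate_sumstats(x)
  }
  load_ld <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("LD matrix file not found: ", x, call. = FALSE)
      return(read_ld_matrix(x))
    }
    validate_ld_matrix(x)
  }
  structure(list(exposure = load_stats(exposure, "exposure"),
                 outcome = load_stats(outcome, "outcome"),
                 mediator = load_stats(mediator, "mediator"),
                 eqtl = load_stats(eqtl, "eqtl"),
                 ld = load_ld(ld), gene = gene,
                 selection = selection, selection_eqtl = selection_eqtl,
                 methods = methods, b_method = b_method,
                 n_boot = n_boot, n_sim = n_sim, seed = as.integer(seed),
                 alpha = alpha, output_dir = output_dir),
            class = "study_config")
}

#' Convenience config from a simulated bundle
#'
#' @param sim An `mr_sim_study` from [simulate_mediation_study()].
#' @param ... Passed to [study_config()].
#' @return A `study_config`.
#' @export
study_config_from_simulation <- function(sim, ...) {
  stopifnot(inherits(sim, "mr_sim_study"))
  study_config(exposure = sim$exposure, outcome = sim$outcome,
               mediator = sim$mediator, eqtl = sim$eqtl, ld = sim$ld,
               gene = sim$gene, ...)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.arm_diagnostics <- function(table, n_sim, seed, methods) {
  t <- .retained(table)
  J <- nrow(t)
  list(
    heterogeneity = if (J >= 2) cochran_q(table) else NULL,
    egger_intercept = if (J >= 3) egger_intercept_test(table) else NULL,
    presso = if (J >= 4) mr_presso(table, n_sim = n_sim, seed = seed) else NULL,
    leave_one_out = if (J >= 2) leave_one_out(table) else NULL,
    plots = funnel_and_scatter_data(
      table, methods = intersect(methods, c("ivw", "egger")))
  )
}

.estimates_df <- function(fits) {
  do.call(rbind, lapply(fits, as.data.frame))
}

#' Run the full two-step MR mediation study
#'
#' Executes, from a single [study_config()]: (1) forward MR of exposure on
#' outcome (total effect `c`), (2) reverse MR of outcome on exposure
#' (effect `d`), (3) MR of exposure on mediator (effect `a`), (4) cis-eQTL
#' MR and SMR of mediator on outcome (effect `b`), (5) the mediation
#' decomposition `c' = c - a*b` with the proportion-mediated interval, and
#' (6) the sensitivity battery for every arm. All stochastic steps consume
#' sub-seeds derived from the config seed, so a run is fully reproducible.
#'
#' @param config A [study_config()].
#' @return A list of class `mr_study_report` with per-arm results (`arms`),
#'   the `mediation` result, a `summary` table, a run `log`, and the
#'   `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  arms <- list()

  run_arm <- function(name, from, to, ld, sel, seed_offset, eqtl_arm = FALSE) {
    ins <- .stage(paste0(name, "_selection"), {
      if (eqtl_arm) {
        select_cis_eqtls(from, cfg$gene$chrom, cfg$gene$start, cfg$gene$end,
                         ld, sel, verbose = FALSE)
      } else {
        select_instruments(from, ld, sel, verbose = FALSE)
      }
    })
    note("%s: %d instrument(s) selected", name, nrow(ins))
    tab <- .stage(paste0(name, "_harmonization"), harmonize(ins, to))
    J <- nrow(.retained(tab))
    note("%s: %d SNP(s) retained after harmonization", name, J)
    if (J == 0) .stage(paste0(name, "_harmonization"),
                       stop("no SNPs retained", call. = FALSE))
    feasible <- cfg$methods[vapply(cfg$methods, function(m) {
      m %in% c("ivw", "ivw_fixed") || J >= 3
    }, logical(1))]
    fits <- .stage(paste0(name, "_estimation"),
                   .run_methods(tab, feasible, cfg$n_boot,
                                cfg$seed + seed_offset))
    diags <- .stage(paste0(name, "_diagnostics"),
                    .arm_diagnostics(tab, cfg$n_sim,
                                     cfg$seed + seed_offset + 5L,
                                     cfg$methods))
    list(instruments = ins, table = tab, estimates = fits,
         diagnostics = diags)
  }

  arms$forward <- run_arm("forward", cfg$exposure, cfg$outcome, cfg$ld,
                          cfg$selection, 0L)
  arms$reverse <- run_arm("reverse", cfg$outcome, cfg$exposure, cfg$ld,
                          cfg$selection, 10L)
  if (!is.null(cfg$mediator)) {
    arms$exposure_mediator <- run_arm("exposure_mediator", cfg$exposure,
                                      cfg$mediator, cfg$ld, cfg$selection, 20L)
  }
  if (!is.null(cfg$eqtl)) {
    if (is.null(cfg$gene)) {
      .stage("mediator_outcome_selection",
             stop("eQTL arm requires a gene locus", call. = FALSE))
    }
    arms$mediator_outcome <- run_arm("mediator_outcome", cfg$eqtl,
                                     cfg$outcome, cfg$ld,
                                     cfg$selection_eqtl, 30L, eqtl_arm = TRUE)
    # SMR on the top (smallest-p) harmonized cis-eQTL
    tab_b <- .retained(arms$mediator_outcome$table)
    ins_b <- arms$mediator_outcome$instruments
    ins_b <- ins_b[ins_b$snp_id %in% tab_b$snp_id, , drop = FALSE]
    top <- ins_b[which.min(ins_b$pval), ]
    row <- tab_b[tab_b$snp_id == top$snp_id, ]
    arms$mediator_outcome$estimates$smr <- .stage("smr",
      mr_smr(list(beta = row$beta_exp, se = row$se_exp),
             list(beta = row$beta_out, se = row$se_out)))
    note("smr: top cis-eQTL %s", top$snp_id)
  }

  mediation <- NULL
  if (!is.null(arms$exposure_mediator) && !is.null(arms$mediator_outcome)) {
    a_fit <- arms$exposure_mediator$estimates$ivw
    b_fit <- if (cfg$b_method == "smr") {
      arms$mediator_outcome$estimates$smr
    } else {
      arms$mediator_outcome$estimates$ivw
    }
    c_fit <- arms$forward$estimates$ivw
    if (!is.null(a_fit) && !is.null(b_fit) && !is.null(c_fit)) {
      mediation <- .stage("mediation",
                          two_step_mediation(a_fit, b_fit, c_fit))
    } else {
      note("mediation skipped: IVW fits unavailable (methods = %s)",
           paste(cfg$methods, collapse = ","))
    }
  }

  summary_rows <- list()
  for (arm in names(arms)) {
    df <- .estimates_df(arms[[arm]]$estimates)
    if (is.null(df)) next
    df <- cbind(arrow = arm, df, significant = df$pval < cfg$alpha)
    summary_rows[[arm]] <- df
  }
  summary <- if (length(summary_rows) > 0) {
    do.call(rbind, summary_rows)
  } else {
    NULL
  }
  rownames(summary) <- NULL

  bundle <- structure(list(arms = arms, mediation = mediation,
                           summary = summary, log = log, config = cfg),
                      class = "mr_study_report")
  if (!is.null(cfg$output_dir)) .write_bundle(bundle, cfg$output_dir)
  bundle
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$summary)) {
    .write_tsv(bundle$summary, file.path(dir, "summary.tsv"))
  }
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  for (arm in names(bundle$arms)) {
    a <- bundle$arms[[arm]]
    .write_tsv(as.data.frame(a$table), file.path(dir, paste0(arm, "_harmonized.tsv")))
    est_df <- .estimates_df(a$estimates)
    if (!is.null(est_df)) {
      .write_tsv(est_df, file.path(dir, paste0(arm, "_estimates.tsv")))
    }
    if (!is.null(a$diagnostics$leave_one_out)) {
      .write_tsv(a$diagnostics$leave_one_out,
                 file.path(dir, paste0(arm, "_leave_one_out.tsv")))
    }
    .write_tsv(a$diagnostics$plots$scatter, file.path(dir, paste0(arm, "_scatter.tsv")))
    .write_tsv(a$diagnostics$plots$funnel, file.path(dir, paste0(arm, "_funnel.tsv")))
  }
  if (!is.null(bundle$mediation)) {
    m <- bundle$mediation
    .write_tsv(data.frame(a = m$a, se_a = m$se_a, b = m$b, se_b = m$se_b,
                          c = m$c, se_c = m$se_c, indirect = m$indirect,
                          se_indirect = m$se_indirect, c_prime = m$c_prime,
                          se_c_prime = m$se_c_prime, proportion = m$proportion,
                          proportion_se = m$proportion_se,
                          ci_low = m$proportion_ci[1],
                          ci_high = m$proportion_ci[2]),
               file.path(dir, "mediation.tsv"))
  }
  invisible(dir)
}

#' Render a deterministic text report for a study
#'
#' @param bundle An `mr_study_report` from [run_study()].
#' @param file Optional path; when given the report lines are written there.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle, file = NULL) {
  stopifnot(inherits(bundle, "mr_study_report"))
  num <- function(x) sprintf("%.6g", x)
  lines <- c("Two-step MR mediation study report",
             strrep("=", 34), "", "Run log:",
             paste0("  ", bundle$log), "")
  for (arm in names(bundle$arms)) {
    a <- bundle$arms[[arm]]
    lines <- c(lines, sprintf("[%s]", arm))
    for (m in names(a$estimates)) {
      e <- a$estimates[[m]]
      lines <- c(lines, sprintf(
        "  %-16s beta %s (se %s), OR %s [%s, %s], p %s, %d SNPs",
        m, num(e$beta), num(e$se), num(e$or_), num(e$ci_low),
        num(e$ci_high), num(e$pval), e$n_snps))
    }
    d <- a$diagnostics
    if (!is.null(d$heterogeneity)) {
      lines <- c(lines, sprintf("  Cochran Q %s on %d df, p %s",
                                num(d$heterogeneity$q), d$heterogeneity$df,
                                num(d$heterogeneity$pval)))
    }
    if (!is.null(d$egger_intercept)) {
      lines <- c(lines, sprintf("  Egger intercept %s (se %s), p %s",
                                num(d$egger_intercept$estimate),
                                num(d$egger_intercept$se),
                                num(d$egger_intercept$pval)))
    }
    if (!is.null(d$presso)) {
      lines <- c(lines, sprintf("  MR-PRESSO global p %s%s",
                                num(d$presso$global_p),
                                if (length(d$presso$outlier_ids) > 0) {
                                  paste0(", outliers: ",
                                         paste(d$presso$outlier_ids, collapse = ", "))
                                } else {
                                  ", no outliers"
                                }))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$mediation)) {
    m <- bundle$mediation
    lines <- c(lines, "[mediation]",
               sprintf("  a %s (se %s); b %s (se %s); c %s (se %s)",
                       num(m$a), num(m$se_a), num(m$b), num(m$se_b),
                       num(m$c), num(m$se_c)),
               sprintf("  indirect (a x b) %s (se %s)",
                       num(m$indirect), num(m$se_indirect)),
               sprintf("  direct (c') %s (se %s)",
                       num(m$c_prime), num(m$se_c_prime)),
               sprintf("  proportion mediated %s%% [%s%%, %s%%]",
                       num(100 * m$proportion),
                       num(100 * m$proportion_ci[1]),
                       num(100 * m$proportion_ci[2])),
               "")
  }
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' Diagnostic plots
#'
#' Base-graphics renderings of the standard two-sample MR displays: the
#' per-SNP scatter with fitted method lines, the funnel of ratio against
#' precision, a forest of method estimates, and the leave-one-out forest.
#'
#' @param table Harmonized instrument table.
#' @param fits `fits` table from [funnel_and_scatter_data()].
#' @param estimates List of [mr_estimate()] objects.
#' @param loo Leave-one-out table from [leave_one_out()].
#' @param main Plot title.
#' @return `NULL`, invisibly; called for the side effect of drawing.
#' @name mr-plots
NULL

#' @rdname mr-plots
#' @export
mr_scatter_plot <- function(table, fits = NULL, main = "SNP effects") {
  t <- .retained(table)
  graphics::plot(t$beta_exp, t$beta_out, pch = 19,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", main = main)
  graphics::segments(t$beta_exp, t$beta_out - t$se_out,
                     t$beta_exp, t$beta_out + t$se_out)
  graphics::segments(t$beta_exp - t$se_exp, t$beta_out,
                     t$beta_exp + t$se_exp, t$beta_out)
  if (!is.null(fits) && nrow(fits) > 0) {
    for (i in seq_len(nrow(fits))) {
      graphics::abline(fits$intercept[i], fits$slope[i], col = i + 1, lty = i)
    }
    graphics::legend("topleft", legend = fits$method, col = seq_len(nrow(fits)) + 1,
                     lty = seq_len(nrow(fits)), bty = "n")
  }
  invisible(NULL)
}

#' @rdname mr-plots
#' @export
mr_funnel_plot <- function(table, main = "Funnel") {
  r <- .table_ratios(table)
  ivw <- sum(r$weight * r$ratio) / sum(r$weight)
  graphics::plot(r$ratio, 1 / r$se_ratio, pch = 19,
                 xlab = "Wald ratio", ylab = "Precision (1/se)", main = main)
  graphics::abline(v = ivw, lty = 2)
  invisible(NULL)
}

#' @rdname mr-plots
#' @export
mr_forest_plot <- function(estimates, main = "MR estimates") {
  df <- .estimates_df(estimates)
  n <- nrow(df)
  graphics::plot(df$beta, seq_len(n), yaxt = "n", pch = 19,
                 xlim = range(df$beta - 1.96 * df$se, df$beta + 1.96 * df$se),
                 xlab = "Causal estimate (additive scale)", ylab = "", main = main)
  graphics::segments(df$beta - 1.96 * df$se, seq_len(n),
                     df$beta + 1.96 * df$se, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = df$method, las = 1)
  graphics::abline(v = 0, lty = 2)
  invisible(NULL)
}

#' @rdname mr-plots
#' @export
mr_loo_plot <- function(loo, main = "Leave-one-out") {
  n <- nrow(loo)
  graphics::plot(loo$beta, seq_len(n), yaxt = "n", pch = 19,
                 xlim = range(loo$beta - 1.96 * loo$se, loo$beta + 1.96 * loo$se),
                 xlab = "IVW estimate", ylab = "", main = main)
  graphics::segments(loo$beta - 1.96 * loo$se, seq_len(n),
                     loo$beta + 1.96 * loo$se, seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = loo$excluded, las = 1)
  graphics::abline(v = loo$beta[n], lty = 2)
  invisible(NULL)
}
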