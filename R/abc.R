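#' Build an ABC reference table
#'
#' Simulates `n_per_scenario` datasets per candidate scenario, drawing every
#' parameter from its prior, computes the summary-statistic vector of each,
#' and z-normalizes the statistics by the reference-table mean and standard
#' deviation (stored so observed data can be placed on the same scale).
#' Statistics with zero variance across the table are dropped with a
#' warning and recorded.
#'
#' @param scenarios Named list of `scenario` objects (>= 2 for model choice).
#' @param n_per_scenario Simulated datasets per scenario.
#' @param sample_sizes Named integer vector of samples per deme (all
#'   scenarios must share the deme design).
#' @param L Locus length in sites.
#' @param seed Integer seed.
#' @param model Mutation model (default `"jukes_cantor"`, robust to prior
#'   draws implying many substitutions).
#' @param level Unit level for [summary_stats()] (default `"deme"`).
#' @return A `reference_table`: list with `scenario` (factor), `stats`
#'   (raw matrix), `stats_norm`, `params` (list of per-scenario parameter
#'   data frames), `center`, `scale`, `dropped`, `n_per_scenario`,
#'   `sample_sizes`, `L`, `model`, `level`, `seed`.
#' @export
build_reference <- function(scenarios, n_per_scenario, sample_sizes, L,
                            seed = 1L, model = "jukes_cantor",
                            level = "deme") {
  stopifnot(length(scenarios) >= 1L, n_per_scenario >= 1L)
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  set.seed(seed)
  rows <- vector("list", length(scenarios) * n_per_scenario)
  params <- stats::setNames(vector("list", length(scenarios)),
                            names(scenarios))
  scen_lab <- character(length(rows))
  r <- 0L
  for (sn in names(scenarios)) {
    pl <- vector("list", n_per_scenario)
    for (i in seq_len(n_per_scenario)) {
      sd_ <- simulate_dataset(scenarios[[sn]], sample_sizes, L = L,
                              model = model)
      r <- r + 1L
      rows[[r]] <- summary_stats(sd_, level = level)
      scen_lab[r] <- sn
      pl[[i]] <- sd_$truth$params
    }
    params[[sn]] <- as.data.frame(do.call(rbind, pl))
  }
  stats <- do.call(rbind, rows)
  center <- colMeans(stats)
  scale <- apply(stats, 2L, stats::sd)
  dropped <- colnames(stats)[scale == 0 | !is.finite(scale)]
  if (length(dropped))
    warning("dropping zero-variance statistics: ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(colnames(stats), dropped)
  structure(list(scenario = factor(scen_lab, levels = names(scenarios)),
                 stats = stats,
                 stats_norm = sweep(sweep(stats[, keep, drop = FALSE], 2L,
                                          center[keep]), 2L, scale[keep], "/"),
                 params = params, center = center, scale = scale,
                 dropped = dropped, n_per_scenario = n_per_scenario,
                 sample_sizes = sample_sizes, L = L, model = model,
                 level = level, seed = seed),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x$stats_norm), "rows (",
      paste(levels(x$scenario), collapse = ", "), "),",
      ncol(x$stats_norm), "statistics\n")
  invisible(x)
}

# place an observed summary-statistic vector on the reference-table scale
normalize_observed <- function(rt, observed) {
  keep <- colnames(rt$stats_norm)
  if (!all(keep %in% names(observed)))
    stop("observed statistics are missing: ",
         paste(setdiff(keep, names(observed)), collapse = ", "))
  (observed[keep] - rt$center[keep]) / rt$scale[keep]
}

#' ABC scenario choice by rejection plus multinomial logistic regression
#'
#' Retains the `retain` fraction of reference rows closest to the observed
#' statistics (Euclidean distance on the normalized scale) and fits a
#' multinomial logistic regression of the scenario indicator on the retained
#' statistics centered at the observed point; the posterior probabilities
#' are the fitted class probabilities at that point, with 95% confidence
#' intervals from the regression's asymptotic covariance (delta method).
#' When the regression is singular or fails, rejection-sampling proportions
#' (with binomial confidence intervals) are reported instead and flagged.
#'
#' @param rt A `reference_table`.
#' @param observed Named summary-statistic vector of the observed data (same
#'   layout as the table rows).
#' @param retain Retained fraction (default 0.01).
#' @return An `abc_model_choice`: list with `posterior` (data frame
#'   `scenario`, `prob`, `lo`, `hi`), `selected_scenario`,
#'   `retained_fraction`, `n_retained`, `method` (`"logistic"` or
#'   `"rejection"`), `retained_idx`.
#' @export
model_choice <- function(rt, observed, retain = 0.01) {
  z <- normalize_observed(rt, observed)
  X <- sweep(rt$stats_norm, 2L, z)              # centered at the observed point
  dist <- sqrt(rowSums(X^2))
  m <- max(2L, ceiling(retain * nrow(X)))
  sel <- order(dist)[seq_len(m)]
  scen <- droplevels(rt$scenario[sel])
  all_levels <- levels(rt$scenario)
  missing_sc <- setdiff(all_levels, levels(scen))
  if (length(missing_sc))
    warning("scenario(s) absent from the retained set, probability floored ",
            "at 0: ", paste(missing_sc, collapse = ", "))

  res <- NULL
  # the regression needs retained rows well in excess of the statistic
  # count, or its fitted probabilities saturate on separable sets; below
  # 10 rows per statistic the rejection proportions are reported instead
  if (nlevels(scen) >= 2L && m >= 10L * ncol(X)) {
    df <- data.frame(scenario = scen, X[sel, , drop = FALSE])
    fit <- tryCatch(
      nnet::multinom(scenario ~ ., data = df, trace = FALSE, maxit = 300L),
      error = function(e) NULL)
    if (!is.null(fit)) res <- tryCatch(multinom_point_ci(fit),
                                       error = function(e) NULL)
  }
  method <- "logistic"
  if (is.null(res)) {
    method <- "rejection"
    pr <- as.vector(prop.table(table(scen)))
    se <- sqrt(pr * (1 - pr) / m)
    res <- data.frame(scenario = levels(scen), prob = pr,
                      lo = pmax(0, pr - 1.96 * se),
                      hi = pmin(1, pr + 1.96 * se))
  }
  if (length(missing_sc))
    res <- rbind(res, data.frame(scenario = missing_sc, prob = 0,
                                 lo = 0, hi = 0))
  res <- res[match(all_levels, res$scenario), ]
  rownames(res) <- NULL
  structure(list(posterior = res,
                 selected_scenario = res$scenario[which.max(res$prob)],
                 retained_fraction = retain, n_retained = m,
                 method = method, retained_idx = sel),
            class = "abc_model_choice")
}

# fitted class probabilities at the centering point (covariates = 0) with
# delta-method 95% CIs from the multinomial regression's vcov
multinom_point_ci <- function(fit) {
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(fit$lev[2L], names(cf)))
  eta <- c(0, cf[, "(Intercept)"])
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  K <- length(p)
  V <- stats::vcov(fit)
  int_ix <- grep("\\(Intercept\\)", colnames(V))
  Vi <- V[int_ix, int_ix, drop = FALSE]         # order: classes 2..K
  se <- vapply(seq_len(K), function(k) {
    # dp_k / d eta_j = p_k (1[k == j] - p_j), j = 2..K
    g <- p[k] * ((seq_len(K) == k) - p)[-1L]
    sqrt(max(0, g %*% Vi %*% g))
  }, numeric(1))
  data.frame(scenario = fit$lev, prob = unname(p),
             lo = pmax(0, p - 1.96 * se), hi = pmin(1, p + 1.96 * se))
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$method, ", retained ", x$n_retained,
      " rows):\n", sep = "")
  for (i in seq_len(nrow(x$posterior)))
    cat(sprintf("  %-20s %.4f (95%% CI %.4f-%.4f)%s\n",
                x$posterior$scenario[i], x$posterior$prob[i],
                x$posterior$lo[i], x$posterior$hi[i],
                if (x$posterior$scenario[i] == x$selected_scenario) " *" else ""))
  invisible(x)
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Restricts the reference table to one scenario, retains the rows closest
#' to the observed statistics, and adjusts the retained parameter draws by a
#' local-linear regression on the (observed-centered) statistics; posterior
#' summaries are the median and 2.5/97.5 percentiles of the adjusted draws.
#' With fewer than 50 retained rows the adjustment is skipped and flagged.
#'
#' @param rt A `reference_table`.
#' @param observed Named summary-statistic vector.
#' @param scenario_name Scenario to estimate under (default: first level).
#' @param retain Retained fraction of that scenario's rows (default 0.01).
#' @param adjust Apply the regression adjustment (default TRUE).
#' @return An `abc_parameters`: list with `summary` (data frame `parameter`,
#'   `median`, `lo`, `hi`), `adjusted` (draw matrix), `n_retained`,
#'   `adjustment_applied`.
#' @export
estimate_parameters <- function(rt, observed, scenario_name = levels(rt$scenario)[1L],
                                retain = 0.01, adjust = TRUE) {
  ix <- which(rt$scenario == scenario_name)
  if (!length(ix)) stop("no reference rows for scenario ", scenario_name)
  z <- normalize_observed(rt, observed)
  X <- sweep(rt$stats_norm[ix, , drop = FALSE], 2L, z)
  dist <- sqrt(rowSums(X^2))
  m <- max(2L, ceiling(retain * length(ix)))
  sel <- order(dist)[seq_len(m)]
  theta <- as.matrix(rt$params[[scenario_name]][sel, , drop = FALSE])
  Xs <- X[sel, , drop = FALSE]
  applied <- FALSE
  if (adjust && m >= 50L) {
    for (j in seq_len(ncol(theta))) {
      fit <- stats::lm.fit(cbind(1, Xs), theta[, j])
      beta <- fit$coefficients[-1L]
      beta[is.na(beta)] <- 0
      theta[, j] <- theta[, j] - Xs %*% beta    # slide draws to the observed point
    }
    applied <- TRUE
  }
  qs <- t(apply(theta, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  structure(list(summary = data.frame(parameter = colnames(theta),
                                      median = qs[, 1], lo = qs[, 2],
                                      hi = qs[, 3], row.names = NULL),
                 adjusted = theta, n_retained = m,
                 adjustment_applied = applied),
            class = "abc_parameters")
}

#' @export
print.abc_parameters <- function(x, ...) {
  cat("ABC parameter posteriors (", x$n_retained, " retained draws",
      if (!x$adjustment_applied) ", unadjusted", "):\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Confusion-matrix error rates of ABC scenario choice
#'
#' Simulates `n_pods` pseudo-observed datasets per scenario from its priors,
#' classifies each with [model_choice()] against the reference table, and
#' reports per-scenario type I error (fraction of its own pods not assigned
#' to it) and mean type II error (mean over other scenarios of the fraction
#' of their pods assigned to it).
#'
#' @param scenarios Named list of `scenario` objects (the table's candidates).
#' @param rt A `reference_table` built from the same scenarios.
#' @param n_pods Pseudo-observed datasets per scenario (default 100; < 20
#'   warns).
#' @param retain Retained fraction for each classification.
#' @param seed Integer seed.
#' @return An `abc_confusion`: list with `errors` (data frame `scenario`,
#'   `type1`, `type2`), `confusion` (assignment-count matrix, rows =
#'   generating scenario), `n_pods`, `seed`.
#' @export
confusion_errors <- function(scenarios, rt, n_pods = 100L, retain = 0.01,
                             seed = 1L) {
  if (n_pods < 20L) warning("n_pods < 20 gives noisy error estimates")
  if (is.null(names(scenarios)))
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  stopifnot(identical(sort(names(scenarios)), sort(levels(rt$scenario))))
  set.seed(seed)
  lev <- levels(rt$scenario)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (sn in lev) {
    for (i in seq_len(n_pods)) {
      pod <- simulate_dataset(scenarios[[sn]], rt$sample_sizes, L = rt$L,
                              model = rt$model)
      obs <- summary_stats(pod, level = rt$level)
      mc <- suppressWarnings(model_choice(rt, obs, retain = retain))
      conf[sn, mc$selected_scenario] <- conf[sn, mc$selected_scenario] + 1L
    }
  }
  prop <- conf / n_pods
  type1 <- 1 - diag(prop)
  type2 <- vapply(seq_along(lev), function(k)
    mean(prop[-k, k]), numeric(1))
  structure(list(errors = data.frame(scenario = lev, type1 = unname(type1),
                                     type2 = unname(type2)),
                 confusion = conf, n_pods = n_pods, seed = seed),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("ABC confusion errors over", x$n_pods, "pods per scenario:\n")
  print(x$errors, digits = 3)
  invisible(x)
}

#' Write an ABC reference table (columnar TSV + JSON header sidecar)
#' @param rt A `reference_table`.
#' @param stem Path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return The stem, invisibly.
#' @export
write_reference <- function(rt, stem) {
  df <- data.frame(scenario = rt$scenario, rt$stats, check.names = FALSE)
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_per_scenario = rt$n_per_scenario, scenarios = levels(rt$scenario),
         sample_sizes = as.list(rt$sample_sizes), L = rt$L,
         model = rt$model, level = rt$level, seed = rt$seed,
         center = as.list(rt$center), scale = as.list(rt$scale),
         dropped = rt$dropped),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
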