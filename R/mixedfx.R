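#' Variance-ratio intraclass correlations
#'
#' Effect-size ICCs for random-intercept models grouped by skier-session:
#' the adjusted ICC excludes the fixed-effect variance from the denominator,
#' `var_random / (var_random + var_residual)`, while the conditional ICC
#' includes it, `var_random / (var_random + var_residual + var_fixed)`.
#' `icc_cond <= icc_adj` always, with equality iff `var_fixed = 0`; a large
#' gap between them signals a meaningful fixed effect.
#'
#' @param var_random between-session (random intercept) variance, >= 0.
#' @param var_residual residual variance, >= 0.
#' @param var_fixed variance of the fixed-effect linear predictor, >= 0.
#' @return the ICC in \[0, 1\].
#' @export
icc_adj <- function(var_random, var_residual) {
  if (var_random < 0 || var_residual < 0) stop("variances must be >= 0")
  den <- var_random + var_residual
  if (den <= 0) stop("all-zero denominator")
  var_random / den
}

#' @rdname icc_adj
#' @export
icc_cond <- function(var_random, var_residual, var_fixed) {
  if (var_random < 0 || var_residual < 0 || var_fixed < 0)
    stop("variances must be >= 0")
  den <- var_random + var_residual + var_fixed
  if (den <= 0) stop("all-zero denominator")
  var_random / den
}

#' Conditional ICC from marginal and conditional R-squared
#'
#' Since the marginal R2 (fixed effects only) and the conditional R2 (fixed
#' plus random) share a denominator, `r2m + icc_cond = r2c`, so the
#' conditional ICC is simply their difference.
#'
#' @param r2m marginal R-squared, in \[0, r2c\].
#' @param r2c conditional R-squared, in \[r2m, 1\].
#' @return `r2c - r2m`.
#' @export
icc_cond_from_r2 <- function(r2m, r2c) {
  if (any(r2m > r2c)) stop("r2m must not exceed r2c")
  if (any(r2m < 0 | r2c > 1)) stop("R-squared values must lie in [0, 1]")
  r2c - r2m
}

#' Marginal and conditional R-squared from variance components
#'
#' Variance-partition R2 for mixed models:
#' `r2m = var_fixed / (var_fixed + var_random + var_residual)` and
#' `r2c = (var_fixed + var_random) / (same denominator)`. For non-normal
#' families the components are taken on the latent (log-link) scale, with
#' the distribution-specific residual variance (`trigamma(shape)` for the
#' gamma family).
#'
#' @param var_fixed,var_random,var_residual latent-scale variance
#'   components, or alternatively a single `ski_mixed_fit` object as the
#'   first argument.
#' @return named vector `c(r2m = ..., r2c = ...)`.
#' @export
r2_nakagawa <- function(var_fixed, var_random, var_residual) {
  if (inherits(var_fixed, "ski_mixed_fit")) {
    f <- var_fixed
    var_random <- f$var_random; var_residual <- f$var_residual
    var_fixed <- f$var_fixed
  }
  den <- var_fixed + var_random + var_residual
  if (den <= 0) stop("degenerate denominator: all variance components zero")
  c(r2m = var_fixed / den, r2c = (var_fixed + var_random) / den)
}

#' Classify a fixed effect from p-value and ICC pair
#'
#' Two-step rule: a fixed effect is `negligible` when its p-value is not
#' significant, or when the adjusted and conditional ICC are essentially
#' equal (within `tol`) — adding the fixed-effect variance to the
#' denominator then changes nothing, so the effect is not large enough to
#' matter despite significance. Otherwise the conditional ICC is bucketed
#' with inverted intraclass-correlation cut-offs: below 0.5 `very strong`,
#' 0.5-0.75 `strong`, 0.75-0.9 `moderate`, above 0.9 `small`.
#'
#' @param p fixed-effect p-value.
#' @param icc_adj,icc_cond the two ICCs of the fitted model.
#' @param alpha significance level.
#' @param tol equality tolerance for `icc_adj` vs `icc_cond`.
#' @return one of `"negligible"`, `"small"`, `"moderate"`, `"strong"`,
#'   `"very strong"`.
#' @export
classify_effect <- function(p, icc_adj, icc_cond, alpha = 0.05, tol = 0.01) {
  if (is.na(p) || is.na(icc_adj) || is.na(icc_cond)) return(NA_character_)
  if (p >= alpha) return("negligible")
  if (abs(icc_adj - icc_cond) < tol) return("negligible")
  if (icc_cond < 0.5) "very strong"
  else if (icc_cond < 0.75) "strong"
  else if (icc_cond < 0.9) "moderate"
  else "small"
}

## Comparable AIC across candidate response families. For the lognormal
## family (normal model on log responses) the Jacobian of the log transform
## is added so the AIC refers to the density of the original response.
family_race <- function(data, form_fixed) {
  y <- data$value
  f_norm <- stats::as.formula(paste("value ~", form_fixed,
                                    "+ (1 | session_id)"))
  f_log <- stats::as.formula(paste("log(value) ~", form_fixed,
                                   "+ (1 | session_id)"))
  candidates <- list(normal = list(
    fit = function(d) glmmTMB::glmmTMB(f_norm, data = d,
                                       family = stats::gaussian()),
    aic_adjust = 0))
  if (all(y > 0)) {
    candidates$lognormal <- list(
      fit = function(d) glmmTMB::glmmTMB(f_log, data = d,
                                         family = stats::gaussian()),
      aic_adjust = 2 * sum(log(y)))
    candidates$gamma <- list(
      fit = function(d) glmmTMB::glmmTMB(f_norm, data = d,
                                         family = stats::Gamma(link = "log")),
      aic_adjust = 0)
  }
  candidates
}

#' Fit the random-intercept model of one outcome
#'
#' Fits `value ~ run + leg + run:leg + (1 | session_id)` (or `value ~ run +
#' (1 | session_id)` for cycle-level outcomes) by maximum likelihood with
#' glmmTMB, and derives the full effect-size summary: latent-scale variance
#' components, fixed-predictor variance (empirical variance of the
#' fixed-effect linear predictor over the observed design), marginal and
#' conditional R2, adjusted and conditional ICC, Wald z p-values per term,
#' estimated marginal means over the balanced run-by-leg grid with Wald 95%
#' CIs, and Last-minus-First differences per leg (back-transformed to the
#' response scale for log-link families).
#'
#' With `family = "auto"` the normal, lognormal (normal on log responses,
#' AIC corrected by the log-transform Jacobian so the candidates are
#' comparable) and gamma (log link) families are raced and the lowest AIC
#' wins; families requiring positive responses drop out of the race when
#' any response is non-positive.
#'
#' @param data data.frame with columns `value`, `run` (`"First"`/`"Last"`),
#'   `session_id`, and `leg` (`"IL"`/`"OL"`) unless `fixed = "run_only"`.
#'   Rows with missing values are dropped listwise.
#' @param fixed `"run_leg"` (full factorial) or `"run_only"`.
#' @param family `"auto"`, `"normal"`, `"lognormal"` or `"gamma"`.
#' @return an object of class `ski_mixed_fit`: a list with the fitted model,
#'   chosen family, variance components, `r2m`, `r2c`, `icc_adj`,
#'   `icc_cond`, `p` (named per term), `emmeans`, `emmean_diff`, `aic_table`
#'   and a `singular` flag (random-intercept variance collapsed to zero).
#' @export
fit_metric_model <- function(data, fixed = c("run_leg", "run_only"),
                             family = c("auto", "normal", "lognormal",
                                        "gamma")) {
  fixed <- match.arg(fixed)
  family <- match.arg(family)
  need <- c("value", "run", "session_id",
            if (fixed == "run_leg") "leg")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  data$run <- factor(data$run, levels = c("First", "Last"))
  data$session_id <- factor(data$session_id)
  if (fixed == "run_leg") data$leg <- factor(data$leg, levels = c("IL", "OL"))
  if (nlevels(droplevels(data$session_id)) < 2L)
    stop("need at least 2 skier-sessions")
  if (nlevels(droplevels(data$run)) < 2L)
    stop("both run levels must be present")
  if (fixed == "run_leg" && nlevels(droplevels(data$leg)) < 2L)
    stop("both legs must be present")

  form_fixed <- if (fixed == "run_leg") "run * leg" else "run"
  cands <- family_race(data, form_fixed)
  if (family != "auto") {
    if (is.null(cands[[family]]))
      stop("family ", family, " requires strictly positive responses")
    cands <- cands[family]
  }
  fits <- list(); aic <- c()
  for (nm in names(cands)) {
    f <- try(suppressWarnings(cands[[nm]]$fit(data)), silent = TRUE)
    if (inherits(f, "try-error") || is.na(stats::AIC(f))) next
    fits[[nm]] <- f
    aic[nm] <- stats::AIC(f) + cands[[nm]]$aic_adjust
  }
  if (!length(fits)) stop("all candidate families failed to fit")
  chosen <- names(which.min(aic))
  fit <- fits[[chosen]]

  vc <- glmmTMB::VarCorr(fit)$cond$session_id
  var_random <- if (is.null(vc)) 0 else unname(attr(vc, "stddev")^2)
  var_residual <- switch(chosen,
    normal = , lognormal = stats::sigma(fit)^2,
    gamma = trigamma(1 / stats::sigma(fit)^2))
  eta <- stats::predict(fit, re.form = NA, type = "link")
  var_fixed <- if (length(unique(round(eta, 12))) == 1L) 0 else var(eta)
  r2 <- r2_nakagawa(var_fixed, var_random, var_residual)

  co <- summary(fit)$coefficients$cond
  pick_p <- function(term) {
    i <- match(term, rownames(co))
    if (is.na(i)) NA_real_ else co[i, "Pr(>|z|)"]
  }
  p <- c(run = pick_p("runLast"))
  if (fixed == "run_leg")
    p <- c(p, leg = pick_p("legOL"), run_leg = pick_p("runLast:legOL"))

  spec <- if (fixed == "run_leg") ~ run | leg else ~run
  em <- emmeans::emmeans(fit, spec)
  if (chosen %in% c("lognormal", "gamma")) em <- emmeans::regrid(em)
  em_df <- as.data.frame(stats::confint(em))
  est_col <- intersect(c("emmean", "response"), names(em_df))[1]
  names(em_df)[names(em_df) == est_col] <- "emmean"
  diffs <- emmeans::contrast(em, "revpairwise",
                             by = if (fixed == "run_leg") "leg" else NULL)
  diff_df <- as.data.frame(stats::confint(diffs))
  names(diff_df)[names(diff_df) == "estimate"] <- "diff"

  structure(list(
    family = chosen, fit = fit, n = nrow(data), fixed = fixed,
    aic_table = aic,
    var_random = var_random, var_residual = var_residual,
    var_fixed = var_fixed,
    r2m = unname(r2["r2m"]), r2c = unname(r2["r2c"]),
    icc_adj = icc_adj(var_random, var_residual),
    icc_cond = icc_cond(var_random, var_residual, var_fixed),
    p = p,
    emmeans = em_df, emmean_diff = diff_df,
    grand_mean = mean(data$value),
    singular = var_random < 1e-8), class = "ski_mixed_fit")
}

#' @export
print.ski_mixed_fit <- function(x, ...) {
  cat("Random-intercept fit (", x$family, " family, n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  var_random %.4g  var_residual %.4g  var_fixed %.4g%s\n",
              x$var_random, x$var_residual, x$var_fixed,
              if (x$singular) "  [singular]" else ""))
  cat(sprintf("  R2m %.3f  R2c %.3f  ICC_adj %.3f  ICC_cond %.3f\n",
              x$r2m, x$r2c, x$icc_adj, x$icc_cond))
  cat("  p-values:", paste(names(x$p), signif(x$p, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Coefficient-of-variation decomposition of a fitted model
#'
#' Attributes the dispersion of the response to three sources, each as a CV
#' in percent of the grand mean: between skier-sessions (`cv_random`),
#' within skier-session (`cv_intra`, the residual), and systematic
#' fixed-effect spread (`cv_syst`). For log-link families the latent-scale
#' variances map to response-scale CVs via `sqrt(exp(v) - 1)`.
#'
#' @param fit a `ski_mixed_fit`.
#' @return named vector `c(cv_random, cv_intra, cv_syst)`, percent.
#' @export
cv_decomposition <- function(fit) {
  stopifnot(inherits(fit, "ski_mixed_fit"))
  if (fit$family == "normal") {
    if (fit$grand_mean <= 0) stop("grand mean must be positive for a CV")
    f <- function(v) 100 * sqrt(v) / fit$grand_mean
  } else {
    f <- function(v) 100 * sqrt(exp(v) - 1)
  }
  c(cv_random = f(fit$var_random), cv_intra = f(fit$var_residual),
    cv_syst = f(fit$var_fixed))
}

#' Simulate a tidy outcome table with known variance components
#'
#' Balanced two-run, two-leg, repeated-turn design used for parameter
#' recovery, type-I-error and coverage checks of the model layer. For the
#' normal family the stated components act on the response scale; for the
#' lognormal and gamma families they act on the log scale around
#' `log(mean)` (gamma shape is `1 / sigma2_res`).
#'
#' @param n_sessions number of skier-sessions (random-effect groups).
#' @param n_turns turns per session, run and leg.
#' @param mean grand mean of the response.
#' @param sigma2_id between-session variance.
#' @param sigma2_res residual (turn-to-turn) variance.
#' @param run_effect Last-minus-First shift.
#' @param leg_effect OL-minus-IL shift.
#' @param interaction_effect extra shift in the Last:OL cell.
#' @param family `"normal"`, `"lognormal"` or `"gamma"`.
#' @param two_legs simulate both legs (`FALSE` gives a run-only design).
#' @param seed integer seed.
#' @return data.frame with columns `session_id`, `run`, `leg`, `value`.
#' @export
simulate_metrics_table <- function(n_sessions, n_turns, mean = 40,
                                   sigma2_id = 4, sigma2_res = 1,
                                   run_effect = 0, leg_effect = 0,
                                   interaction_effect = 0,
                                   family = c("normal", "lognormal", "gamma"),
                                   two_legs = TRUE, seed = 1L) {
  family <- match.arg(family)
  with_seed(seed, {
    legs <- if (two_legs) c("IL", "OL") else "IL"
    d <- expand.grid(session_id = sprintf("S%02d", seq_len(n_sessions)),
                     turn = seq_len(n_turns), run = c("First", "Last"),
                     leg = legs, stringsAsFactors = FALSE)
    u <- rnorm(n_sessions, 0, sqrt(sigma2_id))
    names(u) <- sprintf("S%02d", seq_len(n_sessions))
    shift <- run_effect * (d$run == "Last") + leg_effect * (d$leg == "OL") +
      interaction_effect * (d$run == "Last" & d$leg == "OL")
    if (family == "normal") {
      d$value <- mean + u[d$session_id] + shift +
        rnorm(nrow(d), 0, sqrt(sigma2_res))
    } else if (family == "lognormal") {
      d$value <- exp(log(mean) + u[d$session_id] + shift +
                       rnorm(nrow(d), 0, sqrt(sigma2_res)))
    } else {
      shape <- 1 / sigma2_res
      mu <- exp(log(mean) + u[d$session_id] + shift)
      d$value <- rgamma(nrow(d), shape = shape, scale = mu / shape)
    }
    d[, c("session_id", "run", "leg", "value")]
  })
}

#' Fit all outcome models of a metrics table
#'
#' Groups the tidy per-turn table by (metric, channel), fits the
#' random-intercept model of each group (full run-by-leg factorial for
#' leg-level outcomes, run-only for the cycle-level amplitude and run time),
#' and assembles one report row per model with p-values, variance
#' components, R2s, ICCs, the effect classification of the run factor, the
#' CV decomposition and the Last-minus-First estimated marginal mean
#' differences per leg with 95% CIs. One row of the report corresponds to
#' one statistical test on the run factor; no multiplicity correction is
#' applied.
#'
#' @param metrics a tidy metrics table (see [validate_metrics_table()]), or
#'   a data.frame with at least `session_id`, `run_label`, `leg`, `channel`,
#'   `metric`, `value`.
#' @param family response family passed to [fit_metric_model()].
#' @param alpha significance level for classification.
#' @param tol ICC equality tolerance for classification.
#' @param min_sessions groups observed in fewer sessions are skipped.
#' @return data.frame with one row per fitted (metric, channel) model; the
#'   fitted objects are attached as the `"fits"` attribute.
#' @export
analyze_metrics <- function(metrics, family = "auto", alpha = 0.05,
                            tol = 0.01, min_sessions = 2L) {
  run_only_metrics <- c("amplitude_deg", "run_time_s")
  groups <- unique(metrics[, c("metric", "channel")])
  out <- NULL
  fits <- list()
  for (g in seq_len(nrow(groups))) {
    met <- groups$metric[g]; ch <- groups$channel[g]
    sel <- metrics$metric == met &
      (is.na(ch) & is.na(metrics$channel) |
         !is.na(ch) & !is.na(metrics$channel) & metrics$channel == ch)
    d <- metrics[sel, ]
    d <- data.frame(value = d$value, run = d$run_label, leg = d$leg,
                    session_id = d$session_id)
    if (length(unique(d$session_id)) < min_sessions) next
    fixed <- if (met %in% run_only_metrics) "run_only" else "run_leg"
    fit <- try(fit_metric_model(d, fixed = fixed, family = family),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    # CVs are undefined for outcomes with non-positive grand mean
    # (e.g. flexion velocities); report them as missing
    cv <- try(cv_decomposition(fit), silent = TRUE)
    if (inherits(cv, "try-error"))
      cv <- c(cv_random = NA_real_, cv_intra = NA_real_, cv_syst = NA_real_)
    dd <- fit$emmean_diff
    row <- data.frame(
      metric = met, channel = ch, family = fit$family, n = fit$n,
      p_run = fit$p[["run"]],
      p_leg = if ("leg" %in% names(fit$p)) fit$p[["leg"]] else NA_real_,
      p_run_leg = if ("run_leg" %in% names(fit$p)) fit$p[["run_leg"]]
                  else NA_real_,
      var_random = fit$var_random, var_residual = fit$var_residual,
      var_fixed = fit$var_fixed, r2m = fit$r2m, r2c = fit$r2c,
      icc_adj = fit$icc_adj, icc_cond = fit$icc_cond,
      run_effect_class = classify_effect(fit$p[["run"]], fit$icc_adj,
                                         fit$icc_cond, alpha, tol),
      cv_random = cv[["cv_random"]], cv_intra = cv[["cv_intra"]],
      cv_syst = cv[["cv_syst"]],
      singular = fit$singular, stringsAsFactors = FALSE)
    if (fit$fixed == "run_leg" && "leg" %in% names(dd)) {
      for (lg in c("IL", "OL")) {
        i <- which(dd$leg == lg)[1]
        row[[paste0("diff_", lg)]] <- dd$diff[i]
        row[[paste0("diff_", lg, "_lo")]] <- dd$lower.CL[i]
        row[[paste0("diff_", lg, "_hi")]] <- dd$upper.CL[i]
      }
    } else {
      row$diff <- dd$diff[1]
      row$diff_lo <- dd$lower.CL[1]
      row$diff_hi <- dd$upper.CL[1]
    }
    key <- paste(met, ch, sep = ":")
    fits[[key]] <- fit
    out <- rbind_fill(out, row)
  }
  if (is.null(out)) stop("no data: nothing to analyze")
  attr(out, "fits") <- fits
  out
}

## rbind for data.frames whose columns may differ (run-only vs factorial rows)
rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA
  rbind(a, b[names(a)])
}
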