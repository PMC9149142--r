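#' Per-group summary of one outcome at one site
#'
#' Exact counts, means and sample standard deviations (divisor n-1) for the
#' two gender groups. These summaries are the sole ingredients of the
#' standardized effect a site releases.
#'
#' @param values Numeric per-subject scores.
#' @param groups Character per-subject gender, `"M"`/`"F"`.
#' @return A `group_summary`: list with `n`, `mean`, `sd`, each a named
#'   vector over `c("M", "F")`. `sd` is `NA` (flagged) for a group with
#'   fewer than 2 subjects.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (!all(groups %in% c("M", "F"))) {
    stop("groups must be coded M/F", call. = FALSE)
  }
  n <- c(M = sum(groups == "M"), F = sum(groups == "F"))
  if (any(n == 0L)) {
    stop("degenerate design: gender group(s) absent: ",
         paste(names(n)[n == 0L], collapse = ", "), call. = FALSE)
  }
  if (sum(n) < 3L) {
    stop("insufficient data: fewer than 3 subjects in total", call. = FALSE)
  }
  mu <- c(M = mean(values[groups == "M"]), F = mean(values[groups == "F"]))
  sdv <- c(M = if (n["M"] >= 2L) stats::sd(values[groups == "M"]) else NA_real_,
           F = if (n["F"] >= 2L) stats::sd(values[groups == "F"]) else NA_real_)
  structure(list(n = n, mean = mu, sd = sdv), class = "group_summary")
}

#' Cohen's d (F - M) and its sampling variance from group summaries
#'
#' Standardized mean difference in pooled-SD units, signed female minus
#' male so that the published convention (males more severe gives negative
#' d) holds:
#' \deqn{d = (\bar y_F - \bar y_M)/s_p,\quad
#'       s_p^2 = \frac{(n_M-1)s_M^2 + (n_F-1)s_F^2}{n_M+n_F-2}}
#' with the conventional large-sample variance
#' \deqn{v = \frac{n_M+n_F}{n_M n_F} + \frac{d^2}{2(n_M+n_F)}.}
#' No small-sample (Hedges) correction by default; set `correct = TRUE`
#' to multiply d by J = 1 - 3/(4 df - 1) (and v by J^2).
#'
#' @param gs A [group_summary()].
#' @param correct Apply the Hedges small-sample correction (default FALSE).
#' @return List with `d`, `v`, `n_M`, `n_F`.
#' @export
cohens_d <- function(gs, correct = FALSE) {
  stopifnot(inherits(gs, "group_summary"))
  n_M <- unname(gs$n["M"]); n_F <- unname(gs$n["F"])
  df <- n_M + n_F - 2L
  if (df < 1L) stop("insufficient data: pooled df < 1", call. = FALSE)
  ss <- function(g) if (gs$n[g] >= 2L) (gs$n[g] - 1L) * gs$sd[g]^2 else 0
  sp2 <- unname((ss("M") + ss("F")) / df)
  if (sp2 <= 0) {
    stop("zero-variance outcome: pooled SD is 0", call. = FALSE)
  }
  d <- unname((gs$mean["F"] - gs$mean["M"]) / sqrt(sp2))
  ntot <- n_M + n_F
  if (correct) d <- d * (1 - 3 / (4 * df - 1))
  v <- ntot / (n_M * n_F) + d^2 / (2 * ntot)
  list(d = d, v = v, n_M = n_M, n_F = n_F)
}

#' One site's standardized effect for one outcome
#'
#' @param site_id Site label. @param outcome One of [outcome_names()].
#' @param d Standardized mean difference (F - M, pooled-SD units).
#' @param v Sampling variance of d. @param n_M,n_F Group counts.
#' @return An `effect_estimate`.
#' @export
effect_estimate <- function(site_id, outcome, d, v, n_M, n_F) {
  if (!outcome %in% outcome_names()) {
    stop("unknown outcome '", outcome, "'", call. = FALSE)
  }
  if (!is.finite(v) || v <= 0) stop("v must be > 0", call. = FALSE)
  if (v < (n_M + n_F) / (n_M * n_F) - 1e-12) {
    stop("v below the count-only floor (n_M+n_F)/(n_M*n_F)", call. = FALSE)
  }
  structure(list(site_id = site_id, outcome = outcome, d = d, v = v,
                 n_M = as.integer(n_M), n_F = as.integer(n_F)),
            class = "effect_estimate")
}

#' Site-local analysis: score subjects, release only summary effects
#'
#' Runs the full within-site pipeline — scoring every subject, then one
#' standardized gender effect per outcome — and returns a flat record of
#' scalars and counts only. This is the complete payload a site shares; it
#' contains no container whose length scales with the site's sample size.
#'
#' @param table A validated [canonical_table()].
#' @param model A [factor_model()]. @param cw A [composite_weights()].
#' @param policy Missing-data policy forwarded to [score_table()].
#' @param correct Hedges small-sample correction flag (see [cohens_d()]).
#' @return A `local_result`: list with `site_id`, `effects` (data.frame:
#'   outcome, d, v, n_M, n_F — one row per outcome), `warnings`.
#' @export
local_compute <- function(table, model = default_factor_model(),
                          cw = default_composite_weights(),
                          policy = "error", correct = FALSE) {
  scores <- score_table(table, model, cw, policy = policy)
  warnings <- character()
  n <- c(M = sum(scores$gender == "M"), F = sum(scores$gender == "F"))
  if (any(n > 0L & n < 5L)) {
    warnings <- c(warnings, sprintf(
      "site '%s': small gender cell (n_M=%d, n_F=%d); estimates unstable",
      site_id(table), n["M"], n["F"]))
  }
  rows <- lapply(outcome_names(), function(oc) {
    est <- tryCatch(
      cohens_d(group_summary(scores[[oc]], scores$gender), correct = correct),
      error = function(e) {
        stop("site '", site_id(table), "', outcome '", oc, "': ",
             conditionMessage(e), call. = FALSE)
      })
    data.frame(outcome = oc, d = est$d, v = est$v,
               n_M = est$n_M, n_F = est$n_F, stringsAsFactors = FALSE)
  })
  effects <- do.call(rbind, rows)
  rownames(effects) <- NULL
  structure(list(site_id = site_id(table), effects = effects,
                 warnings = warnings),
            class = "local_result")
}

#' @export
print.local_result <- function(x, ...) {
  cat("Local result for site '", x$site_id, "' (",
      x$effects$n_M[1], " M / ", x$effects$n_F[1], " F):\n", sep = "")
  print(cbind(outcome = x$effects$outcome,
              round(x$effects[, c("d", "v")], 4)), row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
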