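#' Cochran's Q heterogeneity statistic
#'
#' \deqn{Q = \sum_i w_i (d_i - \bar d)^2,\quad w_i = 1/v_i,\quad
#'       \bar d = \sum w_i d_i / \sum w_i} (fixed-effect weights).
#' Q is 0 for a single estimate.
#'
#' @param d Numeric effect estimates. @param v Their sampling variances.
#' @return Q (length 1).
#' @export
cochran_q <- function(d, v) {
  stopifnot(length(d) == length(v), length(d) >= 1L, all(v > 0))
  if (length(d) == 1L) return(0)
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  sum(w * (d - dbar)^2)
}

#' DerSimonian-Laird estimator of the between-site variance tau^2
#'
#' Closed-form moment estimator,
#' \deqn{\hat\tau^2 = \max\left(0, \frac{Q - (k-1)}{C}\right),\quad
#'       C = \sum w_i - \frac{\sum w_i^2}{\sum w_i}}
#' with fixed-effect weights \eqn{w_i = 1/v_i} (classical, non-iterated).
#'
#' @inheritParams cochran_q
#' @return tau^2 (>= 0).
#' @export
dl_tau2 <- function(d, v) {
  k <- length(d)
  stopifnot(length(v) == k, k >= 1L, all(v > 0))
  if (k <= 1L) return(0)
  w <- 1 / v
  C <- sum(w) - sum(w^2) / sum(w)
  if (C <= 0) return(0)
  max(0, (cochran_q(d, v) - (k - 1)) / C)
}

#' REML estimator of the between-site variance tau^2
#'
#' Maximizes the restricted log-likelihood of the normal-normal model
#' \deqn{\ell_R(\tau^2) = -\tfrac12\sum\log(v_i+\tau^2)
#'   -\tfrac12\log\sum w_i -\tfrac12\sum w_i (d_i-\hat\mu)^2,
#'   \quad w_i = 1/(v_i+\tau^2)}
#' over \eqn{\tau^2 \ge 0} by safeguarded bisection on the restricted
#' score (the derivative of \eqn{\ell_R}): if the score at 0 is
#' non-positive the boundary solution 0 is returned directly; otherwise
#' the root is bracketed by doubling and bisected until the bracket is
#' narrower than `tol`. Bisection is preferred over scoring iterations
#' here because the expected information can badly mismatch the realized
#' curvature on small, unbalanced instances, producing slow oscillation.
#'
#' @inheritParams cochran_q
#' @param tol Convergence tolerance on |delta tau^2|.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   last iterate.
#' @return tau^2 (>= 0).
#' @export
reml_tau2 <- function(d, v, tol = 1e-10, max_iter = 100L) {
  k <- length(d)
  stopifnot(length(v) == k, all(v > 0))
  if (k < 2L) stop("REML requires at least 2 estimates", call. = FALSE)

  score <- function(t) {
    w <- 1 / (v + t)
    mu <- sum(w * d) / sum(w)
    -0.5 * sum(w) + 0.5 * sum(w^2 * (d - mu)^2) + 0.5 * sum(w^2) / sum(w)
  }
  if (score(0) <= 0) return(0)
  lo <- 0
  hi <- max(2 * dl_tau2(d, v), 0.1)
  expand <- 0L
  while (score(hi) > 0 && expand < 60L) {
    lo <- hi
    hi <- 2 * hi
    expand <- expand + 1L
  }
  if (score(hi) > 0) {
    stop("REML for tau^2 did not converge: score positive up to ",
         format(hi), call. = FALSE)
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) return((lo + hi) / 2)
  }
  stop("REML for tau^2 did not converge within ", max_iter,
       " iterations (last iterate ", format((lo + hi) / 2), ")",
       call. = FALSE)
}

#' I^2: percent of total variability attributed to heterogeneity
#'
#' \deqn{I^2 = 100\,\max(0, (Q - (k-1))/Q)}; 0 when Q = 0.
#'
#' @param Q Cochran's Q. @param k Number of estimates.
#' @return I^2 in percent, within [0, 100].
#' @export
i_squared <- function(Q, k) {
  stopifnot(k >= 1L, Q >= 0)
  if (Q == 0) return(0)
  100 * max(0, (Q - (k - 1)) / Q)
}

#' Two-sided Wald confidence interval
#'
#' @param d Estimate. @param se Standard error. @param level Confidence
#'   level (default 0.95; critical value 1.959964...).
#' @return Numeric `c(lb, ub)`.
#' @export
wald_ci <- function(d, se, level = 0.95) {
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  c(lb = d - z_crit * se, ub = d + z_crit * se)
}

#' Pool estimates with random-effects weights at a given tau^2
#'
#' \deqn{w_i^* = 1/(v_i+\tau^2),\quad \hat d = \sum w_i^* d_i / \sum w_i^*,
#'   \quad SE = (\sum w_i^*)^{-1/2}} with Wald z, two-sided normal p, and
#' Wald confidence bounds.
#'
#' @inheritParams cochran_q
#' @param tau2 Between-site variance.
#' @param level Confidence level.
#' @return List: d_pooled, se, z, p, ci_lb, ci_ub, tau2, Q, I2, k.
#' @export
pool_random_effects <- function(d, v, tau2, level = 0.95) {
  k <- length(d)
  stopifnot(length(v) == k, k >= 1L, all(v > 0), tau2 >= 0)
  w <- 1 / (v + tau2)
  d_pooled <- sum(w * d) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- d_pooled / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- wald_ci(d_pooled, se, level)
  Q <- cochran_q(d, v)
  list(d_pooled = d_pooled, se = se, z = z, p = p,
       ci_lb = unname(ci["lb"]), ci_ub = unname(ci["ub"]),
       tau2 = tau2, Q = Q, I2 = i_squared(Q, k), k = k)
}

#' Fit the random-effects meta-analysis across sites
#'
#' The central aggregation step: for each outcome, estimate the
#' between-site variance (DerSimonian-Laird by default, or REML), pool the
#' site effects with inverse-variance random-effects weights, and attach
#' Wald inference and heterogeneity statistics. Input is the list of
#' summary-only site payloads; no record-level data is involved.
#'
#' @param locals List of `local_result` objects (from [local_compute()] or
#'   reconstructed from audited messages). All sites must report the same
#'   outcome set.
#' @param estimator `"DL"` (default) or `"REML"`.
#' @param level Confidence level for the Wald intervals.
#' @return A `meta_result`: list with `pooled` (one row per outcome:
#'   outcome, k, d, se, z, p, ci_lb, ci_ub, tau2, Q, I2), `sites` (the
#'   per-site effect rows), `estimator`, `level`. Methods: `print`,
#'   `summary`, `coef`, `plot`, [forest_rows()], [flag_outlier_sites()].
#' @export
meta_analyze <- function(locals, estimator = c("DL", "REML"), level = 0.95) {
  estimator <- match.arg(estimator)
  stopifnot(length(locals) >= 1L, level > 0, level < 1)
  outcome_sets <- lapply(locals, function(l) sort(l$effects$outcome))
  ref <- outcome_sets[[1L]]
  for (i in seq_along(outcome_sets)) {
    if (!identical(outcome_sets[[i]], ref)) {
      asym <- union(setdiff(outcome_sets[[i]], ref),
                    setdiff(ref, outcome_sets[[i]]))
      stop("aggregation error: outcome sets differ across sites (",
           paste(asym, collapse = ", "), ")", call. = FALSE)
    }
  }
  sites <- do.call(rbind, lapply(locals, function(l) {
    cbind(site_id = l$site_id, l$effects, stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  outcomes <- intersect(outcome_names(), ref)
  pooled <- do.call(rbind, lapply(outcomes, function(oc) {
    rows <- sites[sites$outcome == oc, ]
    tau2 <- if (estimator == "DL" || nrow(rows) < 2L) {
      dl_tau2(rows$d, rows$v)
    } else {
      reml_tau2(rows$d, rows$v)
    }
    p <- pool_random_effects(rows$d, rows$v, tau2, level)
    data.frame(outcome = oc, k = p$k, d = p$d_pooled, se = p$se, z = p$z,
               p = p$p, ci_lb = p$ci_lb, ci_ub = p$ci_ub, tau2 = p$tau2,
               Q = p$Q, I2 = p$I2, stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  structure(list(pooled = pooled, sites = sites, estimator = estimator,
                 level = level, k = length(locals)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Random-effects meta-analysis (", x$estimator, ", ",
      format(100 * x$level), "% Wald CI, k = ", x$k, " sites)\n\n", sep = "")
  tab <- x$pooled
  out <- data.frame(outcome = tab$outcome,
                    d = round_report(tab$d), SE = round_report(tab$se),
                    z = round_report(tab$z), p = round_report(tab$p),
                    ci.lb = round_report(tab$ci_lb),
                    ci.ub = round_report(tab$ci_ub),
                    tau2 = round_report(tab$tau2),
                    Q = round_report(tab$Q), I2 = round_report(tab$I2),
                    stringsAsFactors = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.meta_result <- function(object, ...) {
  stats::setNames(object$pooled$d, object$pooled$outcome)
}

#' @export
summary.meta_result <- function(object, outlier_threshold = 3, ...) {
  flags <- if (object$k >= 2L) {
    flag_outlier_sites(object, threshold = outlier_threshold)
  } else NULL
  structure(list(result = object, flags = flags,
                 outlier_threshold = outlier_threshold),
            class = "summary.meta_result")
}

#' @export
print.summary.meta_result <- function(x, ...) {
  print(x$result)
  if (!is.null(x$flags)) {
    n_flag <- sum(x$flags$flagged)
    cat("\nSite-outlier check (|standardized deviation| > ",
        x$outlier_threshold, "): ", n_flag, " flagged\n", sep = "")
    if (n_flag) {
      print(x$flags[x$flags$flagged, c("site_id", "outcome", "z_dev")],
            row.names = FALSE)
    }
  }
  invisible(x)
}

#' Flag sites whose effect deviates from the pooled value
#'
#' A site is flagged for an outcome when
#' \eqn{|d_i - \hat d| / \sqrt{v_i + \hat\tau^2}} exceeds `threshold`
#' (default 3) — the QC check recommended when aggregating summary
#' statistics one cannot inspect directly.
#'
#' @param result A `meta_result` with k >= 2 sites.
#' @param threshold Flagging threshold on the standardized deviation.
#' @return data.frame: site_id, outcome, z_dev, flagged.
#' @export
flag_outlier_sites <- function(result, threshold = 3) {
  stopifnot(inherits(result, "meta_result"))
  if (result$k < 2L) stop("outlier check needs at least 2 sites",
                          call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(result$pooled)), function(i) {
    oc <- result$pooled$outcome[i]
    rows <- result$sites[result$sites$outcome == oc, ]
    z_dev <- abs(rows$d - result$pooled$d[i]) /
      sqrt(rows$v + result$pooled$tau2[i])
    data.frame(site_id = rows$site_id, outcome = oc, z_dev = z_dev,
               flagged = z_dev > threshold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Forest-table rows for one outcome
#'
#' Per-site point estimates with site-level Wald intervals (using
#' \eqn{\sqrt{v_i}}), random-effects weight percentages (summing to 100),
#' and the pooled summary row.
#'
#' @param result A `meta_result`. @param outcome One of its outcomes.
#' @return A `forest_table`: list with `outcome`, `rows` (site_id, d,
#'   ci_lb, ci_ub, weight), `summary` (pooled row), `level`, `estimator`.
#' @export
forest_rows <- function(result, outcome) {
  stopifnot(inherits(result, "meta_result"))
  hit <- result$pooled$outcome == outcome
  if (!any(hit)) stop("unknown outcome '", outcome, "'", call. = FALSE)
  pooled <- result$pooled[hit, ]
  rows <- result$sites[result$sites$outcome == outcome, ]
  w <- 1 / (rows$v + pooled$tau2)
  ci <- t(vapply(seq_len(nrow(rows)), function(i) {
    wald_ci(rows$d[i], sqrt(rows$v[i]), result$level)
  }, numeric(2)))
  tab <- data.frame(site_id = rows$site_id, d = rows$d,
                    ci_lb = ci[, 1], ci_ub = ci[, 2],
                    weight = 100 * w / sum(w), stringsAsFactors = FALSE)
  structure(list(outcome = outcome, rows = tab,
                 summary = data.frame(d = pooled$d, ci_lb = pooled$ci_lb,
                                      ci_ub = pooled$ci_ub),
                 level = result$level, estimator = result$estimator),
            class = "forest_table")
}
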