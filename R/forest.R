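#' Round for reporting: half away from zero, mixed precision
#'
#' Reported tables use 2 decimal places, switching to 3 when |x| < 0.05 so
#' small effects and p-values near the significance boundary stay visible
#' (0.047 rather than 0.05). Ties round away from zero. Full precision is
#' always retained internally; this rule applies only at the reporting
#' surface.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded under the reporting rule.
#' @export
round_report <- function(x) {
  digits <- ifelse(abs(x) < 0.05, 3L, 2L)
  round_half_away(x, digits)
}

#' @rdname round_report
#' @param digits Decimal places.
#' @export
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Plain-text forest rendering
#'
#' Deterministic fixed-width text: one line per site with d, the site-level
#' confidence interval, the random-effects weight, and an ASCII interval
#' track with a vertical zero line; a summary line carries the pooled
#' diamond. Suitable for terminals and golden-file comparison.
#'
#' @param ft A [forest_rows()] table.
#' @param width Character width of the interval track (default 40).
#' @return Character vector of lines.
#' @export
format_forest_text <- function(ft, width = 40L) {
  stopifnot(inherits(ft, "forest_table"), width >= 11L)
  lo <- min(ft$rows$ci_lb, ft$summary$ci_lb, 0)
  hi <- max(ft$rows$ci_ub, ft$summary$ci_ub, 0)
  pad <- 0.05 * (hi - lo + 1e-9)
  lo <- lo - pad; hi <- hi + pad
  pos <- function(x) 1L + as.integer(round((x - lo) / (hi - lo) * (width - 1)))
  zero_at <- pos(0)
  track <- function(d, l, u, marker) {
    ch <- rep(" ", width)
    ch[seq(pos(l), pos(u))] <- "-"
    ch[zero_at] <- "|"
    ch[pos(d)] <- marker
    paste(ch, collapse = "")
  }
  fmt <- function(x) formatC(round_half_away(x, 2), format = "f", digits = 2,
                             width = 6)
  header <- sprintf("%-10s %6s  [%6s, %6s] %7s  %s", "site", "d", "lb", "ub",
                    "weight", "")
  lines <- vapply(seq_len(nrow(ft$rows)), function(i) {
    r <- ft$rows[i, ]
    sprintf("%-10s %s  [%s, %s] %6.1f%%  %s", r$site_id, fmt(r$d),
            fmt(r$ci_lb), fmt(r$ci_ub), r$weight,
            track(r$d, r$ci_lb, r$ci_ub, "o"))
  }, character(1))
  s <- ft$summary
  summary_line <- sprintf("%-10s %s  [%s, %s] %7s  %s", "RE pooled",
                          fmt(s$d), fmt(s$ci_lb), fmt(s$ci_ub), "",
                          track(s$d, s$ci_lb, s$ci_ub, "<"))
  c(sprintf("%s (random effects, %s, %s%% CI)", ft$outcome, ft$estimator,
            format(100 * ft$level)),
    header, lines, strrep("-", nchar(summary_line[1])), summary_line)
}

#' Render a forest display
#'
#' Draws the per-site intervals, the pooled diamond and the zero line with
#' base graphics. `plot.meta_result` is a convenience wrapper selecting one
#' outcome.
#'
#' @param ft A [forest_rows()] table.
#' @param main Title (defaults to the outcome).
#' @return Invisibly, `ft`.
#' @export
render_forest <- function(ft, main = NULL) {
  stopifnot(inherits(ft, "forest_table"), nrow(ft$rows) >= 1L)
  if (is.null(main)) {
    main <- sprintf("Gender effect on %s (random effects, %s)",
                    ft$outcome, ft$estimator)
  }
  k <- nrow(ft$rows)
  ys <- rev(seq_len(k)) + 1
  xlim <- range(ft$rows$ci_lb, ft$rows$ci_ub, ft$summary$ci_lb,
                ft$summary$ci_ub, 0)
  old <- graphics::par(mar = c(4, 7, 3, 5))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = xlim, ylim = c(0.3, k + 1.7), yaxt = "n",
                 xlab = "Cohen's d (F - M)", ylab = "", main = main,
                 bty = "n")
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::segments(ft$rows$ci_lb, ys, ft$rows$ci_ub, ys)
  graphics::points(ft$rows$d, ys, pch = 15,
                   cex = 0.6 + 1.6 * ft$rows$weight / max(ft$rows$weight))
  graphics::axis(2, at = ys, labels = ft$rows$site_id, las = 1, tick = FALSE)
  graphics::axis(4, at = ys, las = 1, tick = FALSE,
                 labels = sprintf("%.1f%%", ft$rows$weight))
  s <- ft$summary
  h <- 0.25
  graphics::polygon(c(s$ci_lb, s$d, s$ci_ub, s$d), c(1, 1 + h, 1, 1 - h),
                    col = "grey30", border = NA)
  graphics::axis(2, at = 1, labels = "RE pooled", las = 1, tick = FALSE)
  invisible(ft)
}

#' @export
#' @rdname render_forest
#' @param x A `meta_result`. @param outcome Outcome to display.
#' @param ... Passed to [render_forest()].
plot.meta_result <- function(x, outcome = "EXP", ...) {
  render_forest(forest_rows(x, outcome), ...)
}
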