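#' Iterative federated regression of an outcome on gender (and age)
#'
#' The round-based federation mode: the aggregator and the sites exchange
#' model-level quantities until the pooled least-squares fit of
#' `score ~ intercept + gender [+ age]` is reached — without any site ever
#' releasing subject-level data.
#'
#' Two modes:
#' \describe{
#'   \item{`sufficient_stats`}{one round; each site sends its cross-product
#'     block (X'X, X'y, y'y, n) and the aggregator solves the pooled normal
#'     equations — exactly the least-squares fit on the concatenated data.}
#'   \item{`gradient`}{an initial curvature round (each site sends
#'     diag(X'X) and n), then repeated rounds of broadcast coefficients /
#'     returned gradients with a fixed step 1/L, L = trace of the pooled
#'     per-observation curvature; iterates until the largest coefficient
#'     change is below `tol`, converging to the sufficient-statistics
#'     solution.}
#' }
#' The gender predictor is an F indicator (0 = M, 1 = F); `age`, when
#' requested, is standardized with the pooled mean and SD obtained in a
#' preliminary moment round, so the fit still equals the centralized one.
#' Every site-to-aggregator payload passes [privacy_guard()].
#'
#' @param spec A [consortium_spec()].
#' @param site_tables Named list of [canonical_table()]s.
#' @param outcome One of [outcome_names()].
#' @param predictors Character subset of `c("gender", "age")`.
#' @param mode `"sufficient_stats"` (default) or `"gradient"`.
#' @param tol Convergence tolerance on the max absolute coefficient change
#'   (gradient mode).
#' @param max_rounds Round cap for gradient mode; exceeding it is an error
#'   reporting the round count.
#' @param model,cw Scoring configuration.
#' @return List: `coefficients` (named), `mode`, `rounds`, `sigma`
#'   (residual SD, n - p df), `n`, `log` (a `run_log`).
#' @export
run_iterative_regression <- function(spec, site_tables, outcome = "Total",
                                     predictors = "gender",
                                     mode = c("sufficient_stats", "gradient"),
                                     tol = 1e-10, max_rounds = 10000L,
                                     model = default_factor_model(),
                                     cw = default_composite_weights()) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "consortium_spec"),
            all(predictors %in% c("gender", "age")))
  missing_tables <- setdiff(spec$members, names(site_tables))
  if (length(missing_tables)) {
    stop("consortium error: member(s) without a mapped table: ",
         paste(missing_tables, collapse = ", "), call. = FALSE)
  }
  use_age <- "age" %in% predictors
  coef_names <- c("(Intercept)",
                  if ("gender" %in% predictors) "genderF",
                  if (use_age) "age_std")
  p <- length(coef_names)
  messages <- list()
  push <- function(direction, round, site, payload) {
    messages[[length(messages) + 1L]] <<-
      new_message(direction, round, site, payload)
  }

  site_data <- lapply(spec$members, function(s) {
    tab <- site_tables[[s]]
    scores <- score_table(tab, model, cw, policy = spec$parameters$policy)
    y <- scores[[outcome]]
    age <- if (use_age) {
      if (is.null(tab$age)) stop("site '", s, "' has no age column",
                                 call. = FALSE)
      as.numeric(tab$age)[match(scores$subject_id, tab$subject_id)]
    } else NULL
    list(y = y, gender = as.numeric(scores$gender == "F"), age = age)
  })
  names(site_data) <- spec$members

  round_idx <- 0L
  age_center <- NULL
  if (use_age) {
    # moment round: pooled mean/SD of age so standardization is global
    round_idx <- round_idx + 1L
    moments <- lapply(spec$members, function(s) {
      a <- site_data[[s]]$age
      pl <- list(sum = sum(a), sumsq = sum(a^2), n = length(a))
      push("site_to_aggregator", round_idx, s, pl)
      pl
    })
    N <- sum(vapply(moments, `[[`, numeric(1), "n"))
    mu <- sum(vapply(moments, `[[`, numeric(1), "sum")) / N
    ssq <- sum(vapply(moments, `[[`, numeric(1), "sumsq"))
    sd_a <- sqrt((ssq - N * mu^2) / (N - 1))
    age_center <- c(mean = mu, sd = sd_a)
  }
  design <- function(s) {
    dat <- site_data[[s]]
    X <- cbind(1, if ("gender" %in% predictors) dat$gender,
               if (use_age) (dat$age - age_center["mean"]) /
                 age_center["sd"])
    colnames(X) <- coef_names
    X
  }

  if (mode == "sufficient_stats") {
    round_idx <- round_idx + 1L
    blocks <- lapply(spec$members, function(s) {
      X <- design(s); y <- site_data[[s]]$y
      pl <- list(XtX = crossprod(X), Xty = as.vector(crossprod(X, y)),
                 yty = sum(y^2), n = nrow(X))
      privacy_guard(pl, site_n = nrow(X), kind = "suffstats", p = p)
      push("site_to_aggregator", round_idx, s, pl)
      pl
    })
    XtX <- Reduce(`+`, lapply(blocks, `[[`, "XtX"))
    Xty <- Reduce(`+`, lapply(blocks, `[[`, "Xty"))
    yty <- sum(vapply(blocks, `[[`, numeric(1), "yty"))
    N <- sum(vapply(blocks, `[[`, numeric(1), "n"))
    if (qr(XtX)$rank < p) {
      stop("rank error: pooled design is singular", call. = FALSE)
    }
    beta <- solve(XtX, Xty)
    rss <- yty - sum(beta * Xty)
    rounds_used <- round_idx
  } else {
    round_idx <- round_idx + 1L
    curv <- lapply(spec$members, function(s) {
      X <- design(s)
      pl <- list(gradient = diag(crossprod(X)), n = nrow(X))
      privacy_guard(pl, site_n = nrow(X), kind = "gradient", p = p)
      push("site_to_aggregator", round_idx, s, pl)
      pl
    })
    N <- sum(vapply(curv, `[[`, numeric(1), "n"))
    L <- sum(Reduce(`+`, lapply(curv, `[[`, "gradient"))) / N
    step <- 1 / L
    beta <- rep(0, p)
    converged <- FALSE
    for (r in seq_len(max_rounds)) {
      round_idx <- round_idx + 1L
      grads <- lapply(spec$members, function(s) {
        push("aggregator_to_site", round_idx, s, list(beta = beta))
        X <- design(s); y <- site_data[[s]]$y
        pl <- list(gradient = as.vector(crossprod(X, X %*% beta - y)),
                   n = nrow(X))
        privacy_guard(pl, site_n = nrow(X), kind = "gradient", p = p)
        push("site_to_aggregator", round_idx, s, pl)
        pl
      })
      g <- Reduce(`+`, lapply(grads, `[[`, "gradient")) / N
      beta_new <- beta - step * g
      delta <- max(abs(beta_new - beta))
      beta <- beta_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop("gradient mode did not converge within ", max_rounds,
           " rounds (last max coefficient change ", format(delta), ")",
           call. = FALSE)
    }
    yty <- sum(vapply(spec$members,
                      function(s) sum(site_data[[s]]$y^2), numeric(1)))
    Xty <- Reduce(`+`, lapply(spec$members, function(s) {
      as.vector(crossprod(design(s), site_data[[s]]$y))
    }))
    rss <- yty - sum(beta * Xty)
    rounds_used <- round_idx
  }
  beta <- stats::setNames(as.vector(beta), coef_names)
  log <- structure(list(consortium = spec$name,
                        pipeline = paste0(spec$pipeline, ":regression"),
                        parameters = list(outcome = outcome,
                                          predictors = predictors,
                                          mode = mode, tol = tol),
                        messages = messages,
                        status = stats::setNames(
                          rep("complete", length(spec$members)),
                          spec$members),
                        access_log = NULL),
                   class = "run_log")
  list(coefficients = beta, mode = mode, rounds = rounds_used,
       sigma = sqrt(max(rss, 0) / (N - p)), n = N,
       age_standardization = age_center, log = log)
}
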