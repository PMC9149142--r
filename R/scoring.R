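#' SANS factor model: item-to-factor structure and weights
#'
#' Defines which of the 25 SANS items feed each of the five negative-symptom
#' factors (Anhedonia, Asociality, Avolition, BluntedAffect, Alogia), the
#' per-item weights within each factor, and the item set summed for the
#' Total score. Factor scores are weighted means by default, so they live on
#' the same 0-5 scale as the items regardless of how many items a factor
#' has; the Total is a plain sum over its item set.
#'
#' @param item_sets Named list, factor name -> integer vector of item
#'   indices (1-25). Names must be exactly the five factor names.
#' @param item_weights Optional named list, factor name -> numeric weights
#'   (same length as the item set, non-negative, summing to 1). Default:
#'   equal weights, i.e. the factor score is the mean of its items.
#' @param total_item_set Integer vector of item indices summed for Total.
#' @return A `factor_model`.
#' @export
factor_model <- function(item_sets, item_weights = NULL, total_item_set) {
  expected <- c("Anhedonia", "Asociality", "Avolition",
                "BluntedAffect", "Alogia")
  if (!setequal(names(item_sets), expected)) {
    stop("item_sets must be named exactly: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  item_sets <- item_sets[expected]
  for (f in expected) {
    idx <- item_sets[[f]]
    if (!length(idx) || !all(idx %in% 1:25)) {
      stop("item set for factor '", f,
           "' must be a non-empty subset of 1..25", call. = FALSE)
    }
  }
  if (is.null(item_weights)) {
    item_weights <- lapply(item_sets, function(idx) rep(1 / length(idx),
                                                        length(idx)))
  }
  item_weights <- item_weights[expected]
  for (f in expected) {
    w <- item_weights[[f]]
    if (length(w) != length(item_sets[[f]]) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8) {
      stop("weights for factor '", f, "' must be non-negative, one per ",
           "item, and sum to 1", call. = FALSE)
    }
  }
  if (!length(total_item_set) || !all(total_item_set %in% 1:25)) {
    stop("total_item_set must be a non-empty subset of 1..25", call. = FALSE)
  }
  structure(list(item_sets = item_sets, item_weights = item_weights,
                 total_item_set = sort(unique(total_item_set))),
            class = "factor_model")
}

#' Default SANS factor structure shipped with the package
#'
#' A pinned, documented convention (the literature's factor solutions vary
#' and the composite weights of published two-factor models are not
#' standardized): the four SANS symptom subscales map onto the five factors
#' with the anhedonia-asociality subscale split in two, the five global
#' ratings (items 8, 13, 17, 22, 25) are excluded from factors, and the
#' Total sums the 20 non-global items (so an all-5 record totals 100).
#'
#' \itemize{
#'   \item BluntedAffect: items 1-7 (affective flattening)
#'   \item Alogia: items 9-12
#'   \item Avolition: items 14-16 (avolition-apathy)
#'   \item Anhedonia: items 18-19
#'   \item Asociality: items 20-21
#'   \item Total: items 1-7, 9-12, 14-16, 18-21, 23-24
#' }
#' Everything here is overridable through [factor_model()] or a config file.
#'
#' @return A `factor_model`.
#' @export
default_factor_model <- function() {
  factor_model(
    item_sets = list(
      BluntedAffect = 1:7,
      Alogia        = 9:12,
      Avolition     = 14:16,
      Anhedonia     = 18:19,
      Asociality    = 20:21),
    total_item_set = c(1:7, 9:12, 14:16, 18:21, 23:24))
}

#' Two-factor composite weights (MAP / EXP)
#'
#' MAP (Motivation and Pleasure) is a weighted combination of Anhedonia,
#' Asociality and Avolition; EXP (Expressiveness) of BluntedAffect and
#' Alogia. Default: equal weights within each composite.
#'
#' @param map_weights Named non-negative weights over
#'   (Anhedonia, Asociality, Avolition), summing to 1.
#' @param exp_weights Named non-negative weights over
#'   (BluntedAffect, Alogia), summing to 1.
#' @return A `composite_weights` object.
#' @export
composite_weights <- function(
    map_weights = c(Anhedonia = 1 / 3, Asociality = 1 / 3, Avolition = 1 / 3),
    exp_weights = c(BluntedAffect = 0.5, Alogia = 0.5)) {
  check_w <- function(w, want, label) {
    if (!setequal(names(w), want)) {
      stop(label, " must be named over: ", paste(want, collapse = ", "),
           call. = FALSE)
    }
    w <- w[want]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      stop(label, " must be non-negative and sum to 1", call. = FALSE)
    }
    w
  }
  map_weights <- check_w(map_weights,
                         c("Anhedonia", "Asociality", "Avolition"),
                         "map_weights")
  exp_weights <- check_w(exp_weights, c("BluntedAffect", "Alogia"),
                         "exp_weights")
  structure(list(map_weights = map_weights, exp_weights = exp_weights),
            class = "composite_weights")
}

#' @rdname composite_weights
#' @export
default_composite_weights <- function() composite_weights()

# Resolve one subject's item vector against a factor's weights under a
# missing-data policy. Returns the weighted combination or NA (drop).
weighted_items <- function(items, idx, w, policy, label, subject) {
  x <- items[idx]
  if (anyNA(x)) {
    if (policy == "error") {
      miss <- sans_item_names()[idx[is.na(x)][1L]]
      stop("missing item ", miss, " for subject '", subject,
           "' required by ", label,
           " (missing-data policy 'error')", call. = FALSE)
    }
    if (policy == "drop") return(NA_real_)
    keep <- !is.na(x)
    if (!any(keep)) {
      stop("all items of ", label, " missing for subject '", subject, "'",
           call. = FALSE)
    }
    w <- w[keep] / sum(w[keep])
    x <- x[keep]
  }
  sum(w * x)
}

#' Total SANS score for one subject
#'
#' Sum of the ratings over the model's Total item set. Under
#' `policy = "prorate"` a partially missing record contributes the mean of
#' its present Total-set items scaled up to the full set size.
#'
#' @param items Numeric vector of 25 item ratings (NA = missing).
#' @param model A [factor_model()].
#' @param policy Missing-data policy: `"error"`, `"drop"` (returns NA), or
#'   `"prorate"`.
#' @param subject Subject label used in error messages.
#' @return Numeric total (length 1).
#' @export
total_score <- function(items, model = default_factor_model(),
                        policy = c("error", "drop", "prorate"),
                        subject = "?") {
  policy <- match.arg(policy)
  stopifnot(length(items) == 25L)
  idx <- model$total_item_set
  m <- length(idx)
  mean_rating <- weighted_items(as.numeric(items), idx, rep(1 / m, m),
                                policy, "the Total score", subject)
  m * mean_rating
}

#' Five-factor scores for one subject
#'
#' Each factor score is the weighted combination (default: mean) of its
#' items, so it shares the items' 0-5 scale.
#'
#' @inheritParams total_score
#' @return Named numeric vector of the five factor scores.
#' @export
factor_scores <- function(items, model = default_factor_model(),
                          policy = c("error", "drop", "prorate"),
                          subject = "?") {
  policy <- match.arg(policy)
  stopifnot(length(items) == 25L)
  items <- as.numeric(items)
  vapply(names(model$item_sets), function(f) {
    weighted_items(items, model$item_sets[[f]], model$item_weights[[f]],
                   policy, paste0("factor '", f, "'"), subject)
  }, numeric(1))
}

#' MAP / EXP composite scores from five factor scores
#'
#' @param five Named numeric vector of the five factor scores.
#' @param cw A [composite_weights()].
#' @return Named numeric vector `c(MAP = , EXP = )`.
#' @export
composite_scores <- function(five, cw = default_composite_weights()) {
  stopifnot(inherits(cw, "composite_weights"))
  if (!all(is.finite(five))) stop("factor scores must be finite",
                                  call. = FALSE)
  c(MAP = sum(cw$map_weights * five[names(cw$map_weights)]),
    EXP = sum(cw$exp_weights * five[names(cw$exp_weights)]))
}

#' Score every subject in a canonical table
#'
#' Vectorised scoring of the Total, five factors, and MAP/EXP composites.
#' Records failing the missing-data policy are dropped under
#' `policy = "drop"` and raise under `policy = "error"`.
#'
#' @param table A [canonical_table()].
#' @param model A [factor_model()].
#' @param cw A [composite_weights()].
#' @param policy Missing-data policy (see [total_score()]).
#' @return data.frame: subject_id, gender, then one column per outcome in
#'   [outcome_names()] order.
#' @export
score_table <- function(table, model = default_factor_model(),
                        cw = default_composite_weights(),
                        policy = c("error", "drop", "prorate")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "canonical_table"))
  X <- item_matrix(table)
  n <- nrow(X)
  required <- sort(unique(c(model$total_item_set,
                            unlist(model$item_sets, use.names = FALSE))))
  has_missing <- rowSums(is.na(X[, required, drop = FALSE])) > 0L
  if (policy == "error" && any(has_missing)) {
    r <- which(has_missing)[1L]
    it <- required[which(is.na(X[r, required]))[1L]]
    stop("missing item ", sans_item_names()[it], " for subject '",
         table$subject_id[r], "' at site '", site_id(table),
         "' (missing-data policy 'error')", call. = FALSE)
  }
  keep <- if (policy == "drop") !has_missing else rep(TRUE, n)
  X <- X[keep, , drop = FALSE]
  if (!nrow(X)) stop("no usable records at site '", site_id(table),
                     "' after dropping incomplete subjects", call. = FALSE)

  score_factor <- function(idx, w) {
    sub <- X[, idx, drop = FALSE]
    if (policy == "prorate" && anyNA(sub)) {
      W <- matrix(w, nrow(sub), length(w), byrow = TRUE)
      W[is.na(sub)] <- 0
      sw <- rowSums(W)
      if (any(sw == 0)) {
        stop("all items of a factor missing for subject '",
             rownames(sub)[which(sw == 0)[1L]], "'", call. = FALSE)
      }
      rowSums(W * sub, na.rm = TRUE) / sw
    } else {
      as.vector(sub %*% w)
    }
  }
  five <- vapply(names(model$item_sets), function(f) {
    score_factor(model$item_sets[[f]], model$item_weights[[f]])
  }, numeric(nrow(X)))
  five <- matrix(five, nrow = nrow(X),
                 dimnames = list(NULL, names(model$item_sets)))
  m_tot <- length(model$total_item_set)
  total <- m_tot * score_factor(model$total_item_set, rep(1 / m_tot, m_tot))
  map <- as.vector(five[, names(cw$map_weights), drop = FALSE] %*%
                     cw$map_weights)
  exp_ <- as.vector(five[, names(cw$exp_weights), drop = FALSE] %*%
                      cw$exp_weights)
  out <- data.frame(subject_id = table$subject_id[keep],
                    gender = table$gender[keep],
                    Total = total, MAP = map, EXP = exp_,
                    stringsAsFactors = FALSE)
  for (f in c("Anhedonia", "Asociality", "Avolition",
              "BluntedAffect", "Alogia")) {
    out[[f]] <- five[, f]
  }
  out
}

#' Serialize / restore the scoring configuration
#'
#' The factor model and composite weights are written as one structured
#' config (YAML or JSON) and echoed into every results document so a run is
#' reproducible from its outputs alone.
#'
#' @param model A [factor_model()]. @param cw A [composite_weights()].
#' @param path Config file path (.yaml/.yml/.json).
#' @export
write_scoring_config <- function(model, cw, path) {
  obj <- scoring_config_list(model, cw)
  write_config(obj, path)
}

#' @rdname write_scoring_config
#' @export
read_scoring_config <- function(path) {
  cfg <- read_config(path)
  scoring_from_list(cfg)
}

scoring_config_list <- function(model, cw) {
  list(factor_model = list(
         item_sets = lapply(model$item_sets, as.integer),
         item_weights = model$item_weights,
         total_item_set = as.integer(model$total_item_set)),
       composite_weights = list(
         map_weights = as.list(cw$map_weights),
         exp_weights = as.list(cw$exp_weights)))
}

scoring_from_list <- function(cfg) {
  fm <- cfg$factor_model
  model <- factor_model(item_sets = lapply(fm$item_sets, as.integer),
                        item_weights = lapply(fm$item_weights, as.numeric),
                        total_item_set = as.integer(fm$total_item_set))
  cwc <- cfg$composite_weights
  cw <- composite_weights(map_weights = unlist(cwc$map_weights),
                          exp_weights = unlist(cwc$exp_weights))
  list(model = model, cw = cw)
}
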