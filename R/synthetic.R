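#' Demographics of the published seven-site FBIRN consortium
#'
#' The site profiles of the seven-site schizophrenia consortium whose
#' published demographics the generator emulates by default: per-site
#' gender counts, age and duration-of-illness ranges (years), and the SANS
#' Total mean and range. The subject-level data themselves are not public;
#' these profiles (N summing to 187) are the published summary only. Age,
#' duration of illness and the SANS Total descriptives are cosmetic
#' metadata for the generator — the analysis pipeline uses only gender and
#' items.
#'
#' @return data.frame, one row per site: site_id, n_M, n_F, age_lo, age_hi,
#'   age_mean, doi_lo, doi_hi, doi_mean, sans_lo, sans_hi, sans_mean.
#' @export
default_profiles <- function() {
  data.frame(
    site_id = paste0("test", 1:7),
    n_M = c(22L, 14L, 26L, 26L, 10L, 18L, 25L),
    n_F = c(6L, 1L, 9L, 5L, 5L, 13L, 7L),
    age_lo = c(22, 23, 20, 21, 21, 19, 18),
    age_hi = c(53, 58, 60, 62, 51, 56, 60),
    age_mean = c(35.8, 41.7, 44.5, 37.0, 37.1, 36.6, 39.3),
    doi_lo = c(1, 3, 2, 3, 2, 2, 1),
    doi_hi = c(27, 41, 40, 49, 31, 48, 39),
    doi_mean = c(12.3, 19.3, 23.3, 15.3, 16.3, 15.1, 18.5),
    sans_lo = c(1, 9, 2, 0, 0, 4, 0),
    sans_hi = c(61, 54, 63, 48, 44, 45, 53),
    sans_mean = c(19.6, 29.5, 15.9, 20.4, 20.3, 18.6, 19.4),
    stringsAsFactors = FALSE)
}

#' Published pooled gender effects for the same consortium
#'
#' The published random-effects meta-analytic estimates of the gender
#' effect (Cohen's d, F - M) on each outcome, with their reported SE, z,
#' p and Wald interval bounds, at the precision they were printed. Because
#' the subject-level data are not public these numbers serve two roles
#' here: printed (d, SE) pairs are inputs to the confidence-interval
#' arithmetic checks, and the five factor d values are the default
#' ground-truth effects of [published_effect_spec()]. They are never
#' treated as recomputable targets.
#'
#' @return data.frame: outcome, d, se, z, p, ci_lb, ci_ub.
#' @export
published_gender_effects <- function() {
  data.frame(
    outcome = c("Total", "MAP", "EXP", "Anhedonia", "Asociality",
                "Avolition", "BluntedAffect", "Alogia"),
    d = c(-0.29, -0.05, -0.39, 0.094, 0.049, -0.26, -0.36, -0.36),
    se = c(0.18, 0.17, 0.18, 0.18, 0.18, 0.18, 0.18, 0.18),
    z = c(-1.62, -0.30, -2.14, 0.52, 0.22, -1.45, -1.99, -1.97),
    p = c(0.10, 0.76, 0.03, 0.61, 0.83, 0.15, 0.047, 0.04),
    ci_lb = c(-0.64, -0.40, -0.74, -0.26, -0.31, -0.61, -0.71, -0.729),
    ci_ub = c(0.06, 0.29, -0.03, 0.44, 0.39, 0.09, -0.004, -0.001),
    stringsAsFactors = FALSE)
}

#' Ground-truth effect structure for the generator
#'
#' The generative model realized per subject: a shared severity random
#' effect u ~ N(0, sigma_subject^2) (SANS domains are strongly correlated
#' within a person), a per-factor latent level
#' \deqn{L_f = \mu_f + shift_f + u + \delta_f\, s_f\, 1[\mathrm{F}]}
#' where \eqn{s_f} is the population SD of the factor score, and item
#' ratings \eqn{L_f + N(0, \sigma_{item}^2)}, optionally rounded and
#' clipped to the 0-5 scale. The \eqn{\delta_f s_f} calibration makes the
#' population Cohen's d of factor f exactly `delta[f]` when clipping is
#' off; [true_effects()] gives the exact implied d for the Total and the
#' composites. Site-level severity shifts are drawn N(0, tau^2)
#' independently per site and factor by [generate_consortium()].
#'
#' @param mu Named baseline item-scale severity per factor (default 1.0
#'   each, which with clipping lands SANS Totals in the published range).
#' @param delta Named true gender effects per factor, pooled-SD units,
#'   F - M sign (default 0).
#' @param tau Between-site SD of the severity shifts (default 0).
#' @param sigma_subject SD of the shared subject severity effect
#'   (default 1.0 on the 0-5 item scale).
#' @param sigma_item SD of the per-item rating noise (default 0.5: raters
#'   scatter roughly half a rating point around the subject's domain
#'   severity).
#' @param clip Round item ratings to integers and clip to 0-5 (default
#'   TRUE; turn off for exact-calibration estimator studies).
#' @return An `effect_spec`.
#' @export
effect_spec <- function(mu = NULL, delta = NULL, tau = 0,
                        sigma_subject = 1.0, sigma_item = 0.5,
                        clip = TRUE) {
  factors <- c("Anhedonia", "Asociality", "Avolition", "BluntedAffect",
               "Alogia")
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, length(factors)), factors)
    if (!is.null(x)) {
      if (!all(names(x) %in% factors)) {
        stop("effect names must be factors: ",
             paste(factors, collapse = ", "), call. = FALSE)
      }
      out[names(x)] <- x
    }
    out
  }
  stopifnot(tau >= 0, sigma_item > 0, sigma_subject >= 0)
  structure(list(mu = fill(mu, 1.0), delta = fill(delta, 0),
                 tau = tau, sigma_subject = sigma_subject,
                 sigma_item = sigma_item, clip = clip),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @details `published_effect_spec()` is the "paper-like" configuration:
#'   the published five-factor d values wired in as simulation ground
#'   truth over the default seven-site profiles.
#' @export
published_effect_spec <- function(tau = 0, clip = TRUE) {
  pub <- published_gender_effects()
  d5 <- stats::setNames(pub$d, pub$outcome)[
    c("Anhedonia", "Asociality", "Avolition", "BluntedAffect", "Alogia")]
  effect_spec(delta = d5, tau = tau, clip = clip)
}

#' Exact population effects implied by an effect spec (clipping off)
#'
#' Under the generator's latent model the factor-score population d equals
#' `delta[f]` by calibration; the Total and the MAP/EXP composites mix
#' factors with different noise contributions, so their implied d is the
#' analytic weighted form computed here. Used as the truth reference in
#' recovery and coverage studies.
#'
#' @param effects An [effect_spec()].
#' @param model A [factor_model()]. @param cw A [composite_weights()].
#' @return Named numeric of population d over [outcome_names()].
#' @export
true_effects <- function(effects, model = default_factor_model(),
                         cw = default_composite_weights()) {
  su2 <- effects$sigma_subject^2
  si2 <- effects$sigma_item^2
  m <- vapply(model$item_sets, length, integer(1))
  s_f <- sqrt(su2 + si2 / m)                # factor score SD
  offset <- effects$delta[names(m)] * s_f   # gender mean shift per factor
  comp_d <- function(w) {
    w <- w[names(w)]
    num <- sum(w * offset[names(w)])
    sd_c <- sqrt(su2 + sum(w^2 * si2 / m[names(w)]))
    num / sd_c
  }
  # Total: sum over its item set; items of factor f contribute m_f * L_f
  # plus their own noise, attention items carry no gender effect.
  tot_idx <- model$total_item_set
  m_in_total <- vapply(names(m), function(f) {
    length(intersect(model$item_sets[[f]], tot_idx))
  }, integer(1))
  n_items_total <- length(tot_idx)
  tot_offset <- sum(m_in_total * offset)
  tot_sd <- sqrt(n_items_total^2 * su2 + n_items_total * si2)
  out <- c(Total = tot_offset / tot_sd,
           MAP = comp_d(cw$map_weights), EXP = comp_d(cw$exp_weights),
           effects$delta)
  out[outcome_names()]
}

#' Generate one synthetic site table
#'
#' Deterministic under `seed`; counts always match the profile exactly.
#' See [effect_spec()] for the generative model. Age and duration of
#' illness are drawn uniform within the profile's published ranges
#' (cosmetic covariates).
#'
#' @param profile One row of a profile data.frame (see
#'   [default_profiles()]).
#' @param effects An [effect_spec()].
#' @param site_shift Named per-factor severity shift (default all 0).
#' @param seed Integer seed.
#' @param model Factor structure used to place items (defaults to the
#'   shipped structure; globals mirror their factor, attention items carry
#'   no gender effect).
#' @return A [canonical_table()] with `age` and `duration_illness` columns.
#' @export
generate_site <- function(profile, effects, site_shift = NULL, seed = 1L,
                          model = default_factor_model()) {
  stopifnot(inherits(effects, "effect_spec"))
  factors <- names(model$item_sets)
  if (is.null(site_shift)) {
    site_shift <- stats::setNames(rep(0, length(factors)), factors)
  }
  n_M <- as.integer(profile$n_M); n_F <- as.integer(profile$n_F)
  n <- n_M + n_F
  stopifnot(n >= 1L)
  gender <- c(rep("M", n_M), rep("F", n_F))
  with_preserved_seed(seed, {
    u <- stats::rnorm(n, 0, effects$sigma_subject)
    m <- vapply(model$item_sets, length, integer(1))
    s_f <- sqrt(effects$sigma_subject^2 + effects$sigma_item^2 / m)
    X <- matrix(NA_real_, n, 25L)
    # factor of each item; globals (8,13,17,22,25) mirror their subscale's
    # latent, attention items 23-24 get a neutral latent with no effect
    item_factor <- rep(NA_character_, 25L)
    for (f in factors) item_factor[model$item_sets[[f]]] <- f
    item_factor[8L] <- "BluntedAffect"; item_factor[13L] <- "Alogia"
    item_factor[17L] <- "Avolition"; item_factor[22L] <- "Asociality"
    latent <- matrix(0, n, length(factors),
                     dimnames = list(NULL, factors))
    for (f in factors) {
      latent[, f] <- effects$mu[f] + site_shift[f] + u +
        effects$delta[f] * s_f[f] * (gender == "F")
    }
    latent_neutral <- mean(effects$mu) + u
    for (j in 1:25) {
      base <- if (is.na(item_factor[j])) latent_neutral else
        latent[, item_factor[j]]
      X[, j] <- base + stats::rnorm(n, 0, effects$sigma_item)
    }
    if (effects$clip) X <- pmin(pmax(round(X), 0), 5)
    age <- round(stats::runif(n, profile$age_lo, profile$age_hi))
    doi <- round(stats::runif(n, profile$doi_lo, profile$doi_hi))
  })
  df <- data.frame(subject_id = sprintf("%s_S%03d", profile$site_id,
                                        seq_len(n)),
                   gender = gender, stringsAsFactors = FALSE)
  for (j in 1:25) df[[sans_item_names()[j]]] <- X[, j]
  df$age <- age
  df$duration_illness <- doi
  canonical_table(df, profile$site_id)
}

#' Generate a full synthetic consortium
#'
#' Site-level severity shifts are drawn N(0, tau^2) independently per site
#' and factor; each site is then generated under a seed derived from the
#' master seed and the site's index by a stable counter scheme, so adding
#' a site never perturbs the existing ones.
#'
#' @param profiles Profile data.frame (default: the published seven sites).
#' @param effects An [effect_spec()].
#' @param seed Master seed.
#' @param model Factor structure.
#' @return Named list of [canonical_table()]s, with attribute `truth`
#'   (list: delta, tau, per-site shifts, the exact population d from
#'   [true_effects()]).
#' @export
generate_consortium <- function(profiles = default_profiles(),
                                effects = effect_spec(), seed = 1L,
                                model = default_factor_model()) {
  stopifnot(nrow(profiles) >= 1L)
  factors <- names(model$item_sets)
  tables <- vector("list", nrow(profiles))
  shifts <- matrix(0, nrow(profiles), length(factors),
                   dimnames = list(profiles$site_id, factors))
  for (i in seq_len(nrow(profiles))) {
    site_seed <- derive_seed(seed, i)
    shift <- if (effects$tau > 0) {
      with_preserved_seed(derive_seed(seed, i, stream = 1L),
                          stats::rnorm(length(factors), 0, effects$tau))
    } else rep(0, length(factors))
    names(shift) <- factors
    shifts[i, ] <- shift
    tables[[i]] <- generate_site(profiles[i, ], effects, site_shift = shift,
                                 seed = site_seed, model = model)
  }
  names(tables) <- profiles$site_id
  attr(tables, "truth") <- list(delta = effects$delta, tau = effects$tau,
                                shifts = shifts,
                                population_d = true_effects(effects, model))
  tables
}

# Counter-based per-site seed derivation: depends only on the master seed,
# the site index and the stream, and stays inside 32-bit integer range.
derive_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + stream * 15485863)
             %% .Machine$integer.max)
}
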