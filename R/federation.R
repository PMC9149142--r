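#' Consortium specification
#'
#' Names the consortium, pins the analysis pipeline and its parameters, and
#' lists the member sites. The spec is the single source of truth a run is
#' launched from; `read_consortium_spec()`/`write_consortium_spec()` handle
#' the YAML/JSON file form.
#'
#' @param name Consortium name.
#' @param members Character vector of member site ids (>= 1).
#' @param owner Owner site id.
#' @param pipeline Pipeline id; must be registered (see
#'   [registered_pipelines()]).
#' @param pipeline_version Pipeline version string.
#' @param parameters List of analysis parameters (`estimator`, `level`,
#'   `policy`, `min_cell`, optional `dp_epsilon`, plus scoring config
#'   overrides).
#' @return A `consortium_spec`.
#' @export
consortium_spec <- function(name, members, owner = members[1L],
                            pipeline = "sans-gender-meta",
                            pipeline_version = "1",
                            parameters = list()) {
  stopifnot(is.character(name), length(members) >= 1L)
  if (!pipeline %in% registered_pipelines()) {
    stop("pipeline '", pipeline, "' is not registered", call. = FALSE)
  }
  defaults <- list(estimator = "DL", level = 0.95, policy = "error",
                   min_cell = 1L, dp_epsilon = NULL)
  parameters <- utils::modifyList(defaults, parameters)
  structure(list(name = name, pipeline = pipeline,
                 pipeline_version = pipeline_version,
                 members = unique(members), owner = owner,
                 parameters = parameters),
            class = "consortium_spec")
}

#' @rdname consortium_spec
#' @export
registered_pipelines <- function() c("sans-gender-meta")

#' @export
print.consortium_spec <- function(x, ...) {
  cat("Consortium '", x$name, "': pipeline ", x$pipeline, " v",
      x$pipeline_version, ", ", length(x$members), " members (owner ",
      x$owner, ")\n", sep = "")
  invisible(x)
}

#' A single audited message on the bus
#' @keywords internal
new_message <- function(direction, round, site_id, payload) {
  stopifnot(direction %in% c("site_to_aggregator", "aggregator_to_site"))
  list(direction = direction, round = as.integer(round), site_id = site_id,
       payload = payload,
       bytes = length(serialize(payload, NULL, version = 2L)))
}

#' Privacy audit of a site-to-aggregator payload
#'
#' The privacy contract: only derived summary statistics leave a site,
#' never record-level data. The audit is structural — a payload must be
#' exactly one of the pinned wire schemas (the flat per-outcome effect
#' table, a regression sufficient-statistic block, or a gradient block),
#' with every dimension fixed by the pipeline rather than by the site's
#' sample size. Any extra component or attribute, and any atomic vector
#' whose length matches the site's record count outside the pinned shapes,
#' is treated as a record-level leak and aborts the protocol. Group counts
#' below `min_cell` are a hard error; counts below 5 draw a small-cell
#' warning (disclosure risk grows as cells shrink).
#'
#' @param payload The candidate payload.
#' @param site_n The site's record count (used for leak detection).
#' @param min_cell Minimum tolerated group count (default 1).
#' @param kind Wire schema: `"effects"`, `"suffstats"`, or `"gradient"`.
#' @param p Design dimension, required for the regression schemas.
#' @return The payload, invisibly, if it passes; otherwise an error of
#'   class `privacy_violation`.
#' @export
privacy_guard <- function(payload, site_n, min_cell = 1L,
                          kind = c("effects", "suffstats", "gradient"),
                          p = NULL) {
  kind <- match.arg(kind)
  leak <- function(why) {
    stop(structure(class = c("privacy_violation", "error", "condition"),
                   list(message = paste0("privacy violation: ", why),
                        call = NULL)))
  }
  scan_extra_attrs <- function(x, allowed) {
    extra <- setdiff(names(attributes(x)), allowed)
    if (length(extra)) {
      leak(paste0("unexpected attribute(s) in payload: ",
                  paste(extra, collapse = ", ")))
    }
  }
  if (kind == "effects") {
    if (!is.data.frame(payload)) leak("payload is not a flat effect table")
    want <- c("outcome", "d", "v", "n_M", "n_F")
    if (!identical(sort(names(payload)), sort(want))) {
      leak(paste0("effect table columns must be exactly {",
                  paste(want, collapse = ", "), "}"))
    }
    if (nrow(payload) != length(outcome_names())) {
      leak("effect table row count is not the pipeline's outcome count")
    }
    for (col in c("d", "v", "n_M", "n_F")) {
      if (!is.numeric(payload[[col]])) leak("non-numeric effect field")
    }
    if (!is.character(payload$outcome)) leak("non-character outcome field")
    scan_extra_attrs(payload, c("names", "row.names", "class"))
    for (col in names(payload)) {
      scan_extra_attrs(payload[[col]], character())
      if (is.list(payload[[col]])) leak("nested container in effect table")
    }
    counts <- c(payload$n_M, payload$n_F)
    if (any(counts < min_cell)) {
      leak(sprintf("group count %d below min_cell = %d", min(counts),
                   min_cell))
    }
    if (any(counts < 5L)) {
      warning(sprintf("small-cell disclosure risk: group count %d < 5",
                      min(counts)), call. = FALSE)
    }
  } else {
    if (is.null(p)) stop("design dimension p required", call. = FALSE)
    ok_vec <- function(x, len) is.numeric(x) && length(x) == len &&
      is.null(dim(x))
    if (kind == "suffstats") {
      want <- c("XtX", "Xty", "yty", "n")
      if (!is.list(payload) || !identical(sort(names(payload)), sort(want))) {
        leak("sufficient-statistic payload fields must be exactly {XtX, Xty, yty, n}")
      }
      if (!(is.matrix(payload$XtX) && all(dim(payload$XtX) == c(p, p)))) {
        leak("XtX is not a p x p matrix")
      }
      if (!ok_vec(payload$Xty, p)) leak("Xty is not a length-p vector")
      if (!ok_vec(payload$yty, 1L)) leak("yty is not a scalar")
      if (!ok_vec(payload$n, 1L)) leak("n is not a scalar")
    } else {
      want <- c("gradient", "n")
      if (!is.list(payload) || !identical(sort(names(payload)), sort(want))) {
        leak("gradient payload fields must be exactly {gradient, n}")
      }
      if (!ok_vec(payload$gradient, p)) leak("gradient is not length p")
      if (!ok_vec(payload$n, 1L)) leak("n is not a scalar")
    }
    for (el in payload) {
      if (is.atomic(el) && length(el) == site_n && site_n > p^2) {
        leak("payload component length matches the site record count")
      }
    }
  }
  invisible(payload)
}

# In-process "vault": site tables behind an accessor that logs every read,
# so isolation (no site ever reads a foreign table) is auditable.
make_vault <- function(site_tables) {
  log <- data.frame(requester = character(), table = character(),
                    stringsAsFactors = FALSE)
  env <- environment()
  list(
    fetch = function(requester, table_id) {
      env$log <- rbind(env$log, data.frame(requester = requester,
                                           table = table_id,
                                           stringsAsFactors = FALSE))
      site_tables[[table_id]]
    },
    access_log = function() env$log)
}

#' Run the single-shot decentralized pipeline
#'
#' Each member site's analysis executes in an isolated context that can
#' read only that site's own table (every table access is logged and
#' auditable); the site emits exactly one message whose payload is its flat
#' summary-effect table, each message passes [privacy_guard()], and the
#' aggregator fits the meta-analysis from the audited messages alone. The
#' result is numerically identical to the centralized computation on the
#' pooled tables because the released statistics are sufficient for the
#' aggregation.
#'
#' @param spec A [consortium_spec()].
#' @param site_tables Named list of [canonical_table()]s, one per member.
#' @param model,cw Scoring configuration.
#' @param seed Seed for the optional differential-privacy noising.
#' @return A `federated_run`: list with `result` (a `meta_result`), `log`
#'   (a `run_log` of all messages, per-site status, access log).
#' @export
run_single_shot <- function(spec, site_tables,
                            model = default_factor_model(),
                            cw = default_composite_weights(),
                            seed = NULL) {
  stopifnot(inherits(spec, "consortium_spec"))
  missing_tables <- setdiff(spec$members, names(site_tables))
  if (length(missing_tables)) {
    stop("consortium error: member(s) without a mapped table: ",
         paste(missing_tables, collapse = ", "), call. = FALSE)
  }
  pars <- spec$parameters
  vault <- make_vault(site_tables)
  messages <- list()
  status <- stats::setNames(rep("pending", length(spec$members)),
                            spec$members)
  for (s in spec$members) {
    tab <- vault$fetch(s, s)
    local <- tryCatch(
      local_compute(tab, model, cw, policy = pars$policy),
      error = function(e) {
        stop("consortium error at site '", s, "': ", conditionMessage(e),
             call. = FALSE)
      })
    if (!is.null(pars$dp_epsilon)) {
      local <- apply_dp_noise(local, epsilon = pars$dp_epsilon,
                              sensitivity = c(d = 1),
                              seed = if (is.null(seed)) 0L else
                                seed + match(s, spec$members))
    }
    payload <- local$effects
    privacy_guard(payload, site_n = nrow(tab), min_cell = pars$min_cell,
                  kind = "effects")
    messages[[length(messages) + 1L]] <-
      new_message("site_to_aggregator", 1L, s, payload)
    status[s] <- "complete"
  }
  locals <- lapply(messages, function(m) {
    structure(list(site_id = m$site_id, effects = m$payload,
                   warnings = character()), class = "local_result")
  })
  result <- meta_analyze(locals, estimator = pars$estimator,
                         level = pars$level)
  log <- structure(list(consortium = spec$name, pipeline = spec$pipeline,
                        parameters = pars, messages = messages,
                        status = status,
                        access_log = vault$access_log()),
                   class = "run_log")
  structure(list(result = result, log = log), class = "federated_run")
}

#' @export
print.federated_run <- function(x, ...) {
  cat("Federated run: consortium '", x$log$consortium, "', ",
      length(x$log$messages), " messages, all sites ",
      if (all(x$log$status == "complete")) "complete" else "NOT complete",
      "\n\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Replay a run log
#'
#' Re-runs the aggregation from the logged site-to-aggregator messages
#' alone; by construction this reproduces the original `meta_result`
#' bit-for-bit, which is the audit property a reviewer checks.
#'
#' @param log A `run_log` from [run_single_shot()].
#' @return A `meta_result`.
#' @export
replay_run <- function(log) {
  stopifnot(inherits(log, "run_log"))
  locals <- lapply(Filter(function(m) m$direction == "site_to_aggregator",
                          log$messages),
                   function(m) structure(list(site_id = m$site_id,
                                              effects = m$payload,
                                              warnings = character()),
                                         class = "local_result"))
  meta_analyze(locals, estimator = log$parameters$estimator,
               level = log$parameters$level)
}

#' Write a run log as line-delimited JSON for audit
#'
#' @param log A `run_log`. @param path Output file (.jsonl).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  stopifnot(inherits(log, "run_log"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (m in log$messages) {
    rec <- list(direction = m$direction, round = m$round,
                site_id = m$site_id, bytes = m$bytes,
                payload = m$payload)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Laplace-mechanism noising of a site's released effects
#'
#' Adds independent Laplace noise of scale `sensitivity/epsilon` to each
#' designated effect field before release. Group counts are never noised:
#' they drive the aggregation weights and are guarded by the minimum-cell
#' rule instead. Deterministic under `seed`; the caller's random state is
#' preserved.
#'
#' @param local A `local_result`.
#' @param epsilon Privacy budget (> 0).
#' @param sensitivity Named numeric: per-field sensitivity, over fields in
#'   `c("d", "v")`.
#' @param seed Integer seed.
#' @return The noised `local_result`.
#' @export
apply_dp_noise <- function(local, epsilon, sensitivity = c(d = 1),
                           seed = 0L) {
  stopifnot(inherits(local, "local_result"))
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be > 0", call. = FALSE)
  }
  fields <- names(sensitivity)
  if (!length(fields) || !all(fields %in% c("d", "v"))) {
    stop("sensitivity must be named over effect fields {d, v}; ",
         "counts are never noised", call. = FALSE)
  }
  with_preserved_seed(seed, {
    for (f in fields) {
      scale <- sensitivity[[f]] / epsilon
      local$effects[[f]] <- local$effects[[f]] +
        rlaplace(nrow(local$effects), scale)
    }
  })
  local
}

#' Laplace deviates (location 0)
#' @keywords internal
rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read / write a consortium spec file
#'
#' On-disk schema (YAML or JSON): `name`, `pipeline`, `pipeline_version`,
#' `owner`, `members` (list of site ids, or of records with `id`, `data`,
#' `map` paths for [cli_run()]), `parameters`.
#'
#' @param path Spec file path.
#' @export
read_consortium_spec <- function(path) {
  cfg <- read_config(path)
  members <- cfg$members
  if (is.data.frame(members)) members <- split(members, seq_len(nrow(members)))
  ids <- vapply(members, function(m) {
    if (is.list(m)) as.character(m$id) else as.character(m)
  }, character(1))
  spec <- consortium_spec(name = cfg$name, members = ids,
                          owner = if (is.null(cfg$owner)) ids[1L] else
                            cfg$owner,
                          pipeline = if (is.null(cfg$pipeline))
                            "sans-gender-meta" else cfg$pipeline,
                          pipeline_version =
                            if (is.null(cfg$pipeline_version)) "1" else
                              as.character(cfg$pipeline_version),
                          parameters = if (is.null(cfg$parameters))
                            list() else cfg$parameters)
  files <- lapply(members, function(m) {
    if (is.list(m) && !is.null(m$data)) {
      list(id = as.character(m$id), data = as.character(m$data),
           map = as.character(m$map))
    } else NULL
  })
  attr(spec, "member_files") <- Filter(Negate(is.null), files)
  spec
}

#' @rdname read_consortium_spec
#' @param spec A [consortium_spec()].
#' @export
write_consortium_spec <- function(spec, path) {
  stopifnot(inherits(spec, "consortium_spec"))
  obj <- list(name = spec$name, pipeline = spec$pipeline,
              pipeline_version = spec$pipeline_version, owner = spec$owner,
              members = as.list(spec$members),
              parameters = spec$parameters[!vapply(spec$parameters, is.null,
                                                   logical(1))])
  write_config(obj, path)
}
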