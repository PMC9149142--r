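# Shared fixtures and independent oracles. Oracles are deliberately
# straight-line re-derivations that never call the code paths they check.

# A small canonical table built by hand (integer items, both genders).
make_table <- function(n = 10, site = "s1", seed = 1,
                       genders = NULL, items = NULL) {
  set.seed(seed)
  if (is.null(genders)) {
    genders <- c("M", "F", sample(c("M", "F"), n - 2, replace = TRUE))
  }
  df <- data.frame(subject_id = sprintf("%s_%02d", site, seq_len(n)),
                   gender = genders, stringsAsFactors = FALSE)
  if (is.null(items)) {
    items <- matrix(sample(0:5, n * 25, replace = TRUE), n, 25)
  }
  for (j in 1:25) df[[sans_item_names()[j]]] <- items[, j]
  canonical_table(df, site)
}

# A raw (pre-mapping) site file with arbitrary source names, plus its map.
make_raw_site <- function(n = 8, site = "raw1", seed = 2) {
  tab <- as.data.frame(make_table(n, site, seed))
  raw <- tab
  names(raw) <- c("ID", "SEX", sprintf("Q%d", 1:25))
  raw$SEX <- ifelse(raw$SEX == "M", "1", "2")
  vmap <- variable_map(
    site,
    column_bindings = stats::setNames(c("ID", "SEX", sprintf("Q%d", 1:25)),
                                      c("subject_id", "gender",
                                        sans_item_names())),
    gender_value_bindings = c(`1` = "M", `2` = "F"))
  list(raw = raw, vmap = vmap, canonical = canonical_table(tab, site))
}

# Straight-line reference: DL tau2 + random-effects pooling in one pass.
oracle_meta <- function(d, v, level = 0.95) {
  k <- length(d)
  w <- 1 / v
  dbar <- sum(w * d) / sum(w)
  Q <- sum(w * (d - dbar)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (k <= 1 || C <= 0) 0 else max(0, (Q - (k - 1)) / C)
  ws <- 1 / (v + tau2)
  dp <- sum(ws * d) / sum(ws)
  se <- sqrt(1 / sum(ws))
  z <- dp / se
  zc <- qnorm(1 - (1 - level) / 2)
  list(d = dp, se = se, z = z, p = 2 * pnorm(-abs(z)),
       ci_lb = dp - zc * se, ci_ub = dp + zc * se, tau2 = tau2, Q = Q,
       I2 = if (Q == 0) 0 else 100 * max(0, (Q - (k - 1)) / Q))
}

# Dense grid maximization of the restricted log-likelihood over tau2.
oracle_reml_grid <- function(d, v, upper = 5, step = 1e-4) {
  grid <- seq(0, upper, by = step)
  k <- length(d)
  V <- outer(rep(1, length(grid)), v) + grid   # grid x k
  W <- 1 / V
  mu <- rowSums(W * rep(d, each = length(grid))) / rowSums(W)
  R <- rep(d, each = length(grid)) - mu
  ll <- -0.5 * rowSums(log(V)) - 0.5 * log(rowSums(W)) -
    0.5 * rowSums(W * R^2)
  grid[which.max(ll)]
}

# Random per-site (d, v) instances for estimator oracle tests.
random_instance <- function(k) {
  v <- runif(k, 0.02, 1)
  d <- rnorm(k, 0, 0.8)
  list(d = d, v = v)
}

# Default consortium spec over a set of tables.
spec_for <- function(tables, parameters = list()) {
  consortium_spec("test-consortium", members = names(tables),
                  parameters = parameters)
}
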