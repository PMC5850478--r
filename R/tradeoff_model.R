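# Length-dependent translational trade-off for polyprotein repeat number.
#
# A transcript carrying n mature-peptide repeats has ORF length
# L(n) = L0 + lam * n. Each completed translation releases n peptides, but
# per-transcript translation rate falls with length as L^(-beta) (the
# empirical log-log slope of production against ORF length is about -1, i.e.
# roughly reciprocal). Peptide production is therefore
#
#   P(n) = c * n * (L0 + lam * n)^(-beta)
#
# which increases with diminishing returns and, for beta > 1, has an
# interior optimum at n* = L0 / (lam * (beta - 1)).

#' Trade-off model parameters
#'
#' @param c Positive scale in production units (e.g. molecules cell^-1 s^-1).
#' @param beta Length exponent (magnitude of the log-log slope), >= 0.
#' @param L0 Non-repeat ORF length in nt (leader + spacers + tail), > 0.
#' @param lam Added ORF length per repeat in nt, > 0. The default 63 nt is a
#'   13-codon repeat plus an 8-codon spacer.
#' @return A `tradeoff_params` list.
#' @export
tradeoff_params <- function(c = 1, beta = 1.28, L0 = 249, lam = 63) {
  stopifnot(c > 0, beta >= 0, L0 > 0, lam > 0)
  structure(list(c = c, beta = beta, L0 = L0, lam = lam),
            class = "tradeoff_params")
}

#' Peptide production as a function of repeat number
#'
#' @param n Repeat number(s), integer >= 1 (vectorised).
#' @param params A [tradeoff_params()] object.
#' @return `c * n * (L0 + lam * n)^(-beta)`.
#' @export
production <- function(n, params = tradeoff_params()) {
  stopifnot(inherits(params, "tradeoff_params"), all(n >= 1))
  params$c * n * (params$L0 + params$lam * n)^(-params$beta)
}

#' Optimal repeat number under the trade-off
#'
#' Integer argmax of [production()] over `1..n_max` (by direct evaluation)
#' together with the real-valued stationary point
#' `L0 / (lam * (beta - 1))`, which is finite only for `beta > 1`; for
#' `beta <= 1` production is strictly increasing and the stationary point is
#' reported as `Inf`.
#'
#' @param params A [tradeoff_params()] object.
#' @param n_max Upper bound of the search range.
#' @return List with `n_opt` (integer argmax), `n_star` (real stationary
#'   point or `Inf`), and `production_at_opt`.
#' @export
optimal_repeat_number <- function(params = tradeoff_params(), n_max = 100L) {
  stopifnot(n_max >= 1L)
  p <- production(seq_len(n_max), params)
  n_star <- if (params$beta > 1) params$L0 / (params$lam * (params$beta - 1)) else Inf
  list(n_opt = which.max(p), n_star = n_star, production_at_opt = max(p))
}

#' Log-log slope of production against ORF length
#'
#' Ordinary least squares of `log(production)` on `log(length_nt)`; the
#' length-dependence summary used to compare wildtype with asc1 mutants.
#'
#' @param observations Data frame with columns `length_nt` and `production`
#'   (> 0), optionally `group`.
#' @param by_group If `TRUE` and a `group` column is present, fit each group
#'   separately.
#' @return Data frame with `group`, `slope`, `intercept`, `se_slope`, `n`.
#' @export
loglog_slope <- function(observations, by_group = FALSE) {
  stopifnot(all(c("length_nt", "production") %in% names(observations)))
  if (any(observations$production <= 0)) stop("production values must be > 0")
  fit1 <- function(df, g) {
    if (nrow(df) < 3L) stop("need at least 3 observations")
    m <- stats::lm(log(production) ~ log(length_nt), data = df)
    cf <- summary(m)$coefficients
    # a flat response has zero slope but summary() on a perfect fit warns;
    # coefficients are still exact
    data.frame(group = g, slope = cf[2L, 1L], intercept = cf[1L, 1L],
               se_slope = cf[2L, 2L], n = nrow(df), stringsAsFactors = FALSE)
  }
  if (by_group && "group" %in% names(observations)) {
    do.call(rbind, lapply(split(observations, observations$group),
                          function(df) fit1(df, df$group[1L])))
  } else {
    fit1(observations, "all")
  }
}

#' Fit the trade-off exponent from production observations
#'
#' With repeat number `n` and the length map `L(n) = L0 + lam * n` known,
#' the model is linear after transformation:
#' `log P - log n = log c - beta * log(L0 + lam * n)`.
#' Ordinary least squares returns `beta` (as minus the slope) and `c` (as
#' the exponentiated intercept) with standard errors (delta method for `c`).
#'
#' @param observations Data frame with columns `n` (>= 3 distinct values)
#'   and `production` (> 0).
#' @param L0,lam Known length-map constants (nt).
#' @return List with `c`, `beta`, `se_c`, `se_beta`, and the underlying
#'   `lm` fit.
#' @export
fit_beta <- function(observations, L0 = 249, lam = 63) {
  stopifnot(all(c("n", "production") %in% names(observations)))
  if (any(observations$production <= 0)) stop("production values must be > 0")
  if (length(unique(observations$n)) < 2L)
    stop("singular design: need at least 2 distinct repeat numbers")
  y <- log(observations$production) - log(observations$n)
  x <- log(L0 + lam * observations$n)
  m <- stats::lm(y ~ x)
  cf <- summary(m)$coefficients
  list(c = exp(cf[1L, 1L]), beta = -cf[2L, 1L],
       se_c = exp(cf[1L, 1L]) * cf[1L, 2L], se_beta = cf[2L, 2L], fit = m)
}

#' Reinitiation simulation parameters
#'
#' Parameters of a deliberately minimal mechanism sketch of intrapolysomal
#' ribosome reinitiation (closed-loop recycling): fresh initiations arrive
#' as a memoryless (Poisson) stream; after each termination the ribosome
#' reinitiates on the same transcript with probability `q`, which may
#' decrease with transcript length. The event-level details are modelling
#' choices, not measured biology.
#'
#' @param k_on Fresh initiation rate (events per unit time), > 0.
#' @param q Reinitiation probability per termination: a single number in
#'   `[0, 1)` or a function of transcript length `q(L)`.
#' @param horizon Simulated time span.
#' @param seed RNG seed.
#' @return A `reinit_params` list.
#' @export
reinit_params <- function(k_on = 1, q = 0.5, horizon = 1000, seed = 1L) {
  stopifnot(k_on > 0, horizon > 0)
  if (is.numeric(q)) stopifnot(q >= 0, q < 1)
  structure(list(k_on = k_on, q = q, horizon = horizon, seed = as.integer(seed)),
            class = "reinit_params")
}

#' Simulate steady-state initiation rates under ribosome reinitiation
#'
#' Monte-Carlo estimate of the total initiation rate per transcript: each
#' fresh initiation spawns a run of `1 + Geometric(1 - q)` translation
#' rounds, so the expected total rate has the closed form `k_on / (1 - q)`.
#' The returned standard error treats the total as compound Poisson
#' (variance estimated by the sum of squared run lengths).
#'
#' @param params A [reinit_params()] object.
#' @param lengths Transcript lengths at which to evaluate `q(L)`; ignored
#'   (single condition) when `q` is a plain number.
#' @return Data frame with `length`, `q`, `rate` (estimate), `se`,
#'   `ci_lo`, `ci_hi`, and `rate_closed_form`.
#' @export
simulate_reinitiation <- function(params = reinit_params(), lengths = NA_real_) {
  stopifnot(inherits(params, "reinit_params"))
  set.seed(params$seed)
  qfun <- if (is.function(params$q)) params$q else function(L) params$q
  do.call(rbind, lapply(lengths, function(L) {
    q <- qfun(L)
    if (q < 0 || q >= 1) stop("reinitiation probability must lie in [0, 1)")
    n_fresh <- stats::rpois(1L, params$k_on * params$horizon)
    runs <- if (n_fresh > 0L) 1L + stats::rgeom(n_fresh, 1 - q) else integer(0)
    total <- sum(runs)
    rate <- total / params$horizon
    se <- sqrt(sum(as.numeric(runs)^2)) / params$horizon
    data.frame(length = L, q = q, rate = rate, se = se,
               ci_lo = rate - 1.96 * se, ci_hi = rate + 1.96 * se,
               rate_closed_form = params$k_on / (1 - q))
  }))
}
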