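# Phenotype statistics: plate-adjusted least-squares means with Tukey HSD
# and compact-letter display, pheromone-response fold changes, two-reference
# qPCR normalisation, competitive mating success, and relative log growth.

#' Compact-letter display by insert-and-absorb
#'
#' Assigns lowercase letters to groups so that two groups share a letter if
#' and only if their pairwise comparison is not significant at `alpha`
#' (the letters printed above group means in figures).
#'
#' @param groups Character vector of group names.
#' @param pairwise Data frame with columns `group1`, `group2`, `p_value`.
#' @param alpha Significance level.
#' @return Named character vector of letter strings.
#' @export
cld_letters <- function(groups, pairwise, alpha = 0.05) {
  cols <- list(groups)  # each column = a set of mutually non-distinct groups
  sig <- pairwise[pairwise$p_value < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop duplicates and any column strictly contained in another
    new_cols <- unique(lapply(new_cols, function(col) sort(unique(col))))
    keep <- vapply(seq_along(new_cols), function(a) {
      !any(vapply(seq_along(new_cols), function(b) {
        b != a && length(new_cols[[b]]) > length(new_cols[[a]]) &&
          all(new_cols[[a]] %in% new_cols[[b]])
      }, logical(1L)))
    }, logical(1L))
    cols <- new_cols[keep]
  }
  letts <- vapply(groups, function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1L)))],
          collapse = "")
  }, character(1L))
  names(letts) <- groups
  letts
}

#' Plate-adjusted least-squares means with Tukey HSD
#'
#' Fits an additive fixed-effects linear model
#' `value ~ group + plate (+ treatment) (+ group:treatment)` by least
#' squares and reports per-group adjusted (least-squares) means -- group
#' means after removing variance attributable to plate (and treatment)
#' differences, evaluated at equal weights for the nuisance factor levels.
#' On a balanced design the adjusted means equal the raw group means.
#' Pairwise comparisons use the studentized range (Tukey HSD) with the
#' model's residual degrees of freedom, and a compact-letter display is
#' attached.
#'
#' @param table Long-format data frame with a response column plus the
#'   factor columns named below.
#' @param response Response column name (default `"value"`).
#' @param group,plate,treatment Factor column names; `plate` and
#'   `treatment` may be `NULL` to omit the term.
#' @param transform `"identity"` or `"log"`: scale on which the model is
#'   fit. With `"log"`, means are reported back on the response scale
#'   (geometric means).
#' @param interaction Include a `group:treatment` interaction.
#' @param alpha Significance level for the letter display.
#' @return List with `means` (group, emmean, se, df, letters), `pairwise`
#'   (group1, group2, estimate, se, t_ratio, p_value), and the `lm` fit.
#' @export
lsmeans_plate <- function(table, response = "value", group = "group",
                          plate = "plate", treatment = NULL,
                          transform = c("identity", "log"),
                          interaction = FALSE, alpha = 0.05) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(table), group %in% names(table))
  df <- table
  df$.y <- if (transform == "log") {
    if (any(df[[response]] <= 0)) stop("log transform requires positive values")
    log(df[[response]])
  } else df[[response]]
  df$.g <- factor(df[[group]])
  if (nlevels(df$.g) < 1L) stop("no groups")
  if (nlevels(df$.g) == 1L) {
    # degenerate single-group table: report the plain mean, nothing to compare
    means <- data.frame(group = levels(df$.g), emmean = mean(df$.y),
                        se = stats::sd(df$.y) / sqrt(nrow(df)),
                        df = nrow(df) - 1L, stringsAsFactors = FALSE)
    if (transform == "log") means$response_mean <- exp(means$emmean)
    means$letters <- "a"
    return(list(means = means,
                pairwise = data.frame(group1 = character(0),
                                      group2 = character(0),
                                      estimate = numeric(0), se = numeric(0),
                                      t_ratio = numeric(0),
                                      p_value = numeric(0)),
                model = NULL, transform = transform))
  }
  terms <- ".g"
  if (!is.null(plate) && plate %in% names(table) &&
      length(unique(df[[plate]])) > 1L) {
    df$.plate <- factor(df[[plate]])
    terms <- c(terms, ".plate")
  }
  if (!is.null(treatment) && treatment %in% names(table) &&
      length(unique(df[[treatment]])) > 1L) {
    df$.trt <- factor(df[[treatment]])
    terms <- c(terms, ".trt")
    if (interaction) terms <- c(terms, ".g:.trt")
  }
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  m <- stats::lm(form, data = df)
  alias <- stats::alias(m)$Complete
  if (!is.null(alias))
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(alias), collapse = ", "))
  em <- emmeans::emmeans(m, ".g")
  es <- as.data.frame(em)
  means <- data.frame(group = as.character(es$.g), emmean = es$emmean,
                      se = es$SE, df = es$df, stringsAsFactors = FALSE)
  if (transform == "log") means$response_mean <- exp(means$emmean)

  if (nlevels(df$.g) >= 2L) {
    pw <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "tukey"))
    gg <- strsplit(as.character(pw$contrast), " - ", fixed = TRUE)
    # emmeans backquotes level names that are not syntactic; strip them
    unq <- function(x) gsub("^`|`$", "", x)
    pairwise <- data.frame(group1 = unq(vapply(gg, `[`, character(1L), 1L)),
                           group2 = unq(vapply(gg, `[`, character(1L), 2L)),
                           estimate = pw$estimate, se = pw$SE,
                           t_ratio = pw$t.ratio, p_value = pw$p.value,
                           stringsAsFactors = FALSE)
    means$letters <- unname(cld_letters(means$group, pairwise, alpha)[means$group])
  } else {
    pairwise <- data.frame(group1 = character(0), group2 = character(0),
                           estimate = numeric(0), se = numeric(0),
                           t_ratio = numeric(0), p_value = numeric(0))
    means$letters <- "a"
  }
  list(means = means, pairwise = pairwise, model = m, transform = transform)
}

#' Fold response between two treatment arms
#'
#' Ratio of geometric means (e.g. pheromone secretion with vs without
#' a-factor) with a log-scale Welch confidence interval.
#'
#' @param table Long-format data frame with `treatment` and a value column.
#' @param response Value column name.
#' @param treatments Length-2 character vector `c(numerator, denominator)`.
#' @param conf Confidence level.
#' @return List with `fold`, `ci_lo`, `ci_hi`, `n`.
#' @export
fold_response <- function(table, response = "value",
                          treatments = c("plus_a", "minus_a"), conf = 0.95) {
  stopifnot("treatment" %in% names(table), response %in% names(table),
            length(treatments) == 2L)
  a <- table[[response]][table$treatment == treatments[1L]]
  b <- table[[response]][table$treatment == treatments[2L]]
  if (!length(a) || !length(b))
    stop("missing treatment arm: ",
         treatments[c(!length(a), !length(b))][1L])
  if (any(c(a, b) <= 0)) stop("values must be positive for a fold ratio")
  if (length(a) > 1L && length(b) > 1L) {
    tt <- stats::t.test(log(a), log(b), conf.level = conf)
    list(fold = exp(mean(log(a)) - mean(log(b))),
         ci_lo = exp(tt$conf.int[1L]), ci_hi = exp(tt$conf.int[2L]),
         n = c(length(a), length(b)))
  } else {
    list(fold = exp(mean(log(a)) - mean(log(b))), ci_lo = NA_real_,
         ci_hi = NA_real_, n = c(length(a), length(b)))
  }
}

#' Relative transcript abundance from qPCR Ct values
#'
#' Normalises a target Ct against the mean of two reference-gene Cts
#' (equivalently, the geometric mean of the two reference abundances):
#' `efficiency^(mean(ref Cts) - Ct_target)`. Vectorised over replicates.
#'
#' @param ct_target Target-gene Ct value(s).
#' @param ct_ref1,ct_ref2 Reference-gene Ct values.
#' @param efficiency Amplification efficiency per cycle, in (1, 2]
#'   (2 = perfect doubling).
#' @return Relative abundance(s).
#' @export
qpcr_relative <- function(ct_target, ct_ref1, ct_ref2, efficiency = 2) {
  if (anyNA(c(ct_target, ct_ref1, ct_ref2)))
    stop("missing Ct value (target or reference)")
  stopifnot(efficiency > 1, efficiency <= 2)
  efficiency^((ct_ref1 + ct_ref2) / 2 - ct_target)
}

#' Competitive mating success
#'
#' Ratio of matings secured by a focal strain to those of a reference
#' competitor; 1 means parity. The confidence interval transforms a
#' binomial CI on the focal proportion `p` through the odds `p / (1 - p)`.
#'
#' @param focal,competitor Mating counts (non-negative, total > 0).
#' @param conf Confidence level.
#' @return List with `ratio` (`Inf` when the competitor count is 0),
#'   `ci_lo`, `ci_hi`, `p_focal`.
#' @export
mating_success <- function(focal, competitor, conf = 0.95) {
  stopifnot(focal >= 0, competitor >= 0, focal + competitor > 0)
  total <- focal + competitor
  bt <- stats::binom.test(focal, total, conf.level = conf)
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  list(ratio = if (competitor == 0) Inf else focal / competitor,
       ci_lo = odds(bt$conf.int[1L]), ci_hi = odds(bt$conf.int[2L]),
       p_focal = focal / total)
}

#' Relative log growth rate against a competitor
#'
#' Difference of per-unit-time log-slopes: least squares of `log(count)` on
#' time for focal and competitor trajectories; 0 means equal growth.
#'
#' @param focal,competitor Positive cell/colony counts at `times`.
#' @param times Time points (>= 2), e.g. hours.
#' @return List with `log_growth_diff`, `slope_focal`, `slope_competitor`.
#' @export
relative_log_growth <- function(focal, competitor, times) {
  stopifnot(length(times) >= 2L, length(focal) == length(times),
            length(competitor) == length(times))
  if (any(focal <= 0) || any(competitor <= 0)) stop("counts must be positive")
  sf <- stats::coef(stats::lm(log(focal) ~ times))[[2L]]
  sc <- stats::coef(stats::lm(log(competitor) ~ times))[[2L]]
  list(log_growth_diff = sf - sc, slope_focal = sf, slope_competitor = sc)
}
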