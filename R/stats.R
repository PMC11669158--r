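# Group summaries and tests used by the binding and plate-reader assays:
# per-strain mean +/- SD, one-way ANOVA, Holm-Sidak step-down multiple
# comparisons versus the control strain, and the two fluorescence
# normalizations (blank/OD and antibody ratio).

#' Blank-subtracted, OD-normalized fluorescence
#'
#' Plate-reader normalization: fluorescence minus the medium blank, divided
#' by the culture's optical density at 700 nm.
#'
#' @param fluorescence Raw fluorescence (a.u.).
#' @param blank Blank fluorescence (a.u.).
#' @param od700 Optical density at 700 nm; must be positive.
#' @return Normalized fluorescence, \code{(fluorescence - blank) / od700}.
#' @export
normalize_by_od <- function(fluorescence, blank, od700) {
  if (any(od700 <= 0)) stop("od700 must be > 0", call. = FALSE)
  (fluorescence - blank) / od700
}

#' Antibody labeling ratio
#'
#' Surface-display readout: fluorescence of antibody-labeled cells divided
#' by the fluorescence of the same strain without antibody; 1 means no
#' display signal above baseline.
#'
#' @param f_with Normalized fluorescence with antibody.
#' @param f_without Normalized fluorescence without antibody; must be
#'   positive.
#' @return The ratio \code{f_with / f_without}.
#' @export
antibody_ratio <- function(f_with, f_without) {
  if (any(f_without <= 0)) stop("f_without must be > 0", call. = FALSE)
  f_with / f_without
}

check_group_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("strain", "value") %in% names(table)))
  if (anyNA(table$value)) stop("group table contains NA values", call. = FALSE)
  n <- table(table$strain)
  if (length(n) < 2L) stop("need at least 2 strains", call. = FALSE)
  if (any(n < 2L))
    stop("every strain needs at least 2 values", call. = FALSE)
  invisible(NULL)
}

#' One-way analysis of variance
#'
#' Direct between/within sum-of-squares decomposition over the strain
#' groups, returning the F statistic, its p-value, and the pooled
#' within-group mean square and degrees of freedom reused by the follow-up
#' comparisons versus control. All groups exactly constant (zero within
#' variance) is a degenerate input and raises an error.
#'
#' @param table Data frame with columns \code{strain} and \code{value};
#'   at least 2 strains with at least 2 values each.
#' @return List with \code{F}, \code{p}, \code{mse_within},
#'   \code{df_within}, \code{df_between}.
#' @export
one_way_anova <- function(table) {
  check_group_table(table)
  groups <- split(table$value, table$strain)
  k <- length(groups)
  n_tot <- nrow(table)
  grand <- mean(table$value)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df_between <- k - 1L
  df_within <- n_tot - k
  if (ss_within == 0)
    stop("degenerate input: zero within-group variance, F undefined",
         call. = FALSE)
  mse_within <- ss_within / df_within
  f_stat <- (ss_between / df_between) / mse_within
  list(F = f_stat,
       p = stats::pf(f_stat, df_between, df_within, lower.tail = FALSE),
       mse_within = mse_within, df_within = df_within,
       df_between = df_between)
}

significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Holm-Sidak multiple comparisons versus a control strain
#'
#' The classical follow-up to a one-way ANOVA when every strain is compared
#' to one control: per non-control strain a t statistic using the pooled
#' within-group mean square,
#' \code{t = (mean_i - mean_c) / sqrt(mse * (1/n_i + 1/n_c))} with the
#' ANOVA's within degrees of freedom and a two-sided p-value; then the
#' Sidak step-down adjustment — raw p sorted ascending,
#' \code{adj_k = 1 - (1 - p_k)^(m - k + 1)} over the m comparisons, with the
#' running maximum enforcing monotonicity. Significance tiers are assigned
#' on the adjusted p at 0.05 / 0.01 / 0.001.
#'
#' @param table Data frame with columns \code{strain} and \code{value}.
#' @param control Label of the control strain; must be present.
#' @return Data frame with one row per non-control strain (input order):
#'   \code{strain}, \code{n}, \code{mean}, \code{sd}, \code{t_statistic},
#'   \code{raw_p}, \code{adjusted_p}, \code{significance_tier}.
#' @export
holm_sidak_vs_control <- function(table, control) {
  check_group_table(table)
  if (!control %in% table$strain)
    stop("control strain not present: ", control, call. = FALSE)
  aov_fit <- one_way_anova(table)
  groups <- split(table$value, table$strain)
  others <- setdiff(unique(table$strain), control)
  gc <- groups[[control]]
  res <- do.call(rbind, lapply(others, function(s) {
    g <- groups[[s]]
    se <- sqrt(aov_fit$mse_within * (1 / length(g) + 1 / length(gc)))
    t_stat <- (mean(g) - mean(gc)) / se
    data.frame(strain = s, n = length(g), mean = mean(g), sd = stats::sd(g),
               t_statistic = t_stat,
               raw_p = 2 * stats::pt(-abs(t_stat), aov_fit$df_within),
               stringsAsFactors = FALSE)
  }))
  m <- nrow(res)
  res$adjusted_p <- NA_real_
  ord <- order(res$raw_p)            # stable: ties keep input order
  adj_sorted <- 1 - (1 - res$raw_p[ord])^(m - seq_len(m) + 1)
  # an adjusted p dominates its raw p by definition; pmax also guards the
  # floating-point identity 1 - (1 - p) != p at exponent 1
  adj_sorted <- pmin(1, pmax(cummax(adj_sorted), res$raw_p[ord]))
  res$adjusted_p[ord] <- adj_sorted
  res$significance_tier <- significance_tier(res$adjusted_p)
  rownames(res) <- NULL
  res
}

#' Per-strain summary of a group table
#'
#' Mean, standard deviation and n per strain — the numbers behind the
#' mean +/- SD bars of the assay figures.
#'
#' @param table Data frame with columns \code{strain} and \code{value}.
#' @return Data frame with \code{strain}, \code{n}, \code{mean}, \code{sd}.
#' @export
group_summary <- function(table) {
  stopifnot(is.data.frame(table), all(c("strain", "value") %in% names(table)))
  groups <- split(table$value, table$strain)
  out <- data.frame(strain = names(groups),
                    n = vapply(groups, length, integer(1)),
                    mean = vapply(groups, mean, numeric(1)),
                    sd = vapply(groups, stats::sd, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[match(unique(table$strain), out$strain), , drop = FALSE]
}
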