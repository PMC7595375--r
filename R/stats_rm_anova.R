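#' Validate a balanced within-subject outcome table
#'
#' @param table data.frame with columns `subject`, and the factor/value
#'   columns named by the other arguments.
#' @param factors character vector of within-subject factor column names.
#' @param value value column name.
#' @param subject subject column name.
#' @keywords internal
check_outcome_table <- function(table, factors, value = "value",
                                subject = "subject",
                                allow_replicates = FALSE) {
  need <- c(subject, factors, value)
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("outcome table is missing columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(table[[value]])))
    stop("outcome table contains non-finite values")
  counts <- table(lapply(table[c(subject, factors)],
                         function(x) factor(as.character(x))))
  bad <- if (allow_replicates)
    length(unique(as.vector(counts))) != 1L || any(counts < 1L)
  else any(counts != 1L)
  if (bad)
    stop("unbalanced design: every subject x ", paste(factors, collapse = " x "),
         " cell must contain ", if (allow_replicates) "the same number of values"
         else "exactly one value", " (no imputation is performed)")
  invisible(table)
}

# within-subject SS decomposition for a balanced s x a (x b) design
# returns list of SS terms from cell/marginal means
ss_decompose <- function(table, factors, value, subject) {
  y <- table[[value]]
  s <- factor(as.character(table[[subject]]))
  f1 <- factor(as.character(table[[factors[1]]]))
  two_way <- length(factors) == 2L
  gm <- mean(y)
  m_s <- tapply(y, s, mean)
  m_a <- tapply(y, f1, mean)
  n <- nlevels(s); a <- nlevels(f1)
  if (two_way) {
    f2 <- factor(as.character(table[[factors[2]]]))
    b <- nlevels(f2)
    m_b <- tapply(y, f2, mean)
    m_ab <- tapply(y, list(f1, f2), mean)
    m_sa <- tapply(y, list(s, f1), mean)
    m_sb <- tapply(y, list(s, f2), mean)
    ss_subj <- a * b * sum((m_s - gm)^2)
    ss_a <- n * b * sum((m_a - gm)^2)
    ss_b <- n * a * sum((m_b - gm)^2)
    ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
    ss_sa <- b * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + gm)^2)
    ss_sb <- a * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_sab <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_sa - ss_sb
    list(two_way = TRUE, n = n, a = a, b = b, ss_total = ss_tot,
         ss_subject = ss_subj,
         ss = c(ss_a, ss_b, ss_ab), ss_err = c(ss_sa, ss_sb, ss_sab),
         df = c(a - 1, b - 1, (a - 1) * (b - 1)),
         df_err = (n - 1) * c(a - 1, b - 1, (a - 1) * (b - 1)))
  } else {
    m_sa <- tapply(y, list(s, f1), mean)
    ss_subj <- a * sum((m_s - gm)^2)
    ss_a <- n * sum((m_a - gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_sa <- ss_tot - ss_subj - ss_a
    list(two_way = FALSE, n = n, a = a, ss_total = ss_tot,
         ss_subject = ss_subj,
         ss = ss_a, ss_err = ss_sa,
         df = a - 1, df_err = (n - 1) * (a - 1))
  }
}

#' Two-way repeated-measures ANOVA
#'
#' Univariate within-subject decomposition of a balanced complete
#' subject x factor-A x factor-B design: each within-subject effect is
#' tested against its own subject-by-effect error stratum
#' (`F = MS_effect / MS_(subject x effect)`). Sums of squares are the
#' classical balanced-design (Type III) sums. Effect size is eta squared,
#' `SS_effect / SS_total` (total includes the between-subject stratum). If
#' factor B has a single level the interaction and B rows are dropped and
#' the result is the one-way repeated-measures ANOVA over factor A.
#'
#' No sphericity correction is applied by default; `gg_correction = TRUE`
#' applies the Greenhouse-Geisser epsilon to the df used for p-values.
#'
#' @param table data.frame in long format, one row per cell.
#' @param factors character(2): factor column names (A, B).
#' @param value,subject column names.
#' @param gg_correction logical, Greenhouse-Geisser-adjusted p-values.
#' @return object of class `rm_anova_result`: data.frame with columns
#'   `term`, `SS`, `df`, `MS`, `F`, `p`, `eta_squared`; effect rows are each
#'   followed by their `Residual` row. Attributes `ss_subject`, `ss_total`,
#'   `n_subjects`.
#' @export
rm_anova_2way <- function(table, factors = c("visual", "platform"),
                          value = "value", subject = "subject",
                          gg_correction = FALSE) {
  stopifnot(length(factors) %in% 1:2)
  # drop single-level factors -> one-way decomposition
  factors <- factors[vapply(factors, function(f)
    length(unique(table[[f]])) > 1L, logical(1))]
  if (length(factors) == 0L) stop("all factors have a single level")
  check_outcome_table(table, factors, value, subject)
  d <- ss_decompose(table, factors, value, subject)
  if (d$n < 2L) stop("need at least 2 subjects")
  terms <- if (d$two_way) c(factors, paste(factors, collapse = " x ")) else factors
  ms <- d$ss / d$df
  ms_err <- d$ss_err / d$df_err
  Fv <- ms / ms_err
  df_num <- d$df; df_den <- d$df_err
  if (gg_correction) {
    eps <- vapply(seq_along(terms), function(i)
      gg_epsilon(table, terms[i], factors, value, subject), numeric(1))
    df_num <- df_num * eps; df_den <- df_den * eps
  }
  p <- stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
  rows <- data.frame(
    term = as.vector(rbind(terms, "Residual")),
    SS = as.vector(rbind(d$ss, d$ss_err)),
    df = as.vector(rbind(d$df, d$df_err)),
    MS = as.vector(rbind(ms, ms_err)),
    F = as.vector(rbind(Fv, NA_real_)),
    p = as.vector(rbind(p, NA_real_)),
    eta_squared = as.vector(rbind(d$ss / d$ss_total, NA_real_)),
    stringsAsFactors = FALSE)
  structure(rows, class = c("rm_anova_result", "data.frame"),
            ss_subject = d$ss_subject, ss_total = d$ss_total,
            n_subjects = d$n)
}

# Greenhouse-Geisser epsilon for one within-subject effect, computed from
# the covariance of the subject-level effect scores
gg_epsilon <- function(table, term, factors, value, subject) {
  s <- factor(table[[subject]])
  if (grepl(" x ", term, fixed = TRUE)) {
    cell <- interaction(table[[factors[1]]], table[[factors[2]]])
  } else {
    cell <- factor(table[[term]])
  }
  m <- tapply(table[[value]], list(s, cell), mean)
  S <- stats::cov(m)
  k <- ncol(S)
  C <- diag(k) - 1 / k   # centring projection spans the effect space loosely
  SC <- C %*% S %*% C
  ev <- eigen(SC, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  sum(ev)^2 / (length(ev) * sum(ev^2))
}

#' Simple contrasts against a reference level
#'
#' For each non-reference level of `factor`, the contrast estimate is the
#' mean over subjects of the per-subject (level minus reference) difference,
#' averaged over the other within-subject factor. The standard error is
#' pooled from the factor's subject-by-factor error stratum,
#' `SE = sqrt(2 * MS_error / n)` on the subject-by-level means, with
#' `df = (n - 1) * (a - 1)`; two-sided p from the t distribution. No
#' multiple-testing adjustment is applied.
#'
#' @param table long-format outcome table.
#' @param factor factor column to contrast (default `"visual"`).
#' @param reference reference level (default `"EO"`).
#' @param value,subject column names.
#' @return object of class `contrast_result`: data.frame with columns
#'   `comparison`, `estimate`, `SE`, `t`, `df`, `p`.
#' @export
simple_contrasts <- function(table, factor = "visual", reference = "EO",
                             value = "value", subject = "subject") {
  levs <- unique(as.character(table[[factor]]))
  if (!reference %in% levs)
    stop(sprintf("reference level '%s' not found in factor '%s'", reference, factor))
  check_outcome_table(table, factor, value, subject, allow_replicates = TRUE)
  # collapse over any other factors: subject x level means
  m <- tapply(table[[value]],
              list(factor(table[[subject]]), factor(table[[factor]], levels = levs)),
              mean)
  n <- nrow(m); a <- ncol(m)
  gm <- mean(m)
  resid <- m - outer(rowMeans(m), rep(1, a)) - outer(rep(1, n), colMeans(m)) + gm
  df_err <- (n - 1) * (a - 1)
  ms_err <- sum(resid^2) / df_err
  se <- sqrt(2 * ms_err / n)
  others <- setdiff(levs, reference)
  est <- colMeans(m)[others] - colMeans(m)[[reference]]
  tv <- est / se
  structure(
    data.frame(comparison = paste0(others, " - ", reference),
               estimate = unname(est), SE = se, t = unname(tv), df = df_err,
               p = 2 * stats::pt(-abs(unname(tv)), df_err),
               stringsAsFactors = FALSE),
    class = c("contrast_result", "data.frame"))
}

#' Post-hoc analysis within one platform condition
#'
#' Restricts the outcome table to a single level of the platform factor and
#' runs a one-way repeated-measures ANOVA over the visual conditions plus
#' simple contrasts against the reference level.
#'
#' @param table long-format outcome table.
#' @param platform_level platform level to restrict to.
#' @param factor visual factor column (default `"visual"`).
#' @param platform platform factor column (default `"platform"`).
#' @param reference reference visual level (default `"EO"`).
#' @param value,subject column names.
#' @return list with elements `anova` (`rm_anova_result`) and `contrasts`
#'   (`contrast_result`).
#' @export
single_level_posthoc <- function(table, platform_level, factor = "visual",
                                 platform = "platform", reference = "EO",
                                 value = "value", subject = "subject") {
  if (!platform_level %in% table[[platform]])
    stop(sprintf("platform level '%s' not present", platform_level))
  sub <- table[table[[platform]] == platform_level, , drop = FALSE]
  list(anova = rm_anova_2way(sub, factors = factor, value = value,
                             subject = subject),
       contrasts = simple_contrasts(sub, factor = factor,
                                    reference = reference,
                                    value = value, subject = subject))
}

#' Normalise outcome columns before a combined ANOVA
#'
#' The combined two-way design mixes outcome parameters with different units
#' as levels of the platform factor (two sway velocities in deg/s, two sway
#' powers in deg^2 samples). To make them commensurable each platform level
#' is normalised across all its rows: `"zscore"` (default) centres and
#' scales to unit SD; `"log"` takes log10 then z-scores; `"raw"` leaves
#' values untouched.
#'
#' @param table long-format outcome table.
#' @param method `"zscore"`, `"log"`, or `"raw"`.
#' @param platform,value column names.
#' @return the table with the value column normalised per platform level.
#' @export
normalize_outcomes <- function(table, method = c("zscore", "log", "raw"),
                               platform = "platform", value = "value") {
  method <- match.arg(method)
  if (method == "raw") return(table)
  v <- table[[value]]
  if (method == "log") {
    if (any(v <= 0)) stop("log normalisation requires strictly positive values")
    v <- log10(v)
  }
  for (lev in unique(table[[platform]])) {
    idx <- table[[platform]] == lev
    v[idx] <- (v[idx] - mean(v[idx])) / stats::sd(v[idx])
  }
  table[[value]] <- v
  table
}
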