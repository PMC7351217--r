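# Agreement / reliability statistics: two-way ANOVA mean squares, ICC with
# F-based confidence intervals, Sorensen-Dice overlap, SEM, paired t test,
# ICC sample-size planning, kernel-count percent difference.

#' Two-way ANOVA mean squares for a subjects x raters table
#'
#' Decomposes a complete two-way layout with one observation per cell into
#' between-subject, between-rater and residual mean squares — the building
#' blocks of every single-rater ICC form and of the standard error of
#' measurement.
#'
#' @param table A [ratings_table()] (or bare numeric matrix).
#' @return List of class `mean_squares` with `ms_rows`, `ms_cols`,
#'   `ms_error` and their degrees of freedom `df_rows`, `df_cols`,
#'   `df_error`, plus `n`, `k`, `grand_mean`.
#' @export
two_way_anova <- function(table) {
  y <- ratings_values(table)
  n <- nrow(y); k <- ncol(y)
  gm <- mean(y)
  rm_ <- rowMeans(y)
  cm <- colMeans(y)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  resid <- y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  ss_err <- sum(resid^2)
  structure(list(
    ms_rows = ss_rows / (n - 1), df_rows = n - 1L,
    ms_cols = ss_cols / (k - 1), df_cols = k - 1L,
    ms_error = ss_err / ((n - 1) * (k - 1)), df_error = (n - 1L) * (k - 1L),
    n = n, k = k, grand_mean = gm
  ), class = "mean_squares")
}

ratings_values <- function(table) {
  if (inherits(table, "incomplete_ratings"))
    stop_validation(
      "ratings for '%s' are incomplete (e.g. subject %s / rater %s); %s",
      table$parameter, table$missing$subject[1],
      table$missing$rater_or_trial[1],
      "complete the table or exclude those subjects")
  y <- if (inherits(table, "ratings_table")) table$values else as.matrix(table)
  if (anyNA(y))
    stop_validation("ratings table has missing cells; complete or exclude")
  if (nrow(y) < 2L || ncol(y) < 2L)
    stop_validation("need >= 2 subjects and >= 2 raters")
  y
}

#' Reliability band for an ICC estimate
#'
#' Thresholds 0.5 / 0.75 / 0.9 split poor, moderate, good and excellent
#' reliability; estimates exactly on a threshold take the higher band.
#'
#' @param estimate ICC value(s).
#' @return Character vector of band labels.
#' @export
reliability_band <- function(estimate) {
  cut(estimate, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' Intraclass correlation coefficient (single rater) with 95% CI
#'
#' Single-measure ICCs from the two-way mean squares, in either form:
#' \describe{
#'   \item{consistency}{\eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E)} —
#'     systematic rater offsets do not count as disagreement.}
#'   \item{absolute_agreement}{\eqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E +
#'     (k/n)(MS_C - MS_E))} — rater offsets penalised.}
#' }
#' Under the McGraw-Wong conventions the point estimates coincide for
#' two-way random and two-way mixed models; `model` is recorded in the
#' result label so outputs are never reported as a bare, ambiguous
#' "ICC(x,1)".  Confidence intervals use the standard F constructions
#' (exact for consistency; Satterthwaite degrees of freedom for absolute
#' agreement).
#'
#' @param table A [ratings_table()] or numeric matrix.
#' @param form `"consistency"` or `"absolute_agreement"`.
#' @param model `"two_way_mixed"` or `"two_way_random"` (label only for
#'   single-rater point estimates).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `model_label`, `reliability_band`, `degenerate`, plus the
#'   `mean_squares`.
#' @export
icc <- function(table,
                form = c("consistency", "absolute_agreement"),
                model = c("two_way_mixed", "two_way_random"),
                conf_level = 0.95) {
  form <- match.arg(form)
  model <- match.arg(model)
  ms <- two_way_anova(table)
  n <- ms$n; k <- ms$k
  msr <- ms$ms_rows; msc <- ms$ms_cols; mse <- ms$ms_error
  alpha <- 1 - conf_level
  label <- sprintf("ICC(%s,1), %s",
                   if (form == "consistency") "C" else "A",
                   gsub("_", "-", model))
  degenerate <- FALSE
  if (msr < 1e-300 && msc < 1e-300 && mse < 1e-300) {
    # zero total variance: every cell identical, ICC undefined
    res <- list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                model_label = label, reliability_band = NA_character_,
                degenerate = TRUE, mean_squares = ms, form = form,
                conf_level = conf_level)
    class(res) <- "icc_result"
    return(res)
  }
  if (form == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (n >= 3) {
      if (mse > 0) {
        fobs <- msr / mse
        fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
        fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
        ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
      } else {
        ci <- c(1, 1)
      }
    } else ci <- c(NA_real_, NA_real_)
  } else {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    est <- if (denom > 0) (msr - mse) / denom else NA_real_
    if (is.na(est)) degenerate <- TRUE
    if (n >= 3 && !is.na(est)) {
      if (mse > 0 || msc > 0) {
        r <- est
        if (abs(1 - r) < 1e-12) {
          ci <- c(1, 1)
        } else {
          a <- k * r / (n * (1 - r))
          b <- 1 + k * r * (n - 1) / (n * (1 - r))
          v <- (a * msc + b * mse)^2 /
            ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
          f1 <- qf(1 - alpha / 2, n - 1, v)
          f2 <- qf(1 - alpha / 2, v, n - 1)
          ci <- c(
            n * (msr - f1 * mse) /
              (f1 * (k * msc + (k * n - k - n) * mse) + n * msr),
            n * (f2 * msr - mse) /
              (k * msc + (k * n - k - n) * mse + n * f2 * msr))
        }
      } else {
        ci <- c(1, 1)
      }
    } else ci <- c(NA_real_, NA_real_)
  }
  # The F-based intervals presuppose a non-negative ICC; for strongly
  # negative estimates (possible in tiny degenerate samples) they can be
  # undefined.  Report NA rather than NaN, matching reference tools.
  if (any(is.nan(ci) | is.infinite(ci))) ci <- c(NA_real_, NA_real_)
  if (!anyNA(ci)) {
    ci[1] <- min(ci[1], est)
    ci[2] <- max(ci[2], est)
  }
  res <- list(estimate = est, ci_low = ci[1], ci_high = ci[2],
              model_label = label,
              reliability_band = reliability_band(est),
              degenerate = degenerate, mean_squares = ms, form = form,
              conf_level = conf_level)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate || is.na(x$estimate)) {
    cat(sprintf("%s: undefined (degenerate table)\n", x$model_label))
  } else {
    cat(sprintf("%s = %.3f [%.3f, %.3f] (%s)\n", x$model_label, x$estimate,
                x$ci_low, x$ci_high, x$reliability_band))
  }
  invisible(x)
}

#' Sorensen-Dice coefficient between two masks
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}; two empty masks are defined as
#' perfectly agreeing (returns 1 with a warning).
#'
#' @param a,b [roi_mask()] objects or logical matrices of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  if (!is.logical(ma) || !is.logical(mb))
    stop_validation("masks must be logical matrices or roi_mask objects")
  if (!all(dim(ma) == dim(mb)))
    stop_validation("mask shapes differ: %s vs %s",
                    paste(dim(ma), collapse = "x"),
                    paste(dim(mb), collapse = "x"))
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(ma & mb) / (na + nb)
}

#' Standard error of measurement
#'
#' `sem = sqrt(MS_E)` from the two-way ANOVA; `sem_pct` scales it by the
#' grand mean of all cells (for a 2-trial table, the mean of trial 1 and
#' trial 2), in percent.
#'
#' @param table A [ratings_table()] or numeric matrix.
#' @return List with `sem`, `sem_pct` (NA with a flag when the grand mean
#'   is 0), `grand_mean`, and the `mean_squares`.
#' @export
sem <- function(table) {
  ms <- two_way_anova(table)
  s <- sqrt(ms$ms_error)
  if (abs(ms$grand_mean) < 1e-300) {
    warning("grand mean is 0; SEM% undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * s / ms$grand_mean
  }
  list(sem = s, sem_pct = pct, grand_mean = ms$grand_mean,
       mean_squares = ms)
}

#' Paired t test on subject-matched measurements
#'
#' Classical paired t on the differences with `n - 1` degrees of freedom
#' and a two-sided p value.  Zero-variance differences are flagged: all
#' zero gives `t = 0, p = 1`; a constant nonzero difference gives an
#' infinite t with `p = 0`.
#'
#' @param x,y Equal-length numeric vectors (`n >= 2`), paired by subject.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_validation("x and y must have equal length >= 2")
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(md) * Inf, p = 0, df = n - 1L, mean_diff = md,
                degenerate = TRUE))
  }
  tstat <- md / (sdd / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1), df = n - 1L,
       mean_diff = md, degenerate = FALSE)
}

#' Subjects needed to detect an ICC against a null value
#'
#' Hypothesis-test sample size for an intraclass correlation (the
#' ANOVA-F / log step-down construction of Walter, Eliasziw and Donner,
#' which later planning methodology builds on):
#' \deqn{n = 1 + \frac{2 k (z_{1-\alpha/2} + z_{power})^2}
#'                    {(k - 1)\, (\ln C_0)^2},\qquad
#'       C_0 = \frac{1 + k\rho_0/(1-\rho_0)}{1 + k\rho_1/(1-\rho_1)}}
#' rounded up to an integer.
#'
#' @param rho_alt Hypothesised ICC (alternative), in (0, 1).
#' @param rho_null Null-hypothesis ICC, in `[0, 1)`, `< rho_alt`.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power in (0, 1).
#' @param k Ratings (raters/trials) per subject, >= 2.
#' @return Integer number of subjects.
#' @examples
#' icc_sample_size(0.75, 0, 0.05, 0.80, 2)  # 10
#' @export
icc_sample_size <- function(rho_alt, rho_null = 0, alpha = 0.05,
                            power = 0.80, k = 2) {
  if (!is_scalar_number(rho_alt) || rho_alt <= 0 || rho_alt >= 1)
    stop_validation("rho_alt must be in (0, 1)")
  if (!is_scalar_number(rho_null) || rho_null < 0 || rho_null >= 1)
    stop_validation("rho_null must be in [0, 1)")
  if (rho_alt <= rho_null)
    stop_validation("rho_alt must exceed rho_null")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0, 1)")
  if (!is_scalar_number(power) || power <= 0 || power >= 1)
    stop_validation("power must be in (0, 1)")
  if (!is_scalar_number(k) || k < 2 || k != round(k))
    stop_validation("k must be an integer >= 2")
  c0 <- (1 + k * rho_null / (1 - rho_null)) /
    (1 + k * rho_alt / (1 - rho_alt))
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)
  as.integer(ceiling(n - 1e-9))
}

#' Percent difference between two kernel counts
#'
#' `100 |a - b| / mean(a, b)`; used to compare ROI sizes via the number of
#' admissible kernels they contain.
#'
#' @param count_a,count_b Non-negative kernel counts, not both zero.
#' @return Percent difference.
#' @export
kernel_count_diff <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0)
    stop_validation("kernel counts must be >= 0")
  if (count_a == 0 && count_b == 0)
    stop_validation("kernel count difference undefined when both are 0")
  100 * abs(count_a - count_b) / mean(c(count_a, count_b))
}
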