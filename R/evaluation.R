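#' Error statistics for estimated vs. reference cuff BP
#'
#' With per-window errors \eqn{x_i = BP_{est,i} - BP_{cuf,i}}:
#' ME = mean(x); MAD = mean(|x|); SSE = sum(x^2);
#' sigma = sqrt(SSE/(n-1)); c.v. = sigma/ME (reported as \code{NA} when
#' ME is zero); SD = sqrt(mean((x - mean(x))^2)) (the population
#' 1/n divisor, used for AAMI-style mean +/- SD reporting); RMSE =
#' sqrt(SSE/n).  Note the c.v. explodes when ME is near zero -- that
#' is a property of the statistic, and such values are flagged.
#'
#' @param est,cuf Numeric vectors (mmHg), equal length, n >= 2.
#' @return Object of class \code{patbp_error_summary}: a list with
#'   \code{me}, \code{mad}, \code{sse}, \code{sigma}, \code{cv},
#'   \code{sd}, \code{rmse}, \code{n}.
#' @export
error_summary <- function(est, cuf) {
  stopifnot(length(est) == length(cuf), length(est) >= 2L)
  x <- est - cuf
  n <- length(x)
  me <- mean(x)
  sse <- sum(x^2)
  sigma <- sqrt(sse / (n - 1))
  structure(list(
    me = me,
    mad = mean(abs(x)),
    sse = sse,
    sigma = sigma,
    cv = if (me == 0) NA_real_ else sigma / me,
    sd = sqrt(mean((x - me)^2)),
    rmse = sqrt(sse / n),
    n = n), class = "patbp_error_summary")
}

#' @export
print.patbp_error_summary <- function(x, ...) {
  cat(sprintf(
    "BP estimation errors (n = %d)\n  ME %.4f +/- SD %.4f mmHg, MAD %.4f mmHg\n",
    x$n, x$me, x$sd, x$mad))
  cat(sprintf("  SSE %.4f mmHg^2, sigma %.4f, RMSE %.4f, c.v. %s\n",
              x$sse, x$sigma, x$rmse,
              if (is.na(x$cv)) "undefined (ME = 0)" else
                sprintf("%.4f", x$cv)))
  invisible(x)
}

#' Pooled Pearson correlation between estimated and cuff BP
#'
#' All windows of all subjects are pooled into one product-moment
#' correlation per model/channel.
#'
#' @param est,cuf Numeric vectors, equal length, n >= 3, each with
#'   non-zero variance.
#' @return Correlation coefficient R.
#' @export
pearson_correlation <- function(est, cuf) {
  stopifnot(length(est) == length(cuf), length(est) >= 3L)
  if (stats::var(est) == 0 || stats::var(cuf) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(est, cuf)
}

#' AAMI compliance verdict for an error summary
#'
#' The AAMI device-acceptance bound: |mean error| <= 5 mmHg and error
#' SD <= 8 mmHg, both inclusive.
#'
#' @param summary A [error_summary()] result, or any list with
#'   \code{me} and \code{sd}.
#' @param mean_limit,sd_limit Bounds (mmHg), defaults 5 and 8.
#' @return List with \code{mean_ok}, \code{sd_ok}, \code{pass}.
#' @export
aami_verdict <- function(summary, mean_limit = 5, sd_limit = 8) {
  mean_ok <- abs(summary$me) <= mean_limit
  sd_ok <- abs(summary$sd) <= sd_limit
  list(mean_ok = mean_ok, sd_ok = sd_ok, pass = mean_ok && sd_ok)
}

#' Kruskal-Wallis rank test across model error groups
#'
#' Thin wrapper around [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with g - 1 df).  The degenerate
#' all-identical case is reported as H = 0, p = 1.
#'
#' @param groups List of numeric vectors, each nonempty, >= 2 groups.
#' @return List with \code{statistic} (H), \code{df}, \code{p_value}.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) > 0L))
  values <- unlist(groups, use.names = FALSE)
  if (max(values) == min(values))
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise rank-mean z statistics
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)},}
#' with the tie correction \eqn{T = \sum_t (t^3 - t) / (12 (N - 1))},
#' two-sided normal p-values, and a multiplicity correction (default
#' Bonferroni, any [stats::p.adjust()] method).
#'
#' @param groups List of numeric vectors (optionally named).
#' @param method Multiplicity correction, default \code{"bonferroni"}.
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{z}, \code{p_unadjusted}, \code{p_adjusted}.
#' @export
dunn_posthoc <- function(groups, method = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) > 0L))
  g <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(g))
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_len(g), lengths(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, idx, mean)
  nn <- lengths(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(g, 2L)
  res <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[i] + 1 / nn[j]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  }, c(z = 0, p = 0))
  out <- data.frame(group1 = labels[pairs[1L, ]],
                    group2 = labels[pairs[2L, ]],
                    z = res["z", ],
                    p_unadjusted = res["p", ],
                    p_adjusted = stats::p.adjust(res["p", ],
                                                 method = method))
  rownames(out) <- NULL
  out
}

#' Sensitivity of dMK-BH accuracy to the vascular parameter gamma
#'
#' For each gamma on the grid the dMK-BH model is recalibrated for
#' every subject (advanced PTP on that subject's calibration pairs),
#' evaluated on the subject's monitoring windows, and the pooled MAD
#' over all subjects is recorded separately for SBP and DBP.  Grid
#' points where calibration fails for every subject are marked
#' missing.
#'
#' @param subjects List, one element per subject: a list with
#'   \code{calib} (data.frame \code{pat}, \code{sbp}, \code{dbp},
#'   optionally \code{round}) and \code{monitor} (data.frame
#'   \code{pat}, \code{sbp}, \code{dbp}: monitoring windows paired
#'   with cuff readings).
#' @param grid Strictly increasing gamma values (mmHg^-1) in (0, 0.1];
#'   default 0.0005 to 0.05 in steps of 0.0005, covering the range
#'   where per-subject optima typically concentrate.
#' @return Object of class \code{patbp_gamma_sweep}: list with
#'   \code{grid}, \code{mad_sbp}, \code{mad_dbp}, \code{argmin_sbp},
#'   \code{argmin_dbp}.
#' @export
gamma_sweep <- function(subjects,
                        grid = seq(0.0005, 0.05, by = 0.0005)) {
  stopifnot(length(grid) >= 1L, all(diff(grid) > 0) || length(grid) == 1L,
            all(grid > 0), all(grid <= 0.1))
  mad_sbp <- mad_dbp <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    err_s <- err_d <- numeric(0)
    for (subj in subjects) {
      fit <- tryCatch(
        ptp_calibrate("dMK-BH", subj$calib, gamma = grid[gi]),
        error = function(e) NULL)
      if (is.null(fit)) next
      est <- estimate_bp(fit, subj$monitor$pat, warn_crossed = FALSE)
      err_s <- c(err_s, est$sbp - subj$monitor$sbp)
      err_d <- c(err_d, est$dbp - subj$monitor$dbp)
    }
    if (length(err_s)) {
      mad_sbp[gi] <- mean(abs(err_s))
      mad_dbp[gi] <- mean(abs(err_d))
    }
  }
  structure(list(grid = grid, mad_sbp = mad_sbp, mad_dbp = mad_dbp,
                 argmin_sbp = grid[which.min(mad_sbp)],
                 argmin_dbp = grid[which.min(mad_dbp)]),
            class = "patbp_gamma_sweep")
}

#' @export
print.patbp_gamma_sweep <- function(x, ...) {
  cat(sprintf(
    "gamma sweep over [%g, %g] (%d points)\n  pooled-MAD argmin: SBP at gamma = %g, DBP at gamma = %g mmHg^-1\n",
    min(x$grid), max(x$grid), length(x$grid), x$argmin_sbp,
    x$argmin_dbp))
  invisible(x)
}

#' @export
plot.patbp_gamma_sweep <- function(x, ...) {
  graphics::plot(x$grid, x$mad_sbp, type = "l", col = "firebrick",
                 xlab = "gamma (mmHg^-1)", ylab = "pooled MAD (mmHg)",
                 ylim = range(x$mad_sbp, x$mad_dbp, na.rm = TRUE), ...)
  graphics::lines(x$grid, x$mad_dbp, col = "steelblue")
  graphics::legend("topright", c("SBP", "DBP"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
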