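#' The five supported BP-PAT model identifiers
#'
#' Four vascular-elasticity (VE) models derived from the Moens-Korteweg
#' equation -- \code{"MK-EE"} (logarithmic), \code{"L-MK"} (linear),
#' \code{"MK-BH"} and \code{"dMK-BH"} (both via the Bramwell-Hill
#' equation) -- and one elastic-tube (ET) model, \code{"M-M"}, derived
#' from conservation of mass and momentum.
#'
#' @return Character vector of the five model ids.
#' @export
bp_model_ids <- function() c("MK-EE", "L-MK", "MK-BH", "dMK-BH", "M-M")

match_model_id <- function(model) {
  if (!is.character(model) || length(model) != 1L)
    stop("'model' must be a single model id string", call. = FALSE)
  ids <- bp_model_ids()
  hit <- match(toupper(model), toupper(ids))
  if (is.na(hit))
    stop("unknown model id '", model, "'; expected one of: ",
         paste(ids, collapse = ", "), call. = FALSE)
  ids[hit]
}

#' Number of cuff-BP/PAT pairs needed to calibrate a model exactly
#'
#' Point-to-point-pairing (PTP) calibration solves a model's free
#' parameters exactly from as many (mean PAT, cuff BP) pairs as the
#' model has unknowns per channel: one for the baseline-anchored
#' MK-BH/dMK-BH, two for the two-coefficient MK-EE/L-MK, three for the
#' three-coefficient M-M.
#'
#' @param model A model id (see [bp_model_ids()]).
#' @return Integer count of calibration points.
#' @export
required_calibration_points <- function(model) {
  model <- match_model_id(model)
  c("MK-EE" = 2L, "L-MK" = 2L, "MK-BH" = 1L, "dMK-BH" = 1L,
    "M-M" = 3L)[[model]]
}

#' Construct the baseline state used by the MK-BH and dMK-BH models
#'
#' Pulse pressure and mean BP are derived from the systolic/diastolic
#' anchors: PP0 = SBP0 - DBP0 and MBP0 = SBP0/3 + 2 DBP0/3.
#'
#' @param sbp0,dbp0 Baseline systolic and diastolic pressure (mmHg).
#' @param pat0 Baseline pulse arrival time (s).
#' @param gamma Vascular information parameter (mmHg^-1); about 0.031
#'   for healthy young adults.
#' @return A list with elements \code{sbp0}, \code{dbp0}, \code{pat0},
#'   \code{pp0}, \code{mbp0}, \code{gamma}.
#' @export
baseline_state <- function(sbp0, dbp0, pat0, gamma = 0.031) {
  stopifnot(is.finite(sbp0), is.finite(dbp0), is.finite(pat0),
            is.finite(gamma))
  if (!(sbp0 > dbp0 && dbp0 > 0))
    stop("need sbp0 > dbp0 > 0", call. = FALSE)
  if (pat0 <= 0) stop("pat0 must be positive", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  list(sbp0 = sbp0, dbp0 = dbp0, pat0 = pat0,
       pp0 = sbp0 - dbp0, mbp0 = sbp0 / 3 + 2 * dbp0 / 3,
       gamma = gamma)
}

new_patbp_model <- function(model, coefficients = NULL, baseline = NULL,
                            audit = NULL) {
  structure(
    list(model = model, coefficients = coefficients,
         baseline = baseline, audit = audit),
    class = "patbp_model")
}

# The M-M (elastic tube) channel response, isolated so its functional
# form -- BP = a + sqrt(b + c / PAT^2) -- is swappable in one place.
mm_channel <- function(a, b, c, pat) {
  radicand <- b + c / pat^2
  if (any(radicand < 0))
    stop("M-M model: no real solution (negative radicand) at PAT = ",
         paste(signif(pat[radicand < 0], 6), collapse = ", "),
         call. = FALSE)
  a + sqrt(radicand)
}

#' Evaluate a BP-PAT model at given pulse arrival times
#'
#' Forward evaluation of a fitted (or manually constructed) model,
#' returning systolic and diastolic estimates per PAT value:
#' \describe{
#'   \item{MK-EE}{\eqn{SBP = a_1 \ln PAT + b_1}, likewise DBP with the
#'     primed coefficients.}
#'   \item{L-MK}{\eqn{SBP = a_2 + b_2 PAT}, likewise DBP.}
#'   \item{MK-BH}{\eqn{SBP = SBP_0 - (2/(\gamma PAT_0)) (PAT - PAT_0)};
#'     \eqn{DBP = SBP - PP_0 (PAT_0/PAT)^2} with SBP the model's own
#'     estimate at the same PAT.}
#'   \item{dMK-BH}{\eqn{DBP = MBP_0 + (2/\gamma) \ln(PAT_0/PAT) -
#'     (PP_0/3) (PAT_0/PAT)^2}; \eqn{SBP = DBP + PP_0 (PAT_0/PAT)^2}.}
#'   \item{M-M}{\eqn{BP = a_3 + \sqrt{b_3 + c_3 / PAT^2}} per channel.}
#' }
#' Estimates with \code{sbp <= dbp} are physiologically implausible but
#' are returned (the models do behave this way in parts of their
#' domain); a warning flags them.
#'
#' @param object A \code{patbp_model} (from [calibrate_bp_model()] or
#'   [ptp_calibrate()]).
#' @param pat Numeric vector of pulse arrival times (s), all positive.
#' @param warn_crossed Warn when sbp <= dbp for some PAT (default TRUE).
#' @return A data.frame with columns \code{pat}, \code{sbp}, \code{dbp}
#'   (mmHg).
#' @export
estimate_bp <- function(object, pat, warn_crossed = TRUE) {
  stopifnot(inherits(object, "patbp_model"))
  if (!is.numeric(pat) || length(pat) == 0L || any(!is.finite(pat)) ||
      any(pat <= 0))
    stop("'pat' must be a vector of positive finite times (s)",
         call. = FALSE)
  model <- object$model
  cf <- object$coefficients
  bl <- object$baseline
  if (model == "MK-EE") {
    sbp <- cf$sbp[["a"]] * log(pat) + cf$sbp[["b"]]
    dbp <- cf$dbp[["a"]] * log(pat) + cf$dbp[["b"]]
  } else if (model == "L-MK") {
    sbp <- cf$sbp[["a"]] + cf$sbp[["b"]] * pat
    dbp <- cf$dbp[["a"]] + cf$dbp[["b"]] * pat
  } else if (model == "MK-BH") {
    sbp <- bl$sbp0 - (2 / (bl$gamma * bl$pat0)) * (pat - bl$pat0)
    dbp <- sbp - bl$pp0 * (bl$pat0 / pat)^2
  } else if (model == "dMK-BH") {
    # re-centred form of MBP0 + (2/g) ln(PAT0/PAT) - (PP0/3)(PAT0/PAT)^2
    # (and SBP = DBP + PP0 (PAT0/PAT)^2): both collapse to the exact
    # baseline floats at PAT = PAT0
    L <- log(bl$pat0 / pat)
    q <- (bl$pat0 / pat)^2
    dbp <- bl$dbp0 + (2 / bl$gamma) * L + (bl$pp0 / 3) * (1 - q)
    sbp <- bl$sbp0 + (2 / bl$gamma) * L + (2 * bl$pp0 / 3) * (q - 1)
  } else if (model == "M-M") {
    sbp <- mm_channel(cf$sbp[["a"]], cf$sbp[["b"]], cf$sbp[["c"]], pat)
    dbp <- mm_channel(cf$dbp[["a"]], cf$dbp[["b"]], cf$dbp[["c"]], pat)
  } else stop("unknown model id '", model, "'", call. = FALSE)
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)))
    stop(model, ": non-finite BP estimate", call. = FALSE)
  if (warn_crossed && any(sbp <= dbp))
    warning(model, ": sbp <= dbp for ", sum(sbp <= dbp),
            " PAT value(s)", call. = FALSE)
  data.frame(pat = pat, sbp = sbp, dbp = dbp)
}

# Exact two-point fit for one logarithmic channel: BP = a ln(PAT) + b.
fit_log_channel <- function(pat, bp) {
  d <- log(pat[1L]) - log(pat[2L])
  if (abs(d) < .Machine$double.eps * 8)
    stop("degenerate calibration subset: duplicate PAT values",
         call. = FALSE)
  a <- (bp[1L] - bp[2L]) / d
  c(a = a, b = bp[1L] - a * log(pat[1L]))
}

# Exact two-point fit for one linear channel: BP = a + b PAT.
fit_lin_channel <- function(pat, bp) {
  d <- pat[1L] - pat[2L]
  if (abs(d) < .Machine$double.eps * 8)
    stop("degenerate calibration subset: duplicate PAT values",
         call. = FALSE)
  b <- (bp[1L] - bp[2L]) / d
  c(a = bp[1L] - b * pat[1L], b = b)
}

# Exact three-point fit for one M-M channel.  (BP_i - a)^2 = b + c u_i
# with u = 1/PAT^2; pairwise subtraction removes b, leaving a 2x2
# linear system in (a, c).
fit_mm_channel <- function(pat, bp) {
  u <- 1 / pat^2
  if (min(dist(u)) < .Machine$double.eps * 64)
    stop("degenerate calibration subset: duplicate PAT values",
         call. = FALSE)
  # (BP_i^2 - BP_j^2) - 2 a (BP_i - BP_j) = c (u_i - u_j)
  A <- rbind(c(-2 * (bp[1L] - bp[2L]), -(u[1L] - u[2L])),
             c(-2 * (bp[2L] - bp[3L]), -(u[2L] - u[3L])))
  rhs <- c(-(bp[1L]^2 - bp[2L]^2), -(bp[2L]^2 - bp[3L]^2))
  if (abs(det(A)) < .Machine$double.eps * 64)
    stop("degenerate calibration subset: singular M-M system",
         call. = FALSE)
  ac <- solve(A, rhs)
  a <- ac[1L]; cc <- ac[2L]
  b <- (bp[1L] - a)^2 - cc * u[1L]
  if (any(b + cc * u < 0))
    stop("M-M model: no real solution at a calibration point",
         call. = FALSE)
  # sqrt branch: require BP_i - a = +sqrt(.) at every point, else the
  # forward model cannot reproduce the data.
  if (any(bp - a < 0))
    stop("M-M model: no real solution (negative branch required)",
         call. = FALSE)
  c(a = a, b = b, c = cc)
}

#' Calibrate a BP-PAT model exactly from the minimal number of points
#'
#' Solves a model's parameters in closed form from exactly
#' [required_calibration_points()] pairs of (mean PAT, cuff SBP, cuff
#' DBP) -- the point-to-point-pairing (PTP) principle.  The round-trip
#' law holds: evaluating the returned model at the calibration PATs
#' reproduces every calibration BP to numerical precision.
#'
#' @param model Model id (see [bp_model_ids()]).
#' @param pairs data.frame with columns \code{pat} (s), \code{sbp} and
#'   \code{dbp} (mmHg); exactly as many rows as the model needs.
#' @param gamma Vascular parameter (mmHg^-1); used by MK-BH/dMK-BH only.
#' @return An object of class \code{patbp_model}.
#' @examples
#' m <- calibrate_bp_model("L-MK",
#'   data.frame(pat = c(0.25, 0.20), sbp = c(120, 135), dbp = c(80, 88)))
#' predict(m, pat = 0.22)
#' @export
calibrate_bp_model <- function(model, pairs, gamma = 0.031) {
  model <- match_model_id(model)
  pairs <- as.data.frame(pairs)
  need <- c("pat", "sbp", "dbp")
  if (!all(need %in% names(pairs)))
    stop("'pairs' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  k <- required_calibration_points(model)
  if (nrow(pairs) != k)
    stop(model, " needs exactly ", k, " calibration point(s), got ",
         nrow(pairs), call. = FALSE)
  if (any(pairs$pat <= 0)) stop("PAT values must be positive", call. = FALSE)
  if (any(pairs$sbp <= pairs$dbp))
    stop("calibration pairs must satisfy sbp > dbp", call. = FALSE)
  if (model %in% c("MK-BH", "dMK-BH")) {
    bl <- baseline_state(pairs$sbp[1L], pairs$dbp[1L], pairs$pat[1L],
                         gamma = gamma)
    return(new_patbp_model(model, baseline = bl))
  }
  fit <- switch(model,
    "MK-EE" = fit_log_channel,
    "L-MK"  = fit_lin_channel,
    "M-M"   = fit_mm_channel)
  new_patbp_model(model, coefficients = list(
    sbp = fit(pairs$pat, pairs$sbp),
    dbp = fit(pairs$pat, pairs$dbp)))
}

#' @export
print.patbp_model <- function(x, ...) {
  cat("BP-PAT model: ", x$model, "\n", sep = "")
  if (!is.null(x$baseline)) {
    b <- x$baseline
    cat(sprintf(
      "  baseline: SBP0 = %.2f, DBP0 = %.2f mmHg, PAT0 = %.4f s\n",
      b$sbp0, b$dbp0, b$pat0))
    cat(sprintf("  PP0 = %.2f, MBP0 = %.2f mmHg, gamma = %.4g mmHg^-1\n",
                b$pp0, b$mbp0, b$gamma))
  }
  if (!is.null(x$coefficients)) {
    cat("  SBP channel: ",
        paste(names(x$coefficients$sbp),
              signif(x$coefficients$sbp, 6), sep = " = ",
              collapse = ", "), "\n", sep = "")
    cat("  DBP channel: ",
        paste(names(x$coefficients$dbp),
              signif(x$coefficients$dbp, 6), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$audit))
    cat(sprintf("  PTP calibration: %d subset(s) used, %d skipped\n",
                x$audit$n_used, x$audit$n_skipped))
  invisible(x)
}

#' @export
coef.patbp_model <- function(object, ...) {
  if (!is.null(object$baseline)) {
    b <- object$baseline
    return(c(sbp0 = b$sbp0, dbp0 = b$dbp0, pat0 = b$pat0,
             pp0 = b$pp0, mbp0 = b$mbp0, gamma = b$gamma))
  }
  cf <- object$coefficients
  out <- c(cf$sbp, cf$dbp)
  names(out) <- c(paste0("sbp.", names(cf$sbp)),
                  paste0("dbp.", names(cf$dbp)))
  out
}

#' Predict BP from PAT with a fitted model
#'
#' @param object A \code{patbp_model}.
#' @param pat Numeric vector of pulse arrival times (s).
#' @param ... Passed to [estimate_bp()].
#' @return data.frame with columns \code{pat}, \code{sbp}, \code{dbp}.
#' @export
predict.patbp_model <- function(object, pat, ...) {
  estimate_bp(object, pat, ...)
}

#' @export
summary.patbp_model <- function(object, ...) {
  structure(list(model = object$model, coefficients = coef(object),
                 audit = object$audit),
            class = "summary.patbp_model")
}

#' @export
print.summary.patbp_model <- function(x, ...) {
  cat("BP-PAT model: ", x$model, "\n\nParameters:\n", sep = "")
  print(signif(x$coefficients, 6))
  if (!is.null(x$audit)) {
    cat(sprintf("\nPTP calibration audit: %d subsets used, %d skipped\n",
                x$audit$n_used, x$audit$n_skipped))
    if (x$audit$n_skipped > 0)
      cat("  skip reasons: ",
          paste(unique(x$audit$skips$reason), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Plot a fitted model's SBP/DBP response curves over a PAT range
#'
#' @param x A \code{patbp_model}.
#' @param pat_range Range of PAT (s) to draw over.
#' @param n Number of grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.patbp_model <- function(x, pat_range = c(0.15, 0.40), n = 200, ...) {
  pat <- seq(pat_range[1L], pat_range[2L], length.out = n)
  est <- estimate_bp(x, pat, warn_crossed = FALSE)
  graphics::plot(est$pat, est$sbp, type = "l", col = "firebrick",
                 xlab = "PAT (s)", ylab = "BP (mmHg)",
                 ylim = range(est$sbp, est$dbp),
                 main = paste(x$model, "response"), ...)
  graphics::lines(est$pat, est$dbp, col = "steelblue")
  graphics::legend("topright", c("SBP", "DBP"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(est)
}

#' Serialize model parameters to JSON / read them back
#'
#' Parameters round-trip bit-exactly (full double precision).
#'
#' @param object A \code{patbp_model}.
#' @param path File path for the JSON output.
#' @return \code{write_model_json} returns \code{path} invisibly;
#'   \code{read_model_json} returns the reconstructed
#'   \code{patbp_model}.
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "patbp_model"))
  payload <- list(model = object$model)
  if (!is.null(object$coefficients))
    payload$coefficients <- lapply(object$coefficients, as.list)
  if (!is.null(object$baseline)) payload$baseline <- object$baseline
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17))  # 17 significant: lossless doubles
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path)
  cf <- NULL
  if (!is.null(payload$coefficients))
    cf <- lapply(payload$coefficients, function(ch) unlist(ch))
  bl <- if (!is.null(payload$baseline)) lapply(payload$baseline, as.numeric)
  new_patbp_model(match_model_id(payload$model), coefficients = cf,
                  baseline = bl)
}
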