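#' Pair cuff readings with co-temporal averaged-PAT windows
#'
#' Each cuff reading is matched to the PAT window whose span overlaps
#' it most (one-to-one, greedy by overlap); matches whose window start
#' differs from the cuff start by more than \code{max_offset} are
#' dropped and counted.
#'
#' @param cuff data.frame with columns \code{t_start}, \code{t_end},
#'   \code{sbp}, \code{dbp} (time-sorted).
#' @param windows data.frame with columns \code{t_start}, \code{t_end},
#'   \code{pat_bar}, \code{n_beats} (time-sorted; see
#'   [average_pat_windows()]).
#' @param max_offset Maximum |window start - cuff start| (s), default 5.
#' @return data.frame with columns \code{t_start}, \code{pat} (the
#'   window mean PAT), \code{sbp}, \code{dbp}; attribute
#'   \code{n_unpaired} counts cuff readings left unmatched.
#' @export
pair_cuff_with_pat <- function(cuff, windows, max_offset = 5) {
  cuff <- as.data.frame(cuff); windows <- as.data.frame(windows)
  stopifnot(all(c("t_start", "t_end", "sbp", "dbp") %in% names(cuff)),
            all(c("t_start", "t_end", "pat_bar") %in% names(windows)))
  used <- logical(nrow(windows))
  out <- vector("list", nrow(cuff))
  n_unpaired <- 0L
  for (i in seq_len(nrow(cuff))) {
    ov <- pmin(cuff$t_end[i], windows$t_end) -
      pmax(cuff$t_start[i], windows$t_start)
    ov[used] <- -Inf
    j <- which.max(ov)
    if (length(j) == 0L || ov[j] <= 0 ||
        abs(windows$t_start[j] - cuff$t_start[i]) > max_offset) {
      n_unpaired <- n_unpaired + 1L
      next
    }
    used[j] <- TRUE
    out[[i]] <- data.frame(t_start = cuff$t_start[i],
                           pat = windows$pat_bar[j],
                           sbp = cuff$sbp[i], dbp = cuff$dbp[i])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(t_start = numeric(), pat = numeric(),
                      sbp = numeric(), dbp = numeric())
  rownames(res) <- NULL
  if (n_unpaired > 0L)
    message(n_unpaired, " cuff reading(s) left unpaired")
  attr(res, "n_unpaired") <- n_unpaired
  res
}

#' Advanced point-to-point-pairing calibration with subset averaging
#'
#' One calibration round is a block of four (mean PAT, cuff SBP/DBP)
#' pairs.  For a model needing k points, every C(4, k) subset of each
#' round is calibrated exactly via [calibrate_bp_model()] (4 subsets
#' for the 1- and 3-point models, 6 for the 2-point ones); degenerate
#' or no-real-solution subsets are skipped with a recorded reason.
#' Every scalar parameter is then averaged arithmetically over all
#' successful subsets of all rounds (for the baseline models PP0 and
#' MBP0 are recomputed from the averaged SBP0/DBP0 so the baseline
#' identities still hold).  The result is the subject's frozen
#' monitoring parameter set: calibration is done once.
#'
#' @param model Model id (see [bp_model_ids()]).
#' @param pairs data.frame with columns \code{pat}, \code{sbp},
#'   \code{dbp} and optionally \code{round}; without a \code{round}
#'   column consecutive blocks of \code{pairs_per_round} rows form the
#'   rounds.
#' @param gamma Vascular parameter (mmHg^-1), default 0.031; an input
#'   constant, never fitted.
#' @param pairs_per_round Pairs per round, default 4.
#' @param min_pat_spread For multi-point models, the smallest pairwise
#'   mean-PAT separation (s) a subset must have to be used; default
#'   0.002 (twice the 1 kHz delineation resolution).  Separations at
#'   or below timing resolution carry no slope information and would
#'   amplify cuff error without bound.
#' @return A \code{patbp_model} whose \code{audit} element records the
#'   per-subset parameters and skip reasons.
#' @export
ptp_calibrate <- function(model, pairs, gamma = 0.031,
                          pairs_per_round = 4L,
                          min_pat_spread = 0.002) {
  model <- match_model_id(model)
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("pat", "sbp", "dbp") %in% names(pairs)))
  if (is.null(pairs$round))
    pairs$round <- rep(seq_len(ceiling(nrow(pairs) / pairs_per_round)),
                       each = pairs_per_round)[seq_len(nrow(pairs))]
  k <- required_calibration_points(model)
  fits <- list(); skips <- list()
  for (r in unique(pairs$round)) {
    block <- pairs[pairs$round == r, , drop = FALSE]
    if (nrow(block) < k) {
      skips[[length(skips) + 1L]] <-
        data.frame(round = r, subset = NA_character_,
                   reason = "round smaller than required point count")
      next
    }
    subsets <- utils::combn(nrow(block), k, simplify = FALSE)
    for (s in subsets) {
      if (k > 1L &&
          min(diff(sort(block$pat[s]))) < min_pat_spread) {
        skips[[length(skips) + 1L]] <-
          data.frame(round = r, subset = paste(s, collapse = ","),
                     reason = "degenerate calibration subset: PAT spread below resolution")
        next
      }
      fit <- tryCatch(
        calibrate_bp_model(model, block[s, c("pat", "sbp", "dbp")],
                           gamma = gamma),
        error = function(e) e)
      if (inherits(fit, "error")) {
        skips[[length(skips) + 1L]] <-
          data.frame(round = r,
                     subset = paste(s, collapse = ","),
                     reason = conditionMessage(fit))
      } else {
        fits[[length(fits) + 1L]] <- fit
      }
    }
  }
  skips <- if (length(skips)) do.call(rbind, skips) else
    data.frame(round = integer(), subset = character(),
               reason = character())
  if (length(fits) == 0L)
    stop("PTP calibration failed for ", model,
         ": no usable subset.\n",
         paste(sprintf("  round %s subset {%s}: %s", skips$round,
                       skips$subset, skips$reason), collapse = "\n"),
         call. = FALSE)
  audit <- list(model = model, n_used = length(fits),
                n_skipped = nrow(skips), skips = skips,
                subset_params = t(vapply(fits, coef,
                                         numeric(length(coef(fits[[1L]]))))))
  avg <- colMeans(audit$subset_params)
  if (model %in% c("MK-BH", "dMK-BH")) {
    out <- new_patbp_model(model,
      baseline = baseline_state(avg[["sbp0"]], avg[["dbp0"]],
                                avg[["pat0"]], gamma = gamma),
      audit = audit)
  } else {
    sb <- grepl("^sbp\\.", names(avg)); db <- grepl("^dbp\\.", names(avg))
    cs <- avg[sb]; names(cs) <- sub("^sbp\\.", "", names(cs))
    cd <- avg[db]; names(cd) <- sub("^dbp\\.", "", names(cd))
    out <- new_patbp_model(model,
      coefficients = list(sbp = cs, dbp = cd), audit = audit)
  }
  out
}
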