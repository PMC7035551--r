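# Independent oracles, written naively and kept free of package code
# paths so the dual-route checks stay meaningful.

naive_error_stats <- function(est, cuf) {
  x <- est - cuf
  n <- length(x)
  me <- sum(x) / n
  sse <- sum(x^2)
  sigma <- sqrt(sse / (n - 1))
  list(me = me,
       mad = sum(abs(x)) / n,
       sse = sse,
       sigma = sigma,
       cv = if (me == 0) NA_real_ else sigma / me,
       sd = sqrt(sum((x - me)^2) / n),
       rmse = sqrt(sse / n))
}

# Rank-based H with tie correction, from first principles.
naive_kruskal_h <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact-curve calibration pairs for a given model id, generated from
# known parameters; returns list(pairs, truth) where truth is the
# coef() vector the calibration should recover.
exact_pairs <- function(model, pats, gamma = 0.031) {
  if (model %in% c("MK-BH", "dMK-BH")) {
    bl <- baseline_state(123, 76, 0.24, gamma = gamma)
    obj <- calibrate_bp_model(model, data.frame(pat = 0.24, sbp = 123,
                                                dbp = 76), gamma = gamma)
    est <- estimate_bp(obj, pats, warn_crossed = FALSE)
    list(pairs = data.frame(pat = pats, sbp = est$sbp, dbp = est$dbp),
         truth = coef(obj), object = obj)
  } else if (model == "MK-EE") {
    sbp <- -67.2213 * log(pats) + 26.8115
    dbp <- -35 * log(pats) + 30
    list(pairs = data.frame(pat = pats, sbp = sbp, dbp = dbp),
         truth = c(sbp.a = -67.2213, sbp.b = 26.8115,
                   dbp.a = -35, dbp.b = 30))
  } else if (model == "L-MK") {
    sbp <- 195 - 300 * pats
    dbp <- 140 - 250 * pats
    list(pairs = data.frame(pat = pats, sbp = sbp, dbp = dbp),
         truth = c(sbp.a = 195, sbp.b = -300, dbp.a = 140,
                   dbp.b = -250))
  } else if (model == "M-M") {
    sbp <- 60 + sqrt(2000 + 100 / pats^2)
    dbp <- 40 + sqrt(1500 + 80 / pats^2)
    list(pairs = data.frame(pat = pats, sbp = sbp, dbp = dbp),
         truth = c(sbp.a = 60, sbp.b = 2000, sbp.c = 100,
                   dbp.a = 40, dbp.b = 1500, dbp.c = 80))
  } else stop("unknown model")
}

# Random non-degenerate calibration points for a model.
random_pairs <- function(model, k) {
  repeat {
    pats <- sort(runif(k, 0.18, 0.35))
    if (k == 1L || min(diff(pats)) > 0.01) break
  }
  sbp <- runif(k, 110, 150)
  dbp <- sbp - runif(k, 30, 50)
  data.frame(pat = pats, sbp = sbp, dbp = dbp)
}

# Build a coefficient-model object directly from known parameters.
new_model_for_test <- function(model, sbp, dbp) {
  patbp:::new_patbp_model(model, coefficients = list(sbp = sbp,
                                                     dbp = dbp))
}

withr_local_tempfile <- function() tempfile(fileext = ".json")
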