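# Time-series-feature track: an "efficient" feature library with the slow
# families excluded (no entropy features, matrix profile, CWT peak counts,
# partial autocorrelation, aggregated linear trend, or Dickey-Fuller
# statistics), -999 imputation, variance filtering fitted on training rows
# only, Bayesian hyperparameter search over the XGBoost space, and
# split-frequency feature importance aggregated by group.

# ---- feature calculators ----
# Names follow the group__parameter convention so that importance can be
# aggregated by the prefix before the first "__".

welchDensity <- function(v, coeffs = c(2, 5, 8)) {
  n <- length(v)
  seg <- min(256L, n)
  step <- max(seg %/% 2L, 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  starts <- seq(1L, n - seg + 1L, by = step)
  acc <- numeric(seg)
  for (s in starts) {
    x <- v[s:(s + seg - 1L)] * win
    acc <- acc + Mod(stats::fft(x))^2
  }
  psd <- acc / (length(starts) * sum(win^2))
  stats::setNames(psd[coeffs + 1L],
                  paste0("spkt_welch_density__coeff_", coeffs))
}

lempelZiv <- function(v, bins) {
  brk <- stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                         names = FALSE)
  brk[1] <- -Inf
  brk[length(brk)] <- Inf
  brk <- unique(brk)
  s <- as.integer(cut(v, brk))
  n <- length(s)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  words <- 0L
  i <- 1L
  len <- 1L
  while (i + len - 1L <= n) {
    w <- paste(s[i:(i + len - 1L)], collapse = ",")
    if (is.null(seen[[w]])) {
      seen[[w]] <- TRUE
      words <- words + 1L
      i <- i + len
      len <- 1L
    } else {
      len <- len + 1L
    }
  }
  words / n
}

numberPeaks <- function(v, support) {
  n <- length(v)
  if (n < 2 * support + 1) return(0L)
  e <- stats::embed(v, 2L * support + 1L)
  mid <- support + 1L
  others <- e[, -mid, drop = FALSE]
  mx <- do.call(pmax, as.data.frame(others))
  sum(e[, mid] > mx)
}

rickerWavelet <- function(points, a) {
  t <- seq_len(points) - (points + 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

changeQuantiles <- function(v, ql, qh, isabs, agg) {
  qs <- stats::quantile(v, c(ql, qh), names = FALSE)
  inside <- v >= qs[1] & v <= qs[2]
  sel <- inside[-1] & inside[-length(inside)]
  d <- diff(v)[sel]
  if (isabs) d <- abs(d)
  if (!length(d)) return(0)
  if (agg == "mean") mean(d) else stats::var(d)
}

linearTrend <- function(v) {
  n <- length(v)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), v)
  slope <- fit$coefficients[2]
  r <- suppressWarnings(stats::cor(t, v))
  c(linear_trend__attr_slope = unname(slope),
    linear_trend__attr_intercept = unname(fit$coefficients[1]),
    linear_trend__attr_rvalue = if (is.finite(r)) r else 0)
}

# Full feature vector for one univariate series.
tsFeatureVector <- function(v) {
  n <- length(v)
  m <- mean(v)
  s <- stats::sd(v)
  d <- diff(v)
  out <- c(
    mean = m, median = stats::median(v), standard_deviation = s,
    variance = s^2, maximum = max(v), minimum = min(v),
    sum_values = sum(v), abs_energy = sum(v^2),
    root_mean_square = sqrt(mean(v^2)),
    mean_abs_change = mean(abs(d)), mean_change = mean(d),
    absolute_sum_of_changes = sum(abs(d)),
    mean_second_derivative_central = mean(diff(d)) / 2,
    skewness = if (s > 0) mean((v - m)^3) / s^3 else NA_real_,
    kurtosis = if (s > 0) mean((v - m)^4) / s^4 - 3 else NA_real_,
    count_above_mean = sum(v > m), count_below_mean = sum(v < m),
    longest_strike_above_mean = longestRun(v > m),
    longest_strike_below_mean = longestRun(v < m),
    first_location_of_maximum = (which.max(v) - 1) / n,
    last_location_of_maximum = 1 - (which.max(rev(v)) - 1) / n,
    first_location_of_minimum = (which.min(v) - 1) / n,
    ratio_value_number_to_time_series_length = length(unique(v)) / n,
    variance_larger_than_standard_deviation = as.numeric(s^2 > s))
  qs <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  out <- c(out, stats::setNames(stats::quantile(v, qs, names = FALSE),
                                paste0("quantile__q_", qs)))
  ac <- as.numeric(stats::acf(v, lag.max = 40, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  out <- c(out, stats::setNames(ac[1:9], paste0("autocorrelation__lag_", 1:9)),
           agg_autocorrelation__f_agg_mean = mean(ac),
           agg_autocorrelation__f_agg_median = stats::median(ac),
           agg_autocorrelation__f_agg_var = stats::var(ac))
  rs <- c(0.5, 1, 1.5, 2, 2.5, 3, 5, 6, 7, 10)
  out <- c(out, stats::setNames(
    vapply(rs, function(r) if (s > 0) mean(abs(v - m) > r * s) else 0, 1),
    paste0("ratio_beyond_r_sigma__r_", rs)))
  f <- stats::fft(v)
  out <- c(out,
           stats::setNames(Mod(f[1:11]),
                           paste0("fft_coefficient__attr_abs__coeff_", 0:10)),
           stats::setNames(Arg(f[2:12]),
                           paste0("fft_coefficient__attr_angle__coeff_", 1:11)))
  chunks <- split(v, cut(seq_len(n), 10, labels = FALSE))
  er <- vapply(chunks, function(ch) sum(ch^2), 1)
  er <- if (sum(er) > 0) er / sum(er) else rep(0, length(er))
  out <- c(out, stats::setNames(er, paste0(
    "energy_ratio_by_chunks__num_segments_10__segment_focus_",
    seq_along(er) - 1)))
  cm <- cumsum(abs(v))
  imq <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), function(q) {
    if (cm[n] == 0) return(1)
    (which(cm >= q * cm[n])[1]) / n
  }, 1)
  out <- c(out, stats::setNames(
    imq, paste0("index_mass_quantile__q_", c(0.1, 0.25, 0.5, 0.75, 0.9))))
  out <- c(out, stats::setNames(
    vapply(c(2L, 5L, 10L), function(b) lempelZiv(v, b), 1),
    paste0("lempel_ziv_complexity__bins_", c(2, 5, 10))))
  rng <- list(c(-1, 1), c(0, 1), c(-2, 2))
  out <- c(out, stats::setNames(
    vapply(rng, function(r) sum(v >= r[1] & v < r[2]), 1),
    vapply(rng, function(r)
      paste0("range_count__min_", r[1], "__max_", r[2]), "")))
  out <- c(out, welchDensity(v))
  cqSpec <- list(c(0, 0.2, 1, NA), c(0.2, 0.8, 1, NA), c(0.8, 1, 1, NA),
                 c(0, 0.2, 0, NA), c(0.2, 0.8, 0, NA))
  for (agg in c("mean", "var")) {
    for (sp in cqSpec) {
      out[paste0("change_quantiles__ql_", sp[1], "__qh_", sp[2],
                 "__isabs_", sp[3] == 1, "__f_agg_", agg)] <-
        changeQuantiles(v, sp[1], sp[2], sp[3] == 1, agg)
    }
  }
  np <- c(1L, 3L, 5L, 10L, 50L)
  out <- c(out, stats::setNames(
    vapply(np, function(k) as.numeric(numberPeaks(v, k)), 1),
    paste0("number_peaks__n_", np)))
  out <- c(out,
           count_above__t_0 = mean(v > 0),
           count_below__t_0 = mean(v <= 0))
  ms <- c(-1, 0, 1)
  out <- c(out, stats::setNames(
    vapply(ms, function(mm) sum(diff(v > mm) != 0), 1),
    paste0("number_crossing_m__m_", ms)))
  for (w in c(2L, 10L)) {
    psi <- rickerWavelet(min(10L * w, n), w)
    cw <- stats::convolve(v, rev(psi), type = "filter")
    pick <- pmin(c(1L, 6L, 11L), length(cw))
    out <- c(out, stats::setNames(
      cw[pick], paste0("cwt_coefficients__coeff_", c(0, 5, 10), "__w_", w)))
  }
  for (lag in c(1L, 2L, 3L)) {
    out[paste0("c3__lag_", lag)] <-
      mean(v[seq_len(n - 2 * lag)] * v[seq_len(n - 2 * lag) + lag] *
             v[seq_len(n - 2 * lag) + 2 * lag])
    out[paste0("time_reversal_asymmetry_statistic__lag_", lag)] <-
      mean(v[seq_len(n - 2 * lag) + 2 * lag]^2 *
             v[seq_len(n - 2 * lag) + lag] -
             v[seq_len(n - 2 * lag) + lag] * v[seq_len(n - 2 * lag)]^2)
  }
  out <- c(out, linearTrend(v),
           cid_ce__normalize_false = sqrt(sum(d^2)),
           cid_ce__normalize_true =
             if (s > 0) sqrt(sum((d / s)^2)) else NA_real_)
  out
}

longestRun <- function(b) {
  r <- rle(b)
  hits <- r$lengths[r$values]
  if (length(hits)) max(hits) else 0L
}

#' Extract the time-series feature table
#'
#' Computes the package's efficient feature set (with the time-consuming
#' families excluded) on each record. Features are computed per lead and
#' suffixed \code{__lead_k} when more than one lead is requested; the
#' default uses the first lead only.
#'
#' @param records List of \linkS4class{EcgRecord}.
#' @param leads Integer vector of lead indices (default first lead).
#' @return Data frame, one row per record (rownames = record ids), all
#'   columns numeric (possibly NA; see [imputeAndFilter()]).
#' @export
extractFeatures <- function(records, leads = 1L) {
  if (!length(records)) stop("records must be non-empty")
  rows <- lapply(records, function(rec) {
    feats <- lapply(leads, function(l) {
      fv <- tsFeatureVector(rec@signal[l, ])
      if (length(leads) > 1) names(fv) <- paste0(names(fv), "__lead_", l)
      fv
    })
    unlist(feats)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- make.unique(vapply(records, recordId, character(1)))
  tab
}

#' Impute missing values and drop low-variance features
#'
#' Missing entries become exactly \code{fill} (default -999). Column
#' variances are computed on the training rows only and columns with
#' variance <= \code{varThreshold} are dropped; the retained-column list is
#' stored in the \code{"retainedColumns"} attribute and can be re-applied
#' to new tables via \code{columns}, so validation/test rows never
#' influence the filter.
#'
#' @param table Feature data frame from [extractFeatures()].
#' @param fill Imputation constant.
#' @param varThreshold Variance threshold (default 0: drop constants only).
#' @param trainRows Row indices/names defining the training set (default:
#'   all rows).
#' @param columns Previously persisted retained-column list; when given,
#'   the variance filter is not re-fitted.
#' @return Filtered, imputed data frame.
#' @export
imputeAndFilter <- function(table, fill = -999, varThreshold = 0,
                            trainRows = NULL, columns = NULL) {
  tab <- as.data.frame(table)
  tab[] <- lapply(tab, function(col) {
    col[!is.finite(col)] <- fill
    col
  })
  if (is.null(columns)) {
    tr <- if (is.null(trainRows)) seq_len(nrow(tab)) else trainRows
    vars <- vapply(tab[tr, , drop = FALSE], stats::var, 1)
    columns <- names(tab)[is.finite(vars) & vars > varThreshold]
    if (!length(columns))
      stop("variance threshold removed every feature; lower varThreshold")
  }
  out <- tab[, columns, drop = FALSE]
  attr(out, "retainedColumns") <- columns
  out
}

#' The XGBoost hyperparameter search space
#'
#' min_features_to_select: uniform on [10, nFeatures]; max_depth: uniform
#' on [2, 100]; gamma, eta, scale_pos_weight, reg_lambda, reg_alpha:
#' log-uniform on [1e-3, 1e3].
#'
#' @param nFeatures Number of candidate features (upper bound for feature
#'   elimination).
#' @return List of parameter descriptors consumed by [tuneAndFit()].
#' @export
searchSpace <- function(nFeatures) {
  list(
    list(name = "min_features_to_select", low = 10, high = nFeatures,
         log = FALSE, integer = TRUE),
    list(name = "max_depth", low = 2, high = 100, log = FALSE,
         integer = TRUE),
    list(name = "gamma", low = 1e-3, high = 1e3, log = TRUE,
         integer = FALSE),
    list(name = "eta", low = 1e-3, high = 1e3, log = TRUE, integer = FALSE),
    list(name = "scale_pos_weight", low = 1e-3, high = 1e3, log = TRUE,
         integer = FALSE),
    list(name = "reg_lambda", low = 1e-3, high = 1e3, log = TRUE,
         integer = FALSE),
    list(name = "reg_alpha", low = 1e-3, high = 1e3, log = TRUE,
         integer = FALSE))
}

unitToParams <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    p <- space[[j]]
    val <- if (p$log) exp(log(p$low) + u[j] * (log(p$high) - log(p$low)))
    else p$low + u[j] * (p$high - p$low)
    if (p$integer) val <- as.integer(round(val))
    out[[p$name]] <- val
  }
  out
}

# Small Gaussian-process (RBF kernel) expected-improvement optimizer over
# the unit hypercube; the initial design comes from a Latin hypercube.
gpExpectedImprovement <- function(X, y, cand, lengthscale = 0.3,
                                  nugget = 1e-4) {
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-9)
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  K <- k(X, X) + diag(nugget, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  Ks <- k(cand, X)
  mu <- as.numeric(Ks %*% alpha)
  vhalf <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(vhalf^2), 1e-12)
  sdev <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best) / sdev
  ei <- sdev * (z * stats::pnorm(z) + stats::dnorm(z))
  ei
}

fitBooster <- function(x, y, params, nClasses, nrounds, seed) {
  p <- list(objective = if (nClasses > 2) "multi:softprob"
            else "binary:logistic",
            max_depth = params$max_depth, eta = min(params$eta, 1),
            gamma = params$gamma, lambda = params$reg_lambda,
            alpha = params$reg_alpha,
            scale_pos_weight = params$scale_pos_weight,
            nthread = 1, verbosity = 0, seed = seed)
  if (nClasses > 2) p$num_class <- nClasses
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

boosterScores <- function(bst, x, nClasses) {
  pr <- predict(bst, xgboost::xgb.DMatrix(as.matrix(x)))
  if (nClasses > 2) {
    if (is.null(dim(pr))) pr <- matrix(pr, ncol = nClasses, byrow = TRUE)
    pr
  } else {
    cbind(1 - pr, pr)
  }
}

rankFeatures <- function(bst, featureNames) {
  imp <- tryCatch(xgboost::xgb.importance(model = bst),
                  error = function(e) NULL)
  if (is.null(imp) || !nrow(imp)) return(featureNames)
  ranked <- imp$Feature[order(-imp$Frequency)]
  c(ranked, setdiff(featureNames, ranked))
}

#' Bayesian-optimized XGBoost over the feature table
#'
#' Each trial samples a configuration from the search space (Latin
#' hypercube warm-up, then Gaussian-process expected improvement), performs
#' importance-ranked feature elimination down to
#' \code{min_features_to_select}, fits the booster, and scores validation
#' macro-F1. The best configuration's model and feature list are returned.
#'
#' @param table Imputed/filtered feature table ([imputeAndFilter()]).
#' @param labels Character vector of record labels, aligned with rows.
#' @param space Search space (default [searchSpace()] over the table).
#' @param nTrials Evaluation budget (the study caps this at 100).
#' @param seed Seed for sampling, splitting and boosting.
#' @param valFraction Held-out fraction used as the tuning objective.
#' @param nrounds Boosting rounds per fit.
#' @return Object of class \code{tsboostFit}: booster, best params,
#'   selected features, class set, and the full trial log.
#' @export
tuneAndFit <- function(table, labels, space = NULL, nTrials = 100L,
                       seed = 1L, valFraction = 0.25, nrounds = 60L) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes in labels")
  if (is.null(space)) space <- searchSpace(ncol(table))
  nP <- length(space)
  y <- match(labels, classes) - 1L
  n <- nrow(table)
  va <- withSeed(as.integer(seed) + 17L, {
    unlist(lapply(classes, function(cl) {
      ix <- sample(which(labels == cl))
      ix[seq_len(max(1, round(valFraction * length(ix))))]
    }))
  })
  tr <- setdiff(seq_len(n), va)
  evalOne <- function(params) {
    full <- fitBooster(table[tr, , drop = FALSE], y[tr], params,
                       length(classes), nrounds, seed)
    ranked <- rankFeatures(full, colnames(table))
    keep <- ranked[seq_len(min(params$min_features_to_select,
                               length(ranked)))]
    bst <- fitBooster(table[tr, keep, drop = FALSE], y[tr], params,
                      length(classes), nrounds, seed)
    sc <- boosterScores(bst, table[va, keep, drop = FALSE], length(classes))
    pred <- classes[max.col(sc, ties.method = "first")]
    scheme <- new("LabelScheme", mode = "multiclass", classes = classes,
                  codeMap = stats::setNames(classes, classes))
    f1 <- unname(computeMetrics(labels[va], pred, scheme)@macro["f1"])
    list(f1 = f1, model = bst, features = keep)
  }
  nInit <- min(max(5L, nTrials %/% 4L), nTrials)
  trials <- list()
  best <- list(f1 = -Inf)
  withSeed(as.integer(seed), {
    U <- lhs::randomLHS(nInit, nP)
    for (t in seq_len(nTrials)) {
      u <- if (t <= nInit) U[t, ] else {
        cand <- matrix(stats::runif(256 * nP), 256, nP)
        X <- do.call(rbind, lapply(trials, `[[`, "u"))
        yv <- vapply(trials, `[[`, 1, "f1")
        ei <- gpExpectedImprovement(X, yv, cand)
        cand[which.max(ei), ]
      }
      params <- unitToParams(u, space)
      res <- evalOne(params)
      trials[[t]] <- list(u = u, params = params, f1 = res$f1)
      if (res$f1 > best$f1) {
        best <- list(f1 = res$f1, params = params, model = res$model,
                     features = res$features)
      }
    }
  })
  log_ <- do.call(rbind, lapply(seq_along(trials), function(i)
    data.frame(trial = i, as.data.frame(trials[[i]]$params),
               val_macro_f1 = trials[[i]]$f1)))
  structure(list(booster = best$model, params = best$params,
                 features = best$features, classes = classes,
                 val_macro_f1 = best$f1, trials = log_,
                 trainRows = tr, valRows = va),
            class = "tsboostFit")
}

#' @export
print.tsboostFit <- function(x, ...) {
  cat(sprintf("tsboostFit: %d classes, %d selected features, val macro-F1 %.3f (%d trials)\n",
              length(x$classes), length(x$features), x$val_macro_f1,
              nrow(x$trials)))
  invisible(x)
}

#' Predict with a tuned boosting model
#' @param fit A \code{tsboostFit}.
#' @param table Imputed feature table containing the fit's features.
#' @return List with \code{scores} (rows x classes) and \code{decisions}.
#' @export
predictTsBoost <- function(fit, table) {
  sc <- boosterScores(fit$booster, table[, fit$features, drop = FALSE],
                      length(fit$classes))
  colnames(sc) <- fit$classes
  list(scores = sc,
       decisions = fit$classes[max.col(sc, ties.method = "first")])
}

#' Grouped split-frequency feature importance
#'
#' Per-feature importance is the relative frequency with which the feature
#' is used to split, normalized to sum 1; grouped importance sums these
#' within the name prefix before the first double underscore.
#'
#' @param fit A \code{tsboostFit}.
#' @param groupByPrefix Aggregate into feature groups (default TRUE).
#' @return Data frame (group, n_features, importance), descending.
#' @export
featureImportance <- function(fit, groupByPrefix = TRUE) {
  if (!inherits(fit, "tsboostFit") || is.null(fit$booster))
    stop("featureImportance requires a fitted tsboostFit")
  imp <- xgboost::xgb.importance(model = fit$booster)
  w <- imp$Frequency / sum(imp$Frequency)
  if (!groupByPrefix) {
    return(data.frame(feature = imp$Feature, importance = w)[order(-w), ])
  }
  aggregateImportance(imp$Feature, w)
}

# Sum normalized per-feature weights within the name prefix before the
# first "__"; returns (group, n_features, importance) in descending order.
aggregateImportance <- function(features, weights) {
  grp <- sub("__.*$", "", features)
  agg <- stats::aggregate(weights, by = list(group = grp), FUN = sum)
  cnt <- stats::aggregate(weights, by = list(group = grp), FUN = length)
  out <- data.frame(group = agg$group, n_features = cnt$x,
                    importance = agg$x)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
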