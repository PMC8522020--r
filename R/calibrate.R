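# Per-participant calibration of PIR island features to accelerometer
# activity: Gaussian process regression with a constant + dot-product +
# white-noise kernel (primary), with OLS and gradient-boosted-tree
# baselines, hyperparameter search, and predictive uncertainty.

# ---- Gaussian process with kernel k(x, x') = s0 + x.x' + sn * delta ----
#
# The Gram matrix is K = s0 * 11' + X X' + sn * I = Z Z' + sn * I with
# Z = [X, sqrt(s0) 1], so the marginal likelihood and posterior are
# computed through the low-rank (Woodbury) identities in O(n p^2):
#   |K| = sn^(n-m) |B|,        B = sn I_m + Z'Z,  m = p + 1
#   K^-1 v = (v - Z B^-1 Z'v) / sn

gp_nll <- function(theta, X, y) {
  s0 <- exp(theta[1]); sn <- exp(theta[2])
  n <- nrow(X)
  Z <- cbind(X, sqrt(s0))
  m <- ncol(Z)
  B <- crossprod(Z)
  diag(B) <- diag(B) + sn
  ch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Zty <- crossprod(Z, y)
  w <- backsolve(ch, forwardsolve(t(ch), Zty))
  alpha <- (y - Z %*% w) / sn
  quad <- sum(y * alpha)
  logdet <- (n - m) * log(sn) + 2 * sum(log(diag(ch)))
  as.numeric(0.5 * (quad + logdet + n * log(2 * pi)))
}

# Targets are standardized internally (the GP prior has zero mean on the
# standardized activity scale, and the dot-product kernel carries no
# signal-variance hyperparameter); predictions are transformed back.
fit_gpr <- function(X, y, seed = 1L, restarts = 5L) {
  y_center <- mean(y)
  y_scale <- sd(y)
  y <- (y - y_center) / y_scale
  vy <- 1
  n <- nrow(X)
  inits <- with_substream(seed, "gpr_init", {
    cbind(log(vy) + rnorm(restarts, 0, 1.5),
          log(vy * 0.1) + rnorm(restarts, 0, 1.5))
  })
  inits[1, ] <- c(log(vy), log(vy * 0.1))  # deterministic first restart
  lower <- c(log(vy * 1e-9), log(vy * 1e-9))
  upper <- c(log(vy * 1e6), log(vy * 1e6))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      optim(pmin(pmax(inits[r, ], lower), upper), gp_nll, X = X, y = y,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("GP optimisation failed", call. = FALSE)
  fit <- gp_precompute(X, y, exp(best$par[1]), exp(best$par[2]))
  fit$y_center <- y_center
  fit$y_scale <- y_scale
  fit$log_marginal <- -best$value
  fit
}

# Posterior bookkeeping for fixed kernel constants (targets assumed
# already centred/scaled by the caller unless y_center/y_scale set).
gp_precompute <- function(X, y, s0, sn) {
  Z <- cbind(X, sqrt(s0))
  B <- crossprod(Z)
  diag(B) <- diag(B) + sn
  Binv <- chol2inv(chol(B))
  alpha <- (y - Z %*% (Binv %*% crossprod(Z, y))) / sn
  list(sigma0_sq = s0, sigman_sq = sn, X = X,
       G = crossprod(Z), Binv = Binv, alpha = as.numeric(alpha),
       sum_alpha = sum(alpha), Xt_alpha = as.numeric(crossprod(X, alpha)),
       y_center = 0, y_scale = 1)
}

predict_gpr <- function(fit, Xs) {
  mean <- fit$sigma0_sq * fit$sum_alpha +
    as.numeric(Xs %*% fit$Xt_alpha)
  Zt <- cbind(Xs, sqrt(fit$sigma0_sq))
  A <- Zt %*% fit$G
  term1 <- rowSums(A * Zt)
  term2 <- rowSums((A %*% fit$Binv) * A)
  kss <- fit$sigma0_sq + rowSums(Xs^2) + fit$sigman_sq
  var <- kss - (term1 - term2) / fit$sigman_sq
  data.frame(mean = fit$y_center + fit$y_scale * mean,
             sd = fit$y_scale * sqrt(pmax(var, 0)))
}

# ---- gradient-boosted trees -------------------------------------------

gbt_default_params <- function() {
  list(max_depth = 3L, eta = 0.1, nrounds = 200L, subsample = 0.9)
}

draw_gbt_params <- function(n_draws) {
  data.frame(max_depth = sample(2:6, n_draws, replace = TRUE),
             eta = exp(runif(n_draws, log(0.01), log(0.3))),
             nrounds = sample(50:500, n_draws, replace = TRUE),
             subsample = runif(n_draws, 0.5, 1.0))
}

fit_gbt <- function(X, y, params, seed = 1L) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = list(max_depth = as.integer(params$max_depth),
                                   eta = params$eta,
                                   subsample = params$subsample,
                                   objective = "reg:squarederror",
                                   nthread = 1,
                                   seed = as.integer(seed)),
                     data = dtrain, nrounds = as.integer(params$nrounds),
                     verbose = 0)
}

predict_gbt <- function(booster, X) {
  as.numeric(predict(booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

# Random-search 3-fold CV on one participant's calibration islands.
search_gbt_single <- function(X, y, n_draws, folds, seed) {
  with_substream(seed, "gbt_search", {
    cand <- draw_gbt_params(n_draws)
    fold <- sample(rep_len(seq_len(folds), nrow(X)))
    scores <- vapply(seq_len(n_draws), function(j) {
      errs <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
        m <- fit_gbt(X[tr, , drop = FALSE], y[tr], cand[j, ], seed)
        mean((predict_gbt(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    as.list(cand[which.min(scores), ])
  })
}

#' Cohort-level hyperparameter search
#'
#' Selects shared gradient-boosted-tree hyperparameters by random search
#' under 3-fold cross-validation split at the participant level: for each
#' fold split, one model is fitted on the pooled (per-participant
#' standardized) calibration islands of the training-fold participants
#' and scored by squared error on the held-out participants. Targets are
#' standardized per participant for scoring so apartments with large
#' activity scales do not dominate. The selected hyperparameters are then
#' used for the per-participant fits.
#'
#' @param islands_list List of `activity_islands`, one per participant
#'   (calibration windows only).
#' @param algorithm Only `"gbt"` has searchable hyperparameters; `"gpr"`
#'   optimizes its kernel constants by marginal likelihood per fit and
#'   `"lr"` is ordinary least squares, so both return `NULL`.
#' @param n_draws Number of random-search draws (default 25).
#' @param folds Number of participant-level folds (default 3).
#' @param seed Integer seed.
#' @return A named list of hyperparameters, or `NULL`.
#' @export
search_hyperparams <- function(islands_list, algorithm = "gbt",
                               n_draws = 25L, folds = 3L, seed = 1L) {
  if (algorithm != "gbt") return(NULL)
  prep <- lapply(islands_list, function(isl) {
    cal <- isl[!is.na(isl$target), , drop = FALSE]
    std <- suppressWarnings(fit_standardizer(cal))
    y <- cal$target
    list(X = apply_standardizer(std, cal), y = (y - mean(y)) / sd(y))
  })
  np <- length(prep)
  with_substream(seed, "gbt_cohort_search", {
    cand <- draw_gbt_params(n_draws)
    fold <- sample(rep_len(seq_len(min(folds, np)), np))
    scores <- vapply(seq_len(n_draws), function(j) {
      errs <- vapply(unique(fold), function(f) {
        tr <- which(fold != f)
        if (!length(tr)) return(NA_real_)
        Xtr <- do.call(rbind, lapply(prep[tr], `[[`, "X"))
        ytr <- unlist(lapply(prep[tr], `[[`, "y"))
        m <- fit_gbt(Xtr, ytr, cand[j, ], seed)
        te <- which(fold == f)
        mean(unlist(lapply(prep[te], function(p)
          (predict_gbt(m, p$X) - p$y)^2)))
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    as.list(cand[which.min(scores), ])
  })
}

#' Fit a calibration model
#'
#' Learns the mapping from standardized island features to accelerometer
#' activity on one participant's calibration islands. `"gpr"` (the
#' primary method) maximizes the marginal likelihood of the constant +
#' dot-product + white-noise kernel over (sigma0^2, sigman^2) from
#' multiple seeded restarts and provides a predictive standard deviation;
#' `"lr"` is ordinary least squares; `"gbt"` fits gradient-boosted trees
#' with hyperparameters from `params` or, failing that, from a random
#' search under 3-fold cross-validation on the calibration islands.
#' Islands without targets (insufficient wear coverage) are excluded.
#'
#' @param islands An `activity_islands` data.frame (calibration window).
#' @param algorithm `"gpr"`, `"lr"` or `"gbt"`.
#' @param seed Integer seed; fits are deterministic given it.
#' @param params Optional pre-selected hyperparameters (see
#'   [search_hyperparams()]).
#' @param n_draws,folds Random-search budget when `params` is `NULL`.
#' @param restarts Number of marginal-likelihood restarts for GPR.
#' @param feature_columns Feature columns to use; defaults to the island
#'   feature set for the islands' rooms.
#' @return A `calibration_model`.
#' @export
fit_calibration <- function(islands, algorithm = c("gpr", "lr", "gbt"),
                            seed = 1L, params = NULL, n_draws = 25L,
                            folds = 3L, restarts = 5L,
                            feature_columns = NULL) {
  algorithm <- match.arg(algorithm)
  cal <- islands[!is.na(islands$target), , drop = FALSE]
  if (nrow(cal) < 10L) {
    stop("insufficient calibration data: need >= 10 islands with targets, have ",
         nrow(cal), call. = FALSE)
  }
  y <- cal$target
  if (var(y) == 0) stop("degenerate targets: all islands have identical accelerometer activity",
                        call. = FALSE)
  std <- suppressWarnings(fit_standardizer(cal, columns = feature_columns))
  X <- apply_standardizer(std, cal)

  fit <- switch(algorithm,
    gpr = fit_gpr(X, y, seed = seed, restarts = restarts),
    lr = {
      f <- stats::lm.fit(cbind(1, X), y)
      list(coef = coef(f))
    },
    gbt = {
      if (is.null(params)) {
        params <- search_gbt_single(X, y, n_draws, folds, seed)
      }
      list(booster = fit_gbt(X, y, params, seed), params = params)
    })

  structure(list(algorithm = algorithm, standardizer = std, fit = fit,
                 participant_id = attr(islands, "participant_id"),
                 calibration_days = length(unique(cal$day)),
                 n_islands = nrow(cal),
                 kernel = if (algorithm == "gpr")
                   list(sigma0_sq = fit$sigma0_sq,
                        sigman_sq = fit$sigman_sq) else NULL),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s, %d islands over %d days\n",
              x$algorithm, x$n_islands, x$calibration_days))
  if (x$algorithm == "gpr") {
    cat(sprintf("  kernel: sigma0^2 = %.4g, sigman^2 = %.4g\n",
                x$kernel$sigma0_sq, x$kernel$sigman_sq))
  }
  invisible(x)
}

#' Predict calibrated activity for islands
#'
#' Applies the model's own standardizer and returns one prediction per
#' island. For GPR the predictive standard deviation of the marginal
#' Gaussian (including the white-noise term) is returned and grows for
#' inputs far from the calibration support.
#'
#' @param model A `calibration_model`.
#' @param islands An `activity_islands` data.frame.
#' @param clip If `TRUE` (default), clip predicted means at zero (targets
#'   are non-negative sums); raw means are kept in column `raw_mean`.
#' @return data.frame with `mean`, `raw_mean`, and for GPR `sd`.
#' @export
predict_calibration <- function(model, islands, clip = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  missing_cols <- setdiff(model$standardizer$columns,
                          names(as.data.frame(islands)))
  if (length(missing_cols)) {
    stop("feature dimension mismatch; islands lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- apply_standardizer(model$standardizer, islands)
  out <- switch(model$algorithm,
    gpr = predict_gpr(model$fit, X),
    lr = data.frame(mean = as.numeric(cbind(1, X) %*% model$fit$coef)),
    gbt = data.frame(mean = predict_gbt(model$fit$booster, X)))
  out$raw_mean <- out$mean
  if (clip) out$mean <- pmax(0, out$mean)
  out
}

#' Wear-time learning curve
#'
#' For each number of calibration days in `days_grid`, fits a calibration
#' model per participant on the islands of the first `d` days of wearable
#' data and evaluates on all islands beyond day 30, reporting the global
#' (participant-averaged) island-restricted daily correlation and mean
#' absolute error per algorithm.
#'
#' @param islands_list List of `activity_islands`, one per participant,
#'   covering the full observation span (>= 60 days of wearable data).
#' @param days_grid Calibration durations in days; entries must be <= 30.
#' @param algorithms Character vector from `"gpr"`, `"lr"`, `"gbt"`.
#' @param seed Integer seed.
#' @param eval_after Evaluation uses islands from day `eval_after`
#'   onwards (default 30, counted from each participant's first wear
#'   day).
#' @return data.frame with columns `days`, `algorithm`, `mae`,
#'   `rho_tilde`.
#' @export
weartime_curve <- function(islands_list, days_grid = c(1, 7, 14, 21, 30),
                           algorithms = "gpr", seed = 1L,
                           eval_after = 30) {
  if (any(days_grid > 30)) {
    stop("days_grid entries must be <= 30 (calibration window)",
         call. = FALSE)
  }
  grid <- expand.grid(days = days_grid, algorithm = algorithms,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    d <- grid$days[g]; alg <- grid$algorithm[g]
    per <- lapply(islands_list, function(isl) {
      d0 <- min(isl$day[!is.na(isl$target)])
      cal <- isl[isl$day < d0 + d, , drop = FALSE]
      ev <- isl[isl$day >= d0 + eval_after, , drop = FALSE]
      model <- tryCatch(fit_calibration(cal, algorithm = alg,
                                        seed = seed),
                        error = function(e) NULL)
      if (is.null(model)) {
        # a short calibration window can fall below the minimum island
        # count for some participants; those cells are excluded from
        # the global average
        warning(sprintf("calibration with %d day(s) skipped for one participant (too few islands)",
                        d), call. = FALSE)
        return(c(mae = NA_real_, rho_tilde = NA_real_))
      }
      pred <- predict_calibration(model, ev)
      met <- island_metrics(pred, ev)
      c(mae = met$mae, rho_tilde = met$rho_tilde)
    })
    per <- do.call(rbind, per)
    data.frame(days = d, algorithm = alg,
               mae = mean(per[, "mae"], na.rm = TRUE),
               rho_tilde = mean(per[, "rho_tilde"], na.rm = TRUE))
  })
  do.call(rbind, res)
}

# Island-level MAE and the island-restricted daily correlation for one
# participant's evaluation islands.
island_metrics <- function(pred, islands, min_islands_per_day = 2L) {
  ok <- !is.na(islands$target)
  err <- abs(pred$mean[ok] - islands$target[ok])
  mae <- if (any(ok)) mean(err) else NA_real_
  df <- data.frame(day = islands$day[ok], pred = pred$mean[ok],
                   target = islands$target[ok])
  agg <- stats::aggregate(cbind(pred, target) ~ day, df, sum)
  counts <- table(df$day)
  agg <- agg[counts[as.character(agg$day)] >= min_islands_per_day, ,
             drop = FALSE]
  rho <- if (nrow(agg) >= 3 && sd(agg$pred) > 0 && sd(agg$target) > 0)
    cor(agg$pred, agg$target) else NA_real_
  list(mae = mae, rho_tilde = rho)
}
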