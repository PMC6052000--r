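#' Quartile outlier rule
#'
#' Flags values at least \code{k} interquartile ranges above the third or
#' below the first quartile (default k = 2.2). Columns with zero IQR
#' (constant bulk) produce no outliers: the rule is vacuous there.
#'
#' @param x numeric vector (n >= 4; NAs are never flagged).
#' @param k IQR multiplier.
#' @return logical mask, TRUE for outliers.
#' @export
detect_outliers <- function(x, k = 2.2) {
  if (sum(is.finite(x)) < 4) stop("need at least 4 finite values")
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  out <- x > q[2] + k * iqr | x < q[1] - k * iqr
  out[is.na(out)] <- FALSE
  out
}

#' Bivariate Pearson screen of regression candidates
#'
#' Pearson correlation and two-sided p-value of each candidate predictor
#' against the outcome. Factors are expanded to binary treatment
#' indicators. Zero-variance columns are excluded with a warning.
#'
#' @param table data.frame of predictors and outcome.
#' @param outcome name of the outcome column.
#' @param candidates candidate column names (default: all except the
#'   outcome).
#' @return data.frame: \code{variable}, \code{r}, \code{p}, ordered by
#'   decreasing |r|.
#' @export
pearson_screen <- function(table, outcome, candidates = NULL) {
  if (!outcome %in% names(table)) stop("no column '", outcome, "'")
  y <- table[[outcome]]
  if (is.null(candidates)) candidates <- setdiff(names(table), outcome)
  cols <- list()
  for (v in candidates) {
    x <- table[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      for (lev in levels(x)[-1])
        cols[[paste0(v, lev)]] <- as.numeric(x == lev)
    } else cols[[v]] <- x
  }
  rows <- lapply(names(cols), function(v) {
    x <- cols[[v]]
    if (stats::var(x, na.rm = TRUE) < .Machine$double.eps) {
      warning("zero-variance candidate '", v, "' excluded")
      return(NULL)
    }
    ct <- stats::cor.test(x, y)
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Durbin-Watson statistic of ordered residuals
#'
#' \code{DW = sum (e_i - e_(i-1))^2 / sum e_i^2}, in [0, 4]; 2 indicates
#' independent residuals. Following the interpretation guideline used with
#' this workflow, values below 1.08 flag problematic positive correlation.
#'
#' @param residuals residuals in their natural (specimen) order.
#' @param flag_below flag threshold.
#' @return DW statistic with attribute \code{"flagged"}.
#' @export
durbin_watson <- function(residuals, flag_below = 1.08) {
  e <- residuals
  if (length(e) < 3) stop("need at least 3 residuals")
  den <- sum(e^2)
  if (den <= 0) stop("degenerate residuals: zero sum of squares")
  dw <- sum(diff(e)^2) / den
  attr(dw, "flagged") <- dw < flag_below
  dw
}

# tolerance (1 - R_k^2) of each model-matrix column regressed on the others
.tolerances <- function(mm) {
  p <- ncol(mm)
  vapply(seq_len(p), function(k) {
    y <- mm[, k]
    X <- cbind(1, mm[, -k, drop = FALSE])
    r <- stats::lm.fit(X, y)$residuals
    vy <- sum((y - mean(y))^2)
    if (vy <= 0) return(0)
    sum(r^2) / vy
  }, numeric(1))
}

#' Backward stepwise linear regression with tolerance gate
#'
#' The multiple-regression workflow for the multiscale variable table:
#' candidates failing the collinearity tolerance gate (\code{1 - R_k^2 <
#' tolerance_min} when regressed on the other candidates) are excluded up
#' front; the model then starts from all remaining candidates and
#' iteratively removes the predictor with the largest partial-F p-value
#' exceeding \code{p_remove}. After each removal, excluded candidates may
#' re-enter if their add-one partial-F p-value falls below \code{p_enter}
#' (switchable). Factors are treated as units (multi-df F tests). Numeric
#' predictors are standardized internally, making the selection invariant
#' to affine rescaling; reported coefficients are on the original scale.
#' The Durbin-Watson statistic of the final residuals (row order) is
#' reported.
#'
#' @param table data.frame with predictors and outcome.
#' @param outcome outcome column name.
#' @param candidates candidate predictor names (default all others).
#' @param p_enter probability of F to enter (re-entry), default 0.05.
#' @param p_remove probability of F to remove, default 0.10.
#' @param tolerance_min minimum tolerance \code{1 - R_k^2}, default 0.01.
#' @param allow_reentry allow removed/gated-in candidates to re-enter.
#' @return object of class \code{"stepwise_fit"}: \code{retained},
#'   \code{model} (the final \code{lm}), \code{coefficients} (matrix with
#'   SEs), \code{r_squared}, \code{overall_p}, \code{dw}, \code{trace}
#'   (data.frame of actions), \code{gated_out}, \code{call_args}.
#' @export
backward_stepwise <- function(table, outcome, candidates = NULL,
                              p_enter = 0.05, p_remove = 0.10,
                              tolerance_min = 0.01, allow_reentry = TRUE) {
  if (!outcome %in% names(table)) stop("no column '", outcome, "'")
  if (is.null(candidates)) candidates <- setdiff(names(table), outcome)
  dat <- table[c(outcome, candidates)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 2)
    stop("need n > number of candidates + 2")
  # standardize numeric predictors (affine invariance of the selection)
  scales <- list()
  for (v in candidates) {
    if (is.numeric(dat[[v]])) {
      s <- stats::sd(dat[[v]])
      if (s <= 0) stop("zero-variance candidate '", v, "'")
      scales[[v]] <- c(center = mean(dat[[v]]), scale = s)
      dat[[v]] <- (dat[[v]] - mean(dat[[v]])) / s
    } else dat[[v]] <- factor(dat[[v]])
  }
  # tolerance gate on model-matrix columns; a variable is gated out when
  # any of its columns is near-perfectly explained by the other candidates
  mm_all <- stats::model.matrix(
    stats::reformulate(candidates), data = dat)[, -1, drop = FALSE]
  asg <- attr(stats::model.matrix(stats::reformulate(candidates),
                                  data = dat), "assign")[-1]
  tol <- .tolerances(mm_all)
  gated <- unique(candidates[asg[tol < tolerance_min]])
  if (length(gated) >= length(candidates))
    stop("singular design: all candidates gated out; offending columns: ",
         paste(candidates, collapse = ", "))
  active <- setdiff(candidates, gated)
  pool <- if (allow_reentry) gated else character(0)
  trace <- list()
  note <- function(action, var, p) trace[[length(trace) + 1L]] <<-
    data.frame(step = length(trace) + 1L, action = action, variable = var,
               p = p)
  for (g in gated) note("gated_out", g, NA_real_)

  fit_formula <- function(vars) {
    f <- if (length(vars)) stats::reformulate(vars, response = outcome)
    else stats::as.formula(paste(outcome, "~ 1"))
    stats::lm(f, data = dat)
  }
  fit <- fit_formula(active)
  repeat {
    changed <- FALSE
    if (length(active)) {
      dr <- stats::drop1(fit, test = "F")
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- rownames(dr)[-1]
      worst <- names(pv)[which.max(pv)]
      if (length(worst) && max(pv, na.rm = TRUE) > p_remove) {
        active <- setdiff(active, worst)
        pool <- union(pool, if (allow_reentry) worst else character(0))
        note("removed", worst, max(pv, na.rm = TRUE))
        fit <- fit_formula(active)
        changed <- TRUE
      }
    }
    if (!changed && allow_reentry && length(pool)) {
      scope <- stats::reformulate(union(active, pool))
      ad <- stats::add1(fit, scope = scope, test = "F")
      pv <- ad[["Pr(>F)"]][-1]
      names(pv) <- rownames(ad)[-1]
      pv <- pv[names(pv) %in% pool]
      if (length(pv) && min(pv, na.rm = TRUE) < p_enter) {
        best <- names(pv)[which.min(pv)]
        # re-check tolerance against the current active set
        cand2 <- c(active, best)
        mm2 <- stats::model.matrix(stats::reformulate(cand2),
                                   data = dat)[, -1, drop = FALSE]
        if (all(.tolerances(mm2) >= tolerance_min)) {
          active <- cand2
          pool <- setdiff(pool, best)
          note("entered", best, min(pv, na.rm = TRUE))
          fit <- fit_formula(active)
          changed <- TRUE
        } else pool <- setdiff(pool, best)
      }
    }
    if (!changed) break
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- if (!is.null(fstat))
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  else NA_real_
  # back-transform numeric coefficients to the original scale
  co <- sm$coefficients
  for (v in intersect(rownames(co), names(scales)))
    co[v, 1:2] <- co[v, 1:2] / scales[[v]]["scale"]
  dw <- durbin_watson(stats::residuals(fit))
  structure(list(retained = active, model = fit, coefficients = co,
                 scales = scales,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 overall_p = unname(overall_p), dw = dw,
                 dw_flagged = attr(dw, "flagged"),
                 trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(step = integer(0), action = character(0),
                                 variable = character(0), p = numeric(0)),
                 gated_out = gated,
                 call_args = list(outcome = outcome,
                                  candidates = candidates,
                                  p_enter = p_enter, p_remove = p_remove,
                                  tolerance_min = tolerance_min,
                                  allow_reentry = allow_reentry)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backward stepwise regression for", x$call_args$outcome, "\n")
  cat(sprintf("retained: %s\n",
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("R^2 = %.3f (adj %.3f), overall p = %.3g, DW = %.3f%s\n",
              x$r_squared, x$adj_r_squared, x$overall_p, x$dw,
              if (x$dw_flagged) " [flagged < 1.08]" else ""))
  if (length(x$gated_out))
    cat("gated out by tolerance:", paste(x$gated_out, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stepwise_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients (original scale):\n")
  stats::printCoefmat(object$coefficients)
  cat("\nSelection trace:\n")
  print(object$trace, row.names = FALSE)
  invisible(object)
}

#' @export
coef.stepwise_fit <- function(object, ...) object$coefficients[, 1]

#' @export
residuals.stepwise_fit <- function(object, ...)
  stats::residuals(object$model)

#' @export
predict.stepwise_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  nd <- as.data.frame(newdata)
  for (v in names(object$scales))
    if (v %in% names(nd))
      nd[[v]] <- (nd[[v]] - object$scales[[v]]["center"]) /
        object$scales[[v]]["scale"]
  stats::predict(object$model, newdata = nd, ...)
}
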