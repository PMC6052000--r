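#' Schema of the multiscale regression table
#'
#' Numeric per-specimen predictors: equilibrium stress \code{s_eq} and its
#' change between 1 and 10 percent strain \code{d_seq} (MPa), dynamic modulus
#' \code{Estar} (MPa), loss tangent \code{tan_delta}, collagen
#' disorganization \code{CSD} and its strain change \code{dCSD} (deg),
#' \code{cellularity} (cells/mm^2), F-actin positive fraction \code{factin}
#' (%), fiber mean slack length \code{SL_mn} (mm), nuclear disorganization
#' \code{nCSD} and its change \code{dnCSD} (deg). Categorical:
#' \code{healing} (uninjured / wk2 / wk6) and \code{loading}
#' (quasi / low / high). Outcomes: \code{nAR}, \code{dnAR}.
#'
#' @return character vector of the numeric predictor names.
#' @export
regression_schema <- function() {
  c("s_eq", "d_seq", "Estar", "tan_delta", "CSD", "dCSD",
    "cellularity", "factin", "SL_mn", "nCSD", "dnCSD")
}

# plausible specimen-level means and SDs for each numeric predictor
.schema_scale <- function() {
  data.frame(
    var = regression_schema(),
    mean = c(2, 3, 200, 0.10, 10, -2, 1000, 20, 5.05, 15, -3),
    sd   = c(0.8, 1, 50, 0.03, 3, 1, 300, 5, 0.03, 5, 2),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic multiscale regression table
#'
#' Numeric predictors are drawn multivariate normal with a given correlation
#' structure (on the standardized scale) and then shifted to plausible
#' specimen-level units; categorical healing and loading-group columns are
#' assigned in rotation. The outcome is a linear model on the model-matrix
#' columns named in \code{coefficients} plus residual noise, optionally
#' AR(1)-correlated in row order.
#'
#' @param n number of specimens (rows).
#' @param coefficients named numeric vector; names must be numeric predictor
#'   names (from [regression_schema()]) or dummy-coded categorical columns
#'   (\code{healingwk2}, \code{healingwk6}, \code{loadinglow},
#'   \code{loadinghigh}). Coefficients are on the standardized predictor
#'   scale for numeric variables. Default: nAR generated from cellularity,
#'   nCSD and healing.
#' @param collinearity_matrix correlation matrix over the 11 numeric
#'   predictors (default identity). Must be positive definite.
#' @param resid_sd residual SD of the outcome.
#' @param ar1_rho lag-1 autocorrelation of the residuals (0 = independent).
#' @param intercept outcome intercept (baseline nAR).
#' @param outcome_name name of the generated outcome column.
#' @param seed integer RNG seed.
#' @return data.frame of class \code{c("regression_table", "data.frame")}
#'   with attribute \code{"truth"} (list: coefficients, resid_sd, ar1_rho,
#'   intercept).
#' @export
gen_regression_table <- function(n,
                                 coefficients = c(cellularity = 0.6,
                                                  nCSD = -0.5,
                                                  healingwk2 = 1.0,
                                                  healingwk6 = 0.5),
                                 collinearity_matrix = NULL,
                                 resid_sd = 0.3, ar1_rho = 0,
                                 intercept = 2.5,
                                 outcome_name = "nAR", seed = 1L) {
  sc <- .schema_scale()
  p <- nrow(sc)
  if (is.null(collinearity_matrix)) collinearity_matrix <- diag(p)
  if (!isTRUE(all.equal(dim(collinearity_matrix), c(p, p))))
    stop("collinearity_matrix must be ", p, " x ", p)
  R <- chol(collinearity_matrix)  # errors if not positive definite
  withr_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p) %*% R
    colnames(Z) <- sc$var
    X <- sweep(sweep(Z, 2, sc$sd, "*"), 2, sc$mean, "+")
    tab <- as.data.frame(X)
    # crossed assignment (healing cycles within loading) so the two
    # factors are not confounded
    tab$healing <- factor(c("uninjured", "wk2", "wk6")[(seq_len(n) - 1) %%
                                                         3 + 1],
                          levels = c("uninjured", "wk2", "wk6"))
    tab$loading <- factor(c("quasi", "low", "high")[((seq_len(n) - 1) %/%
                                                       3) %% 3 + 1],
                          levels = c("quasi", "low", "high"))
    mm <- stats::model.matrix(~ . - 1, data = cbind(as.data.frame(Z),
                                                    tab[c("healing", "loading")]))
    # dummy columns carry factor-level names: healingwk2, loadinghigh, ...
    bad <- setdiff(names(coefficients), colnames(mm))
    if (length(bad))
      stop("unknown coefficient target(s): ", paste(bad, collapse = ", "))
    eta <- as.numeric(mm[, names(coefficients), drop = FALSE] %*%
                        coefficients)
    eps <- stats::rnorm(n, 0, resid_sd)
    if (ar1_rho != 0) {
      e <- numeric(n)
      e[1] <- eps[1]
      for (i in 2:n) e[i] <- ar1_rho * e[i - 1] +
          sqrt(1 - ar1_rho^2) * eps[i]
      eps <- e
    }
    tab[[outcome_name]] <- intercept + eta + eps
    attr(tab, "truth") <- list(coefficients = coefficients,
                               resid_sd = resid_sd, ar1_rho = ar1_rho,
                               intercept = intercept,
                               outcome = outcome_name)
    class(tab) <- c("regression_table", "data.frame")
    tab
  })
}
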