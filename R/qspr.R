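#' Fit a single-descriptor QSPR regression
#'
#' Fits one of the three regression families relating a physicochemical
#' property \eqn{P} to a topological index \eqn{TI} by ordinary least
#' squares:
#' \deqn{P = A + b\,TI \quad\textrm{(linear)}}
#' \deqn{P = A + b\,TI + c\,TI^2 \quad\textrm{(quadratic)}}
#' \deqn{P = A + b\,\ln TI \quad\textrm{(logarithmic)}}
#'
#' The returned object carries the statistics conventionally reported for
#' such models: sample size \eqn{N}, intercept \eqn{A}, coefficients
#' \eqn{b} (and \eqn{c}), correlation \eqn{r} (signed by \eqn{b} for the
#' single-predictor families, the multiple correlation for the quadratic),
#' \eqn{r^2}, the overall \eqn{F} statistic on \eqn{(k, n - k - 1)} degrees
#' of freedom, and its p-value.
#'
#' Before fitting, the design is screened: non-finite design entries, a
#' constant predictor, or a standardized-design condition number above
#' \code{1e8} raise a \code{"qspr_degenerate_error"} carrying the diagnostic
#' (never a silent all-zero fit).  In practice this rejects exactly the
#' quadratic fits on raw exponential-index values, whose \eqn{[TI, TI^2]}
#' columns are numerically collinear at double precision.
#'
#' @param formula a two-sided formula with one response and one predictor,
#'   e.g. \code{MW ~ SDD}.  The predictor enters untransformed; the
#'   \code{family} argument controls the model equation (for
#'   \code{"logarithmic"} the fit is on \eqn{\ln TI}).
#' @param data a data frame containing the two variables (e.g. the merged
#'   output of [qspr_data()]).
#' @param family \code{"linear"}, \code{"quadratic"} or
#'   \code{"logarithmic"}.
#' @return An object of class \code{"qspr"} with \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{residuals}, \code{fitted},
#'   \code{plot} and \code{simulate} methods.
#' @examples
#' d <- qspr_data("published")
#' fit <- qspr(MW ~ SDD, d, family = "linear")
#' coef(fit)                      # A = 25.43, b = 4.962
#' predict(fit, x = 48.3333)      # about 265 g/mol
#' @seealso [qspr_table()] for the full 6 x 6 x 3 model sweep.
#' @export
qspr <- function(formula, data, family = c("linear", "quadratic",
                                           "logarithmic")) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("'formula' must have exactly one response and one predictor")
  qspr_fit(x = mf[[2L]], y = mf[[1L]], family = family,
           xname = names(mf)[2L], yname = names(mf)[1L],
           call = match.call())
}

#' Fit a QSPR family from raw vectors
#'
#' Workhorse behind [qspr()]; useful when the predictor is already a bare
#' vector (e.g. an exact integer log-index column, which the logarithmic
#' family should receive via \code{x_is_log = TRUE}).
#'
#' @param x predictor (index) values.
#' @param y response (property) values.
#' @inheritParams qspr
#' @param xname,yname display names used by the methods.
#' @param x_is_log for the logarithmic family only: \code{x} is already
#'   \eqn{\ln TI} and is used as-is.
#' @param call stored call.
#' @return A \code{"qspr"} object.
#' @export
qspr_fit <- function(x, y, family = c("linear", "quadratic", "logarithmic"),
                     xname = "TI", yname = "P", x_is_log = FALSE,
                     call = NULL) {
  family <- match.arg(family)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  if (anyNA(x) || anyNA(y))
    stop("missing values in regression inputs")
  n <- length(y)
  k <- if (family == "quadratic") 2L else 1L
  if (n < k + 2L)
    stop(sprintf("need at least %d observations for a %s fit", k + 2L, family))

  if (family == "logarithmic" && !x_is_log) {
    if (any(x <= 0))
      stop(errorCondition(
        "logarithmic family requires strictly positive index values",
        class = c("qspr_domain_error", "qspr_error", "error", "condition")))
    z <- log(x)
  } else {
    z <- x
  }

  X <- if (family == "quadratic") cbind(1, z, z^2) else cbind(1, z)
  check_design(X)

  dat <- data.frame(.y = y, .x = z)
  m <- if (family == "quadratic") {
    stats::lm(.y ~ .x + I(.x^2), data = dat)
  } else {
    stats::lm(.y ~ .x, data = dat)
  }
  # summary.lm warns on noiseless data ("essentially perfect fit"); exact
  # recovery at sigma = 0 is a supported case here, not an anomaly
  sm <- suppressWarnings(summary(m))
  co <- stats::coef(m)
  r2 <- sm$r.squared
  b <- unname(co[2L])
  r <- if (k == 1L) sign(b) * sqrt(r2) else sqrt(r2)
  df1 <- k
  df2 <- n - k - 1L
  Fstat <- unname(sm$fstatistic[["value"]])
  structure(
    list(family = family, xname = xname, yname = yname,
         n = n, A = unname(co[1L]), b = b,
         c = if (k == 2L) unname(co[3L]) else NA_real_,
         r = r, r2 = r2, F = Fstat, df1 = df1, df2 = df2,
         p.value = f_pvalue(Fstat, df1, df2),
         sigma = sm$sigma,
         x = x, z = z, y = y,
         fitted.values = unname(stats::fitted(m)),
         residuals = unname(stats::residuals(m)),
         call = call),
    class = "qspr")
}

# degenerate-design screen used by the fitter: raw entries must be finite,
# predictors non-constant, and the standardized design well conditioned
check_design <- function(X) {
  P <- X[, -1L, drop = FALSE]
  if (any(!is.finite(P)))
    stop_degenerate("non-finite design entries (index magnitude exceeds double precision)",
                    Inf)
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0))
    stop_degenerate("constant predictor column", Inf)
  cc <- condition_check(cbind(1, scale(P)))
  if (!cc$pass)
    stop_degenerate(
      "standardized design is ill-conditioned (numerically collinear predictors)",
      cc$condition)
  invisible(TRUE)
}

stop_degenerate <- function(msg, condition_number) {
  cond <- errorCondition(
    sprintf("degenerate fit: %s [condition estimate %s, threshold 1e8]",
            msg, format(condition_number, digits = 3)),
    condition_number = condition_number,
    class = c("qspr_degenerate_error", "qspr_error", "error", "condition"))
  stop(cond)
}

#' Condition diagnostic for a design matrix
#'
#' Estimates the 2-norm condition number of a design matrix via its singular
#' values and compares it against a documented threshold of \code{1e8}
#' (roughly half of double precision's significant digits).  Raw designs
#' built from exponential-index columns fail; their centered and scaled
#' variants pass whenever the predictors are not numerically collinear.
#'
#' @param X numeric design matrix (including any intercept column).
#' @param threshold pass/fail cutoff for the condition estimate.
#' @return A list with \code{condition}, \code{threshold} and logical
#'   \code{pass}.
#' @export
condition_check <- function(X, threshold = 1e8) {
  X <- as.matrix(X)
  if (any(!is.finite(X)))
    return(list(condition = Inf, threshold = threshold, pass = FALSE))
  d <- svd(X, nu = 0L, nv = 0L)$d
  cond <- if (min(d) == 0) Inf else max(d) / min(d)
  list(condition = cond, threshold = threshold,
       pass = is.finite(cond) && cond <= threshold)
}

#' Upper-tail p-value of the overall F test
#'
#' @param F observed F statistic (non-negative).
#' @param df1,df2 numerator and denominator degrees of freedom (positive).
#' @return The upper-tail probability in \code{[0, 1]}.
#' @examples
#' f_pvalue(0, 1, 13)    # 1
#' f_pvalue(1, 1, 1)     # 0.5
#' @export
f_pvalue <- function(F, df1, df2) {
  if (!is.finite(F) || F < 0) stop("'F' must be a non-negative number")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' @export
print.qspr <- function(x, ...) {
  eq <- switch(x$family,
    linear = sprintf("%s = %.3f %+.3f %s", x$yname, x$A, x$b, x$xname),
    quadratic = sprintf("%s = %.3f %+.3f %s %+.3f %s^2",
                        x$yname, x$A, x$b, x$xname, x$c, x$xname),
    logarithmic = sprintf("%s = %.3f %+.3f ln(%s)",
                          x$yname, x$A, x$b, x$xname))
  cat(sprintf("QSPR %s model: %s\n", x$family, eq))
  cat(sprintf("  n = %d, r = %.3f, r2 = %.3f, F(%d,%d) = %.3f, p = %s\n",
              x$n, x$r, x$r2, x$df1, x$df2, x$F,
              format.pval(x$p.value, digits = 3, eps = 5e-4)))
  invisible(x)
}

#' @export
summary.qspr <- function(object, ...) {
  structure(list(fit = object), class = "summary.qspr")
}

#' @export
print.summary.qspr <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual sd = %.4f on %d df\n", f$sigma, f$df2))
  cat(sprintf("  mean point: (%.4f, %.4f); fitted at mean predictor = %.4f\n",
              mean(f$z), mean(f$y),
              f$A + f$b * mean(f$z) +
                (if (is.na(f$c)) 0 else f$c * mean(f$z)^2)))
  invisible(x)
}

#' @export
coef.qspr <- function(object, ...) {
  if (object$family == "quadratic")
    c(A = object$A, b = object$b, c = object$c)
  else c(A = object$A, b = object$b)
}

#' Evaluate a fitted QSPR model at new index values
#'
#' @param object a \code{"qspr"} fit.
#' @param newdata optional data frame containing the predictor column.
#' @param x alternatively, a numeric vector of index values.
#' @param ... unused.
#' @return Predicted property values.
#' @export
predict.qspr <- function(object, newdata = NULL, x = NULL, ...) {
  if (is.null(x)) {
    if (is.null(newdata)) return(object$fitted.values)
    if (!object$xname %in% names(newdata))
      stop("'newdata' must contain column '", object$xname, "'")
    x <- newdata[[object$xname]]
  }
  z <- if (object$family == "logarithmic") {
    if (any(x <= 0))
      stop(errorCondition(
        "logarithmic model cannot be evaluated at non-positive index values",
        class = c("qspr_domain_error", "qspr_error", "error", "condition")))
    log(x)
  } else x
  object$A + object$b * z + (if (is.na(object$c)) 0 else object$c * z^2)
}

#' @export
residuals.qspr <- function(object, ...) object$residuals

#' @export
fitted.qspr <- function(object, ...) object$fitted.values

#' @export
simulate.qspr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  out <- as.data.frame(replicate(
    nsim, object$fitted.values + stats::rnorm(object$n, 0, object$sigma),
    simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.qspr <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
                 main = sprintf("%s ~ %s (%s)", x$yname, x$xname, x$family),
                 pch = 19, ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200L)
  graphics::lines(xs, predict(x, x = xs), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Fit all QSPR models of the study design
#'
#' Sweeps the full model grid: 6 indices x 6 properties x 3 families (108
#' fits).  Fits whose design fails the degeneracy screen (quadratic models
#' on raw exponential-index values) are reported as degenerate rows with the
#' diagnostic message rather than silently-zero coefficients.
#'
#' For the \code{"computed"} source the logarithmic family regresses the
#' exponential indices on their exact integer log-values; for published
#' sources it takes the log of the tabulated value.
#'
#' @inheritParams regression_input_table
#' @param families subset of families to fit.
#' @return A data frame with one row per model: \code{Index},
#'   \code{Property}, \code{Family}, \code{N}, \code{A}, \code{b}, \code{c},
#'   \code{r}, \code{r2}, \code{F}, \code{P}, \code{degenerate},
#'   \code{note}.
#' @export
qspr_table <- function(source = c("published", "computed",
                                  "published_with_corrections"),
                       families = c("linear", "quadratic", "logarithmic")) {
  source <- match.arg(source)
  inp <- regression_input_table(source)
  idx_names <- c("ABC_R", "GA", "EPi1", "EPi2", "GAPi", "SDD")
  prop_names <- c("MP", "BP", "WS", "D", "VP", "MW")

  rows <- list()
  for (ix in idx_names) {
    for (pr in prop_names) {
      for (fam in families) {
        xl <- fam == "logarithmic" && ix %in% c("EPi1", "EPi2")
        xv <- if (xl) inp$indices[[paste0("ln", ix)]] else inp$indices[[ix]]
        yv <- inp$properties[[pr]]
        fit <- tryCatch(
          qspr_fit(xv, yv, family = fam, xname = ix, yname = pr,
                   x_is_log = xl),
          qspr_error = function(e) e)
        if (inherits(fit, "qspr")) {
          rows[[length(rows) + 1L]] <- data.frame(
            Index = ix, Property = pr, Family = fam, N = fit$n,
            A = fit$A, b = fit$b, c = fit$c, r = fit$r, r2 = fit$r2,
            F = fit$F, P = fit$p.value, degenerate = FALSE, note = "",
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            Index = ix, Property = pr, Family = fam, N = length(yv),
            A = NA_real_, b = NA_real_, c = NA_real_, r = NA_real_,
            r2 = NA_real_, F = NA_real_, P = NA_real_, degenerate = TRUE,
            note = conditionMessage(fit), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "source") <- source
  out
}

#' Merged index/property data frame for formula fitting
#'
#' Convenience view joining the index and property matrices of
#' [regression_input_table()], suitable for [qspr()]'s formula interface.
#'
#' @inheritParams regression_input_table
#' @return A 15-row data frame with \code{Name}, the six index columns, the
#'   \code{lnEPi1}/\code{lnEPi2} columns, and the six property columns.
#' @export
qspr_data <- function(source = c("published", "computed",
                                 "published_with_corrections")) {
  inp <- regression_input_table(match.arg(source))
  merge(inp$indices, inp$properties, by = "Name", sort = FALSE)
}

#' Round a model table to the study's reporting precision
#'
#' Coefficients and statistics to three decimals; p-values below 0.0005
#' print as \code{"0.000"}.
#'
#' @param tbl output of [qspr_table()].
#' @return A data frame with rounded numeric columns and a character
#'   \code{P} column.
#' @export
format_qspr_table <- function(tbl) {
  out <- tbl
  for (col in c("A", "b", "c", "r", "r2", "F"))
    out[[col]] <- round(out[[col]], 3L)
  out$P <- ifelse(is.na(tbl$P), NA_character_, sprintf("%.3f", tbl$P))
  out
}
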