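#' Fit the mass-action model of complex formation
#'
#' Fits `f_complex = Ka * f_T * f_M` across subjects: a least-squares line
#' through the origin for the complex frequency on the product of singlet
#' T-cell and monocyte frequencies, together with the nonparametric Spearman
#' correlation of the two quantities. Under constant affinity (e.g. healthy
#' subjects), complex frequency is a linear function of the frequency
#' product and the slope estimates the cohort association constant Ka. The
#' origin constraint is physical: no complexes can form when either partner
#' population is absent.
#'
#' @param formula A formula `f_complex ~ f_T : f_M` (or `f_T * f_M`); with two
#'   variables on the right-hand side their product is the regressor. A
#'   single right-hand-side variable is used as the (precomputed) product.
#' @param data Data frame containing the variables, one row per subject.
#'   Rows with undefined values are dropped with a message.
#' @return An object of class `mass_action` with components `coefficients`
#'   (named `Ka`), `se`, `rho`, `rho_p`, `n`, `fitted.values`, `residuals`,
#'   `model`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`, `confint`.
#' @export
#' @examples
#' d <- data.frame(f_T = runif(10, 0.1, 0.5), f_M = runif(10, 0.02, 0.1))
#' d$f_complex <- 2 * d$f_T * d$f_M
#' coef(mass_action(f_complex ~ f_T : f_M, d))
mass_action <- function(formula, data) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars_rhs <- all.vars(formula[[3]])
  var_lhs <- all.vars(formula[[2]])
  if (length(var_lhs) != 1L || !length(vars_rhs) %in% 1:2) {
    stop("formula must be response ~ f_T : f_M (or a precomputed product)",
         call. = FALSE)
  }
  miss <- setdiff(c(var_lhs, vars_rhs), names(data))
  if (length(miss)) stop(sprintf("variable '%s' not in data", miss[1]), call. = FALSE)
  y <- data[[var_lhs]]
  x <- if (length(vars_rhs) == 2L) data[[vars_rhs[1]]] * data[[vars_rhs[2]]]
       else data[[vars_rhs[1]]]
  ok <- is.finite(x) & is.finite(y)
  if (any(!ok)) message(sprintf("dropping %d subject(s) with undefined values", sum(!ok)))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("mass_action requires >= 3 subjects with defined values", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all frequency products are zero", call. = FALSE)
  slope <- sum(x * y) / sxx
  fitted <- slope * x
  res <- y - fitted
  se <- sqrt(sum(res^2) / (n - 1) / sxx)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined", call. = FALSE)
    rho <- NA_real_; rho_p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  structure(list(coefficients = c(Ka = slope), se = c(Ka = se),
                 rho = rho, rho_p = rho_p, n = n,
                 fitted.values = fitted, residuals = res,
                 model = data.frame(x = x, y = y),
                 call = match.call(), formula = formula),
            class = "mass_action")
}

#' @export
print.mass_action <- function(x, ...) {
  cat("Mass-action fit (through origin):\n  ")
  cat(deparse(x$formula), "\n")
  cat(sprintf("  Ka = %.4g (SE %.3g), n = %d subjects\n",
              x$coefficients[["Ka"]], x$se[["Ka"]], x$n))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n", x$rho, x$rho_p))
  invisible(x)
}

#' @export
summary.mass_action <- function(object, ...) {
  tval <- object$coefficients / object$se
  out <- list(call = object$call, n = object$n,
              coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se,
                                   `t value` = tval,
                                   `Pr(>|t|)` = 2 * stats::pt(-abs(tval),
                                                              df = object$n - 1)),
              rho = object$rho, rho_p = object$rho_p,
              sigma = sqrt(sum(object$residuals^2) / (object$n - 1)))
  class(out) <- "summary.mass_action"
  out
}

#' @export
print.summary.mass_action <- function(x, ...) {
  cat("Mass-action model: complex frequency ~ Ka * (f_T * f_M), through origin\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual SD %.4g on %d subjects; Spearman rho = %.3f (p = %.3g)\n",
              x$sigma, x$n, x$rho, x$rho_p))
  invisible(x)
}

#' @export
coef.mass_action <- function(object, ...) object$coefficients

#' @export
fitted.mass_action <- function(object, ...) object$fitted.values

#' @export
residuals.mass_action <- function(object, ...) object$residuals

#' @export
confint.mass_action <- function(object, parm = "Ka", level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- stats::qt(c(a, 1 - a), df = object$n - 1)
  est <- object$coefficients[["Ka"]]
  ci <- matrix(est + q * object$se[["Ka"]], nrow = 1,
               dimnames = list("Ka", sprintf("%.1f %%", 100 * c(a, 1 - a))))
  ci
}

#' Predict complex frequencies from a mass-action fit
#'
#' @param object A `mass_action` fit.
#' @param newdata Optional data frame with the formula's right-hand-side
#'   variables (or a numeric vector of frequency products).
#' @param ... Unused.
#' @return Predicted complex frequencies.
#' @export
predict.mass_action <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  vars_rhs <- all.vars(object$formula[[3]])
  x <- if (is.numeric(newdata)) newdata
       else if (length(vars_rhs) == 2L) newdata[[vars_rhs[1]]] * newdata[[vars_rhs[2]]]
       else newdata[[vars_rhs[1]]]
  object$coefficients[["Ka"]] * x
}

#' @export
simulate.mass_action <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate(object, nsim)))
  sigma <- sqrt(sum(object$residuals^2) / (object$n - 1))
  out <- as.data.frame(replicate(nsim, pmax(0, object$fitted.values +
                                              stats::rnorm(object$n, 0, sigma))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a mass-action fit
#'
#' Complex frequency against the product of singlet T-cell and monocyte
#' frequencies, with the through-origin fitted line.
#'
#' @param x A `mass_action` fit.
#' @param ... Passed to [plot.default()].
#' @export
plot.mass_action <- function(x, ...) {
  args <- list(x = x$model$x, y = x$model$y,
               xlab = expression(f[T] %*% f[M]),
               ylab = expression(f[complex]),
               main = sprintf("Mass action: Ka = %.3g, rho = %.2f",
                              x$coefficients[["Ka"]], x$rho),
               pch = 19, col = "grey30")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(graphics::plot.default, args)
  graphics::abline(a = 0, b = x$coefficients[["Ka"]], col = "firebrick", lwd = 2)
  invisible(x)
}
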