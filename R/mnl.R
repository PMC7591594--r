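#' Multinomial logistic regression with McFadden's pseudo-R-squared
#'
#' Fits a baseline-category multinomial logit by Newton-Raphson on the
#' full log-likelihood (convergence when the log-likelihood changes by
#' less than `tol`, with step halving). Each non-reference outcome level
#' gets one coefficient per design column; the reference level carries no
#' coefficients. Wald 95% confidence intervals and p-values come from the
#' inverse observed information, and McFadden's pseudo-R-squared is
#' `1 - LL / LL0` with `LL0` the intercept-only log-likelihood.
#'
#' @param data data.frame holding the outcome and predictors.
#' @param outcome name of the outcome column (factor or character, >= 2
#'   levels present).
#' @param predictors character vector of predictor column names (numeric
#'   or logical); may be empty for the null model.
#' @param reference reference outcome level (default: first level).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `breath_mnl` with components
#'   `coefficients` (matrix, one row per non-reference level),
#'   `se`, `vcov`, `loglik`, `loglik_null`, `mcfadden_r2`, `levels`,
#'   `reference`, `fitted` (matrix of class probabilities), `n`, `call`.
#' @examples
#' d <- data.frame(y = rep(c("a", "b"), c(50, 40)),
#'                 x = c(rep(0:1, c(40, 10)), rep(0:1, c(10, 30))))
#' fit <- fit_multinomial(d, "y", "x")
#' coef(fit)  # log odds ratio log(6) for x
#' @export
fit_multinomial <- function(data, outcome, predictors = character(),
                            reference = NULL, tol = 1e-8, max_iter = 100L) {
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found", call. = FALSE)
  used <- c(outcome, predictors)
  if (anyNA(data[, used, drop = FALSE])) {
    stop("missing values in the outcome or predictor columns", call. = FALSE)
  }
  y <- factor(y)
  if (nlevels(y) < 2L) stop("outcome needs at least 2 levels", call. = FALSE)
  if (!is.null(reference)) {
    if (!reference %in% levels(y)) {
      stop("reference level not present in the outcome", call. = FALSE)
    }
    y <- stats::relevel(y, ref = reference)
  }
  X <- build_design(data, predictors)
  fit <- mnl_newton(y, X, tol = tol, max_iter = max_iter)
  if (fit$loglik > -1e-4 && max(abs(fit$B)) > 10) {
    stop("non-convergence: perfect separation (the likelihood is maximised at infinite coefficients)",
         call. = FALSE)
  }
  null_ll <- mnl_null_loglik(y)
  r2 <- if (null_ll < 0) 1 - fit$loglik / null_ll else 0
  structure(
    list(coefficients = fit$B, se = fit$se, vcov = fit$vcov,
         loglik = fit$loglik, loglik_null = null_ll,
         mcfadden_r2 = r2, levels = levels(y), reference = levels(y)[1L],
         fitted = fit$P, n = length(y), iterations = fit$iter,
         outcome = outcome, predictors = predictors,
         call = match.call()),
    class = "breath_mnl")
}

build_design <- function(data, predictors) {
  n <- nrow(data)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop(sprintf("predictor '%s' not found", p), call. = FALSE)
    if (is.logical(v)) v <- as.numeric(v)
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(p, levels(v)[-1L])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, as.numeric(v))
      colnames(X)[ncol(X)] <- p
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear columns %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X
}

# class probabilities for coefficient matrix B ((K-1) x p)
mnl_probs <- function(B, X) {
  eta <- X %*% t(B)                      # n x (K-1)
  m <- pmax(0, apply(eta, 1L, max))
  denom <- exp(-m) + rowSums(exp(eta - m))
  P <- exp(eta - m) / denom              # non-reference
  cbind(exp(-m) / denom, P)              # reference first
}

mnl_loglik <- function(B, X, Y) {
  P <- mnl_probs(B, X)
  sum(Y * log(pmax(P, 1e-300)))
}

mnl_null_loglik <- function(y) {
  n_k <- table(y)
  sum(n_k * log(n_k / length(y)))
}

mnl_newton <- function(y, X, tol = 1e-8, max_iter = 100L) {
  K <- nlevels(y)
  p <- ncol(X)
  n <- length(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, K - 1L, p,
              dimnames = list(levels(y)[-1L], colnames(X)))
  ll <- mnl_loglik(B, X, Y)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- mnl_probs(B, X)
    Pk <- P[, -1L, drop = FALSE]
    grad <- as.vector(vapply(seq_len(K - 1L), function(k) {
      crossprod(X, Y[, k + 1L] - Pk[, k])
    }, numeric(p)))
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (k in seq_len(K - 1L)) {
      for (l in k:(K - 1L)) {
        w <- if (k == l) Pk[, k] * (1 - Pk[, k]) else -Pk[, k] * Pk[, l]
        blk <- crossprod(X, X * w)
        ik <- ((k - 1L) * p + 1L):(k * p)
        il <- ((l - 1L) * p + 1L):(l * p)
        H[ik, il] <- blk
        H[il, ik] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, grad), error = function(e) {
      stop("non-convergence: singular information matrix (possible separation)",
           call. = FALSE)
    })
    # step halving on the likelihood
    lam <- 1
    repeat {
      B_new <- B + lam * t(matrix(step, p, K - 1L))
      ll_new <- mnl_loglik(B_new, X, Y)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    delta <- ll_new - ll
    B <- B_new
    ll <- ll_new
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (max(abs(B)) > 15) {
      stop("non-convergence: coefficients diverging (perfect separation?)",
           call. = FALSE)
    }
    stop("non-convergence: Newton iterations exhausted", call. = FALSE)
  }
  # observed information at the optimum
  P <- mnl_probs(B, X)
  Pk <- P[, -1L, drop = FALSE]
  H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
  for (k in seq_len(K - 1L)) {
    for (l in k:(K - 1L)) {
      w <- if (k == l) Pk[, k] * (1 - Pk[, k]) else -Pk[, k] * Pk[, l]
      blk <- crossprod(X, X * w)
      ik <- ((k - 1L) * p + 1L):(k * p)
      il <- ((l - 1L) * p + 1L):(l * p)
      H[ik, il] <- blk
      H[il, ik] <- t(blk)
    }
  }
  V <- solve(H)
  se <- t(matrix(sqrt(pmax(diag(V), 0)), p, K - 1L))
  dimnames(se) <- dimnames(B)
  nm <- as.vector(outer(colnames(X), levels(y)[-1L],
                        function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(nm, nm)
  list(B = B, se = se, vcov = V, loglik = ll, P = P, iter = iter)
}

#' @export
coef.breath_mnl <- function(object, ...) object$coefficients

#' @export
vcov.breath_mnl <- function(object, ...) object$vcov

#' @export
logLik.breath_mnl <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Coefficient table of a fitted multinomial model
#'
#' One row per non-reference level and design column with the estimate B,
#' the odds ratio exp(B), the Wald 95% confidence interval and p-value.
#'
#' @param object a `breath_mnl` fit.
#' @param conf_level confidence level (default 0.95).
#' @param ... unused.
#' @export
summary.breath_mnl <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  B <- object$coefficients
  se <- object$se
  tab <- data.frame(
    level = rep(rownames(B), each = ncol(B)),
    predictor = rep(colnames(B), times = nrow(B)),
    B = as.vector(t(B)),
    exp_B = exp(as.vector(t(B))),
    ci_low = as.vector(t(B - z * se)),
    ci_high = as.vector(t(B + z * se)),
    p = 2 * stats::pnorm(-abs(as.vector(t(B / se)))),
    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = object$loglik,
                 loglik_null = object$loglik_null,
                 mcfadden_r2 = object$mcfadden_r2,
                 reference = object$reference, n = object$n),
            class = "summary.breath_mnl")
}

#' @export
print.summary.breath_mnl <- function(x, digits = 3, ...) {
  cat(sprintf("Multinomial logit (reference: %s), n = %d\n", x$reference, x$n))
  tab <- x$table
  tab$B <- round(tab$B, digits)
  tab$exp_B <- round(tab$exp_B, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("logLik %.3f (null %.3f), McFadden R2 = %.4f\n",
              x$loglik, x$loglik_null, x$mcfadden_r2))
  invisible(x)
}

#' @export
print.breath_mnl <- function(x, ...) {
  cat(sprintf("<breath_mnl> %d levels (reference %s), %d obs, McFadden R2 = %.4f\n",
              length(x$levels), x$reference, x$n, x$mcfadden_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted class probabilities or classes
#'
#' @param object a `breath_mnl` fit.
#' @param newdata optional data.frame with the predictor columns; omitted,
#'   the fitted probabilities are returned.
#' @param type `"probs"` for the probability matrix (columns in level
#'   order, reference first) or `"class"` for the most probable level.
#' @param ... unused.
#' @export
predict.breath_mnl <- function(object, newdata = NULL,
                               type = c("probs", "class"), ...) {
  type <- match.arg(type)
  P <- if (is.null(newdata)) {
    object$fitted
  } else {
    mnl_probs(object$coefficients, build_design(newdata, object$predictors))
  }
  colnames(P) <- object$levels
  if (type == "probs") return(P)
  factor(object$levels[max.col(P)], levels = object$levels)
}

#' Response residuals of a multinomial fit
#'
#' Indicator-minus-probability residuals: an n-by-K matrix whose row sums
#' are zero.
#'
#' @param object a `breath_mnl` fit.
#' @param data the data the model was fitted to.
#' @param ... unused.
#' @export
residuals.breath_mnl <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    stop("residuals.breath_mnl() needs the fitting data (outcome column)",
         call. = FALSE)
  }
  y <- factor(data[[object$outcome]], levels = object$levels)
  Y <- matrix(0, length(y), length(object$levels),
              dimnames = list(NULL, object$levels))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y - object$fitted
}

#' Simulate outcomes from a fitted multinomial model
#'
#' @param object a `breath_mnl` fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a data.frame of factors, one column per simulation.
#' @export
simulate.breath_mnl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- object$fitted
  out <- replicate(nsim, {
    idx <- apply(P, 1L, function(p) sample.int(length(p), 1L, prob = p))
    factor(object$levels[idx], levels = object$levels)
  }, simplify = FALSE)
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' Coefficient plot of a multinomial fit
#'
#' Dot-and-whisker plot of the non-intercept coefficients with Wald 95%
#' intervals, one panel row per coefficient.
#'
#' @param x a `breath_mnl` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.breath_mnl <- function(x, ...) {
  s <- summary(x)$table
  s <- s[s$predictor != "(Intercept)", , drop = FALSE]
  if (nrow(s) == 0L) {
    stop("no non-intercept coefficients to plot", call. = FALSE)
  }
  lab <- paste(s$level, s$predictor, sep = ": ")
  yy <- rev(seq_len(nrow(s)))
  graphics::plot(s$B, yy, xlim = range(c(s$ci_low, s$ci_high, 0)),
                 yaxt = "n", ylab = "", xlab = "coefficient (log-odds)",
                 pch = 19, ...)
  graphics::segments(s$ci_low, yy, s$ci_high, yy)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = yy, labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' McFadden's pseudo-R-squared
#'
#' @param object a `breath_mnl` fit.
#' @return `1 - LL / LL0`, in `[0, 1]` when `LL0 < 0`.
#' @export
mcfadden_r2 <- function(object) {
  stopifnot(inherits(object, "breath_mnl"))
  object$mcfadden_r2
}
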