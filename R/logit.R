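#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary group label on bout-duration
#' features, in the conventional coding 0 = acute insomnia, 1 = healthy.
#' The model is `ln(p / (1 - p)) = b0 + b1 x1 + ... + bk xk` with no
#' interaction terms. IRLS iterates weighted least-squares solves of the
#' score equations; convergence is declared when the largest absolute
#' coefficient change drops below `tol` (default 1e-8) within `max_iter`
#' iterations. Standard errors come from the inverse observed information
#' `(X'WX)^{-1}` at the optimum, and p-values are two-sided Wald tests
#' against the standard normal. Quasi-separated data are flagged via a
#' diverging coefficient norm (> 1e4): the fit is returned at the last
#' iterate with `converged = FALSE` and a warning, never silently clipped.
#'
#' @param X Numeric matrix or data frame of predictors (subjects x
#'   features), no intercept column, no missing values.
#' @param y Binary labels (0/1 or logical), one per row of `X`; 1 = healthy
#'   control.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @return A list of class `logistic_model`: `beta`, `se`, `p` (named
#'   vectors, intercept first), `converged`, `n_iter`, `n`, plus the final
#'   log-likelihood `loglik`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y),
            all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("labels are all one class; logistic fit is degenerate",
         call. = FALSE)
  }
  terms <- c("(Intercept)", colnames(X) %||% paste0("x", seq_len(ncol(X))))
  Xd <- cbind(1, X)
  k <- ncol(Xd)
  beta <- numeric(k)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    # guard the weighted solve against vanishing weights at extreme eta
    w <- pmax(w, 1e-12)
    info <- crossprod(Xd, Xd * w)
    score <- crossprod(Xd, y - mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      break
    }
    beta_new <- beta + drop(step)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (sqrt(sum(beta^2)) > 1e4) {
      separated <- TRUE
      break
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (separated) {
    warning("possible complete separation: coefficient norm diverged; ",
            "estimates reported at last iterate", call. = FALSE)
  } else if (!converged) {
    warning(sprintf(
      "IRLS did not converge in %d iterations (possible separation); ",
      iter), "estimates reported at last iterate", call. = FALSE)
  }
  eta <- drop(Xd %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(Xd, Xd * w)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(diag(cov))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  loglik <- sum(y * log(pmax(mu, 1e-300)) +
                  (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(
    list(
      beta = setNames(beta, terms), se = setNames(se, terms),
      p = setNames(pval, terms), converged = converged && !separated,
      n_iter = iter, n = length(y), loglik = loglik
    ),
    class = "logistic_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logistic log-likelihood at a given coefficient vector
#'
#' Utility used for optimality diagnostics: the Bernoulli log-likelihood of
#' labels `y` under coefficients `beta` (intercept first).
#'
#' @param X Predictor matrix without intercept column.
#' @param y Binary labels.
#' @param beta Coefficient vector, length `ncol(X) + 1`.
#' @return The log-likelihood (scalar).
#' @export
logistic_loglik <- function(X, y, beta) {
  Xd <- cbind(1, as.matrix(X))
  eta <- drop(Xd %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Coefficient table for a fitted logistic model
#'
#' Report rows in the fixed order intercept, then the five bout-duration
#' bins (1-3, 4-5, 6-30, 31-60, >60 minutes). Values are carried at full
#' precision; display rounding is left to the caller (reports round to 3
#' decimals).
#'
#' @param model A [fit_logistic()] result.
#' @return A tibble with columns `term`, `estimate`, `se`, `p`.
#' @export
coefficient_table <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  tibble::tibble(
    term = names(model$beta),
    estimate = unname(model$beta),
    se = unname(model$se),
    p = unname(model$p)
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d, %s after %d IRLS iterations)\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  tab <- coefficient_table(x)
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$p <- signif(tab$p, 3)
  print.data.frame(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}
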