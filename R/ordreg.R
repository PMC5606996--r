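# Link functions ---------------------------------------------------------

#' Link specification for cumulative-link models
#'
#' Returns the cumulative distribution function, density and quantile
#' function of a latent-noise distribution.  The probit link corresponds to
#' standard Gaussian latent noise; the logit link to standard logistic noise.
#'
#' @param name `"probit"` (default) or `"logit"`.
#' @return A list with elements `name`, `cdf(q, lower.tail = TRUE)`,
#'   `pdf(x)` and `qf(p)`.
#' @examples
#' lk <- make_link("probit")
#' lk$cdf(0) # 0.5
#' @export
make_link <- function(name = c("probit", "logit")) {
  name <- match.arg(name)
  if (name == "probit") {
    list(name = "probit", cdf = stats::pnorm, pdf = stats::dnorm,
         qf = stats::qnorm)
  } else {
    list(name = "logit", cdf = stats::plogis, pdf = stats::dlogis,
         qf = stats::qlogis)
  }
}

.as_link <- function(link) {
  if (is.character(link)) make_link(link) else link
}

# P(lo < Z <= hi) computed in the numerically favourable tail.
.interval_prob <- function(lo, hi, F) {
  out <- numeric(length(lo))
  pos <- is.finite(lo) & lo > 0
  out[!pos] <- F(hi[!pos]) - F(lo[!pos])
  if (any(pos)) {
    out[pos] <- F(lo[pos], lower.tail = FALSE) - F(hi[pos], lower.tail = FALSE)
  }
  out
}

# Cumulative probability --------------------------------------------------

#' Cumulative category probability of the proportional-odds model
#'
#' Computes `P(Y <= level | x) = F(alpha[level] - beta * x)` where `F` is the
#' link CDF.  The latent-variable convention `z* = beta * x + eps` is used,
#' so a positive `beta` means the response tends to higher categories as `x`
#' grows, and `P(Y <= i | x)` is nonincreasing in `x`.
#'
#' @param alphas Strictly increasing numeric vector of `k` intercepts.
#' @param beta Slope (scalar).
#' @param x Covariate value(s).
#' @param level Boundary index in `1..k`.
#' @param link Link name or object from [make_link()].
#' @return Numeric vector of probabilities, one per element of `x`.
#' @examples
#' cum_prob(c(-1, 1), beta = 0.5, x = 2, level = 2) # pnorm(0) = 0.5
#' @export
cum_prob <- function(alphas, beta, x, level, link = "probit") {
  .check_alphas(alphas)
  stopifnot(length(level) == 1L, level >= 1L, level <= length(alphas))
  lk <- .as_link(link)
  lk$cdf(alphas[level] - beta * x)
}

.check_alphas <- function(alphas) {
  if (length(alphas) < 1L || anyNA(alphas) ||
      (length(alphas) > 1L && any(diff(alphas) <= 0))) {
    stop("invalid parameters: 'alphas' must be strictly increasing",
         call. = FALSE)
  }
  invisible(alphas)
}

# Negative log-likelihood -------------------------------------------------

#' Negative log-likelihood of the cumulative-link model
#'
#' For grades coded `0..k` and `k` intercepts, each observation contributes
#' `-log(F(alpha[y + 1] - beta x) - F(alpha[y] - beta x))` with the
#' conventions `alpha[0] = -Inf`, `alpha[k + 1] = +Inf`.  Returns `+Inf`
#' (not an error) when some observed category has probability zero.
#'
#' @param alphas Increasing intercept vector (length `k`).
#' @param beta Slope.
#' @param x Covariate vector.
#' @param grades Integer grades in `0..k`, same length as `x`.
#' @inheritParams cum_prob
#' @return Scalar negative log-likelihood.
#' @export
ordreg_nll <- function(alphas, beta, x, grades, link = "probit") {
  .check_alphas(alphas)
  lk <- .as_link(link)
  stopifnot(length(x) == length(grades), all(grades >= 0),
            all(grades <= length(alphas)))
  .nll_unchecked(alphas, beta, x, grades, lk)
}

# optimizer-facing NLL: tied intercepts (gap underflow) give zero category
# probability and hence +Inf rather than a validation error
.nll_unchecked <- function(alphas, beta, x, grades, lk) {
  cuts <- c(-Inf, alphas, Inf)
  hi <- cuts[grades + 2L] - beta * x
  lo <- cuts[grades + 1L] - beta * x
  p <- .interval_prob(lo, hi, lk$cdf)
  if (any(p <= 0)) return(Inf)
  -sum(log(p))
}

# gradient of the NLL in (alphas, beta); assumes all category probs > 0
.ordreg_grad_ab <- function(alphas, beta, x, grades, lk) {
  k <- length(alphas)
  cuts <- c(-Inf, alphas, Inf)
  hi <- cuts[grades + 2L] - beta * x
  lo <- cuts[grades + 1L] - beta * x
  p <- pmax(.interval_prob(lo, hi, lk$cdf), 1e-300)
  du <- ifelse(is.finite(hi), lk$pdf(hi), 0)
  dl <- ifelse(is.finite(lo), lk$pdf(lo), 0)
  w <- 1 / p
  g_alpha <- vapply(seq_len(k), function(j) {
    -(sum(du[grades == j - 1L] * w[grades == j - 1L]) -
        sum(dl[grades == j] * w[grades == j]))
  }, numeric(1))
  g_beta <- sum(x * (du - dl) * w)
  c(g_alpha, g_beta)
}

# unconstrained parameterization: theta = (a1, log-gaps..., beta)
.theta_to_ab <- function(theta, k) {
  if (k == 1L) {
    list(alphas = theta[1L], beta = theta[2L])
  } else {
    list(alphas = cumsum(c(theta[1L], exp(theta[2:k]))), beta = theta[k + 1L])
  }
}

.ab_to_theta <- function(alphas, beta) {
  k <- length(alphas)
  if (k == 1L) c(alphas, beta) else c(alphas[1L], log(diff(alphas)), beta)
}

# Fitting -----------------------------------------------------------------

#' Proportional-odds cumulative-link regression on a single covariate
#'
#' Maximum-likelihood fit of the cumulative-link model
#' `P(Y <= i | x) = F(alpha_i - beta x)` for an ordinal response with
#' `k + 1` ordered categories and a single real covariate (typically the
#' expression of one gene).  A single slope `beta` is shared by all category
#' boundaries (the proportional-odds assumption); only the `k` intercepts
#' `alpha_i` differ.  The default probit link takes `F` to be the standard
#' Gaussian CDF, corresponding to a latent variable `z* = beta x + eps`,
#' `eps ~ N(0, 1)`, cut at the `alpha_i`.
#'
#' Optimization runs on an unconstrained parameterization (first intercept
#' plus log-gaps, which enforces the intercept ordering) with an analytic
#' gradient: quasi-Newton iterations followed by Newton polishing until the
#' gradient norm drops below `tol`.  Initialization is deterministic, from
#' the marginal category frequencies with `beta = 0`.  The covariate is
#' centred internally; estimates and standard errors are reported on the
#' original scale.  Standard errors come from the inverse observed
#' information; Wald `z = estimate / SE` with two-tailed normal p-values.
#'
#' Quasi-complete separation (a fit drifting to infinite parameters) is
#' flagged via `separated`; its p-values are set to 1 so that such genes are
#' never called significant downstream.
#'
#' @param formula,data Model formula `grade ~ expression` with a single
#'   numeric covariate; `grade` may be an ordered factor or integer codes.
#' @param x,grades Alternative low-level interface ([ordreg_fit()]):
#'   covariate vector and integer grades `0..k`.
#' @param link `"probit"` (default) or `"logit"`.
#' @param tol Convergence tolerance on the gradient norm (default `1e-8`).
#' @param max_iter Maximum quasi-Newton iterations (default 200).
#' @return An object of class `"ordreg"`: a list with components `alphas`,
#'   `beta`, `se_alphas`, `se_beta`, `z_values`, `p_values` (named, one per
#'   parameter), `vcov`, `loglik`, `converged`, `separated`, `n_obs`, `k`,
#'   `link`, `levels`.
#' @seealso [screen_genes()] for applying the fit across a matrix.
#' @examples
#' set.seed(1)
#' x <- rnorm(120)
#' z <- 1.2 * x + rnorm(120)
#' y <- findInterval(z, c(-1, 0.5, 1.5))
#' fit <- ordreg_fit(x, y)
#' summary(fit)
#' @export
ordreg <- function(formula, data, link = "probit", tol = 1e-8,
                   max_iter = 200L) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) {
    stop("'formula' must have exactly one covariate", call. = FALSE)
  }
  y <- mf[[1L]]
  if (is.factor(y)) {
    levels_y <- levels(y)
    grades <- as.integer(y) - 1L
  } else {
    levels_y <- as.character(sort(unique(y)))
    grades <- match(y, sort(unique(y))) - 1L
  }
  x <- mf[[2L]]
  if (!is.numeric(x)) stop("covariate must be numeric", call. = FALSE)
  out <- ordreg_fit(x, grades, link = link, tol = tol, max_iter = max_iter,
                    levels = levels_y)
  out$call <- match.call()
  out
}

#' @rdname ordreg
#' @param levels Optional character labels for the ordered categories.
#' @export
ordreg_fit <- function(x, grades, link = "probit", tol = 1e-8,
                       max_iter = 200L, levels = NULL) {
  lk <- .as_link(link)
  stopifnot(length(x) == length(grades))
  keep <- is.finite(x) & !is.na(grades)
  x <- x[keep]; grades <- as.integer(grades[keep])
  n <- length(x)
  obs_levels <- sort(unique(grades))
  if (length(obs_levels) < 2L) {
    stop("need at least 2 observed grade levels", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("covariate is constant; refusing to fit", call. = FALSE)
  }
  # recode observed levels to contiguous 0..k
  grades <- match(grades, obs_levels) - 1L
  k <- length(obs_levels) - 1L
  if (is.null(levels)) levels <- as.character(obs_levels)

  xbar <- mean(x)
  xc <- x - xbar

  fn <- function(theta) {
    ab <- .theta_to_ab(theta, k)
    .nll_unchecked(ab$alphas, ab$beta, xc, grades, lk)
  }
  gr <- function(theta) {
    ab <- .theta_to_ab(theta, k)
    g_ab <- .ordreg_grad_ab(ab$alphas, ab$beta, xc, grades, lk)
    # chain rule through the log-gap reparameterization
    g_alpha <- g_ab[seq_len(k)]
    g_theta <- numeric(k + 1L)
    g_theta[1L] <- sum(g_alpha)
    if (k > 1L) {
      for (j in 2:k) g_theta[j] <- exp(theta[j]) * sum(g_alpha[j:k])
    }
    g_theta[k + 1L] <- g_ab[k + 1L]
    g_theta
  }

  # deterministic start: link-quantiles of marginal cumulative frequencies
  freq <- tabulate(grades + 1L, nbins = k + 1L) / n
  alpha0 <- lk$qf(pmin(pmax(cumsum(freq)[seq_len(k)], 1e-6), 1 - 1e-6))
  if (any(diff(alpha0) <= 0)) alpha0 <- seq(-1, 1, length.out = k)
  theta <- .ab_to_theta(alpha0, 0)

  opt <- stats::optim(theta, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  # Newton polish to the requested gradient-norm tolerance
  g <- gr(theta)
  it <- 0L
  while (sqrt(sum(g^2)) >= tol && it < 50L) {
    H <- tryCatch(stats::optimHess(theta, fn, gr), error = function(e) NULL)
    step <- if (!is.null(H)) {
      tryCatch(solve(H, g), error = function(e) g * 1e-3)
    } else g * 1e-3
    f0 <- fn(theta)
    lam <- 1
    repeat {
      cand <- theta - lam * step
      fc <- fn(cand)
      if (is.finite(fc) && fc <= f0) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- theta; break }
    }
    theta <- cand
    g <- gr(theta)
    it <- it + 1L
  }
  converged <- sqrt(sum(g^2)) < tol

  ab <- .theta_to_ab(theta, k)
  alphas_c <- ab$alphas; beta <- ab$beta
  loglik <- -fn(theta)

  # observed information in the (alpha, beta) parameterization (centred x)
  nll_ab <- function(p) .nll_unchecked(p[seq_len(k)], p[k + 1L], xc, grades, lk)
  gr_ab <- function(p) .ordreg_grad_ab(p[seq_len(k)], p[k + 1L], xc, grades, lk)
  H <- tryCatch(stats::optimHess(c(alphas_c, beta), nll_ab, gr_ab),
                error = function(e) NULL)
  V_c <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL

  separated <- !converged || is.null(V_c) || any(!is.finite(V_c)) ||
    any(diag(V_c) <= 0) || max(abs(c(alphas_c, beta))) > 25

  # de-centre: alpha = alpha_c + beta * xbar
  alphas <- alphas_c + beta * xbar
  if (!is.null(V_c) && all(is.finite(V_c))) {
    J <- diag(k + 1L)
    J[seq_len(k), k + 1L] <- xbar
    V <- J %*% V_c %*% t(J)
  } else {
    V <- matrix(NA_real_, k + 1L, k + 1L)
  }
  par_names <- c(paste0("alpha", seq_len(k)), "beta")
  dimnames(V) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(V), 0))
  est <- c(alphas, beta)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  if (separated) p[] <- 1
  names(est) <- names(se) <- names(z) <- names(p) <- par_names

  structure(list(
    alphas = alphas, beta = beta,
    se_alphas = se[seq_len(k)], se_beta = se[[k + 1L]],
    z_values = z, p_values = p, vcov = V,
    loglik = loglik, converged = converged, separated = separated,
    n_obs = n, k = k, link = lk$name, levels = levels,
    call = sys.call(-1L)
  ), class = "ordreg")
}

# S3 methods ---------------------------------------------------------------

#' @method print ordreg
#' @export
print.ordreg <- function(x, ...) {
  cat("Cumulative-link (proportional-odds) regression,", x$link, "link\n")
  cat(sprintf("%d observations, %d ordered categories\n", x$n_obs, x$k + 1L))
  cat("Coefficients:\n")
  print(coef(x))
  if (!x$converged) cat("Warning: fit did not converge\n")
  if (x$separated) cat("Note: separation detected; p-values set to 1\n")
  invisible(x)
}

#' @method coef ordreg
#' @export
coef.ordreg <- function(object, ...) {
  stats::setNames(c(object$alphas, object$beta),
                  c(paste0("alpha", seq_len(object$k)), "beta"))
}

#' @method vcov ordreg
#' @export
vcov.ordreg <- function(object, ...) object$vcov

#' @method logLik ordreg
#' @export
logLik.ordreg <- function(object, ...) {
  structure(object$loglik, df = object$k + 1L, nobs = object$n_obs,
            class = "logLik")
}

#' @method summary ordreg
#' @export
summary.ordreg <- function(object, ...) {
  tab <- cbind(Estimate = coef(object),
               `Std. Error` = c(object$se_alphas, object$se_beta),
               `z value` = object$z_values,
               `Pr(>|z|)` = object$p_values)
  out <- list(coefficients = tab, loglik = object$loglik,
              converged = object$converged, separated = object$separated,
              link = object$link, n_obs = object$n_obs, k = object$k)
  class(out) <- "summary.ordreg"
  out
}

#' @method print summary.ordreg
#' @export
print.summary.ordreg <- function(x, ...) {
  cat("Cumulative-link (proportional-odds) regression,", x$link, "link\n")
  cat(sprintf("%d observations, %d ordered categories\n", x$n_obs, x$k + 1L))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("log-likelihood: %.4f  converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Predicted category probabilities from a cumulative-link fit
#'
#' @param object An `"ordreg"` fit.
#' @param newdata Numeric covariate vector.
#' @param type `"prob"` for per-category probabilities (matrix), `"cumprob"`
#'   for `P(Y <= i)` at each boundary, `"class"` for the modal category
#'   index (0-based).
#' @param ... Unused.
#' @method predict ordreg
#' @export
predict.ordreg <- function(object, newdata,
                           type = c("prob", "cumprob", "class"), ...) {
  type <- match.arg(type)
  lk <- make_link(object$link)
  x <- as.numeric(newdata)
  cp <- vapply(seq_len(object$k),
               function(i) lk$cdf(object$alphas[i] - object$beta * x),
               numeric(length(x)))
  cp <- matrix(cp, nrow = length(x))
  colnames(cp) <- paste0("P(Y<=", seq_len(object$k) - 1L, ")")
  if (type == "cumprob") return(cp)
  pr <- cbind(cp, 1) - cbind(0, cp)
  colnames(pr) <- object$levels[seq_len(object$k + 1L)]
  if (type == "prob") return(pr)
  max.col(pr) - 1L
}

#' Simulate grades from a fitted cumulative-link model
#'
#' @param object An `"ordreg"` fit.
#' @param nsim Number of simulated grade vectors.
#' @param seed Optional RNG seed.
#' @param newdata Covariate vector to simulate at (required).
#' @param ... Unused.
#' @return A data frame with `nsim` columns of integer grades `0..k`.
#' @method simulate ordreg
#' @export
simulate.ordreg <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata, type = "prob")
  out <- replicate(nsim, apply(pr, 1L, function(p) {
    sample.int(length(p), 1L, prob = p) - 1L
  }))
  as.data.frame(matrix(out, nrow = length(newdata)))
}

#' Plot fitted cumulative probabilities against the covariate
#'
#' Draws `P(Y <= i | x)` for each category boundary over the covariate range;
#' under the proportional-odds assumption these curves are horizontal shifts
#' of one another.
#'
#' @param x An `"ordreg"` fit.
#' @param xlim Covariate range; defaults to roughly +/- 3 latent SD around
#'   the intercept region.
#' @param ... Passed to [graphics::matplot()].
#' @method plot ordreg
#' @export
plot.ordreg <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) {
    ctr <- if (x$beta != 0) range(x$alphas / x$beta) else c(-1, 1)
    span <- max(3 / max(abs(x$beta), 0.5), diff(ctr))
    xlim <- c(min(ctr) - span, max(ctr) + span)
  }
  xs <- seq(xlim[1], xlim[2], length.out = 200)
  cp <- predict(x, xs, type = "cumprob")
  graphics::matplot(xs, cp, type = "l", lty = 1,
                    xlab = "covariate", ylab = "P(Y <= i | x)", ...)
  invisible(x)
}
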