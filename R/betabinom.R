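#' Beta-binomial log probability mass
#'
#' Mean-precision parameterisation: the per-trial success probability is
#' Beta(a, b) with `a = mu * phi`, `b = (1 - mu) * phi`, so `mu` is the mean
#' proportion and `phi` the precision (larger `phi`, less overdispersion;
#' the binomial is the `phi -> Inf` limit).
#'
#' @param k Successes, `0 <= k <= n`.
#' @param n Trials.
#' @param mu Mean proportion in (0, 1).
#' @param phi Precision (dispersion) parameter, > 0.
#' @return Log-probability, vectorised over arguments.
#' @export
betabinom_logpmf <- function(k, n, mu, phi) {
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("phi must be > 0", call. = FALSE)
  a <- mu * phi
  b <- (1 - mu) * phi
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Specify a candidate fertilization-success model
#'
#' Describes one candidate beta-binomial regression of fertilized counts:
#' which intercolony proximity metric enters (if any), whether night of
#' spawning is a fixed effect, optional release-time quadratic nested within
#' night, depth class, dispersal group, and a colony random intercept.
#'
#' @param proximity One of `"nn"`, `"density_2"`, `"density_5"`,
#'   `"density_10"`, `"weighted_area"`, or `"none"`.
#' @param night Include the night fixed effect (indicator for night 2)?
#' @param time_quadratic Include release time and its square, with separate
#'   slopes per night?
#' @param depth Include depth class (shallow reference)?
#' @param dispersal Include the dispersal-group categorical?
#' @param random_intercept Colony-identity Gaussian random intercept?
#' @param label Display label (defaults to a description of the terms).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(proximity = "nn", night = TRUE, time_quadratic = FALSE,
                       depth = FALSE, dispersal = FALSE,
                       random_intercept = FALSE, label = NULL) {
  proximity <- match.arg(proximity, c("nn", "density_2", "density_5",
                                      "density_10", "weighted_area", "none"))
  if (is.null(label)) {
    extras <- c(if (time_quadratic) "time" , if (depth) "depth",
                if (dispersal) "dispersal")
    label <- paste0(proximity, if (night) "+night",
                    if (length(extras)) paste0("+", paste(extras,
                                                          collapse = "+")))
  }
  structure(list(proximity = proximity, night = night,
                 time_quadratic = time_quadratic, depth = depth,
                 dispersal = dispersal, random_intercept = random_intercept,
                 label = label),
            class = "model_spec")
}

#' The default candidate-model set
#'
#' One model per proximity metric, each with the night fixed effect: the
#' standard comparison set for ranking proximity metrics by AIC.
#'
#' @return Named list of [model_spec()] objects.
#' @export
default_model_set <- function() {
  metrics <- c("nn", "density_2", "density_5", "density_10", "weighted_area")
  stats::setNames(lapply(metrics, model_spec), metrics)
}

# metric-table column backing each proximity term
prox_column <- function(proximity, metrics) {
  col <- switch(proximity,
                nn = "nn_m",
                density_2 = "density_2m",
                density_5 = "density_5m",
                density_10 = "density_10m",
                weighted_area = grep("^weighted_area", names(metrics),
                                     value = TRUE)[1],
                none = NA_character_)
  if (!is.na(col) && (is.null(col) || !col %in% names(metrics)))
    stop("metrics table lacks a column for proximity term '", proximity, "'",
         call. = FALSE)
  col
}

#' Assemble the regression design for a candidate model
#'
#' Joins fertilization samples to their colony neighbourhood metrics (and,
#' when requested, spawn times, depth classes and dispersal groups) and
#' builds the fixed-effects design matrix. Release time is converted to
#' minutes since the first release of that night, then centred at the
#' per-night mean and scaled by the per-night SD before the quadratic is
#' formed; the centring constants are retained so predictions use the same
#' scaling.
#'
#' @param samples Fertilization-sample table.
#' @param metrics Neighbourhood-metrics table ([compute_all_metrics()]).
#' @param events Spawn-event table; required when `spec$time_quadratic`.
#' @param spec A [model_spec()].
#' @param colonies Colony table; required when `spec$depth`.
#' @return List of class `bb_design` with elements `X` (design matrix),
#'   `k`, `n` (response counts), `colony` (factor), `spec`, `scaling`.
#' @export
build_design <- function(samples, metrics, events = NULL, spec = model_spec(),
                         colonies = NULL) {
  df <- data.frame(colony_id = samples$colony_id, night = samples$night,
                   stringsAsFactors = FALSE)
  if (spec$proximity != "none") {
    col <- prox_column(spec$proximity, metrics)
    idx <- match(samples$colony_id, metrics$colony_id)
    if (anyNA(idx))
      stop("missing covariate '", spec$proximity, "' for colony ",
           samples$colony_id[which(is.na(idx))[1]], call. = FALSE)
    df[[spec$proximity]] <- metrics[[col]][idx]
  }
  scaling <- NULL
  if (spec$time_quadratic) {
    if (is.null(events))
      stop("spawn events required for the release-time terms", call. = FALSE)
    key <- paste(samples$colony_id, samples$night)
    ekey <- paste(events$colony_id, events$night)
    idx <- match(key, ekey)
    if (anyNA(idx) || anyNA(events$release_minute[idx]))
      stop("missing covariate 'release time' for colony ",
           samples$colony_id[which(is.na(idx) |
                                     is.na(events$release_minute[idx]))[1]],
           call. = FALSE)
    raw <- as.numeric(events$release_minute[idx]) - 1  # minutes since first
    scaling <- lapply(split(raw, samples$night), function(v) {
      s <- stats::sd(v)
      list(center = mean(v), scale = if (is.na(s) || s == 0) 1 else s)
    })
    df$time_raw <- raw
  }
  if (spec$depth) {
    if (is.null(colonies))
      stop("colony table required for the depth-class term", call. = FALSE)
    idx <- match(samples$colony_id, colonies$colony_id)
    if (anyNA(idx))
      stop("missing covariate 'depth_class' for colony ",
           samples$colony_id[which(is.na(idx))[1]], call. = FALSE)
    df$depth_class <- colonies$depth_class[idx]
  }
  if (spec$dispersal) {
    if (!"dispersal_group" %in% names(samples) ||
        anyNA(samples$dispersal_group))
      stop("missing covariate 'dispersal_group' in samples", call. = FALSE)
    df$dispersal_group <- samples$dispersal_group
  }
  structure(list(X = build_X(df, spec, scaling),
                 k = as.numeric(samples$n_fertilized),
                 n = as.numeric(samples$n_scored),
                 colony = factor(samples$colony_id),
                 spec = spec, scaling = scaling),
            class = "bb_design")
}

# shared fixed-effects row builder; df columns depend on the spec
build_X <- function(df, spec, scaling = NULL) {
  m <- nrow(df)
  X <- matrix(1, m, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$proximity != "none") {
    if (is.null(df[[spec$proximity]]))
      stop("newdata lacks term '", spec$proximity, "'", call. = FALSE)
    X <- cbind(X, matrix(as.numeric(df[[spec$proximity]]), ncol = 1,
                         dimnames = list(NULL, spec$proximity)))
  }
  if (spec$night) {
    check_night(df$night)
    X <- cbind(X, night2 = as.numeric(df$night == "n2"))
  }
  if (spec$time_quadratic) {
    if (is.null(df$time_raw)) stop("newdata lacks term 'time_raw'",
                                   call. = FALSE)
    z <- numeric(m)
    for (ng in names(scaling)) {
      i <- df$night == ng
      z[i] <- (df$time_raw[i] - scaling[[ng]]$center) / scaling[[ng]]$scale
    }
    i1 <- as.numeric(df$night == "n1")
    i2 <- as.numeric(df$night == "n2")
    X <- cbind(X, n1_time = i1 * z, n2_time = i2 * z,
               n1_time2 = i1 * z^2, n2_time2 = i2 * z^2)
  }
  if (spec$depth) {
    if (is.null(df$depth_class)) stop("newdata lacks term 'depth_class'",
                                      call. = FALSE)
    X <- cbind(X, depth_deeper = as.numeric(df$depth_class == "deeper"))
  }
  if (spec$dispersal) {
    if (is.null(df$dispersal_group))
      stop("newdata lacks term 'dispersal_group'", call. = FALSE)
    g <- factor(df$dispersal_group)
    if (nlevels(g) > 1) {
      D <- stats::model.matrix(~g)[, -1, drop = FALSE]
      colnames(D) <- paste0("dispersal_", levels(g)[-1])
      X <- cbind(X, D)
    }
  }
  X
}

#' Fit a beta-binomial regression by maximum likelihood
#'
#' Maximises the beta-binomial log-likelihood (logit link on the mean,
#' precision `phi` optimised on the log scale) over the fixed-effect
#' coefficients by quasi-Newton (BFGS) iteration, restarting from up to
#' three jittered starting points if the optimiser reports
#' non-convergence. With `random_intercept = TRUE` a per-colony Gaussian
#' intercept is integrated out of the likelihood by adaptive Gauss-Hermite
#' quadrature (15 nodes centred and scaled at each colony's conditional
#' mode); its standard deviation is optimised on the log scale and the
#' variance is reported (bounded below at zero by construction).
#'
#' Standard errors come from the inverse observed information (numerical
#' Hessian at the optimum); AIC counts every estimated parameter
#' (coefficients + dispersion + random-effect variance when present).
#' Because the random-effect variance is typically estimated at the zero
#' boundary in these data, a second AIC that does not count it is also
#' reported as `aic_no_re` for random-intercept fits.
#'
#' @param design A [build_design()] object (or a bare design matrix, in
#'   which case `k`, `n`, `colony` must be supplied).
#' @param k,n Optional response counts when `design` is a matrix.
#' @param colony Optional colony factor when `design` is a matrix.
#' @param random_intercept Integrate a colony random intercept?
#' @param n_quad Gauss-Hermite nodes for the random-intercept integral.
#' @param control Passed to [stats::optim()]; defaults set `reltol = 1e-10`.
#' @return An object of class `bb_fit`: coefficients, standard errors, Wald
#'   p-values, `dispersion` (phi), `random_intercept_variance`,
#'   `log_likelihood`, `aic`, `n_obs`, `converged`, plus the model spec and
#'   time scaling needed by [predict_mean()].
#' @export
fit_betabinom_glm <- function(design, k = NULL, n = NULL, colony = NULL,
                              random_intercept = NULL, n_quad = 15,
                              control = list()) {
  if (inherits(design, "bb_design")) {
    X <- design$X; k <- design$k; n <- design$n; colony <- design$colony
    spec <- design$spec; scaling <- design$scaling
    if (is.null(random_intercept)) random_intercept <- spec$random_intercept
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    spec <- NULL; scaling <- NULL
    if (is.null(random_intercept)) random_intercept <- FALSE
  }
  stopifnot(length(k) == nrow(X), length(n) == nrow(X), all(k >= 0),
            all(k <= n))
  p <- ncol(X)
  if (nrow(X) < p + 2)
    stop("need at least ", p + 2, " observations for ", p, " coefficients",
         call. = FALSE)
  note <- character()
  if (all(k == 0) || all(k == n))
    note <- c(note, "degenerate response: all counts at one boundary")

  gh <- pracma::gaussHermite(n_quad)
  cidx <- if (random_intercept) split(seq_along(k), colony) else NULL

  # log(phi) is soft-bounded: beyond exp(15) the fit is numerically
  # indistinguishable from binomial while lgamma differences degrade
  nll <- function(theta) {
    beta <- theta[1:p]
    lphi <- theta[p + 1]
    pen <- 0
    if (lphi > 15) { pen <- 0.01 * (lphi - 15)^2; lphi <- 15 }
    if (lphi < -15) { pen <- 0.01 * (lphi + 15)^2; lphi <- -15 }
    phi <- exp(lphi)
    eta <- drop(X %*% beta)
    if (!random_intercept) {
      mu <- stats::plogis(eta)
      mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
      ll <- sum(betabinom_logpmf(k, n, mu, phi))
    } else {
      sdre <- exp(theta[p + 2])
      ll <- sum(vapply(cidx, function(ix)
        loglik_colony(eta[ix], k[ix], n[ix], phi, sdre, gh), numeric(1)))
    }
    if (!is.finite(ll)) return(1e10)
    pen - ll
  }

  # binomial GLM start for the coefficients
  beta0 <- tryCatch(
    stats::glm.fit(X, cbind(k, n - k),
                   family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  start <- c(beta0, log(10), if (random_intercept) log(0.3))
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 1000), control)

  opt <- stats::optim(start, nll, method = "BFGS", control = ctrl)
  tries <- 0
  while (opt$convergence != 0 && tries < 3) {
    tries <- tries + 1
    jit <- start + stats::rnorm(length(start), 0, 0.25 * tries)
    opt2 <- stats::optim(jit, nll, method = "BFGS", control = ctrl)
    if (opt2$value < opt$value || opt2$convergence == 0) opt <- opt2
  }
  converged <- opt$convergence == 0
  boundary_re <- FALSE
  if (random_intercept) {
    # the profile likelihood in log(sd) flattens toward -Inf, where the
    # model degenerates to the fixed-effects fit; if that boundary is at
    # least as good as the interior optimum, the MLE of the variance is 0
    fe <- c(opt$par[1:p], opt$par[p + 1], log(1e-9))
    fe_val <- nll(fe)
    if (fe_val <= opt$value + 1e-6) {
      opt$par <- fe
      opt$value <- fe_val
      boundary_re <- TRUE
      note <- c(note, "random-intercept variance estimated at the 0 boundary")
    }
  }

  if (boundary_re) {
    # curvature in log(sd) is zero at the boundary; take the observed
    # information of the degenerate (fixed-effects) profile
    H <- tryCatch(stats::optimHess(opt$par[1:(p + 1)], function(th)
      nll(c(th, log(1e-9))), control = ctrl), error = function(e) NULL)
  } else {
    H <- tryCatch(stats::optimHess(opt$par, nll, control = ctrl),
                  error = function(e) NULL)
  }
  se_all <- rep(NA_real_, length(opt$par))
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se_all[seq_along(dv)][dv > 0] <- sqrt(dv[dv > 0])
      if (any(dv[1:p] <= 0)) {
        converged <- FALSE
        note <- c(note, "observed information not positive definite")
      }
    }
  }

  beta <- stats::setNames(unname(opt$par[1:p]), colnames(X))
  se <- stats::setNames(unname(se_all[1:p]), colnames(X))
  phi <- exp(min(unname(opt$par[p + 1]), 15))
  re_var <- if (random_intercept && !boundary_re)
    exp(unname(opt$par[p + 2]))^2 else 0
  ll <- -opt$value
  npar <- p + 1 + as.integer(random_intercept)
  fit <- structure(list(
    coefficients = beta,
    standard_errors = se,
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    dispersion = phi,
    random_intercept_variance = re_var,
    log_likelihood = ll,
    aic = 2 * npar - 2 * ll,
    aic_no_re = if (random_intercept) 2 * (npar - 1) - 2 * ll else NULL,
    n_obs = length(k),
    n_par = npar,
    converged = converged,
    family = "betabinomial",
    spec = spec,
    scaling = scaling,
    note = note
  ), class = "bb_fit")
  fit
}

# marginal log-likelihood of one colony's observations, integrating the
# Gaussian random intercept by adaptive Gauss-Hermite quadrature: the
# integrand is centred at its mode (a few Newton steps from b = 0) and
# scaled by its curvature there, then evaluated at all nodes in one
# vectorised pass
loglik_colony <- function(eta, k, n, phi, sdre, gh) {
  fvec <- function(b) {  # log integrand at each element of b
    mu <- stats::plogis(outer(eta, b, "+"))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    a1 <- mu * phi
    b1 <- (1 - mu) * phi
    lp <- lchoose(n, k) + lbeta(k + a1, n - k + b1) - lbeta(a1, b1)
    colSums(lp) + stats::dnorm(b, 0, sdre, log = TRUE)
  }
  if (sdre < 1e-6) {  # degenerate limit: point mass at zero
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    return(sum(betabinom_logpmf(k, n, mu, phi)))
  }
  m <- 0
  eps <- 1e-4
  h <- 1 / sdre^2
  for (it in 1:6) {  # Newton on the log integrand
    fv <- fvec(c(m - eps, m, m + eps))
    g1 <- (fv[3] - fv[1]) / (2 * eps)
    h2 <- -(fv[3] - 2 * fv[2] + fv[1]) / eps^2
    if (!is.finite(h2) || h2 < 1e-8) h2 <- 1 / sdre^2
    step <- g1 / h2
    step <- max(min(step, 2 * sdre + 1), -2 * sdre - 1)
    m <- m + step
    h <- h2
    if (abs(step) < 1e-8) break
  }
  s <- 1 / sqrt(h)
  lg <- fvec(m + sqrt(2) * s * gh$x)
  log(sqrt(2) * s) + logsumexp(log(gh$w) + gh$x^2 + lg)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(x$family, "regression fit",
      if (!is.null(x$spec)) paste0("[", x$spec$label, "]"), "\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors,
               `Pr(>|z|)` = x$p_values)
  print(round(tab, 4))
  cat("dispersion phi:", format(x$dispersion, digits = 4),
      " RE variance:", format(x$random_intercept_variance, digits = 4), "\n")
  cat("logLik:", format(x$log_likelihood, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      " n:", x$n_obs,
      " converged:", x$converged, "\n")
  if (length(x$note)) cat("note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Population-level predicted fertilization proportions
#'
#' Inverse-logit of the fixed-effects linear predictor (random intercept at
#' zero). `newdata` must supply the raw covariates of the fitted model:
#' the proximity metric under its term name (e.g. `nn`), `night`
#' (`"n1"`/`"n2"`), `time_raw` (minutes since first release) for time terms,
#' `depth_class`, `dispersal_group`.
#'
#' @param fit A `bb_fit`.
#' @param newdata A data.frame of covariates.
#' @return Numeric vector of predicted proportions.
#' @export
predict_mean <- function(fit, newdata) {
  stopifnot(inherits(fit, "bb_fit"))
  if (is.null(fit$spec))
    stop("fit carries no model spec; cannot rebuild the design", call. = FALSE)
  X <- build_X(as.data.frame(newdata), fit$spec, fit$scaling)
  miss <- setdiff(colnames(X), names(fit$coefficients))
  if (length(miss))
    stop("fit lacks coefficient(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  drop(stats::plogis(X %*% fit$coefficients[colnames(X)]))
}

#' Reference fertilization-distance model
#'
#' The fitted best model for the studied *Acropora hyacinthus* population:
#' logit(mean fertilization) = -0.849 - 0.16 nn - 1.01 I(night 2), with
#' nearest-gravid-neighbour distance `nn` in metres. Used as the default
#' truth in the synthetic-data generator and as the source curve for the
#' cubic approximation.
#'
#' @param phi Beta-binomial precision attached to the fit (the generator
#'   default).
#' @return A `bb_fit` usable with [predict_mean()] and [fit_cubic()].
#' @export
reference_fit <- function(phi = 8) {
  structure(list(
    coefficients = c("(Intercept)" = -0.849, nn = -0.16, night2 = -1.01),
    standard_errors = c("(Intercept)" = 0.22, nn = 0.05, night2 = 0.30),
    p_values = NULL,
    dispersion = phi,
    random_intercept_variance = 0,
    log_likelihood = NA_real_,
    aic = NA_real_,
    n_obs = NA_integer_,
    n_par = 4L,
    converged = TRUE,
    family = "betabinomial",
    spec = model_spec("nn", night = TRUE),
    scaling = NULL,
    note = character()
  ), class = "bb_fit")
}

#' Fit a plain binomial regression
#'
#' The binomial-limit counterpart of [fit_betabinom_glm()] (no
#' overdispersion parameter), fitted with [stats::glm()] and wrapped in the
#' same result shape. Used for spawning-intensity and gamete-damage
#' comparisons where counts are small and overdispersion is not estimable.
#'
#' @inheritParams fit_betabinom_glm
#' @return A `bb_fit` with `family = "binomial"` and `dispersion = Inf`.
#' @export
fit_binomial_glm <- function(design, k = NULL, n = NULL) {
  if (inherits(design, "bb_design")) {
    X <- design$X; k <- design$k; n <- design$n
    spec <- design$spec; scaling <- design$scaling
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    spec <- NULL; scaling <- NULL
  }
  g <- stats::glm(cbind(k, n - k) ~ X - 1, family = stats::binomial())
  beta <- stats::setNames(stats::coef(g), colnames(X))
  se <- stats::setNames(sqrt(diag(stats::vcov(g))), colnames(X))
  structure(list(
    coefficients = beta,
    standard_errors = se,
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    dispersion = Inf,
    random_intercept_variance = 0,
    log_likelihood = as.numeric(stats::logLik(g)),
    aic = stats::AIC(g),
    n_obs = length(k),
    n_par = ncol(X),
    converged = g$converged,
    family = "binomial",
    spec = spec,
    scaling = scaling,
    note = character()
  ), class = "bb_fit")
}

#' Compare candidate fertilization-success models by AIC
#'
#' Fits every candidate [model_spec()] to the same samples and returns a
#' comparison table sorted by ascending AIC, one row per model with its
#' coefficient estimates, standard errors and Wald p-values. Non-converged
#' fits are flagged but still listed. The fitted objects are attached as
#' attribute `"fits"`.
#'
#' @param specs List of [model_spec()] objects (>= 2).
#' @inheritParams build_design
#' @param random_intercept Override the specs' random-intercept settings
#'   (`NULL` = honour each spec).
#' @return A `data.frame` of class `model_comparison`.
#' @export
compare_models <- function(specs, samples, metrics, events = NULL,
                           colonies = NULL, random_intercept = NULL) {
  if (length(specs) < 2)
    stop("configuration error: need at least two candidate models",
         call. = FALSE)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "label")
  fits <- lapply(specs, function(sp) {
    d <- build_design(samples, metrics, events, sp, colonies)
    fit_betabinom_glm(d, random_intercept = random_intercept)
  })
  fmt_terms <- function(f) {
    nm <- setdiff(names(f$coefficients), "(Intercept)")
    paste(sprintf("%s = %.3g (%.2g)", nm, f$coefficients[nm],
                  f$standard_errors[nm]), collapse = "; ")
  }
  fmt_p <- function(f) {
    nm <- setdiff(names(f$coefficients), "(Intercept)")
    paste(sprintf("%.3g", f$p_values[nm]), collapse = "; ")
  }
  tab <- data.frame(
    model = names(specs),
    proximity = vapply(specs, `[[`, character(1), "proximity"),
    night = vapply(specs, `[[`, logical(1), "night"),
    other_fixed = vapply(specs, function(sp)
      paste(c(if (sp$time_quadratic) "time", if (sp$depth) "depth",
              if (sp$dispersal) "dispersal"), collapse = "+"),
      character(1)),
    coefficients = vapply(fits, fmt_terms, character(1)),
    p = vapply(fits, fmt_p, character(1)),
    intercept = vapply(fits, function(f) f$coefficients[["(Intercept)"]],
                       numeric(1)),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aic)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Aligned-text rendering of a model comparison
#'
#' @param tab A [compare_models()] table.
#' @return Character vector of lines.
#' @export
format_model_comparison <- function(tab) {
  df <- as.data.frame(tab)[c("model", "night", "other_fixed",
                             "coefficients", "p", "aic", "converged")]
  df$aic <- sprintf("%.1f", df$aic)
  utils::capture.output(print(df, right = FALSE, row.names = FALSE))
}

#' Randomised-quantile residuals for a beta-binomial fit
#'
#' For each observation draws a uniform point between the fitted CDF just
#' below and at the observed count and maps it through the standard-normal
#' quantile function; well-specified models give standard-normal residuals,
#' inspected externally via a QQ plot.
#'
#' @param fit A `bb_fit`.
#' @param design The `bb_design` the model was fitted to.
#' @param seed Seed for the uniform jitter.
#' @return data.frame with columns `colony_id`, `residual`.
#' @export
quantile_residuals <- function(fit, design, seed = 1L) {
  stopifnot(inherits(design, "bb_design"))
  set.seed(seed)
  mu <- drop(stats::plogis(design$X %*%
                             fit$coefficients[colnames(design$X)]))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  res <- vapply(seq_along(design$k), function(i) {
    ks <- 0:design$n[i]
    pmf <- exp(betabinom_logpmf(ks, design$n[i], mu[i], fit$dispersion))
    cdf <- cumsum(pmf) / sum(pmf)
    hi <- cdf[design$k[i] + 1]
    lo <- if (design$k[i] == 0) 0 else cdf[design$k[i]]
    stats::qnorm(stats::runif(1, lo, hi))
  }, numeric(1))
  data.frame(colony_id = as.character(design$colony), residual = res,
             stringsAsFactors = FALSE)
}
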