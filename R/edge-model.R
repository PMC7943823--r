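#' Candidate models for canopy height change
#'
#' The candidate set compares purely linear predictors against the
#' asymptotic edge-effect form `delta = a - b * exp(-c * D_edge)`, where the
#' plateau `a` is a linear function of TPI and initial canopy height
#' (optionally with TCH x TPI and TCH x D interactions) and the exponential
#' term captures the saturating influence of distance from the plantation
#' edge.
#'
#' @param name model name.
#' @param linear_terms character subset of `c("tpi", "tch_2014", "d_edge",
#'   "tch_tpi", "tch_d")` entering the linear predictor (the intercept is
#'   implicit).
#' @param edge logical: include the asymptotic `- b exp(-c D)` component.
#' @return an object of class `edge_model_spec`.
#' @export
model_spec <- function(name, linear_terms = c("tpi", "tch_2014"),
                       edge = TRUE) {
  allowed <- c("tpi", "tch_2014", "d_edge", "tch_tpi", "tch_d")
  if (!all(linear_terms %in% allowed))
    stop("unknown linear term(s): ",
         paste(setdiff(linear_terms, allowed), collapse = ", "))
  if (anyDuplicated(linear_terms)) stop("duplicated linear terms")
  par_names <- c("beta0", paste0("beta_", sub("2014", "", linear_terms)))
  par_names <- sub("beta_tch_$", "beta_tch", par_names)
  if (edge) par_names <- c(par_names, "b", "c")
  structure(list(name = name, linear_terms = linear_terms, edge = edge,
                 par_names = par_names),
            class = "edge_model_spec")
}

#' @describeIn model_spec The default candidate set: linear, linear with a
#'   linear distance term, the asymptotic edge model, and the asymptotic
#'   model with both interactions.
#' @export
build_candidates <- function() {
  list(
    linear = model_spec("linear", c("tpi", "tch_2014"), edge = FALSE),
    linear_edge = model_spec("linear_edge", c("tpi", "tch_2014", "d_edge"),
                             edge = FALSE),
    asymptotic = model_spec("asymptotic", c("tpi", "tch_2014"), edge = TRUE),
    asymptotic_interactions = model_spec(
      "asymptotic_interactions",
      c("tpi", "tch_2014", "tch_tpi", "tch_d"), edge = TRUE))
}

# design matrix of the linear predictor (intercept first)
spec_design <- function(spec, table) {
  cols <- list(`(Intercept)` = rep(1, nrow(table)))
  for (term in spec$linear_terms)
    cols[[term]] <- switch(term,
      tpi = table$tpi,
      tch_2014 = table$tch_2014,
      d_edge = table$d_edge,
      tch_tpi = table$tch_2014 * table$tpi,
      tch_d = table$tch_2014 * table$d_edge)
  X <- do.call(cbind, cols)
  colnames(X) <- spec$par_names[seq_len(ncol(X))]
  X
}

# Gaussian ML log-likelihood from a residual sum of squares
gaussian_loglik <- function(rss, n) {
  sigma2 <- rss / n
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' AIC from parameter count and log-likelihood
#'
#' `AIC = 2k - 2 lnL`.
#'
#' @param k number of estimated parameters (including the residual variance
#'   and, for spatial fits, the correlogram range).
#' @param log_lik maximized log-likelihood.
#' @return AIC.
#' @export
aic_value <- function(k, log_lik) 2 * k - 2 * log_lik

new_edge_fit <- function(spec, coefficients, vcov, rss, n, method,
                         rho = NA_real_, sse_path = numeric(0),
                         extra_k = 1, log_det = 0, row_signature = NA_real_) {
  log_lik <- gaussian_loglik(rss, n) - log_det
  k <- length(coefficients) + extra_k
  structure(list(spec = spec, coefficients = coefficients, vcov = vcov,
                 sigma = sqrt(rss / max(1, n - length(coefficients))),
                 rss = rss, n = n, logLik = log_lik, k = k,
                 aic = aic_value(k, log_lik), method = method, rho = rho,
                 sse_path = sse_path, row_signature = row_signature),
            class = "edge_model_fit")
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat(sprintf("<edge_model_fit> %s (%s), n = %d\n", x$spec$name, x$method,
              x$n))
  print(round(x$coefficients, 5))
  cat(sprintf("  sigma = %.4f, logLik = %.1f, AIC = %.1f", x$sigma,
              x$logLik, x$aic))
  if (is.finite(x$rho)) cat(sprintf(", correlogram range = %.1f m", x$rho))
  cat("\n")
  invisible(x)
}

# eta, and Jacobian wrt (beta, b, c) for an edge spec
edge_eta <- function(theta, X, D, edge) {
  p_lin <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p_lin)])
  if (edge) {
    b <- theta[p_lin + 1]; cc <- theta[p_lin + 2]
    eta <- eta - b * exp(-cc * D)
  }
  eta
}

edge_jacobian <- function(theta, X, D) {
  p_lin <- ncol(X)
  b <- theta[p_lin + 1]; cc <- theta[p_lin + 2]
  E <- exp(-cc * D)
  cbind(X, -E, b * D * E)
}

# Damped (Levenberg) Gauss-Newton for the edge model on possibly whitened
# data. `whiten` maps a vector to the decorrelated scale (identity for NLS).
# The decay rate is optimized on the log scale to stay positive. Returns the
# accepted-step SSE path for the monotonicity assertion.
gauss_newton_edge <- function(y, X, D, theta0, whiten = identity,
                              max_iter = 200, tol = 1e-12) {
  p_lin <- ncol(X)
  theta <- theta0
  yw <- whiten(y)
  sse_of <- function(th) {
    r <- yw - whiten(edge_eta(th, X, D, edge = TRUE))
    sum(r^2)
  }
  sse <- sse_of(theta)
  path <- sse
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- edge_jacobian(theta, X, D)
    # chain rule for log(c): d eta/d log c = c * d eta/d c
    J[, p_lin + 2] <- J[, p_lin + 2] * theta[p_lin + 2]
    Jw <- apply(J, 2, whiten)
    rw <- yw - whiten(edge_eta(theta, X, D, edge = TRUE))
    g <- crossprod(Jw, rw)
    H <- crossprod(Jw)
    improved <- FALSE
    for (try in 1:12) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta
        cand[seq_len(p_lin + 1)] <- theta[seq_len(p_lin + 1)] +
          step[seq_len(p_lin + 1)]
        cand[p_lin + 2] <- theta[p_lin + 2] * exp(step[p_lin + 2])
        sse_new <- sse_of(cand)
        if (is.finite(sse_new) && sse_new <= sse) {
          theta <- cand
          improved <- TRUE
          lambda <- max(lambda / 3, 1e-12)
          conv <- (sse - sse_new) <= tol * (1 + sse)
          sse <- sse_new
          path <- c(path, sse)
          if (conv) return(list(theta = theta, sse = sse, path = path,
                                converged = TRUE, iter = it))
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!improved)
      return(list(theta = theta, sse = sse, path = path, converged = TRUE,
                  iter = it))
  }
  list(theta = theta, sse = sse, path = path, converged = FALSE,
       iter = max_iter)
}

#' Fit a candidate model by (nonlinear) least squares
#'
#' Linear candidates are solved exactly by ordinary least squares. The
#' asymptotic candidates are fitted by damped Gauss-Newton with an analytic
#' Jacobian, multi-started over a grid of decay rates; for each starting
#' rate the remaining coefficients start at their profiled linear
#' least-squares solution, and the best converged start (lowest residual sum
#' of squares) is kept. The decay rate is optimized on the log scale so it
#' stays positive.
#'
#' @param spec an [model_spec()].
#' @param table a pixel table; only analysis rows (empty `excluded_by`) are
#'   used.
#' @param c_starts starting grid for the decay rate (per metre).
#' @return an `edge_model_fit` with coefficients, covariance, ML
#'   log-likelihood and AIC (`k` counts the residual variance).
#' @export
fit_nls <- function(spec, table, c_starts = c(0.001, 0.005, 0.02)) {
  rows <- analysis_rows(table)
  rows <- rows[stats::complete.cases(
    rows[, c("delta_tch", "tpi", "tch_2014", "d_edge")]), , drop = FALSE]
  p <- length(spec$par_names)
  if (nrow(rows) < 10 * p)
    stop("need at least ", 10 * p, " rows to fit ", spec$name)
  y <- rows$delta_tch
  X <- spec_design(spec, rows)
  sig <- sum(y) + nrow(rows)
  if (!spec$edge) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    XtXinv <- chol2inv(chol(crossprod(X)))
    vc <- XtXinv * rss / (nrow(rows) - ncol(X))
    dimnames(vc) <- list(spec$par_names, spec$par_names)
    cf <- stats::setNames(fit$coefficients, spec$par_names)
    return(new_edge_fit(spec, cf, vc, rss, nrow(rows), "nls",
                        row_signature = sig))
  }
  D <- rows$d_edge
  best <- NULL
  for (c0 in c_starts) {
    E <- exp(-c0 * D)
    st <- stats::lm.fit(cbind(X, -E), y)$coefficients
    if (st[ncol(X) + 1] <= 0) st[ncol(X) + 1] <- diff(range(y)) / 2
    theta0 <- c(st, c0)
    res <- gauss_newton_edge(y, X, D, theta0)
    if (is.null(best) || res$sse < best$sse) best <- res
  }
  if (is.null(best) || !all(is.finite(best$theta)))
    stop("nonlinear least squares failed to converge from all starts")
  theta <- stats::setNames(best$theta, spec$par_names)
  J <- edge_jacobian(theta, X, D)
  H <- crossprod(J)
  vc <- tryCatch(chol2inv(chol(H)) * best$sse / (nrow(rows) - p),
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(spec$par_names, spec$par_names)
  new_edge_fit(spec, theta, vc, best$sse, nrow(rows), "nls",
               sse_path = best$path, row_signature = sig)
}

#' Fit with an exponential spatial correlation structure
#'
#' Generalized least squares with residual correlation
#' `exp(-d_ij / rho)` between pixels, all parameters by maximum likelihood:
#' the residual variance is profiled out, the mean-function coefficients are
#' obtained by Gauss-Newton on Cholesky-whitened data for each candidate
#' range, and the range itself by golden-section search on the profiled
#' log-likelihood over `rho_interval` (log scale). No nugget by default; a
#' `nugget` fraction in [0, 1) mixes in uncorrelated variance.
#'
#' @param spec an [model_spec()].
#' @param table pixel table (needs `x`, `y`); at most `n_max` analysis rows
#'   (dense covariance algebra).
#' @param rho fix the correlogram range (m) instead of estimating it.
#' @param rho_interval search interval for the range (m).
#' @param nugget uncorrelated variance fraction (default 0).
#' @param n_max guard on the dense-matrix problem size.
#' @return an `edge_model_fit` with `rho` set; `k` counts the coefficients,
#'   the variance and (when estimated) the range.
#' @export
fit_gls_spatial <- function(spec, table, rho = NULL,
                            rho_interval = c(1, 1000), nugget = 0,
                            n_max = 6000) {
  rows <- analysis_rows(table)
  rows <- rows[stats::complete.cases(
    rows[, c("delta_tch", "tpi", "tch_2014", "d_edge", "x", "y")]), ,
    drop = FALSE]
  n <- nrow(rows)
  if (n > n_max) stop("spatial GLS limited to ", n_max,
                      " rows (dense covariance); subsample first")
  p <- length(spec$par_names)
  if (n < 10 * p) stop("need at least ", 10 * p, " rows")
  if (!spec$edge) stop("spatial GLS is implemented for the asymptotic spec")
  y <- rows$delta_tch
  X <- spec_design(spec, rows)
  D <- rows$d_edge
  dmat <- as.matrix(stats::dist(cbind(rows$x, rows$y)))
  sig <- sum(y) + n

  nls_fit <- fit_nls(spec, rows)
  theta_warm <- nls_fit$coefficients

  eval_rho <- function(r, theta_start) {
    C <- (1 - nugget) * exp(-dmat / r)
    diag(C) <- 1
    R <- NULL
    for (jit in c(0, 1e-8, 1e-6)) {
      R <- tryCatch(chol(C + diag(jit, n)), error = function(e) NULL)
      if (!is.null(R)) break
    }
    if (is.null(R)) stop("Cholesky factorization failed at range ", r)
    whiten <- function(v) backsolve(R, v, transpose = TRUE)
    gn <- gauss_newton_edge(y, X, D, theta_start, whiten = whiten)
    log_det <- sum(log(diag(R)))
    ll <- gaussian_loglik(gn$sse, n) - log_det
    list(ll = ll, gn = gn, R = R, whiten = whiten, log_det = log_det)
  }

  if (is.null(rho)) {
    # golden-section on log(rho)
    gr <- (sqrt(5) - 1) / 2
    lo <- log(rho_interval[1]); hi <- log(rho_interval[2])
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- eval_rho(exp(x1), theta_warm); f2 <- eval_rho(exp(x2), theta_warm)
    for (i in 1:25) {
      if (hi - lo < 0.02) break
      if (f1$ll > f2$ll) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo)
        f1 <- eval_rho(exp(x1), f2$gn$theta)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo)
        f2 <- eval_rho(exp(x2), f1$gn$theta)
      }
    }
    if (f1$ll > f2$ll) { rho_hat <- exp(x1); ev <- f1 }
    else { rho_hat <- exp(x2); ev <- f2 }
    extra_k <- 2
  } else {
    rho_hat <- rho
    ev <- eval_rho(rho, theta_warm)
    extra_k <- 1
  }
  theta <- stats::setNames(ev$gn$theta, spec$par_names)
  J <- edge_jacobian(theta, X, D)
  Jw <- apply(J, 2, ev$whiten)
  vc <- tryCatch(chol2inv(chol(crossprod(Jw))) * ev$gn$sse / (n - p),
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(spec$par_names, spec$par_names)
  new_edge_fit(spec, theta, vc, ev$gn$sse, n, "gls", rho = rho_hat,
               sse_path = ev$gn$path, extra_k = extra_k,
               log_det = ev$log_det, row_signature = sig)
}

#' Select the best candidate by AIC
#'
#' @param fits list of `edge_model_fit`s on the identical rows.
#' @return the minimum-AIC fit, with the comparison table (name, k, logLik,
#'   AIC, delta AIC) attached as attribute `"aic_table"`.
#' @export
select_by_aic <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare")
  sigs <- vapply(fits, function(f) f$row_signature, numeric(1))
  if (max(abs(sigs - sigs[1])) > 1e-6 * (1 + abs(sigs[1])))
    stop("fits were made on differing row sets; AIC is not comparable")
  aics <- unname(vapply(fits, function(f) f$aic, numeric(1)))
  tab <- tibble::tibble(
    name = unname(vapply(fits, function(f) f$spec$name, character(1))),
    k = unname(vapply(fits, function(f) f$k, numeric(1))),
    logLik = unname(vapply(fits, function(f) f$logLik, numeric(1))),
    aic = aics, delta_aic = aics - min(aics))
  best <- fits[[which.min(aics)]]
  attr(best, "aic_table") <- tab[order(tab$aic), ]
  best
}

#' Subset-permutation ensemble of model fits
#'
#' Repeatedly fits the model to random pixel subsets to measure the
#' stability of the coefficients with subset size. Each repetition draws one
#' random permutation of the analysis rows and uses its first 3000/4000/5000
#' elements, so subsets are nested within a repetition (a common-random-
#' number device that sharpens the size comparison) and independent across
#' repetitions. Per size the per-parameter mean, coefficient of variation
#' (CV% = 100 sd/|mean|) and median are reported.
#'
#' @param table pixel table.
#' @param sizes subset sizes (default 3000, 4000, 5000).
#' @param reps repetitions per size (default 24).
#' @param seed integer seed governing all subset draws.
#' @param spec model to fit (default the asymptotic edge model).
#' @param method `"nls"` (default) or `"gls"` (honouring the spatial fit's
#'   size contract).
#' @param ... passed to the fitting function.
#' @return object of class `edge_ensemble`: per size a list with `params`
#'   (reps x p matrix), `mean`, `sd`, `cv_pct`, `median`, `se` and the
#'   repetition seeds.
#' @export
subset_ensemble <- function(table, sizes = c(3000, 4000, 5000), reps = 24,
                            seed = 1, spec = build_candidates()$asymptotic,
                            method = c("nls", "gls"), ...) {
  method <- match.arg(method)
  rows <- analysis_rows(table)
  n <- nrow(rows)
  if (any(sizes > n)) stop("subset size exceeds available rows (", n, ")")
  fit_fun <- if (method == "nls") fit_nls else fit_gls_spatial
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, reps)
  p <- length(spec$par_names)
  params <- lapply(sizes, function(s) matrix(NA_real_, reps, p,
    dimnames = list(NULL, spec$par_names)))
  names(params) <- as.character(sizes)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    perm <- sample.int(n)
    for (si in seq_along(sizes)) {
      idx <- perm[seq_len(sizes[si])]
      fit <- fit_fun(spec, rows[idx, , drop = FALSE], ...)
      params[[si]][r, ] <- fit$coefficients
    }
  }
  out <- lapply(seq_along(sizes), function(si) {
    m <- params[[si]]
    mu <- colMeans(m); sdv <- apply(m, 2, stats::sd)
    list(subset_size = sizes[si], n_reps = reps, params = m, mean = mu,
         sd = sdv, cv_pct = 100 * sdv / abs(mu),
         median = apply(m, 2, stats::median), se = sdv / sqrt(reps),
         seeds = rep_seeds)
  })
  names(out) <- as.character(sizes)
  structure(out, class = "edge_ensemble", spec = spec, method = method,
            n_total = n)
}

#' @export
print.edge_ensemble <- function(x, ...) {
  cat(sprintf("<edge_ensemble> %s fits, %d repetitions, %d total rows\n",
              attr(x, "method"), x[[1]]$n_reps, attr(x, "n_total")))
  for (s in names(x)) {
    cat(sprintf("  size %s: median ", s))
    cat(paste(sprintf("%s=%.4g", names(x[[s]]$median), x[[s]]$median),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample-size-corrected confidence intervals
#'
#' Confidence intervals estimated on an n-pixel subset are shrunk to the
#' full N-pixel dataset: `CI_corrected = CI_model * sqrt(n / N)` about the
#' point estimate.
#'
#' @param fit an `edge_model_fit`.
#' @param n subset size used for fitting.
#' @param N full dataset size (`n <= N`).
#' @param level confidence level (default 0.95).
#' @return tibble with estimate, model CI and corrected CI per parameter.
#' @export
corrected_intervals <- function(fit, n, N, level = 0.95) {
  if (n <= 0 || n > N) stop("need 0 < n <= N")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))
  hw <- z * se
  f <- sqrt(n / N)
  tibble::tibble(parameter = names(fit$coefficients),
                 estimate = unname(fit$coefficients),
                 lower_model = unname(fit$coefficients - hw),
                 upper_model = unname(fit$coefficients + hw),
                 lower_corrected = unname(fit$coefficients - hw * f),
                 upper_corrected = unname(fit$coefficients + hw * f),
                 scale_factor = f)
}

#' Predict canopy height change
#'
#' `delta = beta0 + beta_tpi TPI + beta_tch TCH + [interactions] -
#' b exp(-c D)`, with an optional delta-method confidence band when a
#' coefficient covariance is supplied.
#'
#' @param params named coefficient vector (`beta0`, `beta_tpi`, `beta_tch`,
#'   optional `beta_tch_tpi`, `beta_tch_d`, and `b`, `c`).
#' @param tpi,tch_2014,d_edge predictor values (vectorized; `d_edge >= 0`).
#' @param vcov optional coefficient covariance for the confidence band.
#' @param level confidence level.
#' @param ci_scale optional extra scaling of the CI half-width (e.g.
#'   `sqrt(n/N)` for the full-dataset correction).
#' @return numeric vector of predictions, or a tibble with `pred`, `lower`,
#'   `upper` when `vcov` is given.
#' @export
predict_delta_tch <- function(params, tpi, tch_2014, d_edge, vcov = NULL,
                              level = 0.95, ci_scale = 1) {
  if (any(d_edge < 0, na.rm = TRUE)) stop("d_edge must be non-negative")
  k <- length(tpi); stopifnot(length(tch_2014) %in% c(1, k) || k == 1)
  df <- data.frame(tpi = tpi, tch_2014 = tch_2014, d_edge = d_edge)
  g <- function(nm) if (nm %in% names(params)) params[[nm]] else 0
  E <- exp(-g("c") * df$d_edge)
  pred <- g("beta0") + g("beta_tpi") * df$tpi + g("beta_tch") * df$tch_2014 +
    g("beta_tch_tpi") * df$tch_2014 * df$tpi +
    g("beta_tch_d") * df$tch_2014 * df$d_edge -
    g("b") * E
  if (is.null(vcov)) return(pred)
  grad <- sapply(names(params), function(nm) switch(nm,
    beta0 = rep(1, nrow(df)),
    beta_tpi = df$tpi,
    beta_tch = df$tch_2014,
    beta_tch_tpi = df$tch_2014 * df$tpi,
    beta_tch_d = df$tch_2014 * df$d_edge,
    b = -E,
    c = g("b") * df$d_edge * E))
  grad <- matrix(grad, nrow = nrow(df))
  se <- sqrt(pmax(0, rowSums((grad %*% vcov) * grad)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(pred = pred, lower = pred - z * se * ci_scale,
                 upper = pred + z * se * ci_scale)
}

#' Distance at which net canopy height change reaches zero
#'
#' For the asymptotic model the zero crossing is
#' `D0 = -ln(A / b) / c` with plateau `A = beta0 + beta_tpi TPI +
#' beta_tch TCH` (+ TCH x TPI interaction when present): defined when the
#' interior plateau is positive and the at-edge value negative
#' (`0 < A < b`); `NA` otherwise (no crossing).
#'
#' @param params named coefficients (as in [predict_delta_tch()]; a
#'   `beta_tch_d` interaction has no closed-form crossing and is rejected).
#' @param tpi,tch_2014 conditions (vectorized).
#' @return distance (m) or `NA` where no crossing exists.
#' @export
edge_penetration_distance <- function(params, tpi, tch_2014) {
  g <- function(nm) if (nm %in% names(params)) params[[nm]] else 0
  if (g("c") <= 0) stop("decay rate c must be positive")
  if (g("beta_tch_d") != 0)
    stop("no closed-form crossing with a TCH x D interaction")
  A <- g("beta0") + g("beta_tpi") * tpi + g("beta_tch") * tch_2014 +
    g("beta_tch_tpi") * tch_2014 * tpi
  b <- g("b")
  out <- ifelse(A > 0 & A < b, -log(A / b) / g("c"), NA_real_)
  unname(out)
}

#' Prediction curves for canopy scenarios
#'
#' Height-change predictions against distance from the edge for a grid of
#' initial canopy heights (default short, medium, tall: 5, 20, 35 m) and
#' topographic positions (default the valley and hilltop quantiles -8.2 and
#' 9.0), using the ensemble's median parameters with a corrected confidence
#' band from the across-repetition parameter covariance.
#'
#' @param ensemble an [subset_ensemble()] result (the largest size is used),
#'   or a named parameter vector (no band unless `vcov` supplied).
#' @param tch_set initial canopy heights (m).
#' @param tpi_set topographic position values.
#' @param d_grid distances from the edge (m).
#' @param N full dataset size for the `sqrt(n/N)` CI correction (defaults to
#'   the ensemble's total row count).
#' @param level confidence level.
#' @param vcov optional covariance when `ensemble` is a plain vector.
#' @return tibble with `tch_2014`, `tpi`, `d_edge`, `pred`, `lower`,
#'   `upper`.
#' @export
prediction_curves <- function(ensemble, tch_set = c(5, 20, 35),
                              tpi_set = c(-8.2, 9.0),
                              d_grid = seq(0, 1000, by = 10), N = NULL,
                              level = 0.95, vcov = NULL) {
  if (length(d_grid) == 0) stop("empty distance grid")
  if (inherits(ensemble, "edge_ensemble")) {
    top <- ensemble[[length(ensemble)]]
    params <- top$median
    vcov <- stats::cov(top$params)
    n_sub <- top$subset_size
    if (is.null(N)) N <- attr(ensemble, "n_total")
    ci_scale <- sqrt(n_sub / N)
  } else {
    params <- ensemble
    ci_scale <- 1
  }
  grid <- expand.grid(tch_2014 = tch_set, tpi = tpi_set, d_edge = d_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (is.null(vcov)) {
    pred <- predict_delta_tch(params, grid$tpi, grid$tch_2014, grid$d_edge)
    return(tibble::tibble(tch_2014 = grid$tch_2014, tpi = grid$tpi,
                          d_edge = grid$d_edge, pred = pred,
                          lower = NA_real_, upper = NA_real_))
  }
  pr <- predict_delta_tch(params, grid$tpi, grid$tch_2014, grid$d_edge,
                          vcov = vcov, level = level, ci_scale = ci_scale)
  tibble::tibble(tch_2014 = grid$tch_2014, tpi = grid$tpi,
                 d_edge = grid$d_edge, pred = pr$pred, lower = pr$lower,
                 upper = pr$upper)
}

#' Fit an exponential variogram to residuals
#'
#' Empirical semivariogram on binned pair distances (pairs subsampled for
#' large inputs), fitted with the exponential model
#' `gamma(h) = nugget + (sill - nugget) (1 - exp(-h / range))` by weighted
#' least squares (weights = pair counts). Used to check that simulated noise
#' honours its configured correlogram range.
#'
#' @param x,y coordinates (m).
#' @param values residual values.
#' @param max_dist largest pair distance used (m).
#' @param n_bins number of distance bins.
#' @param max_points subsample size for the pair computation.
#' @return list with `range`, `nugget`, `sill` and the binned variogram
#'   tibble.
#' @export
fit_exponential_variogram <- function(x, y, values, max_dist = 600,
                                      n_bins = 20, max_points = 3000) {
  n <- length(x)
  if (n > max_points) {
    keep <- sample.int(n, max_points)
    x <- x[keep]; y <- y[keep]; values <- values[keep]
    n <- max_points
  }
  dd <- stats::dist(cbind(x, y))
  gv <- stats::dist(cbind(values, 0))^2 / 2  # (vi - vj)^2 / 2 via dist trick
  ok <- dd <= max_dist & dd > 0
  h <- as.numeric(dd)[ok]; g <- as.numeric(gv)[ok]
  bins <- cut(h, breaks = seq(0, max_dist, length.out = n_bins + 1))
  emp <- tibble::tibble(
    h = tapply(h, bins, mean),
    gamma = tapply(g, bins, mean),
    n_pairs = as.integer(table(bins)))
  emp <- emp[!is.na(emp$gamma), ]
  obj <- function(par) {
    ng <- par[1]^2; sill <- ng + par[2]^2; rg <- exp(par[3])
    fitv <- ng + (sill - ng) * (1 - exp(-emp$h / rg))
    sum(emp$n_pairs * (emp$gamma - fitv)^2)
  }
  s0 <- sqrt(max(emp$gamma, na.rm = TRUE))
  op <- stats::optim(c(s0 / 2, s0, log(max_dist / 6)), obj,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  list(range = exp(op$par[3]), nugget = op$par[1]^2,
       sill = op$par[1]^2 + op$par[2]^2, variogram = emp)
}
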