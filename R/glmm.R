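# Random-intercept logistic mixed models (the multi-level models used for
# momentary pain), estimated by maximum likelihood with adaptive Gauss-Hermite
# quadrature. Observations i are nested in participants j; the model is
#
#   logit P(y_ij = 1 | u_j) = x_ij' gamma + u_j,   u_j ~ N(0, sigma_u^2)
#
# and the marginal likelihood integrates u_j out per participant.

# Map an arbitrary grouping vector to consecutive integers 1..J.
group_index <- function(group) {
  f <- factor(group)
  list(g = as.integer(f), J = nlevels(f), levels = levels(f))
}

# Per-group sums of x (length n) -> vector length J, in group order 1..J.
group_sum <- function(x, g, J) {
  out <- numeric(J)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Posterior modes and curvatures of the per-group random-effect density
# h_j(u) = sum_i log Bern(y_ij | logistic(eta0_ij + u)) + log phi(u; 0, s^2).
# Newton iterations, vectorised over groups; h_j is strictly concave.
posterior_modes <- function(y, eta0, g, J, sigma_u, tol = 1e-10, max_iter = 100L) {
  s2 <- sigma_u^2
  u <- numeric(J)
  for (it in seq_len(max_iter)) {
    eta <- eta0 + u[g]
    mu <- stats::plogis(eta)
    grad <- group_sum(y - mu, g, J) - u / s2
    hess <- -(group_sum(mu * (1 - mu), g, J) + 1 / s2)
    step <- grad / hess
    step <- pmax(pmin(step, 5), -5) # guard against overshoot at extreme eta
    u <- u - step
    if (max(abs(step)) < tol) break
  }
  eta <- eta0 + u[g]
  mu <- stats::plogis(eta)
  hess <- -(group_sum(mu * (1 - mu), g, J) + 1 / s2)
  list(mode = u, curv = -hess)
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Evaluates \eqn{\sum_j \log \int \prod_i \mathrm{Bern}(y_{ij} \mid
#' \mathrm{logistic}(x_{ij}'\gamma + u)) \, \phi(u; 0, \sigma_u^2)\, du},
#' each participant-level integral approximated by adaptive Gauss-Hermite
#' quadrature centred at the participant's posterior mode. When
#' `sigma_u = 0` the mixture degenerates and the ordinary logistic
#' log-likelihood is returned exactly.
#'
#' @param y binary outcome vector (0/1)
#' @param X design matrix (rows match `y`)
#' @param group participant identifier per row
#' @param gamma fixed-effect coefficients (length `ncol(X)`)
#' @param sigma_u random-intercept standard deviation (>= 0)
#' @param nodes number of quadrature nodes (default 25)
#' @return the marginal log-likelihood (scalar)
#' @export
marginal_loglik <- function(y, X, group, gamma, sigma_u, nodes = 25L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(gamma) == ncol(X), sigma_u >= 0)
  eta0 <- drop(X %*% gamma)
  bad <- which(!is.finite(eta0))
  if (length(bad))
    stop("non-finite linear predictor at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (sigma_u < 1e-10)
    return(sum(log_bernoulli_logit(y, eta0)))
  gi <- group_index(group)
  g <- gi$g; J <- gi$J
  pm <- posterior_modes(y, eta0, g, J, sigma_u)
  tau <- 1 / sqrt(pm$curv)
  gh <- gauss_hermite(nodes)
  A <- matrix(NA_real_, J, nodes)
  for (k in seq_len(nodes)) {
    uk <- pm$mode + sqrt(2) * tau * gh$nodes[k]
    etak <- eta0 + uk[g]
    A[, k] <- group_sum(log_bernoulli_logit(y, etak), g, J) +
      stats::dnorm(uk, 0, sigma_u, log = TRUE) +
      gh$nodes[k]^2 + log(gh$weights[k])
  }
  m <- apply(A, 1L, max)
  ll_j <- m + log(rowSums(exp(A - m))) + log(sqrt(2) * tau)
  sum(ll_j)
}

# Gradient of the marginal log-likelihood wrt (gamma, log sigma_u) by the
# Fisher identity: d/dtheta log L_j = E_posterior[d/dtheta log f_j(y, u)],
# with the posterior expectation taken on the same adaptive quadrature grid
# as the likelihood. (The node locations' own dependence on theta contributes
# only at the quadrature-error level, which is negligible at >= 25 nodes.)
marginal_score <- function(y, X, g, J, gamma, sigma_u, nodes = 25L) {
  p <- ncol(X)
  eta0 <- drop(X %*% gamma)
  if (sigma_u < 1e-10) {
    mu <- stats::plogis(eta0)
    return(c(drop(crossprod(X, y - mu)), 0))
  }
  pm <- posterior_modes(y, eta0, g, J, sigma_u)
  tau <- 1 / sqrt(pm$curv)
  gh <- gauss_hermite(nodes)
  A <- matrix(NA_real_, J, nodes)
  Gg <- array(0, c(J, nodes, p))
  Gs <- matrix(NA_real_, J, nodes)
  for (k in seq_len(nodes)) {
    uk <- pm$mode + sqrt(2) * tau * gh$nodes[k]
    etak <- eta0 + uk[g]
    resid <- y - stats::plogis(etak)
    A[, k] <- group_sum(log_bernoulli_logit(y, etak), g, J) +
      stats::dnorm(uk, 0, sigma_u, log = TRUE) +
      gh$nodes[k]^2 + log(gh$weights[k])
    for (c in seq_len(p)) Gg[, k, c] <- group_sum(resid * X[, c], g, J)
    Gs[, k] <- uk^2 / sigma_u^2 - 1
  }
  W <- exp(A - apply(A, 1L, max))
  P <- W / rowSums(W)
  grad <- numeric(p + 1L)
  for (c in seq_len(p)) grad[c] <- sum(P * Gg[, , c])
  grad[p + 1L] <- sum(P * Gs)
  grad
}

# Hessian of the negative log-likelihood at theta: central differences of the
# analytic score (symmetrised). More accurate and ~7x cheaper than
# second-differencing the likelihood itself.
num_hessian <- function(ngr, theta, h = 1e-5) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  hi <- pmax(abs(theta), 1) * h
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- hi[j]
    H[, j] <- (ngr(theta + e) - ngr(theta - e)) / (2 * hi[j])
  }
  (H + t(H)) / 2
}

#' Fit a random-intercept logistic mixed model
#'
#' Maximum likelihood via adaptive Gauss-Hermite quadrature (default 25
#' nodes). Predictor columns are internally standardised for optimisation and
#' the coefficients, standard errors and covariance mapped back to the
#' original scale, so reported effects are per raw unit of the predictor
#' (e.g. per ohm/m). Starting values are the ordinary logistic fit for the
#' fixed effects and sigma_u = 1. Wald standard errors come from the inverse
#' observed information at the optimum.
#'
#' @param y binary outcome (0/1); must contain both classes
#' @param X design matrix with named columns; an `(Intercept)` column of ones
#'   is expected for models with an intercept
#' @param group participant identifier per row
#' @param nodes quadrature nodes (default 25)
#' @param max_iter optimiser iteration cap
#' @param tol relative convergence tolerance
#' @return an object of class `kneebis_glmm` with elements `coefficients`,
#'   `se`, `z`, `p`, `odds_ratios`, `sigma_u2`, `loglik`, `vcov`,
#'   `converged`, `separation_flag`, `n_obs`, `n_groups`
#' @export
glmm_logit <- function(y, X, group, nodes = 25L, max_iter = 500L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot estimate", call. = FALSE)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  ones <- apply(X, 2L, function(v) all(v == 1))
  is_icpt <- logical(p)
  if ("(Intercept)" %in% colnames(X)) {
    is_icpt[match("(Intercept)", colnames(X))] <- TRUE
  } else if (any(ones)) {
    is_icpt[which(ones)[1L]] <- TRUE
  }
  constant <- apply(X, 2L, function(v) all(v == v[1L]))
  degen <- !is_icpt & constant
  if (any(degen))
    stop("degenerate predictor column(s): ",
         paste(colnames(X)[degen], collapse = ", "), call. = FALSE)

  # standardise non-intercept columns for the optimiser
  ctr <- ifelse(is_icpt, 0, colMeans(X))
  scl <- ifelse(is_icpt, 1, apply(X, 2L, stats::sd))
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")

  gi <- group_index(group)
  # starting values only; separation there is handled by the flagged final fit
  start_glm <- suppressWarnings(stats::glm.fit(Xs, y, family = stats::binomial()))
  theta0 <- c(pmax(pmin(start_glm$coefficients, 10), -10), 0) # log sigma_u = 0

  nll <- function(theta) {
    -marginal_loglik(y, Xs, gi$g, theta[seq_len(p)], exp(theta[p + 1L]),
                     nodes = nodes)
  }
  ngr <- function(theta) {
    -marginal_score(y, Xs, gi$g, gi$J, theta[seq_len(p)],
                    exp(theta[p + 1L]), nodes = nodes)
  }
  opt <- stats::optim(theta0, nll, gr = ngr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  theta <- opt$par
  # Newton polish to pin the optimum beyond BFGS's termination noise
  H <- num_hessian(ngr, theta)
  f_cur <- nll(theta)
  for (it in seq_len(8L)) {
    g <- ngr(theta)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- theta - step
    f_cand <- nll(cand)
    if (!is.finite(f_cand) || f_cand > f_cur + 1e-8) break
    theta <- cand
    f_cur <- f_cand
    if (max(abs(step)) < 1e-9) break
    H <- num_hessian(ngr, theta)
  }
  H <- num_hessian(ngr, theta)
  V_std <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1L, p + 1L))

  # map standardised-scale coefficients back: beta = T %*% beta_std
  gam_std <- theta[seq_len(p)]
  Tm <- diag(1 / scl, p, p)
  icpt <- which(is_icpt)[1L]
  if (!is.na(icpt)) Tm[icpt, ] <- ifelse(seq_len(p) == icpt, 1, -ctr / scl)
  gamma <- drop(Tm %*% gam_std)
  V <- Tm %*% V_std[seq_len(p), seq_len(p), drop = FALSE] %*% t(Tm)
  se <- sqrt(pmax(diag(V), 0))
  names(gamma) <- names(se) <- colnames(X)
  z <- gamma / se
  fit <- list(
    coefficients = gamma,
    se = se,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    odds_ratios = exp(gamma),
    sigma_u2 = unname(exp(2 * theta[p + 1L])),
    loglik = -f_cur,
    vcov = V,
    converged = opt$convergence == 0L,
    separation_flag = any(abs(gamma) > 15),
    n_obs = length(y),
    n_groups = gi$J,
    nodes = nodes
  )
  class(fit) <- "kneebis_glmm"
  fit
}

#' @export
print.kneebis_glmm <- function(x, ...) {
  cat("Random-intercept logistic mixed model (adaptive GHQ,",
      x$nodes, "nodes)\n")
  cat(sprintf("  n_obs = %d, n_groups = %d, logLik = %.3f, sigma_u^2 = %.3f\n",
              x$n_obs, x$n_groups, x$loglik, x$sigma_u2))
  tab <- data.frame(
    beta = round(x$coefficients, 4),
    `exp(beta)` = round(x$odds_ratios, 4),
    SE = round(x$se, 4),
    p = signif(x$p, 3),
    check.names = FALSE
  )
  print(tab)
  if (x$separation_flag) cat("  warning: possible quasi-separation\n")
  if (!x$converged) cat("  warning: optimiser did not converge\n")
  invisible(x)
}

#' Intraclass correlation for a binary-outcome null model
#'
#' Latent-threshold convention for dichotomous outcomes: the level-1 residual
#' variance is that of the standard logistic distribution, \eqn{\pi^2/3}, so
#' \eqn{\mathrm{ICC} = \sigma_u^2 / (\sigma_u^2 + \pi^2/3)}. The complementary
#' share `1 - ICC` is the within-person variance proportion.
#'
#' @param fit a `kneebis_glmm` fit from an intercept-only (null) model
#' @return the ICC (proportion in `[0, 1]`)
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "kneebis_glmm"))
  if (length(fit$coefficients) != 1L)
    stop("icc() is defined for the intercept-only null model", call. = FALSE)
  fit$sigma_u2 / (fit$sigma_u2 + pi^2 / 3)
}

#' Specify one model of the pain-prediction family
#'
#' `null` is intercept-only (used for the ICC); `model1` has Group, the
#' per-length impedance metric (PLZ) and its CV as main effects; `model2`
#' adds PLZ-by-Group and CV-by-Group interactions; `model3` is model 2
#' restricted to the OA subset, which removes all Group terms.
#'
#' @param name one of `"null"`, `"model1"`, `"model2"`, `"model3"`
#' @param metric `"r128"` (per-length resistance, 128 kHz) or `"x40"`
#'   (per-length reactance, 40 kHz)
#' @param configuration electrode configuration, `"long"` or `"trans"`
#' @param quadrature_nodes,max_iter,tol estimation controls
#' @return a `kneebis_model_spec` list
#' @export
model_spec <- function(name = c("null", "model1", "model2", "model3"),
                       metric = c("r128", "x40"),
                       configuration = c("long", "trans"),
                       quadrature_nodes = 25L, max_iter = 500L, tol = 1e-10) {
  name <- match.arg(name)
  metric <- match.arg(metric)
  configuration <- match.arg(configuration)
  spec <- list(name = name, metric = metric, configuration = configuration,
               subset = if (name == "model3") "OA_only" else "all",
               quadrature_nodes = as.integer(quadrature_nodes),
               max_iter = as.integer(max_iter), tol = tol)
  class(spec) <- "kneebis_model_spec"
  spec
}

# Assemble outcome/design/group for a spec from a reduced-metrics table
# (layout: participant_id, group, day, call, config, plr128_mean, plr128_cv,
#  plx40_mean, plx40_cv, pain).
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "kneebis_model_spec"))
  d <- data[data$config == spec$configuration, , drop = FALSE]
  if (spec$subset == "OA_only") d <- d[d$group == 1, , drop = FALSE]
  mcol <- if (spec$metric == "r128") "plr128_mean" else "plx40_mean"
  ccol <- if (spec$metric == "r128") "plr128_cv" else "plx40_cv"
  if (spec$name == "null") {
    d <- d[!is.na(d$pain), , drop = FALSE]
    X <- matrix(1, nrow(d), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    d <- d[!is.na(d$pain) & !is.na(d[[mcol]]) & !is.na(d[[ccol]]), , drop = FALSE]
    plz <- d[[mcol]]; cv <- d[[ccol]]; grp <- d$group
    X <- switch(spec$name,
      model1 = cbind(`(Intercept)` = 1, group = grp, plz = plz, cv = cv),
      model2 = cbind(`(Intercept)` = 1, group = grp, plz = plz, cv = cv,
                     `plz:group` = plz * grp, `cv:group` = cv * grp),
      model3 = cbind(`(Intercept)` = 1, plz = plz, cv = cv))
  }
  list(y = d$pain, X = X, group = d$participant_id, n = nrow(d))
}

#' Fit one model of the family to a reduced-metrics table
#'
#' @param spec a [model_spec()]
#' @param data reduced-metrics table as written by [reduce_study()] (columns
#'   `participant_id, group, day, call, config, plr128_mean, plr128_cv,
#'   plx40_mean, plx40_cv, pain`)
#' @return a `kneebis_glmm` fit with the spec attached as `$spec`
#' @export
fit_model <- function(spec, data) {
  des <- build_design(spec, data)
  fit <- glmm_logit(des$y, des$X, des$group, nodes = spec$quadrature_nodes,
                    max_iter = spec$max_iter, tol = spec$tol)
  fit$spec <- spec
  fit
}

#' Run the full model battery
#'
#' Models 1 and 2 are each fitted four ways — {per-length resistance at
#' 128 kHz, per-length reactance at 40 kHz} crossed with {longitudinal,
#' transverse} — giving 8 fits; model 3 is fitted the same four ways on the
#' OA subset, for 12 fits total. Fits are labelled
#' `<model>_<metric>_<configuration>`.
#'
#' @param data reduced-metrics table (see [fit_model()])
#' @param nodes quadrature nodes for every fit
#' @return a named list of `kneebis_glmm` fits, class `kneebis_model_family`
#' @export
run_model_family <- function(data, nodes = 25L) {
  fits <- list()
  for (model in c("model1", "model2", "model3")) {
    for (metric in c("r128", "x40")) {
      for (config in c("long", "trans")) {
        spec <- model_spec(model, metric, config, quadrature_nodes = nodes)
        key <- paste(model, metric, config, sep = "_")
        fits[[key]] <- fit_model(spec, data)
      }
    }
  }
  class(fits) <- "kneebis_model_family"
  fits
}

#' Tabulate a model battery in report form
#'
#' One row per (model, metric, configuration, term) with the coefficient,
#' odds ratio, Wald SE and p-value, mirroring the conventional
#' beta (Exp.) / SE / p layout. The number of Wald tests performed is attached
#' as attribute `n_tests` (no multiplicity correction is applied).
#'
#' @param x a `kneebis_model_family`
#' @param ... unused
#' @return a data.frame
#' @export
as.data.frame.kneebis_model_family <- function(x, ...) {
  rows <- lapply(names(x), function(key) {
    f <- x[[key]]
    data.frame(model = f$spec$name, metric = f$spec$metric,
               config = f$spec$configuration,
               term = names(f$coefficients),
               beta = unname(f$coefficients),
               exp_beta = unname(f$odds_ratios),
               se = unname(f$se), p = unname(f$p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- sum(out$term != "(Intercept)")
  out
}

#' Fit the null (intercept-only) models and report ICCs
#'
#' One null model per electrode configuration; the binary-outcome ICC uses
#' the latent \eqn{\pi^2/3} residual convention (see [icc()]).
#'
#' @param data reduced-metrics table
#' @param nodes quadrature nodes
#' @return data.frame with columns `config`, `icc`, `within_person_share`,
#'   `sigma_u2`, `n_obs`
#' @export
fit_null_models <- function(data, nodes = 25L) {
  out <- lapply(c("long", "trans"), function(config) {
    fit <- fit_model(model_spec("null", configuration = config,
                                quadrature_nodes = nodes), data)
    data.frame(config = config, icc = icc(fit),
               within_person_share = 1 - icc(fit),
               sigma_u2 = fit$sigma_u2, n_obs = fit$n_obs)
  })
  do.call(rbind, out)
}
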