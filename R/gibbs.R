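# Gibbs sampler for Gaussian linear mixed models with any number of
# crossed random-effect families. Each family contributes z * u[g] to the
# linear predictor, where g maps rows to levels and z is a (possibly
# constant) covariate; levels within a family are iid Gaussian with a
# family-specific SD. Full conditionals for the effects and the fixed
# coefficients are Gaussian; the SDs are updated by univariate slice
# sampling, which accommodates Gamma and half-t priors alike.

# One-dimensional slice sampler (Neal 2003, stepping out + shrinkage).
slice1d <- function(logf, x0, w = 1, max_steps = 30L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

log_prior_sd <- function(sigma, prior) {
  switch(prior$kind,
    gamma = dgamma(sigma, shape = prior$shape, rate = prior$rate,
                   log = TRUE),
    half_t = dt(sigma / prior$scale, df = prior$df, log = TRUE) -
      log(prior$scale),
    flat = 0,
    abort(paste0("Unknown prior kind: ", prior$kind))
  )
}

# log posterior of log(sigma) for a family with L levels and effect
# sum-of-squares S (Jacobian of the log transform included).
logpost_scale <- function(theta, L, S, prior) {
  sigma <- exp(theta)
  if (!is.finite(sigma) || sigma < 1e-10) return(-Inf)
  -L * theta - S / (2 * sigma^2) + log_prior_sd(sigma, prior) + theta
}

#' Gibbs sampler for a crossed random-effects Gaussian model
#'
#' Low-level engine behind the MCMC ICC estimator and [fit_bml()].
#' Samples `y = X b + sum_f z_f u_f[g_f] + e` with iid Gaussian effects
#' per family and configurable priors on the family SDs; the residual SD
#' prior defaults to flat.
#'
#' @param y Numeric response.
#' @param X Fixed-effect design matrix (full column rank).
#' @param families Named list; each element a list with `index` (factor or
#'   integer level per row), `z` (covariate, scalar 1 or numeric per row)
#'   and `prior` (list with `kind` `"gamma"`/`"half_t"`/`"flat"` and its
#'   parameters).
#' @param resid_prior Prior for the residual SD (same format).
#' @param chains,warmup,draws Number of chains and post-warmup draws per
#'   chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param keep_effects Names of families whose realized effect draws are
#'   stored (memory scales with levels x draws).
#' @param sweeps Interweaving moves that improve mixing along the
#'   non-identified location directions of crossed designs. Each element is
#'   either `list(type = "fixed", family, col)` — resample the family mean
#'   jointly with the fixed coefficient `col` (requires `X[, col]` equal to
#'   the family covariate and a flat prior on the coefficient) — or
#'   `list(type = "family", child, parent, map)` — resample the shared
#'   location between a child family and its parent (`map` gives the
#'   parent level of each child level). Both are exact Gibbs updates of
#'   the reparameterized posterior, so the stationary distribution is
#'   unchanged.
#' @return List with matrices `scales` (draws x families, last column
#'   `sigma_e`), `beta`, `chain` (chain index per draw) and `effects`
#'   (named list of draw matrices, with level labels as columns).
#' @keywords internal
#' @export
gibbs_lmm <- function(y, X, families, resid_prior = list(kind = "flat"),
                      chains = 2, warmup = 400, draws = 800, seed = NULL,
                      keep_effects = character(), sweeps = list()) {
  n <- length(y)
  p <- ncol(X)
  fam_names <- names(families)
  stopifnot(!is.null(fam_names), all(nzchar(fam_names)))
  fams <- lapply(families, function(f) {
    idx <- as.integer(factor(f$index))
    lev <- levels(factor(f$index))
    z <- if (length(f$z) == 1L) rep(f$z, n) else f$z
    list(idx = idx, lev = lev, L = length(lev), z = z,
         sz2 = as.vector(rowsum(z^2, idx)), prior = f$prior)
  })
  names(fams) <- fam_names
  XtX <- crossprod(X)
  XtX_chol <- chol(XtX)
  qr_X <- qr(X)
  run_chain <- function(chain_id) {
    if (!is.null(seed)) {
      set.seed((as.integer(seed) + chain_id) %% .Machine$integer.max)
    }
    beta <- qr.coef(qr_X, y)
    us <- lapply(fams, function(f) numeric(f$L))
    sigma <- setNames(rep(max(sd(y) / 2, 1e-3), length(fams) + 1L),
                      c(fam_names, "sigma_e"))
    contrib <- lapply(fams, function(f) numeric(n))
    fit_r <- numeric(n)
    total <- warmup + draws
    sc_out <- matrix(NA_real_, draws, length(sigma),
                     dimnames = list(NULL, names(sigma)))
    beta_out <- matrix(NA_real_, draws, p,
                       dimnames = list(NULL, colnames(X)))
    eff_out <- lapply(setNames(keep_effects, keep_effects), function(nm)
      matrix(NA_real_, draws, fams[[nm]]$L,
             dimnames = list(NULL, fams[[nm]]$lev)))
    for (it in seq_len(total)) {
      xb <- drop(X %*% beta)
      se2 <- sigma["sigma_e"]^2
      for (fn in fam_names) {
        f <- fams[[fn]]
        r <- y - xb - (fit_r - contrib[[fn]])
        szr <- as.vector(rowsum(f$z * r, f$idx))
        prec <- f$sz2 / se2 + 1 / sigma[fn]^2
        mu <- (szr / se2) / prec
        u <- rnorm(f$L, mu, sqrt(1 / prec))
        us[[fn]] <- u
        new_contrib <- f$z * u[f$idx]
        fit_r <- fit_r - contrib[[fn]] + new_contrib
        contrib[[fn]] <- new_contrib
        S <- sum(u^2)
        th <- slice1d(function(t) logpost_scale(t, f$L, S, f$prior),
                      log(sigma[fn]))
        sigma[fn] <- exp(th)
      }
      # beta | rest
      r <- y - fit_r
      bhat <- qr.coef(qr_X, r)
      beta <- bhat + backsolve(XtX_chol,
                               rnorm(p)) * sigma["sigma_e"]
      xb <- drop(X %*% beta)
      # residual SD
      rss <- sum((y - xb - fit_r)^2)
      th <- slice1d(function(t) logpost_scale(t, n, rss, resid_prior),
                    log(sigma["sigma_e"]))
      sigma["sigma_e"] <- exp(th)
      # interweaving location sweeps (likelihood-invariant Gibbs moves)
      if (length(sweeps)) {
        for (sw in sweeps) {
          if (sw$type == "fixed") {
            u <- us[[sw$family]]
            L <- fams[[sw$family]]$L
            delta <- rnorm(1, mean(u), sigma[sw$family] / sqrt(L))
            us[[sw$family]] <- u - delta
            beta[sw$col] <- beta[sw$col] + delta
          } else {
            u <- us[[sw$child]]
            v <- us[[sw$parent]]
            sc2 <- sigma[sw$child]^2
            sp2 <- sigma[sw$parent]^2
            ssum <- as.vector(rowsum(u, sw$map))
            L_a <- as.vector(rowsum(rep(1, length(u)), sw$map))
            prec <- L_a / sc2 + 1 / sp2
            mu_d <- (ssum / sc2 - v / sp2) / prec
            delta <- rnorm(length(v), mu_d, sqrt(1 / prec))
            us[[sw$child]] <- u - delta[sw$map]
            us[[sw$parent]] <- v + delta
          }
        }
        for (fn in fam_names) {
          f <- fams[[fn]]
          contrib[[fn]] <- f$z * us[[fn]][f$idx]
        }
        fit_r <- Reduce(`+`, contrib)
      }
      if (it > warmup) {
        d <- it - warmup
        sc_out[d, ] <- sigma
        beta_out[d, ] <- beta
        for (nm in keep_effects) eff_out[[nm]][d, ] <- us[[nm]]
      }
    }
    list(scales = sc_out, beta = beta_out, effects = eff_out)
  }
  res <- lapply(seq_len(chains), run_chain)
  out <- list(
    scales = do.call(rbind, lapply(res, `[[`, "scales")),
    beta = do.call(rbind, lapply(res, `[[`, "beta")),
    chain = rep(seq_len(chains), each = draws),
    effects = if (length(keep_effects)) {
      setNames(lapply(keep_effects, function(nm)
        do.call(rbind, lapply(res, function(r) r$effects[[nm]]))),
        keep_effects)
    } else list(),
    families = lapply(fams, function(f) f[c("lev", "L")]),
    chains = chains, warmup = warmup, draws = draws
  )
  out
}

# Split-Rhat (potential scale reduction on half-chains).
split_rhat <- function(x, chain) {
  halves <- split(x, paste0(chain, "_",
                            stats::ave(seq_along(x), chain,
                                       FUN = function(i)
                                         as.integer(seq_along(i) >
                                                    length(i) / 2))))
  m <- length(halves)
  n <- min(lengths(halves))
  if (n < 2 || m < 2) return(NA_real_)
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_sum <- function(x, chain) {
  sum(vapply(split(x, chain), function(h)
    as.numeric(coda::effectiveSize(h)), numeric(1)))
}

mcmc_diagnostics <- function(draws_mat, chain) {
  purrr::map_dfr(colnames(draws_mat), function(p) {
    x <- draws_mat[, p]
    q <- quantile(x, c(0.05, 0.95))
    tail_ess <- min(ess_sum(as.numeric(x <= q[1]), chain),
                    ess_sum(as.numeric(x >= q[2]), chain))
    tibble(parameter = p,
           rhat = split_rhat(x, chain),
           ess_bulk = ess_sum(x, chain),
           ess_tail = tail_ess)
  })
}
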