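# Marginal maximum likelihood estimation of dichotomous item response models
# by EM (Bock-Aitkin expected counts on Gauss-Hermite grids). Four model
# kinds are supported:
#   unidimensional  P(x=1) = link(c + a_g * thetaG)
#   bifactor        P(x=1) = link(c + a_g * thetaG + a_s * theta_s), all
#                   factors orthogonal standard normal; the marginal
#                   likelihood uses the bi-factor dimension reduction
#                   (conditional on thetaG the specific factors are
#                   independent, so the integral is an outer 1-D quadrature
#                   over thetaG of per-factor inner 1-D quadratures)
#   second_order    P(x=1) = link(c + a * theta_s), theta_s = gamma_s * eta +
#                   sqrt(1 - gamma_s^2) * eps_s (same reduction over eta)
#   correlated      P(x=1) = link(c + a * theta_s), theta ~ N(0, R) with unit
#                   variances; tensor quadrature, limited to <= 3 factors
# Missing responses are skipped from the person product (MAR/ML).

#' Describe an item response model
#'
#' @param item_map tibble with columns `item` and `factor` mapping every item
#'   to exactly one specific factor (at least 3 items per factor).
#' @param model_kind one of `"bifactor"`, `"unidimensional"`, `"correlated"`,
#'   `"second_order"`.
#' @param general_factor_name label for the general factor.
#' @return A `bifactor_spec` list.
#' @export
bifactor_spec <- function(item_map,
                          model_kind = c("bifactor", "unidimensional",
                                         "correlated", "second_order"),
                          general_factor_name = "general") {
  model_kind <- match.arg(model_kind)
  item_map <- as_tibble(item_map)
  assert_that(all(c("item", "factor") %in% names(item_map)),
              "item_map needs columns item and factor")
  assert_that(!anyDuplicated(item_map$item),
              "every item must map to exactly one specific factor")
  n_per <- table(item_map$factor)
  assert_that(all(n_per >= 3),
              "each specific factor needs at least 3 items for identification")
  structure(list(item_map = item_map, model_kind = model_kind,
                 general_factor_name = general_factor_name,
                 factors = unique(item_map$factor)),
            class = "bifactor_spec")
}

# ---- internal helpers ------------------------------------------------------

# split an items tibble into response matrix + bookkeeping, aligned to a spec
irt_data <- function(items, spec) {
  item_cols <- setdiff(names(items), "id")
  assert_that(setequal(item_cols, spec$item_map$item),
              "items and spec$item_map must cover the same items")
  X <- as.matrix(items[spec$item_map$item])
  storage.mode(X) <- "double"
  assert_that(all(X %in% c(0, 1, NA)), "item responses must be 0, 1 or missing")
  list(X = X, ids = items$id,
       X1 = ifelse(is.na(X), 0, X),          # observed endorsements
       X0 = ifelse(is.na(X), 0, 1 - X),      # observed non-endorsements
       obs = 0 + !is.na(X),
       fac = spec$item_map$factor)
}

# exact weighted-logistic Newton M-step: maximize sum r*eta - n*log(1+e^eta)
# over beta for eta = D beta; returns capped (|slope| <= cap) estimates
newton_logistic <- function(D, r, n, start, cap = 8, tol = 1e-9, max_iter = 50) {
  beta <- start
  keep <- n > 0
  Dk <- D[keep, , drop = FALSE]; rk <- r[keep]; nk <- n[keep]
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Dk %*% beta)
    p <- plogis(eta)
    g <- crossprod(Dk, rk - nk * p)
    wgt <- pmax(nk * p * (1 - p), 1e-12)
    H <- crossprod(Dk * wgt, Dk)
    step <- tryCatch(solve(H, g), error = function(e) rep(0, length(beta)))
    beta <- beta + step
    beta[-1] <- pmin(pmax(beta[-1], -cap), cap)  # slope cap (Heywood guard)
    beta[1] <- pmin(pmax(beta[1], -30), 30)
    if (max(abs(step)) < tol) break
  }
  beta
}

start_intercepts <- function(X) {
  p <- colMeans(X, na.rm = TRUE)
  qlogis(pmin(pmax(p, 0.05), 0.95))
}

# ---- likelihood building blocks -------------------------------------------

# per-factor grid log-likelihood: n x (Qg*Qs) matrix, qs fastest within qg
factor_grid_loglik <- function(dat, idx, eta_grid) {
  # log probabilities computed on the log scale (stable at extreme nodes)
  lp1 <- plogis(eta_grid, log.p = TRUE)     # J_s x G
  lp0 <- plogis(-eta_grid, log.p = TRUE)
  dat$X1[, idx, drop = FALSE] %*% lp1 + dat$X0[, idx, drop = FALSE] %*% lp0
}

# bifactor-style marginal quantities for given per-factor eta grids.
# Returns Lbar per factor (n x Qg), person likelihood L, total loglik.
reduced_marginal <- function(dat, factors, eta_grids, idx_list, gq) {
  Q <- length(gq$x)
  Wmat <- kronecker(diag(Q), matrix(gq$w, ncol = 1))   # (Qg*Qs) x Qg
  E_list <- Lbar_list <- vector("list", length(factors))
  for (s in seq_along(factors)) {
    ll <- factor_grid_loglik(dat, idx_list[[s]], eta_grids[[s]])
    E_list[[s]] <- exp(ll)
    Lbar_list[[s]] <- E_list[[s]] %*% Wmat
  }
  P <- Reduce(`*`, Lbar_list)
  L <- as.vector(P %*% gq$w)
  list(E = E_list, Lbar = Lbar_list, P = P, L = L, loglik = sum(log(L)))
}

# expected counts for the items of factor s on its (qg, qs) grid
expected_counts <- function(dat, idx, E_s, Lbar_s, P, L, gq) {
  Q <- length(gq$x)
  R_s <- (P / Lbar_s) * rep(gq$w, each = nrow(P)) / L     # n x Qg
  post <- E_s * R_s[, rep(seq_len(Q), each = Q), drop = FALSE]
  post <- post * rep(rep(gq$w, times = Q), each = nrow(post))
  list(n = crossprod(post, dat$obs[, idx, drop = FALSE]),
       r = crossprod(post, dat$X1[, idx, drop = FALSE]),
       post = post)
}

# ---- response-pattern collapsing ------------------------------------------
# Persons sharing a response pattern on a factor's items contribute identical
# per-factor grid likelihoods, so the E-step runs on unique patterns and the
# per-person pieces are recovered by indexing. This makes the EM cost nearly
# independent of the sample size.

collapse_patterns <- function(dat, idx) {
  Xs <- dat$X[, idx, drop = FALSE]
  key <- apply(ifelse(is.na(Xs), "M", Xs), 1, paste, collapse = "")
  g <- match(key, unique(key))
  first <- which(!duplicated(g))[order(unique(g))]
  list(g = g,
       X1 = dat$X1[first, idx, drop = FALSE],
       X0 = dat$X0[first, idx, drop = FALSE],
       obs = dat$obs[first, idx, drop = FALSE])
}

# unique-pattern grid likelihood for one factor
pattern_grid_E <- function(pat, eta_grid) {
  exp(pat$X1 %*% plogis(eta_grid, log.p = TRUE) +
        pat$X0 %*% plogis(-eta_grid, log.p = TRUE))
}

# expected counts on the (qg, qs) grid from collapsed patterns:
# R_s (n x Qg) holds each person's outer-posterior weight, aggregated to
# pattern groups before the grid expansion.
pattern_counts <- function(pat, Eu, R_s, gq) {
  Q <- length(gq$x)
  Ragg <- rowsum(R_s, pat$g)
  post <- Eu * Ragg[, rep(seq_len(Q), each = Q), drop = FALSE]
  post <- post * rep(rep(gq$w, times = Q), each = nrow(post))
  list(n = crossprod(post, pat$obs), r = crossprod(post, pat$X1))
}

# ---- model-kind engines ----------------------------------------------------

em_unidimensional <- function(dat, gq, tol, max_iter, cap) {
  J <- ncol(dat$X)
  pat <- collapse_patterns(dat, seq_len(J))
  counts <- as.vector(table(pat$g))
  a <- rep(1, J); cc <- start_intercepts(dat$X)
  ll_trace <- numeric(0)
  converged <- FALSE; change <- NA_real_
  D <- cbind(1, gq$x)
  for (iter in seq_len(max_iter)) {
    eta <- matrix(cc, J, length(gq$x)) + outer(a, gq$x)
    Eu <- pattern_grid_E(pat, eta)
    Lu <- as.vector(Eu %*% gq$w)
    ll_trace <- c(ll_trace, sum(counts * log(Lu)))
    post <- Eu * rep(gq$w, each = nrow(Eu)) * (counts / Lu)
    Nq <- crossprod(post, pat$obs); Rq <- crossprod(post, pat$X1)
    old <- c(a, cc)
    for (j in seq_len(J)) {
      b <- newton_logistic(D, Rq[, j], Nq[, j], c(cc[j], a[j]), cap = cap)
      cc[j] <- b[1]; a[j] <- b[2]
    }
    if (a[1] < 0) a <- -a                     # sign anchor
    change <- max(abs(c(a, cc) - old))
    if (change < tol) { converged <- TRUE; break }
  }
  list(a_g = a, a_s = rep(0, J), c = cc, ll_trace = ll_trace,
       iterations = length(ll_trace), converged = converged, change = change)
}

# shared E-step scaffolding for the two reduced (outer x inner) kinds
reduced_em <- function(dat, factors, gq, tol, max_iter, make_eta, m_step) {
  Q <- length(gq$x)
  idx_list <- lapply(factors, function(f) which(dat$fac == f))
  pats <- lapply(idx_list, function(idx) collapse_patterns(dat, idx))
  Wmat <- kronecker(diag(Q), matrix(gq$w, ncol = 1))
  state <- NULL
  ll_trace <- numeric(0); converged <- FALSE; change <- NA_real_
  for (iter in seq_len(max_iter)) {
    Eu_list <- Lbar_list <- vector("list", length(factors))
    for (s in seq_along(factors)) {
      Eu <- pattern_grid_E(pats[[s]], make_eta(s, idx_list[[s]]))
      Eu_list[[s]] <- Eu
      Lbar_list[[s]] <- (Eu %*% Wmat)[pats[[s]]$g, , drop = FALSE]
    }
    P <- Reduce(`*`, Lbar_list)
    L <- as.vector(P %*% gq$w)
    ll_trace <- c(ll_trace, sum(log(L)))
    old <- param_vector <- NULL
    for (s in seq_along(factors)) {
      R_s <- (P / Lbar_list[[s]]) * rep(gq$w, each = nrow(P)) / L
      ec <- pattern_counts(pats[[s]], Eu_list[[s]], R_s, gq)
      m_step(s, idx_list[[s]], ec)
    }
    st <- environment(m_step)$snapshot()
    if (!is.null(state)) change <- max(abs(st - state))
    state <- st
    if (iter > 1 && change < tol) { converged <- TRUE; break }
  }
  list(ll_trace = ll_trace, iterations = length(ll_trace),
       converged = converged, change = change)
}

em_bifactor <- function(dat, factors, gq, tol, max_iter, cap) {
  J <- ncol(dat$X)
  Q <- length(gq$x)
  grid_qg <- rep(gq$x, each = Q); grid_qs <- rep(gq$x, times = Q)
  a_g <- rep(1, J); a_s <- rep(1, J); cc <- start_intercepts(dat$X)
  D <- cbind(1, grid_qg, grid_qs)
  make_eta <- function(s, idx) {
    matrix(cc[idx], length(idx), Q * Q) + outer(a_g[idx], grid_qg) +
      outer(a_s[idx], grid_qs)
  }
  snapshot <- function() c(a_g, a_s, cc)
  m_step <- function(s, idx, ec) {
    for (k in seq_along(idx)) {
      j <- idx[k]
      b <- newton_logistic(D, ec$r[, k], ec$n[, k],
                           c(cc[j], a_g[j], a_s[j]), cap = cap)
      cc[j] <<- b[1]; a_g[j] <<- b[2]; a_s[j] <<- b[3]
    }
  }
  res <- reduced_em(dat, factors, gq, tol, max_iter, make_eta, m_step)
  # sign anchors (likelihood-invariant reflections, applied once)
  for (f in factors) {
    idx <- which(dat$fac == f)
    if (a_s[idx[1]] < 0) a_s[idx] <- -a_s[idx]
  }
  if (a_g[1] < 0) a_g <- -a_g
  c(list(a_g = a_g, a_s = a_s, c = cc), res)
}

em_second_order <- function(dat, factors, gq, tol, max_iter, cap) {
  J <- ncol(dat$X)
  Q <- length(gq$x)
  grid_qg <- rep(gq$x, each = Q); grid_qs <- rep(gq$x, times = Q)
  a <- rep(1, J); cc <- start_intercepts(dat$X)
  gam <- rep(0.6, length(factors))
  t_grid <- function(g) g * grid_qg + sqrt(1 - g^2) * grid_qs
  make_eta <- function(s, idx) {
    matrix(cc[idx], length(idx), Q * Q) + outer(a[idx], t_grid(gam[s]))
  }
  snapshot <- function() c(a, cc, gam)
  m_step <- function(s, idx, ec) {
    D <- cbind(1, t_grid(gam[s]))
    for (k in seq_along(idx)) {
      j <- idx[k]
      b <- newton_logistic(D, ec$r[, k], ec$n[, k], c(cc[j], a[j]), cap = cap)
      cc[j] <<- b[1]; a[j] <<- b[2]
    }
    # conditional maximization over the higher-order loading gamma_s
    obj <- function(g) {
      tg2 <- t_grid(g)
      tot <- 0
      for (k in seq_along(idx)) {
        eta <- cc[idx[k]] + a[idx[k]] * tg2
        log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
        tot <- tot + sum(ec$r[, k] * eta - ec$n[, k] * log1pe)
      }
      tot
    }
    gam[s] <<- optimize(obj, c(-0.995, 0.995), maximum = TRUE)$maximum
  }
  res <- reduced_em(dat, factors, gq, tol, max_iter, make_eta, m_step)
  # sign anchors: flip each first-order factor so its anchor loading is
  # positive (reflecting eps_s and gamma_s together), then the higher-order
  # factor so gamma_1 is positive
  for (s in seq_along(factors)) {
    idx <- which(dat$fac == factors[s])
    if (a[idx[1]] < 0) { a[idx] <- -a[idx]; gam[s] <- -gam[s] }
  }
  if (gam[1] < 0) gam <- -gam
  c(list(a_g = a * gam[match(dat$fac, factors)],
         a_s = a * sqrt(1 - gam[match(dat$fac, factors)]^2),
         loading = a, gamma = setNames(gam, factors), c = cc), res)
}

em_correlated <- function(dat, factors, gq, tol, max_iter, cap) {
  K <- length(factors)
  assert_that(K <= 3,
              "correlated model kind supports at most 3 factors (tensor quadrature); use the second_order kind for more")
  J <- ncol(dat$X)
  Qc <- if (K <= 2) length(gq$x) else 15L
  gqc <- gauss_hermite_normal(Qc)
  z_grid <- as.matrix(expand.grid(rep(list(gqc$x), K)))
  w_grid <- apply(as.matrix(expand.grid(rep(list(gqc$w), K))), 1, prod)
  fac_idx <- match(dat$fac, factors)
  a <- rep(1, J); cc <- start_intercepts(dat$X)
  R <- diag(K)
  ll_trace <- numeric(0); converged <- FALSE; change <- NA_real_
  for (iter in seq_len(max_iter)) {
    Theta <- z_grid %*% chol(R)                    # rows: theta = t(chol(R)) z
    eta <- matrix(cc, J, nrow(Theta)) + a * t(Theta)[fac_idx, , drop = FALSE]
    ll_mat <- factor_grid_loglik(dat, seq_len(J), eta)
    E <- exp(ll_mat)
    L <- as.vector(E %*% w_grid)
    ll_trace <- c(ll_trace, sum(log(L)))
    post <- E * rep(w_grid, each = nrow(E)) / L
    Nq <- crossprod(post, dat$obs); Rq <- crossprod(post, dat$X1)
    old <- c(a, cc, R[lower.tri(R)])
    for (j in seq_len(J)) {
      D <- cbind(1, Theta[, fac_idx[j]])
      b <- newton_logistic(D, Rq[, j], Nq[, j], c(cc[j], a[j]), cap = cap)
      cc[j] <- b[1]; a[j] <- b[2]
    }
    cs <- colSums(post)
    S <- crossprod(Theta * cs, Theta) / nrow(dat$X)
    R <- stats::cov2cor(S)
    change <- max(abs(c(a, cc, R[lower.tri(R)]) - old))
    if (change < tol) { converged <- TRUE; break }
  }
  # sign anchors: reflecting a factor flips its loadings and its rows/columns
  # of the correlation matrix (likelihood-invariant)
  for (s in seq_len(K)) {
    idx <- which(fac_idx == s)
    if (a[idx[1]] < 0) {
      a[idx] <- -a[idx]
      R[s, ] <- -R[s, ]; R[, s] <- -R[, s]; R[s, s] <- 1
    }
  }
  list(a_g = rep(0, J), a_s = a, c = cc, factor_cor = R,
       ll_trace = ll_trace, iterations = length(ll_trace),
       converged = converged, change = change)
}

# ---- public fitting interface ---------------------------------------------

#' Fit an item response model by marginal maximum likelihood
#'
#' @param items filtered item response tibble (`id` + 0/1/NA item columns).
#' @param spec a [bifactor_spec()].
#' @param quadrature_points Gauss-Hermite points per latent dimension.
#' @param tol EM stopping rule: maximum absolute parameter change.
#' @param max_iter EM iteration cap; non-convergence is flagged, never
#'   silently dropped.
#' @param cap Heywood guard: discriminations are capped at `|a| <= cap` and
#'   flagged when the cap binds.
#' @return An object of class `irt_fit`: per-item parameters, marginal
#'   log-likelihood, free-parameter count, convergence record, and (for the
#'   correlated kind) the estimated factor correlation matrix.
#' @export
fit_item_model <- function(items, spec, quadrature_points = 21, tol = 1e-4,
                           max_iter = 500, cap = 8) {
  dat <- irt_data(items, spec)
  gq <- gauss_hermite_normal(quadrature_points)
  J <- ncol(dat$X); K <- length(spec$factors)
  fit <- switch(spec$model_kind,
    unidimensional = em_unidimensional(dat, gq, tol, max_iter, cap),
    bifactor = em_bifactor(dat, spec$factors, gq, tol, max_iter, cap),
    second_order = em_second_order(dat, spec$factors, gq, tol, max_iter, cap),
    correlated = em_correlated(dat, spec$factors, gq, tol, max_iter, cap))
  k <- switch(spec$model_kind,
    unidimensional = 2 * J,
    bifactor = 3 * J,
    second_order = 2 * J + K,
    correlated = 2 * J + K * (K - 1) / 2)
  if (!fit$converged) {
    warn(sprintf("EM did not converge in %d iterations (last change %.2e)",
                 fit$iterations, fit$change))
  }
  capped <- spec$item_map$item[pmax(abs(fit$a_g), abs(fit$a_s)) >= cap - 1e-8]
  params <- tibble(item = spec$item_map$item, factor = spec$item_map$factor,
                   a_g = fit$a_g, a_s = fit$a_s, c = fit$c)
  out <- structure(list(params = params, kind = spec$model_kind, link = "logistic",
                 loglik = fit$ll_trace[length(fit$ll_trace)],
                 n_params = k, n_persons = nrow(dat$X), n_items = J,
                 factor_cor = fit$factor_cor %||% NULL,
                 gamma = fit$gamma %||% NULL, loading = fit$loading %||% NULL,
                 convergence = list(converged = fit$converged,
                                    iterations = fit$iterations,
                                    final_change = fit$change,
                                    ll_trace = fit$ll_trace,
                                    capped_items = capped),
                 spec = spec, quadrature_points = quadrature_points),
            class = "irt_fit")
  # report the marginal log-likelihood at the final parameter values (the
  # trace records it at the parameters entering each iteration)
  out$loglik <- irt_loglik(out, items)
  out$convergence$ll_trace <- c(out$convergence$ll_trace, out$loglik)
  out
}

#' Evaluate the marginal log-likelihood of a fitted model on data
#'
#' Recomputes the marginal log-likelihood at the fitted parameters, optionally
#' on a different quadrature (used to check quadrature refinement).
#'
#' @param fit an `irt_fit`.
#' @param items item response tibble (defaults set at fit time are not stored;
#'   pass the same data used to fit).
#' @param quadrature_points points per dimension.
#' @param per_person return the per-person log-likelihood vector instead of
#'   the sum.
#' @return Scalar log-likelihood (or vector if `per_person`).
#' @export
irt_loglik <- function(fit, items, quadrature_points = fit$quadrature_points,
                       per_person = FALSE) {
  spec <- fit$spec
  dat <- irt_data(items, spec)
  gq <- gauss_hermite_normal(quadrature_points)
  Q <- length(gq$x)
  p <- fit$params
  if (fit$kind == "unidimensional") {
    eta <- matrix(p$c, nrow(p), Q) + outer(p$a_g, gq$x)
    L <- as.vector(exp(factor_grid_loglik(dat, seq_len(nrow(p)), eta)) %*% gq$w)
  } else if (fit$kind %in% c("bifactor", "second_order")) {
    grid_qg <- rep(gq$x, each = Q); grid_qs <- rep(gq$x, times = Q)
    idx_list <- lapply(spec$factors, function(f) which(dat$fac == f))
    eta_grids <- lapply(seq_along(spec$factors), function(s) {
      idx <- idx_list[[s]]
      matrix(p$c[idx], length(idx), Q * Q) + outer(p$a_g[idx], grid_qg) +
        outer(p$a_s[idx], grid_qs)
    })
    L <- reduced_marginal(dat, spec$factors, eta_grids, idx_list, gq)$L
  } else {
    K <- length(spec$factors)
    Qc <- if (K <= 2) Q else 15L
    gqc <- gauss_hermite_normal(Qc)
    z_grid <- as.matrix(expand.grid(rep(list(gqc$x), K)))
    w_grid <- apply(as.matrix(expand.grid(rep(list(gqc$w), K))), 1, prod)
    Theta <- z_grid %*% chol(fit$factor_cor)
    fac_idx <- match(dat$fac, spec$factors)
    eta <- matrix(p$c, nrow(p), nrow(Theta)) +
      p$a_s * t(Theta)[fac_idx, , drop = FALSE]
    L <- as.vector(exp(factor_grid_loglik(dat, seq_len(nrow(p)), eta)) %*% w_grid)
  }
  if (per_person) log(L) else sum(log(L))
}

#' Fit the SDS-style two-factor negative symptom model
#'
#' A correlated two-factor model (avolition and lack of emotional
#' expressivity) with a freely estimated inter-factor correlation.
#'
#' @param items item response tibble.
#' @param map item-to-factor map (two factors); defaults to the table's
#'   `item_map` attribute.
#' @inheritParams fit_item_model
#' @return An `irt_fit` of kind `"correlated"` with `$factor_cor`.
#' @export
fit_sds_two_factor <- function(items, map = attr(items, "item_map"), ...) {
  assert_that(!is.null(map), "an item-to-factor map is required")
  assert_that(length(unique(map$factor)) == 2,
              "the SDS model uses exactly two factors")
  fit_item_model(items, bifactor_spec(map, model_kind = "correlated"), ...)
}
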