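# Fit indices, reliability/strength indices, EAP scoring and broom-style
# methods for fitted item response models.

#' Information-criterion fit indices
#'
#' `AIC = -2 LL + 2k`, `BIC = -2 LL + k ln(N)`,
#' `SABIC = -2 LL + k ln((N + 2) / 24)`.
#'
#' @param fit an `irt_fit`.
#' @return One-row tibble with `loglik`, `k`, `n`, `AIC`, `BIC`, `SABIC`.
#' @export
fit_indices <- function(fit) {
  if (!fit$convergence$converged) {
    warn("fit indices computed from a non-converged model")
  }
  ll <- fit$loglik; k <- fit$n_params; n <- fit$n_persons
  tibble(loglik = ll, k = k, n = n,
         AIC = -2 * ll + 2 * k,
         BIC = -2 * ll + k * log(n),
         SABIC = -2 * ll + k * log((n + 2) / 24))
}

# omega / omega_H / H from standardized loadings; errors name the offending
# item if any communality reaches 1
omega_indices <- function(lambda_g, lambda_s, factor, item = NULL) {
  comm <- lambda_g^2 + lambda_s^2
  if (any(comm >= 1)) {
    bad <- (item %||% as.character(which(comm >= 1)))[comm >= 1]
    abort(paste("standardized loadings imply communality >= 1 for item(s):",
                paste(bad, collapse = ", ")))
  }
  num_g <- sum(lambda_g)^2
  num_s <- tapply(lambda_s, factor, function(l) sum(l)^2)
  denom <- num_g + sum(num_s) + sum(1 - comm)
  H_one <- function(l) 1 / (1 + 1 / sum(l^2 / (1 - l^2)))
  H_spec <- vapply(split(lambda_s, factor), H_one, numeric(1))[names(num_s)]
  H <- tibble(factor = c("general", names(num_s)),
              H = unname(c(H_one(lambda_g), H_spec)))
  list(omega_total = (num_g + sum(num_s)) / denom,
       omega_hierarchical = num_g / denom,
       H = H)
}

#' Reliability and strength indices of a bi-factor model
#'
#' Discriminations are converted to standardized loadings on the
#' underlying-variable scale, `lambda = a* / sqrt(1 + sum(a*^2))` with
#' `a* = a / 1.702` under the logistic link, and summarized as McDonald's
#' omega (total), omega hierarchical (general factor share), and the
#' construct replicability index H per factor.
#'
#' @param fit a converged `irt_fit` of kind `"bifactor"`.
#' @return A `reliability_report` list: `loadings` tibble, `omega_total`,
#'   `omega_hierarchical`, `H` tibble.
#' @export
reliability_indices <- function(fit) {
  assert_that(fit$kind == "bifactor",
              "reliability indices are defined for the bifactor kind")
  D <- if (fit$link == "logistic") logistic_D else 1
  ag <- fit$params$a_g / D
  as_ <- fit$params$a_s / D
  norm <- sqrt(1 + ag^2 + as_^2)
  lambda_g <- ag / norm
  lambda_s <- as_ / norm
  idx <- omega_indices(lambda_g, lambda_s, fit$params$factor, fit$params$item)
  structure(list(
    loadings = tibble(item = fit$params$item, factor = fit$params$factor,
                      lambda_g = lambda_g, lambda_s = lambda_s),
    omega_total = idx$omega_total,
    omega_hierarchical = idx$omega_hierarchical,
    H = idx$H), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("omega = %.3f, omega_H = %.3f\n", x$omega_total,
              x$omega_hierarchical))
  print(x$H)
  invisible(x)
}

#' Expected a-posteriori factor scores
#'
#' Posterior means and standard deviations of the latent traits given each
#' person's observed responses, by quadrature over the fitted model's latent
#' space. Deterministic given model and data; persons with no observed items
#' are dropped and listed in `attr(, "dropped")`. The model-implied EAP
#' reliability per trait (`1 - mean posterior variance`) is attached as
#' `attr(, "reliability")`.
#'
#' @param fit an `irt_fit`.
#' @param items the item response tibble to score.
#' @return Tibble `id`, one column per trait (general first where the model
#'   has one), and `sd_<trait>` posterior SDs.
#' @export
eap_scores <- function(fit, items) {
  spec <- fit$spec
  dat <- irt_data(items, spec)
  gq <- gauss_hermite_normal(fit$quadrature_points)
  Q <- length(gq$x)
  p <- fit$params
  n <- nrow(dat$X)
  scored <- rowSums(dat$obs) > 0

  if (fit$kind == "unidimensional") {
    eta <- matrix(p$c, nrow(p), Q) + outer(p$a_g, gq$x)
    E <- exp(factor_grid_loglik(dat, seq_len(nrow(p)), eta))
    L <- as.vector(E %*% gq$w)
    post <- E * rep(gq$w, each = n) / L
    m1 <- as.vector(post %*% gq$x); m2 <- as.vector(post %*% gq$x^2)
    out <- tibble(id = dat$ids, general = m1,
                  sd_general = sqrt(pmax(m2 - m1^2, 0)))
    mean_cov <- matrix(mean((m2 - m1^2)[scored]), 1, 1,
                       dimnames = list("general", "general"))
  } else if (fit$kind %in% c("bifactor", "second_order")) {
    grid_qg <- rep(gq$x, each = Q); grid_qs <- rep(gq$x, times = Q)
    idx_list <- lapply(spec$factors, function(f) which(dat$fac == f))
    eta_grids <- lapply(seq_along(spec$factors), function(s) {
      idx <- idx_list[[s]]
      matrix(p$c[idx], length(idx), Q * Q) + outer(p$a_g[idx], grid_qg) +
        outer(p$a_s[idx], grid_qs)
    })
    m <- reduced_marginal(dat, spec$factors, eta_grids, idx_list, gq)
    post_g <- (m$P * rep(gq$w, each = n)) / m$L
    m1 <- as.vector(post_g %*% gq$x); m2 <- as.vector(post_g %*% gq$x^2)
    out <- tibble(id = dat$ids, general = m1,
                  sd_general = sqrt(pmax(m2 - m1^2, 0)))
    K <- length(spec$factors)
    # conditional inner-posterior mean of each reported trait given thetaG,
    # used for first/second moments and the posterior cross-covariances
    mcond <- vector("list", K)   # each n x Q
    msq <- vector("list", K)
    for (s in seq_len(K)) {
      theta_grid <- if (fit$kind == "second_order") {
        g <- fit$gamma[[spec$factors[s]]]
        g * grid_qg + sqrt(1 - g^2) * grid_qs
      } else grid_qs
      WX <- kronecker(diag(Q), matrix(gq$w, ncol = 1) ) * theta_grid
      WX2 <- kronecker(diag(Q), matrix(gq$w, ncol = 1)) * theta_grid^2
      mcond[[s]] <- (m$E[[s]] %*% WX) / m$Lbar[[s]]
      msq[[s]] <- (m$E[[s]] %*% WX2) / m$Lbar[[s]]
      s1 <- rowSums(post_g * mcond[[s]])
      s2 <- rowSums(post_g * msq[[s]])
      out[[spec$factors[s]]] <- s1
      out[[paste0("sd_", spec$factors[s])]] <- sqrt(pmax(s2 - s1^2, 0))
    }
    # average posterior covariance over scored persons
    traits <- c("general", spec$factors)
    mean_cov <- matrix(0, K + 1, K + 1, dimnames = list(traits, traits))
    mean_cov[1, 1] <- mean((m2 - m1^2)[scored])
    for (s in seq_len(K)) {
      egs <- rowSums(post_g * mcond[[s]] * rep(gq$x, each = n))
      mean_cov[1, s + 1] <- mean_cov[s + 1, 1] <-
        mean((egs - m1 * out[[spec$factors[s]]])[scored])
      mean_cov[s + 1, s + 1] <- mean(out[[paste0("sd_", spec$factors[s])]][scored]^2)
      if (s > 1) for (t in seq_len(s - 1)) {
        est <- rowSums(post_g * mcond[[s]] * mcond[[t]])
        mean_cov[s + 1, t + 1] <- mean_cov[t + 1, s + 1] <-
          mean((est - out[[spec$factors[s]]] * out[[spec$factors[t]]])[scored])
      }
    }
  } else {                                         # correlated
    K <- length(spec$factors)
    Qc <- if (K <= 2) Q else 15L
    gqc <- gauss_hermite_normal(Qc)
    z_grid <- as.matrix(expand.grid(rep(list(gqc$x), K)))
    w_grid <- apply(as.matrix(expand.grid(rep(list(gqc$w), K))), 1, prod)
    Theta <- z_grid %*% chol(fit$factor_cor)
    fac_idx <- match(dat$fac, spec$factors)
    eta <- matrix(p$c, nrow(p), nrow(Theta)) +
      p$a_s * t(Theta)[fac_idx, , drop = FALSE]
    E <- exp(factor_grid_loglik(dat, seq_len(nrow(p)), eta))
    L <- as.vector(E %*% w_grid)
    post <- E * rep(w_grid, each = n) / L
    out <- tibble(id = dat$ids)
    mean_cov <- matrix(0, K, K, dimnames = list(spec$factors, spec$factors))
    m1s <- matrix(0, n, K)
    for (s in seq_len(K)) {
      s1 <- as.vector(post %*% Theta[, s]); s2 <- as.vector(post %*% Theta[, s]^2)
      m1s[, s] <- s1
      out[[spec$factors[s]]] <- s1
      out[[paste0("sd_", spec$factors[s])]] <- sqrt(pmax(s2 - s1^2, 0))
      mean_cov[s, s] <- mean((s2 - s1^2)[scored])
      if (s > 1) for (t in seq_len(s - 1)) {
        est <- as.vector(post %*% (Theta[, s] * Theta[, t]))
        mean_cov[s, t] <- mean_cov[t, s] <- mean((est - m1s[, s] * m1s[, t])[scored])
      }
    }
  }

  dropped <- tibble(id = dat$ids[!scored], reason = "all items missing")
  out <- out[scored, ]
  trait_cols <- setdiff(names(out), c("id", grep("^sd_", names(out), value = TRUE)))
  rel <- vapply(trait_cols, function(tc) 1 - mean(out[[paste0("sd_", tc)]]^2),
                numeric(1))
  attr(out, "dropped") <- dropped
  attr(out, "reliability") <- rel
  attr(out, "mean_posterior_cov") <- mean_cov
  attr(out, "prior_cov") <- if (fit$kind == "correlated") fit$factor_cor else
    diag(length(trait_cols))
  out
}

#' Attenuation-corrected (or standardized) dimension scores
#'
#' EAP scores shrink toward zero by their reliability, which attenuates
#' regression slopes when the scores are used as outcomes. `"disattenuate"`
#' divides each trait by its model-implied EAP reliability so downstream
#' slopes estimate latent-scale effects; `"unit"` standardizes to mean 0 /
#' SD 1; `"none"` returns EAP scores as-is.
#'
#' @param scores output of [eap_scores()].
#' @param method `"disattenuate"`, `"unit"` or `"none"`.
#' @return Tibble with the same trait columns rescaled.
#' @export
rescale_scores <- function(scores,
                           method = c("disattenuate", "unit", "none"),
                           min_shrinkage = 0.3) {
  method <- match.arg(method)
  rel <- attr(scores, "reliability")
  out <- scores
  trait_cols <- names(rel)
  if (method == "disattenuate") {
    # multivariate shrinkage correction: under the normal approximation the
    # EAP vector satisfies E[theta_hat | theta] = A theta with
    # A = I - Vbar R^-1 (Vbar the average posterior covariance, R the prior
    # covariance), so theta_hat A^-T has latent-scale slopes. This also
    # removes the cross-dimension leakage of EAP scores, not only the
    # per-trait shrinkage. A carries a near-null direction in bi-factor
    # models (the general-vs-specifics trade-off is weakly identified from
    # scores), so the inverse is truncated: singular values below
    # `min_shrinkage` are not amplified beyond 1/min_shrinkage.
    V <- attr(scores, "mean_posterior_cov")
    R <- attr(scores, "prior_cov")
    A <- diag(nrow(V)) - V %*% solve(R)
    sv <- svd(A)
    Ainv <- sv$v %*% (t(sv$u) / pmax(sv$d, min_shrinkage))
    # renormalize so each trait's own shrinkage is corrected exactly
    # (diag(W A) = 1) while the weakly identified contrast stays damped;
    # the price is bounded cross-trait leakage instead of amplified noise
    W <- diag(1 / diag(Ainv %*% A)) %*% Ainv
    M <- as.matrix(scores[trait_cols])
    corrected <- M %*% t(W)
    for (k in seq_along(trait_cols)) out[[trait_cols[k]]] <- corrected[, k]
  } else {
    for (tc in trait_cols) {
      out[[tc]] <- switch(method,
        unit = standardize(scores[[tc]]),
        none = scores[[tc]])
    }
  }
  attr(out, "reliability") <- rel
  attr(out, "rescale_method") <- method
  out
}

# ---- broom-style methods ---------------------------------------------------

#' @method tidy irt_fit
#' @export
tidy.irt_fit <- function(x, ...) x$params

#' @method glance irt_fit
#' @export
glance.irt_fit <- function(x, ...) {
  fi <- suppressWarnings(fit_indices(x))
  tibble(kind = x$kind, loglik = x$loglik, k = x$n_params, n = x$n_persons,
         AIC = fi$AIC, BIC = fi$BIC, SABIC = fi$SABIC,
         converged = x$convergence$converged,
         iterations = x$convergence$iterations)
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("<irt_fit> %s model: %d items, %d persons, logLik %.2f (%s, %d EM iterations)\n",
              x$kind, x$n_items, x$n_persons, x$loglik,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}

#' Plot item discriminations of a fitted model
#'
#' @param object an `irt_fit`.
#' @param ... unused.
#' @return A ggplot: per-item general and specific discriminations.
#' @method autoplot irt_fit
#' @export
autoplot.irt_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$params, cols = c("a_g", "a_s"),
                           names_to = "loading", values_to = "a")
  d$loading <- ifelse(d$loading == "a_g", "general", "specific")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$a,
                                  y = stats::reorder(.data$item, .data$a),
                                  colour = .data$loading)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$factor), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "discrimination (logistic metric)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
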