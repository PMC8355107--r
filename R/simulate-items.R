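# Two-parameter-logistic bi-factor item response simulation and the default
# synthetic item banks.

#' Construct an item bank
#'
#' An item bank holds, per dichotomous item, the specific-factor label, the
#' general discrimination `a_g`, the specific discrimination `a_s` and the
#' intercept `c`, under a logistic (default) or probit link:
#' `P(X = 1) = link(c + a_g * theta_G + a_s * theta_s)`.
#'
#' Identification conventions are checked at construction: every factor must
#' carry at least one item with non-negative general discrimination, and each
#' item's marginal endorsement at standard-normal latent traits must lie in
#' (0.05, 0.95).
#'
#' @param items tibble with columns `item`, `factor`, `a_g`, `a_s`, `c`.
#' @param link `"logistic"` or `"probit"`.
#' @return The validated tibble with class `item_bank` and a `link` attribute.
#' @export
item_bank <- function(items, link = c("logistic", "probit")) {
  link <- match.arg(link)
  items <- as_tibble(items)
  assert_that(all(c("item", "factor", "a_g", "a_s", "c") %in% names(items)),
              "item bank needs columns item, factor, a_g, a_s, c")
  assert_that(!anyDuplicated(items$item), "item ids must be unique")
  ok_anchor <- all(tapply(items$a_g, items$factor, function(a) any(a >= 0)))
  assert_that(ok_anchor, "each factor needs an anchor item with a_g >= 0")
  marg <- item_marginal_endorsement(items, link)
  assert_that(all(marg > 0.05 & marg < 0.95),
              "item intercepts must imply marginal endorsement in (0.05, 0.95)")
  structure(items, class = c("item_bank", class(items)), link = link)
}

#' Model-implied marginal endorsement of each item
#'
#' The linear predictor `c + a_g theta_G + a_s theta_s` is normal with mean
#' `c` and variance `a_g^2 + a_s^2` at standard-normal orthogonal traits, so
#' the marginal reduces to a one-dimensional Gauss-Hermite integral.
#'
#' @param items an item bank (or a tibble with the same columns).
#' @param link `"logistic"` or `"probit"`.
#' @param n_quad quadrature points.
#' @return Numeric vector of endorsement probabilities, one per item.
#' @export
item_marginal_endorsement <- function(items, link = c("logistic", "probit"),
                                      n_quad = 41) {
  link <- match.arg(link)
  gq <- gauss_hermite_normal(n_quad)
  fn <- item_link(link)
  a_tot <- sqrt(items$a_g^2 + items$a_s^2)
  vapply(seq_len(nrow(items)), function(j) {
    sum(gq$w * fn(items$c[j] + a_tot[j] * gq$x))
  }, numeric(1))
}

#' Default 23-item symptom bank (cases)
#'
#' A fixed OPCRIT-like bank of 23 dichotomous items spanning one general
#' factor and five specific factors (positive, negative, disorganization,
#' mania, depression), with discriminations and intercepts typical of
#' observer-rated psychosis items (marginal endorsement roughly 0.15-0.55).
#'
#' @return An [item_bank()].
#' @export
default_item_bank <- function() {
  item_bank(tibble(
    item = c(sprintf("pos%d", 1:6), sprintf("neg%d", 1:5),
             sprintf("dis%d", 1:4), sprintf("man%d", 1:4),
             sprintf("dep%d", 1:4)),
    factor = rep(c("positive", "negative", "disorganization", "mania",
                   "depression"), times = c(6, 5, 4, 4, 4)),
    a_g = c(1.0, 1.2, 0.9, 1.1, 1.0, 1.3,
            0.9, 1.1, 1.0, 0.8, 1.2,
            1.0, 1.2, 0.9, 1.1,
            0.8, 1.0, 1.1, 0.9,
            1.0, 0.9, 1.2, 1.1),
    a_s = c(1.6, 1.5, 1.4, 1.7, 1.8, 1.5,
            1.5, 1.6, 1.4, 1.7, 1.3,
            1.2, 1.0, 1.3, 1.1,
            1.1, 1.3, 1.0, 1.2,
            1.0, 1.2, 1.1, 1.3),
    c = c(-0.4, -0.8, 0.2, -1.2, -0.2, -1.0,
          -0.6, -1.0, 0.0, -1.3, -0.3,
          -1.0, -0.5, -1.2, 0.1,
          -1.2, -0.9, -0.4, -1.4,
          -0.3, -0.7, -1.1, 0.0)))
}

#' Default psychotic-experience bank (controls)
#'
#' CAPE-like subset of the case bank: the positive, negative and depression
#' items (15 items, three specific factors).
#' @return An [item_bank()].
#' @export
control_item_bank <- function() {
  bank <- default_item_bank()
  item_bank(bank[bank$factor %in% c("positive", "negative", "depression"), ],
            link = attr(bank, "link"))
}

#' Default negative-symptom (SDS-like) two-factor bank
#'
#' Eight items loading on two correlated specific factors, avolition and
#' (lack of) emotional expressivity, with no general factor (`a_g = 0`).
#' @return An [item_bank()].
#' @export
sds_item_bank <- function() {
  item_bank(tibble(
    item = c(sprintf("avo%d", 1:4), sprintf("exp%d", 1:4)),
    factor = rep(c("avolition", "emotional_expressivity"), each = 4),
    a_g = 0,
    a_s = c(1.4, 1.6, 1.2, 1.5, 1.5, 1.3, 1.7, 1.4),
    c = c(-0.5, -0.9, -0.2, -1.1, -0.7, -0.3, -1.0, -0.5)))
}

#' Simulate dichotomous item responses from latent traits
#'
#' `P(X_ij = 1) = link(c_j + a_g_j * theta_G_i + a_s_j * theta_s(j)_i)`;
#' entries are then masked missing completely at random at `missing_rate`.
#'
#' @param theta_table tibble with column `id` plus `theta_general` (omitted if
#'   the bank has all `a_g = 0`) and one `theta_<factor>` column per specific
#'   factor used by the bank.
#' @param bank an [item_bank()].
#' @param missing_rate MCAR missingness rate, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return A tibble `id` + one 0/1/NA column per item, with the item-to-factor
#'   map in `attr(, "item_map")`.
#' @export
simulate_item_responses <- function(theta_table, bank, missing_rate = 0, seed) {
  assert_that(missing_rate >= 0 && missing_rate < 0.5,
              "missing_rate must lie in [0, 0.5)")
  fac_cols <- paste0("theta_", unique(bank$factor))
  missing_cols <- setdiff(fac_cols, names(theta_table))
  assert_that(length(missing_cols) == 0,
              paste("theta_table lacks columns:", paste(missing_cols, collapse = ", ")))
  g <- if ("theta_general" %in% names(theta_table)) theta_table$theta_general else {
    assert_that(all(bank$a_g == 0), "bank has general loadings but no theta_general column")
    rep(0, nrow(theta_table))
  }
  fn <- item_link(attr(bank, "link") %||% "logistic")
  n <- nrow(theta_table)
  with_substream(seed, "items", {
    resp <- matrix(NA_integer_, n, nrow(bank))
    for (j in seq_len(nrow(bank))) {
      th_s <- theta_table[[paste0("theta_", bank$factor[j])]]
      pr <- fn(bank$c[j] + bank$a_g[j] * g + bank$a_s[j] * th_s)
      resp[, j] <- rbinom(n, 1L, pr)
    }
    if (missing_rate > 0) {
      resp[matrix(runif(n * nrow(bank)) < missing_rate, n)] <- NA_integer_
    }
    out <- as_tibble(as.data.frame(resp))
    names(out) <- bank$item
    out <- dplyr::bind_cols(tibble(id = theta_table$id), out)
    attr(out, "item_map") <- tibble(item = bank$item, factor = bank$factor)
    out
  })
}
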