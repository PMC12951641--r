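#' Confirmatory factor model fit by maximum likelihood
#'
#' Fits the covariance structure `Sigma = Lambda Phi Lambda' + Psi` to the
#' sample covariance `S` of an indicator table by minimising the ML
#' discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`.
#' Identification fixes every factor variance to 1 and leaves all loadings
#' free; inter-factor correlations are free parameters. For the classic
#' eight-indicator layout this gives 17 free parameters (df 19) for the
#' two-factor model and 16 (df 20) for the one-factor model. The model
#' chi-square is `(n - 1) * F` at the optimum.
#'
#' Optimisation uses L-BFGS-B with the analytic gradient of `F`
#' (`dF = tr[Omega dSigma]`, `Omega = Sigma^-1 (Sigma - S) Sigma^-1`) and a
#' small deterministic multi-start against local minima. Uniquenesses are
#' bounded below at a small positive value; a fit that ends on that bound is
#' flagged as a Heywood case.
#'
#' @param indicators Wide indicator tibble (participants x indicators); any
#'   `participant_id` column is dropped automatically.
#' @param factors Named list mapping factor names to indicator column names,
#'   e.g. `list(MT = ..., MP = ...)`; a single entry gives the one-factor
#'   model.
#' @param n_starts Number of optimisation starts (default 3).
#' @param extra_starts Optional list of additional full start vectors
#'   (loadings, correlations, uniquenesses) — used internally to seed the
#'   full model with a nested model's solution so the nested fit can never
#'   beat it.
#' @return An object of class `cfa_fit`: loadings, factor correlation matrix
#'   `phi`, `uniquenesses`, `discrepancy`, `chi_square`, `df`, `p_value`,
#'   `n`, `converged`, `heywood`.
#' @export
fit_factor_model <- function(indicators, factors, n_starts = 3L,
                             extra_starts = list()) {
  X <- indicators[setdiff(names(indicators), "participant_id")]
  vars <- unlist(factors, use.names = FALSE)
  stopifnot(all(vars %in% names(X)), !anyDuplicated(vars), length(factors) >= 1L)
  X <- as.matrix(X[vars])
  n <- nrow(X)
  p <- ncol(X)
  q <- length(factors)
  S <- stats::cov(X)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("sample covariance is not positive definite", call. = FALSE)
  }
  fmap <- rep(seq_len(q), lengths(factors))      # factor index per indicator
  n_corr <- q * (q - 1L) / 2L
  n_free <- p + n_corr + p                       # loadings + correlations + uniquenesses
  df <- p * (p + 1L) / 2L - n_free
  stopifnot(df >= 0L)

  unpack <- function(theta) {
    lam <- theta[seq_len(p)]
    rho <- if (n_corr > 0) theta[p + seq_len(n_corr)] else numeric(0)
    psi <- theta[p + n_corr + seq_len(p)]
    Phi <- diag(q)
    if (n_corr > 0) {
      Phi[lower.tri(Phi)] <- rho
      Phi <- Phi + t(Phi) - diag(q)
    }
    L <- matrix(0, p, q)
    L[cbind(seq_len(p), fmap)] <- lam
    list(L = L, Phi = Phi, psi = psi)
  }
  obj <- function(theta) {
    pr <- unpack(theta)
    Sigma <- pr$L %*% pr$Phi %*% t(pr$L) + diag(pr$psi, p)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    determinant(Sigma, logarithm = TRUE)$modulus[1] +
      sum(diag(solve(Sigma, S))) -
      determinant(S, logarithm = TRUE)$modulus[1] - p
  }
  grad <- function(theta) {
    pr <- unpack(theta)
    Sigma <- pr$L %*% pr$Phi %*% t(pr$L) + diag(pr$psi, p)
    Si <- tryCatch(solve(Sigma), error = function(e) NULL)
    if (is.null(Si)) return(rep(0, length(theta)))
    Omega <- Si %*% (Sigma - S) %*% Si
    gL <- 2 * Omega %*% pr$L %*% pr$Phi
    g_lam <- gL[cbind(seq_len(p), fmap)]
    g_rho <- if (n_corr > 0) {
      A <- t(pr$L) %*% Omega %*% pr$L
      2 * A[lower.tri(A)]
    } else numeric(0)
    g_psi <- diag(Omega)
    c(g_lam, g_rho, g_psi)
  }

  sd_x <- sqrt(diag(S))
  base_start <- c(0.7 * sd_x, rep(0.3, n_corr), 0.5 * diag(S))
  jitter <- list(1, 0.6, 1.4)
  # correlation bounds of exactly +/-1 keep nested one-factor solutions inside
  # the feasible set (Sigma stays PD through the positive uniquenesses)
  lower <- c(rep(-Inf, p), rep(-1, n_corr), rep(1e-4 * max(diag(S)), p))
  upper <- c(rep(Inf, p), rep(1, n_corr), rep(Inf, p))

  starts <- lapply(seq_len(min(n_starts, length(jitter))), function(s) {
    th0 <- base_start
    th0[seq_len(p)] <- th0[seq_len(p)] * jitter[[s]]
    th0
  })
  starts <- c(starts, lapply(extra_starts, function(th) {
    stopifnot(length(th) == n_free)
    pmin(pmax(th, lower), upper)
  }))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("factor model optimisation failed", call. = FALSE)
  if (best$convergence != 0L) {
    # line searches can fail on an active correlation bound; a restart from
    # the incumbent usually terminates cleanly
    polish <- tryCatch(
      stats::optim(best$par, obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value + 1e-10) best <- polish
  }
  converged <- best$convergence == 0L
  if (!converged) {
    # accept a bound-constrained stationary point: projected gradient ~ 0
    g <- grad(best$par)
    at_lo <- best$par <= lower + 1e-8
    at_hi <- best$par >= upper - 1e-8
    g[at_lo & g > 0] <- 0
    g[at_hi & g < 0] <- 0
    converged <- max(abs(g)) < 1e-4
  }
  pr <- unpack(best$par)
  heywood <- any(pr$psi <= 2e-4 * max(diag(S)))
  Fmin <- max(best$value, 0)
  chi_sq <- if (converged) (n - 1) * Fmin else NA_real_
  loadings <- matrix(0, p, q, dimnames = list(vars, names(factors)))
  loadings[cbind(seq_len(p), fmap)] <- best$par[seq_len(p)]
  structure(
    list(factors = factors, loadings = loadings,
         phi = structure(pr$Phi, dimnames = list(names(factors), names(factors))),
         uniquenesses = stats::setNames(pr$psi, vars),
         discrepancy = Fmin, chi_square = chi_sq, df = df,
         p_value = if (is.na(chi_sq)) NA_real_ else
           stats::pchisq(chi_sq, df, lower.tail = FALSE),
         n = n, p = p, n_free = n_free,
         converged = converged, heywood = heywood),
    class = "cfa_fit"
  )
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("<cfa_fit> %d factor(s), %d indicators, n = %d\n",
              length(x$factors), x$p, x$n))
  cat(sprintf("  chi-square(%d) = %.3f, p = %.4g%s%s\n", x$df, x$chi_square,
              x$p_value,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$heywood) " [Heywood]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confirmatory factor fit
#'
#' One row per estimated parameter: loadings (`term = indicator`, `type =
#' "loading"`, with the factor name), uniquenesses, and inter-factor
#' correlations.
#'
#' @param x A `cfa_fit`.
#' @param ... Unused.
#' @return Tibble with `type`, `term`, `factor`, `estimate`.
#' @method tidy cfa_fit
#' @export
tidy.cfa_fit <- function(x, ...) {
  fmap <- rep(names(x$factors), lengths(x$factors))
  load_tbl <- tibble::tibble(
    type = "loading", term = rownames(x$loadings), factor = fmap,
    estimate = x$loadings[cbind(seq_len(x$p), match(fmap, colnames(x$loadings)))]
  )
  uniq_tbl <- tibble::tibble(type = "uniqueness", term = names(x$uniquenesses),
                             factor = NA_character_,
                             estimate = unname(x$uniquenesses))
  q <- length(x$factors)
  corr_tbl <- if (q > 1) {
    idx <- which(lower.tri(x$phi), arr.ind = TRUE)
    tibble::tibble(
      type = "factor_correlation",
      term = paste(colnames(x$phi)[idx[, 2]], colnames(x$phi)[idx[, 1]], sep = "~~"),
      factor = NA_character_, estimate = x$phi[idx]
    )
  } else NULL
  dplyr::bind_rows(load_tbl, corr_tbl, uniq_tbl)
}

#' Glance at a confirmatory factor fit
#'
#' @param x A `cfa_fit`.
#' @param ... Unused.
#' @return One-row tibble: `chi_square`, `df`, `p_value`, `n_free`, `n`,
#'   `converged`, `heywood`.
#' @method glance cfa_fit
#' @export
glance.cfa_fit <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value,
                 n_free = x$n_free, n = x$n,
                 converged = x$converged, heywood = x$heywood)
}

#' Chi-square difference test of nested factor models
#'
#' Compares a restricted model (e.g. one factor) against the full model it
#' nests in (e.g. two correlated factors):
#' `Delta chi2 = chi2_restricted - chi2_full` on `Delta df` degrees of
#' freedom, upper-tail p. A slightly negative difference (optimizer
#' tolerance) is floored at zero with a warning.
#'
#' @param fit_restricted,fit_full `cfa_fit` objects, restricted nested in
#'   full (`df_restricted > df_full`).
#' @return One-row tibble: `delta_chi_square`, `delta_df`, `p_value`.
#' @export
chisq_difference <- function(fit_restricted, fit_full) {
  stopifnot(inherits(fit_restricted, "cfa_fit"), inherits(fit_full, "cfa_fit"),
            fit_restricted$df > fit_full$df,
            fit_restricted$converged, fit_full$converged)
  d <- fit_restricted$chi_square - fit_full$chi_square
  if (d < -1e-6) warning("restricted model fits better than full; nesting suspect",
                         call. = FALSE)
  d <- max(d, 0)
  ddf <- fit_restricted$df - fit_full$df
  tibble::tibble(delta_chi_square = d, delta_df = ddf,
                 p_value = stats::pchisq(d, ddf, lower.tail = FALSE))
}

#' Compare one- versus two-factor models on an indicator table
#'
#' Convenience wrapper: fits the two-factor model given by `factors`, the
#' one-factor collapse of the same indicators, and returns both fits with
#' the chi-square difference test.
#'
#' @param indicators Wide indicator tibble.
#' @param factors Two-entry named list defining the two-factor model.
#' @param n_starts Optimisation starts per fit.
#' @return List: `fit_two`, `fit_one`, `test` (tibble from
#'   [chisq_difference()]), `preferred` (`"two"` if p < 0.05 else `"one"`).
#' @export
compare_factor_models <- function(indicators, factors, n_starts = 3L) {
  stopifnot(length(factors) == 2L)
  fit_one <- fit_factor_model(
    indicators, list(g = unlist(factors, use.names = FALSE)), n_starts)
  # seed the full model at the one-factor solution (rho -> 1) so the nested
  # model can never appear to fit better than the model containing it
  p <- fit_one$p
  nested_start <- c(fit_one$loadings[, 1L], 1, unname(fit_one$uniquenesses))
  fit_two <- fit_factor_model(indicators, factors, n_starts,
                              extra_starts = list(nested_start))
  test <- chisq_difference(fit_one, fit_two)
  list(fit_two = fit_two, fit_one = fit_one, test = test,
       preferred = if (test$p_value < 0.05) "two" else "one")
}

#' Split-half consistency of the factor-model comparison
#'
#' Splits participants deterministically (`"odd_even"` by row parity or
#' `"first_second"` by row order), runs the one- versus two-factor comparison
#' within each half, and reports whether both halves prefer the same model.
#'
#' @param indicators Wide indicator tibble.
#' @param factors Two-entry named list defining the two-factor model.
#' @param split `"odd_even"` or `"first_second"`.
#' @param n_starts Optimisation starts per fit.
#' @return Tibble with one row per half: `half`, `n`, `delta_chi_square`,
#'   `delta_df`, `p_value`, `preferred`; attribute `consistent`.
#' @export
split_half_consistency <- function(indicators, factors,
                                   split = c("odd_even", "first_second"),
                                   n_starts = 3L) {
  split <- match.arg(split)
  n <- nrow(indicators)
  p_ind <- length(unlist(factors))
  if (n < 2L * (p_ind + 2L)) stop("too few participants to split", call. = FALSE)
  idx <- seq_len(n)
  halves <- if (split == "odd_even") {
    list(idx[idx %% 2L == 1L], idx[idx %% 2L == 0L])
  } else {
    list(idx[idx <= n %/% 2L], idx[idx > n %/% 2L])
  }
  out <- purrr::imap(halves, function(rows, h) {
    cmp <- compare_factor_models(indicators[rows, ], factors, n_starts)
    dplyr::mutate(cmp$test, half = h, n = length(rows),
                  preferred = cmp$preferred, .before = 1L)
  }) |> dplyr::bind_rows()
  attr(out, "consistent") <- length(unique(out$preferred)) == 1L
  out
}
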