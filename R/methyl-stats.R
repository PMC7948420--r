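#' Read a methylation-state count table
#'
#' TSV with columns `strain`, `replicate`, `me0`, `me1`, `me2`, `me3`; values
#' are either raw counts or per-replicate fractions (see `counts_mode` in the
#' fitting functions).
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_methyl_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

methyl_states <- c("me0", "me1", "me2", "me3")

# Collapse a strain/replicate table into per-(strain, state) multinomial
# weights. In fraction mode each replicate's fractions are treated as a
# weighted multinomial observation of size effective_n.
methyl_weights <- function(data, effective_n = 1000, counts_mode = FALSE) {
  stopifnot(all(c("strain", methyl_states) %in% names(data)))
  vals <- as.matrix(data[, methyl_states])
  if (any(vals < 0)) stop("state counts/fractions must be non-negative")
  if (!counts_mode) {
    rs <- rowSums(vals)
    if (any(rs == 0)) stop("empty replicate: all-zero state fractions")
    vals <- vals / rs * effective_n
  }
  strains <- unique(as.character(data$strain))
  w <- t(vapply(strains, function(s)
    colSums(vals[data$strain == s, , drop = FALSE]), numeric(4)))
  rownames(w) <- strains
  w
}

po_probs <- function(theta, beta_s) {
  cum <- stats::plogis(c(theta, Inf) - beta_s)
  diff(c(0, cum))
}

po_negll <- function(par, w, n_strains) {
  theta <- par[1:3]
  if (is.unsorted(theta, strictly = TRUE)) return(1e12)
  beta <- c(0, par[-(1:3)])
  ll <- 0
  for (s in seq_len(n_strains)) {
    p <- pmax(po_probs(theta, beta[s]), 1e-300)
    ll <- ll + sum(w[s, ] * log(p))
  }
  -ll
}

po_negll_grad <- function(par, w, n_strains) {
  theta <- par[1:3]
  beta <- c(0, par[-(1:3)])
  g_theta <- numeric(3)
  g_beta <- numeric(n_strains - 1L)
  for (s in seq_len(n_strains)) {
    eta <- theta - beta[s]
    FF <- stats::plogis(eta)
    ff <- FF * (1 - FF)
    p <- pmax(diff(c(0, FF, 1)), 1e-300)
    r <- w[s, ] / p
    # theta_k enters p_k with +f_k and p_{k+1} with -f_k
    g_theta <- g_theta + r[1:3] * ff - r[2:4] * ff
    if (s > 1L) {
      fpad <- c(0, ff, 0)
      g_beta[s - 1L] <- -sum(r * (fpad[2:5] - fpad[1:4]))
    }
  }
  -c(g_theta, g_beta)
}

#' Fit the proportional-odds model to methylation-state data
#'
#' Maximum-likelihood cumulative-logit regression of the ordered methylation
#' states (me0 < me1 < me2 < me3) on strain, with a common slope per strain
#' (the proportional-odds assumption): `logit P(Y <= j | strain) =
#' theta_j - beta_strain`, `beta` fixed at 0 for the reference strain.
#' `exp(beta)` is the common odds ratio of a strain sitting above any state
#' boundary relative to the reference. Optimization is BFGS warm start
#' followed by Newton iterations with step-halving; convergence requires
#' gradient norm below `grad_tol`.
#'
#' @param data Strain/replicate table (see [read_methyl_counts()]).
#' @param reference Reference strain label (default: first strain).
#' @param effective_n Effective multinomial size per replicate when `data`
#'   holds fractions (default 1000). Declared precision: p-values scale with
#'   it.
#' @param counts_mode Set TRUE when `data` holds raw counts.
#' @param grad_tol Convergence tolerance on the gradient norm.
#' @return Object of class `ordinal_fit`: `cutpoints` (3, increasing),
#'   `beta` (named per strain, reference 0), `odds_ratio`, `se`, `p_value`,
#'   `logLik`, `vcov`, `npar`, `n_total`, `strains`, `reference`,
#'   `converged`, `grad_norm`, `separation`.
#' @export
fit_proportional_odds <- function(data, reference = NULL, effective_n = 1000,
                                  counts_mode = FALSE, grad_tol = 1e-6) {
  w <- methyl_weights(data, effective_n, counts_mode)
  strains <- rownames(w)
  if (is.null(reference)) reference <- strains[1]
  if (!reference %in% strains) stop("reference strain not present in data")
  if (any(rowSums(w) == 0)) stop("empty strain: zero total weight")
  w <- w[c(reference, setdiff(strains, reference)), , drop = FALSE]
  strains <- rownames(w)
  S <- length(strains)
  if (sum(colSums(w) > 0) < 2L) stop("need >= 2 observed states overall")

  pooled <- colSums(w) / sum(w)
  cum <- pmin(pmax(cumsum(pooled)[1:3], 1e-6), 1 - 1e-6)
  start <- c(stats::qlogis(cum), rep(0, S - 1L))
  # enforce strictly increasing start
  start[1:3] <- sort(start[1:3]) + c(0, 1e-6, 2e-6)

  f <- function(p) po_negll(p, w, S)
  gr <- function(p) po_negll_grad(p, w, S)
  opt <- stats::optim(start, f, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  par <- opt$par
  # Newton polish with step-halving
  g <- gr(par)
  iter <- 0L
  while (sqrt(sum(g^2)) > grad_tol && iter < 50L) {
    H <- stats::optimHess(par, f)
    step <- tryCatch(-solve(H, g), error = function(e) -g)
    t <- 1
    f0 <- f(par)
    while (t > 1e-8 && f(par + t * step) > f0 + 1e-12) t <- t / 2
    if (t <= 1e-8) break
    par <- par + t * step
    g <- gr(par)
    iter <- iter + 1L
  }
  grad_norm <- sqrt(sum(g^2))
  separation <- any(abs(par[-(1:3)]) > 15)
  if (grad_norm > grad_tol && !separation) {
    stop("proportional-odds fit did not converge (gradient norm ",
         format(grad_norm), ")")
  }
  H <- stats::optimHess(par, f)
  vc <- tryCatch(solve(H), error = function(e) {
    separation <<- TRUE
    matrix(NA_real_, length(par), length(par))
  })
  if (separation) {
    warning("possible complete separation: extreme coefficient or singular ",
            "information matrix; estimates and p-values are unreliable")
  }
  theta <- unname(par[1:3])
  beta <- stats::setNames(c(0, unname(par[-(1:3)])), strains)
  se <- stats::setNames(c(NA_real_, sqrt(pmax(diag(vc)[-(1:3)], 0))), strains)
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  structure(
    list(cutpoints = theta, beta = beta, odds_ratio = exp(beta),
         se = se, p_value = pv, logLik = -f(par), vcov = vc,
         npar = length(par), n_total = sum(w), strains = strains,
         reference = reference, weights = w, model = "proportional_odds",
         converged = grad_norm <= grad_tol, grad_norm = grad_norm,
         separation = separation),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("<ordinal_fit> %s, %d strains (ref %s), logLik %.3f\n",
              x$model, length(x$strains), x$reference, x$logLik))
  if (x$model == "proportional_odds") {
    for (s in setdiff(x$strains, x$reference)) {
      cat(sprintf("  %s: OR = %.3f, p = %.3g\n", s, x$odds_ratio[s],
                  x$p_value[s]))
    }
  }
  invisible(x)
}

#' Fit the adjacent-category model with per-boundary slopes
#'
#' Relaxes the proportional-odds assumption: `log(P(Y = j+1) / P(Y = j) |
#' strain) = alpha_j + gamma_{j,strain}` with a separate slope per boundary
#' and strain (`gamma` fixed at 0 for the reference). With a single
#' categorical covariate this is the saturated multinomial model, so the ML
#' solution is the weighted per-strain state proportions and is computed in
#' closed form. Zero cells make some coefficients infinite and are flagged.
#'
#' @inheritParams fit_proportional_odds
#' @return Object of class `ordinal_fit` with `alpha` (3 intercepts),
#'   `gamma` (3 x strains slope matrix), `probs` (fitted per-strain state
#'   distributions), `logLik`, `npar`, `zero_cells`.
#' @export
fit_adjacent_category <- function(data, reference = NULL, effective_n = 1000,
                                  counts_mode = FALSE) {
  w <- methyl_weights(data, effective_n, counts_mode)
  strains <- rownames(w)
  if (is.null(reference)) reference <- strains[1]
  if (!reference %in% strains) stop("reference strain not present in data")
  if (any(rowSums(w) == 0)) stop("empty strain: zero total weight")
  w <- w[c(reference, setdiff(strains, reference)), , drop = FALSE]
  strains <- rownames(w)
  probs <- w / rowSums(w)
  zero_cells <- any(probs == 0)
  lr <- log(probs[, 2:4, drop = FALSE]) - log(probs[, 1:3, drop = FALSE])
  alpha <- lr[1, ]
  gamma <- sweep(lr, 2L, alpha)
  ll <- sum(ifelse(w > 0, w * log(probs), 0))
  structure(
    list(alpha = alpha, gamma = gamma, probs = probs, logLik = ll,
         npar = 3L * length(strains), n_total = sum(w), strains = strains,
         reference = reference, weights = w, model = "adjacent_category",
         converged = TRUE, zero_cells = zero_cells),
    class = "ordinal_fit"
  )
}

#' Likelihood-ratio test between nested ordinal fits
#'
#' Compares a proportional-odds fit against the richer adjacent-category fit
#' on the same data; the chi-square reference has degrees of freedom equal to
#' the parameter-count difference.
#'
#' @param fit_null,fit_alt `ordinal_fit` objects on the same data, with
#'   `fit_alt` at least as rich as `fit_null`.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "ordinal_fit"), inherits(fit_alt, "ordinal_fit"))
  if (!setequal(fit_null$strains, fit_alt$strains) ||
      abs(fit_null$n_total - fit_alt$n_total) > 1e-6 ||
      fit_alt$npar < fit_null$npar) {
    stop("non-nested inputs: fits must share data and fit_alt must be at ",
         "least as rich as fit_null")
  }
  stat <- 2 * (fit_alt$logLik - fit_null$logLik)
  if (stat < -1e-6) {
    stop("non-nested inputs: alternative log-likelihood below null")
  }
  stat <- max(stat, 0)
  df <- fit_alt$npar - fit_null$npar
  p <- if (df == 0L) as.numeric(stat <= 1e-8) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Per-strain odds-ratio report
#'
#' Tabulates the common odds ratio, Wald confidence interval, p-value and the
#' figure-style significance flag (`**` for p < 0.01) for each non-reference
#' strain of a proportional-odds fit.
#'
#' @param fit A proportional-odds `ordinal_fit`.
#' @param conf_level Confidence level for the Wald interval.
#' @return data.frame with one row per non-reference strain.
#' @export
odds_ratio_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "ordinal_fit"), fit$model == "proportional_odds")
  s <- setdiff(fit$strains, fit$reference)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    strain = s,
    odds_ratio = unname(fit$odds_ratio[s]),
    ci_low = unname(exp(fit$beta[s] - zq * fit$se[s])),
    ci_high = unname(exp(fit$beta[s] + zq * fit$se[s])),
    p_value = unname(fit$p_value[s]),
    significance = ifelse(fit$p_value[s] < 0.01, "**", "")
  )
}
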