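## Zero-inflated negative binomial (ZINB) likelihood, fitting, and the
## likelihood-ratio differential expression test.
##
## Model per observation i:
##   logit pi_i  = gamma0 + gamma1 * g_i          (structural-zero / dropout)
##   log   mu_i  = beta0  + beta1  * g_i + o_i    (NB mean, o_i = offset)
##   y_i ~ pi_i * delta_0 + (1 - pi_i) * NB(mu_i, theta)
## with NB(k | mu, theta) the mean/dispersion parameterization
## Gamma(k + theta) / (Gamma(theta) k!) * (theta/(theta+mu))^theta *
## (mu/(theta+mu))^k.

# stable per-observation ZINB log density; eta_pi = NULL means pi = 0
.zinb_ll_vec <- function(y, eta_pi, eta_mu, log_theta) {
  theta <- exp(log_theta)
  mu <- exp(eta_mu)
  nb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (is.null(eta_pi)) return(nb)
  # log pi and log(1 - pi) from the logit, numerically stable
  lp <- -log1p(exp(-eta_pi))        # log(pi)
  l1p <- -log1p(exp(eta_pi))        # log(1 - pi)
  out <- l1p + nb
  z <- y == 0
  if (any(z)) {
    a <- lp[z] ; b <- l1p[z] + nb[z]
    m <- pmax(a, b)
    out[z] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

#' ZINB log-likelihood
#'
#' Total log-likelihood of counts under the two-component ZINB regression
#' with a binary group covariate in both components and an offset on the
#' count mean.
#'
#' @param params numeric parameter vector. With `zero_inflated = TRUE`:
#'   `c(gamma0, gamma1, beta0, beta1, log_theta)` when `group` is supplied,
#'   `c(gamma0, beta0, log_theta)` otherwise. With `zero_inflated = FALSE`
#'   the gamma entries are omitted and `pi = 0`.
#' @param y non-negative integer counts.
#' @param group binary 0/1 group indicator, or `NULL` for the
#'   intercept-only model.
#' @param offset per-observation offset on `log mu` (e.g. log total UMIs);
#'   0 when `NULL`.
#' @param zero_inflated logical; `FALSE` reduces to plain NB regression.
#' @return the scalar log-likelihood.
#' @export
zinb_loglik <- function(params, y, group = NULL, offset = NULL,
                        zero_inflated = TRUE) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop2("y must be non-negative integers")
  if (is.null(offset)) offset <- rep(0, length(y))
  g <- if (is.null(group)) NULL else as.numeric(group)
  if (zero_inflated) {
    if (is.null(g)) {
      eta_pi <- rep(params[1], length(y)); eta_mu <- params[2] + offset
      lt <- params[3]
    } else {
      eta_pi <- params[1] + params[2] * g
      eta_mu <- params[3] + params[4] * g + offset
      lt <- params[5]
    }
  } else {
    eta_pi <- NULL
    if (is.null(g)) { eta_mu <- params[1] + offset; lt <- params[2] }
    else { eta_mu <- params[1] + params[2] * g + offset; lt <- params[3] }
  }
  if (!is.finite(lt)) return(-Inf)
  sum(.zinb_ll_vec(y, eta_pi, eta_mu, lt))
}

# per-observation partial derivatives of the ZINB log density wrt
# (eta_pi, eta_mu, log_theta); eta_pi = NULL means the pi = 0 reduction
.zinb_grad_vec <- function(y, eta_pi, eta_mu, log_theta) {
  theta <- exp(log_theta)
  mu <- exp(eta_mu)
  z <- y == 0
  # NB count-component partials
  d_mu_nb <- y - (y + theta) * mu / (mu + theta)
  d_lt_nb <- theta * (digamma(y + theta) - digamma(theta) +
                        log(theta / (theta + mu)) + (mu - y) / (mu + theta))
  if (is.null(eta_pi)) {
    return(list(d_pi = NULL, d_mu = d_mu_nb, d_lt = d_lt_nb))
  }
  pii <- stats::plogis(eta_pi)
  d_pi <- -pii                      # y > 0 case: d log(1-pi) / d eta
  d_mu <- d_mu_nb
  d_lt <- d_lt_nb
  if (any(z)) {
    p0 <- exp(theta * (log_theta - log(theta + mu[z])))
    L <- pii[z] + (1 - pii[z]) * p0
    d_pi[z] <- pii[z] * (1 - pii[z]) * (1 - p0) / L
    d_mu[z] <- -(1 - pii[z]) * p0 * theta * mu[z] / (mu[z] + theta) / L
    d_lt[z] <- (1 - pii[z]) * p0 * theta *
      (log(theta / (theta + mu[z])) + mu[z] / (theta + mu[z])) / L
  }
  list(d_pi = d_pi, d_mu = d_mu, d_lt = d_lt)
}

# gradient of the total log-likelihood wrt the packed parameter vector
.zinb_grad <- function(params, y, g, offset, zero_inflated) {
  if (is.null(offset)) offset <- rep(0, length(y))
  if (zero_inflated) {
    if (is.null(g)) {
      gr <- .zinb_grad_vec(y, rep(params[1], length(y)), params[2] + offset,
                           params[3])
      c(sum(gr$d_pi), sum(gr$d_mu), sum(gr$d_lt))
    } else {
      gr <- .zinb_grad_vec(y, params[1] + params[2] * g,
                           params[3] + params[4] * g + offset, params[5])
      c(sum(gr$d_pi), sum(gr$d_pi * g), sum(gr$d_mu), sum(gr$d_mu * g),
        sum(gr$d_lt))
    }
  } else {
    if (is.null(g)) {
      gr <- .zinb_grad_vec(y, NULL, params[1] + offset, params[2])
      c(sum(gr$d_mu), sum(gr$d_lt))
    } else {
      gr <- .zinb_grad_vec(y, NULL, params[1] + params[2] * g + offset,
                           params[3])
      c(sum(gr$d_mu), sum(gr$d_mu * g), sum(gr$d_lt))
    }
  }
}

# deterministic starting values: moment-based, zero-heavy, NB-lean
.zinb_starts <- function(y, g, offset, zero_inflated) {
  if (is.null(offset)) offset <- rep(0, length(y))
  rate <- y / exp(offset)
  m <- max(mean(rate), 1e-8)
  v <- stats::var(rate)
  lt0 <- log(min(max(m^2 / max(v - m, 1e-8), 0.1), 100))
  b0 <- log(m)
  b1 <- 0
  if (!is.null(g)) {
    m1 <- max(mean(rate[g == 1]), 1e-8); m0 <- max(mean(rate[g == 0]), 1e-8)
    b0 <- log(m0); b1 <- log(m1) - log(m0)
  }
  f0 <- min(max(mean(y == 0), 0.02), 0.98)
  g0 <- stats::qlogis(f0 / 2 + 0.01)
  if (!zero_inflated) {
    base <- c(b0, if (!is.null(g)) b1, lt0)
    return(list(base, base + c(rep(0, length(base) - 1), 1),
                base - c(rep(0, length(base) - 1), 1)))
  }
  if (is.null(g)) {
    list(c(g0, b0, lt0), c(1, b0, lt0), c(-4, b0, lt0))
  } else {
    list(c(g0, 0, b0, b1, lt0), c(1, 0, b0, b1, lt0), c(-4, 0, b0, b1, lt0))
  }
}

#' Fit the ZINB regression by maximum likelihood
#'
#' Quasi-Newton (BFGS) optimization of the ZINB log-likelihood on
#' `(gamma, beta, log theta)` from three deterministic starting points
#' (moment-based, zero-heavy, NB-lean); the best converged fit is
#' returned. When `y` contains no zeros the zero component is fixed at
#' `pi = 0` and a plain NB regression is fitted.
#'
#' @param y non-negative integer counts (>= 3 observations per group).
#' @param group binary 0/1 indicator, or `NULL` for intercept-only.
#' @param offset per-observation offset on `log mu`.
#' @param zero_inflated force the zero component on/off; default: on iff
#'   zeros are present.
#' @return an object of class `zinb_fit` with components `coefficients`
#'   (`zero` and `count` coefficient vectors), `theta`, `log_theta`,
#'   `logLik`, `converged`, `df` (number of free parameters), `n`, and
#'   `zero_inflated`.
#' @export
fit_zinb <- function(y, group = NULL, offset = NULL, zero_inflated = NULL) {
  if (!is.null(group)) {
    g <- as.numeric(group)
    if (min(table(g)) < 3) stop2("need >= 3 observations per group")
  } else g <- NULL
  if (all(y == 0)) {
    out <- structure(list(coefficients = list(zero = NA, count = NA),
                          theta = NA_real_, log_theta = NA_real_,
                          logLik = NA_real_, converged = FALSE,
                          df = 0L, n = length(y), zero_inflated = TRUE,
                          degenerate = "all-zero"),
                     class = "zinb_fit")
    return(out)
  }
  if (is.null(zero_inflated)) zero_inflated <- any(y == 0)
  starts <- .zinb_starts(y, g, offset, zero_inflated)
  nll <- function(p) {
    v <- -zinb_loglik(p, y, g, offset, zero_inflated)
    if (!is.finite(v)) 1e12 else v
  }
  ngr <- function(p) {
    gr <- -.zinb_grad(p, y, g, offset, zero_inflated)
    gr[!is.finite(gr)] <- 0
    gr
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(
      stats::optim(st, nll, gr = ngr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit$converged <- fit$convergence == 0 && is.finite(fit$value)
    if (is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop2("ZINB optimization failed from every start")
  p <- best$par
  if (zero_inflated) {
    if (is.null(g)) {
      zero <- c(gamma0 = p[1]); count <- c(beta0 = p[2]); lt <- p[3]
    } else {
      zero <- c(gamma0 = p[1], gamma1 = p[2])
      count <- c(beta0 = p[3], beta1 = p[4]); lt <- p[5]
    }
  } else {
    zero <- c(gamma0 = -Inf)
    if (is.null(g)) { count <- c(beta0 = p[1]); lt <- p[2] }
    else { count <- c(beta0 = p[1], beta1 = p[2]); lt <- p[3] }
  }
  structure(list(coefficients = list(zero = zero, count = count),
                 theta = exp(lt), log_theta = lt,
                 logLik = -best$value, converged = best$converged,
                 df = length(p), n = length(y),
                 zero_inflated = zero_inflated),
            class = "zinb_fit")
}

#' @export
coef.zinb_fit <- function(object, ...) {
  c(stats::setNames(object$coefficients$zero,
                    paste0("zero.", names(object$coefficients$zero))),
    stats::setNames(object$coefficients$count,
                    paste0("count.", names(object$coefficients$count))),
    log_theta = object$log_theta)
}

#' @export
logLik.zinb_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated negative binomial fit (n =", x$n, ")\n")
  if (!is.null(x$degenerate)) {
    cat("  degenerate:", x$degenerate, "- not testable\n")
    return(invisible(x))
  }
  cat("  zero component: ",
      paste(names(x$coefficients$zero),
            sprintf("%.4f", x$coefficients$zero), collapse = ", "), "\n")
  cat("  count component:",
      paste(names(x$coefficients$count),
            sprintf("%.4f", x$coefficients$count), collapse = ", "), "\n")
  cat("  theta:", sprintf("%.4f", x$theta),
      " logLik:", sprintf("%.3f", x$logLik),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.zinb_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' ZINB likelihood-ratio differential expression
#'
#' Per gene, the full model (group term in both the dropout and count
#' components) is compared against the null (no group terms) by a
#' likelihood-ratio test: `Lambda = 2 (ll_full - ll_null)`, with the upper
#' tail of a chi-squared on 2 df (1 df when the zero component is disabled
#' because the gene has no zero counts). Log total UMIs enters the count
#' component as an offset. Reported alongside: the average log2 fold change
#' on back-transformed normalized expression
#' `log2((mean(expm1 x_in) + 1) / (mean(expm1 x_out) + 1))`, and the
#' detection fractions from raw counts. Genes detected in fewer than
#' `min_pct` of cells in both groups are skipped (recorded in the
#' `"skipped"` attribute).
#'
#' @param counts raw genes x cells count matrix.
#' @param norm matching normalized matrix (for the fold-change statistic).
#' @param cluster_cells,comparison_cells barcode vectors of the two groups
#'   (non-overlapping, both non-empty).
#' @param min_pct detection-fraction floor below which (in both groups) a
#'   gene is not tested.
#' @param adjust multiple-testing adjustment: `"bonferroni"` (default) or
#'   `"BH"`, applied over tested genes.
#' @param pseudocount pseudocount of the fold-change statistic.
#' @return a data frame of class `de_result` with columns `gene`,
#'   `avg_log2fc`, `pct_in`, `pct_out`, `p_raw`, `p_adj`, `converged`,
#'   ordered by increasing `p_raw`; skipped genes in `attr(, "skipped")`.
#' @export
lrt_de <- function(counts, norm, cluster_cells, comparison_cells,
                   min_pct = 0.10, adjust = c("bonferroni", "BH"),
                   pseudocount = 1) {
  adjust <- match.arg(adjust)
  if (!length(cluster_cells) || !length(comparison_cells))
    stop2("both cell groups must be non-empty")
  if (length(intersect(cluster_cells, comparison_cells)))
    stop2("cell groups overlap")
  all_cells <- c(cluster_cells, comparison_cells)
  miss <- setdiff(all_cells, colnames(counts))
  if (length(miss)) stop2("unknown cells: ", paste(miss, collapse = ", "))
  cm <- as_dense(counts[, all_cells, drop = FALSE])
  g <- rep(c(1, 0), c(length(cluster_cells), length(comparison_cells)))
  offset <- log(colSums(cm))
  det_in <- rowMeans(cm[, g == 1, drop = FALSE] > 0)
  det_out <- rowMeans(cm[, g == 0, drop = FALSE] > 0)
  test <- det_in >= min_pct | det_out >= min_pct
  if (!any(test)) stop2("all genes below the detection floor")
  xin <- norm[, cluster_cells, drop = FALSE]
  xout <- norm[, comparison_cells, drop = FALSE]

  genes <- rownames(cm)[test]
  stat <- p_raw <- numeric(length(genes))
  conv <- logical(length(genes))
  dfs <- integer(length(genes))
  for (k in seq_along(genes)) {
    y <- cm[genes[k], ]
    zi <- any(y == 0)
    full <- fit_zinb(y, g, offset, zero_inflated = zi)
    null <- fit_zinb(y, NULL, offset, zero_inflated = zi)
    lam <- 2 * (full$logLik - null$logLik)
    ok <- isTRUE(full$converged) && isTRUE(null$converged) &&
      is.finite(lam) && lam > -1e-6
    stat[k] <- max(lam, 0)
    dfs[k] <- if (zi) 2L else 1L
    conv[k] <- ok
    p_raw[k] <- if (ok) stats::pchisq(stat[k], df = dfs[k], lower.tail = FALSE)
                else NA_real_
  }
  p_adj <- stats::p.adjust(p_raw,
                           method = if (adjust == "BH") "BH" else "bonferroni")
  lfc <- log2((rowMeans(expm1(xin[genes, , drop = FALSE])) + pseudocount) /
              (rowMeans(expm1(xout[genes, , drop = FALSE])) + pseudocount))
  out <- data.frame(gene = genes, avg_log2fc = as.numeric(lfc),
                    pct_in = det_in[genes], pct_out = det_out[genes],
                    p_raw = p_raw, p_adj = p_adj, converged = conv,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- rownames(cm)[!test]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Biomarker threshold filter
#'
#' Keeps differential-expression records satisfying all of: adjusted
#' p-value below `alpha`, average log2 fold change above `min_lfc`,
#' detection in at least `min_pct` of the defining cluster's cells, and a
#' detection-fraction difference of at least `min_pct_diff` over the
#' comparison group. Input order is preserved.
#'
#' @param results data frame with columns `avg_log2fc`, `pct_in`,
#'   `pct_out`, `p_adj` (e.g. [lrt_de()] output or a published table).
#' @param alpha adjusted p-value threshold (strict).
#' @param min_lfc log2 fold-change threshold (strict).
#' @param min_pct minimum in-cluster detection fraction (inclusive).
#' @param min_pct_diff minimum detection-fraction difference (inclusive).
#' @return the surviving rows, order preserved.
#' @export
biomarker_filter <- function(results, alpha = 0.05, min_lfc = 1.0,
                             min_pct = 0.5, min_pct_diff = 0.5) {
  need <- c("avg_log2fc", "pct_in", "pct_out", "p_adj")
  if (!all(need %in% names(results)))
    stop2("results must have columns ", paste(need, collapse = ", "))
  keep <- results$p_adj < alpha &
    results$avg_log2fc > min_lfc &
    results$pct_in >= min_pct &
    (results$pct_in - results$pct_out) >= min_pct_diff
  keep[is.na(keep)] <- FALSE
  results[keep, , drop = FALSE]
}
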