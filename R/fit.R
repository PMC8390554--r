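#' Build a design matrix from a sample sheet
#'
#' Constructs a full-rank model matrix from the named covariates (factors
#' expanded to treatment contrasts with the first level as reference; for
#' `group`, "control" is forced to be the reference when present).  Columns
#' that are constant or aliased are dropped with a message.
#'
#' @param sheet sample-sheet `data.frame`.
#' @param covariates character vector of column names; defaults to those of
#'   `group`, `age`, `sex`, `pmi`, `batch` present and non-constant.
#' @param interactions character vector of `a:b` interaction terms.
#' @param surrogates optional numeric matrix of surrogate columns
#'   (samples x k) appended as `SV1..SVk`.
#' @return numeric design matrix with an intercept.
#' @export
buildDesign <- function(sheet, covariates = NULL, interactions = NULL,
                        surrogates = NULL) {
  if (is.null(covariates)) {
    cand <- c("group", "age", "sex", "pmi", "batch")
    covariates <- cand[vapply(cand, function(v)
      v %in% names(sheet) && length(unique(sheet[[v]])) > 1, TRUE)]
  }
  stopIfNot(length(covariates) > 0, "no usable covariates in sample sheet")
  df <- sheet[, covariates, drop = FALSE]
  for (v in covariates)
    if (is.character(df[[v]])) {
      lev <- sort(unique(df[[v]]))
      if (v == "group" && "control" %in% lev)
        lev <- c("control", setdiff(lev, "control"))
      df[[v]] <- factor(df[[v]], levels = lev)
    }
  terms <- c(covariates, interactions)
  X <- stats::model.matrix(stats::reformulate(terms), data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    pdmLog("dropping aliased design column(s): %s", paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  if (!is.null(surrogates) && NCOL(surrogates) > 0) {
    surrogates <- as.matrix(surrogates)
    colnames(surrogates) <- paste0("SV", seq_len(ncol(surrogates)))
    X <- cbind(X, surrogates)
  }
  X
}

#' Estimate surrogate variables by residual PCA
#'
#' Each cytosine's m values are regressed on the known covariates; principal
#' components of the residual matrix whose variance share exceeds
#' `varThreshold` (study rule: 5%) become surrogate columns.  Missing m
#' values are imputed with the site mean before the residual step, solely for
#' this estimation.
#'
#' @param m m-value matrix (sites x samples), `NA` allowed.
#' @param design known-covariate design matrix (samples x p).
#' @param varThreshold variance-share cutoff for retaining a component.
#' @return list with `scores` (samples x k, orthogonal), `k`, and
#'   `var_explained` (shares of all components).  `k = 0` yields a 0-column
#'   score matrix, which is valid.
#' @export
estimateSurrogates <- function(m, design, varThreshold = 0.05) {
  stopIfNot(nrow(design) >= ncol(design) + 2,
            "need at least 2 more samples than known covariates")
  mi <- m
  rm_ <- rowMeans(mi, na.rm = TRUE)
  idx <- which(is.na(mi), arr.ind = TRUE)
  if (nrow(idx)) mi[idx] <- rm_[idx[, 1]]
  ok <- is.finite(rm_) & apply(mi, 1, function(r) var(r) > 0)
  mi <- mi[ok, , drop = FALSE]
  H <- design %*% solve(crossprod(design), t(design))
  R <- mi - mi %*% t(H)           # residuals of every site in one pass
  R <- R - rowMeans(R)
  sv <- svd(R, nu = 0, nv = min(dim(R)))
  share <- sv$d^2 / sum(sv$d^2)
  k <- sum(share > varThreshold)
  if (k == 0)
    return(list(scores = matrix(0, ncol(m), 0), k = 0, var_explained = share))
  ## Final scores are re-estimated from the centered (covariate-unadjusted)
  ## matrix at sites that load on the residual components.  Scores taken
  ## straight from the residual PCA are orthogonal to the design, so the
  ## contrast coefficients would absorb any chance alignment between the
  ## latent factor and the contrast — a per-site bias that inflates type-I
  ## error.  Weighting sites by the residual variance share explained by the
  ## k components recovers the factors in full without capturing
  ## design-driven signal.
  lam <- R %*% sv$v[, seq_len(k), drop = FALSE]
  rss <- rowSums(R^2)
  w <- rowSums(lam^2) / pmax(rss, .Machine$double.eps)
  C <- (mi - rowMeans(mi)) * w
  svf <- svd(C, nu = 0, nv = min(k, min(dim(C))))
  scores <- svf$v[, seq_len(k), drop = FALSE]
  list(scores = qr.Q(qr(scores)), k = k, var_explained = share)
}

## median of a non-negative vector via partial sort (hot path)
fastMedian <- function(x) {
  n <- length(x)
  h <- n %/% 2L
  if (n %% 2L) sort.int(x, partial = h + 1L)[h + 1L]
  else {
    sx <- sort.int(x, partial = c(h, h + 1L))
    (sx[h] + sx[h + 1L]) / 2
  }
}

## Huber-psi IRLS for one response; returns NULL when under-determined.
## Normal-equation solves: designs are small and well conditioned here.
irlsHuber <- function(X, y, maxIter, tol, c_huber) {
  n <- length(y); p <- ncol(X)
  R0 <- tryCatch(chol(crossprod(X)), error = function(e) NULL)
  if (is.null(R0)) return(NULL)
  beta <- drop(backsolve(R0, backsolve(R0, crossprod(X, y),
                                       transpose = TRUE)))
  w <- rep(1, n)
  Rw <- R0
  for (it in seq_len(maxIter)) {
    r <- y - drop(X %*% beta)
    s <- fastMedian(abs(r)) / 0.6744898
    if (s <= .Machine$double.eps^0.5) { w <- rep(1, n); Rw <- R0; break }
    w <- pmin(1, c_huber * s / abs(r))
    Xw <- X * w
    Rw <- tryCatch(chol(crossprod(Xw, X)), error = function(e) NULL)
    if (is.null(Rw)) return(NULL)
    newbeta <- drop(backsolve(Rw, backsolve(Rw, crossprod(Xw, y),
                                            transpose = TRUE)))
    delta <- max(abs(newbeta - beta))
    beta <- newbeta
    if (delta < tol) break
  }
  r <- y - drop(X %*% beta)
  df <- n - p
  ## Huber-weight consistency factor E[min(1, c/|z|) z^2] = 2*pnorm(c) - 1
  ## under Gaussian residuals; without it sigma is biased low and tests
  ## anticonservative
  if (all(w == 1)) {
    sigma2 <- sum(r^2) / df
  } else {
    K <- 2 * pnorm(c_huber) - 1
    sigma2 <- sum(w * r^2) / (K * df)
  }
  cov_unscaled <- chol2inv(Rw)   # (X' W X)^-1 at the final weights
  list(coef = beta, sigma = sqrt(sigma2), df = df, cov_unscaled = cov_unscaled)
}

#' Per-cytosine robust linear fits
#'
#' Fits each cytosine's m values against the design by M-estimation:
#' iteratively reweighted least squares with the Huber psi function (tuning
#' constant 1.345), residual scale re-estimated each iteration by the MAD,
#' convergence when the largest coefficient change drops below `tol` or
#' `maxIter` (study value 100) is reached.  With all residuals inside
#' `c * scale` every weight is 1 and the result equals ordinary least
#' squares.  Cytosines whose complete cases leave the design rank-deficient
#' (or fewer than rank + 2 observations) are skipped and counted.
#'
#' @param m m-value matrix (sites x samples), `NA` for missing.
#' @param design design matrix (samples x p), full rank.
#' @param contrasts numeric matrix (p x K) of contrast coefficients; default
#'   one contrast per non-intercept design column.
#' @param maxIter,tol IRLS controls.
#' @param huberC Huber tuning constant.
#' @return list (class `pdm_fit`): `effects` and `stdev_unscaled`
#'   (sites x K), `coefficients` (sites x p), `sigma`, `df` (per site),
#'   `design`, `contrasts`, `skipped` (row names of unfittable sites).
#' @export
fitRobust <- function(m, design, contrasts = NULL, maxIter = 100,
                      tol = 1e-6, huberC = 1.345) {
  m <- as.matrix(m)
  p <- ncol(design)
  stopIfNot(qr(design)$rank == p, "design matrix is rank deficient")
  if (is.null(contrasts)) {
    keep <- setdiff(colnames(design), "(Intercept)")
    contrasts <- diag(p)[, match(keep, colnames(design)), drop = FALSE]
    rownames(contrasts) <- colnames(design)
    colnames(contrasts) <- keep
  }
  contrasts <- as.matrix(contrasts)
  K <- ncol(contrasts)
  G <- nrow(m)
  eff <- matrix(NA_real_, G, K, dimnames = list(rownames(m), colnames(contrasts)))
  sdu <- eff
  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(m), colnames(design)))
  sigma <- rep(NA_real_, G); dfv <- rep(NA_real_, G)
  skipped <- character()
  complete <- !is.na(m)
  for (i in seq_len(G)) {
    obs <- complete[i, ]
    if (sum(obs) < p + 2) { skipped <- c(skipped, rownames(m)[i]); next }
    Xo <- if (all(obs)) design else design[obs, , drop = FALSE]
    f <- irlsHuber(Xo, m[i, obs], maxIter, tol, huberC)
    if (is.null(f)) { skipped <- c(skipped, rownames(m)[i]); next }
    coefs[i, ] <- f$coef
    sigma[i] <- f$sigma
    dfv[i] <- f$df
    eff[i, ] <- drop(crossprod(contrasts, f$coef))
    sdu[i, ] <- sqrt(pmax(diag(crossprod(contrasts, f$cov_unscaled %*% contrasts)), 0))
  }
  if (length(skipped))
    pdmLog("skipped %d site(s) with under-determined fits", length(skipped))
  structure(list(effects = eff, stdev_unscaled = sdu, coefficients = coefs,
                 sigma = sigma, df = dfv, design = design,
                 contrasts = contrasts, skipped = skipped),
            class = "pdm_fit")
}

## Newton inversion of the trigamma function (for EB moment matching)
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-8) break
    }
    x
  }, 0)
}

#' Empirical-Bayes moderation of robust fits
#'
#' Estimates the scaled inverse-chi-square prior (d0, s0^2) of the residual
#' variances by moment matching of log sample variances (digamma/trigamma
#' inversion with Newton iterations), shrinks each variance to
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, and forms moderated
#' t statistics \eqn{t = \beta / (\tilde s \cdot \mathrm{se_{unscaled}})}
#' with two-sided p values on d + d0 degrees of freedom.  When the observed
#' variances show no excess dispersion over chi-square sampling noise, d0 is
#' capped at 1e7 (documented ceiling) rather than erroring.
#'
#' @param fit a `pdm_fit` from [fitRobust()].
#' @return the fit, extended with `t`, `p` (sites x K), `df_prior`,
#'   `s2_prior`, `s2_post`, `df_total`.
#' @export
moderateEBayes <- function(fit) {
  s2 <- fit$sigma^2
  df <- fit$df
  ok <- which(is.finite(s2) & s2 > 0 & df > 0)
  stopIfNot(length(ok) >= 10, "need >= 10 cytosines with positive residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    if (!is.finite(d0) || d0 > 1e7) d0 <- 1e7
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## no excess dispersion over chi-square sampling noise: degenerate prior
    ## at the (geometric) mean observed variance, d0 capped
    d0 <- 1e7
    s02 <- exp(mean(z))
  }
  s2_post <- rep(NA_real_, length(s2))
  s2_post[ok] <- (d0 * s02 + df[ok] * s2[ok]) / (d0 + df[ok])
  tmat <- fit$effects / (sqrt(s2_post) * fit$stdev_unscaled)
  df_total <- df + d0
  pmat <- 2 * pt(-abs(tmat), df_total)
  fit$t <- tmat
  fit$p <- pmat
  fit$df_prior <- d0
  fit$s2_prior <- s02
  fit$s2_post <- s2_post
  fit$df_total <- df_total
  fit
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p values in `[0, 1]` (`NA` allowed).
#' @return q values, `q >= p` elementwise.
#' @export
adjustBH <- function(p) p.adjust(p, method = "BH")

#' Percentage-point effect sizes
#'
#' Back-transforms each cytosine's fitted m values to beta values
#' (\eqn{B = 2^m/(2^m+1)}), refits the same linear design on those B values
#' by least squares, and reports each contrast's coefficient times 100 as
#' percentage points per unit covariate.
#'
#' @param fit a `pdm_fit` from [fitRobust()].
#' @return matrix (sites x K) of percentage-point changes.
#' @export
percentChange <- function(fit) {
  X <- fit$design
  fitted_m <- fit$coefficients %*% t(X)          # sites x samples
  Bhat <- mToBeta(fitted_m)
  XtXi_Xt <- solve(crossprod(X), t(X))
  betaB <- Bhat %*% t(XtXi_Xt)                   # sites x p
  pct <- 100 * betaB %*% fit$contrasts
  dimnames(pct) <- dimnames(fit$effects)
  pct
}

#' Per-cytosine differential-methylation analysis
#'
#' Composes the full modelling chain: shrunken M-value transform (factor
#' 1000, or 2000 when CpH sites are present), residual-PCA surrogate
#' estimation, per-cytosine robust IRLS fits, contrast extraction,
#' empirical-Bayes moderation, BH adjustment per contrast, and
#' percentage-point effect sizes.  Sites with `q < fdr_q` are flagged
#' significant.
#'
#' @param counts a preprocessed [MethylCountSet-class] (or a beta matrix via
#'   `beta`).
#' @param config a [panelConfig()] list.
#' @param covariates,interactions passed to [buildDesign()].
#' @param contrasts contrast matrix (rows = design columns) or `NULL` for the
#'   default case-vs-control contrast (`groupcase`) plus any other
#'   non-intercept columns named in `report_contrasts`.
#' @param report_contrasts names of contrasts to report; default `groupcase`
#'   if present, else all non-intercept columns.
#' @param surrogates logical, estimate surrogate variables (default `TRUE`).
#' @param beta optional beta matrix overriding `betaValues(counts)`.
#' @param sheet sample sheet; defaults to `sampleSheet(counts)`.
#' @return `data.frame` (class `pdm_fit_table`), one row per cytosine x
#'   contrast: key columns, `contrast`, `beta_m`, `pct_change`, `sigma`,
#'   `df_resid`, `t_mod`, `p`, `q`, `direction`, `significant`; attributes
#'   `df_prior`, `s2_prior`, `n_surrogates`.
#' @export
runDifferential <- function(counts, config = panelConfig(),
                            covariates = NULL, interactions = NULL,
                            contrasts = NULL, report_contrasts = NULL,
                            surrogates = TRUE, beta = NULL, sheet = NULL) {
  if (is.null(beta)) beta <- betaValues(counts)
  if (is.null(sheet)) sheet <- sampleSheet(counts)
  keys <- if (is(counts, "MethylCountSet")) cytosineKeys(counts) else NULL
  f <- if (!is.null(keys) && any(keys$context == "CpH"))
    config$shrink_factor_cph else config$shrink_factor
  m <- betaToM(beta, f)
  X0 <- buildDesign(sheet, covariates, interactions)
  sv <- if (surrogates)
    estimateSurrogates(m, X0, config$sv_var_threshold)
  else list(scores = matrix(0, nrow(X0), 0), k = 0)
  ## keep enough residual df for per-site fits (small-cohort guard)
  kmax <- max(0, nrow(X0) - ncol(X0) - 4)
  if (sv$k > kmax) {
    pdmLog("capping surrogates at %d (of %d) to preserve residual df",
           kmax, sv$k)
    sv$k <- kmax
    sv$scores <- sv$scores[, seq_len(kmax), drop = FALSE]
  }
  X <- buildDesign(sheet, covariates, interactions, surrogates = sv$scores)
  if (!is.null(contrasts)) {
    C <- matrix(0, ncol(X), ncol(as.matrix(contrasts)),
                dimnames = list(colnames(X), colnames(as.matrix(contrasts))))
    C[rownames(as.matrix(contrasts)), ] <- as.matrix(contrasts)
  } else C <- NULL
  fit <- fitRobust(m, X, contrasts = C, maxIter = config$irls_max_iter,
                   tol = config$irls_tol, huberC = config$huber_c)
  fit <- moderateEBayes(fit)
  pct <- percentChange(fit)
  cn <- colnames(fit$effects)
  if (is.null(report_contrasts))
    report_contrasts <- if ("groupcase" %in% cn) "groupcase" else
      grep("^SV\\d+$", cn, invert = TRUE, value = TRUE)
  rows <- lapply(report_contrasts, function(cc) {
    q <- adjustBH(fit$p[, cc])
    out <- data.frame(
      key = rownames(m),
      contrast = cc,
      beta_m = fit$effects[, cc],
      pct_change = pct[, cc],
      sigma = fit$sigma,
      df_resid = fit$df,
      t_mod = fit$t[, cc],
      p = fit$p[, cc],
      q = q,
      direction = sign(fit$effects[, cc]),
      stringsAsFactors = FALSE)
    out$significant <- !is.na(q) & q < config$fdr_q
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(keys)) {
    res <- cbind(keys[match(res$key, rownames(keys)), ], res)
    rownames(res) <- NULL
  }
  attr(res, "df_prior") <- fit$df_prior
  attr(res, "s2_prior") <- fit$s2_prior
  attr(res, "n_surrogates") <- sv$k
  attr(res, "shrink_factor") <- f
  class(res) <- c("pdm_fit_table", "data.frame")
  res
}
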