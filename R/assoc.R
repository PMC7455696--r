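#' Additive genomic relationship matrix
#'
#' Centred, frequency-standardised dosages averaged over sites:
#' `K = X X' / m` with `X[i,j] = (d[i,j] - 2 p_j) / sqrt(2 p_j (1 - p_j))`.
#' Monomorphic sites are dropped; missing dosages are mean-imputed
#' (centred to 0).
#'
#' @param d dosage matrix (`n x m`, samples as rows) or a `geno_matrix`.
#' @return symmetric `n x n` matrix, positive semi-definite up to rounding.
#' @export
grm <- function(d) {
  if (inherits(d, "geno_matrix")) d <- dosage(d)
  if (nrow(d) < 2L) stop_input("need >= 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  v <- apply(d, 2, function(x) var(x[!is.na(x)]))
  poly <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  if (!any(poly)) stop_input("all sites monomorphic")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  x <- sweep(d, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  tcrossprod(x) / ncol(x)
}

# build a fixed-effect design from a data.frame/matrix of covariates
covar_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (is.matrix(covariates)) {
    if (!("(Intercept)" %in% colnames(covariates)))
      covariates <- cbind(`(Intercept)` = 1, covariates)
    return(covariates)
  }
  df <- as.data.frame(covariates)
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  model.matrix(~ ., data = df)
}

#' REML variance components under a GRM polygenic model
#'
#' Fits `y = W b + g + e` with `g ~ N(0, Vg K)` and `e ~ N(0, Ve I)` by
#' restricted maximum likelihood, profiling over `delta = Ve / Vg` on the
#' eigenbasis of K (one eigendecomposition, then a 1-D optimisation with
#' convergence tolerance 1e-8 on log-delta).
#'
#' @param y phenotype vector.
#' @param covariates data.frame or design matrix of fixed covariates (an
#'   intercept is added); `NULL` for intercept only.
#' @param K relationship matrix from [grm()].
#' @return object of class `vc_fit`: `Vg`, `Ve`, `h2`, `beta`, `logREML`,
#'   `converged`, `degenerate`, plus the eigendecomposition for reuse by
#'   [assoc_scan()].
#' @export
fit_null <- function(y, covariates = NULL, K = NULL) {
  n <- length(y)
  if (is.null(K) || nrow(K) != n) stop_input("K must be n x n matching y")
  W <- covar_design(covariates, n)
  if (qr(W)$rank < ncol(W)) stop_input("constant or collinear covariates in the null design")
  p <- ncol(W)
  eig <- eigen(K, symmetric = TRUE)
  d_eig <- pmax(eig$values, 0)
  ys <- crossprod(eig$vectors, y)
  Ws <- crossprod(eig$vectors, W)
  ldWW <- determinant(crossprod(W), logarithm = TRUE)$modulus

  prof <- function(log_delta) {
    delta <- exp(log_delta)
    lam <- d_eig + delta
    wi <- 1 / lam
    WtW <- crossprod(Ws * wi, Ws)
    Wty <- crossprod(Ws * wi, ys)
    beta <- solve(WtW, Wty)
    r <- ys - Ws %*% beta
    rss <- sum(r^2 * wi)
    vg <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * vg) + (n - p) + sum(log(lam)) +
                  determinant(WtW, logarithm = TRUE)$modulus - ldWW)
    list(ll = as.numeric(ll), vg = vg, delta = delta, beta = beta)
  }
  opt <- optimize(function(ld) prof(ld)$ll, interval = c(-12, 12),
                  maximum = TRUE, tol = 1e-8)
  # compare against the boundaries (h2 -> 1 and h2 -> 0)
  cand <- c(opt$maximum, -12, 12)
  lls <- vapply(cand, function(ld) prof(ld)$ll, 0)
  best <- prof(cand[which.max(lls)])
  vg <- best$vg; ve <- best$vg * best$delta
  degenerate <- var(y) < .Machine$double.eps || (vg + ve) < 1e-10 * var(y)
  if (degenerate) warning("degenerate fit: residual model has (near-)zero variance")
  structure(list(Vg = vg, Ve = ve, h2 = vg / (vg + ve), delta = best$delta,
                 beta = drop(best$beta), logREML = max(lls),
                 converged = is.finite(max(lls)), degenerate = degenerate,
                 eigen = list(U = eig$vectors, d = d_eig), W = W, y = y),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("vc_fit: Vg = %.4g, Ve = %.4g, h2 = %.3f (logREML %.2f)\n",
              x$Vg, x$Ve, x$h2, x$logREML))
  invisible(x)
}

#' Mixed-model association scan
#'
#' Per-SNP Wald test with the covariance structure fixed at the null REML
#' estimates (single-fit approximation): data are rotated to the GRM
#' eigenbasis, weighted by `1/(Vg d_i + Ve)`, and each SNP is tested by a
#' weighted least-squares t-test given the covariates. With an identity GRM
#' this reduces exactly to OLS covariate-adjusted regression.
#'
#' @param gm a `geno_matrix` (or dosage matrix) for the scanned SNPs.
#' @param vc a `vc_fit` from [fit_null()] on the same samples (carries `y`
#'   and the covariate design).
#' @return data.frame `id`, `chrom`, `pos` (1-based), `beta`, `se`, `stat`,
#'   `p`, sorted by position; monomorphic SNPs keep an `NA` row.
#' @export
assoc_scan <- function(gm, vc) {
  d <- if (inherits(gm, "geno_matrix")) dosage(gm) else as.matrix(gm)
  n <- nrow(d)
  if (n != length(vc$y)) stop_input("sample mismatch between genotypes and null fit")
  U <- vc$eigen$U
  w <- 1 / (vc$Vg * vc$eigen$d + vc$Ve)
  sw <- sqrt(w)
  ys <- crossprod(U, vc$y) * sw
  Ws <- crossprod(U, vc$W) * sw
  qrW <- qr(Ws)
  yr <- qr.resid(qrW, ys)
  dimp <- d
  cm <- colMeans(d, na.rm = TRUE)
  nas <- which(is.na(dimp))
  if (length(nas)) dimp[nas] <- cm[(nas - 1) %/% n + 1]
  Gs <- crossprod(U, dimp) * sw
  Gr <- qr.resid(qrW, Gs)
  gg <- colSums(Gr^2)
  gy <- colSums(Gr * as.vector(yr))
  beta <- gy / gg
  df <- n - ncol(Ws) - 1L
  rss <- sum(yr^2) - beta^2 * gg
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  mono <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) < 2L)
  beta[mono] <- se[mono] <- tstat[mono] <- pval[mono] <- NA_real_
  if (inherits(gm, "geno_matrix"))
    data.frame(id = gm$ids, chrom = gm$chrom, pos = gm$pos + 1L,
               beta = beta, se = se, stat = tstat, p = pval,
               row.names = NULL, stringsAsFactors = FALSE)
  else
    data.frame(id = colnames(d) %||% paste0("snp", seq_len(ncol(d))),
               chrom = NA_character_, pos = seq_len(ncol(d)),
               beta = beta, se = se, stat = tstat, p = pval,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' @param p vector of p-values.
#' @return lambda, the median association chi-square over its null
#'   expectation.
#' @export
genomic_lambda <- function(p) {
  chi <- stats::qchisq(1 - p, df = 1)
  median(chi, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Fraction of genetic variance explained by a genotyped segment
#'
#' Fits the segment's genotype classes (e.g. founder-origin diplotype
#' classes) jointly with the covariates by least squares; the segment
#' variance is the class-frequency-weighted variance of the fitted class
#' effects, reported as a fraction of the additive genetic variance Vg from
#' the null REML fit. Classes with fewer than `min_class_n` members are
#' merged into the class with the nearest mean phenotype (logged).
#'
#' @param classes factor/character vector of per-sample segment classes.
#' @param y phenotype vector.
#' @param covariates covariates as in [fit_null()].
#' @param vc a `vc_fit` supplying Vg.
#' @param min_class_n minimum class size before merging (default 3).
#' @return list `fraction` (clipped to 1 with a warning if exceeded),
#'   `fraction_raw`, `segment_variance`, `class_effects`, `class_freq`,
#'   `Vg`.
#' @export
variance_explained <- function(classes, y, covariates = NULL, vc,
                               min_class_n = 3L) {
  cls <- as.character(classes)
  repeat {
    tab <- table(cls)
    small <- names(tab)[tab < min_class_n]
    if (!length(small) || length(tab) <= 1L) break
    s <- small[1L]
    means <- tapply(y, cls, mean)
    others <- setdiff(names(tab), s)
    target <- others[which.min(abs(means[others] - means[s]))]
    log_info(sprintf("variance_explained: merging class '%s' (n=%d) into '%s'",
                     s, tab[s], target))
    cls[cls == s] <- target
  }
  W <- covar_design(covariates, length(y))
  f <- factor(cls)
  X <- cbind(W, model.matrix(~ f)[, -1, drop = FALSE])
  fit <- lm.fit(X, y)
  co <- fit$coefficients
  eff <- c(0, co[seq(ncol(W) + 1L, length(co))])
  eff[is.na(eff)] <- 0
  names(eff) <- levels(f)
  freq <- as.numeric(table(f)) / length(y)
  mu <- sum(freq * eff)
  segvar <- sum(freq * (eff - mu)^2)
  frac <- segvar / vc$Vg
  if (is.finite(frac) && frac > 1) warning("segment variance exceeds Vg; fraction clipped to 1")
  list(fraction = min(frac, 1), fraction_raw = frac, segment_variance = segvar,
       class_effects = eff, class_freq = stats::setNames(freq, levels(f)),
       Vg = vc$Vg)
}
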