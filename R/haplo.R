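# Haplotype frequency estimation over tag SNPs, rare-haplotype grouping,
# substitution-effect estimation (Y = Xb + Zu + e) and backward-elimination
# multi-locus SNP selection.

# enumerate the compatible (unordered) haplotype pairs for one unphased
# multilocus genotype (vector of 0/1/2); first heterozygous site is fixed
# to break the mirror symmetry
enumerate_pairs <- function(g) {
  het <- which(g == 1L)
  base <- as.integer(g == 2L)  # homozygous sites fully determined
  if (!length(het)) {
    h <- paste(base, collapse = "")
    return(list(h1 = h, h2 = h))
  }
  free <- het[-1L]
  k <- length(free)
  n_combo <- 2L^k
  h1 <- h2 <- character(n_combo)
  for (r in seq_len(n_combo)) {
    a <- b <- base
    a[het[1L]] <- 0L; b[het[1L]] <- 1L  # fix first het: unordered pairs
    if (k) {
      bits <- as.integer(intToBits(r - 1L))[seq_len(k)]
      a[free] <- bits
      b[free] <- 1L - bits
    }
    h1[r] <- paste(a, collapse = "")
    h2[r] <- paste(b, collapse = "")
  }
  list(h1 = h1, h2 = h2)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Classic multilocus EM over the enumerable diplotype space: each
#' individual's unphased tag-SNP genotype is expanded into its compatible
#' haplotype pairs, and frequencies are iterated from a uniform start until
#' the largest frequency change drops below `tol` (default 1e-6) or
#' `max_iter` iterations. The log-likelihood is non-decreasing across
#' iterations (tracked in `ll_path`). Individuals with missing tag
#' genotypes are dropped with a message.
#'
#' @param geno dosage matrix (`n x m`, 0/1/2) over at most ~20 tag SNPs.
#' @param max_iter,tol convergence controls.
#' @return object of class `hap_freqs`: `freq` (named, sums to 1),
#'   `posteriors` (per individual data.frame `h1`, `h2`, `prob`),
#'   `ll_path`, `n_iter`, `converged`, `n_used`.
#' @export
em_haplotype_freqs <- function(geno, max_iter = 1000L, tol = 1e-6) {
  geno <- as.matrix(geno)
  if (ncol(geno) > 20L) stop_input("more than ~20 tag SNPs: diplotype space not enumerable")
  ok <- stats::complete.cases(geno)
  if (!all(ok)) log_info(sprintf("EM: dropping %d individuals with missing tag genotypes", sum(!ok)))
  geno <- geno[ok, , drop = FALSE]
  if (!nrow(geno)) stop_input("no complete individuals")
  pairs <- apply(geno, 1L, enumerate_pairs, simplify = FALSE)
  haps <- unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2))))
  f <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  ll_path <- numeric(0)
  for (it in seq_len(max_iter)) {
    counts <- stats::setNames(rep(0, length(haps)), haps)
    ll <- 0
    post <- lapply(pairs, function(p) {
      w <- ifelse(p$h1 == p$h2, f[p$h1]^2, 2 * f[p$h1] * f[p$h2])
      tot <- sum(w)
      list(w = w / tot, tot = tot)
    })
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]; w <- post[[i]]$w
      ll <- ll + log(post[[i]]$tot)
      for (j in seq_along(w)) {
        counts[p$h1[j]] <- counts[p$h1[j]] + w[j]
        counts[p$h2[j]] <- counts[p$h2[j]] + w[j]
      }
    }
    ll_path <- c(ll_path, ll)
    f_new <- counts / (2 * nrow(geno))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  posteriors <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    w <- ifelse(p$h1 == p$h2, f[p$h1]^2, 2 * f[p$h1] * f[p$h2])
    data.frame(h1 = p$h1, h2 = p$h2, prob = w / sum(w), stringsAsFactors = FALSE)
  })
  structure(list(freq = sort(f, decreasing = TRUE), posteriors = posteriors,
                 ll_path = ll_path, n_iter = length(ll_path),
                 converged = length(ll_path) < max_iter || isTRUE(delta < tol),
                 n_used = nrow(geno)),
            class = "hap_freqs")
}

#' Haplotype frequencies and design from phased chromatids
#'
#' The phased entry point that bypasses the EM: counts tag-SNP haplotype
#' strings directly over chromatids.
#'
#' @param gm a phased `geno_matrix` restricted to the tag SNPs (or a
#'   chromatid-by-site 0/1 matrix).
#' @return list `freq` (named frequencies) and `strings` (per chromatid).
#' @export
hap_freqs_phased <- function(gm) {
  h <- if (inherits(gm, "geno_matrix")) {
    if (!gm$phased) stop_input("input is not phased; use em_haplotype_freqs()")
    gm$hap
  } else as.matrix(gm)
  ok <- rowSums(is.na(h)) == 0L
  strings <- apply(h[ok, , drop = FALSE], 1L, paste, collapse = "")
  f <- table(strings) / length(strings)
  list(freq = sort(stats::setNames(as.numeric(f), names(f)), decreasing = TRUE),
       strings = strings)
}

#' Group rare haplotypes into an "Other" class
#'
#' Haplotypes with frequency strictly above `min_freq` are kept
#' individually; the remainder are pooled into one `"Other"` class carrying
#' their summed frequency.
#'
#' @param freq named frequency vector summing to 1.
#' @param min_freq grouping threshold (default 0.01).
#' @return list `freq` (majors then `Other`), `members` (haplotypes pooled
#'   into Other).
#' @export
group_rare <- function(freq, min_freq = 0.01) {
  if (abs(sum(freq) - 1) > 1e-6) stop_input("frequencies must sum to 1")
  major <- freq[freq > min_freq]
  rare <- freq[freq <= min_freq]
  out <- sort(major, decreasing = TRUE)
  if (length(rare)) out <- c(out, Other = sum(rare))
  list(freq = out, members = names(rare))
}

#' Per-individual haplotype dosage design
#'
#' Builds the `Z` matrix of the haplotype model: one column per major
#' haplotype plus `"Other"`, each row holding the individual's 0/1/2 copy
#' count; rows sum to 2.
#'
#' @param strings chromatid haplotype strings, two consecutive entries per
#'   individual (as from [hap_freqs_phased()]).
#' @param grouping result of [group_rare()].
#' @return `n x H` matrix.
#' @export
hap_design <- function(strings, grouping) {
  major <- setdiff(names(grouping$freq), "Other")
  lab <- ifelse(strings %in% major, strings, "Other")
  cols <- names(grouping$freq)
  n <- length(strings) / 2L
  Z <- matrix(0L, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    for (s in lab[c(2L * i - 1L, 2L * i)]) Z[i, s] <- Z[i, s] + 1L
  }
  Z
}

#' Haplotype substitution effects
#'
#' Least-squares fit of `Y = X beta + Z u + e` under a sum-to-zero
#' constraint on the haplotype effects `u` (no reference haplotype is
#' singled out; effects are expressed as substitution effects around the
#' mean). Covariates enter unpenalised; rank deficiency of the constrained
#' design beyond the one forced constraint is an error naming the aliased
#' columns.
#'
#' @param y phenotype vector.
#' @param covariates covariates as in [fit_null()] (e.g. sex).
#' @param Z haplotype dosage design from [hap_design()] (rows sum to 2).
#' @return list `effects` (data.frame `haplotype`, `effect`, `se`, sorted
#'   ascending by effect), `beta` (covariate effects), `sigma`, `fitted`.
#' @export
substitution_effects <- function(y, covariates = NULL, Z) {
  n <- length(y)
  if (nrow(Z) != n) stop_input("Z rows must match y")
  if (any(abs(rowSums(Z) - 2) > 1e-9)) stop_input("each row of Z must sum to 2")
  H <- ncol(Z)
  W <- covar_design(covariates, n)
  # sum-to-zero contrast: u = C alpha with C = rbind(I, -1)
  C <- rbind(diag(H - 1L), rep(-1, H - 1L))
  X <- cbind(W, Z %*% C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop_input("aliased columns in haplotype design: ",
               paste(aliased, collapse = ", "))
  }
  fit <- lm(y ~ X - 1)
  co <- coef(fit)
  V <- vcov(fit)
  ai <- seq(ncol(W) + 1L, ncol(X))
  alpha <- co[ai]
  u <- as.vector(C %*% alpha)
  Vu <- C %*% V[ai, ai] %*% t(C)
  eff <- data.frame(haplotype = colnames(Z), effect = u, se = sqrt(diag(Vu)),
                    stringsAsFactors = FALSE)
  eff <- eff[order(eff$effect), ]
  rownames(eff) <- NULL
  list(effects = eff,
       beta = stats::setNames(co[seq_len(ncol(W))], colnames(W)),
       sigma = summary(fit)$sigma, fitted = fitted(fit))
}

#' Backward-elimination multi-locus SNP selection
#'
#' Iteratively fits the joint linear model (covariates + background SNPs,
#' always retained + candidate SNPs), computes per-candidate Wald p-values,
#' and applies a Benjamini-Hochberg FDR test across candidates. While any
#' candidate fails the FDR threshold, the single candidate with the largest
#' p-value is dropped (ties: larger position) and the model refitted; the
#' procedure stops when all surviving candidates pass. The BH adjustment
#' uses the *initial* number of candidates in every round, so that on
#' purely null data the expected probability of retaining any SNP is about
#' the FDR level. If the starting predictor count reaches `n`, candidates
#' are pre-screened to the `n/2` best marginal p-values (logged).
#' Collinear candidates are resolved by dropping the later-position member.
#'
#' @param y phenotype vector.
#' @param candidates dosage matrix of candidate SNPs (columns named by id).
#' @param positions positions of the candidates (for tie-breaking), same
#'   order as columns.
#' @param background dosage matrix of background-control SNPs (always
#'   retained), or `NULL`.
#' @param covariates covariates as in [fit_null()].
#' @param fdr FDR threshold (default 0.05).
#' @return list `retained` (ids), `retained_index`, `final_p`, `audit`
#'   (per-round data.frame: round, n_candidates, dropped, drop_p, reason).
#' @export
backward_elimination <- function(y, candidates, positions = NULL,
                                 background = NULL, covariates = NULL,
                                 fdr = 0.05) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("snp", seq_len(ncol(candidates)))
  positions <- positions %||% seq_len(ncol(candidates))
  n <- length(y)
  W <- covar_design(covariates, n)
  B <- if (is.null(background)) NULL else as.matrix(background)
  alive <- seq_len(ncol(candidates))
  fixed_cols <- ncol(W) + (if (is.null(B)) 0L else ncol(B))
  if (fixed_cols + length(alive) >= n) {
    marg <- vapply(alive, function(j) {
      f <- lm.fit(cbind(W, candidates[, j]), y)
      r1 <- sum(f$residuals^2); r0 <- sum(lm.fit(W, y)$residuals^2)
      fstat <- (r0 - r1) / (r1 / (n - ncol(W) - 1L))
      stats::pf(fstat, 1, n - ncol(W) - 1L, lower.tail = FALSE)
    }, 0)
    keep_n <- max(1L, floor(n / 2) - fixed_cols)
    alive <- alive[order(marg)][seq_len(min(keep_n, length(alive)))]
    alive <- sort(alive)
    log_info(sprintf("backward elimination: pre-screened %d -> %d candidates by marginal p",
                     ncol(candidates), length(alive)))
  }
  m0 <- length(alive)
  audit <- list(); round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    if (!length(alive)) break
    X <- cbind(W, B, candidates[, alive, drop = FALSE])
    fit <- lm.fit(X, y)
    co <- fit$coefficients
    ci <- seq(ncol(X) - length(alive) + 1L, ncol(X))
    if (anyNA(co[-ci])) stop_input("collinear covariate/background design")
    if (anyNA(co[ci])) {
      bad <- alive[is.na(co[ci])]
      drop_j <- bad[which.max(positions[bad])]
      audit[[round_i]] <- data.frame(round = round_i, n_candidates = length(alive),
                                     dropped = colnames(candidates)[drop_j],
                                     drop_p = NA_real_, reason = "collinear")
      alive <- setdiff(alive, drop_j)
      next
    }
    df <- n - fit$rank
    sigma2 <- sum(fit$residuals^2) / df
    R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se <- sqrt(diag(R) * sigma2)[order(fit$qr$pivot)][ci]
    tstat <- co[ci] / se
    pval <- 2 * pt(-abs(tstat), df)
    padj <- p.adjust(pval, method = "BH", n = m0)
    if (all(padj <= fdr)) {
      audit[[round_i]] <- data.frame(round = round_i, n_candidates = length(alive),
                                     dropped = NA_character_, drop_p = NA_real_,
                                     reason = "all pass")
      break
    }
    worst <- which(pval == max(pval))
    drop_k <- worst[which.max(positions[alive[worst]])]
    drop_j <- alive[drop_k]
    audit[[round_i]] <- data.frame(round = round_i, n_candidates = length(alive),
                                   dropped = colnames(candidates)[drop_j],
                                   drop_p = pval[drop_k], reason = "fails FDR")
    alive <- setdiff(alive, drop_j)
  }
  final_p <- NULL
  if (length(alive)) {
    X <- cbind(W, B, candidates[, alive, drop = FALSE])
    fit <- lm.fit(X, y)
    ci <- seq(ncol(X) - length(alive) + 1L, ncol(X))
    df <- n - fit$rank
    sigma2 <- sum(fit$residuals^2) / df
    R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se <- sqrt(diag(R) * sigma2)[order(fit$qr$pivot)][ci]
    final_p <- stats::setNames(2 * pt(-abs(fit$coefficients[ci] / se), df),
                               colnames(candidates)[alive])
  }
  list(retained = colnames(candidates)[alive], retained_index = alive,
       final_p = final_p, audit = do.call(rbind, audit))
}
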