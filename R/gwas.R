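#' Repeated-measures mixed-model association scan
#'
#' Two-stage scheme for a GWAS of territory wealth with repeated records per
#' individual. Stage one fits the SNP-free null model by REML
#' ([fit_lmm_reml()]): wealth on fixed sex and year (factor) effects with a
#' genomic-relatedness-structured individual effect plus an independent
#' individual identity effect. Stage two holds the estimated variance
#' components fixed and estimates each SNP's effect and standard error by
#' generalised least squares against the null covariance; significance is a
#' Wald test, `(beta / se)^2` against chi-squared with 1 df. SNPs below the
#' MAF floor or with zero variance get `NA` p-values and are counted in the
#' `n_skipped` attribute.
#'
#' @param records Data frame of breeding records (`individual_id`, `year`,
#'   `wealth`).
#' @param geno Dosage matrix (individuals x SNPs, rownames ids) covering all
#'   record individuals.
#' @param K Genomic relationship matrix over (at least) the record
#'   individuals.
#' @param info Optional data frame `individual_id`, `sex` for the fixed sex
#'   effect.
#' @param snp_map Optional tibble `snp_id`, `chrom`, `pos` (one row per SNP
#'   column).
#' @param min_maf MAF floor for tested SNPs, default 0.01.
#' @return A tibble of class `gwas_result` with columns `snp_id`, `chrom`,
#'   `pos`, `maf`, `beta`, `se`, `wald`, `p`; attributes `null_fit` and
#'   `n_skipped`.
#' @export
gwas_scan <- function(records, geno, K, info = NULL, snp_map = NULL,
                      min_maf = 0.01) {
  check_columns(records, c("individual_id", "year", "wealth"), "records")
  ids <- as.character(records$individual_id)
  gids <- rownames(geno)
  if (is.null(gids)) abort("`geno` must carry individual ids as rownames")
  missing <- setdiff(unique(ids), gids)
  if (length(missing)) {
    abort(sprintf("individuals with records but no genotypes: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (is.null(rownames(K))) abort("`K` must carry individual ids as dimnames")

  n <- nrow(records)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(info)) {
    check_columns(info, c("individual_id", "sex"), "info")
    sx <- info$sex[match(records$individual_id, info$individual_id)]
    if (length(unique(sx)) > 1) {
      X <- cbind(X, sex = as.numeric(factor(sx)) - 1)
    }
  }
  if (length(unique(records$year)) > 1) {
    Xy <- model.matrix(~ factor(records$year))[, -1, drop = FALSE]
    colnames(Xy) <- paste0("year", sort(unique(records$year))[-1])
    X <- cbind(X, Xy)
  }

  uids <- unique(ids)
  fi <- factor(ids, levels = uids)
  Z <- model.matrix(~ 0 + fi)
  Ksub <- unclass(K)[uids, uids, drop = FALSE]
  random <- list(genomic = list(Z = Z, K = Ksub))
  if (anyDuplicated(ids)) random$individual <- fi
  null_fit <- fit_lmm_reml(records$wealth, X = X, random = random)
  if (!null_fit$converged) abort("GWAS null model did not converge; aborting scan")

  # rebuild P at the fitted components
  th <- null_fit$sigma2
  V <- diag(th[["residual"]], n) + th[[1]] * (Z %*% Ksub %*% t(Z))
  if (length(th) == 3) V <- V + th[[2]] * tcrossprod(Z)
  Vinv <- chol2inv(chol_jitter(V, "null-model covariance"))
  XtVi <- crossprod(X, Vinv)
  P <- Vinv - t(XtVi) %*% solve(XtVi %*% X, XtVi)
  Py <- drop(P %*% records$wealth)

  gind <- geno[uids, , drop = FALSE]
  p_hat <- colMeans(gind) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  snp_var <- colMeans(gind^2) - colMeans(gind)^2
  test <- maf >= min_maf & maf > 0 & snp_var > 0
  m <- ncol(geno)
  beta <- se <- rep(NA_real_, m)
  if (any(test)) {
    S <- geno[match(ids, gids), test, drop = FALSE]
    PS <- P %*% S
    xPx <- colSums(S * PS)
    xPy <- drop(crossprod(S, Py))
    beta[test] <- xPy / xPx
    se[test] <- 1 / sqrt(xPx)
  }
  wald <- (beta / se)^2
  p <- pchisq(wald, df = 1, lower.tail = FALSE)

  if (is.null(snp_map)) {
    snp_map <- tibble::tibble(
      snp_id = colnames(geno) %||% paste0("snp", seq_len(m)),
      chrom = "1", pos = seq_len(m))
  }
  out <- tibble::tibble(
    snp_id = snp_map$snp_id, chrom = snp_map$chrom, pos = snp_map$pos,
    maf = unname(maf), beta = beta, se = se, wald = wald, p = p
  )
  attr(out, "null_fit") <- null_fit
  attr(out, "n_skipped") <- sum(!test)
  class(out) <- c("gwas_result", class(out))
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 38705)  # 1.29e-6
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  check_number(n_tests, "n_tests", lower = 1)
  alpha / n_tests
}

#' Top-ranked SNPs of a scan
#'
#' Ranks by ascending p-value; ties are broken by descending Wald statistic,
#' then by genomic position (chromosome, then position), so the ranking is
#' deterministic. SNPs with missing p-values are excluded.
#'
#' @param result A `gwas_result`.
#' @param k Number of SNPs to return (default 100).
#' @return The top `k` rows with a `rank` column.
#' @export
top_k <- function(result, k = 100) {
  ok <- result[!is.na(result$p), ]
  check_number(k, "k", lower = 1, upper = nrow(ok))
  ord <- order(ok$p, -ok$wald, ok$chrom, ok$pos)
  out <- ok[ord[seq_len(k)], ]
  out$rank <- seq_len(k)
  out
}
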