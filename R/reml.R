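#' Fit a Gaussian linear mixed model by REML
#'
#' General variance-component engine used by the animal model, the genomic
#' heritability fits and the GWAS null model. Random structures may be plain
#' grouping factors (independent random intercepts) or carry a covariance
#' matrix among levels (e.g. a pedigree A-matrix or a genomic relationship
#' matrix). Estimation uses average-information (AI) updates with a
#' gradient-EM fallback whenever an AI step would leave the parameter space
#' or decrease the restricted likelihood; components are constrained
#' nonnegative (held at a small boundary when pinned there). Convergence is
#' declared when the restricted log-likelihood changes by less than `tol`.
#'
#' With a single covariance-structured term observed once per level, the fit
#' is computed exactly via the spectral decomposition of the covariance
#' matrix (one-dimensional profiled REML), which is much faster and cannot
#' fail to converge.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (defaults to an intercept). Must be
#'   full rank; otherwise the fit fails naming the collinear columns.
#' @param random Named list of random structures. Each element is either a
#'   grouping vector/factor of length `length(y)`, or a list with elements
#'   `Z` (incidence matrix, observations x levels) and optionally `K`
#'   (covariance among levels; identity when omitted), or a covariance matrix
#'   `K` applying directly to observations.
#' @param max_iter,tol Iteration cap and restricted log-likelihood tolerance.
#' @return An object of class `lmm_fit`: variance components (`sigma2`) with
#'   standard errors from the inverse AI matrix, fixed effects, restricted
#'   log-likelihood, iteration count and convergence flag.
#' @export
fit_lmm_reml <- function(y, X = NULL, random = list(), max_iter = 200, tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) abort("need at least 3 observations")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) abort("`X` must have one row per observation")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    abort(sprintf("fixed-effect design is singular; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!length(random)) abort("`random` must contain at least one structure")
  if (is.null(names(random)) || any(names(random) == "")) {
    names(random) <- paste0("term", seq_along(random))
  }
  terms <- purrr::imap(random, function(r, nm) normalize_random_term(r, n, nm))

  # Spectral fast path: one covariance term observed once per level.
  if (length(terms) == 1 && !is.null(terms[[1]]$K) && terms[[1]]$identity_Z) {
    return(reml_single_K(y, X, terms[[1]]$K, term_name = names(terms)[1]))
  }

  V_list <- purrr::map(terms, function(tr) {
    if (is.null(tr$K)) tcrossprod(tr$Z) else tr$Z %*% tr$K %*% t(tr$Z)
  })
  reml_ai(y, X, V_list, max_iter = max_iter, tol = tol)
}

normalize_random_term <- function(r, n, nm) {
  if (is.list(r) && !is.data.frame(r)) {
    Z <- as.matrix(r$Z %||% diag(n))
    K <- if (!is.null(r$K)) as.matrix(r$K) else NULL
  } else if (is.matrix(r)) {
    if (nrow(r) == n && ncol(r) == n && isTRUE(all.equal(r, t(r), tolerance = 1e-8))) {
      Z <- diag(n); K <- as.matrix(r)
    } else {
      Z <- as.matrix(r); K <- NULL  # treat as incidence
    }
  } else {
    f <- factor(r)
    if (length(f) != n) abort(sprintf("grouping `%s` must have length %d", nm, n))
    Z <- model.matrix(~ 0 + f)
    K <- NULL
  }
  if (nrow(Z) != n) abort(sprintf("random term `%s`: Z must have %d rows", nm, n))
  if (!is.null(K) && (nrow(K) != ncol(Z) || ncol(K) != ncol(Z))) {
    abort(sprintf("random term `%s`: K dimension does not match Z columns", nm))
  }
  identity_Z <- nrow(Z) == ncol(Z) && isTRUE(all.equal(unname(Z), diag(n)))
  list(Z = unname(Z), K = if (is.null(K)) NULL else unname(K), identity_Z = identity_Z)
}

# Dense AI-REML over arbitrary covariance contributions V_list (+ residual I).
reml_ai <- function(y, X, V_list, max_iter = 200, tol = 1e-8) {
  n <- length(y)
  r <- length(V_list)
  comp_names <- c(names(V_list), "residual")
  vy <- var(y)
  lb <- 1e-6 * vy
  ub <- 1e4 * vy
  theta <- rep(vy / (r + 1), r + 1)

  eval_theta <- function(theta) {
    V <- diag(theta[r + 1], n)
    for (k in seq_len(r)) V <- V + theta[k] * V_list[[k]]
    cholV <- chol_jitter(V, "mixed-model covariance matrix")
    Vinv <- chol2inv(cholV)
    XtVi <- crossprod(X, Vinv)
    XtViX <- XtVi %*% X
    cholXX <- chol_jitter(XtViX, "X' V^-1 X")
    P <- Vinv - t(XtVi) %*% chol2inv(cholXX) %*% XtVi
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cholV))) + 2 * sum(log(diag(cholXX))) + sum(y * Py))
    list(ll = ll, P = P, Py = Py, Vinv = Vinv, XtVi = XtVi, XtViX = XtViX)
  }

  st <- eval_theta(theta)
  ll_old <- st$ll
  converged <- FALSE
  iter <- 0
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    W <- matrix(0, n, r + 1)
    score <- numeric(r + 1)
    for (k in seq_len(r)) {
      Vk_Py <- drop(V_list[[k]] %*% st$Py)
      W[, k] <- Vk_Py
      score[k] <- -0.5 * (sum(st$P * V_list[[k]]) - sum(st$Py * Vk_Py))
    }
    W[, r + 1] <- st$Py
    score[r + 1] <- -0.5 * (sum(diag(st$P)) - sum(st$Py^2))
    PW <- st$P %*% W
    AI <- 0.5 * crossprod(W, PW)

    step <- tryCatch(solve(AI + diag(1e-10 * mean(diag(AI)), r + 1), score),
                     error = function(e) NULL)
    proposal <- if (is.null(step)) NULL else theta + drop(step)
    # gradient-EM fallback: theta_k + theta_k^2/n * (y'P Vk P y - tr(P Vk))
    em_update <- theta + (theta^2 / n) * (2 * score)

    eval_or_null <- function(th) {
      tryCatch(eval_theta(th), error = function(e) NULL)
    }
    used <- NULL
    if (!is.null(proposal) && all(is.finite(proposal))) {
      cand <- proposal
      for (half in 0:8) {
        cand_c <- pmin(pmax(cand, lb), ub)
        st_new <- eval_or_null(cand_c)
        if (!is.null(st_new) && st_new$ll >= ll_old - 1e-10) {
          used <- list(theta = cand_c, st = st_new)
          break
        }
        cand <- (cand + theta) / 2
      }
    }
    if (is.null(used)) {
      em_theta <- pmin(pmax(em_update, lb), ub)
      st_new <- eval_or_null(em_theta)
      if (is.null(st_new)) break  # cannot improve without losing definiteness
      used <- list(theta = em_theta, st = st_new)
    }
    theta <- used$theta
    st <- used$st
    if (abs(st$ll - ll_old) < tol && iter > 1) {
      ll_old <- st$ll
      converged <- TRUE
      break
    }
    ll_old <- st$ll
  }
  if (!converged) {
    warn("REML did not converge within the iteration cap; returning best iterate")
  }

  beta_cov <- solve(st$XtViX)
  beta <- drop(beta_cov %*% (st$XtVi %*% y))
  AIinv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, r + 1, r + 1))
  names(theta) <- comp_names
  dimnames(AIinv) <- list(comp_names, comp_names)
  structure(list(
    sigma2 = theta,
    se_sigma2 = sqrt(pmax(diag(AIinv), 0)),
    AIinv = AIinv,
    beta = setNames(beta, colnames(X)),
    se_beta = setNames(sqrt(diag(beta_cov)), colnames(X)),
    loglik = ll_old,
    iterations = iter,
    converged = converged,
    n = n,
    boundary = theta <= lb * 1.000001,
    method = "ai"
  ), class = "lmm_fit")
}

# Exact REML for y = X b + a + e, a ~ N(0, s2a K): profiled 1-D optimisation
# over h = s2a / (s2a + s2e) in the eigenbasis of K.
reml_single_K <- function(y, X, K, term_name = "genetic", eig = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(h) {
    lam <- h * d + (1 - h)
    w <- 1 / lam
    XtWX <- crossprod(Xt, w * Xt)
    ch <- chol(XtWX)
    beta <- drop(chol2inv(ch) %*% crossprod(Xt, w * yt))
    res <- yt - drop(Xt %*% beta)
    quad <- sum(w * res^2)
    s2p <- quad / (n - p)
    ll <- -0.5 * ((n - p) * log(s2p) + sum(log(lam)) + 2 * sum(log(diag(ch))) + (n - p))
    list(ll = ll, s2p = s2p, beta = beta, w = w, res = res, XtWX_inv = chol2inv(ch))
  }
  opt <- optimize(function(h) prof(h)$ll, interval = c(1e-9, 1 - 1e-9),
                  maximum = TRUE, tol = 1e-10)
  h <- opt$maximum
  # boundary checks
  for (hb in c(1e-9, 1 - 1e-9)) if (prof(hb)$ll > opt$objective + 1e-9) h <- hb
  fit <- prof(h)
  s2a <- h * fit$s2p
  s2e <- (1 - h) * fit$s2p
  theta <- c(s2a, s2e)

  # AI matrix at the optimum, all in the eigenbasis (V_a has diagonal d).
  v <- s2a * d + s2e
  vinv <- 1 / v
  XtViX_inv <- chol2inv(chol(crossprod(Xt, vinv * Xt)))
  Pv <- function(u) vinv * u - vinv * drop(Xt %*% (XtViX_inv %*% crossprod(Xt, vinv * u)))
  Py <- Pv(yt)
  wa <- d * Py; we <- Py
  AI <- 0.5 * matrix(c(sum(wa * Pv(wa)), sum(wa * Pv(we)),
                       sum(wa * Pv(we)), sum(we * Pv(we))), 2, 2)
  AIinv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  comp_names <- c(term_name, "residual")
  names(theta) <- comp_names
  dimnames(AIinv) <- list(comp_names, comp_names)
  beta_cov <- fit$s2p * fit$XtWX_inv
  structure(list(
    sigma2 = theta,
    se_sigma2 = sqrt(pmax(diag(AIinv), 0)),
    AIinv = AIinv,
    beta = setNames(fit$beta, colnames(X)),
    se_beta = setNames(sqrt(diag(beta_cov)), colnames(X)),
    loglik = fit$ll,
    iterations = 1L,
    converged = TRUE,
    n = n,
    boundary = c(h <= 2e-9, h >= 1 - 2e-9),
    method = "eigen"
  ), class = "lmm_fit")
}

# Variance ratios theta_k / sum(theta) with delta-method SEs from the inverse
# AI matrix. Returns a tibble (component, estimate, se, lower, upper).
vc_ratios <- function(fit) {
  theta <- fit$sigma2
  S <- sum(theta)
  k <- length(theta)
  purrr::map_dfr(seq_len(k), function(i) {
    ratio <- theta[i] / S
    g <- rep(-theta[i] / S^2, k)
    g[i] <- g[i] + 1 / S
    v <- if (all(is.finite(fit$AIinv))) drop(t(g) %*% fit$AIinv %*% g) else NA_real_
    se <- if (is.finite(v)) sqrt(max(v, 0)) else NA_real_
    tibble::tibble(
      component = names(theta)[i],
      ratio = unname(ratio),
      se = se,
      lower = if (is.na(se)) NA_real_ else max(0, ratio - 1.96 * se),
      upper = if (is.na(se)) NA_real_ else min(1, ratio + 1.96 * se)
    )
  })
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model fit by REML (", x$method, ")\n", sep = "")
  cat("  n =", x$n, " iterations =", x$iterations,
      " converged =", x$converged, "\n")
  cat("  restricted logLik =", format(x$loglik, digits = 8), "\n")
  cat("Variance components:\n")
  print(round(rbind(estimate = x$sigma2, se = x$se_sigma2), 5))
  invisible(x)
}
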