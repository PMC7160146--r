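#' REML variance-component estimation (GREML / GREML-LDMS)
#'
#' Restricted maximum likelihood estimation of one variance component per
#' genetic relationship matrix plus a residual, with fixed-effect
#' covariates. Single-GRM fits are solved exactly in the eigenbasis of the
#' GRM (the covariance is diagonal there), with Fisher-scoring updates;
#' multi-GRM fits (e.g. 7 MAF x 2 LD bins) use average-information REML
#' with an EM first step, GCTA-style. Iterations stop when the restricted
#' log-likelihood changes by less than `tol` (default 1e-8); negative
#' components are constrained to zero. Standard errors come from the
#' (average) information matrix at convergence.
#'
#' @param phenotype Numeric vector: 0/1 case-control status or a
#'   quantitative trait.
#' @param grms A [compute_grm()] object, a bare relationship matrix, or a
#'   (possibly named) list of them — one variance component each.
#' @param covariates Optional matrix/tibble of fixed-effect covariates (an
#'   intercept is always included).
#' @param K Optional population prevalence; if supplied and the phenotype is
#'   binary, the liability-scale transformation
#'   ([observed_to_liability()]) is applied with P = sample case
#'   proportion.
#' @param max_iter,tol Iteration controls.
#' @param decomposition Optional precomputed `eigen(A, symmetric = TRUE)` of
#'   the single GRM, reusable across phenotypes on the same samples.
#' @return An object of class `heritability_fit`: per-component variances
#'   and SEs, residual variance, `h2_observed` (+ SE), `h2_liability` when
#'   `K` is given, convergence flag and iteration trajectory.
#' @export
reml_fit <- function(phenotype, grms, covariates = NULL, K = NULL,
                     max_iter = 100, tol = 1e-8, decomposition = NULL) {
  if (inherits(grms, "grm_matrix") || is.matrix(grms)) grms <- list(grms)
  Ks <- lapply(grms, function(g) if (inherits(g, "grm_matrix")) g$A else g)
  names(Ks) <- names(grms) %||% paste0("G", seq_along(Ks))
  if (is.null(names(Ks)) || any(names(Ks) == "")) {
    names(Ks) <- paste0("G", seq_along(Ks))
  }
  y <- as.numeric(phenotype)
  n <- length(y)
  for (A in Ks) {
    if (!all(dim(A) == c(n, n))) abort("GRM dimensions must match phenotype")
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) abort("covariate design is rank deficient")

  fit <- if (length(Ks) == 1L) {
    reml_eigen(y, Ks[[1L]], X, max_iter, tol, decomposition)
  } else {
    reml_ai(y, Ks, X, max_iter, tol)
  }

  comp_names <- c(names(Ks), "residual")
  vc <- setNames(fit$sigma2, comp_names)
  se <- setNames(fit$se, comp_names)
  total <- sum(vc)
  gen <- sum(vc[-length(vc)])
  h2 <- gen / total
  # delta-method SE of h2 from the component covariance
  grad <- c(rep(vc[["residual"]] / total^2, length(Ks)), -gen / total^2)
  h2_se <- sqrt(drop(t(grad) %*% fit$cov %*% grad))
  out <- list(
    components = tibble::tibble(component = comp_names,
                                variance = unname(vc), se = unname(se)),
    h2_observed = h2, h2_observed_se = h2_se,
    h2_liability = NA_real_, h2_liability_se = NA_real_,
    K = K, P = NA_real_,
    converged = fit$converged, n_iter = fit$n_iter,
    loglik = fit$loglik, trajectory = fit$trajectory,
    n = n
  )
  if (!is.null(K) && all(y %in% c(0, 1))) {
    P <- mean(y)
    fac <- observed_to_liability(1, K, P)
    out$h2_liability <- h2 * fac
    out$h2_liability_se <- h2_se * fac
    out$P <- P
  }
  class(out) <- "heritability_fit"
  if (!fit$converged) {
    warn("REML did not converge; fit is flagged (see $trajectory)")
  }
  out
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat("<heritability_fit> h2_observed = ", signif(x$h2_observed, 4),
      " (SE ", signif(x$h2_observed_se, 3), ")", sep = "")
  if (!is.na(x$h2_liability)) {
    cat(", h2_liability = ", signif(x$h2_liability, 4),
        " (SE ", signif(x$h2_liability_se, 3), ", K = ", x$K, ")", sep = "")
  }
  cat("\n", nrow(x$components) - 1L, " genetic component(s), ",
      x$n_iter, " iterations, converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

# Single-GRM REML in the eigenbasis: V = sg*D + se*I is diagonal there, so
# every iteration is O(n p^2) after one symmetric eigendecomposition.
reml_eigen <- function(y, A, X, max_iter, tol, decomposition = NULL) {
  n <- length(y)
  eg <- decomposition %||% eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- drop(crossprod(eg$vectors, y))
  Xs <- crossprod(eg$vectors, X)
  p <- ncol(Xs)
  vy <- var(y)
  s <- c(vy / 2, vy / 2)  # (genetic, residual)
  floor_v <- 1e-8 * vy
  ll_terms <- function(s) {
    v <- s[1] * d + s[2]
    w <- 1 / v
    XtWX <- crossprod(Xs * w, Xs)
    cXtWX <- chol(XtWX)
    beta <- backsolve(cXtWX, forwardsolve(t(cXtWX), crossprod(Xs * w, ys)))
    r <- ys - drop(Xs %*% beta)
    Py <- w * r
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cXtWX))) + sum(ys * Py))
    list(v = v, w = w, Py = Py, ll = ll, XtWX_chol = cXtWX)
  }
  traj <- numeric(0)
  converged <- FALSE
  st <- ll_terms(s)
  info <- NULL
  for (it in seq_len(max_iter)) {
    w <- st$w
    Py <- st$Py
    # P = W - WX (X'WX)^-1 X'W ; formed explicitly (n x p small)
    WX <- Xs * w
    B <- backsolve(st$XtWX_chol,
                   forwardsolve(t(st$XtWX_chol), t(WX)))  # (X'WX)^-1 X'W
    P <- diag(w) - WX %*% B
    P2 <- P * P
    tr_PD <- sum(diag(P) * d)
    tr_P <- sum(diag(P))
    # scores: y'P D P y = sum(d * Py^2) since P y is already in eigenbasis
    sc <- c(-0.5 * (tr_PD - sum(d * Py^2)),
            -0.5 * (tr_P - sum(Py^2)))
    info <- matrix(c(
      0.5 * drop(t(d) %*% P2 %*% d), 0.5 * sum(P2 %*% d),
      0.5 * sum(P2 %*% d), 0.5 * sum(P2)
    ), 2, 2)
    if (!all(is.finite(info)) || det(info) <= 0) {
      abort("singular information matrix in REML")
    }
    delta <- solve(info, sc)
    s_new <- pmax(s + delta, floor_v)
    st_new <- ll_terms(s_new)
    # step halving if the restricted likelihood decreased
    h <- 0
    while (st_new$ll < st$ll - 1e-12 && h < 20) {
      delta <- delta / 2
      s_new <- pmax(s + delta, floor_v)
      st_new <- ll_terms(s_new)
      h <- h + 1
    }
    traj <- c(traj, st_new$ll)
    done <- abs(st_new$ll - st$ll) < tol
    s <- s_new
    st <- st_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  cov <- solve(info)
  list(sigma2 = s, se = sqrt(pmax(diag(cov), 0)), cov = cov,
       converged = converged, n_iter = length(traj), loglik = st$ll,
       trajectory = traj)
}

# Multi-component AI-REML on full matrices (EM first step, then average
# information with step halving), for the MAF x LD binned analysis.
reml_ai <- function(y, Ks, X, max_iter, tol) {
  n <- length(y)
  k <- length(Ks)
  vy <- var(y)
  s <- rep(vy / (k + 1), k + 1)
  floor_v <- 1e-8 * vy
  state <- function(s) {
    V <- diag(rep(s[k + 1], n))
    for (j in seq_len(k)) V <- V + s[j] * Ks[[j]]
    cV <- chol(V)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cX <- chol(XtViX)
    P <- Vi - ViX %*% backsolve(cX, forwardsolve(t(cX), t(ViX)))
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                    sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }
  st <- state(s)
  traj <- numeric(0)
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(max_iter)) {
    Py <- st$Py
    P <- st$P
    q <- vector("list", k + 1)
    trPK <- numeric(k + 1)
    yPKPy <- numeric(k + 1)
    for (j in seq_len(k)) {
      q[[j]] <- drop(Ks[[j]] %*% Py)
      trPK[j] <- sum(P * Ks[[j]])  # both symmetric
      yPKPy[j] <- sum(Py * q[[j]])
    }
    q[[k + 1]] <- Py
    trPK[k + 1] <- sum(diag(P))
    yPKPy[k + 1] <- sum(Py^2)
    sc <- -0.5 * (trPK - yPKPy)
    if (it == 1L) {
      # EM step: robust far from the optimum
      s_new <- pmax(s + s^2 * (yPKPy - trPK) / n, floor_v)
    } else {
      AI <- matrix(0, k + 1, k + 1)
      Pq <- lapply(q, function(v) drop(P %*% v))
      for (a in seq_len(k + 1)) {
        for (b in a:(k + 1)) {
          AI[a, b] <- AI[b, a] <- 0.5 * sum(q[[a]] * Pq[[b]])
        }
      }
      delta <- tryCatch(solve(AI, sc), error = function(e) {
        abort("singular average-information matrix in REML")
      })
      s_new <- pmax(s + delta, floor_v)
    }
    st_new <- state(s_new)
    h <- 0
    while (st_new$ll < st$ll - 1e-12 && h < 20) {
      s_new <- pmax(s + (s_new - s) / 2, floor_v)
      st_new <- state(s_new)
      h <- h + 1
    }
    traj <- c(traj, st_new$ll)
    done <- it > 1L && abs(st_new$ll - st$ll) < tol
    s <- s_new
    st <- st_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (is.null(AI)) {
    # converged in the EM step; build AI once for standard errors
    Py <- st$Py
    P <- st$P
    q <- c(lapply(Ks, function(Kj) drop(Kj %*% Py)), list(Py))
    AI <- matrix(0, k + 1, k + 1)
    Pq <- lapply(q, function(v) drop(P %*% v))
    for (a in seq_len(k + 1)) {
      for (b in a:(k + 1)) {
        AI[a, b] <- AI[b, a] <- 0.5 * sum(q[[a]] * Pq[[b]])
      }
    }
  }
  cov <- tryCatch(solve(AI), error = function(e) {
    abort("singular average-information matrix in REML")
  })
  list(sigma2 = s, se = sqrt(pmax(diag(cov), 0)), cov = cov,
       converged = converged, n_iter = length(traj), loglik = st$ll,
       trajectory = traj)
}
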