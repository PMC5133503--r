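#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Internal maximum-likelihood engine.
##
## All models are multivariate normal with mean  X_stack beta  and covariance
##   Omega = 2 Phi (x) G  +  I (x) E  (+  K (x) u u')
## over the stacked trait vector (individual-major, time point inner).
## Mean coefficients are profiled out by GLS inside the likelihood kernels;
## the optimizer only sees the covariance parameters, passed through a
## log-Cholesky transform so that G and E stay positive semidefinite without
## explicit constraints.
## ---------------------------------------------------------------------------

.nChol <- function(k) k * (k + 1L) / 2L

## theta (log-diag first, then strict lower triangle column-major) -> L
.cholFromTheta <- function(theta, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(theta[seq_len(k)])
  if (k > 1L) L[lower.tri(L)] <- theta[(k + 1L):.nChol(k)]
  L
}

.thetaFromChol <- function(L) {
  k <- nrow(L)
  dg <- pmax(diag(L), 1e-8)
  c(log(dg), L[lower.tri(L)])
}

.thetaFromCov <- function(M) {
  k <- nrow(M)
  L <- tryCatch(t(chol(M)), error = function(e) t(chol(M + 0.05 * mean(diag(M)) * diag(k))))
  .thetaFromChol(L)
}

## Relatedness structure reusable across fits on the same individuals:
## additive relationship matrix and its per-pedigree eigen decomposition.
.pedStruct <- function(ped, ids, phi = NULL) {
  fam <- ped@famid[match(ids, ped@id)]
  ord <- order(match(fam, unique(fam)))
  ids <- ids[ord]
  fam <- fam[ord]
  n <- length(ids)
  if (is.null(phi)) phi <- kinshipMatrix(ped)
  A <- 2 * phi[ids, ids, drop = FALSE]
  blocks <- split(seq_len(n), factor(fam, levels = unique(fam)))
  d <- numeric(n)
  U <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    e <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
    d[idx] <- e$values
    U[[b]] <- e$vectors
  }
  rot <- function(M) {
    M <- as.matrix(M)
    out <- M
    for (b in seq_along(blocks)) {
      idx <- blocks[[b]]
      out[idx, ] <- crossprod(U[[b]], M[idx, , drop = FALSE])
    }
    out
  }
  list(ids = ids, fam = fam, A = A, d = d, rot = rot)
}

## Prepare a dataset for repeated fits: kinship, per-pedigree eigen
## decomposition, rotated trait/design, overall scale.
## Y: n x k trait matrix (id rownames); X: covariate matrix (no intercept);
## ped: Pedigree; cache: optional .pedStruct over the same individuals.
.prepareVC <- function(Y, X, ped, cache = NULL) {
  if (is.null(dim(Y))) Y <- cbind(Y)
  ids <- rownames(Y)
  if (is.null(ids)) stop("trait matrix needs id rownames")
  missing <- setdiff(ids, pedIds(ped))
  if (length(missing))
    stop("individual(s) not in the pedigree: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (is.null(X)) X <- matrix(0, nrow(Y), 0, dimnames = list(ids, NULL))
  X <- as.matrix(X)[ids, , drop = FALSE]
  if (anyNA(X)) stop("covariates contain missing values")
  ## drop individuals with no observed trait value at all
  allmiss <- rowSums(!is.na(Y)) == 0L
  if (any(allmiss)) {
    Y <- Y[!allmiss, , drop = FALSE]
    X <- X[!allmiss, , drop = FALSE]
    ids <- ids[!allmiss]
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  if (qr(X1)$rank < ncol(X1)) {
    cn <- colnames(X1)
    stop("mean-model design is rank deficient (collinear columns among: ",
         paste(cn, collapse = ", "), ")")
  }
  if (is.null(cache) || !setequal(cache$ids, ids))
    cache <- .pedStruct(ped, ids)
  ord <- match(cache$ids, ids)
  ids <- ids[ord]
  Y <- Y[ord, , drop = FALSE]
  X1 <- X1[ord, , drop = FALSE]
  n <- length(ids)
  k <- ncol(Y)
  s <- stats::sd(Y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("trait has zero variance")
  Ys <- Y / s
  complete <- !anyNA(Ys)
  rot <- cache$rot
  list(ids = ids, n = n, k = k, s = s, fam = cache$fam, A = cache$A,
       Y = Y, Ys = Ys, X1 = X1, complete = complete, rot = rot,
       d = cache$d,
       Yt = if (complete) rot(Ys) else NULL,
       Xt = rot(X1),
       Sy = if (complete) stats::cov(Ys) else {
         V <- stats::cov(Ys, use = "pairwise.complete.obs")
         V[!is.finite(V)] <- 0
         V
       })
}

## moment (Haseman-Elston-style) start: in the rotated basis the expected
## residual cross-product for individual i is d_i G + E, so regressing the
## empirical products on the eigenvalues d_i gives closed-form starts for
## G (slope) and E (intercept).
.momentStart <- function(prep) {
  k <- prep$k
  R <- qr.resid(qr(prep$Xt), prep$Yt)
  d <- prep$d
  vd <- stats::var(d)
  if (!is.finite(vd) || vd < 1e-10) return(NULL)
  G0 <- E0 <- matrix(0, k, k)
  for (t in seq_len(k)) {
    for (s in t:k) {
      cc <- R[, t] * R[, s]
      sl <- stats::cov(cc, d) / vd
      G0[t, s] <- G0[s, t] <- sl
      E0[t, s] <- E0[s, t] <- mean(cc) - sl * mean(d)
    }
  }
  clip <- function(M, floor) {
    e <- eigen(M, symmetric = TRUE)
    v <- pmax(e$values, floor)
    e$vectors %*% (v * t(e$vectors))
  }
  tot <- mean(diag(G0) + diag(E0))
  if (!is.finite(tot) || tot <= 0) return(NULL)
  c(.thetaFromCov(clip(G0, 0.01 * tot)), .thetaFromCov(clip(E0, 0.05 * tot)))
}

## covariance starts: moment estimator first, then sample-covariance splits
.defaultStarts <- function(prep, extra = numeric(0)) {
  S <- prep$Sy
  k <- prep$k
  S <- 0.8 * S + 0.2 * mean(diag(S)) * diag(k)  # shrink for stability
  out <- lapply(c(0.5, 0.15, 0.85), function(h)
    c(.thetaFromCov(h * S), .thetaFromCov((1 - h) * S), extra))
  if (prep$complete) {
    ms <- tryCatch(.momentStart(prep), error = function(e) NULL)
    if (!is.null(ms)) out <- c(list(c(ms, extra)), out)
  }
  out
}

.covBounds <- function(k, nKern = 0L) {
  nc <- .nChol(k)
  lowd <- rep(c(-8, -15), c(k, nc - k))
  upd <- rep(c(4, 15), c(k, nc - k))
  list(lower = c(lowd, lowd, rep(-8, nKern)),
       upper = c(upd, upd, rep(3, nKern)))
}

## Shared optimizer driver. obj maps theta -> -loglik (standardized scale);
## gr, when given, is its analytic gradient.
.optimize <- function(obj, starts, lower, upper, gr = NULL) {
  best <- NULL
  for (si in seq_along(starts)) {
    fit <- tryCatch(
      stats::nlminb(starts[[si]], obj, gradient = gr,
                    lower = lower, upper = upper,
                    control = list(iter.max = 400, eval.max = 2000,
                                   rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective - 1e-9) best <- fit
    ## extra starts only when the optimizer genuinely failed; a boundary
    ## optimum (e.g. a cross-time genetic correlation of 1) is legitimate
    ok <- fit$convergence == 0 ||
      (!is.null(gr) && max(abs(gr(fit$par))) < 0.05)
    if (si == 1L && ok) break
  }
  best
}

## Core fit on prepared data.
## mode: "none", "shared", "free" (SNV mean effect)
## g: dosage vector (original order = prep$ids) or NULL
## Z: kernel loadings (n x m, K = Z Z') or NULL
## kernelShared: equal per-trait kernel loading u_t (TRUE) or free (FALSE)
.fitEngine <- function(prep, mode = "none", g = NULL, Z = NULL,
                       kernelShared = TRUE, init = NULL) {
  k <- prep$k
  n <- prep$n
  nc <- .nChol(k)
  modeI <- match(mode, c("none", "shared", "free")) - 1L
  if (is.na(modeI)) stop("unknown mode: ", mode)
  hasK <- !is.null(Z)
  nKern <- if (!hasK) 0L else if (kernelShared) 1L else k
  bounds <- .covBounds(k, nKern)
  p0 <- ncol(prep$Xt)

  if (prep$complete && !hasK && k == 1L)
    return(.fitUni1(prep, modeI, g))
  if (prep$complete) {
    gt <- if (is.null(g)) numeric(n) else drop(prep$rot(g[prep$ids]))
    Zt <- if (hasK) prep$rot(Z[prep$ids, , drop = FALSE]) else NULL
    if (!hasK) {
      ## memoized joint (value, gradient) evaluation for nlminb
      memo <- new.env(parent = emptyenv())
      evalBoth <- function(theta) {
        if (!is.null(memo$theta) && identical(theta, memo$theta))
          return(memo$res)
        r <- .vc_ll_rot_grad(prep$d, prep$Yt, prep$Xt, gt, modeI,
                             theta[1:nc], theta[nc + (1:nc)])
        memo$theta <- theta
        memo$res <- r
        r
      }
      obj <- function(theta) {
        r <- evalBoth(theta)
        if (!isTRUE(r$ok) || !is.finite(r$ll)) 1e10 else -r$ll
      }
      grad <- function(theta) {
        r <- evalBoth(theta)
        if (!isTRUE(r$ok) || !is.finite(r$ll)) numeric(2 * nc) else -r$grad
      }
    } else if (k == 1L) {
      obj <- function(theta) {
        r <- .vc_ll_kern1(prep$d, prep$Yt[, 1], prep$Xt, Zt,
                          exp(2 * theta[1]), exp(2 * theta[2]),
                          exp(2 * theta[3]), gt, modeI > 0L)
        if (!r$ok || !is.finite(r$ll)) 1e10 else -r$ll
      }
    } else {
      if (modeI != 0L) stop("kernel models carry no SNV term")
      obj <- function(theta) {
        G <- tcrossprod(.cholFromTheta(theta[1:nc], k))
        E <- tcrossprod(.cholFromTheta(theta[nc + (1:nc)], k))
        u <- exp(theta[2 * nc + seq_len(nKern)])
        if (kernelShared) u <- rep(u, k)
        r <- .vc_ll_kernmv(prep$d, prep$Yt, prep$Xt, Zt, G, E, u)
        if (!r$ok || !is.finite(r$ll)) 1e10 else -r$ll
      }
    }
  } else {
    ## general path: dense covariance with row/column deletion (MAR)
    dat <- .stackGeneral(prep, g, modeI)
    Kmat <- if (hasK) tcrossprod(Z[prep$ids, , drop = FALSE]) else NULL
    obj <- function(theta) {
      G <- tcrossprod(.cholFromTheta(theta[1:nc], k))
      E <- tcrossprod(.cholFromTheta(theta[nc + (1:nc)], k))
      u <- if (hasK) {
        uu <- exp(theta[2 * nc + seq_len(nKern)])
        if (kernelShared) rep(uu, k) else uu
      } else NULL
      .llGeneral(dat, prep, G, E, Kmat, u)
    }
  }

  starts <- if (!is.null(init)) list(init) else
    .defaultStarts(prep, extra = rep(log(0.25), nKern))
  gradFn <- if (prep$complete && !hasK) grad else NULL
  fit <- .optimize(obj, starts, bounds$lower, bounds$upper, gr = gradFn)
  if (is.null(fit))
    return(list(ll = NA_real_, converged = FALSE, boundary = TRUE,
                iterations = 0L, theta = NULL))

  conv <- fit$convergence == 0
  if (!conv && !is.null(gradFn))
    conv <- max(abs(gradFn(fit$par))) < 0.05  # flat ridge, gradient ~ 0
  theta <- fit$par
  G <- tcrossprod(.cholFromTheta(theta[1:nc], k)) * prep$s^2
  E <- tcrossprod(.cholFromTheta(theta[nc + (1:nc)], k)) * prep$s^2
  u <- if (nKern) exp(theta[2 * nc + seq_len(nKern)]) * prep$s else numeric(0)
  ## recover profiled mean coefficients at the optimum
  beta <- .betaAt(prep, theta, modeI, g, Z, kernelShared, nKern, nc)
  dgl <- c(theta[1:k], theta[nc + (1:k)], theta[2 * nc + seq_len(nKern)])
  boundary <- any(dgl <= .covBounds(k, nKern)$lower[c(1:k, nc + (1:k),
                   if (nKern) 2 * nc + seq_len(nKern))] + 1e-4)
  ## log-likelihood back on the original trait scale
  Nobs <- sum(!is.na(prep$Ys))
  list(ll = -fit$objective - Nobs * log(prep$s),
       theta = theta, G = G, E = E, u = u, beta = beta,
       converged = conv, boundary = boundary,
       iterations = as.integer(fit$iterations), obj = obj, nc = nc,
       mode = mode, nKern = nKern)
}

## Univariate complete-data fit: with Omega = sigma2_e (gamma A + I) both
## the mean coefficients and sigma2_e profile out in closed form, leaving
## an exact 1-D search over log gamma (gamma = sigma2_g / sigma2_e). This
## avoids the flat-valley convergence issues of the generic optimizer.
.fitUni1 <- function(prep, modeI, g) {
  n <- prep$n
  d <- prep$d
  y <- prep$Yt[, 1]
  X <- prep$Xt
  if (modeI > 0L) X <- cbind(X, drop(prep$rot(g[prep$ids])))
  p <- ncol(X)
  profile <- function(lg) {
    v <- exp(lg) * d + 1
    sw <- 1 / sqrt(v)
    Xw <- X * sw
    yw <- y * sw
    qrx <- qr(Xw)
    rss <- sum(qr.resid(qrx, yw)^2)
    s2e <- rss / n
    list(negll = 0.5 * (n * log(2 * pi) + n * log(s2e) + sum(log(v)) + n),
         s2e = s2e, beta = qr.coef(qrx, yw))
  }
  lo <- -14; hi <- 10
  opt <- stats::optimize(function(lg) profile(lg)$negll, c(lo, hi),
                         tol = 1e-9)
  ## compare against the boundary gamma -> 0 (pure environmental model)
  cand <- c(opt$minimum, lo)
  negs <- vapply(cand, function(lg) profile(lg)$negll, numeric(1))
  lg <- cand[which.min(negs)]
  pr <- profile(lg)
  s2g <- exp(lg) * pr$s2e
  theta <- 0.5 * c(log(max(s2g, 1e-12)), log(pr$s2e))
  boundary <- lg <= lo + 0.5 || lg >= hi - 0.5
  obj <- function(th) {
    r <- .vc_ll_rot_grad(prep$d, prep$Yt, prep$Xt,
                         if (modeI > 0L) X[, p] else numeric(n),
                         modeI, th[1], th[2])
    if (!isTRUE(r$ok)) 1e10 else -r$ll
  }
  list(ll = -pr$negll - n * log(prep$s),
       theta = theta, G = matrix(s2g * prep$s^2), E = matrix(pr$s2e * prep$s^2),
       u = numeric(0), beta = drop(pr$beta) * prep$s,
       converged = TRUE, boundary = boundary, iterations = 0L,
       obj = obj, nc = 1L, mode = c("none", "shared", "free")[modeI + 1L],
       nKern = 0L)
}

## evaluate the GLS coefficients at given covariance parameters
.betaAt <- function(prep, theta, modeI, g, Z, kernelShared, nKern, nc) {
  k <- prep$k
  G <- tcrossprod(.cholFromTheta(theta[1:nc], k))
  E <- tcrossprod(.cholFromTheta(theta[nc + (1:nc)], k))
  if (prep$complete) {
    gt <- if (is.null(g)) numeric(prep$n) else drop(prep$rot(g[prep$ids]))
    if (is.null(Z)) {
      r <- .vc_ll_rot(prep$d, prep$Yt, prep$Xt, gt, modeI, G, E)
    } else if (k == 1L) {
      r <- .vc_ll_kern1(prep$d, prep$Yt[, 1], prep$Xt,
                        prep$rot(Z[prep$ids, , drop = FALSE]),
                        exp(2 * theta[1]), exp(2 * theta[2]),
                        exp(2 * theta[3]), gt, modeI > 0L)
    } else {
      u <- exp(theta[2 * nc + seq_len(nKern)])
      if (kernelShared) u <- rep(u, k)
      r <- .vc_ll_kernmv(prep$d, prep$Yt, prep$Xt,
                         prep$rot(Z[prep$ids, , drop = FALSE]), G, E, u)
    }
    if (!isTRUE(r$ok)) return(NULL)
    drop(r$beta) * prep$s
  } else {
    dat <- .stackGeneral(prep, g, modeI)
    Kmat <- if (!is.null(Z)) tcrossprod(Z[prep$ids, , drop = FALSE]) else NULL
    u <- if (nKern) {
      uu <- exp(theta[2 * nc + seq_len(nKern)])
      if (kernelShared) rep(uu, k) else uu
    } else NULL
    .llGeneral(dat, prep, G, E, Kmat, u, wantBeta = TRUE)$beta * prep$s
  }
}

## stacked design and observation mask for the general (missing-data) path
.stackGeneral <- function(prep, g, modeI) {
  n <- prep$n
  k <- prep$k
  X1 <- prep$X1
  p0 <- ncol(X1)
  pg <- if (modeI == 0L) 0L else if (modeI == 1L) 1L else k
  Xs <- matrix(0, n * k, k * p0 + pg)
  for (t in seq_len(k)) {
    rows <- (seq_len(n) - 1L) * k + t
    Xs[rows, (t - 1L) * p0 + seq_len(p0)] <- X1
    if (modeI == 1L) Xs[rows, k * p0 + 1L] <- g[prep$ids]
    if (modeI == 2L) Xs[rows, k * p0 + t] <- g[prep$ids]
  }
  y <- as.vector(t(prep$Ys))  # i-major, t inner
  obs <- !is.na(y)
  list(Xs = Xs[obs, , drop = FALSE], y = y[obs], obs = obs)
}

.llGeneral <- function(dat, prep, G, E, Kmat = NULL, u = NULL,
                       wantBeta = FALSE) {
  n <- prep$n
  Om <- kronecker(prep$A, G) + kronecker(diag(n), E)
  if (!is.null(Kmat) && !is.null(u))
    Om <- Om + kronecker(Kmat, tcrossprod(u))
  Om <- Om[dat$obs, dat$obs, drop = FALSE]
  ch <- tryCatch(chol(Om), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
    if (wantBeta)
      stop(sprintf("covariance not positive definite (min eigenvalue %.3g)", ev))
    return(1e10)
  }
  Xw <- backsolve(ch, dat$Xs, transpose = TRUE)
  yw <- backsolve(ch, dat$y, transpose = TRUE)
  XtX <- crossprod(Xw)
  Xty <- crossprod(Xw, yw)
  beta <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
  if (is.null(beta)) {
    if (wantBeta) stop("rank-deficient design in general path")
    return(1e10)
  }
  quad <- sum(yw^2) - drop(crossprod(beta, Xty))
  ll <- -0.5 * (length(dat$y) * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
  if (wantBeta) list(ll = ll, beta = drop(beta)) else -ll
}

## numerical gradient of the negative log-likelihood at theta
.gradNorm <- function(obj, theta, h = 1e-5) {
  g <- vapply(seq_along(theta), function(i) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (obj(tp) - obj(tm)) / (2 * h)
  }, numeric(1))
  max(abs(g))
}
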