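# Average-information REML for the multi-environment linear mixed model.
#
# The variance model is a sum of structured components:
#   * genetic terms  Z_g (A (x) K) Z_g'  with A a t x t FA (Lambda Lambda' +
#     Psi) or diagonal structure across environments and K an r x r kernel
#     (identity, or a genomic relationship matrix);
#   * simple iid design terms (row / column / block effects);
#   * per-environment spatial residuals sigma2_j * AR1(rho_row) x AR1(rho_col).
# Scores use exact traces computed by aggregating the projection matrix P
# over the incidence structure; updates are average-information steps with
# step-halving against the REML log-likelihood and an EM-style fallback for
# variance-type parameters. Variances are floored at 1e-8 x var(y).

# ---- parameter bookkeeping -------------------------------------------------

init_var_params <- function(spec, floor) {
  s2 <- stats::var(spec$y - stats::lm.fit(spec$X, spec$y)$fitted.values)
  if (!is.finite(s2) || s2 <= 0) s2 <- stats::var(spec$y)
  ng <- length(spec$genetic)
  genetic <- lapply(spec$genetic, function(tm) {
    scaleK <- if (is.null(tm$K)) 1 else mean(diag(tm$K))
    share <- 0.4 * s2 / max(ng, 1) / scaleK
    if (tm$structure == "fa") {
      k <- min(tm$k, max(spec$t - 1L, 1L))
      Lambda <- matrix(0, spec$t, k)
      Lambda[, 1] <- sqrt(share / 2)
      if (k >= 2) for (m in 2:k) Lambda[m:spec$t, m] <- 0.3 * sqrt(share / 2)
      list(structure = "fa", k = k, Lambda = Lambda,
           psi = rep(share / 2, spec$t))
    } else {
      list(structure = "diag", d = rep(share, spec$t))
    }
  })
  iid <- rep(0.05 * s2, length(spec$iid_terms))
  rho0 <- if (spec$estimate_spatial_rho) 0.2 else 0
  list(genetic = genetic,
       iid = iid,
       sp_var = rep(0.5 * s2, spec$t),
       sp_rho_row = rep(rho0, spec$t),
       sp_rho_col = rep(rho0, spec$t),
       floor = floor)
}

# flatten parameters into a vector with a descriptor table
flatten_params <- function(spec, par) {
  vals <- numeric(0)
  desc <- list()
  add <- function(value, kind, term = NA_integer_, i = NA_integer_,
                  j = NA_integer_, lower = -Inf, upper = Inf, m = NA_real_) {
    vals[length(vals) + 1L] <<- value
    desc[[length(desc) + 1L]] <<- list(kind = kind, term = term, i = i, j = j,
                                       lower = lower, upper = upper, m = m)
  }
  for (g in seq_along(par$genetic)) {
    pg <- par$genetic[[g]]
    if (pg$structure == "fa") {
      for (m in seq_len(pg$k)) for (jj in m:spec$t)
        add(pg$Lambda[jj, m], "fa_loading", g, jj, m, m = spec$r)
      for (jj in seq_len(spec$t))
        add(pg$psi[jj], "fa_psi", g, jj, lower = par$floor, m = spec$r)
    } else {
      for (jj in seq_len(spec$t))
        add(pg$d[jj], "diag_var", g, jj, lower = par$floor, m = spec$r)
    }
  }
  for (u in seq_along(par$iid)) {
    m_lev <- length(unique(stats::na.omit(spec$iid_terms[[u]]$level)))
    add(par$iid[u], "iid_var", u, lower = par$floor, m = m_lev)
  }
  for (jj in seq_len(spec$t)) {
    nj <- length(spec$spatial[[jj]]$idx)
    add(par$sp_var[jj], "sp_var", i = jj, lower = par$floor, m = nj)
    if (spec$estimate_spatial_rho) {
      add(par$sp_rho_row[jj], "sp_rho_row", i = jj, lower = -0.999, upper = 0.999)
      add(par$sp_rho_col[jj], "sp_rho_col", i = jj, lower = -0.999, upper = 0.999)
    }
  }
  list(values = vals, desc = desc)
}

unflatten_params <- function(spec, par, values) {
  fp <- flatten_params(spec, par)
  stopifnot(length(values) == length(fp$values))
  out <- par
  idx <- 0L
  for (g in seq_along(par$genetic)) {
    pg <- par$genetic[[g]]
    if (pg$structure == "fa") {
      for (m in seq_len(pg$k)) for (jj in m:spec$t) {
        idx <- idx + 1L; out$genetic[[g]]$Lambda[jj, m] <- values[idx]
      }
      for (jj in seq_len(spec$t)) {
        idx <- idx + 1L; out$genetic[[g]]$psi[jj] <- values[idx]
      }
    } else {
      for (jj in seq_len(spec$t)) {
        idx <- idx + 1L; out$genetic[[g]]$d[jj] <- values[idx]
      }
    }
  }
  for (u in seq_along(par$iid)) { idx <- idx + 1L; out$iid[u] <- values[idx] }
  for (jj in seq_len(spec$t)) {
    idx <- idx + 1L; out$sp_var[jj] <- values[idx]
    if (spec$estimate_spatial_rho) {
      idx <- idx + 1L; out$sp_rho_row[jj] <- values[idx]
      idx <- idx + 1L; out$sp_rho_col[jj] <- values[idx]
    }
  }
  out
}

genetic_A <- function(pg, t) {
  if (pg$structure == "fa") tcrossprod(pg$Lambda) + diag(pg$psi, t)
  else diag(pg$d, t)
}

# ---- V construction and likelihood ----------------------------------------

spatial_lags <- function(spec) {
  lapply(spec$spatial, function(sp) {
    list(lr = abs(outer(sp$rowpos, sp$rowpos, "-")),
         lc = abs(outer(sp$colpos, sp$colpos, "-")))
  })
}

ar1_from_lags <- function(rho_r, rho_c, lg) {
  (rho_r^lg$lr) * (rho_c^lg$lc)
}

ar1_deriv_from_lags <- function(rho_r, rho_c, lg, which) {
  if (which == "row") {
    d <- lg$lr * rho_r^pmax(lg$lr - 1, 0); d[lg$lr == 0] <- 0
    d * rho_c^lg$lc
  } else {
    d <- lg$lc * rho_c^pmax(lg$lc - 1, 0); d[lg$lc == 0] <- 0
    d * rho_r^lg$lr
  }
}

build_V <- function(spec, par, lags, aux) {
  n <- spec$n
  V <- matrix(0, n, n)
  for (g in seq_along(par$genetic)) {
    pg <- par$genetic[[g]]
    A <- genetic_A(pg, spec$t)
    Aplot <- matrix(A[aux$envpair], n, n)
    V <- V + Aplot * aux$kplot[[g]]
  }
  for (u in seq_along(par$iid)) {
    V <- V + par$iid[u] * aux$same_level[[u]]
  }
  for (jj in seq_len(spec$t)) {
    idx <- spec$spatial[[jj]]$idx
    V[idx, idx] <- V[idx, idx] +
      par$sp_var[jj] * ar1_from_lags(par$sp_rho_row[jj], par$sp_rho_col[jj],
                                     lags[[jj]])
  }
  V
}

# precomputed incidence helpers shared across iterations: the plot-level
# kernel gather for every genetic term, the (env, env) index pairs, and
# same-level indicators for iid terms
build_aux <- function(spec) {
  n <- spec$n
  lp <- ifelse(is.na(spec$line_i), 0L, spec$line_i)
  same_line <- (outer(lp, lp, "==")) & (lp > 0L)
  storage.mode(same_line) <- "double"
  lp_pad <- ifelse(is.na(spec$line_i), spec$r + 1L, spec$line_i)
  kplot <- lapply(spec$genetic, function(tm) {
    if (is.null(tm$K)) same_line else tm$K[lp_pad, lp_pad, drop = FALSE]
  })
  # element (i, j) of the n x n gather is A[env_i[i], env_i[j]]; in
  # column-major order position (j-1)*n + i must index A at
  # (env_i[j]-1)*t + env_i[i]
  envpair <- rep((spec$env_i - 1L) * spec$t, each = n) + rep(spec$env_i, n)
  same_level <- lapply(spec$iid_terms, function(tm) {
    lv <- tm$level
    lv0 <- ifelse(is.na(lv), 0L, lv)
    m <- (outer(lv0, lv0, "==")) & (lv0 > 0L)
    storage.mode(m) <- "double"
    m
  })
  list(same_line = same_line, lp_pad = lp_pad, kplot = kplot,
       envpair = envpair, same_level = same_level)
}

# pad kernels once so V construction can index checks to a zero row
pad_kernels <- function(spec) {
  for (g in seq_along(spec$genetic)) {
    K <- spec$genetic[[g]]$K
    if (!is.null(K) && isTRUE(attr(K, "padded"))) next
    if (!is.null(K)) {
      Kp <- matrix(0, spec$r + 1L, spec$r + 1L)
      Kp[seq_len(spec$r), seq_len(spec$r)] <- K
      spec$genetic[[g]]$K <- Kp
      attr(spec$genetic[[g]]$K, "padded") <- TRUE
    }
  }
  spec
}

# log-likelihood only (cheap): one Cholesky plus triangular solves
reml_loglik <- function(spec, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Z <- backsolve(ch, cbind(spec$X, spec$y), transpose = TRUE)
  Zx <- Z[, seq_len(ncol(spec$X)), drop = FALSE]
  zy <- Z[, ncol(Z)]
  XtViX <- crossprod(Zx)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  Xty <- crossprod(Zx, zy)
  beta <- backsolve(chX, backsolve(chX, Xty, transpose = TRUE))
  yPy <- sum(zy^2) - sum(Xty * beta)
  p <- ncol(spec$X)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy +
            (spec$n - p) * log(2 * pi))
}

reml_eval <- function(spec, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% spec$X
  XtViX <- crossprod(spec$X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  Cfix <- chol2inv(chX)
  Viy <- Vi %*% spec$y
  beta <- drop(Cfix %*% crossprod(spec$X, Viy))
  qv <- drop(Viy - ViX %*% (Cfix %*% crossprod(spec$X, Viy)))
  yPy <- sum(spec$y * qv)
  logdetV <- 2 * sum(log(diag(ch)))
  logdetX <- 2 * sum(log(diag(chX)))
  p <- ncol(spec$X)
  ll <- -0.5 * (logdetV + logdetX + yPy + (spec$n - p) * log(2 * pi))
  list(ll = ll, Vi = Vi, ViX = ViX, Cfix = Cfix, qv = qv, beta = beta)
}

# aggregate a symmetric n x n matrix over genotype-by-environment effects
agg_effect <- function(Pm, spec) {
  mask <- !is.na(spec$line_i)
  eff <- (spec$env_i[mask] - 1L) * spec$r + spec$line_i[mask]
  M1 <- rowsum(Pm[mask, , drop = FALSE], eff)
  W <- rowsum(t(M1)[mask, , drop = FALSE], eff)
  lv <- as.integer(rownames(W))
  rt <- spec$r * spec$t
  Wf <- matrix(0, rt, rt)
  Wf[lv, lv] <- W
  Wf
}

# S[j1, j2] = sum_{g1, g2} K[g1, g2] * W[(j1, g1), (j2, g2)]
kernel_contract <- function(Wf, K, r, t) {
  S <- matrix(0, t, t)
  for (j1 in seq_len(t)) for (j2 in seq_len(t)) {
    b1 <- (j1 - 1L) * r + seq_len(r)
    b2 <- (j2 - 1L) * r + seq_len(r)
    S[j1, j2] <- if (is.null(K)) sum(Wf[cbind(b1, b2)]) else
      sum(K[seq_len(r), seq_len(r)] * Wf[b1, b2])
  }
  S
}

# ---- the fitting routine ---------------------------------------------------

#' Fit the multi-environment mixed model by average-information REML
#'
#' Maximises the residual log-likelihood over the factor-analytic genetic,
#' design-term and spatial variance parameters. Updates are
#' average-information steps with step-halving against the log-likelihood
#' and an EM-style fallback for variance parameters; the accepted
#' log-likelihood sequence is non-decreasing. Variances are floored at
#' `1e-8 * var(y)` and autocorrelations constrained to `(-0.999, 0.999)`.
#'
#' @param spec A `melmm_spec` from [build_design()] (possibly modified by
#'   [set_genetic_terms()] / [add_fixed_columns()]).
#' @param start Optional parameter list from a previous fit (`fit$par`) for
#'   warm starting.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum iterations.
#' @param verbose Log each iteration.
#' @return An object of class `melmm_fit`: REML log-likelihood, fixed
#'   effects with standard errors, variance parameter estimates (`par`,
#'   plus tidied `fa`, `spatial`), genotype-by-environment BLUPs, and
#'   convergence diagnostics. Projection pieces (`Vi`, `ViX`, `Cfix`,
#'   `qv`) are retained for downstream genome scanning.
#' @export
reml_fit <- function(spec, start = NULL, tol = 1e-8, maxit = 100, verbose = FALSE) {
  stopifnot(inherits(spec, "melmm_spec"))
  if (spec$n <= ncol(spec$X))
    stop("more fixed-effect levels than plots", call. = FALSE)
  qrX <- qr(spec$X)
  if (qrX$rank < ncol(spec$X)) {
    aliased <- colnames(spec$X)[qrX$pivot[(qrX$rank + 1L):ncol(spec$X)]]
    stop(sprintf("singular fixed-effect design; aliased: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  floor_ <- 1e-8 * stats::var(spec$y)
  spec <- pad_kernels(spec)
  par <- if (is.null(start)) init_var_params(spec, floor_) else {
    start$floor <- floor_; start
  }
  lags <- spatial_lags(spec)
  aux <- build_aux(spec)

  fp <- flatten_params(spec, par)
  theta <- fp$values
  desc <- fp$desc
  npar <- length(theta)
  clamp <- function(v) {
    for (i in seq_len(npar)) v[i] <- min(max(v[i], desc[[i]]$lower), desc[[i]]$upper)
    v
  }
  theta <- clamp(theta)
  par <- unflatten_params(spec, par, theta)

  ev <- reml_eval(spec, build_V(spec, par, lags, aux))
  if (is.null(ev)) stop("initial variance model not positive definite", call. = FALSE)
  ll <- ev$ll
  grad_norm <- Inf
  converged <- FALSE
  iter <- 0L
  step0 <- 1

  while (iter < maxit) {
    iter <- iter + 1L
    if (is.null(ev)) {
      ev <- reml_eval(spec, build_V(spec, par, lags, aux))
      if (is.null(ev)) { converged <- FALSE; break }
    }
    sc <- reml_scores(spec, par, ev, lags, aux, desc)
    grad_norm <- sqrt(sum(sc$score^2))
    free <- rep(TRUE, npar)
    for (i in seq_len(npar)) {
      lo <- desc[[i]]$lower
      if (is.finite(lo) &&
          theta[i] <= lo + 1e-12 * (1 + abs(lo)) && sc$score[i] < 0)
        free[i] <- FALSE
      up <- desc[[i]]$upper
      if (is.finite(up) &&
          theta[i] >= up - 1e-12 * (1 + abs(up)) && sc$score[i] > 0)
        free[i] <- FALSE
    }
    accepted <- FALSE
    if (any(free)) {
      AI <- sc$AI[free, free, drop = FALSE]
      ridge <- 1e-8 * mean(diag(AI)) + 1e-12
      step_dir <- tryCatch(
        solve(AI + diag(ridge, nrow(AI)), sc$score[free]),
        error = function(e) NULL)
      if (!is.null(step_dir)) {
        stepsize <- step0
        for (h in seq_len(7)) {
          trial <- theta
          trial[free] <- trial[free] + stepsize * step_dir
          trial <- clamp(trial)
          par_t <- unflatten_params(spec, par, trial)
          ll_t <- reml_loglik(spec, build_V(spec, par_t, lags, aux))
          if (!is.null(ll_t) && ll_t >= ll - 1e-10 * (1 + abs(ll))) {
            delta <- ll_t - ll
            theta <- trial; par <- par_t; ev <- NULL
            accepted <- TRUE
            step0 <- min(1, stepsize * 2)
            if (verbose)
              message(sprintf("iter %d: AI step (%d halvings) logLik %.6f",
                              iter, h - 1L, ll_t))
            if (abs(delta) < tol * (1 + abs(ll_t))) converged <- TRUE
            ll <- ll_t
            break
          }
          stepsize <- stepsize / 2
        }
      }
    }
    if (!accepted) {
      # EM-style fallback on variance-type parameters
      trial <- theta
      for (i in seq_len(npar)) {
        k <- desc[[i]]$kind
        if (k %in% c("fa_psi", "diag_var", "iid_var", "sp_var") &&
            is.finite(desc[[i]]$m)) {
          trial[i] <- theta[i] + 2 * theta[i]^2 * sc$score[i] / desc[[i]]$m
        }
      }
      trial <- clamp(trial)
      par_t <- unflatten_params(spec, par, trial)
      ll_t <- reml_loglik(spec, build_V(spec, par_t, lags, aux))
      if (!is.null(ll_t) && ll_t >= ll - 1e-10 * (1 + abs(ll)) &&
          any(trial != theta)) {
        delta <- ll_t - ll
        theta <- trial; par <- par_t; ev <- NULL
        accepted <- TRUE
        if (verbose) message(sprintf("iter %d: EM step logLik %.6f", iter, ll_t))
        if (abs(delta) < tol * (1 + abs(ll_t))) converged <- TRUE
        ll <- ll_t
      }
    }
    if (!accepted) {
      # no improving step available: treat as converged if the gradient on
      # free parameters is negligible, otherwise flag non-convergence
      converged <- grad_norm < 1e-3 * (1 + abs(ll)) || !any(free)
      break
    }
    if (converged) break
  }

  if (is.null(ev)) {
    ev <- reml_eval(spec, build_V(spec, par, lags, aux))
    if (is.null(ev)) stop("variance model left positive-definite domain",
                          call. = FALSE)
  }
  assemble_fit(spec, par, ev, ll, converged, iter, grad_norm)
}

reml_scores <- function(spec, par, ev, lags, aux, desc) {
  n <- spec$n
  P <- ev$Vi - ev$ViX %*% tcrossprod(ev$Cfix, ev$ViX)
  qv <- ev$qv
  npar <- length(desc)
  Ydot <- matrix(0, n, npar)
  trs <- numeric(npar)

  Wf <- NULL
  S_by_term <- list()
  need_gen <- any(vapply(desc, function(d)
    d$kind %in% c("fa_loading", "fa_psi", "diag_var"), logical(1)))
  if (need_gen) {
    Wf <- agg_effect(P, spec)
    for (g in seq_along(par$genetic)) {
      S_by_term[[g]] <- kernel_contract(Wf, spec$genetic[[g]]$K, spec$r, spec$t)
    }
    # aggregated qv for working vectors
    mask <- !is.na(spec$line_i)
    eff <- (spec$env_i[mask] - 1L) * spec$r + spec$line_i[mask]
    qe <- numeric(spec$r * spec$t)
    qa <- rowsum(qv[mask], eff)
    qe[as.integer(rownames(qa))] <- qa
    Qmat <- matrix(qe, spec$r, spec$t)
  }

  for (i in seq_along(desc)) {
    d <- desc[[i]]
    kind <- d$kind
    if (kind %in% c("fa_loading", "fa_psi", "diag_var")) {
      g <- d$term
      pg <- par$genetic[[g]]
      B <- matrix(0, spec$t, spec$t)
      if (kind == "fa_loading") {
        ej <- rep(0, spec$t); ej[d$i] <- 1
        lam <- pg$Lambda[, d$j]
        B <- outer(ej, lam) + outer(lam, ej)
      } else {
        B[d$i, d$i] <- 1
      }
      trs[i] <- sum(B * S_by_term[[g]])
      K <- spec$genetic[[g]]$K
      KQ <- if (is.null(K)) Qmat else
        K[seq_len(spec$r), seq_len(spec$r)] %*% Qmat
      Out <- KQ %*% t(B)
      yd <- numeric(n)
      mask <- !is.na(spec$line_i)
      yd[mask] <- Out[cbind(spec$line_i[mask], spec$env_i[mask])]
      Ydot[, i] <- yd
    } else if (kind == "iid_var") {
      u <- d$term
      Zl <- aux$same_level[[u]]
      trs[i] <- sum(P * Zl)
      lev <- spec$iid_terms[[u]]$level
      maskl <- !is.na(lev)
      s <- rowsum(qv[maskl], lev[maskl])
      yd <- numeric(n)
      yd[maskl] <- s[match(lev[maskl], as.integer(rownames(s)))]
      Ydot[, i] <- yd
    } else if (kind == "sp_var") {
      jj <- d$i
      idx <- spec$spatial[[jj]]$idx
      R <- ar1_from_lags(par$sp_rho_row[jj], par$sp_rho_col[jj], lags[[jj]])
      trs[i] <- sum(P[idx, idx] * R)
      Ydot[idx, i] <- R %*% qv[idx]
    } else if (kind %in% c("sp_rho_row", "sp_rho_col")) {
      jj <- d$i
      idx <- spec$spatial[[jj]]$idx
      dR <- par$sp_var[jj] *
        ar1_deriv_from_lags(par$sp_rho_row[jj], par$sp_rho_col[jj], lags[[jj]],
                            if (kind == "sp_rho_row") "row" else "col")
      trs[i] <- sum(P[idx, idx] * dR)
      Ydot[idx, i] <- dR %*% qv[idx]
    }
  }
  quad <- drop(crossprod(Ydot, qv))
  score <- -0.5 * (trs - quad)
  PY <- P %*% Ydot
  AI <- 0.5 * crossprod(Ydot, PY)
  list(score = score, AI = AI)
}

assemble_fit <- function(spec, par, ev, ll, converged, iter, grad_norm) {
  beta <- ev$beta
  names(beta) <- colnames(spec$X)
  se <- sqrt(pmax(diag(ev$Cfix), 0))
  names(se) <- names(beta)

  # BLUPs per genetic term at the genotype x environment level
  mask <- !is.na(spec$line_i)
  eff <- (spec$env_i[mask] - 1L) * spec$r + spec$line_i[mask]
  qe <- numeric(spec$r * spec$t)
  qa <- rowsum(ev$qv[mask], eff)
  qe[as.integer(rownames(qa))] <- qa
  Qmat <- matrix(qe, spec$r, spec$t)
  blup <- lapply(seq_along(par$genetic), function(g) {
    A <- genetic_A(par$genetic[[g]], spec$t)
    K <- spec$genetic[[g]]$K
    KQ <- if (is.null(K)) Qmat else K[seq_len(spec$r), seq_len(spec$r)] %*% Qmat
    U <- KQ %*% t(A)
    dimnames(U) <- list(spec$lines, spec$envs)
    U
  })
  names(blup) <- vapply(spec$genetic, function(tm) tm$name, character(1))

  fa <- NULL
  g1 <- which(vapply(par$genetic, function(p) p$structure == "fa", logical(1)))
  if (length(g1) > 0L) {
    pg <- par$genetic[[g1[1]]]
    fa <- fa_params(pg$Lambda, pg$psi, envs = spec$envs)
  }
  spat <- spatial_params(spec$envs, par$sp_var,
                         par$sp_rho_row, par$sp_rho_col)
  structure(list(spec = spec, par = par, loglik = ll, beta = beta,
                 beta_se = se, vcov_beta = ev$Cfix, fa = fa, spatial = spat,
                 blup = blup, converged = converged, iterations = iter,
                 grad_norm = grad_norm,
                 Vi = ev$Vi, ViX = ev$ViX, Cfix = ev$Cfix, qv = ev$qv),
            class = "melmm_fit")
}

#' @export
print.melmm_fit <- function(x, ...) {
  cat(sprintf(paste0("Multi-environment mixed model fit (REML)\n",
                     "  plots: %d  environments: %d  lines: %d\n",
                     "  logLik: %.4f  iterations: %d  converged: %s\n"),
              x$spec$n, x$spec$t, x$spec$r, x$loglik, x$iterations,
              x$converged))
  invisible(x)
}

#' Between-environment genetic correlation matrix
#'
#' The correlation form of the estimated genetic covariance
#' `Lambda Lambda' + Psi` from a fitted baseline model.
#'
#' @param fit A converged `melmm_fit` whose genetic term has FA structure.
#' @return t x t correlation matrix with environment dimnames.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "melmm_fit"))
  if (!fit$converged) warning("fit did not converge; correlations indicative only")
  if (is.null(fit$fa)) stop("no FA genetic term in this fit", call. = FALSE)
  D <- fa_covariance(fit$fa)
  v <- diag(D)
  if (any(v <= 1e-12 * max(v)))
    warning("zero-variance environment: correlations undefined there")
  C <- stats::cov2cor(D)
  dimnames(C) <- list(fit$spec$envs, fit$spec$envs)
  C
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy variance and fixed-effect estimates of a mixed-model fit
#'
#' @param x A `melmm_fit`.
#' @param effects `"varcomp"` (default) or `"fixed"`.
#' @param ... Unused.
#' @return A tibble: for variance components, `component`, `term`, `env`,
#'   `estimate`; for fixed effects, `term`, `estimate`, `std.error`.
#' @export
tidy.melmm_fit <- function(x, effects = c("varcomp", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    return(tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                          std.error = unname(x$beta_se)))
  }
  rows <- list()
  for (g in seq_along(x$par$genetic)) {
    pg <- x$par$genetic[[g]]
    nm <- x$spec$genetic[[g]]$name
    if (pg$structure == "fa") {
      for (m in seq_len(ncol(pg$Lambda)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          component = nm, term = sprintf("loading_%d", m), env = x$spec$envs,
          estimate = pg$Lambda[, m])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        component = nm, term = "psi", env = x$spec$envs, estimate = pg$psi)
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        component = nm, term = "variance", env = x$spec$envs, estimate = pg$d)
    }
  }
  for (u in seq_along(x$par$iid)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = x$spec$iid_terms[[u]]$name, term = "variance",
      env = NA_character_, estimate = x$par$iid[u])
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    component = "spatial", term = "sigma2", env = x$spec$envs,
    estimate = x$par$sp_var)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    component = "spatial", term = "rho_row", env = x$spec$envs,
    estimate = x$par$sp_rho_row)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    component = "spatial", term = "rho_col", env = x$spec$envs,
    estimate = x$par$sp_rho_col)
  dplyr::bind_rows(rows)
}

#' One-row fit summary
#'
#' @param x A `melmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `nobs`, `n_fixed`, `n_varcomp`,
#'   `iterations`, `converged`, `grad_norm`.
#' @export
glance.melmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$spec$n, n_fixed = ncol(x$spec$X),
                 n_varcomp = length(flatten_params(x$spec, x$par)$values),
                 iterations = x$iterations, converged = x$converged,
                 grad_norm = x$grad_norm)
}
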