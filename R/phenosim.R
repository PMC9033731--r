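#' Factor-analytic genetic covariance parameters
#'
#' The environment x environment genetic covariance is approximated by
#' `Lambda %*% t(Lambda) + diag(psi)`: a rank-k loading structure plus
#' environment-specific variances.
#'
#' @param loadings t x k matrix of environment loadings.
#' @param psi Length-t vector of specific variances (>= 0).
#' @param envs Optional environment labels (rownames of `loadings`).
#' @return An object of class `fa_params`.
#' @export
fa_params <- function(loadings, psi, envs = NULL) {
  loadings <- as.matrix(loadings)
  stopifnot(length(psi) == nrow(loadings), all(psi >= 0))
  if (!is.null(envs)) rownames(loadings) <- envs
  structure(list(loadings = loadings, psi = psi), class = "fa_params")
}

#' Implied genetic covariance of FA parameters
#' @param fa An `fa_params` object.
#' @return The t x t covariance `Lambda Lambda' + Psi`.
#' @export
fa_covariance <- function(fa) {
  tcrossprod(fa$loadings) + diag(fa$psi, nrow(fa$loadings))
}

#' Per-environment spatial residual parameters
#'
#' @param env Environment labels.
#' @param sigma2 Residual variances (> 0).
#' @param rho_row,rho_col AR1 autocorrelations, `abs(rho) < 1`.
#' @return A tibble of class `spatial_params`.
#' @export
spatial_params <- function(env, sigma2, rho_row = 0, rho_col = 0) {
  stopifnot(all(sigma2 > 0), all(abs(rho_row) < 1), all(abs(rho_col) < 1))
  out <- tibble::tibble(env = env, sigma2 = sigma2,
                        rho_row = rho_row, rho_col = rho_col)
  class(out) <- c("spatial_params", class(tibble::tibble()))
  out
}

#' QTL specification for simulation
#'
#' @param marker Marker names (must exist among the genotype columns).
#' @param kind `"performance"` or `"responsiveness"` per entry.
#' @param effect Additive effect sizes: trait units per allele unit for
#'   performance, trait units per allele unit per covariate unit for
#'   responsiveness.
#' @param covariate Covariate name per entry (`NA` for performance).
#' @return A tibble of class `qtl_spec`.
#' @export
qtl_spec <- function(marker = character(), kind = character(),
                     effect = numeric(), covariate = NA_character_) {
  stopifnot(all(kind %in% c("performance", "responsiveness")),
            all(is.finite(effect) | length(effect) == 0L))
  out <- tibble::tibble(marker = marker, kind = kind, effect = effect,
                        covariate = covariate)
  if (any(out$kind == "responsiveness" & is.na(out$covariate)))
    stop("responsiveness effects need a covariate name", call. = FALSE)
  class(out) <- c("qtl_spec", class(tibble::tibble()))
  out
}

#' Simulate plot-level phenotypes on a field design
#'
#' Generates one trait value per design plot as: environment mean + check
#' effect (checks carry fixed effects only, no genetic value) + planted
#' performance effects `m * a` + planted responsiveness effects
#' `c * m * b` + a line-by-environment genetic deviation drawn with
#' covariance `Lambda Lambda' + Psi` across environments + a spatial
#' residual with per-environment variance and AR1 x AR1 correlation over
#' the grid. Duplicate plots of a line within an environment share all
#' genetic terms and differ only in the spatial residual.
#'
#' @param design A `field_design`.
#' @param genotypes Complete genotype matrix (lines x markers); all
#'   non-check design genotypes must appear among its rownames.
#' @param qtl A [qtl_spec()] (may have zero rows).
#' @param covariates A `climatic_covariates` tibble; required when `qtl`
#'   contains responsiveness effects.
#' @param env_means Named numeric vector of environment means.
#' @param fa An [fa_params()] object with one row per environment (rownames
#'   matching the design environments).
#' @param spatial A [spatial_params()] tibble covering every environment.
#' @param seed Integer seed.
#' @param check_effects Optional named vector of fixed check effects
#'   (default 0).
#' @param trait Trait label stored in the result.
#' @return The design tibble with columns `trait` and `y` appended (class
#'   `trait_observations`).
#' @export
simulate_phenotypes <- function(design, genotypes, qtl = qtl_spec(),
                                covariates = NULL, env_means, fa, spatial,
                                seed, check_effects = NULL, trait = "yield") {
  envs <- unique(design$env)
  stopifnot(all(envs %in% names(env_means)),
            all(envs %in% spatial$env),
            nrow(fa$loadings) == length(envs))
  if (is.null(rownames(fa$loadings))) rownames(fa$loadings) <- envs
  dh <- unique(design$genotype[!design$is_check])
  missing_g <- setdiff(dh, rownames(genotypes))
  if (length(missing_g) > 0L)
    stop(sprintf("design genotypes absent from genotype matrix: %s",
                 paste(utils::head(missing_g, 5), collapse = ", ")),
         call. = FALSE)
  resp <- qtl[qtl$kind == "responsiveness", ]
  if (nrow(resp) > 0L) {
    if (is.null(covariates))
      stop("covariates required for responsiveness effects", call. = FALSE)
    have <- unique(covariates$covariate)
    if (!all(resp$covariate %in% have))
      stop(sprintf("covariate missing for planted responsiveness QTL: %s",
                   paste(setdiff(resp$covariate, have), collapse = ", ")),
           call. = FALSE)
  }
  bad_m <- setdiff(qtl$marker, colnames(genotypes))
  if (length(bad_m) > 0L)
    stop(sprintf("planted QTL markers absent from genotypes: %s",
                 paste(bad_m, collapse = ", ")), call. = FALSE)

  withr_seed(seed, {
    r <- length(dh); t <- length(envs)
    # line-by-environment deviations: rows iid N(0, Lambda Lambda' + Psi)
    k <- ncol(fa$loadings)
    U <- matrix(stats::rnorm(r * k), r, k) %*% t(fa$loadings) +
      matrix(stats::rnorm(r * t), r, t) %*% diag(sqrt(fa$psi), t)
    dimnames(U) <- list(dh, rownames(fa$loadings))

    # genetic value per (line, env): planted QTL + FA deviation
    gval <- U[, envs, drop = FALSE]
    perf <- qtl[qtl$kind == "performance", ]
    if (nrow(perf) > 0L) {
      add <- genotypes[dh, perf$marker, drop = FALSE] %*% perf$effect
      gval <- gval + matrix(add, r, t)
    }
    if (nrow(resp) > 0L) {
      for (q in seq_len(nrow(resp))) {
        cv <- covariates[covariates$covariate == resp$covariate[q], ]
        cmat <- matrix(NA_real_, r, t, dimnames = list(dh, envs))
        cmat[cbind(match(cv$line, dh), match(cv$env, envs))] <- cv$value
        if (anyNA(cmat[, envs]))
          stop(sprintf("covariate %s missing for some line x environment",
                       resp$covariate[q]), call. = FALSE)
        gval <- gval + cmat * matrix(genotypes[dh, resp$marker[q]], r, t) *
          resp$effect[q]
      }
    }

    y <- numeric(nrow(design))
    for (e in envs) {
      pe <- which(design$env == e)
      d <- design[pe, ]
      sp <- spatial[spatial$env == e, ]
      nr <- max(d$row); nc <- max(d$column)
      op <- ar1_kron_correlation(sp$rho_row, sp$rho_col, nr, nc)
      Lr <- chol(ar1_matrix(sp$rho_row, nr))
      Lc <- chol(ar1_matrix(sp$rho_col, nc))
      zfull <- sqrt(sp$sigma2) *
        as.vector(t(Lr) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Lc)
      cell <- (d$column - 1L) * nr + d$row
      eps <- zfull[cell]
      base <- env_means[[e]] + eps
      gen <- ifelse(d$is_check,
                    if (is.null(check_effects)) 0 else
                      unname(check_effects[d$genotype]),
                    gval[cbind(match(d$genotype, dh),
                               rep(match(e, envs), nrow(d)))])
      # checks without a supplied effect default to 0
      gen[is.na(gen)] <- 0
      y[pe] <- base + gen
    }
    out <- design
    out$trait <- trait
    out$y <- y
    class(out) <- c("trait_observations", class(tibble::tibble()))
    out
  })
}
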