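# Whole-genome scans for performance and responsiveness QTL.
#
# For each chromosome the baseline genotype-by-environment term is
# re-partitioned into a marker-based additive polygenic term with
# covariance Delta_a (x) G_{-i} (leave-one-chromosome-out genomic
# relationship) plus a residual polygenic term Delta_p (x) I; variance
# parameters are re-estimated once per chromosome under the null and held
# fixed while each interval marker on that chromosome is tested as a fixed
# effect (across-environment effect a for the performance run, marker x
# climatic-covariate interaction b for the responsiveness run).

# covariance structure for the polygenic scan terms Delta_a and Delta_p:
# factor-analytic at the baseline order, with the order capped at t - 1;
# a single environment degenerates to a plain variance. A diagonal
# structure is deliberately NOT used at small t: with correlated
# genotype-by-environment effects a diagonal Delta_p understates the
# variance of line-level contrasts and inflates every scan Wald statistic.
scan_structure <- function(t, k) {
  if (t == 1L) list(structure = "diag", k = 1L)
  else list(structure = "fa", k = min(k, t - 1L))
}

# map marker scores (and optionally covariate values) onto plots
marker_plot_column <- function(spec, score, cvals = NULL) {
  x <- numeric(spec$n)
  mask <- !is.na(spec$line_i)
  x[mask] <- score[spec$line_i[mask]]
  if (!is.null(cvals)) {
    x[mask] <- x[mask] * cvals[cbind(spec$line_i[mask], spec$env_i[mask])]
  }
  x
}

scan_start <- function(spec_scan, baseline, prev_par) {
  if (!is.null(prev_par)) return(prev_par)
  if (is.null(baseline)) return(NULL)
  par <- init_var_params(spec_scan, 1e-8 * stats::var(spec_scan$y))
  bp <- baseline$par
  par$sp_var <- bp$sp_var
  par$sp_rho_row <- bp$sp_rho_row
  par$sp_rho_col <- bp$sp_rho_col
  if (length(par$iid) == length(bp$iid)) par$iid <- bp$iid
  # residual polygenic term inherits the baseline genetic structure when
  # the shapes agree
  if (length(par$genetic) == 2L &&
      identical(par$genetic[[2]]$structure, bp$genetic[[1]]$structure)) {
    par$genetic[[2]] <- bp$genetic[[1]]
  }
  par
}

# evaluate one scan kind against a fixed per-chromosome null fit
scan_chrom_tests <- function(spec, Mu, info, cols, fit_i, kind,
                             covariate_name, cvals) {
  Xm <- vapply(cols, function(j) marker_plot_column(spec, Mu[, j], cvals),
               numeric(spec$n))
  # testability is a property of the marker itself: a monomorphic column
  # has no allelic contrast regardless of the plot structure
  testable <- apply(Mu[, cols, drop = FALSE], 2,
                    function(x) stats::sd(x) > 1e-10)
  eff <- se <- wald <- rep(NA_real_, length(cols))
  if (any(testable)) {
    Xt <- Xm[, testable, drop = FALSE]
    A1 <- fit_i$Vi %*% Xt
    D <- crossprod(Xt, fit_i$ViX)
    sPx <- colSums(Xt * A1) - rowSums((D %*% fit_i$Cfix) * D)
    xPy <- drop(crossprod(Xt, fit_i$qv))
    ok <- sPx > 1e-12
    eff[testable] <- ifelse(ok, xPy / sPx, NA_real_)
    se[testable] <- ifelse(ok, 1 / sqrt(sPx), NA_real_)
    wald[testable] <- ifelse(ok, xPy^2 / sPx, NA_real_)
  }
  tibble::tibble(
    marker = info$marker[cols], chromosome = info$chromosome[cols],
    position = info$position[cols], kind = kind,
    covariate = covariate_name %||% NA_character_,
    effect = eff, se = se, wald = wald,
    p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    untestable = !testable)
}

covariate_matrix <- function(spec, covariates, covariate) {
  cv <- covariates[covariates$covariate == covariate, ]
  if (nrow(cv) == 0L)
    stop(sprintf("covariate '%s' not present", covariate), call. = FALSE)
  rng <- max(cv$value) - min(cv$value)
  if (rng <= 0)
    stop(sprintf(paste0("covariate '%s' is constant (range 0): a responsiveness ",
                        "effect per covariate unit is not identifiable"),
                 covariate), call. = FALSE)
  cvals <- matrix(NA_real_, spec$r, spec$t,
                  dimnames = list(spec$lines, spec$envs))
  sel <- cv$line %in% spec$lines & cv$env %in% spec$envs
  cvals[cbind(match(cv$line[sel], spec$lines), match(cv$env[sel], spec$envs))] <-
    cv$value[sel]
  if (anyNA(cvals))
    stop(sprintf("covariate '%s' missing for some line x environment", covariate),
         call. = FALSE)
  attr(cvals, "range") <- rng
  cvals
}

#' Run all genome-scan kinds over shared per-chromosome null models
#'
#' The per-chromosome null model (marker effect absent, polygenic terms
#' `Delta_a (x) G_{-i}` and `Delta_p (x) I` in place) is identical for the
#' performance run and every responsiveness run, so it is fitted once per
#' chromosome and all requested scan kinds are evaluated against it.
#'
#' @inheritParams scan_performance
#' @param covariates A `climatic_covariates` tibble (needed when
#'   `covariate_names` is non-empty).
#' @param covariate_names Covariates to scan for responsiveness (may be
#'   empty for a performance-only run).
#' @param performance Include the performance run (default TRUE).
#' @return A named list of `qtl_scan` tibbles (`performance`, then one
#'   `resp_<covariate>` per covariate).
#' @export
scan_genome <- function(spec, M, covariates = NULL, covariate_names = character(),
                        performance = TRUE, baseline = NULL, grms = NULL,
                        tol = 1e-6, maxit = 60, verbose = FALSE) {
  info <- marker_info(M)
  Mu <- unclass(M)
  stopifnot(all(spec$lines %in% rownames(Mu)))
  Mu <- Mu[spec$lines, , drop = FALSE]
  chroms <- unique(info$chromosome)
  st <- scan_structure(spec$t, if (spec$t <= 4L) 1L else 2L)
  cmats <- lapply(stats::setNames(covariate_names, covariate_names),
                  function(cv) covariate_matrix(spec, covariates, cv))
  kinds <- c(if (performance) "performance",
             if (length(covariate_names)) paste0("resp_", covariate_names))
  out <- stats::setNames(rep(list(vector("list", length(chroms))), length(kinds)),
                         kinds)
  null_fits <- list()
  prev_par <- NULL
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    G <- if (!is.null(grms)) grms[[ch]] else compute_grm(M, exclude_chromosome = ch)
    G <- G[spec$lines, spec$lines]
    spec_i <- set_genetic_terms(spec, list(
      list(name = "u_a", structure = st$structure, k = st$k, K = G),
      list(name = "u_p", structure = st$structure, k = st$k, K = NULL)))
    fit_i <- reml_fit(spec_i, start = scan_start(spec_i, baseline, prev_par),
                      tol = tol, maxit = maxit, verbose = verbose)
    prev_par <- fit_i$par
    null_fits[[ch]] <- glance(fit_i)
    cols <- which(info$chromosome == ch)
    if (performance)
      out$performance[[ci]] <- scan_chrom_tests(spec, Mu, info, cols, fit_i,
                                                "performance", NULL, NULL)
    for (cv in covariate_names)
      out[[paste0("resp_", cv)]][[ci]] <-
        scan_chrom_tests(spec, Mu, info, cols, fit_i, "responsiveness", cv,
                         cmats[[cv]])
  }
  nf <- dplyr::bind_rows(null_fits, .id = "chromosome")
  res <- lapply(stats::setNames(kinds, kinds), function(kd) {
    x <- dplyr::bind_rows(out[[kd]])
    attr(x, "kind") <- if (kd == "performance") "performance" else "responsiveness"
    attr(x, "covariate") <- if (kd == "performance") NULL else sub("^resp_", "", kd)
    attr(x, "covariate_range") <- if (kd == "performance") NA_real_ else
      attr(cmats[[sub("^resp_", "", kd)]], "range")
    attr(x, "null_fits") <- nf
    class(x) <- c("qtl_scan", class(tibble::tibble()))
    x
  })
  res
}

#' Genome scan for performance QTL
#'
#' Tests every interval marker for a stable across-environment additive
#' effect, against a background of marker-based additive polygenic effects
#' (covariance `Delta_a (x) G_{-i}`, where `G_{-i}` omits the scanned
#' chromosome) and residual polygenic effects (`Delta_p (x) I`). Variance
#' parameters are re-estimated per chromosome under the null and held
#' fixed across that chromosome's markers. Monomorphic markers are flagged
#' untestable, not dropped.
#'
#' @param spec A `melmm_spec` from [build_design()].
#' @param M An `interval_markers` matrix covering `spec$lines`.
#' @param baseline Optional baseline `melmm_fit` used to warm-start the
#'   per-chromosome variance estimation.
#' @param grms Optional named list of precomputed leave-one-chromosome-out
#'   relationship matrices.
#' @param tol,maxit REML controls for the per-chromosome null fits.
#' @param verbose Log progress.
#' @return A `qtl_scan` tibble: `marker`, `chromosome`, `position`, `kind`,
#'   `covariate`, `effect`, `se`, `wald`, `p_value`, `untestable`.
#' @export
scan_performance <- function(spec, M, baseline = NULL, grms = NULL,
                             tol = 1e-6, maxit = 60, verbose = FALSE) {
  scan_genome(spec, M, baseline = baseline, grms = grms, tol = tol,
              maxit = maxit, verbose = verbose)$performance
}

#' Genome scan for climate-responsiveness QTL
#'
#' As [scan_performance()], but the tested fixed effect is the elementwise
#' product of the line x environment climatic covariate (on its raw scale)
#' and the marker score, so the estimated effect is trait units per allele
#' unit per covariate unit. The covariate's numerical range is carried
#' along for normalising reported effects onto the trait scale.
#'
#' @inheritParams scan_performance
#' @param covariates A `climatic_covariates` tibble.
#' @param covariate Name of the covariate to scan.
#' @return A `qtl_scan` tibble (see [scan_performance()]); the covariate
#'   range is attached as attribute `covariate_range`.
#' @export
scan_responsiveness <- function(spec, M, covariates, covariate,
                                baseline = NULL, grms = NULL,
                                tol = 1e-6, maxit = 60, verbose = FALSE) {
  scan_genome(spec, M, covariates = covariates, covariate_names = covariate,
              performance = FALSE, baseline = baseline, grms = grms,
              tol = tol, maxit = maxit,
              verbose = verbose)[[paste0("resp_", covariate)]]
}

#' Genome-wide significance threshold by the effective number of tests
#'
#' Per chromosome, the eigenvalues of the interval-marker correlation
#' matrix give an effective test count
#' `M_eff = sum(1(lambda >= 1) + (lambda - floor(lambda)))`; chromosome
#' counts are summed over the genome, the per-test level is the Sidak
#' adjustment `1 - (1 - alpha)^(1/M_eff)`, and the Wald threshold is the
#' corresponding 1-df chi-square quantile.
#'
#' @param M An `interval_markers` matrix.
#' @param alpha Genome-wide significance level (default 0.05 per scan run).
#' @return A list of class `threshold_spec`: `alpha`, `m_eff`,
#'   `per_test_alpha`, `wald_threshold`, `per_chromosome` (tibble).
#' @export
li_ji_threshold <- function(M, alpha = 0.05) {
  info <- marker_info(M)
  Mu <- unclass(M)
  if (ncol(Mu) < 2L) stop("need at least 2 markers", call. = FALSE)
  per_chr <- purrr::map_dfr(unique(info$chromosome), function(ch) {
    cols <- which(info$chromosome == ch)
    X <- Mu[, cols, drop = FALSE]
    v <- apply(X, 2, stats::var)
    if (any(v <= 1e-12)) {
      warning(sprintf("excluding %d zero-variance marker(s) on %s",
                      sum(v <= 1e-12), ch))
      X <- X[, v > 1e-12, drop = FALSE]
    }
    if (ncol(X) == 0L) return(tibble::tibble(chromosome = ch, m_eff = 0))
    if (ncol(X) == 1L) return(tibble::tibble(chromosome = ch, m_eff = 1))
    lam <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    # the integer-part split is discontinuous at whole numbers; snap
    # eigenvalues within numerical noise of an integer before applying it
    near <- abs(lam - round(lam)) < 1e-8
    lam[near] <- round(lam[near])
    tibble::tibble(chromosome = ch,
                   m_eff = sum((lam >= 1) + (lam - floor(lam))))
  })
  m_eff <- sum(per_chr$m_eff)
  per_test <- 1 - (1 - alpha)^(1 / m_eff)
  structure(list(alpha = alpha, m_eff = m_eff, per_test_alpha = per_test,
                 wald_threshold = stats::qchisq(per_test, df = 1,
                                                lower.tail = FALSE),
                 per_chromosome = per_chr),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(paste0("Genome-wide threshold: alpha = %.3f, M_eff = %.1f,\n",
                     "  per-test alpha = %.3e, Wald threshold = %.2f\n"),
              x$alpha, x$m_eff, x$per_test_alpha, x$wald_threshold))
  invisible(x)
}

#' Prune significant markers within a linkage window
#'
#' Among markers whose Wald statistic exceeds the threshold, iteratively
#' keeps the most significant and discards all same-chromosome markers
#' within `window` cM of a kept marker. Ties in significance are broken
#' towards the lower cM position, making the selection deterministic and
#' order-independent.
#'
#' @param scan A `qtl_scan` tibble.
#' @param threshold A `threshold_spec` or a numeric Wald threshold.
#' @param window Exclusion window in cM (default 30).
#' @return The selected subset of `scan` rows (possibly empty), ordered by
#'   chromosome and position.
#' @export
prune_30cM <- function(scan, threshold, window = 30) {
  thr <- if (inherits(threshold, "threshold_spec")) threshold$wald_threshold
         else threshold
  cand <- scan[!is.na(scan$wald) & scan$wald > thr, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(-cand$wald, cand$chromosome, cand$position), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep & cand$chromosome == cand$chromosome[i] &
              abs(cand$position - cand$position[i]) <= window)) next
    keep[i] <- TRUE
  }
  out <- cand[keep, ]
  out[order(out$chromosome, out$position), ]
}

#' Joint final QTL model over the selected markers
#'
#' Fits all selected interval markers together as fixed effects, with the
#' marker-based polygenic term rebuilt on a relationship matrix that
#' excludes every interval marker within `window` cM of a selected marker
#' (`G_{-s}`), plus the residual polygenic term. Variance parameters are
#' re-estimated once for the joint model. Collinear selected markers are
#' reported and the weaker (by scan Wald statistic) members dropped.
#'
#' @param spec A `melmm_spec`.
#' @param selected Output of [prune_30cM()] (one scan kind; for a
#'   responsiveness scan the covariate and its range are taken from the
#'   scan attributes via `covariates`).
#' @param M The `interval_markers` matrix.
#' @param covariates `climatic_covariates` tibble (responsiveness only).
#' @param window Exclusion half-window in cM around selected markers.
#' @param trait,population Labels recorded on each QTL.
#' @param parents Named character vector `c(A = ..., B = ...)` naming the
#'   parental sources of the +1 and -1 alleles.
#' @param tol,maxit REML controls.
#' @return A tibble of class `qtl_records`: `name`, `trait`, `population`,
#'   `type`, `covariate`, `chromosome`, `position`, `effect`, `se`,
#'   `normalised_effect`, `wald`, `p_value`, `lod`,
#'   `positive_allele_source`.
#' @export
fit_final_model <- function(spec, selected, M, covariates = NULL, window = 30,
                            trait = "trait", population = "POP",
                            parents = c(A = "A", B = "B"),
                            tol = 1e-6, maxit = 60) {
  empty <- tibble::tibble(
    name = character(), trait = character(), population = character(),
    type = character(), covariate = character(), chromosome = character(),
    position = numeric(), effect = numeric(), se = numeric(),
    normalised_effect = numeric(), wald = numeric(), p_value = numeric(),
    lod = numeric(), positive_allele_source = character())
  class(empty) <- c("qtl_records", class(tibble::tibble()))
  if (nrow(selected) == 0L) return(empty)
  kind <- selected$kind[1]
  stopifnot(all(selected$kind == kind))
  info <- marker_info(M)
  Mu <- unclass(M)[spec$lines, , drop = FALSE]

  cvals <- NULL; rng <- NA_real_
  if (kind == "responsiveness") {
    covname <- selected$covariate[1]
    cv <- covariates[covariates$covariate == covname, ]
    rng <- max(cv$value) - min(cv$value)
    cvals <- matrix(NA_real_, spec$r, spec$t,
                    dimnames = list(spec$lines, spec$envs))
    sel <- cv$line %in% spec$lines & cv$env %in% spec$envs
    cvals[cbind(match(cv$line[sel], spec$lines),
                match(cv$env[sel], spec$envs))] <- cv$value[sel]
  }

  sel_now <- selected
  repeat {
    cols <- match(sel_now$marker, info$marker)
    Xq <- vapply(cols, function(j)
      marker_plot_column(spec, Mu[, j], cvals), numeric(spec$n))
    colnames(Xq) <- sel_now$marker
    XX <- cbind(spec$X, Xq)
    qrx <- qr(XX)
    if (qrx$rank == ncol(XX)) break
    aliased <- colnames(XX)[qrx$pivot[(qrx$rank + 1L):ncol(XX)]]
    aliased <- intersect(aliased, sel_now$marker)
    drop_m <- sel_now$marker[sel_now$marker %in% aliased]
    drop_m <- drop_m[which.min(sel_now$wald[match(drop_m, sel_now$marker)])]
    message(sprintf("final model: marker %s aliased with the selection; dropped",
                    drop_m))
    sel_now <- sel_now[sel_now$marker != drop_m, , drop = FALSE]
    if (nrow(sel_now) == 0L) return(empty)
  }

  wins <- tibble::tibble(chromosome = sel_now$chromosome,
                         position = sel_now$position, half_width = window)
  Gs <- tryCatch(compute_grm(M, exclude_windows = wins)[spec$lines, spec$lines],
                 error = function(e) NULL)
  st <- scan_structure(spec$t, if (spec$t <= 4L) 1L else 2L)
  terms <- if (is.null(Gs)) {
    # selection windows cover the whole map: no marker-based kernel left,
    # keep the residual polygenic term only
    message("final model: exclusion windows cover all interval markers; ",
            "fitting the residual polygenic term only")
    list(list(name = "u_p", structure = st$structure, k = st$k, K = NULL))
  } else {
    list(list(name = "u_a", structure = st$structure, k = st$k, K = Gs),
         list(name = "u_p", structure = st$structure, k = st$k, K = NULL))
  }
  spec_f <- set_genetic_terms(spec, terms)
  spec_f <- add_fixed_columns(spec_f, Xq[, sel_now$marker, drop = FALSE])
  fit <- reml_fit(spec_f, tol = tol, maxit = maxit)
  bi <- match(sel_now$marker, names(fit$beta))
  eff <- unname(fit$beta[bi])
  se <- unname(fit$beta_se[bi])
  wald <- (eff / se)^2
  out <- tibble::tibble(
    name = qtl_names(trait, population, sel_now$chromosome),
    trait = trait, population = population, type = kind,
    covariate = if (kind == "responsiveness") sel_now$covariate else NA_character_,
    chromosome = sel_now$chromosome, position = sel_now$position,
    effect = eff, se = se,
    normalised_effect = if (kind == "responsiveness") eff * rng else NA_real_,
    wald = wald,
    p_value = stats::pchisq(wald, 1, lower.tail = FALSE),
    lod = lod_from_wald(wald),
    positive_allele_source = unname(ifelse(eff >= 0, parents["A"], parents["B"])))
  attr(out, "fit") <- fit
  attr(out, "covariate_range") <- rng
  class(out) <- c("qtl_records", class(tibble::tibble()))
  out
}

# Q<trait>.<tag>-<pop>.<chr>[-n] naming
qtl_names <- function(trait, population, chromosome, tag = "clim") {
  tr <- paste0(toupper(substring(trait, 1, 1)), substring(trait, 2, 3))
  base <- sprintf("Q%s.%s-%s.%s", tr, tag, population, chromosome)
  idx <- stats::ave(seq_along(base), base, FUN = seq_along)
  cnt <- stats::ave(seq_along(base), base, FUN = length)
  ifelse(cnt > 1L, sprintf("%s-%d", base, idx), base)
}

#' Normalise a responsiveness effect by the covariate range
#'
#' Multiplies the additive interaction effect (trait units per covariate
#' unit) by the covariate's observed numerical range, putting the effect on
#' the trait scale over the environmental span actually sampled.
#'
#' @param records A `qtl_records` tibble of responsiveness QTL.
#' @param range Covariate range (max - min over line x environment values).
#' @return `records` with `normalised_effect` set.
#' @export
normalise_effect <- function(records, range) {
  if (any(records$type != "responsiveness"))
    stop("normalisation applies to responsiveness records only", call. = FALSE)
  records$normalised_effect <- records$effect * range
  records
}

#' LOD score from a 1-df Wald statistic
#'
#' Uses the chi-square(1) to LOD correspondence `LOD = W / (2 ln 10)`.
#'
#' @param wald Non-negative Wald statistic(s).
#' @return LOD score(s).
#' @export
lod_from_wald <- function(wald) {
  stopifnot(all(wald >= 0, na.rm = TRUE))
  wald / (2 * log(10))
}
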