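#' Build the multi-environment mixed-model specification
#'
#' Assembles the design structures for the baseline multi-environment
#' linear mixed model: fixed environment means and per-environment check
#' means; random genotype-by-environment effects (checks excluded, with a
#' factor-analytic covariance across environments); optional random row and
#' column effects per environment; and per-environment AR1 x AR1 spatial
#' residuals. Plots with missing responses are dropped.
#'
#' @param observations A `trait_observations` tibble (design columns plus
#'   `y`); or any tibble with `env`, `column`, `row`, `genotype`,
#'   `is_check`, `y`.
#' @param design Optional `field_design` if `observations` carries only
#'   plot values; defaults to the design columns of `observations`.
#' @param fa_order FA order k for the genetic covariance; default 1 for up
#'   to 4 environments, 2 for 5 or more. Forced structure `"diag"` when a
#'   single environment is modelled.
#' @param genetic_structure `"fa"` or `"diag"`; default chosen from the
#'   environment count.
#' @param random_row,random_col Include random row / column effects within
#'   each environment (default TRUE).
#' @param block Optional column name in `observations` giving a replicate
#'   block factor to include as a random term.
#' @param estimate_spatial_rho Estimate the AR1 autocorrelations (default
#'   TRUE); if FALSE they are fixed at 0 (independent residuals).
#' @return An object of class `melmm_spec`.
#' @export
build_design <- function(observations, design = NULL, fa_order = NULL,
                         genetic_structure = NULL, random_row = TRUE,
                         random_col = TRUE, block = NULL,
                         estimate_spatial_rho = TRUE) {
  obs <- if (is.null(design)) observations else
    dplyr::bind_cols(design, observations["y"])
  need <- c("env", "column", "row", "genotype", "is_check", "y")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0L)
    stop(sprintf("observations lack columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  obs <- obs[!is.na(obs$y), , drop = FALSE]
  key <- paste(obs$env, obs$column, obs$row)
  if (anyDuplicated(key) > 0L)
    stop(sprintf("duplicate plot position: %s", key[duplicated(key)][1]),
         call. = FALSE)
  envs <- unique(obs$env)
  t <- length(envs)
  lines <- sort(unique(obs$genotype[!obs$is_check]))
  r <- length(lines)
  env_i <- match(obs$env, envs)
  line_i <- ifelse(obs$is_check, NA_integer_, match(obs$genotype, lines))
  if (any(is.na(line_i) & !obs$is_check))
    stop("genotype absent from both DH set and check list", call. = FALSE)
  n <- nrow(obs)

  # fixed part: environment means, then per-environment check means
  X <- matrix(0, n, t, dimnames = list(NULL, paste0("env:", envs)))
  X[cbind(seq_len(n), env_i)] <- 1
  checks <- sort(unique(obs$genotype[obs$is_check]))
  for (ck in checks) {
    for (e in envs) {
      sel <- obs$is_check & obs$genotype == ck & obs$env == e
      if (any(sel)) {
        col <- as.numeric(sel)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- sprintf("check:%s@%s", ck, e)
      }
    }
  }

  if (is.null(genetic_structure)) genetic_structure <- if (t == 1L) "diag" else "fa"
  if (is.null(fa_order)) fa_order <- if (t <= 4L) 1L else 2L
  fa_order <- min(fa_order, max(t - 1L, 1L))
  genetic <- list(list(name = "ge", structure = genetic_structure,
                       k = fa_order, K = NULL))

  iid_terms <- list()
  if (random_row && t >= 1L) {
    lev <- paste(obs$env, obs$row)
    iid_terms <- c(iid_terms, list(list(name = "row", level = match(lev, unique(lev)))))
  }
  if (random_col) {
    lev <- paste(obs$env, obs$column)
    iid_terms <- c(iid_terms, list(list(name = "col", level = match(lev, unique(lev)))))
  }
  if (!is.null(block)) {
    lev <- paste(obs$env, obs[[block]])
    iid_terms <- c(iid_terms, list(list(name = "block", level = match(lev, unique(lev)))))
  }

  spatial <- lapply(envs, function(e) {
    sel <- obs$env == e
    nr <- max(obs$row[sel]); nc <- max(obs$column[sel])
    list(env = e, idx = which(sel), nr = nr, nc = nc,
         rowpos = obs$row[sel], colpos = obs$column[sel])
  })
  names(spatial) <- envs

  structure(list(y = obs$y, X = X, n = n, obs = tibble::as_tibble(obs),
                 envs = envs, lines = lines, r = r, t = t,
                 env_i = env_i, line_i = line_i,
                 genetic = genetic, iid_terms = iid_terms,
                 spatial = spatial,
                 estimate_spatial_rho = estimate_spatial_rho),
            class = "melmm_spec")
}

#' Replace the genetic terms of a model specification
#'
#' Used by the genome scan: the total genotype-by-environment effect is
#' re-partitioned into a marker-based additive term with covariance
#' `Delta_a (x) G` (G a genomic relationship matrix) plus a residual
#' polygenic term with covariance `Delta_p (x) I`.
#'
#' @param spec A `melmm_spec`.
#' @param terms List of genetic term descriptors, each a list with `name`,
#'   `structure` (`"fa"` or `"diag"`), `k` (FA order) and `K` (r x r kernel
#'   matrix or NULL for identity, rows/cols ordered as `spec$lines`).
#' @return The modified `melmm_spec`.
#' @export
set_genetic_terms <- function(spec, terms) {
  stopifnot(inherits(spec, "melmm_spec"))
  for (tm in terms) {
    if (!is.null(tm$K)) stopifnot(nrow(tm$K) == spec$r, ncol(tm$K) == spec$r)
  }
  spec$genetic <- terms
  spec
}

#' Add fixed covariate columns (e.g. marker effects) to the design
#'
#' @param spec A `melmm_spec`.
#' @param cols Matrix of n x m fixed covariate values with column names.
#' @return The modified `melmm_spec`.
#' @export
add_fixed_columns <- function(spec, cols) {
  cols <- as.matrix(cols)
  stopifnot(nrow(cols) == spec$n)
  spec$X <- cbind(spec$X, cols)
  spec
}
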