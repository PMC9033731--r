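test_that("LOD follows the 1-df chi-square correspondence", {
  expect_equal(lod_from_wald(0), 0)
  expect_equal(lod_from_wald(2 * log(10)), 1)
  w <- c(1, 5, 20, 100)
  expect_true(all(diff(lod_from_wald(w)) > 0))
  expect_error(lod_from_wald(-1))
})

test_that("effective test counts collapse duplicated markers", {
  # scores uncorrelated after centring: M_eff equals the marker count
  set.seed(71)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(56), 8, 7))))[, 2:5] * 2
  info <- tibble::tibble(marker = paste0("m", 1:4), chromosome = "C1",
                         position = 1:4, type = "terminal",
                         flank_left = NA, flank_right = NA)
  M <- structure(X, dimnames = list(paste0("L", 1:8), info$marker),
                 info = info, class = c("interval_markers", "matrix", "array"))
  thr <- li_ji_threshold(M, alpha = 0.05)
  expect_equal(thr$m_eff, 4, tolerance = 1e-8)

  # every marker duplicated once: M_eff halves
  X2 <- cbind(X, X)
  info2 <- tibble::tibble(marker = paste0("m", 1:8), chromosome = "C1",
                          position = 1:8, type = "terminal",
                          flank_left = NA, flank_right = NA)
  M2 <- structure(X2, dimnames = list(paste0("L", 1:8), info2$marker),
                  info = info2, class = c("interval_markers", "matrix", "array"))
  thr2 <- li_ji_threshold(M2, alpha = 0.05)
  expect_equal(thr2$m_eff, 4, tolerance = 1e-8)

  # per-test level is the Sidak adjustment at M_eff
  expect_equal(thr$per_test_alpha, 1 - 0.95^(1 / thr$m_eff))
  expect_equal(thr$wald_threshold,
               qchisq(thr$per_test_alpha, 1, lower.tail = FALSE))
})

test_that("linked-map thresholds sit between the two Sidak extremes and match
           a dense eigendecomposition oracle", {
  trial <- make_small_trial(n_lines = 60, n_chr = 3, m_per_chr = 10, seed = 72)
  thr <- li_ji_threshold(trial$M, alpha = 0.05)
  info <- marker_info(trial$M)
  p <- ncol(trial$M)
  expect_gt(thr$m_eff, 3)        # more than one test per chromosome
  expect_lt(thr$m_eff, p)        # fewer than the raw marker count
  # oracle: direct eigendecomposition per chromosome, formula re-derived
  m_eff_oracle <- sum(vapply(unique(info$chromosome), function(ch) {
    lam <- eigen(cor(unclass(trial$M)[, info$chromosome == ch]),
                 symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
  }, numeric(1)))
  expect_equal(thr$m_eff, m_eff_oracle, tolerance = 1e-10)
})

test_that("pruning keeps the strongest marker per 30 cM window", {
  sc <- tibble::tibble(
    marker = paste0("m", 1:5), chromosome = c("C1", "C1", "C1", "C2", "C2"),
    position = c(10, 20, 60, 5, 45), kind = "performance",
    covariate = NA_character_, effect = 1, se = 1,
    wald = c(15, 20, 18, 12, 12), p_value = 0.001, untestable = FALSE)
  sel <- prune_30cM(sc, threshold = 9)
  # 10 and 20 within 30 cM: keep the larger (20 cM, wald 20); 60 kept;
  # C2 at 5 and 45 are 40 cM apart: both kept
  expect_setequal(sel$marker, c("m2", "m3", "m4", "m5"))

  # 40 cM apart on one chromosome: both kept
  sc2 <- sc[sc$marker %in% c("m1", "m3"), ]
  expect_equal(nrow(prune_30cM(sc2, 9)), 2)

  # equal Wald 10 cM apart: lower position wins
  sc3 <- tibble::tibble(marker = c("a", "b"), chromosome = "C1",
                        position = c(12, 22), kind = "performance",
                        covariate = NA_character_, effect = 1, se = 1,
                        wald = c(15, 15), p_value = 0.001, untestable = FALSE)
  expect_equal(prune_30cM(sc3, 9)$marker, "a")

  # idempotent and order-independent
  sel_again <- prune_30cM(sel, 9)
  expect_equal(sel_again$marker, sel$marker)
  shuffled <- sc[c(4, 2, 5, 1, 3), ]
  expect_equal(sort(prune_30cM(shuffled, 9)$marker), sort(sel$marker))

  # below-threshold scan selects nothing
  expect_equal(nrow(prune_30cM(sc, 50)), 0)
})

test_that("a planted performance QTL is located with its sign and size", {
  a <- 0.45
  trial <- make_small_trial(n_lines = 150, n_chr = 2, m_per_chr = 12,
                            qtl = qtl_spec("C1M6", "performance", a), seed = 73)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  sc <- scan_performance(spec, trial$M, tol = 1e-5, maxit = 40)
  thr <- li_ji_threshold(trial$M)
  top <- sc[which.max(sc$wald), ]
  planted <- trial$map$position[trial$map$marker == "C1M6"]
  expect_equal(top$chromosome, "C1")
  expect_lt(abs(top$position - planted), 15)
  expect_gt(top$wald, thr$wald_threshold)
  expect_gt(top$effect, 0)
  expect_equal(top$effect, a, tolerance = 0.35)
  # Wald consistency: (effect / se)^2
  expect_equal(sc$wald, (sc$effect / sc$se)^2, tolerance = 1e-8)
})

test_that("monomorphic markers are flagged untestable, not dropped", {
  trial <- make_small_trial(n_lines = 50, n_chr = 2, m_per_chr = 8, seed = 74)
  Mu <- unclass(trial$M)
  Mu[, 3] <- 1  # force monomorphic
  M2 <- structure(Mu, info = marker_info(trial$M),
                  class = class(trial$M))
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  sc <- scan_performance(spec, M2, tol = 1e-4, maxit = 20)
  expect_true(sc$untestable[3])
  expect_true(is.na(sc$wald[3]))
  expect_equal(nrow(sc), ncol(M2))
})

test_that("responsiveness effects are recovered per covariate unit and scale
           inversely under covariate rescaling", {
  b <- 0.12
  lines <- sprintf("L%03d", 1:120)
  cov <- make_test_covariate(lines, seed = 75)
  trial <- make_small_trial(n_lines = 120, n_chr = 2, m_per_chr = 10,
                            qtl = qtl_spec("C2M5", "responsiveness", b, "cvx"),
                            covariates = cov, seed = 76)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  sc <- scan_responsiveness(spec, trial$M, cov, "cvx", tol = 1e-5, maxit = 40)
  top <- sc[which.max(sc$wald), ]
  planted <- trial$map$position[trial$map$marker == "C2M5"]
  expect_equal(top$chromosome, "C2")
  expect_lt(abs(top$position - planted), 15)
  expect_equal(top$effect, b, tolerance = 0.3)

  # rescaling c -> 3c divides b by 3; the normalised effect is invariant
  cov3 <- cov; cov3$value <- 3 * cov$value
  sc3 <- scan_responsiveness(spec, trial$M, cov3, "cvx", tol = 1e-5, maxit = 40)
  expect_equal(sc3$effect, sc$effect / 3, tolerance = 1e-5)
  expect_equal(sc3$effect * attr(sc3, "covariate_range"),
               sc$effect * attr(sc, "covariate_range"), tolerance = 1e-4)

  # constant covariate is refused
  cov0 <- cov; cov0$value <- 5
  expect_error(scan_responsiveness(spec, trial$M, cov0, "cvx"), "constant")
})

test_that("permuting covariate line labels destroys line-level signal", {
  # anomaly-style covariate (no environment-mean differences) so the
  # planted interaction acts only through line-level covariate variation
  b <- 0.3
  lines <- sprintf("L%03d", 1:120)
  cov <- make_test_covariate(lines, env_levels = c(0, 0, 0),
                             sd_within = 2, seed = 77)
  trial <- make_small_trial(n_lines = 120, n_chr = 2, m_per_chr = 10,
                            qtl = qtl_spec("C2M5", "responsiveness", b, "cvx"),
                            covariates = cov, seed = 78)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  sc <- scan_responsiveness(spec, trial$M, cov, "cvx", tol = 1e-5, maxit = 40)
  thr <- li_ji_threshold(trial$M)
  expect_gt(max(sc$wald, na.rm = TRUE), thr$wald_threshold)
  # permute line labels of the covariate: the signal must collapse
  covp <- withr::with_seed(79, cov |>
    dplyr::group_by(env) |>
    dplyr::mutate(value = value[sample.int(dplyr::n())]) |>
    dplyr::ungroup())
  scp <- scan_responsiveness(spec, trial$M, covp, "cvx", tol = 1e-5, maxit = 40)
  expect_lt(max(scp$wald, na.rm = TRUE), 0.2 * max(sc$wald, na.rm = TRUE))
})

test_that("the joint final model reproduces single-marker estimates and
           excludes selection windows from the relationship matrix", {
  a <- 0.5
  trial <- make_small_trial(n_lines = 150, n_chr = 2, m_per_chr = 12,
                            qtl = qtl_spec("C1M6", "performance", a), seed = 80)
  spec <- build_design(trial$obs, random_row = FALSE, random_col = FALSE)
  sc <- scan_performance(spec, trial$M, tol = 1e-5, maxit = 40)
  thr <- li_ji_threshold(trial$M)
  sel <- prune_30cM(sc, thr)
  expect_gte(nrow(sel), 1)
  rec <- fit_final_model(spec, sel, trial$M, trait = "yield",
                         population = "TST",
                         parents = c(A = "Mace", B = "Gladius"),
                         tol = 1e-5, maxit = 40)
  expect_equal(nrow(rec), nrow(sel))
  i <- which.max(rec$wald)
  # n_s = 1-style consistency at the top locus
  expect_equal(rec$effect[i], sel$effect[i], tolerance = 0.35)
  expect_equal(rec$lod, lod_from_wald(rec$wald))
  expect_true(all(rec$positive_allele_source %in% c("Mace", "Gladius")))
  expect_true(all(is.na(rec$normalised_effect)))

  # exclusion windows: G_{-s} drops exactly the in-window markers
  info <- marker_info(trial$M)
  wins <- tibble::tibble(chromosome = sel$chromosome, position = sel$position,
                         half_width = 30)
  Gs <- compute_grm(trial$M, exclude_windows = wins)
  manual <- rep(TRUE, ncol(trial$M))
  for (w in seq_len(nrow(wins)))
    manual <- manual & !(info$chromosome == wins$chromosome[w] &
                           abs(info$position - wins$position[w]) <= 30)
  expect_equal(attr(Gs, "n_markers"), sum(manual))
})

test_that("normalisation multiplies effects by the covariate range", {
  rec <- tibble::tibble(name = "q", trait = "t", population = "p",
                        type = "responsiveness", covariate = "cvx",
                        chromosome = "C1", position = 5, effect = 0.1,
                        se = 0.02, normalised_effect = NA_real_, wald = 25,
                        p_value = 1e-6, lod = 5.4,
                        positive_allele_source = "A")
  out <- normalise_effect(rec, 3.5)
  expect_equal(out$normalised_effect, 0.35)
  expect_equal(sign(out$normalised_effect), sign(out$effect))
  rec$type <- "performance"
  expect_error(normalise_effect(rec, 3.5), "responsiveness")
})
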