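# exhaustive-enumeration oracle: joint distribution of a three-locus DH
# haplotype under the two-state Markov chain, conditioned on the flanks
enumerate_impute <- function(xl, xr, theta_l, theta_r) {
  states <- c(-1, 1)
  trans <- function(a, b, th) if (a == b) 1 - th else th
  num <- 0; den <- 0
  for (m in states) {
    p <- 0.5 * trans(xl, m, theta_l) * trans(m, xr, theta_r)
    num <- num + m * p
    den <- den + p
  }
  num / den
}

inv_haldane <- function(theta) -50 * log(1 - 2 * theta)

test_that("imputation matches the gamete-enumeration oracle", {
  d <- inv_haldane(0.1)
  map <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c"), chromosome = "C1", position = c(0, d, 2 * d)))
  g <- matrix(c(1, NA, 1), 1, 3, dimnames = list("L1", map$marker))
  out <- impute_missing(g, map)
  expect_equal(out[1, 2], enumerate_impute(1, 1, 0.1, 0.1), tolerance = 1e-12)

  g2 <- matrix(c(1, NA, -1), 1, 3, dimnames = list("L1", map$marker))
  expect_equal(impute_missing(g2, map)[1, 2],
               enumerate_impute(1, -1, 0.1, 0.1), tolerance = 1e-12)

  # asymmetric distances
  d2 <- inv_haldane(0.25)
  map3 <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c"), chromosome = "C1", position = c(0, d, d + d2)))
  g3 <- matrix(c(-1, NA, 1), 1, 3, dimnames = list("L1", map3$marker))
  expect_equal(impute_missing(g3, map3)[1, 2],
               enumerate_impute(-1, 1, 0.1, 0.25), tolerance = 1e-12)
})

test_that("imputation limiting cases behave", {
  map <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c"), chromosome = "C1", position = c(0, 0, 0)))
  g <- matrix(c(1, NA, 1), 1, 3, dimnames = list("L1", map$marker))
  expect_equal(impute_missing(g, map)[1, 2], 1)  # zero recombination

  # symmetric opposite flanks -> 0
  map2 <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c"), chromosome = "C1", position = c(0, 10, 20)))
  g2 <- matrix(c(1, NA, -1), 1, 3, dimnames = list("L1", map2$marker))
  expect_equal(impute_missing(g2, map2)[1, 2], 0, tolerance = 1e-12)

  # single flank: x * (1 - 2 theta)
  g3 <- matrix(c(1, NA, NA), 1, 3, dimnames = list("L1", map2$marker))
  out <- impute_missing(g3, map2)
  expect_equal(out[1, 2], 1 - 2 * haldane(10), tolerance = 1e-12)
  expect_equal(out[1, 3], 1 - 2 * haldane(20), tolerance = 1e-12)

  # no missing data: identity
  g4 <- matrix(c(1, -1, 1), 1, 3, dimnames = list("L1", map2$marker))
  expect_identical(impute_missing(g4, map2), g4)

  # fully missing chromosome for a line is an error
  g5 <- matrix(NA_real_, 1, 3, dimnames = list("L1", map2$marker))
  expect_error(impute_missing(g5, map2), "no observed marker")
})

test_that("imputed values stay in [-1, 1] and shrink with distance", {
  thetas <- c(0.01, 0.1, 0.3, 0.45, 0.49)
  vals <- vapply(thetas, function(th) {
    d <- inv_haldane(th)
    map <- climqtl:::new_linkage_map(tibble::tibble(
      marker = c("a", "b"), chromosome = "C1", position = c(0, d)))
    g <- matrix(c(1, NA), 1, 2, dimnames = list("L1", map$marker))
    impute_missing(g, map)[1, 2]
  }, numeric(1))
  expect_true(all(vals >= -1 & vals <= 1))
  expect_true(all(diff(vals) < 0))   # weaker linkage, more shrinkage
  expect_lt(vals[length(vals)], 0.05)
})

test_that("collapsing keeps only co-segregating co-located duplicates", {
  map <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c", "d"), chromosome = "C1",
    position = c(0, 0, 0, 10)))
  g <- cbind(a = c(1, -1, 1), b = c(1, -1, 1), c = c(-1, -1, 1),
             d = c(1, 1, -1))
  rownames(g) <- sprintf("L%d", 1:3)
  out <- collapse_unique(g, map)
  expect_equal(out$map$marker, c("a", "c", "d"))  # b collapsed into a
  expect_equal(ncol(out$genotypes), 3)
  # idempotent
  out2 <- collapse_unique(out$genotypes, out$map)
  expect_equal(out2$map$marker, out$map$marker)
})

test_that("interval markers are flank means at midpoints plus terminals", {
  map <- climqtl:::new_linkage_map(tibble::tibble(
    marker = c("a", "b", "c"), chromosome = "C1", position = c(0, 10, 30)))
  g <- cbind(a = c(1, 1, -1), b = c(1, -1, -1), c = c(-1, -1, -1))
  rownames(g) <- sprintf("L%d", 1:3)
  M <- make_interval_markers(g, map)
  info <- marker_info(M)
  expect_equal(sum(info$type == "interval"), 2)
  expect_equal(sum(info$type == "terminal"), 2)
  iv <- which(info$type == "interval")
  expect_equal(info$position[iv], c(5, 20))
  expect_equal(unname(M[, info$marker[iv][1]]), c(1, 0, -1))
  expect_true(all(M >= -1 & M <= 1))
  expect_false(anyNA(M))

  # single-marker chromosome passes through
  map1 <- climqtl:::new_linkage_map(tibble::tibble(
    marker = "z", chromosome = "C9", position = 4))
  g1 <- matrix(c(1, -1, 1), 3, 1, dimnames = list(rownames(g), "z"))
  M1 <- make_interval_markers(g1, map1)
  expect_equal(ncol(M1), 1)
  expect_equal(marker_info(M1)$type, "terminal")
})

test_that("interval column count is u - 1 intervals plus terminals", {
  trial <- make_small_trial(n_lines = 40, n_chr = 3, m_per_chr = 9, seed = 21)
  info <- marker_info(trial$M)
  per_chr <- table(info$chromosome, info$type)
  expect_true(all(per_chr[, "interval"] == 8))
  expect_true(all(per_chr[, "terminal"] == 2))
})

test_that("GRM equals brute-force outer-product summation", {
  trial <- make_small_trial(n_lines = 25, n_chr = 2, m_per_chr = 6, seed = 31)
  M <- trial$M
  info <- marker_info(M)
  G <- compute_grm(M, exclude_chromosome = "C1")
  keep <- which(info$chromosome != "C1")
  brute <- matrix(0, nrow(M), nrow(M))
  for (j in keep) brute <- brute + outer(unclass(M)[, j], unclass(M)[, j])
  expect_equal(unclass(G), brute, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(G, "n_markers"), length(keep))

  # window exclusion leaves exactly the markers outside the window
  w <- tibble::tibble(chromosome = "C2", position = 50, half_width = 30)
  Gw <- compute_grm(M, exclude_windows = w)
  kept <- sum(!(info$chromosome == "C2" & abs(info$position - 50) <= 30))
  expect_equal(attr(Gw, "n_markers"), kept)
  expect_error(compute_grm(M, exclude_windows = tibble::tibble(
    chromosome = c("C1", "C2"), position = 50, half_width = 1e6)))

  # PSD: smallest eigenvalue bounded below relative to trace
  ev <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10 * sum(diag(G)))
})
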