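#' Simulate a doubled-haploid population on a linkage map
#'
#' Each line is a doubled gamete from the F1 of two fully informative
#' inbreds: along every chromosome the allele score follows a two-state
#' Markov chain over \{+1, -1\}, switching between adjacent markers with
#' probability equal to the Haldane recombination fraction
#' \eqn{\theta(d) = (1 - e^{-2d/100})/2} for map distance d cM. Chromosomes
#' segregate independently and lines are homozygous throughout (no
#' heterozygous states), as in DH material.
#'
#' @param map A `linkage_map`.
#' @param n_lines Number of DH lines (>= 2).
#' @param seed Integer seed.
#' @return A numeric matrix, lines x markers, entries in \{+1, -1\}, with
#'   line ids as rownames and marker names as colnames.
#' @export
simulate_dh_population <- function(map, n_lines, seed) {
  validate_linkage_map(map)
  if (nrow(map) == 0L) stop("empty map", call. = FALSE)
  stopifnot(n_lines >= 2)
  withr_seed(seed, {
    geno <- matrix(NA_real_, n_lines, nrow(map),
                   dimnames = list(sprintf("L%03d", seq_len(n_lines)),
                                   map$marker))
    for (ch in levels(map$chromosome)) {
      idx <- which(map$chromosome == ch)
      pos <- map$position[idx]
      theta <- haldane(diff(pos))
      x <- matrix(NA_real_, n_lines, length(idx))
      x[, 1] <- sample(c(-1, 1), n_lines, replace = TRUE)
      if (length(idx) > 1L) {
        for (k in seq_along(theta)) {
          switch_ <- stats::runif(n_lines) < theta[k]
          x[, k + 1] <- ifelse(switch_, -x[, k], x[, k])
        }
      }
      geno[, idx] <- x
    }
    geno
  })
}

#' Haldane map function
#'
#' Recombination fraction for a map distance under no interference:
#' \eqn{\theta(d) = (1 - e^{-2d/100})/2} with d in cM.
#'
#' @param d Map distance in cM (vectorised).
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' Numerically encode biparental allele calls
#'
#' Maps the first parent's allele (`A`) to +1 and the second parent's (`B`)
#' to -1; missing calls stay missing. Any other symbol is an error reporting
#' its position.
#'
#' @param raw_calls Character matrix (lines x markers) with entries `"A"`,
#'   `"B"` or `NA`.
#' @return Numeric matrix of the same shape with entries +1, -1, `NA`.
#' @export
#' @examples
#' encode_alleles(matrix(c("A", "B", "B", "A"), 2, 2))
encode_alleles <- function(raw_calls) {
  stopifnot(is.matrix(raw_calls))
  bad <- !(raw_calls %in% c("A", "B")) & !is.na(raw_calls)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid allele call '%s' at row %d, column %d",
                 raw_calls[bad][1], w[1], w[2]), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(raw_calls), ncol(raw_calls),
                dimnames = dimnames(raw_calls))
  out[raw_calls == "A"] <- 1
  out[raw_calls == "B"] <- -1
  out
}

#' Write / read genotype calls as delimited text
#'
#' Alleles are stored as `A`/`B`/`NA` with line ids in the first column and
#' marker names as the header, so files are readable alongside the map.
#'
#' @param genotypes Numeric genotype matrix (+1/-1/NA).
#' @param path File path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns the encoded numeric matrix.
#' @export
write_genotypes <- function(genotypes, path) {
  ab <- matrix(NA_character_, nrow(genotypes), ncol(genotypes),
               dimnames = dimnames(genotypes))
  ab[genotypes == 1] <- "A"
  ab[genotypes == -1] <- "B"
  df <- tibble::as_tibble(ab)
  df <- dplyr::bind_cols(tibble::tibble(line = rownames(genotypes)), df)
  readr::write_csv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  encode_alleles(m)
}
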