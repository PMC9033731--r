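#' Impute missing DH marker scores from flanking markers
#'
#' Replaces each missing score by its conditional expectation given the
#' nearest observed flanking markers on the same chromosome, under the
#' two-state no-interference DH Markov chain with Haldane recombination
#' fractions taken from the map. With observed flanks \eqn{x_L, x_R} and
#' recombination fractions \eqn{\theta_L, \theta_R} from each flank to the
#' missing locus, the posterior over the \{+1, -1\} state is proportional to
#' the product of the two transition probabilities; with a single observed
#' flank the expectation collapses to \eqn{x (1 - 2\theta)}. Imputed values
#' therefore lie in \[-1, +1\] and shrink towards 0 as linkage weakens.
#'
#' @param genotypes Numeric genotype matrix (+1/-1/NA), lines x markers.
#' @param map The `linkage_map` aligned to the columns of `genotypes`.
#' @return A complete genotype matrix (no missing entries).
#' @export
impute_missing <- function(genotypes, map) {
  validate_linkage_map(map)
  stopifnot(ncol(genotypes) == nrow(map))
  out <- genotypes
  for (ch in levels(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position[idx]
    sub <- genotypes[, idx, drop = FALSE]
    miss_lines <- which(rowSums(is.na(sub)) > 0L)
    for (i in miss_lines) {
      x <- sub[i, ]
      obs <- which(!is.na(x))
      if (length(obs) == 0L)
        stop(sprintf("line %s has no observed marker on chromosome %s",
                     rownames(genotypes)[i] %||% i, ch), call. = FALSE)
      for (j in which(is.na(x))) {
        left <- obs[obs < j]
        right <- obs[obs > j]
        l <- if (length(left)) max(left) else NA_integer_
        r <- if (length(right)) min(right) else NA_integer_
        out[i, idx[j]] <- impute_one(
          xl = if (is.na(l)) NA else x[l],
          xr = if (is.na(r)) NA else x[r],
          tl = if (is.na(l)) NA else haldane(pos[j] - pos[l]),
          tr = if (is.na(r)) NA else haldane(pos[r] - pos[j])
        )
      }
    }
  }
  out
}

# conditional expectation of a +1/-1 DH locus given flank scores and
# recombination fractions; one-sided when a flank is absent
impute_one <- function(xl, xr, tl, tr) {
  if (is.na(xl) && is.na(xr)) stop("no flank available", call. = FALSE)
  if (is.na(xl)) return(xr * (1 - 2 * tr))
  if (is.na(xr)) return(xl * (1 - 2 * tl))
  pl <- function(s) if (s == xl) 1 - tl else tl
  pr <- function(s) if (s == xr) 1 - tr else tr
  num <- pl(1) * pr(1) - pl(-1) * pr(-1)
  den <- pl(1) * pr(1) + pl(-1) * pr(-1)
  num / den
}

#' Collapse co-segregating co-located markers to unique positions
#'
#' Markers that share a map position and have identical score vectors carry
#' no extra information for scanning; they are collapsed to a single
#' representative (the first by map order). Co-located markers whose score
#' vectors differ are all retained. The operation is idempotent.
#'
#' @param genotypes Complete genotype matrix.
#' @param map Aligned `linkage_map`.
#' @return A list with elements `genotypes`, `map` (the collapsed pair) and
#'   `summary` (the [compute_map_summary()] of the input).
#' @export
collapse_unique <- function(genotypes, map) {
  validate_linkage_map(map)
  stopifnot(ncol(genotypes) == nrow(map), !anyNA(genotypes))
  key <- paste(map$chromosome, map$position,
               apply(genotypes, 2, paste, collapse = ""), sep = "|")
  keep <- !duplicated(key)
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    map = new_linkage_map(map[keep, , drop = FALSE]),
    summary = compute_map_summary(map, genotypes)
  )
}

#' Build the interval-marker matrix used for genome scans
#'
#' For every interval between adjacent unique positions on a chromosome a
#' pseudo-marker is formed as the mean of its two flanking marker scores,
#' positioned at the interval midpoint; chromosome-terminal markers are
#' carried through unchanged as their own scan columns so chromosome ends
#' remain scannable. A single-marker chromosome is passed through with no
#' interval. Scores lie in \[-1, +1\] and the matrix is complete.
#'
#' @param genotypes Complete, collapsed genotype matrix.
#' @param map Aligned collapsed `linkage_map`.
#' @return A matrix of class `interval_markers`, lines x interval markers,
#'   with an `info` attribute tibble (`marker`, `chromosome`, `position`,
#'   `type` = interval/terminal, `flank_left`, `flank_right`).
#' @export
make_interval_markers <- function(genotypes, map) {
  validate_linkage_map(map)
  stopifnot(ncol(genotypes) == nrow(map), !anyNA(genotypes))
  cols <- list(); info <- list()
  for (ch in levels(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position[idx]
    nm <- map$marker[idx]
    u <- length(idx)
    if (u == 1L) {
      cols[[length(cols) + 1L]] <- genotypes[, idx, drop = FALSE]
      info[[length(info) + 1L]] <- tibble::tibble(
        marker = nm, chromosome = ch, position = pos,
        type = "terminal", flank_left = nm, flank_right = nm)
      next
    }
    term <- c(1L, u)
    cols[[length(cols) + 1L]] <- genotypes[, idx[term], drop = FALSE]
    info[[length(info) + 1L]] <- tibble::tibble(
      marker = nm[term], chromosome = ch, position = pos[term],
      type = "terminal", flank_left = nm[term], flank_right = nm[term])
    left <- seq_len(u - 1L)
    iv <- (genotypes[, idx[left], drop = FALSE] +
             genotypes[, idx[left + 1L], drop = FALSE]) / 2
    colnames(iv) <- sprintf("%s:%s", nm[left], nm[left + 1L])
    cols[[length(cols) + 1L]] <- iv
    info[[length(info) + 1L]] <- tibble::tibble(
      marker = colnames(iv), chromosome = ch,
      position = (pos[left] + pos[left + 1L]) / 2,
      type = "interval", flank_left = nm[left], flank_right = nm[left + 1L])
  }
  M <- do.call(cbind, cols)
  inf <- dplyr::bind_rows(info)
  ord <- order(factor(inf$chromosome, levels = levels(map$chromosome)),
               inf$position)
  M <- M[, ord, drop = FALSE]
  inf <- inf[ord, ]
  colnames(M) <- inf$marker
  structure(M, info = inf, class = c("interval_markers", "matrix", "array"))
}

#' Interval-marker column metadata
#'
#' @param M An `interval_markers` matrix.
#' @return The `info` tibble attached by [make_interval_markers()].
#' @export
marker_info <- function(M) attr(M, "info")

#' Genomic relationship matrix with leave-one-chromosome-out exclusion
#'
#' Computes \eqn{G = M M^T} over the retained interval markers. Exclusions
#' support the two uses in a genome scan: dropping a whole chromosome
#' (\eqn{G_{-i}}, to avoid proximal contamination when scanning chromosome
#' i) and dropping all markers within a cM window of selected markers
#' (\eqn{G_{-s}}, for the final multi-QTL model). No division by marker
#' count is applied; the additive variance component absorbs the scale.
#'
#' @param M An `interval_markers` matrix.
#' @param exclude_chromosome Optional chromosome label to drop.
#' @param exclude_windows Optional tibble/data frame with columns
#'   `chromosome`, `position`, `half_width` (cM): markers on the named
#'   chromosome within `half_width` of `position` are dropped.
#' @return A symmetric positive semi-definite matrix with attribute
#'   `provenance` describing the exclusions and `n_markers` retained.
#' @export
compute_grm <- function(M, exclude_chromosome = NULL, exclude_windows = NULL) {
  info <- marker_info(M)
  keep <- rep(TRUE, ncol(M))
  prov <- "all markers"
  if (!is.null(exclude_chromosome)) {
    keep <- keep & info$chromosome != exclude_chromosome
    prov <- sprintf("excluded chromosome %s", exclude_chromosome)
  }
  if (!is.null(exclude_windows) && nrow(exclude_windows) > 0L) {
    for (w in seq_len(nrow(exclude_windows))) {
      keep <- keep & !(info$chromosome == exclude_windows$chromosome[w] &
                         abs(info$position - exclude_windows$position[w]) <=
                           exclude_windows$half_width[w])
    }
    prov <- paste(prov, sprintf("excluded %d cM-windows", nrow(exclude_windows)),
                  sep = "; ")
  }
  if (!any(keep)) stop("exclusion leaves no markers", call. = FALSE)
  Mk <- unclass(M)[, keep, drop = FALSE]
  G <- tcrossprod(Mk)
  structure(G, provenance = prov, n_markers = sum(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
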