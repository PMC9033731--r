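#' Simulate a linkage map
#'
#' Generates a biparental-style linkage map with markers placed at sorted
#' uniform positions along each chromosome. Scale defaults elsewhere in the
#' package are anchored to dense wheat DH maps (thousands of markers over
#' roughly 3000 cM across 21 chromosomes).
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param markers_per_chromosome Markers on each chromosome (>= 1).
#' @param chromosome_length Genetic length of each chromosome in cM (> 0).
#' @param seed Integer seed; the map is deterministic given the seed.
#'
#' @return A tibble of class `linkage_map` with columns `marker`,
#'   `chromosome` (factor, ordered as generated) and `position` (cM).
#' @export
#' @examples
#' simulate_linkage_map(3, 10, 120, seed = 1)
simulate_linkage_map <- function(n_chromosomes, markers_per_chromosome,
                                 chromosome_length, seed) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chromosome_length > 0)
  map <- withr_seed(seed, {
    purrr::map_dfr(seq_len(n_chromosomes), function(ch) {
      pos <- sort(stats::runif(markers_per_chromosome, 0, chromosome_length))
      tibble::tibble(
        marker = sprintf("C%dM%d", ch, seq_len(markers_per_chromosome)),
        chromosome = sprintf("C%d", ch),
        position = pos
      )
    })
  })
  new_linkage_map(map)
}

new_linkage_map <- function(map) {
  map$chromosome <- factor(map$chromosome, levels = unique(map$chromosome))
  validate_linkage_map(map)
  class(map) <- c("linkage_map", class(tibble::tibble()))
  map
}

validate_linkage_map <- function(map) {
  stopifnot(all(c("marker", "chromosome", "position") %in% names(map)))
  if (anyDuplicated(map$marker) > 0L)
    stop("marker names must be unique", call. = FALSE)
  if (any(map$position < 0)) stop("positions must be non-negative", call. = FALSE)
  ok <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(sorted = !is.unsorted(.data$position), n = dplyr::n())
  if (!all(ok$sorted))
    stop("positions must be non-decreasing within a chromosome", call. = FALSE)
  if (!all(ok$n >= 1L)) stop("every chromosome needs a marker", call. = FALSE)
  invisible(map)
}

#' Summarise a linkage map the way mapping studies report them
#'
#' Computes, over unique map positions, the marker count, unique-position
#' count, total genetic length (sum of per-chromosome spans) and the mean
#' interval between unique positions (length / unique-position count,
#' reported to one decimal). When a genotype matrix is supplied, "unique"
#' means unique on both position and marker score vector, i.e. co-located
#' markers are only merged when they co-segregate.
#'
#' @param map A `linkage_map`.
#' @param genotypes Optional genotype matrix aligned to `map` (see
#'   [encode_alleles()]); used to distinguish co-located markers that do not
#'   co-segregate.
#' @return A one-row tibble: `n_markers`, `n_unique`, `length_cM`,
#'   `mean_interval`.
#' @export
compute_map_summary <- function(map, genotypes = NULL) {
  validate_linkage_map(map)
  if (nrow(map) == 0L) stop("empty map", call. = FALSE)
  spans <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(span = max(.data$position) - min(.data$position))
  len <- sum(spans$span)
  if (is.null(genotypes)) {
    uniq <- map |>
      dplyr::distinct(.data$chromosome, .data$position) |>
      nrow()
  } else {
    stopifnot(ncol(genotypes) == nrow(map))
    key <- paste(map$chromosome, map$position,
                 apply(genotypes, 2, paste, collapse = ""), sep = "|")
    uniq <- length(unique(key))
  }
  tibble::tibble(
    n_markers = nrow(map),
    n_unique = uniq,
    length_cM = len,
    mean_interval = round(len / uniq, 1)
  )
}

#' Mean interval between unique map positions from printed map figures
#'
#' The one-line arithmetic used in published map summary tables: total
#' genetic length divided by the number of unique positions, to one decimal.
#'
#' @param length_cM Total genetic length (cM).
#' @param n_unique Number of unique map positions.
#' @return Mean interval in cM, rounded to one decimal.
#' @export
#' @examples
#' mean_interval_cM(3009, 1429) # 2.1
mean_interval_cM <- function(length_cM, n_unique) {
  stopifnot(length_cM >= 0, n_unique >= 1)
  round(length_cM / n_unique, 1)
}

#' Published linkage-map summary figures
#'
#' Marker counts, unique-position counts and genetic lengths of the five
#' biparental DH population maps from the heat-adaptation study this
#' package emulates, as printed in its map summary table, together with
#' the one-decimal mean interval each pair of figures implies.
#'
#' @return A tibble with columns `population`, `n_lines`, `n_markers`,
#'   `n_unique`, `length_cM`, `mean_interval`.
#' @export
#' @examples
#' published_map_summaries()
published_map_summaries <- function() {
  tibble::tribble(
    ~population, ~n_lines, ~n_markers, ~n_unique, ~length_cM, ~mean_interval,
    "MG",  176L, 5047L, 1429L, 3009, 2.1,
    "SM",  226L, 4950L, 1360L, 3030, 2.2,
    "SG",  369L, 5143L, 1761L, 2998, 1.7,
    "RG",  132L, 5133L, 1183L, 3055, 2.6,
    "L2G", 124L, 5514L, 1132L, 3144, 2.8)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("Linkage map: %d markers on %d chromosomes, %.0f cM total\n",
              nrow(x), dplyr::n_distinct(x$chromosome),
              sum(tapply(x$position, x$chromosome, function(p) max(p) - min(p)))))
  NextMethod()
}

#' Write / read a linkage map as delimited text
#'
#' Plain-text round-trip format: columns `marker`, `chromosome`,
#' `position_cM`, comma separated.
#'
#' @param map A `linkage_map`.
#' @param path File path.
#' @return `write_linkage_map()` returns `path` invisibly;
#'   `read_linkage_map()` returns a `linkage_map`.
#' @export
write_linkage_map <- function(map, path) {
  validate_linkage_map(map)
  out <- tibble::tibble(marker = map$marker,
                        chromosome = as.character(map$chromosome),
                        position_cM = map$position)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_linkage_map
#' @export
read_linkage_map <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  new_linkage_map(tibble::tibble(marker = raw$marker,
                                 chromosome = raw$chromosome,
                                 position = raw$position_cM))
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
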