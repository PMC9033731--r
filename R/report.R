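# Clustering of QTL into loci and their classification on the
# performance x responsiveness adaptation framework.

#' Cluster QTL within a linkage window
#'
#' Single-linkage clustering per chromosome: two QTL join the same cluster
#' when their positions are within `window` cM, and membership chains
#' (records at 0, 9 and 18 cM form one cluster under a 10 cM window).
#' Membership is invariant to record input order.
#'
#' @param records A `qtl_records` tibble (any mix of traits and types).
#' @param window Linkage window in cM (default 10).
#' @return A tibble of class `qtl_clusters`: `cluster`, `chromosome`,
#'   `position_min`, `position_max`, `span`, `n_members`, `members`
#'   (list-column holding the member records).
#' @export
cluster_qtl <- function(records, window = 10) {
  if (nrow(records) == 0L) {
    out <- tibble::tibble(cluster = character(), chromosome = character(),
                          position_min = numeric(), position_max = numeric(),
                          span = numeric(), n_members = integer(),
                          members = list())
    class(out) <- c("qtl_clusters", class(tibble::tibble()))
    return(out)
  }
  rec <- records[order(records$chromosome, records$position), ]
  out <- rec |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(d, key) {
      gap <- c(0, diff(d$position))
      grp <- cumsum(gap > window)
      purrr::map_dfr(unique(grp), function(g) {
        m <- d[grp == g, ]
        tibble::tibble(position_min = min(m$position),
                       position_max = max(m$position),
                       span = max(m$position) - min(m$position),
                       n_members = nrow(m), members = list(m))
      })
    }) |>
    dplyr::ungroup()
  out$cluster <- sprintf("%s@%.1f", out$chromosome, out$position_min)
  out <- out[, c("cluster", "chromosome", "position_min", "position_max",
                 "span", "n_members", "members")]
  class(out) <- c("qtl_clusters", class(tibble::tibble()))
  out
}

#' Flag clusters co-located with anthesis-date QTL
#'
#' A cluster is flagged when any member lies within `window` cM of an
#' anthesis-date QTL on the same chromosome; loci for heat adaptation that
#' are free of such flags can be selected without shifting flowering time.
#'
#' @param clusters A `qtl_clusters` tibble.
#' @param anthesis_qtl A `qtl_records` tibble of anthesis-date QTL (from a
#'   performance scan on the anthesis-date trait).
#' @param window Co-location window in cM (default 10).
#' @return `clusters` with logical column `anthesis_associated` added, plus
#'   attribute `n_anthesis_independent` (count of member QTL in unflagged
#'   clusters).
#' @export
flag_anthesis_association <- function(clusters, anthesis_qtl, window = 10) {
  flag <- purrr::map_lgl(seq_len(nrow(clusters)), function(i) {
    aq <- anthesis_qtl[anthesis_qtl$chromosome == clusters$chromosome[i], ]
    if (nrow(aq) == 0L) return(FALSE)
    m <- clusters$members[[i]]
    any(outer(m$position, aq$position, function(a, b) abs(a - b) <= window))
  })
  clusters$anthesis_associated <- flag
  attr(clusters, "n_anthesis_independent") <-
    sum(clusters$n_members[!flag])
  clusters
}

#' Classify clusters on the performance x responsiveness framework
#'
#' For each cluster and trait, the performance axis (high / neutral / low)
#' is taken from the sign of co-located significant performance QTL
#' relative to the +1 reference allele, and the responsiveness axis
#' (positive / non-responsive / negative) from the signs of co-located
#' temperature-covariate responsiveness QTL; the rainfall covariate's sign
#' is reported separately, since an opposite-signed temperature and
#' rainfall response is the classic genotype-by-environment pattern rather
#' than a conflict. Conflicting signs among co-located temperature
#' responsiveness QTL give the label `"mixed"`. When both axes are
#' non-neutral the linkage phase is reported: `"coupling"` when the
#' higher-performance allele also confers the positive response,
#' `"repulsion"` otherwise.
#'
#' @param clusters A `qtl_clusters` tibble.
#' @return A tibble: `cluster`, `chromosome`, `trait`, `performance`,
#'   `responsiveness`, `rainfall_response`, `phase`, `label`.
#' @export
classify_framework <- function(clusters) {
  purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    m <- clusters$members[[i]]
    purrr::map_dfr(unique(m$trait), function(tr) {
      mt <- m[m$trait == tr, ]
      perf <- mt[mt$type == "performance", ]
      resp <- mt[mt$type == "responsiveness", ]
      temp <- resp[is.na(resp$covariate) | resp$covariate != "gs_rainfall", ]
      rain <- resp[!is.na(resp$covariate) & resp$covariate == "gs_rainfall", ]
      axis <- function(eff) {
        if (length(eff) == 0L) return("neutral")
        s <- unique(sign(eff))
        if (length(s) > 1L) "mixed" else if (s > 0) "high" else "low"
      }
      raxis <- function(eff) {
        if (length(eff) == 0L) return("non-responsive")
        s <- unique(sign(eff))
        if (length(s) > 1L) "mixed" else if (s > 0) "positive" else "negative"
      }
      p <- axis(perf$effect)
      r <- raxis(temp$effect)
      rr <- raxis(rain$effect)
      phase <- if (p %in% c("high", "low") && r %in% c("positive", "negative")) {
        if ((p == "high") == (r == "positive")) "coupling" else "repulsion"
      } else NA_character_
      lbl <- sprintf("%s performance, %s response",
                     switch(p, high = "high", low = "low", neutral = "mean",
                            mixed = "mixed"),
                     switch(r, positive = "positive", negative = "negative",
                            `non-responsive` = "non-responsive", mixed = "mixed"))
      tibble::tibble(cluster = clusters$cluster[i],
                     chromosome = clusters$chromosome[i], trait = tr,
                     performance = p, responsiveness = r,
                     rainfall_response = rr, phase = phase, label = lbl)
    })
  })
}
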