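#' Map genes through an ortholog table
#'
#' @param genes character vector of human gene symbols.
#' @param map data.frame with columns \code{human_symbol},
#'   \code{rodent_symbol} (one-to-one after filtering).
#' @return list with \code{pairs} (data.frame human_symbol,
#'   rodent_symbol) and \code{unmapped} (character vector).
#' @export
map_orthologs <- function(genes, map) {
  genes <- unique(as.character(genes))
  hit <- match(genes, map$human_symbol)
  mapped <- !is.na(hit)
  list(pairs = data.frame(human_symbol = genes[mapped],
                          rodent_symbol = map$rodent_symbol[hit[mapped]],
                          stringsAsFactors = FALSE),
       unmapped = genes[!mapped])
}

#' Monotone trend call for a stage series
#'
#' Spearman correlation of expression against stage order: +1 when
#' rho >= \code{min_abs_rho}, -1 when rho <= -\code{min_abs_rho},
#' otherwise 0. A constant series has no trend (0).
#'
#' @param values expression at each stage, in stage order.
#' @param min_abs_rho trend-call threshold on |rho| (default 0.5).
#' @return +1, -1 or 0.
#' @export
stage_trend <- function(values, min_abs_rho = 0.5) {
  if (length(values) < 3L) stop("need at least 3 stages", call. = FALSE)
  if (stats::var(values) == 0) return(0)
  rho <- stats::cor(rank(values, ties.method = "average"),
                    seq_along(values))
  if (rho >= min_abs_rho) 1L else if (rho <= -min_abs_rho) -1L else 0L
}

#' Upper-tail hypergeometric enrichment of a set overlap
#'
#' P(X >= k) for an overlap of k genes between a human direction set of
#' size K and a rodent direction set of size n drawn from a universe of
#' N genes. Probabilities below machine precision are additionally
#' reported as the bound "< 2.2e-16" rather than a literal zero.
#'
#' @param k observed overlap.
#' @param K human-direction set size.
#' @param n rodent-direction set size.
#' @param N universe size.
#' @return list with \code{p} (raw float) and \code{p_display}
#'   (character).
#' @export
concordance_enrichment <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0)
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N",
         call. = FALSE)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p,
       p_display = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4))
}

#' Cross-species trend concordance test
#'
#' Tests whether human genes changing with age in a given direction are
#' enriched among rodent orthologs showing the same stage-series trend.
#' The universe defaults to mapped orthologs with a determinate trend
#' (nonzero trend call); alternatively all mapped orthologs.
#'
#' @param human_direction named vector (+1/-1) of human age directions,
#'   names = human symbols (mapped orthologs only).
#' @param rodent_trend named vector of rodent trend calls (+1/-1/0) on
#'   the same names.
#' @param direction which direction to test (+1 or -1).
#' @param universe \code{"determinate"} (default) or \code{"mapped"}.
#' @return list: k, K, n, N, p, p_display.
#' @export
trend_concordance <- function(human_direction, rodent_trend,
                              direction = 1,
                              universe = c("determinate", "mapped")) {
  universe <- match.arg(universe)
  common <- intersect(names(human_direction), names(rodent_trend))
  hd <- human_direction[common]
  rt <- rodent_trend[common]
  univ <- if (universe == "determinate") common[rt != 0] else common
  hd <- hd[univ]
  rt <- rt[univ]
  K <- sum(hd == direction)
  n <- sum(rt == direction)
  k <- sum(hd == direction & rt == direction)
  enr <- concordance_enrichment(k, K, n, length(univ))
  c(list(k = k, K = K, n = n, N = length(univ)), enr)
}

#' Delta-delta-Ct fold changes with SEM
#'
#' Standard qPCR relative quantification: per replicate,
#' \code{dCt = Ct_target - Ct_housekeeping}; \code{ddCt = dCt - mean
#' dCt(reference timepoint)}; fold change \code{2^(-ddCt)}. Reports the
#' per-timepoint mean fold change and its standard error of the mean
#' over replicates.
#'
#' @param ct data.frame with columns timepoint, replicate, target_ct,
#'   housekeeping_ct.
#' @param reference_timepoint the baseline timepoint.
#' @return data.frame: timepoint, mean_fold, sem, n_replicates.
#' @export
ddct_fold_change <- function(ct, reference_timepoint) {
  need <- c("timepoint", "replicate", "target_ct", "housekeeping_ct")
  missing <- setdiff(need, colnames(ct))
  if (length(missing) > 0)
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!reference_timepoint %in% ct$timepoint)
    stop("reference timepoint not present in Ct table", call. = FALSE)
  if (anyNA(ct$housekeeping_ct) || anyNA(ct$target_ct))
    stop("missing Ct replicate value", call. = FALSE)
  dct <- ct$target_ct - ct$housekeeping_ct
  ref <- mean(dct[ct$timepoint == reference_timepoint])
  fold <- 2^(-(dct - ref))
  tps <- unique(ct$timepoint)
  do.call(rbind, lapply(tps, function(tp) {
    f <- fold[ct$timepoint == tp]
    data.frame(timepoint = tp, mean_fold = mean(f),
               sem = stats::sd(f) / sqrt(length(f)),
               n_replicates = length(f), stringsAsFactors = FALSE)
  }))
}
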