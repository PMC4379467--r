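#' Per-gene analysis of covariance for age and sex
#'
#' Fits ordinary least squares
#' \code{y = b0 + b1 * age + b2 * I(male) + e} for one gene and returns
#' the two-sided t-test p-values on the age and sex coefficients
#' (n - 3 residual df; equivalent to the partial F test for each term).
#'
#' @param y numeric expression vector.
#' @param ages numeric ages in years.
#' @param sexes character/factor vector with levels male/female
#'   (female is the reference level).
#' @return Named numeric vector \code{c(p_age, p_sex)}.
#' @export
fit_covariance_model <- function(y, ages, sexes) {
  n <- length(y)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  if (length(ages) != n || length(sexes) != n)
    stop("y, ages and sexes must have equal length", call. = FALSE)
  male <- as.numeric(as.character(sexes) == "male")
  if (length(unique(male)) < 2L)
    stop("singular design: only one sex present", call. = FALSE)
  if (stats::var(ages) == 0)
    stop("singular design: age has zero variance", call. = FALSE)
  if (stats::var(y) == 0) {
    warning("zero-variance expression vector: gene skipped")
    return(c(p_age = NA_real_, p_sex = NA_real_))
  }
  fit <- stats::lm(y ~ ages + male)
  ct <- stats::coef(summary(fit))
  c(p_age = ct["ages", "Pr(>|t|)"], p_sex = ct["male", "Pr(>|t|)"])
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Spearman correlation of expression with age
#'
#' Pearson correlation of average-fractional ranks. The p-value is exact
#' (full permutation enumeration) for n <= 9 and otherwise uses the
#' two-sided t approximation with n - 2 df.
#'
#' @param y numeric expression vector.
#' @param ages numeric age vector.
#' @return Named numeric vector \code{c(rho, p_rho)}; \code{NA}s with a
#'   warning when a rank variance is zero.
#' @export
spearman_with_age <- function(y, ages) {
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  ry <- rank(y, ties.method = "average")
  ra <- rank(ages, ties.method = "average")
  if (stats::var(ry) == 0 || stats::var(ra) == 0) {
    warning("zero rank variance: correlation undefined, gene skipped")
    return(c(rho = NA_real_, p_rho = NA_real_))
  }
  rho <- stats::cor(ry, ra)
  if (n <= 9L) {
    perms <- .all_permutations(n)
    # rho is monotone in sum(ry_perm * ra); enumerate that statistic
    obs <- sum(ry * ra)
    stats_all <- as.vector(perms %*% ra)
    mu <- mean(stats_all)
    p <- mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  c(rho = rho, p_rho = min(p, 1))
}

# all n! permutations of rank vector positions (rows), n <= 9
.all_permutations <- function(n, v = NULL) {
  if (is.null(v)) v <- rank(seq_len(n))
  if (n == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(v[i], .all_permutations(n - 1L, v[-i]))))
}

#' Flag significant associations
#'
#' Significance requires both the raw p-value below \code{p_thresh}
#' (strict inequality) and the Benjamini-Hochberg q-value at or below
#' \code{fdr}, applied separately per covariate. The age direction is
#' the sign of the Spearman rho for significant genes and 0 otherwise.
#'
#' @param table association data.frame with columns \code{p_age},
#'   \code{q_age}, \code{p_sex}, \code{q_sex}, \code{rho}.
#' @param p_thresh raw p-value threshold (default 0.001).
#' @param fdr q-value threshold (default 0.05).
#' @return The table with \code{sig_age}, \code{sig_sex} and
#'   \code{direction} columns set.
#' @export
call_significant <- function(table, p_thresh = 0.001, fdr = 0.05) {
  sig <- function(p, q) !is.na(p) & !is.na(q) & p < p_thresh & q <= fdr
  table$sig_age <- sig(table$p_age, table$q_age)
  table$sig_sex <- sig(table$p_sex, table$q_sex)
  table$direction <- ifelse(table$sig_age, sign(table$rho), 0)
  table$direction[is.na(table$direction)] <- 0
  table
}

#' Screen a cohort for age and sex associations
#'
#' The central fitting function: for every gene it fits the covariance
#' model \code{expression ~ age + I(male)} (shared design, solved once by
#' QR for all genes), computes Spearman correlation with age,
#' Benjamini-Hochberg q-values per covariate, and flags significant
#' associations at \code{p < p_thresh} and \code{q <= fdr}.
#'
#' @param expr gene x sample log2 expression matrix; column names must
#'   match \code{meta$sample_id}.
#' @param meta data.frame with columns sample_id, age, sex (and
#'   optionally cohort).
#' @param p_thresh,fdr significance thresholds
#'   (see \code{\link{call_significant}}).
#' @return Object of class \code{assoc_screen}: a list with the
#'   association \code{table} (one row per gene), the thresholds, the
#'   cohort label and sample size. The table has columns gene, beta_age,
#'   beta_sex, p_age, p_sex, q_age, q_sex, rho, p_rho, q_rho, sig_age,
#'   sig_sex, direction.
#' @export
assoc_screen <- function(expr, meta, p_thresh = 0.001, fdr = 0.05) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)) || !identical(colnames(expr), meta$sample_id))
    stop("expression columns must match meta$sample_id exactly", call. = FALSE)
  n <- ncol(expr)
  if (n < 5L) stop("need at least 5 samples", call. = FALSE)
  male <- as.numeric(meta$sex == "male")
  if (length(unique(male)) < 2L)
    stop("singular design: only one sex present", call. = FALSE)
  if (stats::var(meta$age) == 0)
    stop("singular design: age has zero variance", call. = FALSE)

  X <- cbind(intercept = 1, age = meta$age, male = male)
  qr_x <- qr(X)
  df <- n - ncol(X)
  Y <- t(expr)                              # samples x genes
  beta <- qr.coef(qr_x, Y)                  # 3 x genes
  res <- qr.resid(qr_x, Y)
  rss <- colSums(res^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(outer(diag(xtx_inv), rss / df))  # 3 x genes
  tstat <- beta / se
  pmat <- 2 * stats::pt(-abs(tstat), df = df)

  zero_var <- apply(expr, 1, stats::var) == 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance gene(s) skipped")

  # Spearman with age, vectorized: correlate rank rows with rank(age)
  ra <- rank(meta$age, ties.method = "average")
  ry <- t(apply(expr, 1, rank, ties.method = "average"))
  rho <- suppressWarnings(as.vector(stats::cor(t(ry), ra)))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p_rho <- pmin(2 * stats::pt(-abs(tt), df = n - 2), 1)

  tab <- data.frame(gene = rownames(expr),
                    beta_age = beta["age", ], beta_sex = beta["male", ],
                    p_age = pmat["age", ], p_sex = pmat["male", ],
                    rho = rho, p_rho = p_rho,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab[zero_var, c("beta_age", "beta_sex", "p_age", "p_sex", "rho", "p_rho")] <- NA_real_
  ok <- !zero_var
  tab$q_age <- tab$q_sex <- tab$q_rho <- NA_real_
  tab$q_age[ok] <- benjamini_hochberg(tab$p_age[ok])
  tab$q_sex[ok] <- benjamini_hochberg(tab$p_sex[ok])
  tab$q_rho[ok] <- benjamini_hochberg(tab$p_rho[ok])
  tab <- call_significant(tab, p_thresh = p_thresh, fdr = fdr)

  structure(list(table = tab, p_thresh = p_thresh, fdr = fdr,
                 cohort = if (!is.null(meta$cohort)) meta$cohort[1] else NA_character_,
                 n_samples = n),
            class = "assoc_screen")
}

#' @export
print.assoc_screen <- function(x, ...) {
  cat("Age/sex association screen (", x$cohort, ")\n", sep = "")
  cat("  genes tested:    ", nrow(x$table), "\n")
  cat("  samples:         ", x$n_samples, "\n")
  cat("  thresholds:       p <", x$p_thresh, ", BH q <=", x$fdr, "\n")
  cat("  age-associated:  ", sum(x$table$sig_age, na.rm = TRUE),
      "(", sum(x$table$direction > 0), "up,",
      sum(x$table$direction < 0), "down )\n")
  cat("  sex-associated:  ", sum(x$table$sig_sex, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.assoc_screen <- function(object, ...) {
  t <- object$table
  out <- list(cohort = object$cohort,
              n_genes = nrow(t), n_samples = object$n_samples,
              n_sig_age = sum(t$sig_age, na.rm = TRUE),
              n_sig_sex = sum(t$sig_sex, na.rm = TRUE),
              n_up = sum(t$direction > 0), n_down = sum(t$direction < 0),
              top_age = utils::head(t[order(t$p_age), ], 5))
  class(out) <- "summary.assoc_screen"
  out
}

#' @export
print.summary.assoc_screen <- function(x, ...) {
  cat("Association screen summary (", x$cohort, "): ",
      x$n_sig_age, " age-associated (", x$n_up, " up / ", x$n_down,
      " down), ", x$n_sig_sex, " sex-associated of ", x$n_genes,
      " genes in ", x$n_samples, " samples\n", sep = "")
  cat("Top age associations:\n")
  print(x$top_age[, c("gene", "beta_age", "p_age", "q_age", "rho")],
        row.names = FALSE)
  invisible(x)
}

#' Merge cohort screens into a non-redundant association set
#'
#' A (gene, covariate) pair enters the merged set when it is significant
#' in at least one cohort. When cohorts disagree on direction, the
#' cohort with the larger absolute effect (|rho| for age, |beta_sex| for
#' sex) decides; exact ties give direction 0 with a warning.
#'
#' @param tables list of \code{assoc_screen} objects (or their
#'   \code{$table} data.frames), named by cohort.
#' @return data.frame with columns gene, covariate, direction, cohorts
#'   (comma-separated supporting cohorts).
#' @export
merge_nonredundant <- function(tables) {
  if (length(tables) < 1L) stop("need at least one cohort table", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("cohort", seq_along(tables))
  tabs <- lapply(tables, function(t) if (inherits(t, "assoc_screen")) t$table else t)

  rows <- list()
  for (cov in c("age", "sex")) {
    sig_col <- paste0("sig_", cov)
    recs <- do.call(rbind, lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      s <- t[!is.na(t[[sig_col]]) & t[[sig_col]], , drop = FALSE]
      if (nrow(s) == 0) return(NULL)
      eff <- if (cov == "age") s$rho else s$beta_sex
      data.frame(gene = s$gene, cohort = nm, effect = eff,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(recs)) next
    for (g in sort(unique(recs$gene))) {
      r <- recs[recs$gene == g, , drop = FALSE]
      dirs <- sign(r$effect)
      if (length(unique(dirs)) == 1L) {
        d <- dirs[1]
      } else {
        a <- abs(r$effect)
        if (sum(a == max(a)) > 1L && length(unique(dirs[a == max(a)])) > 1L) {
          warning("direction tie for gene '", g, "': direction set to 0")
          d <- 0
        } else {
          d <- dirs[which.max(a)]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, covariate = cov, direction = d,
        cohorts = paste(sort(unique(r$cohort)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), covariate = character(),
                      direction = numeric(), cohorts = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Fisher exact test of association proportions between two gene classes
#'
#' Builds the 2x2 table [associated vs not] x [class_a vs class_b] and
#' returns the two-sided exact hypergeometric p-value (sum of the
#' probabilities of all tables at most as probable as the observed one).
#'
#' @param catalog data.frame with columns symbol, class.
#' @param merged merged association set
#'   (see \code{\link{merge_nonredundant}}).
#' @param class_a,class_b the two classes to compare.
#' @param covariate which covariate's associations to count.
#' @return list with elements \code{table} (2x2 matrix) and \code{p}.
#' @export
class_proportion_test <- function(catalog, merged, class_a, class_b,
                                  covariate = "age") {
  genes_a <- catalog$symbol[catalog$class == class_a]
  genes_b <- catalog$symbol[catalog$class == class_b]
  if (length(genes_a) == 0 || length(genes_b) == 0)
    stop("empty gene class", call. = FALSE)
  assoc <- merged$gene[merged$covariate == covariate]
  tab <- matrix(c(sum(genes_a %in% assoc), sum(!genes_a %in% assoc),
                  sum(genes_b %in% assoc), sum(!genes_b %in% assoc)),
                nrow = 2,
                dimnames = list(c("associated", "not"), c(class_a, class_b)))
  list(table = tab, p = stats::fisher.test(tab)$p.value)
}

#' Per-gene sex difference summary
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of male vs female
#' expression per gene, with per-sex medians.
#'
#' @param expr gene x sample expression matrix.
#' @param meta sample metadata (sample_id, sex).
#' @param genes genes to summarize (default: all rows).
#' @return data.frame: gene, median_male, median_female, p.
#' @export
sex_difference_summary <- function(expr, meta, genes = rownames(expr)) {
  m <- meta$sex == "male"
  f <- meta$sex == "female"
  genes <- intersect(genes, rownames(expr))
  do.call(rbind, lapply(genes, function(g) {
    ym <- expr[g, m]
    yf <- expr[g, f]
    p <- if (sum(m) < 2L || sum(f) < 2L) {
      NA_real_
    } else {
      suppressWarnings(stats::wilcox.test(ym, yf)$p.value)
    }
    # completely tied samples: identical distributions, no evidence
    if (is.nan(p)) p <- 1
    data.frame(gene = g, median_male = stats::median(ym),
               median_female = stats::median(yf), p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Bin samples into age intervals
#'
#' Half-open bins \code{[0,w), [w,2w), ...}; the final bin is closed at
#' 120 years.
#'
#' @param meta sample metadata with an \code{age} column.
#' @param width bin width in years (default 20).
#' @return Character vector of bin labels, one per sample.
#' @export
bin_ages <- function(meta, width = 20) {
  if (width <= 0) stop("bin width must be positive", call. = FALSE)
  last_lo <- floor((120 - 1e-9) / width) * width
  lo <- pmin(floor(meta$age / width) * width, last_lo)
  hi <- lo + width
  ifelse(lo == last_lo,
         sprintf("[%g,120]", lo),
         sprintf("[%g,%g)", lo, hi))
}

#' Gene x age-bin mean expression matrix
#'
#' @param expr gene x sample matrix.
#' @param bins bin label per sample (see \code{\link{bin_ages}}).
#' @param levels optional bin labels to emit as columns (in order); bins
#'   with no samples appear as NA columns.
#' @return gene x bin matrix of arithmetic means.
#' @export
bin_means <- function(expr, bins, levels = NULL) {
  if (is.null(levels))
    levels <- unique(bins[order(as.numeric(sub("^\\[([0-9.]+),.*", "\\1", bins)))])
  out <- sapply(levels, function(b) {
    cols <- bins == b
    if (!any(cols)) return(rep(NA_real_, nrow(expr)))
    rowMeans(expr[, cols, drop = FALSE])
  })
  rownames(out) <- rownames(expr)
  out
}

#' Cluster age-binned expression profiles
#'
#' Agglomerative clustering of row z-scores with distance
#' 1 - Pearson correlation and average linkage, cut at \code{k}
#' clusters. Rows are processed in lexicographic gene order so the
#' result is deterministic. Constant rows cannot be z-scored and are
#' assigned to a residual cluster (label 0) with a warning.
#'
#' @param submatrix gene x bin numeric matrix.
#' @param k number of clusters.
#' @return Integer cluster label per gene, named, in input row order.
#' @export
hierarchical_clusters <- function(submatrix, k) {
  if (ncol(submatrix) < 2L) stop("need at least 2 bins", call. = FALSE)
  ord <- order(rownames(submatrix))
  m <- submatrix[ord, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant row(s) assigned to residual cluster 0")
  labels <- integer(nrow(m))
  names(labels) <- rownames(m)
  mv <- m[!const, , drop = FALSE]
  if (nrow(mv) < k) stop("need at least k non-constant genes", call. = FALSE)
  z <- t(scale(t(mv)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  labels[!const] <- stats::cutree(hc, k = k)
  labels[rownames(submatrix)]
}
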