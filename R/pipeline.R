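#' Configuration for a full pipeline run
#'
#' Either a synthetic run (a \code{\link{synthetic_config}} drives two
#' cohorts sharing one truth table, an interactome and a stage series)
#' or a real-data run driven by file paths. Thresholds apply to both.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; per-stage child seeds are derived
#'   from it deterministically.
#' @param synthetic generate inputs instead of reading files.
#' @param syn \code{\link{synthetic_config}} for cohort 1 (synthetic runs).
#' @param n_samples_cohort2 sample size of the second synthetic cohort.
#' @param interactome_p_in,interactome_p_out,interactome_background
#'   planted-module edge probabilities and background node count for the
#'   synthetic interactome.
#' @param stage_noise_sd noise SD of the synthetic stage series.
#' @param expr_path,meta_path,catalog_path,edges_path,ortholog_path,stages_path
#'   TSV inputs for real-data runs (metadata must carry a cohort column;
#'   ortholog/stage inputs are optional).
#' @param edges_dialect \code{"tsv2col"} or \code{"biogrid_tab2"}.
#' @param raw_protocol if the expression input is raw intensities,
#'   the \code{\link{preprocess_cohort}} protocol to apply; NULL means
#'   the input is already normalized log2 expression.
#' @param p_thresh,fdr association significance thresholds.
#' @param n_random null-ensemble size.
#' @param trend_min_abs_rho stage-trend call threshold.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, synthetic = TRUE,
                       syn = synthetic_config(),
                       n_samples_cohort2 = 149L,
                       interactome_p_in = 0.3, interactome_p_out = 0.02,
                       interactome_background = 500L,
                       stage_noise_sd = 0.25,
                       expr_path = NULL, meta_path = NULL,
                       catalog_path = NULL, edges_path = NULL,
                       edges_dialect = "tsv2col",
                       ortholog_path = NULL, stages_path = NULL,
                       raw_protocol = NULL,
                       p_thresh = 0.001, fdr = 0.05, n_random = 100L,
                       trend_min_abs_rho = 0.5) {
  cfg <- as.list(environment())
  if (!synthetic) {
    for (f in c("expr_path", "meta_path")) {
      if (is.null(cfg[[f]]))
        stop("configuration error: '", f, "' is required for non-synthetic runs",
             call. = FALSE)
    }
  }
  if (p_thresh <= 0 || p_thresh > 1 || fdr <= 0 || fdr > 1)
    stop("configuration error: thresholds must lie in (0, 1]", call. = FALSE)
  if (n_random < 1) stop("configuration error: n_random must be >= 1", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-stage child seeds below 2^31
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 10007) %% 2147483647)
}

#' Validate pipeline inputs
#'
#' Checks matrix/metadata alignment, sex levels, age ranges and catalog
#' coverage, returning findings rather than stopping, so callers can
#' distinguish warnings from errors.
#'
#' @param expr expression matrix.
#' @param meta sample metadata.
#' @param catalog optional gene catalog.
#' @return data.frame with columns \code{level} ("error"/"warning") and
#'   \code{message}; zero rows when everything checks out.
#' @export
validate_inputs <- function(expr, meta, catalog = NULL) {
  findings <- list()
  add <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  extra <- setdiff(colnames(expr), meta$sample_id)
  if (length(extra) > 0)
    add("error", paste0(length(extra),
                        " matrix sample(s) absent from metadata (e.g. '",
                        extra[1], "')"))
  unused <- setdiff(meta$sample_id, colnames(expr))
  if (length(unused) > 0)
    add("warning", paste0(length(unused),
                          " metadata sample(s) absent from the matrix"))
  if (!all(meta$sex %in% c("male", "female")))
    add("error", "sex must be 'male' or 'female'")
  if (length(unique(meta$sex)) < 2L)
    add("error", "only one sex present")
  if (any(meta$age < 0 | meta$age > 120))
    add("error", "ages must lie in [0, 120]")
  if (stats::var(meta$age) == 0)
    add("error", "age has zero variance")
  if (anyNA(expr) || any(!is.finite(expr)))
    add("error", "expression matrix contains missing or non-finite values")
  if (!is.null(catalog)) {
    miss <- setdiff(rownames(expr), catalog$symbol)
    if (length(miss) > 0)
      add("warning", paste0("catalog missing ", length(miss), " of ",
                            nrow(expr), " matrix genes"))
  }
  if (length(findings) == 0)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

.stage <- function(out_dir, name, expr_fun) {
  tryCatch(expr_fun(), error = function(e) {
    writeLines(paste0("FAILED at stage '", name, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full association + network + cross-species pipeline
#'
#' Executes, in order: input generation or loading (with optional raw
#' preprocessing), per-cohort association screening, non-redundant
#' merging, age binning with hierarchical clustering of the
#' age-increasing and age-decreasing gene groups, induced-subnetwork
#' centrality analysis against an edge-subsampled null ensemble, and
#' (when ortholog/stage inputs exist) cross-species trend concordance.
#' All randomness flows from \code{config$seed}; rerunning an identical
#' config reproduces identical outputs. Any stage failure aborts with
#' the stage name and leaves a FAILED marker in the output directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return Object of class \code{run_report}: per-stage summary counts,
#'   comparison results and the output-file manifest.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(out, "FAILED")))
    unlink(file.path(out, "FAILED"))
  manifest <- character()
  emit <- function(obj, name, writer = write_tsv) {
    path <- file.path(out, name)
    writer(obj, path)
    manifest <<- c(manifest, name)
  }

  # --- inputs ---------------------------------------------------------
  inputs <- .stage(out, "inputs", function() {
    if (config$synthetic) {
      syn1 <- config$syn
      syn1$seed <- .child_seed(config$seed, 1)
      c1 <- gen_cohort(syn1, "cohort1")
      syn2 <- syn1
      syn2$n_samples <- as.integer(config$n_samples_cohort2)
      syn2$seed <- .child_seed(config$seed, 2)
      c2 <- gen_cohort(syn2, "cohort2", truth = c1$truth)
      list(cohorts = list(cohort1 = c1, cohort2 = c2), truth = c1$truth,
           catalog = data.frame(symbol = c1$truth$gene, class = "RBP",
                                stringsAsFactors = FALSE))
    } else {
      expr <- read_expression_tsv(config$expr_path)
      meta <- read_metadata_tsv(config$meta_path)
      if (is.null(meta$cohort)) meta$cohort <- "cohort1"
      catalog <- if (!is.null(config$catalog_path))
        read_catalog_tsv(config$catalog_path) else NULL
      cohorts <- lapply(split(meta, meta$cohort), function(mm) {
        e <- expr[, mm$sample_id, drop = FALSE]
        if (!is.null(config$raw_protocol))
          e <- preprocess_cohort(e, protocol = config$raw_protocol)
        list(expr = e, meta = mm, truth = NULL)
      })
      list(cohorts = cohorts, truth = NULL, catalog = catalog)
    }
  })

  # --- validation -----------------------------------------------------
  .stage(out, "validation", function() {
    for (nm in names(inputs$cohorts)) {
      co <- inputs$cohorts[[nm]]
      f <- validate_inputs(co$expr, co$meta, inputs$catalog)
      if (any(f$level == "error"))
        stop(nm, ": ", paste(f$message[f$level == "error"], collapse = "; "))
    }
    invisible(NULL)
  })

  # --- association per cohort ----------------------------------------
  screens <- .stage(out, "association", function() {
    lapply(inputs$cohorts, function(co)
      assoc_screen(co$expr, co$meta,
                   p_thresh = config$p_thresh, fdr = config$fdr))
  })
  for (nm in names(screens))
    emit(screens[[nm]]$table, paste0("association_", nm, ".tsv"))

  merged <- .stage(out, "merge", function() merge_nonredundant(screens))
  emit(merged, "merged_set.tsv")

  # --- age binning + clustering --------------------------------------
  .stage(out, "binning", function() {
    co <- inputs$cohorts[[1]]
    bins <- bin_ages(co$meta)
    bm <- bin_means(co$expr, bins)
    emit(bm, "bin_means_cohort1.tsv", writer = write_matrix_tsv)
    age_set <- merged[merged$covariate == "age", , drop = FALSE]
    for (d in c(1, -1)) {
      g <- age_set$gene[age_set$direction == d]
      g <- intersect(g, rownames(bm))
      if (length(g) >= 3L) {
        labels <- hierarchical_clusters(bm[g, , drop = FALSE], k = 3)
        emit(data.frame(gene = names(labels), cluster = unname(labels),
                        stringsAsFactors = FALSE),
             sprintf("clusters_age_%s.tsv", if (d > 0) "up" else "down"))
      }
    }
    invisible(NULL)
  })

  # --- network --------------------------------------------------------
  net_res <- .stage(out, "network", function() {
    assoc_age <- merged$gene[merged$covariate == "age"]
    if (config$synthetic) {
      module <- inputs$truth$gene[inputs$truth$age_effect != 0]
      net <- gen_interactome(inputs$truth, module,
                             n_background = config$interactome_background,
                             p_in = config$interactome_p_in,
                             p_out = config$interactome_p_out,
                             seed = .child_seed(config$seed, 3))
    } else {
      if (is.null(config$edges_path)) return(NULL)
      net <- parse_interactions(config$edges_path, config$edges_dialect)
    }
    emit(net, "interactome_edges.tsv", writer = write_edges_tsv)
    observed_net <- induced_network(net, assoc_age)
    nonassoc <- setdiff(igraph::V(net)$name, assoc_age)
    null_source <- induced_network(net, nonassoc)
    x <- igraph::ecount(observed_net)
    if (x == 0 || igraph::ecount(null_source) < x)
      return(list(skipped = TRUE,
                  reason = "observed subnetwork empty or null source too small"))
    obs_tab <- centrality_table(observed_net)
    emit(obs_tab, "centrality_observed.tsv")
    ens <- sample_null_ensemble(null_source, x = x, n = config$n_random,
                                seed = .child_seed(config$seed, 4))
    emit(ens$pooled, "centrality_null_pooled.tsv")
    comps <- lapply(c("degree", "betweenness", "closeness", "clustcoef"),
                    function(m) compare_centrality(obs_tab, ens, m))
    comp_df <- do.call(rbind, lapply(comps, function(cmp)
      data.frame(measure = cmp$measure, observed_median = cmp$observed_median,
                 null_median = cmp$null_median, U = cmp$U, p = cmp$p,
                 stringsAsFactors = FALSE)))
    emit(comp_df, "centrality_comparison.tsv")
    list(skipped = FALSE, nodes = igraph::vcount(observed_net), edges = x,
         comparisons = comp_df)
  })

  # --- cross-species --------------------------------------------------
  xsp <- .stage(out, "xspecies", function() {
    age_set <- merged[merged$covariate == "age" & merged$direction != 0, ,
                      drop = FALSE]
    if (nrow(age_set) == 0) return(NULL)
    if (config$synthetic) {
      map <- data.frame(human_symbol = inputs$truth$gene,
                        rodent_symbol = tolower(inputs$truth$gene),
                        stringsAsFactors = FALSE)
      series <- gen_stage_series(inputs$truth,
                                 noise_sd = config$stage_noise_sd,
                                 seed = .child_seed(config$seed, 5))
      rownames(series) <- tolower(rownames(series))
    } else {
      if (is.null(config$ortholog_path) || is.null(config$stages_path))
        return(NULL)
      map <- read_orthologs_tsv(config$ortholog_path)
      series <- read_expression_tsv(config$stages_path)
    }
    om <- map_orthologs(age_set$gene, map)
    pairs <- om$pairs[om$pairs$rodent_symbol %in% rownames(series), ,
                      drop = FALSE]
    if (nrow(pairs) < 2L) return(NULL)
    rt <- apply(series[pairs$rodent_symbol, , drop = FALSE], 1, stage_trend,
                min_abs_rho = config$trend_min_abs_rho)
    names(rt) <- pairs$human_symbol
    hd <- stats::setNames(age_set$direction, age_set$gene)[pairs$human_symbol]
    res <- lapply(c(up = 1, down = -1), function(d)
      trend_concordance(hd, rt, direction = d))
    conc <- data.frame(direction = c("up", "down"),
                       k = sapply(res, `[[`, "k"), K = sapply(res, `[[`, "K"),
                       n = sapply(res, `[[`, "n"), N = sapply(res, `[[`, "N"),
                       p = sapply(res, `[[`, "p"),
                       p_display = sapply(res, `[[`, "p_display"),
                       stringsAsFactors = FALSE)
    emit(conc, "concordance.tsv")
    conc
  })

  report <- structure(list(
    seed = config$seed,
    version = as.character(utils::packageVersion("rbpAge")),
    n_cohorts = length(inputs$cohorts),
    genes_tested = nrow(screens[[1]]$table),
    sig_age = sapply(screens, function(s) sum(s$table$sig_age, na.rm = TRUE)),
    sig_sex = sapply(screens, function(s) sum(s$table$sig_sex, na.rm = TRUE)),
    merged_age = sum(merged$covariate == "age"),
    merged_sex = sum(merged$covariate == "sex"),
    network = net_res,
    concordance = xsp,
    manifest = manifest,
    out_dir = out), class = "run_report")

  rep_df <- data.frame(
    key = c("seed", "genes_tested", "merged_age", "merged_sex",
            "network_nodes", "network_edges"),
    value = c(config$seed, report$genes_tested, report$merged_age,
              report$merged_sex,
              if (!is.null(net_res) && !isTRUE(net_res$skipped)) net_res$nodes else NA,
              if (!is.null(net_res) && !isTRUE(net_res$skipped)) net_res$edges else NA),
    stringsAsFactors = FALSE)
  emit(rep_df, "report.tsv")
  report$manifest <- manifest
  stopifnot(all(file.exists(file.path(out, manifest))))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ") -> ", x$out_dir, "\n", sep = "")
  cat("  cohorts: ", x$n_cohorts, "; genes tested: ", x$genes_tested, "\n", sep = "")
  cat("  merged set: ", x$merged_age, " age-associated, ",
      x$merged_sex, " sex-associated\n", sep = "")
  if (!is.null(x$network) && !isTRUE(x$network$skipped)) {
    cat("  associated subnetwork: ", x$network$nodes, " nodes, ",
        x$network$edges, " edges\n", sep = "")
    print(x$network$comparisons, row.names = FALSE)
  }
  if (!is.null(x$concordance)) {
    cat("  cross-species concordance:\n")
    print(x$concordance, row.names = FALSE)
  }
  cat("  files: ", paste(x$manifest, collapse = ", "), "\n", sep = "")
  invisible(x)
}
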