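#' Configuration for synthetic liver-cohort generation
#'
#' Bundles and validates the parameters of the synthetic expression
#' generator. Defaults emulate the larger of the two liver cohorts the
#' analysis is designed for: 1344 genes, 206 donors aged 1-85 years with
#' both sexes represented, a minority of genes carrying a linear age
#' slope and/or an additive sex shift on top of Gaussian noise.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples (donors).
#' @param age_min,age_max age range in years; ages are drawn uniformly.
#' @param male_fraction probability a sample is male.
#' @param frac_age_assoc fraction of genes with a nonzero age slope.
#' @param frac_sex_assoc fraction of genes with a nonzero sex shift.
#' @param age_slope magnitude of the planted age slope
#'   (expression units per year).
#' @param sex_shift magnitude of the planted male-vs-female shift
#'   (expression units).
#' @param neg_fraction fraction of planted effects given negative sign.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise.
#' @param baseline_mean,baseline_sd per-gene baseline expression is drawn
#'   from N(baseline_mean, baseline_sd^2) (log2 scale).
#' @param seed integer seed; identical config and seed give bit-identical
#'   output.
#'
#' @return An object of class \code{synthetic_config} (a validated list).
#' @export
synthetic_config <- function(n_genes = 1344L, n_samples = 206L,
                             age_min = 1, age_max = 85,
                             male_fraction = 0.64,
                             frac_age_assoc = 0.065,
                             frac_sex_assoc = 0.033,
                             age_slope = 0.05, sex_shift = 1,
                             neg_fraction = 0.5,
                             noise_sd = 1,
                             baseline_mean = 8, baseline_sd = 2,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              age_min = age_min, age_max = age_max,
              male_fraction = male_fraction,
              frac_age_assoc = frac_age_assoc, frac_sex_assoc = frac_sex_assoc,
              age_slope = age_slope, sex_shift = sex_shift,
              neg_fraction = neg_fraction, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid synthetic_config: '", field, "' must be a proportion in [0, 1]",
           call. = FALSE)
  }
  for (f in c("male_fraction", "frac_age_assoc", "frac_sex_assoc", "neg_fraction"))
    chk_prop(f)
  if (cfg$n_genes < 1L) stop("invalid synthetic_config: 'n_genes' must be >= 1", call. = FALSE)
  if (cfg$n_samples < 1L) stop("invalid synthetic_config: 'n_samples' must be >= 1", call. = FALSE)
  if (!(cfg$age_min < cfg$age_max))
    stop("invalid synthetic_config: 'age_min' must be < 'age_max'", call. = FALSE)
  if (cfg$noise_sd < 0) stop("invalid synthetic_config: 'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$baseline_sd < 0) stop("invalid synthetic_config: 'baseline_sd' must be >= 0", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic expression cohort with ground truth
#'
#' Draws ages uniformly on \code{[age_min, age_max]}, sexes as
#' Bernoulli(\code{male_fraction}), and expression as
#' \deqn{y_{gs} = b_g + \beta_g \, \mathrm{age}_s + \gamma_g \, I(\mathrm{male}_s)
#'   + N(0, \sigma^2)}
#' where a configured fraction of genes receive a nonzero age slope
#' \eqn{\beta_g} and/or sex shift \eqn{\gamma_g} (random sign).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param cohort cohort label recorded in the metadata.
#' @param truth optional truth table from a previous call, so that a
#'   second cohort shares the same planted effects.
#'
#' @return A list with components \code{expr} (gene x sample numeric
#'   matrix), \code{meta} (data.frame: sample_id, age, sex, cohort) and
#'   \code{truth} (data.frame: gene, age_effect, sex_effect).
#' @export
gen_cohort <- function(config, cohort = "cohort1", truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  if (is.null(truth)) {
    n_age <- round(config$frac_age_assoc * config$n_genes)
    n_sex <- round(config$frac_sex_assoc * config$n_genes)
    age_idx <- sample.int(config$n_genes, n_age)
    sex_idx <- sample.int(config$n_genes, n_sex)
    age_eff <- numeric(config$n_genes)
    sex_eff <- numeric(config$n_genes)
    sgn <- function(k) ifelse(stats::runif(k) < config$neg_fraction, -1, 1)
    age_eff[age_idx] <- config$age_slope * sgn(n_age)
    sex_eff[sex_idx] <- config$sex_shift * sgn(n_sex)
    truth <- data.frame(gene = genes, age_effect = age_eff,
                        sex_effect = sex_eff, stringsAsFactors = FALSE)
  } else {
    if (!identical(truth$gene, genes))
      stop("supplied truth table does not match the configured gene set", call. = FALSE)
  }
  samples <- sprintf("%s_S%04d", cohort, seq_len(config$n_samples))
  ages <- stats::runif(config$n_samples, config$age_min, config$age_max)
  sexes <- ifelse(stats::runif(config$n_samples) < config$male_fraction,
                  "male", "female")
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  expr <- baseline +
    outer(truth$age_effect, ages) +
    outer(truth$sex_effect, as.numeric(sexes == "male"))
  if (config$noise_sd > 0)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                          nrow = config$n_genes)
  dimnames(expr) <- list(genes, samples)
  meta <- data.frame(sample_id = samples, age = ages, sex = sexes,
                     cohort = cohort, stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, truth = truth)
}

#' Generate a synthetic interactome with a planted dense module
#'
#' Builds an Erdos-Renyi-style undirected simple graph in which edges
#' inside the associated gene set appear with probability \code{p_in}
#' and all other pairs (background-background and associated-background)
#' with probability \code{p_out}. With \code{p_in > p_out} the
#' associated genes form a denser, more clustered module than the
#' background, mirroring the modular structure the centrality analysis
#' is designed to detect.
#'
#' @param truth truth table from \code{\link{gen_cohort}}; background
#'   nodes are drawn from its non-associated genes.
#' @param assoc_genes character vector of associated gene symbols.
#' @param n_background number of background nodes.
#' @param p_in,p_out edge probabilities (must satisfy p_in > p_out).
#' @param seed integer seed.
#'
#' @return An \code{igraph} undirected simple graph with named vertices.
#' @export
gen_interactome <- function(truth, assoc_genes, n_background,
                            p_in, p_out, seed = 1L) {
  if (!is.numeric(p_in) || !is.numeric(p_out) || p_in < 0 || p_in > 1 ||
      p_out < 0 || p_out > 1)
    stop("invalid configuration: 'p_in' and 'p_out' must be probabilities in [0, 1]",
         call. = FALSE)
  if (p_in <= p_out)
    stop("invalid configuration: 'p_in' must exceed 'p_out'", call. = FALSE)
  assoc_genes <- unique(as.character(assoc_genes))
  pool <- setdiff(truth$gene, assoc_genes)
  if (length(pool) >= n_background) {
    background <- pool[seq_len(n_background)]
  } else {
    extra <- sprintf("BG%05d", seq_len(n_background - length(pool)))
    background <- c(pool, extra)
  }
  nodes <- c(assoc_genes, background)
  n <- length(nodes)
  set.seed(seed)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  in_module <- ij[, 1] <= length(assoc_genes) & ij[, 2] <= length(assoc_genes)
  p <- ifelse(in_module, p_in, p_out)
  keep <- stats::runif(nrow(ij)) < p
  edges <- cbind(nodes[ij[keep, 1]], nodes[ij[keep, 2]])
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g)
}

#' Generate a synthetic developmental stage series
#'
#' Emulates a rodent liver series sampled at a few ordered ages (the
#' default mirrors a 2/6/21/104-week design): each gene's expression is
#' its planted age slope times the stage age plus Gaussian noise, so the
#' noise-free trend sign equals the sign of the gene's age effect.
#'
#' @param truth truth table from \code{\link{gen_cohort}}.
#' @param stages strictly increasing vector of at least 3 stage ages.
#' @param noise_sd Gaussian noise SD (expression units).
#' @param seed integer seed.
#'
#' @return Numeric gene x stage matrix; columns named by stage age.
#' @export
gen_stage_series <- function(truth, stages = c(2, 6, 21, 104),
                             noise_sd = 0, seed = 1L) {
  if (length(stages) < 3L)
    stop("at least 3 stages are required", call. = FALSE)
  if (any(diff(stages) <= 0))
    stop("stages must be strictly increasing", call. = FALSE)
  set.seed(seed)
  m <- outer(truth$age_effect, stages)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  dimnames(m) <- list(truth$gene, as.character(stages))
  m
}
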