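#' Configuration for the synthetic world generator
#'
#' Defaults mirror the dimensions of the real inputs the pipeline was built
#' for: 90 Mendelian diseases, 65 complex diseases in six categories, ~600
#' causal genes, ~800 drugs with a heavy-tailed target count (hub targets
#' such as nuclear receptors are targeted by dozens of drugs), a comorbidity
#' density of ~0.5 (2,908 of 5,850 possible pairs), 10 cancers and 37
#' tissues. The planted enrichment effect defaults to a log odds ratio of
#' log(2); the baseline log-odds puts the marginal outcome rate around 10%,
#' with category shifts emulating the surplus of oncology trials.
#'
#' @param n_mendelian,n_complex,n_genes,n_drugs,n_cancers,n_tissues counts.
#' @param genes_per_mendelian mean of the zero-truncated Poisson used for
#'   causal genes per Mendelian disease.
#' @param targets_per_drug_prob success probability of the zero-truncated
#'   geometric for targets per drug (smaller = heavier tail).
#' @param comorbidity_density expected fraction of (Mendelian, complex)
#'   pairs that are comorbid.
#' @param beta0 baseline log-odds of a positive clinical outcome.
#' @param beta_candidate planted log odds ratio of the candidate flag.
#' @param beta_ntargets log-odds increment per known gene target.
#' @param category_effects named numeric vector of per-category log-odds
#'   shifts (names from [DISEASE_CATEGORIES]).
#' @param phase_probs named probabilities used to assign a phase to each
#'   positive pair.
#' @param module_size,mendelian_set_size,drivers_per_cancer planted
#'   co-expression module controls for [generate_expression()].
#' @param module_correlation correlation between module genes' tissue
#'   profiles, in `[0, 1]`.
#' @param seed integer seed; identical seeds give bit-identical worlds.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mendelian = 90L, n_complex = 65L,
                             n_genes = 600L, n_drugs = 800L,
                             n_cancers = 10L, n_tissues = 37L,
                             genes_per_mendelian = 6,
                             targets_per_drug_prob = 0.45,
                             comorbidity_density = 2908 / (90 * 65),
                             beta0 = -2.5,
                             beta_candidate = log(2),
                             beta_ntargets = 0.05,
                             category_effects = c(
                               cardiovascular = -0.4, hormonal = -0.2,
                               immune = 0.2, neoplasms = 0.6,
                               neurological = 0.1, ophthalmological = -0.6),
                             phase_probs = c(PHASE_I = 0.25, PHASE_II = 0.25,
                                             PHASE_III = 0.15, UNKNOWN = 0.15,
                                             INDICATED = 0.20),
                             module_size = 8L, mendelian_set_size = 5L,
                             drivers_per_cancer = 10L,
                             module_correlation = 0.9, seed = 1L) {
  cfg <- list(n_mendelian = as.integer(n_mendelian),
              n_complex = as.integer(n_complex),
              n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
              n_cancers = as.integer(n_cancers),
              n_tissues = as.integer(n_tissues),
              genes_per_mendelian = genes_per_mendelian,
              targets_per_drug_prob = targets_per_drug_prob,
              comorbidity_density = comorbidity_density,
              beta0 = beta0, beta_candidate = beta_candidate,
              beta_ntargets = beta_ntargets,
              category_effects = category_effects,
              phase_probs = phase_probs,
              module_size = as.integer(module_size),
              mendelian_set_size = as.integer(mendelian_set_size),
              drivers_per_cancer = as.integer(drivers_per_cancer),
              module_correlation = module_correlation,
              seed = as.integer(seed))
  counts <- c("n_mendelian", "n_complex", "n_genes", "n_drugs", "n_cancers",
              "n_tissues")
  if (any(vapply(cfg[counts], function(v) v < 1L, logical(1))))
    stop("all counts must be >= 1", call. = FALSE)
  if (cfg$comorbidity_density < 0 || cfg$comorbidity_density > 1)
    stop("comorbidity_density must lie in [0, 1]", call. = FALSE)
  if (cfg$module_correlation < 0 || cfg$module_correlation > 1)
    stop("module_correlation must lie in [0, 1]", call. = FALSE)
  if (cfg$genes_per_mendelian > cfg$n_genes)
    stop("genes_per_mendelian exceeds the gene pool", call. = FALSE)
  if (cfg$module_size > cfg$n_genes)
    stop("module_size exceeds the gene pool", call. = FALSE)
  if (!all(names(cfg$category_effects) %in% DISEASE_CATEGORIES))
    stop("category_effects names must be disease categories", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

.rztpois <- function(n, lambda) {
  # zero-truncated Poisson by inversion of the truncated CDF
  u <- stats::runif(n)
  stats::qpois(stats::ppois(0, lambda) + u * (1 - stats::ppois(0, lambda)),
               lambda)
}

.rztgeom <- function(n, prob) stats::rgeom(n, prob) + 1L

#' Generate a synthetic input bundle with known ground truth
#'
#' Samples disease registries, a comorbidity relation (per-Mendelian counts
#' binomial at the configured density), causal gene sets and a heavy-tailed
#' drug-target map; computes the candidate flag from those maps exactly as
#' the pipeline would; then draws each (drug, complex disease) outcome from
#' the logistic model
#' `logit P = beta0 + beta_candidate * is_candidate + category effect +
#' beta_ntargets * n_targets`.
#' Positive pairs receive a trial phase from `phase_probs` (INDICATED pairs
#' populate the indication table), so `investigated_or_indicated`
#' reconstructs the planted outcome exactly.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_world`: `bundle` (a validated
#'   `comorbid_bundle`), `truth` (config, betas, the sampled pair table with
#'   candidate flags and outcomes).
#' @export
generate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  m_ids <- sprintf("M%03d", seq_len(config$n_mendelian))
  c_ids <- sprintf("C%03d", seq_len(config$n_complex))
  d_ids <- sprintf("D%04d", seq_len(config$n_drugs))

  mendelian <- data.frame(id = m_ids,
                          name = paste("mendelian disease", seq_along(m_ids)))
  # category frequencies follow the real registry's skew
  cat_w <- c(cardiovascular = 4, hormonal = 8, immune = 19, neoplasms = 14,
             neurological = 15, ophthalmological = 5)
  category <- sample(names(cat_w), config$n_complex, replace = TRUE,
                     prob = cat_w / sum(cat_w))
  complex <- data.frame(id = c_ids,
                        name = paste("complex disease", seq_along(c_ids)),
                        category = category)

  k_genes <- pmin(.rztpois(config$n_mendelian, config$genes_per_mendelian),
                  config$n_genes)
  mendelian_genes <- data.frame(
    mendelian_id = rep(m_ids, k_genes),
    gene = unlist(lapply(k_genes, function(k) sample(genes, k)),
                  use.names = FALSE))

  k_com <- stats::rbinom(config$n_mendelian, config$n_complex,
                         config$comorbidity_density)
  comorbidity <- data.frame(
    mendelian_id = rep(m_ids, k_com),
    complex_id = unlist(lapply(k_com, function(k) sample(c_ids, k)),
                        use.names = FALSE))

  k_tgt <- pmin(.rztgeom(config$n_drugs, config$targets_per_drug_prob),
                config$n_genes)
  drug_targets <- data.frame(
    drug_id = rep(d_ids, k_tgt),
    gene = unlist(lapply(k_tgt, function(k) sample(genes, k)),
                  use.names = FALSE))
  drug_targets <- unique(drug_targets)

  bundle0 <- suppressWarnings(comorbid_bundle(
    mendelian = mendelian, mendelian_genes = mendelian_genes,
    complex = complex, comorbidity = comorbidity,
    drug_targets = drug_targets))

  universe <- drug_universe(bundle0)
  if (!length(universe))
    stop("infeasible config: no drug targets a Mendelian causal gene",
         call. = FALSE)
  cands <- candidate_sets(bundle0)
  grid <- expand.grid(drug_id = universe, complex_id = c_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ckey <- unique(paste(cands$drug_id, cands$complex_id, sep = "\r"))
  grid$is_candidate <- as.integer(
    paste(grid$drug_id, grid$complex_id, sep = "\r") %in% ckey)
  nt <- n_targets_per_drug(bundle0)
  grid$n_targets <- as.integer(nt[grid$drug_id])
  cat_map <- stats::setNames(complex$category, complex$id)
  grid$category <- unname(cat_map[grid$complex_id])
  ce <- config$category_effects[grid$category]
  ce[is.na(ce)] <- 0
  eta <- config$beta0 + config$beta_candidate * grid$is_candidate +
    unname(ce) + config$beta_ntargets * grid$n_targets
  grid$outcome <- stats::rbinom(nrow(grid), 1L, stats::plogis(eta))

  pos <- grid[grid$outcome == 1L, , drop = FALSE]
  evidence <- NULL
  indicated <- NULL
  if (nrow(pos)) {
    ph <- sample(names(config$phase_probs), nrow(pos), replace = TRUE,
                 prob = config$phase_probs)
    evidence <- data.frame(drug_id = pos$drug_id, complex_id = pos$complex_id,
                           phase = ph)
    indicated <- evidence[evidence$phase == "INDICATED",
                          c("drug_id", "complex_id"), drop = FALSE]
  }
  bundle <- suppressWarnings(comorbid_bundle(
    mendelian = mendelian, mendelian_genes = mendelian_genes,
    complex = complex, comorbidity = comorbidity,
    drug_targets = drug_targets, evidence = evidence,
    indicated = indicated))
  structure(list(bundle = bundle,
                 truth = list(config = config,
                              beta0 = config$beta0,
                              beta_candidate = config$beta_candidate,
                              beta_ntargets = config$beta_ntargets,
                              category_effects = config$category_effects,
                              pair_table = grid)),
            class = "synthetic_world")
}

#' Generate synthetic expression with a planted co-expression module
#'
#' Background genes get independent Gaussian log-expression across tissues;
#' module genes mix a shared latent tissue profile with independent noise so
#' that any two module genes correlate at `module_correlation`. The planted
#' Mendelian gene set and the first cancer's first driver gene sit inside
#' the module; all other driver genes are background. Values are
#' exponentiated, so they are non-negative and right-skewed like real
#' expression summaries.
#'
#' @param config a [synthetic_config()]; needs `n_tissues >= 3`.
#' @return list of class `synthetic_expression`: `expr` (matrix genes x
#'   tissues), `module_genes`, `mendelian_set`, `cancer_sets` (named list,
#'   the first cancer's first driver is in-module), `config`.
#' @export
generate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_tissues < 3L)
    stop("n_tissues must be at least 3", call. = FALSE)
  if (config$module_size < config$mendelian_set_size + 1L)
    stop("module must hold the Mendelian set plus a driver gene",
         call. = FALSE)
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  z <- matrix(stats::rnorm(config$n_genes * config$n_tissues),
              config$n_genes, config$n_tissues,
              dimnames = list(genes, tissues))
  module <- sample(genes, config$module_size)
  rho <- config$module_correlation
  latent <- stats::rnorm(config$n_tissues)
  z[module, ] <- sqrt(rho) * matrix(latent, config$module_size,
                                    config$n_tissues, byrow = TRUE) +
    sqrt(1 - rho) * z[module, ]
  mu <- stats::rnorm(config$n_genes, 1, 1)
  expr <- exp(z + mu)

  mendelian_set <- module[seq_len(config$mendelian_set_size)]
  in_driver <- module[config$mendelian_set_size + 1L]
  background <- setdiff(genes, module)
  cancer_sets <- list()
  for (i in seq_len(config$n_cancers)) {
    k <- min(config$drivers_per_cancer, length(background))
    drv <- sample(background, k)
    if (i == 1L) drv[1L] <- in_driver
    cancer_sets[[sprintf("CA%02d", i)]] <- drv
  }
  structure(list(expr = expr, module_genes = module,
                 mendelian_set = mendelian_set, cancer_sets = cancer_sets,
                 config = config),
            class = "synthetic_expression")
}

#' Write a synthetic world to TSV files
#'
#' Emits the same seven-table layout [read_bundle()] consumes, plus
#' `ground_truth.json` with the planted parameters and candidate/outcome
#' table.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  write_bundle(world$bundle, dir)
  truth <- world$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
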