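#' @title Synthetic cohorts with planted ground truth
#' @description Generates cohorts with the statistical structure the
#'   derivation pipeline assumes: Gaussian log2 intensities; a strongly
#'   bimodal Y-linked sex marker plus further sex-associated genes; smoking-
#'   and pack-year-associated genes; cancer-associated gene modules realized
#'   as shared per-cluster latent factors (single-factor blocks) whose factor
#'   carries a signed mean shift in cancer samples; and pure-noise filler
#'   genes. Clinical attributes mirror the derivation cohort: 223 cancer /
#'   76 benign samples, older cancer patients, heavier smoking history in
#'   cancer, and bronchoscopy diagnostic in ~74% of cancers.
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' Defaults encode the derivation-study conditions where the study states
#' them (sample sizes and class balance, 11 cancer clusters with the six
#' classifier clusters down/down/up/up/down/down in cancer, age and pack-year
#' class differences) and field-realistic testing conventions elsewhere
#' (log2-scale Gaussian noise of sd 1, within-cluster correlation 0.6, unit
#' factor-scale effects).
#'
#' @param n_cancer,n_benign sample counts per class.
#' @param n_genes total gene count (planted + null filler).
#' @param n_clusters number of planted cancer modules.
#' @param genes_per_cluster genes per planted module.
#' @param cluster_effects signed per-cluster cancer effect on the latent
#'   factor (log2 units; the induced gene-level mean shift is the effect times
#'   the factor loading).
#' @param within_cluster_correlation target pairwise correlation of genes in a
#'   module, in `[0, 1)`.
#' @param n_sex_genes,sex_effect count and log2 shift of sex-associated genes
#'   (the first is a strongly bimodal Y-linked-style marker).
#' @param n_smoking_genes,smoking_effect count and log2 shift of
#'   current-vs-former smoking genes.
#' @param n_py_genes,py_effect count and log2 shift of pack-year genes
#'   (shift applied to samples with > 10 pack-years).
#' @param noise_sd gene-level noise sd in log2 units.
#' @param baseline_mean_range range of per-gene baseline means.
#' @param age_mean_cancer,age_mean_benign,age_sd per-class age distributions.
#' @param py_median_cancer,py_median_benign per-class pack-year medians
#'   (gamma-distributed exposure).
#' @param female_prob,current_prob marginal phenotype frequencies.
#' @param bronch_diag_prob probability a cancer case is diagnosed at
#'   bronchoscopy (benign cases are never bronchoscopy-diagnostic).
#' @param classifier_genes if `TRUE`, the planted genes carry the locked
#'   classifier's gene names (six module gene sets, RPS4Y1 bimodal around the
#'   7.5 cutpoint, SLC7A11/CLDN10/TKT down in current smokers,
#'   RUNX1T1 up / AKR1C2 down with > 10 pack-years) with baselines placed so
#'   the locked CFGC formulas produce informative values.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_cancer = 223, n_benign = 76,
                          n_genes = 2000,
                          n_clusters = 11, genes_per_cluster = 20,
                          cluster_effects = c(-1, -1, 1, 1, -1, 1, 1, -1, -1, -1, 1),
                          within_cluster_correlation = 0.6,
                          n_sex_genes = 20, sex_effect = 1.5,
                          n_smoking_genes = 50, smoking_effect = 2,
                          n_py_genes = 30, py_effect = 1.5,
                          noise_sd = 1,
                          baseline_mean_range = c(4, 10),
                          age_mean_cancer = 65, age_mean_benign = 56, age_sd = 10,
                          py_median_cancer = 43, py_median_benign = 30,
                          female_prob = 123 / 299, current_prob = 127 / 299,
                          bronch_diag_prob = 165 / 223,
                          classifier_genes = FALSE) {
  cfg <- as.list(environment())
  if (length(cfg$cluster_effects) == 1L)
    cfg$cluster_effects <- rep(cfg$cluster_effects, cfg$n_clusters)
  if (length(cfg$cluster_effects) != cfg$n_clusters)
    stop("cluster_effects must have one (signed) value per cluster")
  if (cfg$within_cluster_correlation < 0 || cfg$within_cluster_correlation >= 1)
    stop("within_cluster_correlation must lie in [0, 1)")
  counts <- c(cfg$n_cancer, cfg$n_benign, cfg$n_genes, cfg$n_clusters,
              cfg$genes_per_cluster)
  if (any(counts <= 0)) stop("all counts must be positive")
  planted <- cfg$n_clusters * cfg$genes_per_cluster + cfg$n_sex_genes +
    cfg$n_smoking_genes + cfg$n_py_genes
  if (cfg$n_genes < planted)
    stop(sprintf("n_genes (%d) smaller than planted gene count (%d)",
                 cfg$n_genes, planted))
  structure(cfg, class = "cohort_config")
}

# baselines that spread the locked CFGC logistic forms across (0,1)
locked_cfgc_baselines <- function(cfg) {
  list(SLC7A11 = 8, CLDN10 = 10.5, TKT = 10.64,    # former-smoker means
       RUNX1T1 = 4, AKR1C2 = 6.28)                 # <= 10 pack-year means
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a cohort with ground truth
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the generator is bit-reproducible given the seed
#'   (R's default Mersenne-Twister PRNG).
#' @return list with `dataset` (an `airway_dataset`) and `truth` (planted
#'   cluster memberships, covariate gene lists, per-sample latent factors,
#'   the config and seed).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config
  n <- cfg$n_cancer + cfg$n_benign
  cancer <- rep(c(1L, 0L), c(cfg$n_cancer, cfg$n_benign))

  sample_id <- sprintf("S%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$female_prob, "female", "male")
  smoking <- ifelse(stats::runif(n) < cfg$current_prob, "current", "former")
  shape <- 2.2
  py_scale <- ifelse(cancer == 1L, cfg$py_median_cancer, cfg$py_median_benign) /
    stats::qgamma(0.5, shape)
  pack_years <- stats::rgamma(n, shape = shape, scale = py_scale)
  age <- rtrunc_norm(n, ifelse(cancer == 1L, cfg$age_mean_cancer,
                               cfg$age_mean_benign), cfg$age_sd, 35, 90)
  bronch <- ifelse(cancer == 1L & stats::runif(n) < cfg$bronch_diag_prob, 1L, 0L)
  pheno <- data.frame(sample_id = sample_id, cancer_status = cancer,
                      sex = sex, smoking_status = smoking,
                      pack_years = pack_years, age = round(age, 1),
                      bronchoscopy_diagnostic = bronch,
                      stringsAsFactors = FALSE)

  locked <- if (cfg$classifier_genes) locked_classifier()
  cl_sizes <- rep(cfg$genes_per_cluster, cfg$n_clusters)
  gene_names <- character(0)
  cluster_assignment <- integer(0)
  for (k in seq_len(cfg$n_clusters)) {
    nm <- sprintf("CA%d_G%02d", k, seq_len(cl_sizes[k]))
    if (cfg$classifier_genes) {
      ca <- paste0("CA", k)
      if (ca %in% names(locked$clusters)) {
        mem <- locked$clusters[[ca]]
        nm[seq_along(mem)] <- mem
      }
    }
    gene_names <- c(gene_names, nm)
    cluster_assignment <- c(cluster_assignment, rep(k, cl_sizes[k]))
  }
  sex_names <- sprintf("SEX_G%02d", seq_len(cfg$n_sex_genes))
  smk_names <- sprintf("SMK_G%02d", seq_len(cfg$n_smoking_genes))
  py_names <- sprintf("PY_G%02d", seq_len(cfg$n_py_genes))
  if (cfg$classifier_genes) {
    sex_names[1] <- "RPS4Y1"
    smk_names[seq_len(3)] <- c("SLC7A11", "CLDN10", "TKT")
    py_names[seq_len(2)] <- c("RUNX1T1", "AKR1C2")
  }
  n_null <- cfg$n_genes - length(gene_names) - cfg$n_sex_genes -
    cfg$n_smoking_genes - cfg$n_py_genes
  null_names <- sprintf("NULL_G%04d", seq_len(n_null))
  all_genes <- c(gene_names, sex_names, smk_names, py_names, null_names)

  mu <- stats::runif(cfg$n_genes, cfg$baseline_mean_range[1],
                     cfg$baseline_mean_range[2])
  names(mu) <- all_genes
  x <- matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
              nrow = cfg$n_genes, dimnames = list(all_genes, sample_id))

  rho <- cfg$within_cluster_correlation
  loading <- cfg$noise_sd * sqrt(rho / (1 - rho))
  factors <- matrix(stats::rnorm(cfg$n_clusters * n), nrow = cfg$n_clusters,
                    dimnames = list(paste0("CA", seq_len(cfg$n_clusters)),
                                    sample_id))
  factors <- factors + cfg$cluster_effects * matrix(rep(cancer, each = cfg$n_clusters),
                                                    nrow = cfg$n_clusters)
  for (k in seq_len(cfg$n_clusters)) {
    rows <- which(cluster_assignment == k)
    x[rows, ] <- x[rows, ] + matrix(rep(loading * factors[k, ], each = length(rows)),
                                    nrow = length(rows))
  }

  female <- as.numeric(sex == "female")
  current <- as.numeric(smoking == "current")
  heavy <- as.numeric(pack_years > 10)
  sgn <- function(j) ifelse(j %% 2 == 0, -1, 1)
  for (j in seq_len(cfg$n_sex_genes))
    x[sex_names[j], ] <- x[sex_names[j], ] + sgn(j) * cfg$sex_effect * female
  for (j in seq_len(cfg$n_smoking_genes))
    x[smk_names[j], ] <- x[smk_names[j], ] + sgn(j) * cfg$smoking_effect * current
  for (j in seq_len(cfg$n_py_genes))
    x[py_names[j], ] <- x[py_names[j], ] + sgn(j) * cfg$py_effect * heavy

  if (cfg$classifier_genes) {
    base <- locked_cfgc_baselines(cfg)
    # bimodal Y-marker: female well below the 7.5 cutpoint, male well above
    x["RPS4Y1", ] <- stats::rnorm(n, sd = 0.5) + ifelse(female == 1, 5, 10)
    mu["RPS4Y1"] <- 0
    for (g in c("SLC7A11", "CLDN10", "TKT")) {
      x[g, ] <- stats::rnorm(n, sd = cfg$noise_sd) + base[[g]] -
        cfg$smoking_effect * current
      mu[g] <- 0
    }
    x["RUNX1T1", ] <- stats::rnorm(n, sd = cfg$noise_sd) + base$RUNX1T1 +
      cfg$py_effect * heavy
    x["AKR1C2", ] <- stats::rnorm(n, sd = cfg$noise_sd) + base$AKR1C2 -
      cfg$py_effect * heavy
    mu[c("RUNX1T1", "AKR1C2")] <- 0
  }
  x <- x + mu

  truth <- list(cluster_genes = split(gene_names, cluster_assignment),
                cluster_assignment = stats::setNames(cluster_assignment, gene_names),
                sex_genes = sex_names, smoking_genes = smk_names,
                py_genes = py_names, null_genes = null_names,
                factors = factors, config = cfg, seed = seed)
  names(truth$cluster_genes) <- paste0("CA", names(truth$cluster_genes))
  list(dataset = align_dataset(x, pheno), truth = truth)
}

#' Apply a simulated platform shift
#'
#' Adds an independent gene-wise constant offset (drawn once per gene) to
#' every sample's expression and optionally removes genes entirely, emulating
#' measurement on a second microarray platform where some classifier genes
#' have no probeset.
#'
#' @param d an `airway_dataset`.
#' @param offsets_sd sd of the per-gene offsets (log2 units).
#' @param dropped_genes genes to remove (must exist in `d`).
#' @param seed integer seed for the offsets.
#' @return the shifted `airway_dataset`; per-gene offsets attached as
#'   attribute `"offsets"`.
#' @export
simulate_platform_shift <- function(d, offsets_sd = 1,
                                    dropped_genes = character(0), seed = 1) {
  stopifnot(is_airway_dataset(d))
  unknown <- setdiff(dropped_genes, rownames(d$expression))
  if (length(unknown))
    stop("dropped gene(s) not in dataset: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  offsets <- stats::rnorm(nrow(d$expression), sd = offsets_sd)
  names(offsets) <- rownames(d$expression)
  x <- d$expression + offsets
  keep <- setdiff(rownames(x), dropped_genes)
  out <- structure(list(expression = x[keep, , drop = FALSE],
                        phenotypes = d$phenotypes),
                   class = "airway_dataset")
  attr(out, "offsets") <- offsets
  out
}

#' Simulate feature vectors and outcomes from a classifier
#'
#' Draws classifier-level feature vectors (age, GG, GS, GPY and the CA
#' cluster means) from field-realistic marginal distributions, computes the
#' model score, and draws cancer status as Bernoulli(score). Used for
#' parameter-recovery studies of the fitting procedure.
#'
#' @param model an `airway_classifier`.
#' @param n number of samples.
#' @param seed integer seed.
#' @param ca_means named numeric vector of CA feature means (defaults chosen
#'   to give a cancer prevalence near the derivation cohort's 75%).
#' @return list with `features` (data.frame), `status` (0/1), `score`.
#' @export
simulate_classifier_features <- function(model, n = 2000, seed = 1,
                                         ca_means = c(CA1 = 9, CA2 = 9, CA4 = 8,
                                                      CA7 = 6.5, CA9 = 8, CA10 = 9)) {
  set.seed(seed)
  bimodal <- function(n, p_hi) {
    hi <- stats::runif(n) < p_hi
    ifelse(hi, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  }
  fv <- data.frame(age = rtrunc_norm(n, 62, 10, 35, 90),
                   GG = as.numeric(stats::runif(n) < 0.41),
                   GS = bimodal(n, 0.42),
                   GPY = bimodal(n, 0.80))
  ca <- grep("^CA", names(model$coefficients), value = TRUE)
  for (nm in ca)
    fv[[nm]] <- stats::rnorm(n, mean = if (nm %in% names(ca_means)) ca_means[[nm]] else 7,
                             sd = 1)
  score <- classifier_score(model, fv)
  status <- as.integer(stats::runif(n) < score)
  list(features = fv, status = status, score = score)
}
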