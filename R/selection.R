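#' @title Cancer gene selection, clustering, and cluster reduction
#' @description Genes carrying cancer signal beyond the clinical covariates
#'   are found by regressing the residuals of a covariate-only ("baseline")
#'   logistic model on each gene's expression with a moderated t; selected
#'   genes are grouped by average-linkage hierarchical clustering on
#'   1 - Pearson correlation; each cluster is reduced to 2-4 representative
#'   genes whose running mean tracks the full cluster mean; and repeated
#'   10%-holdout cross-validation picks the cluster subset that best predicts
#'   cancer in the context of the covariates.
#' @name cancer-gene-selection
NULL

#' Fit the covariate-only baseline model
#'
#' Logistic regression of cancer status on GG, GS, GPY and age. Its response
#' residuals (observed status minus fitted probability) are the dependent
#' variable for cancer gene selection.
#'
#' @param d an `airway_dataset`.
#' @param covariates data.frame with per-sample columns `GG`, `GS`, `GPY`
#'   (rows in `d` sample order).
#' @return list with the `glm` `fit`, `fitted` probabilities, and response
#'   `residuals`.
#' @export
fit_baseline <- function(d, covariates) {
  stopifnot(is_airway_dataset(d))
  y <- d$phenotypes$cancer_status
  if (length(unique(y)) < 2L)
    stop("baseline model needs both cancer and benign samples")
  dat <- data.frame(y = y, GG = covariates$GG, GS = covariates$GS,
                    GPY = covariates$GPY, age = d$phenotypes$age)
  fit <- stats::glm(y ~ GG + GS + GPY + age, family = stats::binomial(),
                    data = dat)
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10))
    stop("baseline model shows (near-)perfect separation; ",
         "consider a penalized fit of the covariates")
  list(fit = fit, fitted = unname(p), residuals = unname(y - p))
}

#' Select cancer-associated genes
#'
#' Moderated t of the baseline residuals against each gene's expression
#' (genes as predictor, so residual variances share a scale); genes with
#' |T| above the cutoff are kept with their signed scores.
#'
#' @param d an `airway_dataset`.
#' @param residuals baseline response residuals, one per sample.
#' @param t_cut selection cutoff on |moderated T| (default 2.7).
#' @return data.frame (`gene`, `effect`, `t`, `p`) ordered by decreasing |t|.
#' @export
select_cancer_genes <- function(d, residuals, t_cut = 2.7) {
  stopifnot(is_airway_dataset(d))
  if (length(residuals) != ncol(d$expression))
    stop("residuals must align with the dataset samples")
  mt <- moderated_t(d$expression, residuals, genes_as = "predictor")
  sel <- mt[abs(mt$t) > t_cut, c("gene", "effect", "t", "p")]
  sel[order(-abs(sel$t)), , drop = FALSE]
}

#' Cluster selected genes by expression correlation
#'
#' Average-linkage hierarchical clustering on distance 1 - Pearson correlation
#' (signed, so anti-correlated genes land in different clusters), cut to the
#' requested cluster count. Genes are sorted internally before linkage so the
#' result does not depend on input order.
#'
#' @param d an `airway_dataset`.
#' @param genes gene symbols to cluster (>= 2).
#' @param n_clusters requested cluster count (capped at the gene count).
#' @return list with `assignment` (named integer vector in input gene order),
#'   `tree` (the `hclust` object), `height` (the implied cut height).
#' @export
cluster_genes <- function(d, genes, n_clusters = 11) {
  stopifnot(is_airway_dataset(d))
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("need at least 2 genes to cluster")
  if (n_clusters > length(genes))
    stop("fewer genes than requested clusters")
  ord <- order(genes)
  x <- d$expression[genes[ord], , drop = FALSE]
  dmat <- stats::as.dist(1 - stats::cor(t(x)))
  tree <- stats::hclust(dmat, method = "average")
  assignment <- stats::cutree(tree, k = n_clusters)
  h <- sort(tree$height, decreasing = TRUE)
  height <- if (n_clusters == 1L) Inf else mean(h[c(n_clusters - 1L, n_clusters)])
  list(assignment = assignment[genes], tree = tree, height = height)
}

#' Reduce a cluster to representative genes
#'
#' Greedy forward selection: start from the gene most correlated with the full
#' cluster mean, then repeatedly add the gene that maximizes the correlation
#' of the running subset mean with the full cluster mean; stop once that
#' correlation reaches `r_target` (with at least 2 genes) or at `k_max` genes.
#'
#' @param d an `airway_dataset`.
#' @param genes the cluster's member genes (>= 2).
#' @param k_max maximum representatives (default 4).
#' @param r_target correlation target (default 0.95).
#' @return list with `genes` (representatives) and `correlation` of their mean
#'   with the full cluster mean.
#' @export
reduce_cluster <- function(d, genes, k_max = 4, r_target = 0.95) {
  stopifnot(is_airway_dataset(d))
  genes <- as.character(genes)
  if (length(genes) < 2L) stop("cluster must have at least 2 genes")
  x <- d$expression[genes, , drop = FALSE]
  target <- colMeans(x)
  if (length(genes) == 2L)
    return(list(genes = genes, correlation = 1))
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
    stats::cor(a, b)
  }
  chosen <- genes[which.max(vapply(genes, function(g) safe_cor(x[g, ], target),
                                   numeric(1)))]
  repeat {
    r <- safe_cor(colMeans(x[chosen, , drop = FALSE]), target)
    if ((r >= r_target && length(chosen) >= 2L) || length(chosen) >= k_max ||
        length(chosen) == length(genes))
      break
    rest <- setdiff(genes, chosen)
    gains <- vapply(rest, function(g)
      safe_cor(colMeans(x[c(chosen, g), , drop = FALSE]), target), numeric(1))
    chosen <- c(chosen, rest[which.max(gains)])
  }
  list(genes = chosen,
       correlation = safe_cor(colMeans(x[chosen, , drop = FALSE]), target))
}

stratified_holdout <- function(y, holdout) {
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  n1 <- max(1L, round(length(idx1) * holdout))
  n0 <- max(1L, round(length(idx0) * holdout))
  sort(c(sample(idx1, n1), sample(idx0, n0)))
}

#' Select the cluster subset by cross-validated AUC
#'
#' Forward selection over cluster-mean features added to the covariates
#' (GG, GS, GPY, age), scored by repeated stratified 10%-holdout
#' cross-validated AUC of a logistic fit; keeps adding the cluster giving the
#' largest mean CV AUC while the improvement is positive. Ties break toward
#' fewer clusters, then the lower cluster index.
#'
#' @param d an `airway_dataset`.
#' @param cluster_features samples x clusters matrix of (reduced) cluster
#'   means, columns named `CA<k>`.
#' @param covariates data.frame with `GG`, `GS`, `GPY` per sample.
#' @param holdout holdout fraction per repetition (default 0.10).
#' @param reps repetitions (default 100).
#' @param seed fold seed.
#' @param min_gain smallest mean-CV-AUC improvement worth another cluster.
#' @return list with `chosen` (cluster column names, possibly empty),
#'   `cv_auc` (mean CV AUC of the chosen model) and `baseline_auc`
#'   (covariates-only mean CV AUC).
#' @export
select_cluster_subset <- function(d, cluster_features, covariates,
                                  holdout = 0.10, reps = 100, seed = 1,
                                  min_gain = 0.005) {
  stopifnot(is_airway_dataset(d))
  y <- d$phenotypes$cancer_status
  base <- data.frame(GG = covariates$GG, GS = covariates$GS,
                     GPY = covariates$GPY, age = d$phenotypes$age)
  cluster_features <- as.matrix(cluster_features)

  set.seed(seed)
  folds <- replicate(reps, stratified_holdout(y, holdout), simplify = FALSE)
  cv_auc <- function(cols) {
    dat <- if (length(cols)) cbind(base, cluster_features[, cols, drop = FALSE])
    else base
    aucs <- vapply(folds, function(test) {
      train <- setdiff(seq_along(y), test)
      fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(),
                   data = data.frame(y = y[train], dat[train, , drop = FALSE],
                                     check.names = FALSE)))
      pred <- suppressWarnings(
        stats::predict(fit, newdata = dat[test, , drop = FALSE],
                       type = "response"))
      unname(roc_auc(pred, y[test])$auc)
    }, numeric(1))
    mean(aucs)
  }

  chosen <- character(0)
  best <- cv_auc(chosen)
  baseline_auc <- best
  remaining <- colnames(cluster_features)
  while (length(remaining)) {
    scores <- vapply(remaining, function(cl) cv_auc(c(chosen, cl)), numeric(1))
    k <- which.max(scores)  # which.max takes the first (lowest index) on ties
    if (scores[k] - best <= min_gain) break
    chosen <- c(chosen, remaining[k])
    best <- scores[k]
    remaining <- remaining[-k]
  }
  list(chosen = chosen, cv_auc = best, baseline_auc = baseline_auc)
}
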