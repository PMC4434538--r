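# Independent oracles and fixture builders shared across tests.
# Every oracle here is coded from first principles (literal published
# constants, brute-force enumeration, closed forms) and never calls the
# package functions it is used to check.

# --- brute-force Fisher oracles (probability-mass ordering) -----------------

fisher_2x2_oracle <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  a <- 0:min(rs[1], cs[1])
  keep <- (rs[1] - a) <= cs[2]
  a <- a[keep]
  pr <- dhyper(a, cs[1], cs[2], rs[1])
  pobs <- dhyper(m[1, 1], cs[1], cs[2], rs[1])
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# r x 2 tables: enumerate the first column cell-by-cell
fisher_rx2_oracle <- function(m) {
  rs <- rowSums(m); c1 <- colSums(m)[1]; n <- sum(m)
  r <- nrow(m)
  tab_prob <- function(col1) {
    exp(sum(lchoose(rs, col1)) - lchoose(n, c1))
  }
  cells <- vector("list", r - 1)
  probs <- numeric(0)
  rec <- function(i, left, acc) {
    if (i == r) {
      if (left >= 0 && left <= rs[r]) probs <<- c(probs, tab_prob(c(acc, left)))
      return(invisible())
    }
    for (v in 0:min(rs[i], left)) rec(i + 1, left - v, c(acc, v))
  }
  rec(1, c1, integer(0))
  pobs <- tab_prob(m[, 1])
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- brute-force AUC: concordant pairs plus half-ties ------------------------

auc_pairs_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# --- independent scorer: Table 2 arithmetic with literal constants ----------

locked_score_oracle <- function(age, GG, GS, GPY, CA1, CA2, CA4, CA7, CA9, CA10) {
  y <- 3.3173 + 0.0623 * age + 0.5450 * GG + 0.1661 * GS + 3.0205 * GPY -
    0.4406 * CA1 - 0.3402 * CA2 + 0.1725 * CA4 + 0.5670 * CA7 -
    0.3160 * CA9 - 0.3791 * CA10
  exp(y) / (1 + exp(y))
}

gg_oracle <- function(rps4y1) ifelse(rps4y1 < 7.5, 1, 0)

gs_oracle <- function(slc7a11, clnd10, tkt) {
  x <- 40.8579 - 0.4462 * slc7a11 - 2.1298 * clnd10 - 1.8256 * tkt
  exp(x) / (1 + exp(x))
}

gpy_oracle <- function(runx1t1, akr1c2) {
  x <- -5.1429 + 2.1891 * runx1t1 - 0.9506 * akr1c2
  exp(x) / (1 + exp(x))
}

random_feature_table <- function(n, seed) {
  set.seed(seed)
  data.frame(age = runif(n, 35, 90),
             GG = rbinom(n, 1, 0.5),
             GS = runif(n),
             GPY = runif(n),
             CA1 = runif(n, 2, 14), CA2 = runif(n, 2, 14),
             CA4 = runif(n, 2, 14), CA7 = runif(n, 2, 14),
             CA9 = runif(n, 2, 14), CA10 = runif(n, 2, 14))
}

# --- tiny fixture builders ---------------------------------------------------

make_expression <- function(n_genes = 5, n_samples = 4, seed = 1,
                            genes = sprintf("G%02d", seq_len(n_genes)),
                            samples = sprintf("S%02d", seq_len(n_samples))) {
  set.seed(seed)
  matrix(round(runif(n_genes * n_samples, 2, 14), 4),
         nrow = n_genes, dimnames = list(genes, samples))
}

make_phenotypes <- function(n = 4, seed = 1,
                            samples = sprintf("S%02d", seq_len(n))) {
  set.seed(seed)
  data.frame(sample_id = samples,
             cancer_status = rep_len(c(1L, 0L), n),
             sex = rep_len(c("female", "male"), n),
             smoking_status = rep_len(c("current", "former"), n),
             pack_years = round(runif(n, 1, 80), 1),
             age = round(runif(n, 40, 85), 1),
             bronchoscopy_diagnostic = rep_len(c(1L, 0L, 0L, 0L), n),
             stringsAsFactors = FALSE)
}

# desk-size simulation config: keeps the 11-cluster structure (so the locked
# gene names fit when classifier_genes = TRUE) but plants fewer genes
small_config <- function(n_cancer = 30, n_benign = 20, n_genes = 300, ...) {
  cohort_config(n_cancer = n_cancer, n_benign = n_benign, n_genes = n_genes,
                genes_per_cluster = 4, n_sex_genes = 4, n_smoking_genes = 6,
                n_py_genes = 4, ...)
}

make_dataset <- function(n_genes = 5, n_samples = 6, seed = 1) {
  align_dataset(make_expression(n_genes, n_samples, seed),
                make_phenotypes(n_samples, seed + 1))
}
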