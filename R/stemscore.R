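#' The published 11-gene APL stemness panel
#'
#' The default stemness panel: eleven genes whose mean expression defines
#' the APL stemness score.
#'
#' @param score_scale Expression scale the score is computed on
#'   (documentation field; [stemness_score()] applies log2(TPM + 1)).
#' @return A `stemness_panel`: list with `gene_list` (length 11) and
#'   `score_scale`.
#' @export
apl_stemness_panel <- function(score_scale = "log2(TPM+1)") {
  structure(list(
    gene_list = c("SKAP2", "IL1RAP", "PLD1", "HOPX", "TRIM47", "MAP2K1",
                  "TNFSF4", "OLFML2A", "P2RY14", "NPTX2", "RALA"),
    score_scale = score_scale), class = "stemness_panel")
}

#' Select candidate genes for the stemness panel
#'
#' Combines two views of the stem-like population: the quantity-driven
#' set (genes passing the stem-vs-other-branches thresholds while barely
#' detected outside stem-like cells, i.e. exclusively expressed there)
#' and the quality-driven set (significant DEGs of stem-like cells
#' against normal HSPCs). The default pool is the quality-driven set.
#'
#' @param stem_vs_branches [find_markers()] table, stem-like vs the
#'   other APL branches.
#' @param stem_vs_hspc [find_markers()] table, stem-like vs normal HSPCs.
#' @param exclusivity Maximum detection fraction outside stem-like cells
#'   for the quantity-driven set (default 0.1).
#' @param combine Pool definition: `"quality"` (default), `"union"`, or
#'   `"intersect"`.
#'
#' @return A `candidate_pool`: list with `quantity_driven`,
#'   `quality_driven`, `pool`, `settings`.
#' @export
select_candidates <- function(stem_vs_branches, stem_vs_hspc,
                              exclusivity = 0.1,
                              combine = c("quality", "union", "intersect")) {
  combine <- match.arg(combine)
  quantity <- stem_vs_branches$gene[stem_vs_branches$passes_threshold &
                                      stem_vs_branches$pct_group2 <= exclusivity]
  quality <- stem_vs_hspc$gene[stem_vs_hspc$passes_threshold]
  pool <- switch(combine,
                 quality = quality,
                 union = union(quantity, quality),
                 intersect = intersect(quantity, quality))
  if (length(pool) == 0) {
    abort(sprintf(paste0(
      "empty candidate pool (quantity-driven: %d genes, quality-driven: %d, ",
      "combine = '%s')."), length(quantity), length(quality), combine))
  }
  structure(list(quantity_driven = quantity, quality_driven = quality,
                 pool = pool,
                 settings = list(exclusivity = exclusivity, combine = combine)),
            class = "candidate_pool")
}

#' Label samples by top-decile stem-like proportion
#'
#' Label 1 for samples whose estimated stem-like proportion reaches the
#' `(1 - q)` quantile; ties at the boundary are all labeled 1 (so the
#' positive class may exceed the nominal fraction).
#'
#' @param stem_proportions Named numeric vector or tibble (sample_id,
#'   proportion).
#' @param q Top fraction labeled positive (default 0.10).
#'
#' @return Tibble: sample_id, proportion, label (integer 0/1).
#' @export
label_top_decile <- function(stem_proportions, q = 0.10) {
  if (is.data.frame(stem_proportions)) {
    stem_proportions <- setNames(stem_proportions$proportion,
                                 stem_proportions$sample_id)
  }
  if (length(stem_proportions) < 10) abort("top-decile labeling needs >= 10 samples.")
  if (length(unique(stem_proportions)) == 1) abort("all proportions identical.")
  thr <- unname(quantile(stem_proportions, 1 - q))
  lab <- as.integer(stem_proportions >= thr)
  tibble(sample_id = names(stem_proportions) %||%
           sprintf("S%03d", seq_along(stem_proportions)),
         proportion = unname(stem_proportions), label = lab)
}

#' Fit a LASSO gene panel
#'
#' L1-penalized logistic regression of the binary labels on candidate
#' gene expression, with the penalty chosen by 10-fold cross-validation
#' (minimum CV deviance by default; the one-standard-error rule as an
#' option). The panel is the set of genes with nonzero coefficients at
#' the chosen penalty.
#'
#' @param expression Candidate-gene x sample matrix (any monotone scale;
#'   log2(TPM+1) recommended).
#' @param labels Binary 0/1 vector, one per sample (column).
#' @param folds CV folds (default 10).
#' @param seed Seed controlling the CV fold assignment.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#'
#' @return A `stemness_model`: list with `selected_genes`,
#'   `coefficients` (named, nonzero, excluding intercept), `lambda`,
#'   `lambda_rule`, `cv_folds`, `seed`, `family`, and the underlying
#'   `cv_fit`.
#' @export
fit_lasso_panel <- function(expression, labels, folds = 10, seed = 1L,
                            lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("labels contain a single class.")
  if (min(table(labels)) < 2) abort("need >= 2 samples per class.")
  X <- t(as.matrix(expression))
  zv <- apply(X, 2, sd) == 0
  if (any(zv)) {
    warn(sprintf("dropping %d zero-variance candidate gene(s).", sum(zv)))
    X <- X[, !zv, drop = FALSE]
  }
  cv <- withr::with_seed(seed,
    glmnet::cv.glmnet(X, labels, family = "binomial", nfolds = folds,
                      type.measure = "deviance"))
  s <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(coef(cv, s = s))[, 1]
  co <- co[setdiff(names(co), "(Intercept)")]
  sel <- co[co != 0]
  structure(list(selected_genes = names(sel), coefficients = sel,
                 lambda = s, lambda_rule = lambda_rule, cv_folds = folds,
                 seed = seed, family = "binomial", cv_fit = cv),
            class = "stemness_model")
}

#' @export
print.stemness_model <- function(x, ...) {
  cat(sprintf("<stemness_model> %d genes at lambda = %.4g (%s rule, %d-fold CV)\n",
              length(x$selected_genes), x$lambda, x$lambda_rule, x$cv_folds))
  invisible(x)
}

#' Compute the APL stemness score
#'
#' The score of a sample is the arithmetic mean, over the panel genes
#' present in the table, of log2(TPM + 1). Panel genes missing from the
#' table are excluded with a warning reporting the count.
#'
#' @param bulk Genes x samples TPM matrix (gene rownames), or a tibble
#'   whose first column is the gene id.
#' @param panel A [apl_stemness_panel()] / [fit_lasso_panel()] object, or
#'   a character vector of genes. Default: the published 11-gene panel.
#'
#' @return Tibble: sample_id, score, n_panel_genes_used, n_panel_genes_missing.
#' @export
stemness_score <- function(bulk, panel = apl_stemness_panel()) {
  genes <- if (inherits(panel, "stemness_panel")) panel$gene_list
           else if (inherits(panel, "stemness_model")) panel$selected_genes
           else as.character(panel)
  if (length(genes) == 0) abort("empty panel.")
  B <- as_bulk_matrix(bulk)
  present <- intersect(genes, rownames(B))
  n_missing <- length(genes) - length(present)
  if (length(present) == 0) abort("no panel genes present in the table.")
  if (n_missing > 0) {
    warn(sprintf("%d of %d panel gene(s) missing from the table; excluded.",
                 n_missing, length(genes)))
  }
  sc <- colMeans(log2(B[present, , drop = FALSE] + 1))
  tibble(sample_id = colnames(B), score = unname(sc),
         n_panel_genes_used = length(present),
         n_panel_genes_missing = n_missing)
}

# Log-rank O/E/V accumulation for two groups (g1 logical).
logrank_oev <- function(time, event, g1) {
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0; O2 <- 0; E2 <- 0
  for (t in ut) {
    at <- time >= t
    nt <- sum(at); n1 <- sum(at & g1)
    dt <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1; O2 <- O2 + (dt - d1)
    E1 <- E1 + dt * n1 / nt; E2 <- E2 + dt * (nt - n1) / nt
    if (nt > 1) V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  list(O1 = O1, E1 = E1, O2 = O2, E2 = E2, V = V)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with 1 degree of freedom, computed from
#' the per-event-time hypergeometric observed/expected decomposition.
#'
#' @param survival_data Tibble with columns `time` and `event` (1 =
#'   event, 0 = censored).
#' @param groups Binary/two-level vector, one per row (`TRUE`/1 = group
#'   1, e.g. the high-score group).
#'
#' @return A `logrank_result`: list with `chi_square`, `df`, `p_value`,
#'   and `groups` (tibble: group, n, observed, expected).
#' @export
logrank_test <- function(survival_data, groups) {
  if (length(unique(groups)) != 2) abort("both groups must be non-empty.")
  g1 <- if (is.logical(groups)) groups else groups == sort(unique(groups))[2]
  if (sum(survival_data$event) < 1) abort("need at least one event.")
  oev <- logrank_oev(survival_data$time, survival_data$event, g1)
  chi <- if (oev$V > 0) (oev$O1 - oev$E1)^2 / oev$V else 0
  structure(list(
    chi_square = chi, df = 1L, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
    groups = tibble(group = c("group1", "group2"), n = c(sum(g1), sum(!g1)),
                    observed = c(oev$O1, oev$O2), expected = c(oev$E1, oev$E2))),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4g (df = %d), p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Maximally selected log-rank cutoff
#'
#' Evaluates the standardized log-rank statistic |O - E| / sqrt(V) at
#' every distinct score within the given quantile range (candidates that
#' leave a group empty are skipped) and returns the maximizing cutoff —
#' the smallest on ties. The high group is `score > cutoff`. No
#' small-sample p-value correction is applied to the maximal statistic:
#' the cutoff is the deliverable, and the downstream p-value from
#' [logrank_test()] at this cutoff is optimistic.
#'
#' @param scores Numeric vector, one per subject.
#' @param survival_data Tibble with `time`, `event`, rows aligned with
#'   `scores`.
#' @param quantile_range Score quantiles delimiting the candidate
#'   cutoffs (default 0.10-0.90).
#'
#' @return A `cutoff_result`: list with `cutoff`,
#'   `max_standardized_statistic`, `search_range`, `candidates` (tibble
#'   cutoff, statistic), and `groups` (tibble sample index, group).
#' @export
maxstat_cutoff <- function(scores, survival_data, quantile_range = c(0.10, 0.90)) {
  if (length(unique(scores)) == 1) abort("constant scores: no cutoff exists.")
  if (length(scores) < 10) abort("maxstat needs >= 10 samples.")
  if (sum(survival_data$event) < 2) abort("maxstat needs >= 2 events.")
  qs <- quantile(scores, quantile_range)
  cand <- sort(unique(scores))
  cand <- cand[cand >= qs[1] & cand <= qs[2] & cand < max(scores)]
  if (length(cand) == 0) abort("no candidate cutoffs inside the quantile range.")
  z <- vapply(cand, function(cc) {
    oev <- logrank_oev(survival_data$time, survival_data$event, scores > cc)
    if (oev$V <= 0) return(NA_real_)
    abs(oev$O1 - oev$E1) / sqrt(oev$V)
  }, 0)
  ok <- !is.na(z)
  cand <- cand[ok]; z <- z[ok]
  if (length(cand) == 0) abort("log-rank variance degenerate at every candidate.")
  best <- cand[which.max(z)]  # which.max returns the first (smallest) on ties
  structure(list(cutoff = best, max_standardized_statistic = max(z),
                 search_range = unname(qs),
                 candidates = tibble(cutoff = cand, statistic = z),
                 groups = tibble(index = seq_along(scores),
                                 group = ifelse(scores > best, "high", "low"))),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cutoff = %.4g, max standardized statistic = %.3f\n",
              x$cutoff, x$max_standardized_statistic))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors, via
#' `survival::survfit`.
#'
#' @param survival_data Tibble with `time` and `event`.
#' @param groups Optional grouping vector (one level per row).
#'
#' @return A `km_curve` tibble: (group,) time, n_risk, n_event,
#'   n_censor, estimate, std_error (Greenwood, on the survival scale).
#' @export
km_curve <- function(survival_data, groups = NULL) {
  if (nrow(survival_data) == 0) abort("empty survival table.")
  if (any(survival_data$time < 0)) abort("negative survival times.")
  df <- data.frame(time = survival_data$time, event = survival_data$event)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                  n_censor = fit$n.censor, estimate = fit$surv,
                  std_error = fit$std.err * fit$surv)
  } else {
    df$group <- groups
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
    out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  estimate = fit$surv, std_error = fit$std.err * fit$surv)
  }
  structure(out, class = c("km_curve", class(out)))
}
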