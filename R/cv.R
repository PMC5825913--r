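#' Repeated k-fold cross-validation of genomic prediction
#'
#' The standard evaluation design for genomic selection: per repeat, the
#' genotypes are randomly partitioned into `n_folds` mutually exclusive,
#' near-equal subsets (sizes differ by at most one); each fold in turn is
#' held out, the model is refit on the rest, and predictive ability is the
#' Pearson correlation between predicted and observed phenotypes of the
#' held-out genotypes. With 5 folds and 10 repeats this yields 50
#' evaluations, whose mean is reported.
#'
#' @param model `"rrblup"`, `"brr"`, `"bl"`, `"mean"` (predicts the training
#'   mean - a null baseline), or a function `f(y_train, M_train)` returning
#'   an object with a `predict(fit, M_new)` method.
#' @param y phenotype vector.
#' @param M n x m dosage matrix aligned with `y`.
#' @param n_folds folds per repeat (>= 2, default 5).
#' @param n_repeats repeats (default 10).
#' @param seed RNG seed for the partitions (and, for Bayesian models, the
#'   chains).
#' @param ... passed to the model-fitting function.
#' @return object of class `cv_result`: `evaluations` (data.frame repeat /
#'   fold / r / n_test), `folds` (n x n_repeats assignment matrix),
#'   `mean_ability`, `n_folds`, `n_repeats`, `seed`.
#' @export
cross_validate <- function(model, y, M, n_folds = 5, n_repeats = 10,
                           seed = 1, ...) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  n <- length(y)
  M <- as.matrix(M)
  fitter <- model_fitter(model)
  fold_mat <- make_folds(n, n_folds, n_repeats, seed)
  evals <- list()
  for (r in seq_len(n_repeats)) {
    fold <- fold_mat[, r]
    if (min(table(fold)) < 3) {
      stop("a fold has fewer than 3 test genotypes; reduce n_folds")
    }
    for (f in seq_len(n_folds)) {
      test <- fold == f
      fit <- fitter(y[!test], M[!test, , drop = FALSE], ...)
      pred <- stats::predict(fit, M[test, , drop = FALSE])
      r_val <- suppressWarnings(stats::cor(pred, y[test]))
      evals[[length(evals) + 1]] <- data.frame(
        rep = r, fold = f, r = r_val, n_test = sum(test)
      )
    }
  }
  ev <- do.call(rbind, evals)
  structure(
    list(evaluations = ev, folds = fold_mat,
         mean_ability = mean(ev$r, na.rm = TRUE),
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %d folds x %d repeats = %d evaluations, mean ability %.3f\n",
    x$n_folds, x$n_repeats, nrow(x$evaluations), x$mean_ability))
  invisible(x)
}

# seeded fold assignments: one permutation-based partition per repeat,
# sizes differing by at most one
make_folds <- function(n, n_folds, n_repeats, seed) {
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max %/% 2, n_repeats)
  out <- matrix(0L, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(fold_seeds[r])
    out[, r] <- sample(rep_len(seq_len(n_folds), n))
  }
  out
}

# resolve a model tag to a fitting closure
model_fitter <- function(model) {
  if (is.function(model)) return(model)
  switch(
    model,
    rrblup = function(y, M, ...) fit_rrblup(y, M),
    brr = function(y, M, ...) fit_brr(y, M, ...),
    bl = function(y, M, ...) fit_bayesian_lasso(y, M, ...),
    mean = function(y, M, ...) structure(list(mu = mean(y)),
                                         class = "mean_fit"),
    stop("unknown model tag: ", model)
  )
}

#' @export
predict.mean_fit <- function(object, M_new, ...) {
  rep(object$mu, nrow(as.matrix(M_new)))
}

#' GWAS-p-value marker subsetting experiment
#'
#' Evaluates genomic prediction using marker subsets defined by a ladder of
#' GWAS p-value thresholds (always including `"all"` = no selection), for
#' one or more models, under repeated k-fold cross-validation. Two
#' selection schemes are offered. `within_fold` (the unbiased default)
#' reruns the association scan on each training set only, so the held-out
#' fold never informs marker selection. `full_data` runs one scan on the
#' complete data and reuses its subsets across folds; because the test
#' genotypes contribute to the selection this is optimistically biased, and
#' a message says so - it exists to mirror published single-scan designs.
#'
#' @param y named phenotype vector.
#' @param geno a [genotype_matrix()].
#' @param thresholds descending p-value ladder; the string `"all"` means no
#'   selection (default `c("all", 0.05, 0.01, 1e-3, 1e-4, 1e-5)` plus the
#'   Bonferroni cut for the panel).
#' @param models character vector of model tags (default `"rrblup"`).
#' @param scheme `"within_fold"` or `"full_data"`.
#' @param n_folds,n_repeats,seed cross-validation settings.
#' @param K optional kinship for the scans (default VanRaden on the panel /
#'   training subset).
#' @param ... chain settings passed to Bayesian fitters.
#' @return object of class `subset_experiment`: data.frame `results` with
#'   columns threshold (character), p_cut, model, n_markers (mean over
#'   evaluations), mean_ability, n_evals; plus the scheme and settings.
#' @export
subset_prediction_experiment <- function(y, geno,
                                         thresholds = NULL,
                                         models = "rrblup",
                                         scheme = c("within_fold",
                                                    "full_data"),
                                         n_folds = 5, n_repeats = 10,
                                         seed = 1, K = NULL, ...) {
  scheme <- match.arg(scheme)
  ids <- names(y)
  gsub <- if (is.null(ids)) geno else subset_genotypes(geno, samples = ids)
  M <- impute_dosages(gsub)
  n <- length(y)
  m <- ncol(M)
  if (is.null(thresholds)) {
    thresholds <- c("all", 0.05, 0.01, 1e-3, 1e-4, 1e-5,
                    bonferroni_threshold(0.05, m))
  }
  thr_num <- suppressWarnings(as.numeric(thresholds))
  # "all" first, then descending numeric thresholds
  thr_chr <- as.character(thresholds)
  is_all <- thr_chr == "all"
  thr_chr <- c(thr_chr[is_all], thr_chr[!is_all][order(-thr_num[!is_all])])
  thr_num <- suppressWarnings(as.numeric(thr_chr))

  if (scheme == "full_data") {
    message("subset_prediction_experiment: full_data scheme selects ",
            "markers on the complete data; abilities are optimistically ",
            "biased because test folds inform the selection")
    scan_all <- mlm_scan(y, gsub, K = if (is.null(K))
      vanraden_kinship(gsub) else K)
  }

  fold_mat <- make_folds(n, n_folds, n_repeats, seed)
  res <- list()
  for (mod in models) {
    fitter <- model_fitter(mod)
    for (ti in seq_along(thr_chr)) {
      abilities <- c(); counts <- c()
      for (r in seq_len(n_repeats)) {
        fold <- fold_mat[, r]
        for (f in seq_len(n_folds)) {
          test <- fold == f
          if (thr_chr[ti] == "all") {
            keep <- seq_len(m)
          } else if (scheme == "full_data") {
            keep <- which(scan_all$tested & !is.na(scan_all$p) &
                            scan_all$p <= thr_num[ti])
          } else {
            tr_geno <- subset_genotypes(gsub, samples = which(!test))
            scan_tr <- mlm_scan(y[!test], tr_geno,
                                K = vanraden_kinship(tr_geno))
            keep <- which(scan_tr$tested & !is.na(scan_tr$p) &
                            scan_tr$p <= thr_num[ti])
          }
          counts <- c(counts, length(keep))
          if (length(keep) == 0) {
            abilities <- c(abilities, NA_real_)
            next
          }
          fit <- fitter(y[!test], M[!test, keep, drop = FALSE], ...)
          pred <- stats::predict(fit, M[test, keep, drop = FALSE])
          abilities <- c(abilities,
                         suppressWarnings(stats::cor(pred, y[test])))
        }
      }
      res[[length(res) + 1]] <- data.frame(
        threshold = thr_chr[ti], p_cut = thr_num[ti], model = mod,
        n_markers = mean(counts), mean_ability = mean(abilities,
                                                      na.rm = TRUE),
        n_evals = length(abilities), stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(results = do.call(rbind, res), scheme = scheme,
         n_folds = n_folds, n_repeats = n_repeats, seed = seed),
    class = "subset_experiment"
  )
}

#' @export
print.subset_experiment <- function(x, ...) {
  cat(sprintf("subset_experiment (%s scheme, %d x %d CV):\n",
              x$scheme, x$n_folds, x$n_repeats))
  print(x$results, row.names = FALSE)
  invisible(x)
}
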