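#' Pearson correlation matrix of a cleaned acquisition
#'
#' @param clean a `clean_series` with `status == "ok"`, or an N x T matrix.
#' @return object of class `corr_matrix`: `values` (N x N), `roi` names,
#'   `n_frames`.
#' @export
correlation_matrix <- function(clean) {
  sig <- if (inherits(clean, "clean_series")) clean$signals else clean
  if (is.null(sig)) stop("cannot compute correlations of a discarded series")
  stopifnot(ncol(sig) >= 3)
  sds <- apply(sig, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI: ",
         paste(rownames(sig)[sds == 0], collapse = ", "))
  }
  v <- stats::cor(t(sig))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  structure(list(values = v, roi = rownames(sig), n_frames = ncol(sig)),
            class = "corr_matrix")
}

#' Validate correlation-matrix invariants
#'
#' Symmetry, unit diagonal, entries in [-1, 1], positive semidefiniteness up
#' to a numerical tolerance.
#'
#' @param cm a `corr_matrix` or plain matrix.
#' @param psd_tol eigenvalue tolerance (default 1e-8).
#' @return TRUE invisibly; error describing the violated invariant otherwise.
#' @export
validate_corr_matrix <- function(cm, psd_tol = 1e-8) {
  v <- if (inherits(cm, "corr_matrix")) cm$values else cm
  if (max(abs(v - t(v))) > 1e-10) stop("correlation matrix not symmetric")
  if (max(abs(diag(v) - 1)) > 1e-10) stop("diagonal not unity")
  if (max(abs(v)) > 1 + 1e-10) stop("entries outside [-1, 1]")
  if (min(eigen(v, symmetric = TRUE, only.values = TRUE)$values) < -psd_tol) {
    stop("matrix not positive semidefinite within tolerance")
  }
  invisible(TRUE)
}

#' Fisher z-transform (with clipping near +-1) and its inverse
#'
#' @param r correlation value(s); clipped to +-(1 - 1e-7) before `atanh`.
#' @return transformed value(s).
#' @export
fisher_transform <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @rdname fisher_transform
#' @param z Fisher-scale value(s).
#' @export
inverse_fisher <- function(z) tanh(z)

#' Per-edge Fisher-scale observations for a cohort
#'
#' One row per (acquisition, ROI pair): the Pearson correlation of the
#' cleaned signals and its Fisher transform, with animal and condition
#' metadata. Discarded acquisitions are skipped.
#'
#' @param clean_list list of `clean_series` named by acquisition id.
#' @param manifest cohort manifest data.frame.
#' @param roi an `roi_set`.
#' @return data.frame with columns `acquisition_id`, `animal_id`,
#'   `condition`, `edge`, `i`, `j`, `r`, `z`.
#' @export
edge_observations <- function(clean_list, manifest, roi = default_roi_set()) {
  pairs <- sym_pairs(n_roi(roi), with_diagonal = FALSE)
  labels <- sym_pair_labels(roi, with_diagonal = FALSE)
  out <- lapply(clean_list, function(cs) {
    if (cs$status != "ok") return(NULL)
    row <- manifest[manifest$acquisition_id == cs$source_id, ]
    if (nrow(row) != 1) stop("acquisition ", cs$source_id, " not in manifest")
    r <- correlation_matrix(cs)$values[pairs]
    data.frame(acquisition_id = cs$source_id, animal_id = row$animal_id,
               condition = row$condition, edge = labels,
               i = pairs[, "i"], j = pairs[, "j"], r = r,
               z = fisher_transform(r))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

fit_two_level_mixed <- function(df, value_col, condition_pair,
                                method = c("satterthwaite", "wald")) {
  # shared machinery: random animal intercept, two-level condition fixed
  # effect on `value_col`; OLS fallback when the animal variance collapses
  method <- match.arg(method)
  sub <- df[df$condition %in% condition_pair, , drop = FALSE]
  counts <- table(factor(sub$condition, levels = condition_pair))
  if (any(counts == 0)) {
    return(list(status = "untestable",
                reason = "condition absent"))
  }
  if (length(unique(sub$animal_id)) < 2 || any(counts < 3)) {
    return(list(status = "untestable",
                reason = "fewer than 2 animals or 3 observations/condition"))
  }
  sub$condition <- factor(sub$condition, levels = condition_pair)
  sub$y <- sub[[value_col]]
  fallback <- FALSE
  fit <- suppressWarnings(suppressMessages(
    tryCatch(lmerTest::lmer(y ~ condition + (1 | animal_id), data = sub,
                            REML = TRUE),
             error = function(e) NULL)))
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    fallback <- TRUE
    fit <- stats::lm(y ~ condition, data = sub)
    co <- summary(fit)$coefficients
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    p <- if (method == "wald") 2 * stats::pnorm(-abs(est / se))
         else co[2, "Pr(>|t|)"]
    res <- stats::residuals(fit)
  } else {
    co <- stats::coef(summary(fit))
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    p <- if (method == "wald") 2 * stats::pnorm(-abs(est / se))
         else co[2, "Pr(>|t|)"]
    res <- stats::residuals(fit)
  }
  sh <- if (length(res) >= 3 && length(res) <= 5000 &&
            stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  list(status = "ok", estimate = unname(est), se = unname(se),
       p_raw = unname(p), shapiro_p = sh, n_obs = nrow(sub),
       n_animals = length(unique(sub$animal_id)),
       fit_method = if (fallback) "ols_fallback" else "reml")
}

#' Mixed-model contrast of one edge between two thermal conditions
#'
#' Random-intercept-per-animal linear mixed model on the Fisher-transformed
#' correlations, fitted by REML; the p-value tests the two-level condition
#' coefficient (Satterthwaite t by default, normal-approximation Wald as an
#' option). When the animal variance component collapses to zero the model
#' degenerates to ordinary least squares, flagged in `fit_method`.
#' Residual normality (Shapiro-Wilk) is reported, not used for gating.
#'
#' @param obs `edge_observations()` rows for a single edge.
#' @param condition_pair length-2 character vector; the estimate is
#'   condition 2 minus condition 1 on the Fisher scale.
#' @param method `"satterthwaite"` (default) or `"wald"`.
#' @return one-row data.frame (`estimate`, `se`, `p_raw`, `shapiro_p`,
#'   `n_obs`, `n_animals`, `fit_method`, `status`).
#' @export
edge_mixed_model <- function(obs, condition_pair,
                             method = c("satterthwaite", "wald")) {
  f <- fit_two_level_mixed(obs, "z", condition_pair, method)
  if (f$status != "ok") {
    return(data.frame(edge = obs$edge[1], estimate = NA_real_,
                      se = NA_real_, p_raw = NA_real_, shapiro_p = NA_real_,
                      n_obs = nrow(obs), n_animals = NA_integer_,
                      fit_method = NA_character_, status = f$status))
  }
  data.frame(edge = obs$edge[1], estimate = f$estimate, se = f$se,
             p_raw = f$p_raw, shapiro_p = f$shapiro_p, n_obs = f$n_obs,
             n_animals = f$n_animals, fit_method = f$fit_method,
             status = "ok")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in [0, 1].
#' @param q false discovery rate (default 0.05).
#' @return list with `adjusted` (monotone step-up adjusted p-values, capped
#'   at 1) and `reject` (`adjusted < q`).
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj < q)
}

#' Edge-wise static FC contrast between two conditions
#'
#' Fits the per-edge mixed model for every ROI pair, applies
#' Benjamini-Hochberg over the family of testable edges (up to 45), and
#' assembles the symmetric significance and Fisher-scale effect (delta-z)
#' matrices.
#'
#' @param obs full `edge_observations()` table.
#' @param condition_pair length-2 character vector of condition labels.
#' @param q false discovery rate (default 0.05).
#' @param roi an `roi_set`.
#' @param method p-value method, see [edge_mixed_model()].
#' @return list: `results` (per-edge table with `p_adjusted`,
#'   `significant`), `significance` (N x N logical), `delta_z` (N x N
#'   numeric, NA where untestable), `n_tested`, `q`.
#' @export
compare_conditions <- function(obs, condition_pair, q = 0.05,
                               roi = default_roi_set(),
                               method = c("satterthwaite", "wald")) {
  method <- match.arg(method)
  pairs <- sym_pairs(n_roi(roi), with_diagonal = FALSE)
  labels <- sym_pair_labels(roi, with_diagonal = FALSE)
  res <- do.call(rbind, lapply(seq_along(labels), function(k) {
    e <- obs[obs$edge == labels[k], , drop = FALSE]
    r <- edge_mixed_model(e, condition_pair, method)
    r$i <- pairs[k, "i"]; r$j <- pairs[k, "j"]
    r
  }))
  testable <- res$status == "ok"
  if (!any(testable)) stop("no testable edges for this contrast")
  res$p_adjusted <- NA_real_
  res$significant <- FALSE
  bh <- benjamini_hochberg(res$p_raw[testable], q)
  res$p_adjusted[testable] <- bh$adjusted
  res$significant[testable] <- bh$reject
  n <- n_roi(roi)
  sig <- matrix(FALSE, n, n, dimnames = list(roi$names, roi$names))
  dz <- matrix(NA_real_, n, n, dimnames = list(roi$names, roi$names))
  sig[cbind(res$i, res$j)] <- res$significant
  sig[cbind(res$j, res$i)] <- res$significant
  dz[cbind(res$i, res$j)] <- res$estimate
  dz[cbind(res$j, res$i)] <- res$estimate
  list(results = res, significance = sig, delta_z = dz,
       n_tested = sum(testable), q = q, condition_pair = condition_pair)
}

#' Mean correlation matrix of a condition
#'
#' Element-wise mean of the per-acquisition Pearson matrices of every
#' retained acquisition in a condition (the per-condition summary shown as
#' heatmaps).
#'
#' @param clean_list list of `clean_series`.
#' @param manifest cohort manifest.
#' @param condition condition label.
#' @return N x N numeric matrix.
#' @export
condition_mean_matrix <- function(clean_list, manifest, condition) {
  ids <- manifest$acquisition_id[manifest$condition == condition]
  mats <- lapply(clean_list[names(clean_list) %in% ids], function(cs) {
    if (cs$status != "ok") return(NULL)
    correlation_matrix(cs)$values
  })
  mats <- Filter(Negate(is.null), mats)
  if (!length(mats)) stop("no retained acquisitions in condition ", condition)
  Reduce(`+`, mats) / length(mats)
}
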