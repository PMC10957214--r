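#' Per-ROI z-scoring of a cleaned series
#'
#' Each ROI row is centered by its empirical mean and divided by its sample
#' standard deviation (1/(T-1) normalization), the standardization under
#' which the temporal mean of the cofluctuation products reproduces the
#' Pearson correlation exactly.
#'
#' @param clean a `clean_series` or an N x T matrix.
#' @return z-scored N x T matrix.
#' @export
zscore_series <- function(clean) {
  sig <- if (inherits(clean, "clean_series")) clean$signals else clean
  if (is.null(sig)) stop("cannot z-score a discarded series")
  zscore_rows(sig)
}

#' Per-frame cofluctuation series
#'
#' For z-scored signals, frame t contributes the symmetric matrix
#' C_ij(t) = z_i(t) z_j(t); its upper triangle including the diagonal
#' (55 values for N = 10) is stored as one row. The temporal sum divided by
#' (T-1) reproduces the Pearson correlation matrix exactly.
#'
#' @param z z-scored N x T matrix from [zscore_series()].
#' @param acquisition_id provenance label attached to every frame.
#' @return object of class `cofluctuation_series`: `values` (T x L matrix),
#'   `frames` (data.frame `acquisition_id`, `frame`), `roi` names, `n`.
#' @export
cofluctuation_series <- function(z, acquisition_id = "unknown") {
  n <- nrow(z)
  zt <- t(z)
  p <- sym_pairs(n, with_diagonal = TRUE)
  vals <- zt[, p[, "i"], drop = FALSE] * zt[, p[, "j"], drop = FALSE]
  rn <- rownames(z)
  if (!is.null(rn)) {
    colnames(vals) <- paste(rn[p[, "i"]], rn[p[, "j"]], sep = "~")
  }
  structure(list(values = vals,
                 frames = data.frame(acquisition_id = acquisition_id,
                                     frame = seq_len(ncol(z))),
                 roi = rn, n = n),
            class = "cofluctuation_series")
}

#' Concatenate cofluctuation series across a cohort
#'
#' Frames are stacked in the given (manifest) order, keeping per-frame
#' provenance back to the source acquisition.
#'
#' @param series list of `cofluctuation_series` over the same ROI set.
#' @return one `cofluctuation_series`.
#' @export
concatenate_cohort <- function(series) {
  stopifnot(length(series) >= 1)
  ref <- series[[1]]$roi
  for (s in series) {
    if (!identical(s$roi, ref) || s$n != series[[1]]$n) {
      stop("ROI sets differ between cofluctuation series")
    }
  }
  structure(list(values = do.call(rbind, lapply(series, `[[`, "values")),
                 frames = do.call(rbind, lapply(series, `[[`, "frames")),
                 roi = ref, n = series[[1]]$n),
            class = "cofluctuation_series")
}

#' Outlier scores and filter for cofluctuation frames
#'
#' Each frame's mean L1 distance to all other frames is z-scored (mean/SD
#' over frames, sample SD); frames with score > `threshold` are discarded.
#' The mean distances are computed with per-coordinate sorted prefix sums,
#' never materializing the T x T distance matrix.
#'
#' @param cofl a `cofluctuation_series` or a T x L matrix.
#' @param threshold z-score cutoff (default 3).
#' @return list: `scores` (length T), `keep` (logical), `mean_distance`.
#' @export
outlier_scores <- function(cofl, threshold = 3) {
  v <- if (inherits(cofl, "cofluctuation_series")) cofl$values else cofl
  stopifnot(nrow(v) >= 3)
  md <- mean_l1_distances_cpp(v)
  s <- stats::sd(md)
  scores <- if (s == 0) rep(0, length(md)) else (md - mean(md)) / s
  list(scores = scores, keep = scores <= threshold, mean_distance = md)
}

#' Drop outlier frames from a cofluctuation series
#' @param cofl a `cofluctuation_series`.
#' @param threshold z-score cutoff (default 3).
#' @return filtered `cofluctuation_series` with an `outliers` attribute.
#' @export
filter_outliers <- function(cofl, threshold = 3) {
  os <- outlier_scores(cofl, threshold)
  out <- structure(list(values = cofl$values[os$keep, , drop = FALSE],
                        frames = cofl$frames[os$keep, , drop = FALSE],
                        roi = cofl$roi, n = cofl$n),
                   class = "cofluctuation_series")
  attr(out, "outliers") <- sum(!os$keep)
  out
}

#' L1 k-means (k-medians) brain-state clustering
#'
#' Lloyd-style alternation of manhattan-distance assignment and
#' coordinate-wise-median centroid updates; the best of `restarts` random
#' initializations (k distinct data points each, restart seeds derived from
#' `seed`) by total within-cluster L1 distance is returned. States are
#' relabeled by descending occurrence (ties broken by decreasing centroid
#' L2 norm), so state 1 is always the most frequent.
#'
#' @param x T' x L numeric matrix of retained cofluctuation frames (or a
#'   `cofluctuation_series`).
#' @param k number of clusters.
#' @param restarts random initializations (default 500).
#' @param max_iter Lloyd iteration cap per restart (default 300;
#'   convergence is declared when assignments stop changing).
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `brain_state_model`: `k`, `centroids` (k x L,
#'   reordered), `labels` (length T', in 1..k), `total_within_l1`,
#'   `objective_trace`, `restarts`, `seed`, `state_order` (permutation
#'   applied to the raw cluster indices), `counts`.
#' @export
kmeans_l1 <- function(x, k, restarts = 500, max_iter = 300, seed = 1) {
  if (inherits(x, "cofluctuation_series")) x <- x$values
  stopifnot(is.matrix(x), k >= 1)
  if (nrow(x) < k) stop("K exceeds the number of frames")
  fit <- kmeans_l1_cpp(x, as.integer(k), as.integer(restarts),
                       as.integer(max_iter), as.integer(seed))
  counts <- tabulate(fit$labels, k)
  nrm <- sqrt(rowSums(fit$centroids^2))
  ord <- order(-counts, -nrm)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(k = k, centroids = fit$centroids[ord, , drop = FALSE],
                 labels = relabel[fit$labels],
                 total_within_l1 = fit$objective,
                 objective_trace = fit$objective_trace,
                 restarts = restarts, seed = seed, state_order = ord,
                 counts = counts[ord], best_restart = fit$best_restart),
            class = "brain_state_model")
}

#' @export
#' @method print brain_state_model
print.brain_state_model <- function(x, ...) {
  cat("<brain_state_model> K =", x$k, "states over", sum(x$counts),
      "frames; within-L1 =", format(x$total_within_l1), "\n")
  cat("  occurrence:", paste0(round(100 * x$counts / sum(x$counts), 1), "%",
                              collapse = " "), "\n")
  invisible(x)
}

#' State centroid as a symmetric matrix
#' @param model a `brain_state_model`.
#' @param state state index (1 = most frequent).
#' @param roi an `roi_set` for dimnames.
#' @return N x N symmetric matrix.
#' @export
state_matrix <- function(model, state, roi = default_roi_set()) {
  n <- n_roi(roi)
  m <- devectorize_symmetric(model$centroids[state, ], n = n,
                             with_diagonal = TRUE)
  dimnames(m) <- list(roi$names, roi$names)
  m
}

duda_hart_critical <- function(n, d, alpha) {
  1 - 2 / (pi * d) -
    stats::qnorm(1 - alpha) * sqrt(2 * (1 - 8 / (pi^2 * d)) / (n * d))
}

#' Duda-Hart selection of the number of brain states
#'
#' For each K in 1..`k_max` the data are clustered; every cluster is then
#' tested for a significant two-way split: the ratio of the within-cluster
#' squared error after a 2-means split, Je(2), to the one-cluster squared
#' error Je(1) is compared with the critical value
#' `1 - 2/(pi d) - z_alpha * sqrt(2 (1 - 8/(pi^2 d)) / (n d))`.
#' The split count for K is the number of clusters whose split is
#' significant; the selected K is the smallest whose split count is zero and
#' stays zero through `k_max`. Clusters smaller than `2 d` frames are
#' exempted from the test (counted in `n_exempt`).
#'
#' @param x T' x L matrix (or `cofluctuation_series`).
#' @param k_max largest K examined.
#' @param alpha significance level of the split test (default 0.05).
#' @param restarts k-means restarts per K (clustering by [kmeans_l1()]).
#' @param seed integer seed.
#' @param max_frames optional cap on the number of frames used: a seeded
#'   uniform subsample keeps the selection affordable on long recordings.
#' @return list: `selected_k` (NA if the count never settles at zero),
#'   `table` (per-K split counts and exemptions), `alpha`.
#' @export
duda_hart_k <- function(x, k_max, alpha = 0.05, restarts = 20, seed = 1,
                        max_frames = Inf) {
  if (inherits(x, "cofluctuation_series")) x <- x$values
  stopifnot(k_max >= 1)
  if (nrow(x) > max_frames) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), max_frames), , drop = FALSE]
  }
  d <- ncol(x)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    model <- kmeans_l1(x, k, restarts = restarts, seed = seed + k)
    n_split <- 0L
    n_exempt <- 0L
    for (cl in seq_len(k)) {
      pts <- x[model$labels == cl, , drop = FALSE]
      n_cl <- nrow(pts)
      if (n_cl < 2 * d || nrow(unique(pts)) < 2) {
        n_exempt <- n_exempt + 1L
        next
      }
      je1 <- sum(sweep(pts, 2, colMeans(pts))^2)
      if (je1 == 0) next
      set.seed(seed + 1000L * k + cl)
      km2 <- suppressWarnings(stats::kmeans(pts, centers = 2, nstart = 5,
                                            iter.max = 100,
                                            algorithm = "Lloyd"))
      ratio <- sum(km2$withinss) / je1
      if (ratio < duda_hart_critical(n_cl, d, alpha)) {
        n_split <- n_split + 1L
      }
    }
    rows[[k]] <- data.frame(k = k, split_count = n_split,
                            n_exempt = n_exempt)
  }
  tab <- do.call(rbind, rows)
  sel <- NA_integer_
  zero_tail <- rev(cumprod(rev(tab$split_count == 0)))  # zero through k_max
  if (any(zero_tail == 1)) sel <- tab$k[which(zero_tail == 1)[1]]
  list(selected_k = sel, table = tab, alpha = alpha)
}

#' Per-acquisition brain-state occurrence rates
#'
#' Fraction of each acquisition's retained frames assigned to each state,
#' with animal and condition metadata; states are reported in the model's
#' descending-occurrence order. Rates sum to 1 within each acquisition.
#'
#' @param model a `brain_state_model`.
#' @param frames provenance data.frame (`acquisition_id` per labeled frame,
#'   e.g. the `frames` element of the clustered `cofluctuation_series`).
#' @param manifest cohort manifest.
#' @return data.frame: `animal_id`, `condition`, `acquisition_id`, `state`,
#'   `rate`.
#' @export
occurrence_rates <- function(model, frames, manifest) {
  stopifnot(nrow(frames) == length(model$labels))
  tab <- table(factor(frames$acquisition_id),
               factor(model$labels, levels = seq_len(model$k)))
  rates <- tab / rowSums(tab)
  df <- as.data.frame(rates, stringsAsFactors = FALSE)
  names(df) <- c("acquisition_id", "state", "rate")
  df$state <- as.integer(as.character(df$state))
  meta <- manifest[match(df$acquisition_id, manifest$acquisition_id), ]
  df$animal_id <- meta$animal_id
  df$condition <- meta$condition
  df <- df[order(df$acquisition_id, df$state),
           c("animal_id", "condition", "acquisition_id", "state", "rate")]
  rownames(df) <- NULL
  df
}

#' Animal-by-state composition diagnostic
#'
#' Each animal's share of each state's frames, plus a descriptive chi-square
#' statistic of the animal x state contingency table. Used to check that no
#' brain state is driven by a single animal; reported, never used to gate.
#'
#' @param model a `brain_state_model`.
#' @param frames per-frame provenance (see [occurrence_rates()]).
#' @param manifest cohort manifest.
#' @return list: `composition` (animals x states, columns sum to 1),
#'   `counts`, `chisq`, `df`, `p`.
#' @export
animal_state_homogeneity <- function(model, frames, manifest) {
  animal <- manifest$animal_id[match(frames$acquisition_id,
                                     manifest$acquisition_id)]
  if (length(unique(animal)) < 2) stop("need at least 2 animals")
  counts <- table(factor(animal),
                  factor(model$labels, levels = seq_len(model$k)))
  comp <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use <- e > 0
  chisq <- sum((counts[use] - e[use])^2 / e[use])
  dof <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(composition = unclass(comp), counts = unclass(counts), chisq = chisq,
       df = dof, p = stats::pchisq(chisq, dof, lower.tail = FALSE))
}

#' Condition effects on brain-state occurrence rates
#'
#' Per state: an omnibus linear mixed model of the per-acquisition rate with
#' a multi-level thermal-condition fixed effect and a random animal
#' intercept (Satterthwaite F test; OLS fallback on a degenerate fit). When
#' the omnibus effect is significant at `alpha`, all pairwise condition
#' contrasts are fitted and Benjamini-Hochberg-adjusted at FDR `q` within
#' that state.
#'
#' @param occ an [occurrence_rates()] table.
#' @param q false discovery rate for pairwise contrasts (default 0.05).
#' @param alpha omnibus significance level (default 0.05).
#' @param method p-value method for the pairwise fits.
#' @return list: `omnibus` (per-state data.frame with `p_omnibus`,
#'   `status`), `pairwise` (data.frame of contrasts for significant states,
#'   or NULL), `q`, `alpha`.
#' @export
compare_occurrence <- function(occ, q = 0.05, alpha = 0.05,
                               method = c("satterthwaite", "wald")) {
  method <- match.arg(method)
  conditions <- unique(occ$condition)
  states <- sort(unique(occ$state))
  omni <- vector("list", length(states))
  pw <- list()
  for (s in seq_along(states)) {
    sub <- occ[occ$state == states[s], , drop = FALSE]
    if (length(unique(sub$condition)) < 2) {
      omni[[s]] <- data.frame(state = states[s], p_omnibus = NA_real_,
                              fit_method = NA_character_,
                              status = "untestable")
      next
    }
    sub$condition <- factor(sub$condition)
    fit <- suppressWarnings(suppressMessages(
      tryCatch(lmerTest::lmer(rate ~ condition + (1 | animal_id),
                              data = sub, REML = TRUE),
               error = function(e) NULL)))
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      lmfit <- stats::lm(rate ~ condition, data = sub)
      p_omni <- stats::anova(lmfit)[["Pr(>F)"]][1]
      fm <- "ols_fallback"
    } else {
      a <- stats::anova(fit)  # lmerTest: Satterthwaite F
      p_omni <- a[["Pr(>F)"]][1]
      fm <- "reml"
    }
    omni[[s]] <- data.frame(state = states[s], p_omnibus = p_omni,
                            fit_method = fm, status = "ok")
    if (!is.na(p_omni) && p_omni < alpha) {
      combos <- utils::combn(sort(conditions), 2, simplify = FALSE)
      rows <- lapply(combos, function(cp) {
        f <- fit_two_level_mixed(sub, "rate", cp, method)
        if (f$status != "ok") {
          return(data.frame(state = states[s], condition_a = cp[1],
                            condition_b = cp[2], estimate = NA_real_,
                            p_raw = NA_real_, status = f$status))
        }
        data.frame(state = states[s], condition_a = cp[1],
                   condition_b = cp[2], estimate = f$estimate,
                   p_raw = f$p_raw, status = "ok")
      })
      pr <- do.call(rbind, rows)
      ok <- pr$status == "ok"
      pr$p_adjusted <- NA_real_
      pr$significant <- FALSE
      if (any(ok)) {
        bh <- benjamini_hochberg(pr$p_raw[ok], q)
        pr$p_adjusted[ok] <- bh$adjusted
        pr$significant[ok] <- bh$reject
      }
      pw[[length(pw) + 1]] <- pr
    }
  }
  list(omnibus = do.call(rbind, omni),
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL,
       q = q, alpha = alpha)
}

#' Align estimated states to ground-truth templates
#'
#' Finds the state-to-template assignment maximizing the total Pearson
#' correlation between centroid vectors and vectorized templates
#' (exhaustive over permutations for small K, greedy otherwise).
#'
#' @param model a `brain_state_model`.
#' @param templates list of `state_template`.
#' @return list: `assignment` (template index per state), `correlations`
#'   (per-state correlation with its assigned template).
#' @export
align_states_to_templates <- function(model, templates) {
  k <- model$k
  tv <- vapply(templates, function(tp) {
    vectorize_symmetric(tp$covariance, with_diagonal = TRUE)$values
  }, numeric(ncol(model$centroids)))
  cors <- stats::cor(t(model$centroids), tv)  # k x n_templates
  if (k <= 8 && length(templates) == k) {
    perms <- all_permutations(k)
    scores <- apply(perms, 1, function(p) sum(cors[cbind(seq_len(k), p)]))
    best <- as.integer(perms[which.max(scores), ])
  } else {
    # greedy fallback
    best <- integer(k)
    avail <- seq_len(ncol(cors))
    for (s in order(-apply(cors, 1, max))) {
      pick <- avail[which.max(cors[s, avail])]
      best[s] <- pick
      avail <- setdiff(avail, pick)
      if (!length(avail)) break
    }
  }
  list(assignment = unname(best),
       correlations = unname(cors[cbind(seq_len(k), best)]))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}
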