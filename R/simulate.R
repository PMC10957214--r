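#' Default brain-state covariance templates
#'
#' Seven correlation-scaled, positive-definite 10x10 templates emulating the
#' connectivity patterns the dynamic analysis is designed to recover: one
#' weakly connected state, three states with strong somatomotor-cingulate
#' coupling and somatomotor-hypothalamus anticorrelation, one state with the
#' cingulate decoupled from the rest, and two intermediate states.
#'
#' @param roi an `roi_set` with the three network groups populated.
#' @return list of 7 `state_template` objects (fields `name`, `covariance`,
#'   `description`).
#' @export
make_default_templates <- function(roi = default_roi_set()) {
  stopifnot(all(c("somatomotor", "cingulate", "hypothalamus") %in% roi$groups))
  n <- n_roi(roi)
  sm <- roi_group_idx(roi, "somatomotor")
  cg <- roi_group_idx(roi, "cingulate")
  hy <- roi_group_idx(roi, "hypothalamus")

  blocks <- function(sm_sm, cg_cg, hy_hy, sm_cg, sm_hy, cg_hy) {
    m <- diag(n)
    fill <- function(a, b, r) {
      m[a, b] <<- r
      m[b, a] <<- r
    }
    fill(sm, sm, sm_sm); fill(cg, cg, cg_cg); fill(hy, hy, hy_hy)
    fill(sm, cg, sm_cg); fill(sm, hy, sm_hy); fill(cg, hy, cg_hy)
    diag(m) <- 1
    dimnames(m) <- list(roi$names, roi$names)
    m
  }
  spec <- list(
    list("weak",          blocks(0.08, 0.10, 0.10,  0.05,  0.00,  0.00),
         "weak connectivity everywhere; dominant resting mode"),
    list("intermediate1", blocks(0.35, 0.40, 0.40,  0.25, -0.10, -0.05),
         "moderate somatomotor coupling, mild hypothalamic anticorrelation"),
    list("dichotomy1",    blocks(0.65, 0.65, 0.60,  0.60, -0.35, -0.30),
         "SM-Cg block vs hypothalamus dichotomy"),
    list("cg_decoupled",  blocks(0.60, 0.50, 0.60,  0.05, -0.35,  0.00),
         "cingulate decoupled from all other regions"),
    list("dichotomy2",    blocks(0.70, 0.60, 0.50,  0.60, -0.35, -0.30),
         "SM-Cg block vs hypothalamus dichotomy, variant"),
    list("intermediate2", blocks(0.30, 0.30, 0.30,  0.25,  0.15,  0.15),
         "globally mildly positive connectivity"),
    list("dichotomy3",    blocks(0.75, 0.70, 0.60,  0.70, -0.40, -0.35),
         "strongest SM-Cg coupling vs hypothalamus dichotomy"))
  lapply(spec, function(s) {
    m <- s[[2]]
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-8) stop("template '", s[[1]], "' is not positive definite")
    structure(list(name = s[[1]], covariance = m, description = s[[3]]),
              class = "state_template")
  })
}

#' Default per-condition stationary state occupancies
#'
#' Occupancy vectors over the 7 default templates for each thermal
#' condition: the weak state dominates everywhere (most at neutral 25C), the
#' dichotomy states are elevated in cold fast-down ramps, and the
#' cingulate-decoupled state during sustained cold.
#'
#' @return named list of length-7 probability vectors, one per condition.
#' @export
default_base_occupancy <- function() {
  occ <- list(
    `25C` = c(0.60, 0.08, 0.07, 0.06, 0.07, 0.06, 0.06),
    `15C` = c(0.50, 0.08, 0.08, 0.13, 0.08, 0.06, 0.07),
    `35C` = c(0.54, 0.08, 0.08, 0.08, 0.08, 0.07, 0.07),
    CFD   = c(0.46, 0.07, 0.11, 0.07, 0.11, 0.07, 0.11),
    CFU   = c(0.50, 0.08, 0.10, 0.07, 0.09, 0.07, 0.09))
  warmish <- c(0.54, 0.08, 0.08, 0.07, 0.08, 0.07, 0.08)
  for (cond in c("CSD", "CSU", "WFU", "WFD", "WSU", "WSD")) {
    occ[[cond]] <- warmish
  }
  lapply(occ, function(p) p / sum(p))
}

#' Simulation configuration for synthetic cohorts
#'
#' @param roi an `roi_set`.
#' @param templates list of `state_template` (default
#'   [make_default_templates()]).
#' @param transition_stickiness per-frame probability of staying in the
#'   current latent state (default 0.95).
#' @param base_occupancy named list of per-condition stationary occupancy
#'   vectors over the templates.
#' @param animal_sd SD of the per-animal random offset on occupancy logits
#'   (default 0.3).
#' @param fs sampling rate in Hz (default 2.5).
#' @param frames_per_acq frames per acquisition (default 3000).
#' @param ar_coeff AR(1) smoothing coefficient band-limiting the signals
#'   (default 0.9; 0 disables).
#' @param drift_amplitude SD of the slow cubic drift in z-units (default 0.5).
#' @param global_amplitude SD of the shared global component (default 0.5).
#' @param artifact_rate expected motion bursts per 1000 frames (default 3).
#' @param artifact_gain multiplicative burst amplitude (default 10).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(roi = default_roi_set(),
                       templates = make_default_templates(roi),
                       transition_stickiness = 0.95,
                       base_occupancy = default_base_occupancy(),
                       animal_sd = 0.3, fs = 2.5, frames_per_acq = 3000,
                       ar_coeff = 0.9, drift_amplitude = 0.5,
                       global_amplitude = 0.5, artifact_rate = 3,
                       artifact_gain = 10) {
  stopifnot(transition_stickiness >= 0, transition_stickiness < 1,
            abs(ar_coeff) < 1, animal_sd >= 0, fs > 0, frames_per_acq >= 1,
            artifact_rate >= 0, artifact_gain >= 0)
  k <- length(templates)
  for (p in base_occupancy) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("each base_occupancy vector must be a length-", k,
           " probability vector")
    }
  }
  structure(list(roi = roi, templates = templates,
                 transition_stickiness = transition_stickiness,
                 base_occupancy = base_occupancy, animal_sd = animal_sd,
                 fs = fs, frames_per_acq = frames_per_acq,
                 ar_coeff = ar_coeff, drift_amplitude = drift_amplitude,
                 global_amplitude = global_amplitude,
                 artifact_rate = artifact_rate,
                 artifact_gain = artifact_gain),
            class = "sim_config")
}

ar1_smooth <- function(e, a) {
  # unit-marginal-variance AR(1) recursion along columns of a T x N matrix
  if (a == 0) return(e)
  apply(e * sqrt(1 - a^2), 2, function(col) {
    as.numeric(stats::filter(col, a, method = "recursive"))
  })
}

#' Simulate one acquisition with known ground truth
#'
#' Latent states follow a sticky first-order Markov chain whose stationary
#' distribution is the animal/condition-adjusted occupancy; per-frame draws
#' come from the active template's covariance, AR(1)-smoothed; a cubic
#' drift, a shared global component and sparse multiplicative motion bursts
#' (mirrored as spikes in `motion_ref`) are added on top.
#'
#' @param config a `sim_config`.
#' @param animal_id,condition session metadata; `condition` must appear in
#'   `config$base_occupancy`.
#' @param seed integer seed; the result is fully reproducible from it.
#' @param acquisition_id id for the generated session.
#' @param animal_effect optional length-K logit offset vector (drawn once
#'   per animal by [simulate_cohort()]); if NULL, drawn here from
#'   `N(0, animal_sd)`.
#' @return list with `acquisition` and `ground_truth` (`state_sequence`,
#'   `artifact_mask`, `occupancy_target`, `occupancy_realized`,
#'   `animal_effect`).
#' @export
simulate_acquisition <- function(config, animal_id, condition, seed,
                                 acquisition_id = paste0(animal_id, "_",
                                                         condition),
                                 animal_effect = NULL) {
  if (!condition %in% names(config$base_occupancy)) {
    stop("condition '", condition, "' has no base occupancy vector")
  }
  set.seed(seed)
  k <- length(config$templates)
  n <- n_roi(config$roi)
  tt <- config$frames_per_acq
  if (is.null(animal_effect)) {
    animal_effect <- stats::rnorm(k, 0, config$animal_sd)
  }
  logit <- log(config$base_occupancy[[condition]]) + animal_effect
  occ <- exp(logit - max(logit))
  occ <- occ / sum(occ)

  # sticky Markov chain: on "move" frames draw i.i.d. from the stationary
  # occupancy, so the chain's stationary distribution is exactly `occ`
  move <- stats::runif(tt) > config$transition_stickiness
  move[1] <- TRUE
  draws <- sample.int(k, sum(move), replace = TRUE, prob = occ)
  states <- draws[cumsum(move)]

  chol_list <- lapply(config$templates, function(tp) chol(tp$covariance))
  e <- matrix(stats::rnorm(tt * n), tt, n)
  for (s in unique(states)) {
    rows <- states == s
    e[rows, ] <- e[rows, , drop = FALSE] %*% chol_list[[s]]
  }
  x <- ar1_smooth(e, config$ar_coeff)

  if (config$drift_amplitude > 0) {
    u <- seq(-1, 1, length.out = tt)
    bas <- cbind(u, u^2, u^3)
    for (i in seq_len(n)) {
      d <- bas %*% stats::rnorm(3)
      d <- d / max(stats::sd(d), 1e-12) * config$drift_amplitude
      x[, i] <- x[, i] + d
    }
  }
  if (config$global_amplitude > 0) {
    g <- ar1_smooth(matrix(stats::rnorm(tt), tt, 1), config$ar_coeff)
    x <- x + as.numeric(g) * config$global_amplitude
  }

  # tissue-motion energy averages many pixels: narrow Gaussian baseline
  motion_ref <- pmax(stats::rnorm(tt, 1, 0.1), 0)
  artifact <- rep(FALSE, tt)
  n_burst <- stats::rpois(1, config$artifact_rate * tt / 1000)
  if (n_burst > 0) {
    starts <- sample.int(tt, n_burst, replace = TRUE)
    lens <- sample.int(10, n_burst, replace = TRUE)
    for (b in seq_len(n_burst)) {
      fr <- starts[b]:min(tt, starts[b] + lens[b] - 1L)
      artifact[fr] <- TRUE
    }
    x[artifact, ] <- x[artifact, , drop = FALSE] * config$artifact_gain
    motion_ref[artifact] <- motion_ref[artifact] + config$artifact_gain
  }

  acq <- acquisition(t(x), acquisition_id, animal_id, condition, config$fs,
                     roi = config$roi, motion_ref = motion_ref)
  gt <- list(state_sequence = states, artifact_mask = artifact,
             occupancy_target = occ,
             occupancy_realized = tabulate(states, k) / tt,
             animal_effect = animal_effect)
  list(acquisition = acq, ground_truth = gt)
}

#' Simulate a multi-animal, multi-condition cohort
#'
#' Per-animal occupancy offsets are drawn once per animal and shared across
#' that animal's sessions. When `dir` is given, acquisition files, the
#' manifest and a ground-truth JSON (run-length-encoded state sequences) are
#' written in the package's file formats; otherwise everything stays in
#' memory.
#'
#' @param config a `sim_config`.
#' @param n_animals number of animals.
#' @param acquisitions_per_condition sessions per animal per condition.
#' @param conditions condition labels (each must have a base occupancy).
#' @param seed master integer seed; per-acquisition seeds are derived from
#'   it.
#' @param dir optional output directory.
#' @return list with `manifest` (data.frame), `acquisitions` (list),
#'   `ground_truth` (list, keyed by acquisition_id), `animal_effects`,
#'   `config`, and `dir`.
#' @export
simulate_cohort <- function(config, n_animals, acquisitions_per_condition,
                            conditions, seed, dir = NULL) {
  stopifnot(n_animals >= 1, acquisitions_per_condition >= 1)
  set.seed(seed)
  k <- length(config$templates)
  animal_ids <- sprintf("m%02d", seq_len(n_animals))
  eff <- matrix(stats::rnorm(k * n_animals, 0, config$animal_sd), k,
                n_animals, dimnames = list(NULL, animal_ids))
  grid <- expand.grid(session = seq_len(acquisitions_per_condition),
                      condition = conditions, animal = animal_ids,
                      stringsAsFactors = FALSE)
  acq_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))

  if (!is.null(dir) && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  acqs <- vector("list", nrow(grid))
  gts <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    aid <- sprintf("%s_%s_s%d", grid$animal[r], grid$condition[r],
                   grid$session[r])
    sim <- simulate_acquisition(config, grid$animal[r], grid$condition[r],
                                seed = acq_seeds[r], acquisition_id = aid,
                                animal_effect = eff[, grid$animal[r]])
    acqs[[r]] <- sim$acquisition
    gts[[r]] <- sim$ground_truth
    path <- if (is.null(dir)) "" else file.path(dir, paste0(aid, ".csv"))
    rows[[r]] <- data.frame(acquisition_id = aid,
                            animal_id = grid$animal[r],
                            condition = grid$condition[r],
                            fs_hz = config$fs, path = path)
    if (!is.null(dir)) {
      ok <- tryCatch(write_acquisition(sim$acquisition, path),
                     error = function(e) {
                       stop("failed writing acquisition file ", path, ": ",
                            conditionMessage(e))
                     })
    }
  }
  manifest <- do.call(rbind, rows)
  names(gts) <- manifest$acquisition_id
  names(acqs) <- manifest$acquisition_id
  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    gt_json <- lapply(gts, function(g) {
      r <- rle(g$state_sequence)
      list(state_rle_lengths = r$lengths, state_rle_values = r$values,
           artifact_frames = which(g$artifact_mask),
           occupancy_target = g$occupancy_target,
           occupancy_realized = g$occupancy_realized)
    })
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         digits = NA)
    write_sidecar(file.path(dir, "manifest.csv"),
                  list(seed = seed, config_hash = config_hash(config)))
  }
  list(manifest = manifest, acquisitions = acqs, ground_truth = gts,
       animal_effects = eff, config = config, dir = dir)
}
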