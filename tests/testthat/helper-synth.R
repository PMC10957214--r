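# shared fixture builders: everything is generated in code at test time

# a small, fast simulation configuration for smoke-level tests
quick_sim_config <- function(frames = 400, ...) {
  sim_config(frames_per_acq = frames, ...)
}

# random symmetric matrix
rand_sym <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  (m + t(m)) / 2
}

# balanced Fisher-scale edge observations for mixed-model tests
make_edge_obs <- function(n_animals = 6, obs_per_cond = 2, shift = 0,
                          animal_sd = 0.3, resid_sd = 0.3,
                          conditions = c("25C", "15C")) {
  d <- expand.grid(animal_id = sprintf("m%d", seq_len(n_animals)),
                   condition = conditions,
                   sess = seq_len(obs_per_cond),
                   stringsAsFactors = FALSE)
  a <- rnorm(n_animals, 0, animal_sd)[as.integer(factor(d$animal_id))]
  d$z <- a + rnorm(nrow(d), 0, resid_sd) +
    ifelse(d$condition == conditions[2], shift, 0)
  d$edge <- "S1HLL~M1L"
  d$acquisition_id <- sprintf("a%d", seq_len(nrow(d)))
  d
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  # adjusted value: min over j >= i of m*p_(j)/j, capped at 1
  adj_sorted <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  # step-up rejection: largest k with p_(k) <= k q / m
  ks <- which(ranked <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  list(adjusted = adj, reject = rej)
}

# brute-force mean pairwise L1 distance
mean_l1_bruteforce <- function(v) {
  n <- nrow(v)
  dm <- as.matrix(stats::dist(v, method = "manhattan"))
  rowSums(dm) / (n - 1)
}

# brute-force run enumeration for epoch extraction
epochs_bruteforce <- function(mask, min_len) {
  runs <- list()
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) {
        runs[[length(runs) + 1]] <- c(start = i - 1, length = j - i + 1)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(runs)) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  as.data.frame(do.call(rbind, runs))
}
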