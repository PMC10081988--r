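# Shared fixtures, built in code and memoised per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small labeled phantom cohort
tiny_cohort <- function(grid = 16L, n = 20L, delta = 0.6, noise = 0.05,
                        seed = 1L) {
  key <- paste("cohort", grid, n, delta, noise, seed, sep = "_")
  fixture(key, function() {
    generate_cohort(phantom_spec(grid_size = grid, n_per_class = n,
                                 effect_size = delta, noise_sd = noise,
                                 seed = seed))
  })
}

# brute-force threshold classifier on mean intensity inside the atrophy
# loci: the independent separability oracle for the phantom module
threshold_accuracy <- function(cohort, spec = cohort$spec) {
  lm <- voxgan:::loci_mask(spec)
  x <- vapply(cohort$volumes, function(v) mean(v$data[lm]), numeric(1))
  y <- cohort$labels$label
  # sweep every midpoint between adjacent sorted feature values, both signs
  th <- sort(unique(x))
  cuts <- c(th[1] - 1, (utils::head(th, -1) + utils::tail(th, -1)) / 2,
            th[length(th)] + 1)
  best <- 0
  for (ct in cuts) {
    acc <- mean((x <= ct) == (y == 1))
    best <- max(best, acc, 1 - acc)
  }
  best
}

# brute-force pairwise-concordance AUC oracle (ties count one half)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# flatten every stateful array of a network into one numeric vector
net_state_vec <- function(net) {
  unlist(voxgan:::net_state(net), use.names = FALSE)
}

desk16 <- function() network_spec_desk(16L)
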