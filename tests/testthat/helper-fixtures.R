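# Shared fixtures built in code.

# Gaussian blobs: n_per points per class around the given means (N x p).
make_blobs <- function(n_per, means, sd = 1, seed = 1) {
  means <- as.matrix(means)
  with_seed <- actiseq:::with_seed
  with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(means)), function(k) {
      sweep(matrix(stats::rnorm(n_per * ncol(means), sd = sd), n_per), 2L,
            means[k, ], "+")
    }))
    list(x = x, labels = rep(seq_len(nrow(means)), each = n_per))
  })
}

# Random HMM with Gaussian + categorical emissions, built field by field.
make_random_hmm <- function(n_states, n_dims, seed) {
  set.seed(seed)
  rdirich <- function(n) { u <- stats::runif(n) + 0.05; u / sum(u) }
  A <- t(replicate(n_states, rdirich(n_states)))
  structure(
    list(n_states = n_states,
         pi = rdirich(n_states),
         A = A,
         means = matrix(stats::rnorm(n_states * n_dims, sd = 2), n_states),
         vars = matrix(stats::runif(n_states * n_dims, 0.2, 2), n_states),
         emit_cat = t(replicate(n_states, rdirich(n_states))),
         smoothing = 1, var_floor = 1e-6),
    class = "activity_hmm"
  )
}

random_obs <- function(n_states, n_dims, len, seed) {
  set.seed(seed + 5000)
  observation_sequence(
    scores = matrix(stats::rnorm(len * n_dims), len),
    est_labels = sample.int(n_states, len, replace = TRUE),
    n_classes = n_states
  )
}

# Run the installed CLI in a child R process with the current library paths.
run_cli <- function(args) {
  script <- system.file("cli", "actiseq.R", package = "actiseq")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(script), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = .Platform$path.sep)))
  ))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
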