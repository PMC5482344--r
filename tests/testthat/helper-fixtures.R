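# Expected indicator matrices of the packaged 8x4 worked example,
# transcribed independently of the package's fixture reader.
fixture_drugs <- paste0("d", 1:8)
fixture_targets <- paste0("t", 1:4)

fixture_active <- matrix(c(
  1, 1, 0, 1,
  0, 1, 1, 0,
  1, 0, 0, 0,
  1, 1, 1, 0,
  0, 1, 0, 1,
  1, 0, 0, 1,
  1, 1, 1, 1,
  0, 0, 1, 1
), nrow = 8, byrow = TRUE, dimnames = list(fixture_drugs, fixture_targets))
storage.mode(fixture_active) <- "integer"

fixture_inactive <- matrix(c(
  0, 0, 0, 0,
  0, 0, 0, 1,
  0, 0, 0, 1,
  0, 0, 0, 1,
  1, 0, 0, 0,
  0, 1, 1, 0,
  0, 0, 0, 0,
  0, 1, 0, 0
), nrow = 8, byrow = TRUE, dimnames = list(fixture_drugs, fixture_targets))
storage.mode(fixture_inactive) <- "integer"

fixture_unknown <- matrix(c(
  0, 0, 1, 0,
  1, 0, 0, 0,
  0, 1, 1, 0,
  0, 0, 0, 0,
  0, 0, 1, 0,
  0, 0, 0, 0,
  0, 0, 0, 0,
  1, 0, 0, 0
), nrow = 8, byrow = TRUE, dimnames = list(fixture_drugs, fixture_targets))
storage.mode(fixture_unknown) <- "integer"

# A batch of seeded random networks with varied shapes and status mixes.
random_networks <- function(n_networks = 100, max_drugs = 50,
                            max_targets = 30, base_seed = 2000) {
  lapply(seq_len(n_networks), function(i) {
    dims <- withr::with_seed(base_seed + i, {
      c(sample(max_drugs, 1), sample(max_targets, 1))
    })
    probs <- withr::with_seed(base_seed + 10000 + i, {
      p <- stats::runif(3)
      p / sum(p)
    })
    generate_random_network(dims[1], dims[2], probs[1], probs[2], probs[3],
                            seed = base_seed + 20000 + i)
  })
}

# Fully determined ground truths (no unknown pairs) for masking tests.
random_truths <- function(n_networks, n_drugs, n_targets, base_seed) {
  lapply(seq_len(n_networks), function(i) {
    p_active <- withr::with_seed(base_seed + i, stats::runif(1, 0.1, 0.9))
    generate_random_network(n_drugs, n_targets, p_active, 1 - p_active, 0,
                            seed = base_seed + 5000 + i)
  })
}
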