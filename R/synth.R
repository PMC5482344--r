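#' Generate a seeded random edge-colored network
#'
#' Draws the status of each of the `n_drugs * n_targets` pairs independently
#' from the categorical distribution `(p_active, p_inactive, p_unknown)`.
#' Output is fully determined by `seed`; labels are `d1..dn` / `t1..tm`.
#' Sampling is uniform over pairs — no attempt is made to emulate the
#' target-class popularity bias of real screening data.
#'
#' @param n_drugs,n_targets Network dimensions (>= 1).
#' @param p_active,p_inactive,p_unknown Status probabilities; must lie in
#'   `[0, 1]` and sum to 1 (tolerance 1e-12).
#' @param seed Integer seed (mandatory: synthetic data must be
#'   reproducible).
#' @return A `dtnet` object.
#' @export
#' @examples
#' net <- generate_random_network(5, 4, seed = 1)
#' glance(net)
generate_random_network <- function(n_drugs, n_targets,
                                    p_active = 0.2, p_inactive = 0.3,
                                    p_unknown = 1 - p_active - p_inactive,
                                    seed) {
  if (missing(seed)) abort_invalid("`seed` is mandatory")
  if (!is.numeric(n_drugs) || !is.numeric(n_targets) ||
      n_drugs < 1 || n_targets < 1) {
    abort_invalid("`n_drugs` and `n_targets` must be >= 1")
  }
  p <- c(p_active, p_inactive, p_unknown)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
      abs(sum(p) - 1) > 1e-12) {
    abort_invalid("status probabilities must lie in [0, 1] and sum to 1")
  }
  n <- as.integer(n_drugs); m <- as.integer(n_targets)
  draws <- withr::with_seed(
    as.integer(seed),
    sample(dt_statuses, n * m, replace = TRUE, prob = p)
  )
  dtnet(matrix(draws, nrow = n, ncol = m),
        drugs = paste0("d", seq_len(n)),
        targets = paste0("t", seq_len(m)))
}

#' Mask a ground-truth network into a database-style incomplete view
#'
#' Takes a fully determined network (no unknown pairs) and hides part of
#' it, emulating how public databases present interaction data. A
#' uniformly random `hide_fraction` of the determined pairs becomes
#' `"unknown"`; with `drop_inactives = TRUE` all inactive pairs
#' additionally become unknown (actives-only reporting). Statuses are
#' hidden, never flipped, so the masked view's degree bounds are
#' guaranteed to bracket the truth's active degrees.
#'
#' By default exactly `round(hide_fraction * n * m)` pairs are hidden, so
#' the completeness of the masked view is sharp; `bernoulli = TRUE`
#' switches to independent per-pair hiding with probability
#' `hide_fraction`.
#'
#' @param truth A `dtnet` with no unknown pairs.
#' @param hide_fraction Fraction of determined pairs to hide, in `[0, 1]`.
#' @param drop_inactives Additionally hide all inactive pairs? Default
#'   `FALSE`.
#' @param seed Integer seed (mandatory).
#' @param bernoulli Use per-pair Bernoulli hiding instead of an exact
#'   count? Default `FALSE`.
#' @return A `dtnet` of the same dimensions and labels.
#' @export
#' @examples
#' truth <- generate_random_network(20, 10, 0.4, 0.6, 0, seed = 7)
#' masked <- mask_network(truth, hide_fraction = 0.3, seed = 8)
#' completeness(masked)$c_dt # 0.7
mask_network <- function(truth, hide_fraction, drop_inactives = FALSE,
                         seed, bernoulli = FALSE) {
  check_dtnet(truth)
  if (missing(seed)) abort_invalid("`seed` is mandatory")
  if (any(truth$status == "unknown")) {
    abort_invalid(
      "`truth` must be fully determined (no unknown pairs) to serve as a ground truth"
    )
  }
  if (!is.numeric(hide_fraction) || length(hide_fraction) != 1 ||
      is.na(hide_fraction) || hide_fraction < 0 || hide_fraction > 1) {
    abort_invalid("`hide_fraction` must lie in [0, 1]")
  }
  status <- truth$status
  total <- length(status)
  hidden <- withr::with_seed(as.integer(seed), {
    if (isTRUE(bernoulli)) {
      which(stats::runif(total) < hide_fraction)
    } else {
      sample(total, round(hide_fraction * total))
    }
  })
  status[hidden] <- "unknown"
  if (isTRUE(drop_inactives)) status[status == "inactive"] <- "unknown"
  new_dtnet(status)
}
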