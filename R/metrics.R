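entity_slice <- function(network, entity, side) {
  side <- rlang::arg_match0(side, c("drug", "target"))
  labels <- if (side == "drug") drugs(network) else targets(network)
  i <- match(entity, labels)
  if (is.na(i)) {
    abort_lookup(sprintf("no %s named '%s' in the network", side, entity))
  }
  if (side == "drug") network$status[i, ] else network$status[, i]
}

#' Colored degree of a drug or target
#'
#' Counts the pairs involving one entity that carry a given status. With
#' `status = "active"` this is the degree of polypharmacology (for a drug:
#' the number of targets it is active against) or polyspecificity (for a
#' target: the number of drugs active against it). With `"unknown"` it is
#' the entity's local uncertainty.
#'
#' @param network A `dtnet` object.
#' @param entity Entity label.
#' @param side `"drug"` or `"target"`.
#' @param status One of `"active"`, `"inactive"`, `"unknown"`.
#' @return Integer count.
#' @export
#' @examples
#' net <- load_worked_example()
#' colored_degree(net, "d1", "drug", "active") # polypharmacology of d1
#' colored_degree(net, "t3", "target", "active") # polyspecificity of t3
colored_degree <- function(network, entity, side = c("drug", "target"),
                           status = c("active", "inactive", "unknown")) {
  check_dtnet(network)
  side <- match.arg(side)
  status <- match.arg(status)
  sum(entity_slice(network, entity, side) == status)
}

#' Per-entity interaction profile vectors
#'
#' Each drug or target is summarised by a 3-dimensional Euclidean vector of
#' colored degrees: (active, inactive, unknown). For a drug the components
#' sum to the number of targets; for a target, to the number of drugs —
#' the three colored subnetworks partition the pairs, so each entity's
#' degrees are constrained to the opposite side's cardinality.
#'
#' @param network A `dtnet` object.
#' @param side `"both"` (default), `"drug"`, or `"target"`.
#' @param normalize If `TRUE`, an extra column `frac_unknown` reports the
#'   unknown degree divided by the opposite side's cardinality (a fractional
#'   local uncertainty). Off by default.
#' @return A tibble with columns `entity`, `side`, `active`, `inactive`,
#'   `unknown`, in network order (drugs first).
#' @export
#' @examples
#' entity_profiles(load_worked_example())
entity_profiles <- function(network, side = c("both", "drug", "target"),
                            normalize = FALSE) {
  check_dtnet(network)
  side <- match.arg(side)
  s <- network$status
  count_rows <- function(mat, labels, which_side, denom) {
    out <- tibble::tibble(
      entity = labels,
      side = which_side,
      active = as.integer(unname(rowSums(mat == "active"))),
      inactive = as.integer(unname(rowSums(mat == "inactive"))),
      unknown = as.integer(unname(rowSums(mat == "unknown")))
    )
    if (isTRUE(normalize)) out$frac_unknown <- out$unknown / denom
    out
  }
  res <- list()
  if (side %in% c("both", "drug")) {
    res$drug <- count_rows(s, drugs(network), "drug", ncol(s))
  }
  if (side %in% c("both", "target")) {
    res$target <- count_rows(t(s), targets(network), "target", nrow(s))
  }
  dplyr::bind_rows(res)
}

#' Profile vector of a single entity
#'
#' @inheritParams colored_degree
#' @return A one-row tibble as in [entity_profiles()].
#' @export
profile_vector <- function(network, entity, side = c("drug", "target")) {
  check_dtnet(network)
  side <- match.arg(side)
  slice <- entity_slice(network, entity, side)
  tibble::tibble(
    entity = entity, side = side,
    active = sum(slice == "active"),
    inactive = sum(slice == "inactive"),
    unknown = sum(slice == "unknown")
  )
}

#' Global data completeness
#'
#' Counts the determined and undetermined pairs of the whole network:
#' `mu_plus` actives, `mu_minus` inactives, `mu_star` unknowns (full-matrix
#' sums of the three indicator matrices), and the completeness fraction
#' `c_dt = (mu_plus + mu_minus) / (n * m)` — the fraction of all possible
#' drug-target pairs whose activity status has been determined. `c_dt` is 1
#' exactly when no pair is unknown and 0 when nothing is determined.
#'
#' @param network A `dtnet` object.
#' @return A one-row tibble with columns `mu_plus`, `mu_minus`, `mu_star`,
#'   `c_dt`. `c_dt` is carried at full precision; use [round_half_up()] for
#'   display.
#' @export
#' @examples
#' completeness(load_worked_example()) # c_dt = 26/32 = 0.8125
completeness <- function(network) {
  check_dtnet(network)
  sub <- decompose_network(network)
  mu_plus <- sum(sub$a_plus); mu_minus <- sum(sub$a_minus)
  mu_star <- sum(sub$a_star)
  tibble::tibble(
    mu_plus = mu_plus, mu_minus = mu_minus, mu_star = mu_star,
    c_dt = (mu_plus + mu_minus) / (mu_plus + mu_minus + mu_star)
  )
}

#' Local uncertainty via the degree-sum identity
#'
#' For every entity, active + inactive + unknown degree equals the opposite
#' side's cardinality, so the unknown degree can be recovered without
#' counting unknowns directly: for a drug it is `|T| - active - inactive`,
#' for a target `|D| - active - inactive`. This function computes the
#' uncertainty by that rearrangement — it must (and, by the partition
#' property, does) coincide with `colored_degree(..., "unknown")`.
#'
#' @param network A `dtnet` object.
#' @param entity Optional single entity label; with `side`, returns a bare
#'   count. Omit both to get the full table.
#' @param side `"drug"` or `"target"` when `entity` is given.
#' @return A tibble with columns `entity`, `side`, `uncertainty`, or a
#'   single count when `entity` is supplied.
#' @export
#' @examples
#' local_uncertainty(load_worked_example(), "d3", "drug") # 2
local_uncertainty <- function(network, entity = NULL,
                              side = c("drug", "target")) {
  check_dtnet(network)
  n <- nrow(network$status); m <- ncol(network$status)
  prof <- entity_profiles(network)
  opp <- ifelse(prof$side == "drug", m, n)
  out <- tibble::tibble(
    entity = prof$entity, side = prof$side,
    uncertainty = as.integer(opp - prof$active - prof$inactive)
  )
  if (!is.null(entity)) {
    side <- match.arg(side)
    hit <- out$entity == entity & out$side == side
    if (!any(hit)) {
      abort_lookup(sprintf("no %s named '%s' in the network", side, entity))
    }
    return(out$uncertainty[hit])
  }
  out
}

#' Bounds on the true degrees of polypharmacology and polyspecificity
#'
#' In an incomplete network the observed active degree underestimates the
#' true one whenever unknown pairs are actually active. Assuming all unknown
#' pairs inactive gives the lower bound (the observed active degree);
#' assuming them all active gives the upper bound (active + unknown degree).
#' If every determination is correct, the true degree lies in
#' `[lower, upper]`; the interval width is the entity's local uncertainty,
#' and each new determination can only tighten it. The upper bound never
#' exceeds the opposite side's cardinality — that maximum is attained only
#' when the active subnetwork is complete bipartite.
#'
#' @param network A `dtnet` object.
#' @param entity Optional single entity label (with `side`) to return one
#'   row only.
#' @param side `"drug"` or `"target"` when `entity` is given.
#' @return A tibble with columns `entity`, `side`, `lower`, `upper`.
#' @export
#' @examples
#' degree_bounds(load_worked_example())
degree_bounds <- function(network, entity = NULL,
                          side = c("drug", "target")) {
  check_dtnet(network)
  prof <- entity_profiles(network)
  out <- tibble::tibble(
    entity = prof$entity, side = prof$side,
    lower = as.integer(prof$active),
    upper = as.integer(prof$active + prof$unknown)
  )
  if (!is.null(entity)) {
    side <- match.arg(side)
    hit <- out$entity == entity & out$side == side
    if (!any(hit)) {
      abort_lookup(sprintf("no %s named '%s' in the network", side, entity))
    }
    return(out[hit, , drop = FALSE])
  }
  out
}

#' Distance or similarity between two interaction profiles
#'
#' Compares two 3-component profile vectors (active, inactive, unknown) from
#' the same side. Euclidean distance is 0 exactly for equal vectors; cosine
#' similarity lies in `[0, 1]` because the components are non-negative
#' counts, and equals 1 for parallel vectors. Cosine similarity is undefined
#' for a zero vector and raises an error rather than returning a
#' conventional value, since a silent default would corrupt any downstream
#' clustering.
#'
#' @param p,q One-row profile tibbles (as from [profile_vector()]) or
#'   numeric 3-vectors `(active, inactive, unknown)`.
#' @param metric `"euclidean"` (default) or `"cosine_similarity"`.
#' @return A single number.
#' @export
#' @examples
#' net <- load_worked_example()
#' profile_distance(profile_vector(net, "d2", "drug"),
#'                  profile_vector(net, "d5", "drug"))
profile_distance <- function(p, q,
                             metric = c("euclidean", "cosine_similarity")) {
  metric <- match.arg(metric)
  as_vec <- function(x, name) {
    if (is.data.frame(x)) {
      if (nrow(x) != 1 ||
          !all(c("active", "inactive", "unknown") %in% names(x))) {
        abort_invalid(sprintf(
          "`%s` must be a one-row profile with active/inactive/unknown columns",
          name
        ))
      }
      x <- c(x$active, x$inactive, x$unknown)
    }
    if (!is.numeric(x) || length(x) != 3 || any(x < 0)) {
      abort_invalid(sprintf("`%s` must be a non-negative 3-vector", name))
    }
    as.numeric(x)
  }
  if (is.data.frame(p) && is.data.frame(q) &&
      "side" %in% names(p) && "side" %in% names(q) &&
      !identical(p$side, q$side)) {
    abort_invalid("profiles must come from the same side (both drug or both target)")
  }
  pv <- as_vec(p, "p"); qv <- as_vec(q, "q")
  switch(metric,
    euclidean = sqrt(sum((pv - qv)^2)),
    cosine_similarity = {
      np <- sqrt(sum(pv^2)); nq <- sqrt(sum(qv^2))
      if (np == 0 || nq == 0) {
        abort_invalid(
          "cosine similarity is undefined for a zero profile vector"
        )
      }
      sum(pv * qv) / (np * nq)
    }
  )
}

#' Pairwise profile distances within one side
#'
#' Computes the full pairwise distance (or similarity) table among the
#' drugs or among the targets of a network, for use with any clustering
#' method downstream.
#'
#' @param network A `dtnet` object.
#' @param side `"drug"` or `"target"`.
#' @param metric Passed to [profile_distance()].
#' @return A tibble with columns `from`, `to`, `value`, covering all
#'   unordered pairs (upper triangle, deterministic network order).
#' @export
profile_distances <- function(network, side = c("drug", "target"),
                              metric = c("euclidean", "cosine_similarity")) {
  check_dtnet(network)
  side <- match.arg(side)
  metric <- match.arg(metric)
  prof <- entity_profiles(network, side = side)
  vecs <- as.matrix(prof[, c("active", "inactive", "unknown")])
  idx <- utils::combn(nrow(prof), 2)
  tibble::tibble(
    from = prof$entity[idx[1, ]],
    to = prof$entity[idx[2, ]],
    value = purrr::map2_dbl(
      idx[1, ], idx[2, ],
      function(i, j) profile_distance(vecs[i, ], vecs[j, ], metric)
    )
  )
}

#' Per-entity summary table
#'
#' One row per entity on both sides, combining the colored degrees with the
#' degree bounds: columns `entity`, `side`, `active`, `inactive`, `unknown`,
#' `lower_bound`, `upper_bound`. The network-level completeness report is
#' attached as attribute `"completeness"` and shown by the print method.
#' Row order is deterministic: drugs in network order, then targets.
#'
#' @param network A `dtnet` object.
#' @return A tibble (class `dt_summary`).
#' @export
#' @examples
#' summary_table(load_worked_example())
summary_table <- function(network) {
  check_dtnet(network)
  prof <- entity_profiles(network)
  out <- dplyr::mutate(
    prof,
    dplyr::across(c("active", "inactive", "unknown"), as.integer),
    lower_bound = as.integer(.data$active),
    upper_bound = as.integer(.data$active + .data$unknown)
  )
  attr(out, "completeness") <- completeness(network)
  class(out) <- c("dt_summary", class(out))
  out
}

#' @export
print.dt_summary <- function(x, ...) {
  NextMethod()
  comp <- attr(x, "completeness")
  if (!is.null(comp)) {
    cat(sprintf(
      "# completeness: mu+ = %d, mu- = %d, mu* = %d, c_dt = %s\n",
      comp$mu_plus, comp$mu_minus, comp$mu_star,
      format(round_half_up(comp$c_dt, 3), nsmall = 3)
    ))
  }
  invisible(x)
}

#' Write a summary table as TSV
#'
#' Serialises [summary_table()] output with the fixed column order
#' `entity`, `side`, `active`, `inactive`, `unknown`, `lower_bound`,
#' `upper_bound`.
#'
#' @param summary A `dt_summary` tibble (or a `dtnet`, summarised first).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  if (inherits(summary, "dtnet")) summary <- summary_table(summary)
  cols <- c("entity", "side", "active", "inactive", "unknown",
            "lower_bound", "upper_bound")
  readr::write_tsv(summary[, cols], path)
  invisible(path)
}
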