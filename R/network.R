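#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

new_dtnet <- function(status) {
  stopifnot(is.matrix(status), is.character(status))
  structure(list(status = status), class = "dtnet")
}

validate_labels <- function(drugs, targets) {
  drugs <- trimws(as.character(drugs))
  targets <- trimws(as.character(targets))
  if (length(drugs) < 1 || length(targets) < 1) {
    abort_invalid("a network needs at least one drug and one target")
  }
  if (any(drugs == "") || any(targets == "")) {
    abort_invalid("drug and target labels must be non-empty after trimming")
  }
  if (anyDuplicated(drugs)) {
    abort_invalid(sprintf(
      "duplicate drug labels: %s",
      paste(unique(drugs[duplicated(drugs)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(targets)) {
    abort_invalid(sprintf(
      "duplicate target labels: %s",
      paste(unique(targets[duplicated(targets)]), collapse = ", ")
    ))
  }
  clash <- intersect(drugs, targets)
  if (length(clash)) {
    abort_invalid(sprintf(
      paste0("labels appear on both sides of the bipartite network: %s ",
             "(rename, or use `suffix_sides = TRUE`)"),
      paste(clash, collapse = ", ")
    ))
  }
  list(drugs = drugs, targets = targets)
}

#' Construct an edge-colored drug-target network from a status matrix
#'
#' Low-level constructor. Most users will build networks from activity
#' records with [dt_network()] or from files with [read_edge_list()] /
#' [read_status_matrix()].
#'
#' @param status Character matrix over `"active"`/`"inactive"`/`"unknown"`;
#'   rows are drugs, columns are targets. Row/column names supply the labels
#'   unless `drugs`/`targets` are given.
#' @param drugs,targets Optional label vectors overriding the dimnames.
#' @param suffix_sides If `TRUE`, a label occurring on both sides is
#'   disambiguated by suffixing `:D` / `:T` instead of raising an error.
#'   Bipartite networks require disjoint drug and target label sets.
#' @return A `dtnet` object.
#' @export
dtnet <- function(status, drugs = rownames(status),
                  targets = colnames(status), suffix_sides = FALSE) {
  if (!is.matrix(status)) abort_invalid("`status` must be a matrix")
  status <- matrix(as_status(status), nrow = nrow(status))
  if (anyNA(status)) abort_invalid("`status` must not contain NA")
  if (is.null(drugs)) drugs <- paste0("d", seq_len(nrow(status)))
  if (is.null(targets)) targets <- paste0("t", seq_len(ncol(status)))
  if (isTRUE(suffix_sides)) {
    clash <- intersect(trimws(drugs), trimws(targets))
    if (length(clash)) {
      drugs <- ifelse(trimws(drugs) %in% clash, paste0(trimws(drugs), ":D"), drugs)
      targets <- ifelse(trimws(targets) %in% clash, paste0(trimws(targets), ":T"), targets)
    }
  }
  lab <- validate_labels(drugs, targets)
  if (length(lab$drugs) != nrow(status) || length(lab$targets) != ncol(status)) {
    abort_invalid("label lengths must match the status matrix dimensions")
  }
  dimnames(status) <- list(lab$drugs, lab$targets)
  new_dtnet(status)
}

#' Drug and target labels of a network
#'
#' @param network A `dtnet` object.
#' @return Character vector of labels, in network order.
#' @export
drugs <- function(network) rownames(network$status)

#' @rdname drugs
#' @export
targets <- function(network) colnames(network$status)

check_dtnet <- function(network) {
  if (!inherits(network, "dtnet")) {
    abort_invalid("`network` must be a `dtnet` object (see `dt_network()`)")
  }
  network
}

resolve_conflict <- function(statuses, pair, policy) {
  u <- unique(statuses)
  if (length(u) == 1) return(u)
  switch(policy,
    error = abort_conflict(sprintf(
      "conflicting statuses for pair (%s, %s): %s",
      pair[1], pair[2], paste(statuses, collapse = ", ")
    )),
    any_active = if ("active" %in% u) "active" else "inactive",
    majority = {
      tab <- table(factor(statuses, levels = c("active", "inactive")))
      if (tab[["active"]] == tab[["inactive"]]) "unknown"
      else names(tab)[which.max(tab)]
    }
  )
}

#' Build an edge-colored network from activity records
#'
#' Assembles a ternary (active/inactive/unknown) drug-target network from a
#' long-format table of activity records. Each record asserts either an
#' explicit `status` or a quantitative `value` (uM) that is classified
#' against `threshold` via [classify_activity()]; a record carrying both must
#' agree after classification. Every pair of the drug x target universe
#' receives exactly one status; pairs with no record are `"unknown"`
#' (unknown-by-omission — public databases rarely report inactives, so an
#' unreported pair cannot be assumed inactive).
#'
#' @param records Data frame with columns `drug`, `target`, and `status`
#'   and/or `value` (plus optional `source`). May have zero rows.
#' @param drugs,targets Optional label universes. When given they fix the
#'   row/column order and must cover every label in `records`; pairs not
#'   mentioned by any record become `"unknown"`. When omitted, the universe
#'   is the labels seen in `records`, in first-seen order.
#' @param threshold,direction Passed to [classify_activity()] for records
#'   with a `value` and no `status`.
#' @param conflict How to resolve contradictory determinations for one pair:
#'   `"error"` (default — fail naming the pair), `"any_active"` (one active
#'   determination wins), or `"majority"` (ties resolve to `"unknown"`).
#' @param unknown_as_inactive If `TRUE`, pairs with no record become
#'   `"inactive"` instead of `"unknown"` (decoy-style datasets). Off by
#'   default; assuming absence means inactivity discards information.
#' @param suffix_sides Passed to [dtnet()].
#' @return A `dtnet` object.
#' @export
#' @examples
#' recs <- tibble::tribble(
#'   ~drug, ~target, ~status,
#'   "d1", "t1", "active",
#'   "d1", "t2", "inactive",
#'   "d2", "t1", "active"
#' )
#' net <- dt_network(recs)
#' tidy(net)
dt_network <- function(records, drugs = NULL, targets = NULL,
                       threshold = 10,
                       direction = c("at_most", "at_least"),
                       conflict = c("error", "any_active", "majority"),
                       unknown_as_inactive = FALSE,
                       suffix_sides = FALSE) {
  direction <- match.arg(direction)
  conflict <- match.arg(conflict)
  if (!is.data.frame(records)) {
    abort_invalid("`records` must be a data frame of activity records")
  }
  records <- tibble::as_tibble(records)
  has_status <- "status" %in% names(records)
  has_value <- "value" %in% names(records)
  if (nrow(records) > 0) {
    if (!all(c("drug", "target") %in% names(records))) {
      abort_invalid("`records` must have `drug` and `target` columns")
    }
    if (!has_status && !has_value) {
      abort_invalid("`records` must have a `status` or a `value` column")
    }
    records$drug <- trimws(as.character(records$drug))
    records$target <- trimws(as.character(records$target))
    if (any(records$drug == "") || any(records$target == "")) {
      abort_invalid("record drug/target labels must be non-empty after trimming")
    }
  }

  rec_status <- character(nrow(records))
  if (nrow(records) > 0) {
    explicit <- if (has_status) as_status(records$status) else
      rep(NA_character_, nrow(records))
    measured <- rep(NA_character_, nrow(records))
    if (has_value) {
      if (!is.numeric(records$value)) abort_invalid("`value` must be numeric")
      ok <- !is.na(records$value)
      if (any(ok)) {
        measured[ok] <- classify_activity(records$value[ok], threshold, direction)
      }
    }
    neither <- is.na(explicit) & is.na(measured)
    if (any(neither)) {
      abort_invalid(sprintf(
        "record(s) %s carry neither a status nor a value",
        paste(which(neither), collapse = ", ")
      ))
    }
    both <- !is.na(explicit) & !is.na(measured)
    if (any(explicit[both] == "unknown")) {
      abort_invalid("a record with a measured value cannot assert status 'unknown'")
    }
    disagree <- both & explicit != measured
    if (any(disagree)) {
      i <- which(disagree)[1]
      abort_invalid(sprintf(
        paste0("record %d (%s, %s): explicit status '%s' disagrees with ",
               "value %g uM classified as '%s'"),
        i, records$drug[i], records$target[i], explicit[i],
        records$value[i], measured[i]
      ))
    }
    rec_status <- ifelse(is.na(explicit), measured, explicit)
  }

  seen_drugs <- unique(records$drug)
  seen_targets <- unique(records$target)
  if (is.null(drugs)) drugs <- seen_drugs else {
    drugs <- trimws(as.character(drugs))
    missing_d <- setdiff(seen_drugs, drugs)
    if (length(missing_d)) {
      abort_invalid(sprintf(
        "record drug label(s) outside the supplied universe: %s",
        paste(missing_d, collapse = ", ")
      ))
    }
  }
  if (is.null(targets)) targets <- seen_targets else {
    targets <- trimws(as.character(targets))
    missing_t <- setdiff(seen_targets, targets)
    if (length(missing_t)) {
      abort_invalid(sprintf(
        "record target label(s) outside the supplied universe: %s",
        paste(missing_t, collapse = ", ")
      ))
    }
  }
  if (length(drugs) < 1 || length(targets) < 1) {
    abort_invalid("cannot build a network with an empty drug or target set")
  }

  base <- if (isTRUE(unknown_as_inactive)) "inactive" else "unknown"
  status <- matrix(base, nrow = length(drugs), ncol = length(targets),
                   dimnames = list(drugs, targets))
  if (nrow(records) > 0) {
    keyed <- tibble::tibble(
      drug = records$drug, target = records$target, status = rec_status
    )
    # an explicit "unknown" record asserts nothing beyond the default
    det <- keyed[keyed$status != "unknown", , drop = FALSE]
    per_pair <- dplyr::group_by(det, .data$drug, .data$target)
    resolved <- dplyr::summarise(
      per_pair,
      status = resolve_conflict(
        .data$status, c(.data$drug[1], .data$target[1]), conflict
      ),
      .groups = "drop"
    )
    status[cbind(
      match(resolved$drug, drugs), match(resolved$target, targets)
    )] <- resolved$status
  }
  dtnet(status, drugs = drugs, targets = targets, suffix_sides = suffix_sides)
}

#' Transpose an edge-colored network
#'
#' Swaps the roles of drugs and targets: the result is the m x n network
#' whose "drugs" are the original targets and whose status for
#' `(t_j, d_i)` equals the original status of `(d_i, t_j)`. Nothing
#' substantive changes under transposition — the target-drug relation is the
#' transpose of the drug-target relation, which is why polyspecificity in a
#' network equals polypharmacology in its transpose.
#'
#' @param x A `dtnet` object.
#' @return The transposed `dtnet`.
#' @export
#' @method t dtnet
t.dtnet <- function(x) new_dtnet(t(x$status))

#' @export
print.dtnet <- function(x, ...) {
  n <- nrow(x$status); m <- ncol(x$status)
  counts <- table(factor(x$status, levels = dt_statuses))
  cat(sprintf(
    "<dtnet> %d drugs x %d targets: %d active, %d inactive, %d unknown\n",
    n, m, counts[["active"]], counts[["inactive"]], counts[["unknown"]]
  ))
  invisible(x)
}

#' @export
dim.dtnet <- function(x) dim(x$status)

#' Pairwise status table of a network
#'
#' `tidy()` returns one row per drug-target pair with its status — the
#' long-format view of the ternary matrix, suitable for dplyr/ggplot2 work
#' and for round-tripping through [dt_network()].
#'
#' @param x A `dtnet` object.
#' @param ... Unused.
#' @return A tibble with columns `drug`, `target`, `status`, in drug-major
#'   network order.
#' @method tidy dtnet
#' @export
tidy.dtnet <- function(x, ...) {
  d <- drugs(x); tg <- targets(x)
  tibble::tibble(
    drug = rep(d, each = length(tg)),
    target = rep(tg, times = length(d)),
    status = as.vector(t(x$status))
  )
}

#' One-row network summary
#'
#' `glance()` reports the network dimensions, the edge counts by color and
#' the global data-completeness fraction `c_dt` (see [completeness()]).
#'
#' @param x A `dtnet` object.
#' @param ... Unused.
#' @return A one-row tibble with columns `n_drugs`, `n_targets`, `mu_plus`,
#'   `mu_minus`, `mu_star`, `c_dt`.
#' @method glance dtnet
#' @export
glance.dtnet <- function(x, ...) {
  comp <- completeness(x)
  tibble::tibble(
    n_drugs = nrow(x$status), n_targets = ncol(x$status),
    mu_plus = comp$mu_plus, mu_minus = comp$mu_minus,
    mu_star = comp$mu_star, c_dt = comp$c_dt
  )
}

#' @export
as.matrix.dtnet <- function(x, ...) x$status
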