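#' Edge-list dialect
#'
#' Describes how a long-format interaction file is laid out: the field
#' delimiter, the vocabulary mapping status tokens to statuses, and the
#' unit the value column is expressed in. The default vocabulary accepts
#' `active`/`inactive`/`unknown` case-insensitively plus numeric `1`/`0`
#' tokens in the status column.
#'
#' @param delimiter Field delimiter (default tab).
#' @param status_vocabulary Named character vector mapping lower-cased file
#'   tokens to statuses (`"active"`, `"inactive"`, `"unknown"`).
#' @param unit Unit of the value column (default `"uM"`, the canonical unit
#'   for potency readouts).
#' @return An `edge_list_dialect` object.
#' @export
edge_list_dialect <- function(delimiter = "\t",
                              status_vocabulary = c(
                                active = "active", inactive = "inactive",
                                unknown = "unknown",
                                "1" = "active", "0" = "inactive"
                              ),
                              unit = "uM") {
  if (!is.character(delimiter) || nchar(delimiter) != 1) {
    abort_invalid("`delimiter` must be a single character")
  }
  tokens <- names(status_vocabulary)
  if (is.null(tokens) || anyDuplicated(tolower(tokens))) {
    abort_invalid("status vocabulary tokens must be named and pairwise distinct")
  }
  as_status(status_vocabulary, "status vocabulary")
  structure(
    list(delimiter = delimiter,
         status_vocabulary = stats::setNames(
           as.character(status_vocabulary), tolower(tokens)
         ),
         unit = unit),
    class = "edge_list_dialect"
  )
}

# Read a delimited file keeping original line numbers (comments/blanks
# skipped), so parse errors can point at the offending source line.
read_delim_lines <- function(path, delimiter) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) abort_format(sprintf("%s: no header row found", path))
  lines <- raw[keep]
  numbers <- which(keep)
  tbl <- readr::read_delim(
    I(paste(lines, collapse = "\n")), delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort_format(sprintf(
      "%s: malformed row at line %d (%s)",
      path, numbers[prob$row[1] + 1], prob$expected[1]
    ))
  }
  list(table = tbl, lines = numbers)
}

#' Read an edge list into an edge-colored network
#'
#' Parses a delimited long-format interaction file (header row naming
#' columns `drug`, `target`, and `status` or `value`; `#` lines ignored)
#' and delegates to [dt_network()]. Pairs not mentioned in the file are
#' `"unknown"` when universes are supplied (unknown-by-omission).
#'
#' @param path File path.
#' @param dialect An [edge_list_dialect()].
#' @param threshold,direction Classification of `value` rows, per
#'   [classify_activity()].
#' @param drugs,targets Optional label universes (see [dt_network()]).
#' @param conflict Conflict policy (see [dt_network()]).
#' @return A `dtnet` object.
#' @export
read_edge_list <- function(path, dialect = edge_list_dialect(),
                           threshold = 10,
                           direction = c("at_most", "at_least"),
                           drugs = NULL, targets = NULL,
                           conflict = c("error", "any_active", "majority")) {
  direction <- match.arg(direction)
  conflict <- match.arg(conflict)
  if (!inherits(dialect, "edge_list_dialect")) {
    abort_invalid("`dialect` must be created with `edge_list_dialect()`")
  }
  parsed <- read_delim_lines(path, dialect$delimiter)
  tbl <- parsed$table
  names(tbl) <- tolower(trimws(names(tbl)))
  if (!all(c("drug", "target") %in% names(tbl))) {
    abort_format(sprintf(
      "%s: header must name `drug` and `target` columns (found: %s)",
      path, paste(names(tbl), collapse = ", ")
    ))
  }
  has_status <- "status" %in% names(tbl)
  has_value <- "value" %in% names(tbl)
  if (!has_status && !has_value) {
    abort_format(sprintf(
      "%s: header must name a `status` or a `value` column", path
    ))
  }
  line_of <- function(i) parsed$lines[i + 1] # +1: header is first kept line
  records <- tibble::tibble(drug = tbl$drug, target = tbl$target)
  if (has_status) {
    tok <- tolower(trimws(tbl$status))
    mapped <- dialect$status_vocabulary[tok]
    bad <- which(!is.na(tok) & tok != "" & is.na(mapped))
    if (length(bad)) {
      abort_format(sprintf(
        "%s: unmappable status token '%s' at line %d",
        path, tbl$status[bad[1]], line_of(bad[1])
      ))
    }
    records$status <- unname(mapped)
  }
  if (has_value) {
    val <- suppressWarnings(as.numeric(tbl$value))
    bad <- which(!is.na(tbl$value) & tbl$value != "" & is.na(val))
    if (length(bad)) {
      abort_format(sprintf(
        "%s: non-numeric value '%s' at line %d",
        path, tbl$value[bad[1]], line_of(bad[1])
      ))
    }
    records$value <- val
  }
  if ("source" %in% names(tbl)) records$source <- tbl$source
  dt_network(records, drugs = drugs, targets = targets,
             threshold = threshold, direction = direction,
             conflict = conflict)
}

#' Write a network as an edge list
#'
#' One row per pair in drug-major network order, columns `drug`, `target`,
#' `status`. Unknown pairs are omitted by default, mirroring real database
#' exports that report determined (mostly active) interactions only; set
#' `include_unknown = TRUE` for a lossless file that [read_edge_list()]
#' round-trips exactly (given the network's universes).
#'
#' @param network A `dtnet` object.
#' @param path Output file path.
#' @param dialect An [edge_list_dialect()] (controls the delimiter).
#' @param include_unknown Write unknown pairs too? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, dialect = edge_list_dialect(),
                            include_unknown = FALSE) {
  check_dtnet(network)
  rows <- tidy(network)
  if (!include_unknown) rows <- rows[rows$status != "unknown", , drop = FALSE]
  readr::write_delim(rows, path, delim = dialect$delimiter)
  invisible(path)
}

status_to_cell <- c(active = "1", inactive = "0", unknown = "?")
cell_to_status <- c("1" = "active", "0" = "inactive", "?" = "unknown")

#' Read or write a ternary status matrix
#'
#' The status-matrix format is a CSV holding the full ternary matrix: the
#' first row lists the target labels, the first column the drug labels, and
#' each cell is `1` (active), `0` (inactive) or `?` (unknown). Unlike edge
#' lists, a matrix always carries all n x m cells, so the round trip is
#' lossless.
#'
#' @param path File path.
#' @return `read_status_matrix()` returns a `dtnet`;
#'   `write_status_matrix()` returns `path` invisibly.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_status_matrix(load_worked_example(), tmp)
#' read_status_matrix(tmp)
read_status_matrix <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- raw[!grepl("^\\s*$", raw)]
  if (length(raw) < 2) {
    abort_format(sprintf("%s: need a header row and at least one drug row", path))
  }
  fields <- strsplit(raw, ",", fixed = TRUE)
  header <- trimws(fields[[1]])
  m <- length(header) - 1
  if (m < 1) abort_format(sprintf("%s: header row names no targets", path))
  target_labels <- header[-1]
  n <- length(raw) - 1
  status <- matrix(NA_character_, n, m)
  drug_labels <- character(n)
  for (i in seq_len(n)) {
    row <- trimws(fields[[i + 1]])
    if (length(row) != m + 1) {
      abort_format(sprintf(
        "%s: row %d has %d fields, expected %d", path, i + 1, length(row), m + 1
      ))
    }
    drug_labels[i] <- row[1]
    cells <- row[-1]
    bad <- which(!cells %in% names(cell_to_status))
    if (length(bad)) {
      abort_format(sprintf(
        "%s: invalid cell '%s' at row %d (drug '%s'), column %d (target '%s'); cells must be 1, 0 or ?",
        path, cells[bad[1]], i + 1, drug_labels[i], bad[1], target_labels[bad[1]]
      ))
    }
    status[i, ] <- cell_to_status[cells]
  }
  dtnet(status, drugs = drug_labels, targets = target_labels)
}

#' @rdname read_status_matrix
#' @param network A `dtnet` object.
#' @export
write_status_matrix <- function(network, path) {
  check_dtnet(network)
  cells <- matrix(status_to_cell[network$status], nrow = nrow(network$status))
  lines <- c(
    paste(c("", targets(network)), collapse = ","),
    paste(drugs(network), apply(cells, 1, paste, collapse = ","), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

status_colors <- c(active = "green", inactive = "red", unknown = "black")

#' Export a network as GraphML
#'
#' Writes the edge-colored bipartite graph in GraphML with a node attribute
#' `part` (`drug` or `target`) and edge attributes `status` and `color`
#' (active = green, inactive = red, unknown = black). Unknown pairs are
#' omitted by default; `include_unknown = TRUE` writes one edge per pair.
#'
#' @param network A `dtnet` object.
#' @param path Output file path.
#' @param include_unknown Write edges for unknown pairs? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path, include_unknown = FALSE) {
  check_dtnet(network)
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  key <- function(id, domain, name) {
    xml2::xml_add_child(doc, "key", id = id, `for` = domain,
                        attr.name = name, attr.type = "string")
  }
  key("part", "node", "part")
  key("status", "edge", "status")
  key("color", "edge", "color")
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  add_node <- function(label, part) {
    node <- xml2::xml_add_child(graph, "node", id = label)
    data <- xml2::xml_add_child(node, "data", key = "part")
    xml2::xml_text(data) <- part
  }
  for (d in drugs(network)) add_node(d, "drug")
  for (tg in targets(network)) add_node(tg, "target")
  edges <- tidy(network)
  if (!include_unknown) edges <- edges[edges$status != "unknown", , drop = FALSE]
  purrr::pwalk(edges, function(drug, target, status) {
    edge <- xml2::xml_add_child(graph, "edge", source = drug, target = target)
    ds <- xml2::xml_add_child(edge, "data", key = "status")
    xml2::xml_text(ds) <- status
    dc <- xml2::xml_add_child(edge, "data", key = "color")
    xml2::xml_text(dc) <- unname(status_colors[status])
  })
  tryCatch(
    xml2::write_xml(doc, path),
    error = function(e) abort_format(sprintf("cannot write %s: %s", path,
                                             conditionMessage(e)))
  )
  invisible(path)
}

#' The packaged 8-drug x 4-target worked example
#'
#' A small ternary network of 8 drugs against 4 targets with 19 active, 7
#' inactive and 6 unknown pairs (completeness 26/32), used throughout the
#' documentation and tests. It is stored as a status-matrix CSV under
#' `inst/extdata/worked_example.csv`.
#'
#' @return A `dtnet` object.
#' @export
#' @examples
#' glance(load_worked_example())
load_worked_example <- function() {
  read_status_matrix(
    system.file("extdata", "worked_example.csv", package = "ternet",
                mustWork = TRUE)
  )
}
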