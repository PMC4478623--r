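# Field-level provenance: every (individual, field) pair carries exactly one
# source label (typically a pedigree file name, or "manual" after an edit).
# The table stores the current source only, not a history.

prov_fields <- function(ped) c(PED_ROLE_FIELDS, ped$attr_columns)

new_provenance <- function(ids, fields, default_source) {
  labels <- matrix(default_source, nrow = length(ids), ncol = length(fields),
                   dimnames = list(ids, fields))
  structure(list(labels = labels, default_source = default_source),
            class = "provenance")
}

#' Default provenance table for a pedigree
#'
#' When no metadata file accompanies a pedigree, every field of every
#' individual is attributed to the pedigree file itself.
#'
#' @param ped A pedigree.
#' @param source Source label (default: the file the pedigree was read from,
#'   falling back to the pedigree name).
#' @return A `provenance` object whose domain is exactly the
#'   (id, field) grid of `ped`: one row per member, one column per tracked
#'   field (father, mother, sex, then each attribute column).
#' @export
default_provenance <- function(ped, source = NULL) {
  source <- source %||% ped$source_file %||% ped$name
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  new_provenance(ped$members$id, prov_fields(ped), source)
}

#' @export
print.provenance <- function(x, ...) {
  cat(sprintf("<provenance: %d individual(s) x %d field(s), default source '%s'>\n",
              nrow(x$labels), ncol(x$labels), x$default_source))
  invisible(x)
}

assert_prov_entry <- function(prov, id, field) {
  if (!(id %in% rownames(prov$labels))) {
    stop(sprintf("no provenance row for individual '%s'", id), call. = FALSE)
  }
  if (!(field %in% colnames(prov$labels))) {
    stop(sprintf("no provenance column for field '%s'", field), call. = FALSE)
  }
  invisible(NULL)
}

#' Record the source of one field of one individual
#'
#' Pure update: returns a new table in which only the named entry differs
#' (setting an entry to its current label is a no-op that still returns an
#' equal table). Totality is preserved — the domain never changes.
#'
#' @param prov A `provenance` table.
#' @param id Individual identifier.
#' @param field Field name (father/mother/sex or an attribute column).
#' @param source New source label (non-empty).
#' @export
record_change <- function(prov, id, field, source) {
  assert_prov_entry(prov, id, field)
  stopifnot(is.character(source), length(source) == 1L, nzchar(source))
  prov$labels[id, field] <- source
  prov
}

#' Query the recorded source of one field of one individual
#'
#' @inheritParams record_change
#' @return The source label (length-1 character).
#' @export
trace_source <- function(prov, id, field) {
  assert_prov_entry(prov, id, field)
  unname(prov$labels[id, field])
}

# add a full provenance row for a newly created individual
prov_add_individual <- function(prov, id, source) {
  if (id %in% rownames(prov$labels)) {
    stop(sprintf("provenance row for '%s' already exists", id), call. = FALSE)
  }
  row <- matrix(source, 1L, ncol(prov$labels),
                dimnames = list(id, colnames(prov$labels)))
  prov$labels <- rbind(prov$labels, row)
  prov
}

prov_drop_individual <- function(prov, ids) {
  keep <- !(rownames(prov$labels) %in% ids)
  prov$labels <- prov$labels[keep, , drop = FALSE]
  prov
}

#' Write a provenance metadata file
#'
#' The metadata file mirrors the geometry of its pedigree file: one row per
#' individual in the same order, one column per pedigree column. The first
#' cell repeats the individual's id (self-description); every other cell
#' holds the source label of that individual's corresponding field.
#'
#' @param prov A `provenance` table.
#' @param ped The companion pedigree (defines row order and fields).
#' @param path Output path.
#' @param in_place Allow overwriting a session input.
#' @export
write_metadata <- function(prov, ped, path, in_place = FALSE) {
  refuse_overwrite(path, in_place)
  fields <- prov_fields(ped)
  check_prov_domain(prov, ped)
  lab <- prov$labels[ped$members$id, fields, drop = FALSE]
  lines <- c(paste(c("id", fields), collapse = "\t"),
             if (nrow(lab)) apply(cbind(ped$members$id, lab), 1L,
                                  paste, collapse = "\t"))
  writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Read a provenance metadata file
#'
#' @param path Path of the metadata file.
#' @param ped The companion pedigree; the file must have one row per member
#'   (same ids, same order) and one column per tracked field.
#' @return A `provenance` table.
#' @export
read_metadata <- function(path, ped) {
  if (!file.exists(path)) {
    stop(sprintf("metadata file '%s' does not exist", path), call. = FALSE)
  }
  lines <- gsub("\r$", "", readLines(path, encoding = "UTF-8"))
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) {
    stop(sprintf("metadata file '%s' is empty", path), call. = FALSE)
  }
  fields <- prov_fields(ped)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  expected <- c("id", fields)
  if (!identical(header, expected)) {
    stop(sprintf("metadata header mismatch in '%s': expected %d column(s) [%s], found %d [%s]",
                 path, length(expected), paste(expected, collapse = ", "),
                 length(header), paste(header, collapse = ", ")),
         call. = FALSE)
  }
  body <- lines[-1L]
  if (length(body) != nrow(ped$members)) {
    stop(sprintf("metadata geometry mismatch in '%s': expected %d row(s), found %d",
                 path, nrow(ped$members), length(body)), call. = FALSE)
  }
  cells <- lapply(body, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  nc <- lengths(cells)
  if (any(nc != length(expected))) {
    i <- which(nc != length(expected))[1L]
    stop(sprintf("metadata geometry mismatch in '%s' row %d: expected %d column(s), found %d",
                 path, i, length(expected), nc[i]), call. = FALSE)
  }
  tab <- do.call(rbind, cells)
  if (!identical(tab[, 1L], ped$members$id)) {
    stop(sprintf("metadata ids in '%s' do not match the pedigree row order",
                 path), call. = FALSE)
  }
  labels <- tab[, -1L, drop = FALSE]
  dimnames(labels) <- list(ped$members$id, fields)
  register_session_input(path)
  defaults <- table(labels)
  default_source <- if (length(defaults)) {
    names(defaults)[which.max(defaults)]
  } else {
    ped$source_file %||% ped$name
  }
  structure(list(labels = labels, default_source = default_source),
            class = "provenance")
}

# totality check: provenance domain == pedigree (id, field) grid
check_prov_domain <- function(prov, ped) {
  ids_ok <- setequal(rownames(prov$labels), ped$members$id)
  fields_ok <- setequal(colnames(prov$labels), prov_fields(ped))
  if (!ids_ok || !fields_ok) {
    stop("provenance table does not cover the pedigree's (id, field) domain",
         call. = FALSE)
  }
  if (any(!nzchar(prov$labels))) {
    stop("provenance table contains empty source labels", call. = FALSE)
  }
  invisible(TRUE)
}
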