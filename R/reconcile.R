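# Cross-pedigree comparison of one individual, discordance reconciliation,
# and single-individual editing (add / remove / edit). Everything here is
# copy-on-write: inputs are never modified.

#' Compare one individual's record across two pedigrees
#'
#' Produces one row per field in the union of the two pedigrees' field sets,
#' ordered deterministically: father, mother, sex, then the first pedigree's
#' attribute columns, then attributes present only in the second. A row is
#' `"equal"` iff both pedigrees carry the individual and the field and the
#' values are identical (the missing sentinel counts as a value);
#' `"discordant"` iff both carry it and they differ; `"only-A"`/`"only-B"`
#' when the field or the whole individual exists on one side only.
#'
#' @param a,b Pedigrees.
#' @param id The individual's identifier (under `match_key`).
#' @param match_key Field used to locate the individual in each pedigree
#'   (default the id itself).
#' @return A data frame of class `"field_diff"` with columns `field`,
#'   `value_a`, `value_b`, `status`, and attributes `id`, `name_a`, `name_b`.
#' @export
compare_individual <- function(a, b, id, match_key = "id") {
  locate <- function(ped) {
    keys <- member_keys(ped, ped$members$id, match_key)
    hits <- which(keys == id)
    if (length(hits) > 1L) {
      stop(sprintf("key '%s' is ambiguous in pedigree '%s'", id, ped$name),
           call. = FALSE)
    }
    if (length(hits)) ped$members[hits, , drop = FALSE] else NULL
  }
  ra <- locate(a)
  rb <- locate(b)
  if (is.null(ra) && is.null(rb)) {
    stop(sprintf("no such individual '%s' in pedigree '%s' or '%s'",
                 id, a$name, b$name), call. = FALSE)
  }
  fields <- c(PED_ROLE_FIELDS, a$attr_columns,
              setdiff(b$attr_columns, a$attr_columns))
  val <- function(row, ped, f) {
    if (is.null(row) || !(f %in% c(PED_ROLE_FIELDS, ped$attr_columns))) {
      NA_character_
    } else {
      row[[f]][1L]
    }
  }
  value_a <- vapply(fields, function(f) val(ra, a, f), character(1))
  value_b <- vapply(fields, function(f) val(rb, b, f), character(1))
  status <- ifelse(is.na(value_a) & !is.na(value_b), "only-B",
                   ifelse(!is.na(value_a) & is.na(value_b), "only-A",
                          ifelse(value_a == value_b, "equal", "discordant")))
  status[is.na(value_a) & is.na(value_b)] <- "absent"
  out <- data.frame(field = fields, value_a = unname(value_a),
                    value_b = unname(value_b), status = unname(status),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, id = id, name_a = a$name, name_b = b$name,
            class = c("field_diff", "data.frame"))
}

#' Render a field diff as an aligned text report
#'
#' @param diff A `field_diff` from [compare_individual()].
#' @return Character vector of report lines.
#' @export
format_field_diff <- function(diff) {
  hdr <- c("field", attr(diff, "name_a"), attr(diff, "name_b"), "status")
  show <- function(x) ifelse(is.na(x), "-", x)
  cells <- rbind(hdr, cbind(diff$field, show(diff$value_a),
                            show(diff$value_b), diff$status))
  widths <- apply(nchar(cells), 2L, max)
  apply(cells, 1L, function(r) {
    paste(mapply(function(cell, w) formatC(cell, width = w, flag = "-"),
                 r, widths),
          collapse = "  ")
  })
}

#' Reconcile discordant fields of one individual into a target pedigree
#'
#' Every discordant field reported by [compare_individual()] must be
#' resolved explicitly — an incomplete choice set is an error that lists the
#' unresolved fields, forcing review rather than silent defaulting. A choice
#' is `"A"` or `"B"` (take that pedigree's value) or any other string, which
#' is applied verbatim as an explicit value and attributed to `"manual"`.
#'
#' @param a,b Pedigrees.
#' @param id Individual identifier.
#' @param choices Named list/character vector, one entry per field to set.
#' @param target `"A"` or `"B"`: which pedigree receives the chosen values.
#' @param label_a,label_b Provenance labels for values donated by each
#'   pedigree (default: their source files or names).
#' @param match_key Field used to locate the individual.
#' @return A list with `ped` (the updated target pedigree) and `updates`
#'   (data frame `id`, `field`, `value`, `source` describing the provenance
#'   changes to apply, e.g. via [record_change()]).
#' @export
reconcile_individual <- function(a, b, id, choices = list(),
                                 target = c("A", "B"),
                                 label_a = NULL, label_b = NULL,
                                 match_key = "id") {
  target <- match.arg(target)
  label_a <- label_a %||% a$source_file %||% a$name
  label_b <- label_b %||% b$source_file %||% b$name
  diff <- compare_individual(a, b, id, match_key)
  discordant <- diff$field[diff$status == "discordant"]
  unresolved <- setdiff(discordant, names(choices))
  if (length(unresolved)) {
    stop(sprintf("unresolved discordant field(s) for '%s': %s",
                 id, paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  ped <- if (target == "A") a else b
  i <- assert_member(ped, id)
  updates <- list()
  for (f in names(choices)) {
    if (!(f %in% diff$field)) {
      stop(sprintf("unknown field '%s' in choices", f), call. = FALSE)
    }
    ch <- as.character(choices[[f]])
    if (ch == "A") {
      value <- diff$value_a[diff$field == f]
      source <- label_a
    } else if (ch == "B") {
      value <- diff$value_b[diff$field == f]
      source <- label_b
    } else {
      value <- ch
      source <- "manual"
    }
    if (is.na(value)) {
      stop(sprintf("field '%s' has no value on the chosen side", f),
           call. = FALSE)
    }
    ped <- apply_field(ped, i, f, value)
    updates[[length(updates) + 1L]] <- data.frame(
      id = id, field = f, value = value, source = source,
      stringsAsFactors = FALSE)
  }
  list(ped = ped,
       updates = do.call(rbind, updates) %||% data.frame(
         id = character(0), field = character(0), value = character(0),
         source = character(0), stringsAsFactors = FALSE))
}

apply_field <- function(ped, i, field, value) {
  if (field %in% c("father", "mother")) {
    if (value != ped$missing && !(value %in% ped$members$id)) {
      stop(sprintf("cannot set %s of '%s' to '%s': not in pedigree '%s'",
                   field, ped$members$id[i], value, ped$name), call. = FALSE)
    }
  } else if (field == "sex") {
    if (!(value %in% PED_SEXES)) {
      stop(sprintf("invalid sex value '%s'", value), call. = FALSE)
    }
  } else if (!(field %in% ped$attr_columns)) {
    stop(sprintf("no such field '%s' in pedigree '%s'", field, ped$name),
         call. = FALSE)
  }
  ped$members[[field]][i] <- value
  ped
}

as_member_row <- function(ped, individual) {
  ind <- as.list(individual)
  row <- data.frame(id = ind$id %||% stop("individual needs an 'id'",
                                          call. = FALSE),
                    father = ind$father %||% ped$missing,
                    mother = ind$mother %||% ped$missing,
                    sex = ind$sex %||% "unknown",
                    stringsAsFactors = FALSE)
  for (ac in ped$attr_columns) row[[ac]] <- ind[[ac]] %||% ped$missing
  extra <- setdiff(names(ind), names(row))
  if (length(extra)) {
    stop("unknown field(s) in individual: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  row
}

#' Add a single individual to a pedigree
#'
#' For inserting (or dropping, see [remove_individual()]) one person —
#' e.g. replacing an individual without touching their descendants — the
#' single-individual operations are preferable to the merge algorithms.
#'
#' @param ped A pedigree.
#' @param individual Named list or one-row data frame with `id` and
#'   optionally `father`, `mother`, `sex` and attribute values; omitted
#'   fields default to missing/unknown.
#' @param label Provenance label for the new row (default `"manual"`).
#' @param prov Optional provenance table to extend alongside.
#' @return A list with `ped` and `prov` (`NULL` when no table was given).
#' @export
add_individual <- function(ped, individual, label = "manual", prov = NULL) {
  row <- as_member_row(ped, individual)
  if (row$id %in% ped$members$id) {
    stop(sprintf("individual '%s' already exists in pedigree '%s'",
                 row$id, ped$name), call. = FALSE)
  }
  for (pf in c("father", "mother")) {
    v <- row[[pf]]
    if (v != ped$missing && !(v %in% ped$members$id)) {
      stop(sprintf("%s '%s' of new individual '%s' is not in pedigree '%s'",
                   pf, v, row$id, ped$name), call. = FALSE)
    }
  }
  ped$members <- rbind(ped$members, row[, names(ped$members), drop = FALSE])
  rownames(ped$members) <- NULL
  if (!is.null(prov)) prov <- prov_add_individual(prov, row$id, label)
  list(ped = ped, prov = prov)
}

#' Remove a single individual from a pedigree
#'
#' @param ped A pedigree.
#' @param id Individual to remove.
#' @param cascade `"forbid"` (default; error if anyone references `id` as a
#'   parent, listing the children) or `"detach-children"` (children's
#'   matching parent reference is set to the missing sentinel).
#' @param prov Optional provenance table; the individual's rows are dropped.
#' @return A list with `ped` and `prov`.
#' @export
remove_individual <- function(ped, id, cascade = c("forbid", "detach-children"),
                              prov = NULL) {
  cascade <- match.arg(cascade)
  i <- assert_member(ped, id)
  kids <- ped_children(ped, id)
  if (length(kids) && cascade == "forbid") {
    stop(sprintf("cannot remove '%s': referenced as a parent by %s (use cascade = \"detach-children\")",
                 id, paste(sprintf("'%s'", kids), collapse = ", ")),
         call. = FALSE)
  }
  m <- ped$members[-i, , drop = FALSE]
  m$father[m$father == id] <- ped$missing
  m$mother[m$mother == id] <- ped$missing
  rownames(m) <- NULL
  ped$members <- m
  if (!is.null(prov)) prov <- prov_drop_individual(prov, id)
  list(ped = ped, prov = prov)
}

#' Edit one field of one individual
#'
#' Copy-on-write single-field update. The provenance label is recorded even
#' when the new value equals the old one — re-asserting a value from a new
#' source is itself information.
#'
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @param field `father`, `mother`, `sex` or an attribute column.
#' @param value New value (parent references must resolve or be the
#'   sentinel; sex must be male/female/unknown).
#' @param label Provenance label (default `"manual"`).
#' @param prov Optional provenance table to update alongside.
#' @return A list with `ped` and `prov`.
#' @export
edit_individual <- function(ped, id, field, value, label = "manual",
                            prov = NULL) {
  i <- assert_member(ped, id)
  ped <- apply_field(ped, i, field, as.character(value))
  if (!is.null(prov)) prov <- record_change(prov, id, field, label)
  list(ped = ped, prov = prov)
}
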