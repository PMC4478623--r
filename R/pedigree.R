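# Core in-memory pedigree model: construction, traversal, sublineage
# extraction and structural validation.

PED_MISSING <- "0"
PED_ROLE_FIELDS <- c("father", "mother", "sex")
PED_SEXES <- c("male", "female", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a pedigree
#'
#' A pedigree holds one row per individual: a unique identifier, father and
#' mother references (the literal `"0"` marks a missing parent, following the
#' LINKAGE convention), a sex (`"male"`, `"female"` or `"unknown"`) and an
#' ordered set of named attribute columns (affection status, phenotypes,
#' genotypes, ...). Multiple descent trees, multiple spouses and
#' consanguineous marriage loops are all admitted; only ancestor cycles
#' (an individual being its own ancestor) are structural errors.
#'
#' @param members A data frame with character columns `id`, `father`,
#'   `mother`, `sex` plus any attribute columns. All values are coerced to
#'   character.
#' @param name Label for the family/pedigree.
#' @param attr_columns Ordered attribute column names; defaults to every
#'   member column beyond the four role columns, in order.
#' @param missing The missing-value sentinel used in attribute and parent
#'   fields (default `"0"`).
#' @param source_file Optional name of the file this pedigree was read from;
#'   used as the default provenance label.
#' @return An object of class `"pedigree"`.
#' @seealso [ped_validate()], [ped_descendants()], [ped_sublineage()]
#' @export
ped_new <- function(members, name = "pedigree", attr_columns = NULL,
                    missing = PED_MISSING, source_file = NULL) {
  stopifnot(is.data.frame(members))
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("id", PED_ROLE_FIELDS)
  miss <- setdiff(need, names(members))
  if (length(miss)) {
    stop("pedigree members lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  members[] <- lapply(members, as.character)
  rownames(members) <- NULL

  if (any(!nzchar(members$id))) {
    stop("individual identifiers must be non-empty", call. = FALSE)
  }
  if (any(grepl("[\t\n]", members$id))) {
    stop("individual identifiers must not contain tab or newline characters",
         call. = FALSE)
  }
  dup <- unique(members$id[duplicated(members$id)])
  if (length(dup)) {
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(members$sex), PED_SEXES)
  if (length(bad_sex)) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         " (expected male/female/unknown)", call. = FALSE)
  }

  attr_columns <- attr_columns %||% setdiff(names(members), need)
  if (anyDuplicated(attr_columns)) {
    stop("attribute column names must be unique", call. = FALSE)
  }
  if (length(intersect(attr_columns, need))) {
    stop("attribute columns must be disjoint from the role columns",
         call. = FALSE)
  }
  missing_attr <- setdiff(attr_columns, names(members))
  for (ac in missing_attr) members[[ac]] <- missing
  members <- members[, c(need, attr_columns), drop = FALSE]

  structure(
    list(name = name, members = members, attr_columns = attr_columns,
         missing = missing, source_file = source_file),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree '%s': %d members, %d attribute column(s)>\n",
              x$name, nrow(x$members), length(x$attr_columns)))
  if (nrow(x$members)) {
    print(utils::head(x$members, 10L), row.names = FALSE)
    if (nrow(x$members) > 10L) cat(sprintf("... %d more\n", nrow(x$members) - 10L))
  }
  invisible(x)
}

#' Member identifiers of a pedigree, in file order
#' @param ped A pedigree.
#' @return Character vector of ids.
#' @export
ped_ids <- function(ped) ped$members$id

#' Number of members in a pedigree
#' @param ped A pedigree.
#' @export
ped_size <- function(ped) nrow(ped$members)

#' Look up one individual as a one-row data frame
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @export
ped_member <- function(ped, id) {
  i <- assert_member(ped, id)
  ped$members[i, , drop = FALSE]
}

assert_member <- function(ped, id) {
  stopifnot(is.character(id), length(id) == 1L)
  i <- match(id, ped$members$id)
  if (is.na(i)) {
    stop(sprintf("no such individual '%s' in pedigree '%s'", id, ped$name),
         call. = FALSE)
  }
  i
}

#' Children of an individual, in file order
#' @param ped A pedigree.
#' @param id Individual identifier.
#' @export
ped_children <- function(ped, id) {
  m <- ped$members
  m$id[m$father == id | m$mother == id]
}

#' All descendants of an individual
#'
#' Follows parent-to-child edges transitively: an individual `c` is a child
#' of `p` iff `c`'s father or mother field equals `p`'s id. The result
#' excludes `id` itself and is ordered breadth-first by generation, within a
#' generation by file order, so output is deterministic and diffable.
#' There is no limit on the number of generations traversed.
#'
#' @param ped A pedigree.
#' @param id The individual whose descendants are sought.
#' @return Character vector of descendant ids (possibly empty).
#' @export
ped_descendants <- function(ped, id) {
  assert_member(ped, id)
  m <- ped$members
  out <- character(0)
  seen <- id
  frontier <- id
  while (length(frontier)) {
    kids <- m$id[(m$father %in% frontier | m$mother %in% frontier) &
                   !(m$id %in% seen)]
    out <- c(out, kids)
    seen <- c(seen, kids)
    frontier <- kids
  }
  out
}

#' Extract a sublineage: a root, its descendants, and married-in partners
#'
#' The sublineage rooted at an individual is the scope of every merge
#' operation: the root plus all of its descendants (`descent_ids`), extended
#' by the married-in partners needed so that no child inside the sublineage
#' is left with a dangling parent reference (`member_ids`). The root's own
#' parents are never included. Member order is deterministic: descent
#' members breadth-first by generation (file order within a generation),
#' with each married-in partner inserted when first encountered as a
#' co-parent.
#'
#' @param ped A pedigree.
#' @param root_id The highest individual of the sublineage.
#' @return An object of class `"sublineage"` with elements `root_id`,
#'   `descent_ids` (root first) and `member_ids` (ordered superset).
#' @export
ped_sublineage <- function(ped, root_id) {
  assert_member(ped, root_id)
  descent <- c(root_id, ped_descendants(ped, root_id))
  m <- ped$members
  ord <- character(0)
  for (d in descent) {
    if (!(d %in% ord)) ord <- c(ord, d)
    kids <- m$id[(m$father == d | m$mother == d) & m$id %in% descent]
    for (k in kids) {
      i <- match(k, m$id)
      ps <- c(m$father[i], m$mother[i])
      ps <- ps[ps != ped$missing & ps != d]
      for (p in ps) {
        if (!(p %in% descent) && !(p %in% ord)) ord <- c(ord, p)
      }
    }
  }
  structure(list(root_id = root_id, descent_ids = descent, member_ids = ord),
            class = "sublineage")
}

#' @export
print.sublineage <- function(x, ...) {
  cat(sprintf("<sublineage rooted at '%s': %d descent member(s), %d total>\n",
              x$root_id, length(x$descent_ids), length(x$member_ids)))
  invisible(x)
}

finding <- function(code, id, related, level, message) {
  data.frame(code = code, id = id, related = related, level = level,
             message = message, stringsAsFactors = FALSE)
}

empty_findings <- function() {
  data.frame(code = character(0), id = character(0), related = character(0),
             level = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Validate the structural invariants of a pedigree
#'
#' Returns findings rather than raising errors, so a damaged file can be
#' reported in full. Codes:
#' \describe{
#'   \item{DUPLICATE_ID}{the same id appears on more than one row (error).}
#'   \item{DANGLING_PARENT}{a parent reference names an id absent from the
#'     pedigree (error).}
#'   \item{PARENT_SEX_CONFLICT}{an individual referenced as a father is
#'     recorded female, or as a mother is recorded male (error).}
#'   \item{ANCESTOR_CYCLE}{an individual is its own ancestor (error).
#'     Consanguineous marriage loops are legal and are not flagged.}
#'   \item{HALF_SPECIFIED_PARENTS}{exactly one of the two parents is the
#'     missing sentinel (warning).}
#' }
#'
#' @param ped A pedigree.
#' @return A data frame of findings with columns `code`, `id`, `related`,
#'   `level` and `message`; zero rows means every invariant holds.
#' @export
ped_validate <- function(ped) {
  m <- ped$members
  out <- list(empty_findings())
  sent <- ped$missing
  ids <- m$id

  for (d in unique(ids[duplicated(ids)])) {
    out[[length(out) + 1L]] <- finding(
      "DUPLICATE_ID", d, "", "error",
      sprintf("id '%s' appears %d times", d, sum(ids == d)))
  }

  for (i in seq_len(nrow(m))) {
    for (role in c("father", "mother")) {
      p <- m[[role]][i]
      if (p != sent && !(p %in% ids)) {
        out[[length(out) + 1L]] <- finding(
          "DANGLING_PARENT", m$id[i], p, "error",
          sprintf("'%s' lists %s '%s' who is not in the pedigree",
                  m$id[i], role, p))
      }
    }
  }

  fathers <- unique(m$father[m$father != sent & m$father %in% ids])
  for (p in fathers[vapply(fathers, function(p) {
    m$sex[match(p, ids)] == "female"
  }, logical(1))]) {
    out[[length(out) + 1L]] <- finding(
      "PARENT_SEX_CONFLICT", p, "", "error",
      sprintf("'%s' is referenced as a father but recorded female", p))
  }
  mothers <- unique(m$mother[m$mother != sent & m$mother %in% ids])
  for (p in mothers[vapply(mothers, function(p) {
    m$sex[match(p, ids)] == "male"
  }, logical(1))]) {
    out[[length(out) + 1L]] <- finding(
      "PARENT_SEX_CONFLICT", p, "", "error",
      sprintf("'%s' is referenced as a mother but recorded male", p))
  }

  half <- (m$father == sent) != (m$mother == sent)
  for (i in which(half)) {
    out[[length(out) + 1L]] <- finding(
      "HALF_SPECIFIED_PARENTS", m$id[i], "", "warning",
      sprintf("'%s' has exactly one known parent", m$id[i]))
  }

  # ancestor cycles: reflexive pairs in the transitive closure of child->parent
  if (!anyDuplicated(ids) && nrow(m) > 0L) {
    n <- nrow(m)
    adj <- matrix(FALSE, n, n)
    for (role in c("father", "mother")) {
      p <- match(m[[role]], ids)
      ok <- !is.na(p) & m[[role]] != sent
      adj[cbind(which(ok), p[ok])] <- TRUE
    }
    reach <- adj
    repeat {
      nxt <- reach | ((reach %*% adj) > 0)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    for (i in which(diag(reach))) {
      out[[length(out) + 1L]] <- finding(
        "ANCESTOR_CYCLE", ids[i], "", "error",
        sprintf("'%s' is its own ancestor", ids[i]))
    }
  }

  do.call(rbind, out)
}

#' Do any error-level findings exist?
#' @param findings A findings data frame from [ped_validate()].
#' @export
ped_has_errors <- function(findings) any(findings$level == "error")

assert_valid <- function(ped, what = "pedigree") {
  f <- ped_validate(ped)
  if (ped_has_errors(f)) {
    stop(sprintf("%s '%s' has structural errors: %s", what, ped$name,
                 paste(f$message[f$level == "error"], collapse = "; ")),
         call. = FALSE)
  }
  invisible(f)
}

#' Id-anchored pedigree equality
#'
#' Two pedigrees are considered isomorphic when they contain the same ids
#' and, for every id, the same parent references, sex and attribute values.
#' Member order and attribute column order are immaterial; this is an
#' id-preserving match, deliberately not general graph isomorphism.
#'
#' @param a,b Pedigrees.
#' @return `TRUE`, or `FALSE` carrying a `"witness"` attribute naming the
#'   first difference found.
#' @export
ped_isomorphic <- function(a, b) {
  fail <- function(w) structure(FALSE, witness = w)
  if (!setequal(a$members$id, b$members$id)) {
    extra_a <- setdiff(a$members$id, b$members$id)
    extra_b <- setdiff(b$members$id, a$members$id)
    return(fail(sprintf("member sets differ (only in A: %s; only in B: %s)",
                        paste(extra_a, collapse = ","),
                        paste(extra_b, collapse = ","))))
  }
  if (!setequal(a$attr_columns, b$attr_columns)) {
    return(fail("attribute column sets differ"))
  }
  ids <- sort(a$members$id)
  ma <- a$members[match(ids, a$members$id), , drop = FALSE]
  mb <- b$members[match(ids, b$members$id), , drop = FALSE]
  for (cn in c(PED_ROLE_FIELDS, sort(a$attr_columns))) {
    neq <- which(ma[[cn]] != mb[[cn]])
    if (length(neq)) {
      i <- neq[1L]
      return(fail(sprintf("individual '%s' differs in field '%s' ('%s' vs '%s')",
                          ids[i], cn, ma[[cn]][i], mb[[cn]][i])))
    }
  }
  TRUE
}

#' Restrict a pedigree to a subset of its members
#'
#' Keeps the given ids in file order. Parent references pointing outside the
#' subset are replaced by the missing sentinel when `detach = TRUE`
#' (otherwise left as-is, which may produce DANGLING_PARENT findings).
#'
#' @param ped A pedigree.
#' @param ids Ids to keep.
#' @param detach Replace out-of-subset parent references with the sentinel.
#' @export
ped_subset <- function(ped, ids, detach = TRUE) {
  unknown <- setdiff(ids, ped$members$id)
  if (length(unknown)) {
    stop("unknown id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- ped$members[ped$members$id %in% ids, , drop = FALSE]
  if (detach) {
    m$father[!(m$father %in% m$id) & m$father != ped$missing] <- ped$missing
    m$mother[!(m$mother %in% m$id) & m$mother != ped$missing] <- ped$missing
  }
  ped_new(m, name = ped$name, attr_columns = ped$attr_columns,
          missing = ped$missing, source_file = ped$source_file)
}
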