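# The three merge algorithms (replacement, combination, addition) plus
# duplicate detection and resolution. All operations are pure: the input
# pedigrees and provenance tables are never modified; a new pedigree, a new
# provenance table and a merge report are returned.

#' Describe a merge operation
#'
#' A merge always runs from a source pedigree into a destination pedigree.
#' The scope of the operation is the sublineage of `source_root` (the root,
#' all of its descendants — with no generation limit — and the married-in
#' partners completing parental pairs).
#'
#' @param mode `"replace"` (the destination branch rooted at `dest_anchor`
#'   is removed and the source sublineage takes its place), `"combine"` (the
#'   source sublineage is folded into the destination, eliminating
#'   duplicates) or `"add"` (the source sublineage is appended with its root
#'   becoming a sibling of `dest_anchor`).
#' @param source,dest The source and destination pedigrees.
#' @param source_root Id of the highest source individual to merge.
#' @param dest_anchor Id of the destination individual anchoring the
#'   operation: the root of the replaced branch (replace), the destination
#'   sublineage root (combine), or the sibling-to-be (add). Defaults to
#'   `source_root`, the common case when both pedigrees name the shared
#'   ancestor identically.
#' @param match_key Field name(s) used to equate individuals across the two
#'   pedigrees when eliminating duplicates. The default `"id"` matches on
#'   the identifier; a composite key (e.g. `c("id", "BIRTHYEAR")`) may be
#'   given, in which case same-id individuals that do not match are id
#'   collisions (see `on_collision`).
#' @param on_collision `"error"` (default) or `"rename"`: what to do when an
#'   incoming individual's id already exists in the destination without
#'   being matched as a duplicate. Renaming appends `"@<source name>"` and
#'   is recorded in the report, because silent aliasing corrupts pedigrees.
#' @return A `merge_plan` object for [ped_merge()].
#' @export
merge_plan <- function(mode = c("replace", "combine", "add"), source, dest,
                       source_root, dest_anchor = source_root,
                       match_key = "id", on_collision = c("error", "rename")) {
  mode <- match.arg(mode)
  on_collision <- match.arg(on_collision)
  stopifnot(inherits(source, "pedigree"), inherits(dest, "pedigree"))
  assert_member(source, source_root)
  assert_member(dest, dest_anchor)
  structure(list(mode = mode, source = source, dest = dest,
                 source_root = source_root, dest_anchor = dest_anchor,
                 match_key = match_key, on_collision = on_collision),
            class = "merge_plan")
}

member_keys <- function(ped, ids, match_key) {
  m <- ped$members[match(ids, ped$members$id), , drop = FALSE]
  parts <- lapply(match_key, function(k) {
    if (k == "id") m$id
    else if (k %in% names(m)) m[[k]]
    else stop(sprintf("match key field '%s' not present in pedigree '%s'",
                      k, ped$name), call. = FALSE)
  })
  do.call(paste, c(parts, sep = "\x1f"))
}

#' Find duplicated individuals between a source sublineage and a destination
#'
#' Individuals are equated when their `match_key` values coincide. The
#' pairing must be injective in both directions; any ambiguity (one source
#' individual matching two destination individuals, or vice versa) is an
#' error listing the candidates — a merge never guesses identities.
#'
#' @param sub A `sublineage` extracted from `source`.
#' @param source,dest Pedigrees.
#' @param match_key Field name(s); see [merge_plan()].
#' @return A data frame with columns `source_id` and `dest_id` (zero rows
#'   when the id spaces are disjoint under the key).
#' @export
find_duplicates <- function(sub, source, dest, match_key = "id") {
  src_ids <- sub$member_ids
  dst_ids <- dest$members$id
  if (!length(src_ids) || !length(dst_ids)) {
    return(data.frame(source_id = character(0), dest_id = character(0),
                      stringsAsFactors = FALSE))
  }
  src_keys <- member_keys(source, src_ids, match_key)
  dst_keys <- member_keys(dest, dst_ids, match_key)
  pairs <- lapply(seq_along(src_ids), function(i) {
    hits <- dst_ids[dst_keys == src_keys[i]]
    if (length(hits) > 1L) {
      stop(sprintf("ambiguous duplicate: source '%s' matches destination individuals %s under key [%s]",
                   src_ids[i], paste(sprintf("'%s'", hits), collapse = ", "),
                   paste(match_key, collapse = ", ")), call. = FALSE)
    }
    if (length(hits)) c(src_ids[i], hits) else NULL
  })
  pairs <- do.call(rbind, pairs)
  out <- if (is.null(pairs)) {
    data.frame(source_id = character(0), dest_id = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(source_id = pairs[, 1L], dest_id = pairs[, 2L],
               stringsAsFactors = FALSE)
  }
  dup_dst <- unique(out$dest_id[duplicated(out$dest_id)])
  if (length(dup_dst)) {
    srcs <- out$source_id[out$dest_id == dup_dst[1L]]
    stop(sprintf("ambiguous duplicate: destination '%s' matches source individuals %s under key [%s]",
                 dup_dst[1L], paste(sprintf("'%s'", srcs), collapse = ", "),
                 paste(match_key, collapse = ", ")), call. = FALSE)
  }
  out
}

field_is_missing <- function(field, value, missing) {
  if (field == "sex") value == "unknown" else value == missing
}

#' Resolve one duplicated individual
#'
#' Applies destination precedence: for every field where both records carry
#' a (non-missing) value and the values differ, the destination value is
#' kept and the pair is reported as a conflict. Where the destination value
#' is missing but the source has one, the source value fills the gap and the
#' fill is flagged separately. Parent references follow the same rule.
#'
#' @param source_ind,dest_ind One-row data frames (matching columns) for the
#'   matched pair.
#' @param missing Missing-value sentinel.
#' @return A list with `individual` (the resolved one-row data frame,
#'   keeping the destination id), `conflicts` (field, source_value,
#'   dest_value, kept_value) and `gap_fills` (field, value).
#' @export
resolve_duplicate <- function(source_ind, dest_ind, missing = PED_MISSING) {
  fields <- setdiff(names(dest_ind), "id")
  conflicts <- list()
  fills <- list()
  out <- dest_ind
  for (f in fields) {
    sv <- source_ind[[f]][1L] %||% missing
    dv <- dest_ind[[f]][1L]
    s_miss <- field_is_missing(f, sv, missing)
    d_miss <- field_is_missing(f, dv, missing)
    if (!s_miss && !d_miss && sv != dv) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        field = f, source_value = sv, dest_value = dv, kept_value = dv,
        stringsAsFactors = FALSE)
    } else if (d_miss && !s_miss) {
      out[[f]] <- sv
      fills[[length(fills) + 1L]] <- data.frame(
        field = f, value = sv, stringsAsFactors = FALSE)
    }
  }
  list(individual = out,
       conflicts = do.call(rbind, conflicts) %||% data.frame(
         field = character(0), source_value = character(0),
         dest_value = character(0), kept_value = character(0),
         stringsAsFactors = FALSE),
       gap_fills = do.call(rbind, fills) %||% data.frame(
         field = character(0), value = character(0), stringsAsFactors = FALSE))
}

align_members <- function(m, attrs, missing) {
  for (ac in setdiff(attrs, names(m))) m[[ac]] <- missing
  m[, c("id", PED_ROLE_FIELDS, attrs), drop = FALSE]
}

empty_report_frames <- function() {
  list(duplicate_pairs = data.frame(source_id = character(0),
                                    dest_id = character(0),
                                    stringsAsFactors = FALSE),
       conflicts = data.frame(id = character(0), field = character(0),
                              source_value = character(0),
                              dest_value = character(0),
                              kept_value = character(0),
                              stringsAsFactors = FALSE),
       gap_fills = data.frame(id = character(0), field = character(0),
                              value = character(0), source = character(0),
                              stringsAsFactors = FALSE),
       renamed_ids = data.frame(old = character(0), new = character(0),
                                stringsAsFactors = FALSE))
}

#' Execute a merge plan
#'
#' Runs one of the three merge algorithms on immutable inputs and returns
#' the unified pedigree, its provenance table and a report.
#'
#' **Replacement** removes the destination branch rooted at the anchor (its
#' descent members; married-in partners of removed members are dropped only
#' when nothing ties them to the result any more) and inserts the source
#' sublineage, with the source root inheriting the anchor's parent
#' references so that the new branch occupies the old branch's position.
#'
#' **Combination** folds the source sublineage into the destination:
#' duplicated individuals are represented once, with discordant attribute
#' values resolved by destination precedence, and non-duplicated members are
#' appended with parent references remapped through the duplicate pairing.
#' The output can serve as the destination of a further combination.
#'
#' **Addition** appends the whole source sublineage, making the source root
#' a new sibling of the anchor (it receives the anchor's parents); the
#' anchor must therefore have at least one known parent.
#'
#' In every mode duplicated individuals appear only once in the result, and
#' parent references of imported members that cannot resolve in the result
#' are set to the missing sentinel.
#'
#' @param plan A [merge_plan()].
#' @param source_prov,dest_prov Optional provenance tables for the inputs;
#'   defaults are created with [default_provenance()]. Fields imported from
#'   the source keep (or receive) the source's labels; retained destination
#'   values keep theirs.
#' @return A list with elements `ped` (the unified pedigree), `prov` (its
#'   provenance) and `report` (a `merge_report`: `added_ids`, `removed_ids`,
#'   `duplicate_pairs`, `conflicts`, `gap_fills`, `renamed_ids`).
#' @export
ped_merge <- function(plan, source_prov = NULL, dest_prov = NULL) {
  stopifnot(inherits(plan, "merge_plan"))
  src <- plan$source
  dst <- plan$dest
  assert_valid(src, "source pedigree")
  assert_valid(dst, "destination pedigree")
  source_prov <- source_prov %||% default_provenance(src)
  dest_prov <- dest_prov %||% default_provenance(dst)
  check_prov_domain(source_prov, src)
  check_prov_domain(dest_prov, dst)

  sub <- ped_sublineage(src, plan$source_root)
  anchor <- ped_member(dst, plan$dest_anchor)
  sent <- dst$missing
  frames <- empty_report_frames()

  # --- removal set (replace mode only) --------------------------------
  if (plan$mode == "replace") {
    dest_sub <- ped_sublineage(dst, plan$dest_anchor)
    survivors <- setdiff(dst$members$id, dest_sub$descent_ids)
    partners <- intersect(setdiff(dest_sub$member_ids, dest_sub$descent_ids),
                          survivors)
    dm <- dst$members
    repeat {
      drop <- partners[vapply(partners, function(p) {
        i <- match(p, dm$id)
        kids <- dm$id[(dm$father == p | dm$mother == p) & dm$id %in% survivors]
        parents <- c(dm$father[i], dm$mother[i])
        parents <- parents[parents != sent & parents %in% survivors]
        length(kids) == 0L && length(parents) == 0L
      }, logical(1))]
      if (!length(drop)) break
      survivors <- setdiff(survivors, drop)
      partners <- setdiff(partners, drop)
    }
    removed <- setdiff(dst$members$id, survivors)
  } else {
    if (plan$mode == "add" &&
        anchor$father == sent && anchor$mother == sent) {
      stop(sprintf("cannot attach '%s' as a sibling of founder '%s' (no known parents)",
                   plan$source_root, plan$dest_anchor), call. = FALSE)
    }
    survivors <- dst$members$id
    removed <- character(0)
  }

  # --- duplicates against the surviving destination -------------------
  dest_view <- if (length(removed)) ped_subset(dst, survivors) else dst
  dups <- find_duplicates(sub, src, dest_view, plan$match_key)
  frames$duplicate_pairs <- dups

  res_attrs <- c(dst$attr_columns,
                 setdiff(src$attr_columns, dst$attr_columns))
  res <- align_members(dst$members[dst$members$id %in% survivors, ,
                                   drop = FALSE], res_attrs, sent)
  src_aligned <- align_members(src$members, res_attrs, sent)

  # id map through the duplicate pairing + collision renames
  idmap <- stats::setNames(sub$member_ids, sub$member_ids)
  idmap[dups$source_id] <- dups$dest_id
  added_src <- setdiff(sub$member_ids, dups$source_id)
  colliding <- added_src[added_src %in% survivors]
  if (length(colliding)) {
    if (plan$on_collision == "error") {
      stop(sprintf("id collision: source individual(s) %s already exist in the destination but were not matched as duplicates; reconcile ids or use on_collision = \"rename\"",
                   paste(sprintf("'%s'", colliding), collapse = ", ")),
           call. = FALSE)
    }
    for (old in colliding) {
      new <- paste0(old, "@", src$name)
      while (new %in% c(survivors, unname(idmap))) new <- paste0(new, "+")
      idmap[old] <- new
      frames$renamed_ids <- rbind(frames$renamed_ids, data.frame(
        old = old, new = new, stringsAsFactors = FALSE))
    }
  }

  final_ids <- c(survivors, unname(idmap[added_src]))

  # --- resolve duplicates in place ------------------------------------
  gap_fill_labels <- list()
  for (k in seq_len(nrow(dups))) {
    s_id <- dups$source_id[k]
    d_id <- dups$dest_id[k]
    rr <- resolve_duplicate(src_aligned[src_aligned$id == s_id, , drop = FALSE],
                            res[res$id == d_id, , drop = FALSE], sent)
    row <- rr$individual
    for (pf in intersect(c("father", "mother"), rr$gap_fills$field)) {
      # a gap-filled parent reference came from the source: route it through
      # the duplicate pairing; if it still cannot resolve, drop the fill
      v <- row[[pf]]
      mapped <- unname(idmap[v])
      if (!is.na(mapped)) v <- mapped
      if (!(v %in% final_ids)) v <- sent
      row[[pf]] <- v
      if (v == sent) {
        rr$gap_fills <- rr$gap_fills[rr$gap_fills$field != pf, , drop = FALSE]
      } else {
        rr$gap_fills$value[rr$gap_fills$field == pf] <- v
      }
    }
    res[res$id == d_id, ] <- row
    if (nrow(rr$conflicts)) {
      frames$conflicts <- rbind(frames$conflicts,
                                cbind(id = d_id, rr$conflicts,
                                      stringsAsFactors = FALSE))
    }
    if (nrow(rr$gap_fills)) {
      for (j in seq_len(nrow(rr$gap_fills))) {
        f <- rr$gap_fills$field[j]
        lab <- src_prov_label(source_prov, s_id, f)
        frames$gap_fills <- rbind(frames$gap_fills, data.frame(
          id = d_id, field = f, value = rr$gap_fills$value[j], source = lab,
          stringsAsFactors = FALSE))
        gap_fill_labels[[length(gap_fill_labels) + 1L]] <- c(d_id, f, lab)
      }
    }
  }

  # --- append new members ---------------------------------------------
  reparent <- plan$mode %in% c("replace", "add")
  new_rows <- list()
  for (a in added_src) {
    row <- src_aligned[src_aligned$id == a, , drop = FALSE]
    row$id <- unname(idmap[a])
    if (reparent && a == plan$source_root) {
      row$father <- anchor$father
      row$mother <- anchor$mother
    }
    for (pf in c("father", "mother")) {
      v <- row[[pf]]
      if (v != sent) {
        mapped <- unname(idmap[v])
        if (!is.na(mapped)) v <- mapped
        if (!(v %in% final_ids)) v <- sent
        row[[pf]] <- v
      }
    }
    new_rows[[length(new_rows) + 1L]] <- row
  }
  if (length(new_rows)) res <- rbind(res, do.call(rbind, new_rows))
  rownames(res) <- NULL

  out_ped <- ped_new(res, name = dst$name, attr_columns = res_attrs,
                     missing = sent, source_file = dst$source_file)
  vr <- ped_validate(out_ped)
  if (ped_has_errors(vr)) {
    stop("merge result has structural errors: ",
         paste(vr$message[vr$level == "error"], collapse = "; "),
         call. = FALSE)
  }

  # --- provenance ------------------------------------------------------
  prov <- new_provenance(out_ped$members$id, prov_fields(out_ped),
                         dest_prov$default_source)
  dest_fields <- colnames(dest_prov$labels)
  keep_dest <- intersect(survivors, rownames(prov$labels))
  prov$labels[keep_dest, dest_fields] <-
    dest_prov$labels[keep_dest, dest_fields]
  for (a in added_src) {
    nid <- unname(idmap[a])
    for (f in colnames(prov$labels)) {
      prov$labels[nid, f] <- src_prov_label(source_prov, a, f)
    }
    if (reparent && a == plan$source_root) {
      prov$labels[nid, c("father", "mother")] <- dest_prov$default_source
    }
  }
  for (g in gap_fill_labels) prov$labels[g[1L], g[2L]] <- g[3L]

  report <- structure(
    c(list(mode = plan$mode,
           added_ids = unname(idmap[added_src]),
           removed_ids = removed),
      frames),
    class = "merge_report")
  list(ped = out_ped, prov = prov, report = report)
}

src_prov_label <- function(source_prov, id, field) {
  if (id %in% rownames(source_prov$labels) &&
      field %in% colnames(source_prov$labels)) {
    unname(source_prov$labels[id, field])
  } else {
    source_prov$default_source
  }
}

#' @rdname ped_merge
#' @param source,dest,source_root,dest_anchor,match_key,on_collision Passed
#'   to [merge_plan()].
#' @export
merge_replace <- function(source, dest, source_root,
                          dest_anchor = source_root, match_key = "id",
                          on_collision = "error",
                          source_prov = NULL, dest_prov = NULL) {
  ped_merge(merge_plan("replace", source, dest, source_root, dest_anchor,
                       match_key, on_collision), source_prov, dest_prov)
}

#' @rdname ped_merge
#' @export
merge_combine <- function(source, dest, source_root,
                          dest_anchor = source_root, match_key = "id",
                          on_collision = "error",
                          source_prov = NULL, dest_prov = NULL) {
  ped_merge(merge_plan("combine", source, dest, source_root, dest_anchor,
                       match_key, on_collision), source_prov, dest_prov)
}

#' @rdname ped_merge
#' @export
merge_add <- function(source, dest, source_root, dest_anchor,
                      match_key = "id", on_collision = "error",
                      source_prov = NULL, dest_prov = NULL) {
  ped_merge(merge_plan("add", source, dest, source_root, dest_anchor,
                       match_key, on_collision), source_prov, dest_prov)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf("<merge report: mode '%s'>\n", x$mode))
  cat(sprintf("  added:      %d (%s)\n", length(x$added_ids),
              paste(utils::head(x$added_ids, 8L), collapse = ", ")))
  cat(sprintf("  removed:    %d (%s)\n", length(x$removed_ids),
              paste(utils::head(x$removed_ids, 8L), collapse = ", ")))
  cat(sprintf("  duplicates: %d pair(s)\n", nrow(x$duplicate_pairs)))
  cat(sprintf("  conflicts:  %d (destination values kept)\n",
              nrow(x$conflicts)))
  cat(sprintf("  gap fills:  %d\n", nrow(x$gap_fills)))
  if (nrow(x$renamed_ids)) {
    cat(sprintf("  renamed:    %s\n",
                paste(sprintf("%s->%s", x$renamed_ids$old, x$renamed_ids$new),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a merge report to a sectioned TSV file
#'
#' One `## section` header per report component, followed by tab-separated
#' rows, so the report is both machine-parseable and readable.
#'
#' @param report A `merge_report`.
#' @param path Output path.
#' @export
write_merge_report <- function(report, path) {
  lines <- c(sprintf("## mode\t%s", report$mode),
             "## added_ids", report$added_ids,
             "## removed_ids", report$removed_ids)
  tsv_section <- function(name, df) {
    c(paste0("## ", name),
      paste(names(df), collapse = "\t"),
      if (nrow(df)) apply(df, 1L, paste, collapse = "\t"))
  }
  lines <- c(lines,
             tsv_section("duplicate_pairs", report$duplicate_pairs),
             tsv_section("conflicts", report$conflicts),
             tsv_section("gap_fills", report$gap_fills),
             tsv_section("renamed_ids", report$renamed_ids))
  writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}
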