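# File I/O: the configuration/pedigree/metadata trio, LINKAGE PED export
# and Graphviz DOT export. All text files are tab-delimited, UTF-8, LF on
# write; CRLF is accepted on read.

CONFIG_KEYS <- c("PedigreeFile", "PedigreeName", "NameColumn", "FatherColumn",
                 "MotherColumn", "SexColumn", "MetadataFile",
                 "AttributeColumns", "MissingValue")
CONFIG_REQUIRED <- c("PedigreeFile", "NameColumn", "FatherColumn",
                     "MotherColumn", "SexColumn")

# Paths read as inputs during this R session; writers refuse to overwrite
# them unless explicitly asked to edit in place (non-destructive contract).
.ped_session <- new.env(parent = emptyenv())
.ped_session$inputs <- character(0)

norm_path <- function(path) normalizePath(path, winslash = "/", mustWork = FALSE)

register_session_input <- function(path) {
  .ped_session$inputs <- union(.ped_session$inputs, norm_path(path))
  invisible(NULL)
}

is_session_input <- function(path) norm_path(path) %in% .ped_session$inputs

#' Forget which files were read during this session
#'
#' Writers refuse to overwrite any file read as an input during the current
#' session unless `in_place = TRUE`. This clears that registry (useful in
#' scripts that intentionally start a fresh logical session).
#' @export
ped_session_clear <- function() {
  .ped_session$inputs <- character(0)
  invisible(NULL)
}

refuse_overwrite <- function(path, in_place) {
  if (!in_place && is_session_input(path)) {
    stop(sprintf(paste0("refusing to overwrite session input '%s'; pass ",
                        "in_place = TRUE to edit source files in place"),
                 path), call. = FALSE)
  }
  invisible(NULL)
}

#' Pedigree file dialect
#'
#' @param header_present Whether the pedigree file carries a header row
#'   naming its columns (the default); without a header, column order is
#'   taken from the configuration.
#' @param missing Missing-value sentinel (default `"0"`).
#' @export
ped_dialect <- function(header_present = TRUE, missing = PED_MISSING) {
  structure(list(delimiter = "\t", header_present = header_present,
                 encoding = "UTF-8", missing = missing),
            class = "ped_dialect")
}

#' Build a pedigree configuration in memory
#'
#' @param pedigree_path Path to the pedigree file.
#' @param name_col,father_col,mother_col,sex_col Column headers playing the
#'   four role columns; they must be distinct.
#' @param pedigree_name Optional family label (defaults to the pedigree
#'   file's base name without extension).
#' @param attribute_columns Optional ordered attribute column names; when
#'   `NULL` they are inferred from the pedigree file header.
#' @param metadata_path Optional path of the provenance metadata file.
#' @param appearance Character vector of verbatim appearance-option lines
#'   (accepted, stored and re-emitted, but never interpreted).
#' @export
ped_config <- function(pedigree_path, name_col = "id", father_col = "father",
                       mother_col = "mother", sex_col = "sex",
                       pedigree_name = NULL, attribute_columns = NULL,
                       metadata_path = NULL, appearance = character(0)) {
  roles <- c(name = name_col, father = father_col, mother = mother_col,
             sex = sex_col)
  if (anyDuplicated(roles)) {
    stop("the name/father/mother/sex role columns must be distinct",
         call. = FALSE)
  }
  if (length(intersect(attribute_columns, roles))) {
    stop("attribute columns must be disjoint from the role columns",
         call. = FALSE)
  }
  structure(
    list(pedigree_path = pedigree_path,
         pedigree_name = pedigree_name %||%
           sub("\\.[^.]*$", "", basename(pedigree_path)),
         column_roles = roles,
         attribute_columns = attribute_columns,
         metadata_path = metadata_path,
         appearance = appearance,
         dir = "."),
    class = "ped_config"
  )
}

#' Read a configuration file
#'
#' The grammar is line-oriented `KEY <whitespace> VALUE`, case-sensitive,
#' with `#` comments and blank lines ignored. Recognised keys:
#' `PedigreeFile` (required), `NameColumn`/`FatherColumn`/`MotherColumn`/
#' `SexColumn` (required), `PedigreeName`, `MetadataFile`,
#' `AttributeColumns` (comma-separated), `MissingValue`. Any other line is
#' preserved verbatim as an appearance option and round-trips byte-for-byte
#' through [write_ped_config()].
#'
#' @param path Path to the configuration file.
#' @return A `ped_config` object; relative file paths inside it are resolved
#'   against the configuration file's directory.
#' @export
read_ped_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file '%s' does not exist", path),
         call. = FALSE)
  }
  lines <- gsub("\r$", "", readLines(path, encoding = "UTF-8"))
  keep <- !grepl("^\\s*(#|$)", lines)
  kv <- list()
  appearance <- character(0)
  for (ln in lines[keep]) {
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1]]
    key <- if (length(m)) m[2] else ln
    if (key %in% CONFIG_KEYS) {
      if (key %in% names(kv)) {
        stop(sprintf("duplicate configuration key '%s' in '%s'", key, path),
             call. = FALSE)
      }
      if (length(m) < 3L || !nzchar(trimws(m[3]))) {
        stop(sprintf("configuration key '%s' has no value", key),
             call. = FALSE)
      }
      kv[[key]] <- trimws(m[3])
    } else {
      appearance <- c(appearance, ln)
    }
  }
  missing_req <- CONFIG_REQUIRED[!(CONFIG_REQUIRED %in% names(kv))]
  if (length(missing_req)) {
    role <- c(PedigreeFile = "pedigree file", NameColumn = "name",
              FatherColumn = "father", MotherColumn = "mother",
              SexColumn = "sex")[missing_req]
    stop(sprintf("configuration '%s' is missing required key(s): %s (%s)",
                 path, paste(missing_req, collapse = ", "),
                 paste(role, collapse = ", ")), call. = FALSE)
  }
  attrs <- if (!is.null(kv$AttributeColumns)) {
    trimws(strsplit(kv$AttributeColumns, ",", fixed = TRUE)[[1]])
  }
  cfg <- ped_config(
    pedigree_path = kv$PedigreeFile,
    name_col = kv$NameColumn, father_col = kv$FatherColumn,
    mother_col = kv$MotherColumn, sex_col = kv$SexColumn,
    pedigree_name = kv$PedigreeName, attribute_columns = attrs,
    metadata_path = kv$MetadataFile, appearance = appearance)
  if (!is.null(kv$MissingValue)) cfg$missing <- kv$MissingValue
  cfg$dir <- dirname(path)
  register_session_input(path)
  cfg
}

#' Write a configuration file
#'
#' Known keys are emitted as `KEY<tab>VALUE`; appearance-option lines are
#' re-emitted verbatim, so a read/write cycle preserves them byte-for-byte.
#'
#' @param config A `ped_config`.
#' @param path Output path.
#' @param in_place Allow overwriting a file read during this session.
#' @export
write_ped_config <- function(config, path, in_place = FALSE) {
  refuse_overwrite(path, in_place)
  r <- config$column_roles
  lines <- c(
    paste0("PedigreeFile\t", config$pedigree_path),
    paste0("PedigreeName\t", config$pedigree_name),
    paste0("NameColumn\t", r[["name"]]),
    paste0("FatherColumn\t", r[["father"]]),
    paste0("MotherColumn\t", r[["mother"]]),
    paste0("SexColumn\t", r[["sex"]]))
  if (!is.null(config$attribute_columns)) {
    lines <- c(lines, paste0("AttributeColumns\t",
                             paste(config$attribute_columns, collapse = ",")))
  }
  if (!is.null(config$metadata_path)) {
    lines <- c(lines, paste0("MetadataFile\t", config$metadata_path))
  }
  if (!is.null(config$missing)) {
    lines <- c(lines, paste0("MissingValue\t", config$missing))
  }
  lines <- c(lines, config$appearance)
  writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

resolve_config_path <- function(config, path) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(config$dir, path)
}

sex_from_code <- function(code) {
  out <- c(`1` = "male", `2` = "female", `0` = "unknown")[code]
  unname(out)
}

sex_to_code <- function(sex) {
  unname(c(male = "1", female = "2", unknown = "0")[sex])
}

#' Read a pedigree file described by a configuration
#'
#' Each data row encodes one individual. Fields are tab-separated; rows
#' shorter than the header are padded with the missing sentinel (trailing
#' empty cells), and empty cells are read as the sentinel. Sex is coded
#' `1` = male, `2` = female, `0` = unknown on file. Structural problems
#' beyond parse-level ones (dangling parents, cycles, ...) are deliberately
#' deferred to [ped_validate()] so that a damaged file can still be loaded,
#' inspected and repaired.
#'
#' @param config A `ped_config` (typically from [read_ped_config()]).
#' @param dialect A [ped_dialect()].
#' @return A `pedigree`.
#' @export
read_pedigree <- function(config, dialect = ped_dialect()) {
  path <- resolve_config_path(config, config$pedigree_path)
  if (!file.exists(path)) {
    stop(sprintf("pedigree file '%s' does not exist", path), call. = FALSE)
  }
  sent <- config$missing %||% dialect$missing
  lines <- gsub("\r$", "", readLines(path, encoding = "UTF-8"))
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks

  roles <- config$column_roles
  if (dialect$header_present) {
    if (!length(lines)) {
      stop(sprintf("pedigree file '%s' is empty (expected a header row)", path),
           call. = FALSE)
    }
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
    data_lines <- lines[-1L]
    first_line <- 2L
    absent <- roles[!(roles %in% header)]
    if (length(absent)) {
      stop(sprintf("pedigree file '%s' header lacks role column(s): %s",
                   path, paste(absent, collapse = ", ")), call. = FALSE)
    }
    attrs <- config$attribute_columns %||% setdiff(header, roles)
    missing_attr <- setdiff(attrs, header)
    if (length(missing_attr)) {
      stop(sprintf("pedigree file '%s' header lacks attribute column(s): %s",
                   path, paste(missing_attr, collapse = ", ")), call. = FALSE)
    }
  } else {
    if (is.null(config$attribute_columns)) {
      stop("headerless pedigree files require AttributeColumns in the configuration",
           call. = FALSE)
    }
    attrs <- config$attribute_columns
    header <- c(unname(roles), attrs)
    data_lines <- lines
    first_line <- 1L
  }

  ncol <- length(header)
  rows <- vector("list", length(data_lines))
  for (i in seq_along(data_lines)) {
    f <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) > ncol) {
      stop(sprintf("line %d of '%s': %d fields, expected at most %d",
                   first_line + i - 1L, path, length(f), ncol), call. = FALSE)
    }
    f <- c(f, rep(sent, ncol - length(f)))
    f[!nzchar(f)] <- sent
    rows[[i]] <- f
  }
  tab <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix(character(0), 0L, ncol), stringsAsFactors = FALSE)
  }
  names(tab) <- header

  ids <- tab[[roles[["name"]]]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    d <- dup[1L]
    where <- first_line + which(ids == d) - 1L
    stop(sprintf("duplicate id '%s' in '%s' (lines %s)", d, path,
                 paste(where, collapse = " and ")), call. = FALSE)
  }
  sex_codes <- tab[[roles[["sex"]]]]
  bad <- which(!(sex_codes %in% c("0", "1", "2")))
  if (length(bad)) {
    stop(sprintf("line %d of '%s': invalid sex code '%s' (expected 0/1/2)",
                 first_line + bad[1L] - 1L, path, sex_codes[bad[1L]]),
         call. = FALSE)
  }

  members <- data.frame(id = ids,
                        father = tab[[roles[["father"]]]],
                        mother = tab[[roles[["mother"]]]],
                        sex = sex_from_code(sex_codes),
                        stringsAsFactors = FALSE)
  for (ac in attrs) members[[ac]] <- tab[[ac]]
  register_session_input(path)
  ped_new(members, name = config$pedigree_name, attr_columns = attrs,
          missing = sent, source_file = basename(path))
}

#' Write a pedigree file
#'
#' Output is tab-delimited with a header row: the four role columns (headers
#' taken from `config` when given) followed by the attribute columns.
#' Serialization is deterministic, so two writes of the same pedigree are
#' byte-identical. Files read as inputs in this session are never
#' overwritten unless `in_place = TRUE`.
#'
#' @param ped A pedigree.
#' @param path Output path.
#' @param config Optional `ped_config` supplying the role column headers.
#' @param in_place Allow overwriting a session input.
#' @export
write_pedigree <- function(ped, path, config = NULL, in_place = FALSE) {
  refuse_overwrite(path, in_place)
  roles <- if (!is.null(config)) config$column_roles else
    c(name = "id", father = "father", mother = "mother", sex = "sex")
  header <- c(unname(roles), ped$attr_columns)
  m <- ped$members
  body <- cbind(m$id, m$father, m$mother, sex_to_code(m$sex))
  for (ac in ped$attr_columns) body <- cbind(body, m[[ac]])
  lines <- c(paste(header, collapse = "\t"),
             if (nrow(m)) apply(body, 1L, paste, collapse = "\t"))
  writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Export a pedigree in LINKAGE PED format
#'
#' Emits pre-makeped LINKAGE rows: family id, individual id, father, mother,
#' sex (1/2/0), then the selected attribute columns, with `"0"` for missing
#' and no header row. Identifiers containing whitespace are not
#' LINKAGE-safe; either fix them or request `recode = TRUE`, which replaces
#' every id by a 1-based integer (file order) and writes the id-to-integer
#' map to `map_path` as a two-column TSV so the export can be inverted.
#'
#' @param ped A pedigree.
#' @param path Output path.
#' @param family_id Family identifier for column 1 (default the pedigree name).
#' @param columns Attribute columns to append (default all).
#' @param recode Re-code ids as consecutive integers.
#' @param map_path Where to write the recoding map (default `path` + ".map").
#' @param in_place Allow overwriting a session input.
#' @export
export_linkage_ped <- function(ped, path, family_id = ped$name,
                               columns = ped$attr_columns, recode = FALSE,
                               map_path = paste0(path, ".map"),
                               in_place = FALSE) {
  refuse_overwrite(path, in_place)
  m <- ped$members
  unknown <- setdiff(columns, ped$attr_columns)
  if (length(unknown)) {
    stop("unknown attribute column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  id <- m$id; father <- m$father; mother <- m$mother
  if (recode) {
    code <- as.character(seq_len(nrow(m)))
    names(code) <- m$id
    id <- unname(code[m$id])
    father <- ifelse(m$father == ped$missing, "0", unname(code[m$father]))
    mother <- ifelse(m$mother == ped$missing, "0", unname(code[m$mother]))
    map_lines <- c("id\tcode", paste(m$id, code, sep = "\t"))
    writeLines(enc2utf8(map_lines), map_path, sep = "\n", useBytes = TRUE)
  } else {
    bad <- grepl("\\s", m$id)
    if (any(bad)) {
      stop(sprintf(paste0("id '%s' contains whitespace and cannot be written ",
                          "as LINKAGE; use recode = TRUE"),
                   m$id[which(bad)[1L]]), call. = FALSE)
    }
    father[father == ped$missing] <- "0"
    mother[mother == ped$missing] <- "0"
  }
  body <- cbind(family_id, id, father, mother, sex_to_code(m$sex))
  for (ac in columns) {
    v <- m[[ac]]
    v[v == ped$missing] <- "0"
    body <- cbind(body, v)
  }
  lines <- if (nrow(m)) apply(body, 1L, paste, collapse = "\t") else character(0)
  writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Export a pedigree as a Graphviz DOT digraph
#'
#' One node per individual (shape `box` for males, `ellipse` for females,
#' `diamond` for unknown sex), one point-shaped marriage node per distinct
#' parental pair with at least one known parent, and edges
#' parent -> marriage -> child. Node order follows file order, so the output
#' is deterministic and diffable.
#'
#' @param ped A pedigree.
#' @param path Optional output path; when `NULL` the DOT lines are returned.
#' @return Invisibly, the character vector of DOT lines.
#' @export
export_dot <- function(ped, path = NULL) {
  m <- ped$members
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  shape <- c(male = "box", female = "ellipse", unknown = "diamond")[m$sex]
  lines <- c(sprintf("digraph %s {", q(ped$name)),
             sprintf("  %s [shape=%s, label=%s];", q(m$id), shape, q(m$id)))
  pairs <- character(0)
  sent <- ped$missing
  for (i in seq_len(nrow(m))) {
    if (m$father[i] == sent && m$mother[i] == sent) next
    key <- paste(m$father[i], m$mother[i], sep = "\t")
    if (!(key %in% names(pairs))) {
      mid <- sprintf("m%d", length(pairs) + 1L)
      pairs[key] <- mid
      lines <- c(lines, sprintf("  %s [shape=point, label=\"\"];", q(mid)))
      if (m$father[i] != sent) {
        lines <- c(lines, sprintf("  %s -> %s;", q(m$father[i]), q(mid)))
      }
      if (m$mother[i] != sent) {
        lines <- c(lines, sprintf("  %s -> %s;", q(m$mother[i]), q(mid)))
      }
    }
    lines <- c(lines, sprintf("  %s -> %s;", q(pairs[key]), q(m$id[i])))
  }
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(enc2utf8(lines), path, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}
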