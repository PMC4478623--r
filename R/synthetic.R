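# Synthetic pedigrees and multi-informant views. The generator emulates the
# setting the package exists for: one ground-truth extended family, reported
# by several informants as overlapping sub-pedigrees with omissions and
# attribute discordances. Each view ships with a manifest listing every
# difference from the truth, so tests can predict comparison and merge
# outcomes exactly.

#' Default attribute schema for simulated pedigrees
#'
#' Three columns typical of a family-study pedigree file: an affection
#' status (`AFF`, 1 = unaffected / 2 = affected, rarely missing), a
#' quantitative phenotype recorded in coarse bins (`HT`, height in cm, often
#' unknown for distant relatives) and a single-marker genotype (`GT`).
#' Missing rates reflect that verbal family history yields patchy clinical
#' and genetic data.
#'
#' @return A list of `list(name, domain, missing_rate)` entries.
#' @export
default_attribute_schema <- function() {
  list(
    list(name = "AFF", domain = c("1", "2"), missing_rate = 0.05),
    list(name = "HT", domain = as.character(seq(150L, 195L, 5L)),
         missing_rate = 0.25),
    list(name = "GT", domain = c("1/1", "1/2", "2/2"), missing_rate = 0.2)
  )
}

#' Specification for a simulated ground-truth pedigree
#'
#' @param generations Number of generations (>= 1).
#' @param mean_children Mean number of children per couple (Poisson).
#' @param partner_prob Probability that a lineage member's co-parent is
#'   another lineage member of the same generation (creating a marriage loop
#'   within the pedigree) rather than a married-in partner.
#' @param attribute_schema See [default_attribute_schema()].
#' @param seed Integer seed; generation is fully reproducible.
#' @export
sim_spec <- function(generations = 4L, mean_children = 2.2,
                     partner_prob = 0.15,
                     attribute_schema = default_attribute_schema(),
                     seed = 1L) {
  stopifnot(generations >= 1L, mean_children > 0,
            partner_prob >= 0, partner_prob <= 1)
  structure(list(generations = as.integer(generations),
                 mean_children = mean_children,
                 partner_prob = partner_prob,
                 attribute_schema = attribute_schema,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a ground-truth pedigree
#'
#' Grows a family forward in time from a founder couple: every couple has a
#' Poisson number of children; each reproducing lineage member either pairs
#' with another unpaired, non-sibling lineage member of the same generation
#' (probability `partner_prob`, producing a consanguinity-style loop) or
#' with a synthesized married-in partner, so every child always has two
#' in-pedigree parents. Lineage members are named `G<gen>.<k>`, married-in
#' partners `S<gen>.<k>`. The result always passes [ped_validate()] with no
#' error-level findings and is identical for identical seeds.
#'
#' @param spec A [sim_spec()].
#' @return A `pedigree`.
#' @export
generate_pedigree <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  rows <- list()
  add_row <- function(id, father, mother, sex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      stringsAsFactors = FALSE)
  }
  add_row("G1.1", PED_MISSING, PED_MISSING, "male")
  add_row("S1.1", PED_MISSING, PED_MISSING, "female")
  # a couple exists only once it is known to have children, so married-in
  # partners never enter the pedigree childless
  couples <- list(list(f = "G1.1", m = "S1.1",
                       n = max(1L, stats::rpois(1L, spec$mean_children))))
  spouse_n <- 1L

  for (g in seq_len(spec$generations - 1L)) {
    children <- list()  # generation g + 1 lineage members
    k <- 0L
    for (cp in couples) {
      for (j in seq_len(cp$n)) {
        k <- k + 1L
        id <- sprintf("G%d.%d", g + 1L, k)
        sex <- sample(c("male", "female"), 1L)
        add_row(id, cp$f, cp$m, sex)
        children[[length(children) + 1L]] <- list(id = id, sex = sex,
                                                  father = cp$f)
      }
    }
    if (g + 1L >= spec$generations || !length(children)) {
      couples <- list()
      next
    }
    paired <- character(0)
    couples <- list()
    for (ch in children) {
      if (ch$id %in% paired) next
      n_kids <- stats::rpois(1L, spec$mean_children)
      if (n_kids == 0L) next  # no offspring, no partner enters the pedigree
      partner <- NULL
      if (stats::runif(1L) < spec$partner_prob) {
        cands <- Filter(function(o) {
          o$id != ch$id && !(o$id %in% paired) && o$sex != ch$sex &&
            o$father != ch$father
        }, children)
        if (length(cands)) {
          pick <- cands[[sample.int(length(cands), 1L)]]
          partner <- pick$id
          paired <- c(paired, pick$id)
        }
      }
      if (is.null(partner)) {
        spouse_n <- spouse_n + 1L
        partner <- sprintf("S%d.%d", g + 1L, spouse_n)
        add_row(partner, PED_MISSING, PED_MISSING,
                if (ch$sex == "male") "female" else "male")
      }
      paired <- c(paired, ch$id)
      couples[[length(couples) + 1L]] <- if (ch$sex == "male") {
        list(f = ch$id, m = partner, n = n_kids)
      } else {
        list(f = partner, m = ch$id, n = n_kids)
      }
    }
  }

  m <- do.call(rbind, rows)
  for (sc in spec$attribute_schema) {
    vals <- sample(sc$domain, nrow(m), replace = TRUE)
    vals[stats::runif(nrow(m)) < sc$missing_rate] <- PED_MISSING
    m[[sc$name]] <- vals
  }
  ped_new(m, name = sprintf("sim%d", spec$seed),
          attr_columns = vapply(spec$attribute_schema, `[[`, "", "name"))
}

#' Specification for informant views of a ground-truth pedigree
#'
#' @param n_views Number of informants (>= 2).
#' @param anchor `"lineage-head"` (every informant's view is anchored at the
#'   founder heading the largest sublineage, so views overlap at the top and
#'   can be recombined there) or `"random"` (each view anchored at a random
#'   member).
#' @param omission_rate Base probability that a member is absent from a
#'   view. Knowledge decays with kinship distance from the anchor: a member
#'   at undirected graph distance `d` is retained with probability
#'   `(1 - omission_rate)^max(0, d - 1)`, so informants always know their
#'   immediate relatives and grow hazier outward. Parents of retained
#'   children are always repaired back in, keeping every view structurally
#'   complete.
#' @param discordance_rate Probability that a retained, non-missing
#'   attribute value is mis-reported (replaced by a different value from the
#'   column's observed domain). Role fields are never perturbed.
#' @param seed Integer seed.
#' @export
view_spec <- function(n_views = 2L, anchor = c("lineage-head", "random"),
                      omission_rate = 0.25, discordance_rate = 0.1,
                      seed = 1L) {
  anchor <- match.arg(anchor)
  stopifnot(n_views >= 2L, omission_rate >= 0, omission_rate <= 1,
            discordance_rate >= 0, discordance_rate <= 1)
  structure(list(n_views = as.integer(n_views), anchor = anchor,
                 omission_rate = omission_rate,
                 discordance_rate = discordance_rate,
                 seed = as.integer(seed)),
            class = "view_spec")
}

#' Head of the largest descent lineage
#'
#' The founder (both parents missing) whose sublineage covers the most
#' members; ties broken by file order.
#'
#' @param ped A pedigree.
#' @export
lineage_head <- function(ped) {
  m <- ped$members
  founders <- m$id[m$father == ped$missing & m$mother == ped$missing]
  if (!length(founders)) {
    stop(sprintf("pedigree '%s' has no founder", ped$name), call. = FALSE)
  }
  sizes <- vapply(founders,
                  function(f) length(ped_sublineage(ped, f)$member_ids),
                  integer(1))
  founders[which.max(sizes)]
}

undirected_distance <- function(ped, from) {
  m <- ped$members
  sent <- ped$missing
  ids <- m$id
  nbr <- lapply(seq_along(ids), function(i) {
    ps <- c(m$father[i], m$mother[i])
    ps <- ps[ps != sent & ps %in% ids]
    kids <- ids[m$father == ids[i] | m$mother == ids[i]]
    unique(c(ps, kids))
  })
  names(nbr) <- ids
  d <- stats::setNames(rep(Inf, length(ids)), ids)
  d[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- d[frontier[1L]] + 1
    # distances within a BFS layer are uniform; track layer depth explicitly
    frontier <- nxt
  }
  d
}

#' Split a ground-truth pedigree into overlapping informant views
#'
#' Each view is a valid sub-pedigree as one informant might report it:
#' anchored at an individual, complete nearby, increasingly likely to omit
#' members with kinship distance, and with attribute values occasionally
#' mis-reported. Omission never leaves a retained child with an absent
#' parent — required parents are repaired back in — so every view passes
#' validation and every ancestor chain down to a retained member is intact.
#'
#' @param ped The ground-truth pedigree.
#' @param spec A [view_spec()].
#' @return A list with one element per view: `list(ped, manifest)`, where
#'   `manifest` has `anchor`, `omitted` (ids truly absent from the view) and
#'   `perturbations` (data frame `id`, `field`, `truth_value`,
#'   `view_value`). The manifest is complete: every difference between the
#'   view and the truth appears in it.
#' @export
make_informant_views <- function(ped, spec = view_spec()) {
  stopifnot(inherits(ped, "pedigree"), inherits(spec, "view_spec"))
  if (!nrow(ped$members)) stop("cannot split an empty pedigree", call. = FALSE)
  set.seed(spec$seed)
  head_id <- lineage_head(ped)
  domains <- lapply(ped$attr_columns, function(ac) {
    v <- unique(ped$members[[ac]])
    v[v != ped$missing]
  })
  names(domains) <- ped$attr_columns

  lapply(seq_len(spec$n_views), function(v) {
    anchor <- if (spec$anchor == "lineage-head") head_id else
      sample(ped$members$id, 1L)
    d <- undirected_distance(ped, anchor)
    keep_p <- stats::setNames((1 - spec$omission_rate)^pmax(0, d - 1),
                              names(d))
    keep_p[!is.finite(d)] <- 1 - spec$omission_rate  # disconnected components
    keep <- stats::runif(length(keep_p)) < keep_p
    names(keep) <- names(keep_p)
    keep[anchor] <- TRUE
    # repair: parents of retained children must be retained
    m <- ped$members
    repeat {
      need <- unique(c(m$father[keep[m$id]], m$mother[keep[m$id]]))
      need <- need[need != ped$missing & need %in% m$id]
      missing_par <- need[!keep[need]]
      if (!length(missing_par)) break
      keep[missing_par] <- TRUE
    }
    # an informant does not report the spouse of a forgotten relative:
    # drop parentless members whose children were all omitted
    repeat {
      kept_ids <- m$id[keep[m$id]]
      orphan <- vapply(kept_ids, function(x) {
        i <- match(x, m$id)
        x != anchor &&
          m$father[i] == ped$missing && m$mother[i] == ped$missing &&
          !any((m$father == x | m$mother == x) & m$id %in% kept_ids)
      }, logical(1))
      if (!any(orphan)) break
      keep[kept_ids[orphan]] <- FALSE
    }
    view_ids <- m$id[keep[m$id]]
    if (!length(view_ids)) {
      stop("view specification would produce an empty view", call. = FALSE)
    }
    vp <- ped_subset(ped, view_ids)
    vp$name <- sprintf("%s.v%d", ped$name, v)
    vp$source_file <- sprintf("%s.ped", vp$name)

    pert <- list()
    for (ac in ped$attr_columns) {
      dom <- domains[[ac]]
      if (length(dom) < 2L) next
      for (i in seq_len(nrow(vp$members))) {
        val <- vp$members[[ac]][i]
        if (val != ped$missing && stats::runif(1L) < spec$discordance_rate) {
          alt <- setdiff(dom, val)
          new_val <- alt[sample.int(length(alt), 1L)]
          pert[[length(pert) + 1L]] <- data.frame(
            id = vp$members$id[i], field = ac, truth_value = val,
            view_value = new_val, stringsAsFactors = FALSE)
          vp$members[[ac]][i] <- new_val
        }
      }
    }
    manifest <- list(
      anchor = anchor,
      omitted = setdiff(ped$members$id, view_ids),
      perturbations = do.call(rbind, pert) %||% data.frame(
        id = character(0), field = character(0), truth_value = character(0),
        view_value = character(0), stringsAsFactors = FALSE))
    list(ped = vp, manifest = manifest)
  })
}

#' Write a configuration/pedigree/metadata fixture trio
#'
#' Serializes a pedigree (and its provenance, defaulting to a fresh table
#' labelled with the pedigree file's name) as the three-file dataset the
#' readers consume: `<name>.cfg`, `<name>.ped`, `<name>.meta`.
#'
#' @param ped A pedigree.
#' @param dir Output directory (created if needed).
#' @param name Base name (default the pedigree's name).
#' @param prov Optional provenance table.
#' @return The path of the written configuration file.
#' @export
write_fixture_trio <- function(ped, dir, name = ped$name, prov = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped_file <- paste0(name, ".ped")
  meta_file <- paste0(name, ".meta")
  cfg <- ped_config(pedigree_path = ped_file, pedigree_name = name,
                    attribute_columns = ped$attr_columns,
                    metadata_path = meta_file)
  write_pedigree(ped, file.path(dir, ped_file), config = cfg)
  prov <- prov %||% default_provenance(ped, ped_file)
  write_metadata(prov, ped, file.path(dir, meta_file))
  cfg_path <- file.path(dir, paste0(name, ".cfg"))
  write_ped_config(cfg, cfg_path)
  cfg_path
}

#' Read a fixture trio back
#'
#' @param cfg_path Path of the configuration file.
#' @return A list with `ped`, `prov` and `config`.
#' @export
read_fixture_trio <- function(cfg_path) {
  cfg <- read_ped_config(cfg_path)
  ped <- read_pedigree(cfg)
  prov <- if (!is.null(cfg$metadata_path)) {
    read_metadata(resolve_config_path(cfg, cfg$metadata_path), ped)
  } else {
    default_provenance(ped)
  }
  list(ped = ped, prov = prov, config = cfg)
}
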