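# Shared fixtures and independent oracles. Oracles deliberately use naive
# exhaustive formulations (recursive path enumeration, transitive closure,
# plain set algebra) so they stay independent of the package's traversal
# and merge code paths.

ped_from_text <- function(text, name = "fixture") {
  tab <- utils::read.table(text = text, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  tab$sex <- unname(c(`1` = "male", `2` = "female", `0` = "unknown")[tab$sex])
  ped_new(tab, name = name)
}

# --- schematic merge-example families --------------------------------------

# destination family for the replacement example: branch rooted at B.5
fam_b_replace <- function() ped_from_text("
id  father mother sex AFF
B.1 0      0      1   1
B.2 0      0      2   1
B.3 B.1    B.2    2   1
B.5 B.1    B.2    1   2
B.6 0      0      2   1
B.7 B.5    B.6    1   2
B.8 B.5    B.6    2   1
", name = "famB")

# source family for the replacement example: branch rooted at A.4
fam_a_replace <- function() ped_from_text("
id  father mother sex AFF
A.1 0      0      1   1
A.2 0      0      2   2
A.4 A.1    A.2    1   2
A.5 0      0      2   1
A.6 A.4    A.5    1   1
A.7 A.4    A.5    2   2
", name = "famA")

# combination example: both families know AB.2 and part of the descent
fam_b_combine <- function() ped_from_text("
id   father mother sex AFF
B.1  0      0      1   1
B.2  0      0      2   1
AB.2 B.1    B.2    1   2
AB.4 0      0      2   1
B.6  AB.2   AB.4   2   2
B.7  AB.2   AB.4   1   1
", name = "famB")

fam_a_combine <- function() ped_from_text("
id   father mother sex AFF
AB.2 0      0      1   1
AB.4 0      0      2   2
B.6  AB.2   AB.4   2   1
A.8  AB.2   AB.4   1   2
", name = "famA")

# addition example: A.2's branch becomes a sibling of B.3
fam_a_add <- function() ped_from_text("
id  father mother sex AFF
A.1 0      0      1   1
A.9 0      0      2   1
A.2 A.1    A.9    1   2
A.5 0      0      2   1
A.6 A.2    A.5    2   2
", name = "famA")

fam_b_add <- function() ped_from_text("
id  father mother sex AFF
B.1 0      0      1   1
B.2 0      0      2   2
B.3 B.1    B.2    2   1
B.4 B.1    B.2    1   1
", name = "famB")

# small random pedigree for property tests
rand_ped <- function(seed, generations = 3L, mean_children = 1.7) {
  generate_pedigree(sim_spec(generations = generations,
                             mean_children = mean_children, seed = seed))
}

# disjoint-id copy of a pedigree
prefix_ids <- function(ped, prefix) {
  m <- ped$members
  m$id <- paste0(prefix, m$id)
  m$father <- ifelse(m$father == ped$missing, ped$missing,
                     paste0(prefix, m$father))
  m$mother <- ifelse(m$mother == ped$missing, ped$missing,
                     paste0(prefix, m$mother))
  ped_new(m, name = paste0(prefix, ped$name),
          attr_columns = ped$attr_columns, missing = ped$missing)
}

# --- oracles ---------------------------------------------------------------

# exhaustive ancestor enumeration by recursive path climbing
oracle_ancestors <- function(ped, id) {
  m <- ped$members
  sent <- ped$missing
  rec <- function(x, seen) {
    i <- match(x, m$id)
    if (is.na(i)) return(character(0))
    ps <- c(m$father[i], m$mother[i])
    ps <- setdiff(ps[ps != sent], seen)
    out <- ps
    for (p in ps) out <- union(out, rec(p, c(seen, ps)))
    out
  }
  rec(id, id)
}

# descendants = everyone whose exhaustive ancestor set contains id
oracle_descendants <- function(ped, id) {
  ids <- ped$members$id
  ids[vapply(ids, function(x) id %in% oracle_ancestors(ped, x), logical(1))]
}

# sublineage membership: root + descendants + parents of every descendant
oracle_sublineage_members <- function(ped, root) {
  m <- ped$members
  sent <- ped$missing
  desc <- oracle_descendants(ped, root)
  parents <- unlist(lapply(desc, function(d) {
    i <- match(d, m$id)
    c(m$father[i], m$mother[i])
  }))
  union(c(root, desc), setdiff(parents, sent))
}

# reflexive pairs in the transitive closure of the child -> parent relation
oracle_cycle_ids <- function(ped) {
  m <- ped$members
  ids <- m$id
  n <- length(ids)
  if (!n) return(character(0))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (p in c(m$father[i], m$mother[i])) {
      if (p != ped$missing && p %in% ids) adj[i, p] <- TRUE
    }
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
  ids[diag(reach)]
}

# expected id set of a replacement result, from first principles
oracle_replace_ids <- function(source, dest, source_root, dest_anchor) {
  sent <- dest$missing
  m <- dest$members
  descent <- c(dest_anchor, oracle_descendants(dest, dest_anchor))
  partners <- setdiff(oracle_sublineage_members(dest, dest_anchor), descent)
  survivors <- setdiff(m$id, descent)
  repeat {
    drop <- Filter(function(p) {
      i <- match(p, m$id)
      has_kid <- any((m$father == p | m$mother == p) & m$id %in% survivors)
      par <- c(m$father[i], m$mother[i])
      has_par <- any(par != sent & par %in% survivors)
      !has_kid && !has_par
    }, intersect(partners, survivors))
    if (!length(drop)) break
    survivors <- setdiff(survivors, unlist(drop))
  }
  union(survivors, oracle_sublineage_members(source, source_root))
}

# last-writer-wins replay of provenance edits
oracle_replay_labels <- function(initial, edits) {
  # initial: matrix; edits: data.frame(id, field, source)
  for (i in seq_len(nrow(edits))) {
    initial[edits$id[i], edits$field[i]] <- edits$source[i]
  }
  initial
}

expect_isomorphic <- function(a, b) {
  iso <- ped_isomorphic(a, b)
  testthat::expect_true(isTRUE(iso),
                        info = if (!isTRUE(iso)) attr(iso, "witness"))
}
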