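test_that("duplicate detection equals exhaustive id intersection", {
  src <- fam_a_combine()
  dst <- fam_b_combine()
  sub <- ped_sublineage(src, "AB.2")
  d <- find_duplicates(sub, src, dst)
  expect_setequal(d$source_id, intersect(sub$member_ids, ped_ids(dst)))
  expect_identical(d$source_id, d$dest_id)

  disjoint <- find_duplicates(ped_sublineage(fam_a_add(), "A.2"),
                              fam_a_add(), fam_b_add())
  expect_identical(nrow(disjoint), 0L)

  for (seed in 1:5) {
    truth <- rand_ped(seed, generations = 4L)
    vs <- make_informant_views(truth, view_spec(seed = seed))
    sub <- ped_sublineage(vs[[1]]$ped, lineage_head(vs[[1]]$ped))
    d <- find_duplicates(sub, vs[[1]]$ped, vs[[2]]$ped)
    expect_setequal(d$source_id,
                    intersect(sub$member_ids, ped_ids(vs[[2]]$ped)))
  }
})

test_that("ambiguous duplicate matches are an error, never a guess", {
  src <- ped_from_text("
id father mother sex AFF
s1 0      0      1   2
", name = "src")
  dst <- ped_from_text("
id father mother sex AFF
d1 0      0      1   2
d2 0      0      1   2
", name = "dst")
  sub <- ped_sublineage(src, "s1")
  # under a key that ignores the id, s1 matches both destination members
  expect_error(find_duplicates(sub, src, dst, match_key = c("sex", "AFF")),
               "ambiguous duplicate.*'d1'.*'d2'")
})

test_that("duplicate resolution applies destination precedence and gap-fill", {
  mk <- function(aff, ht) data.frame(id = "x", father = "0", mother = "0",
                                     sex = "male", AFF = aff, HT = ht,
                                     stringsAsFactors = FALSE)
  r <- resolve_duplicate(mk("1", "0"), mk("2", "0"))
  expect_identical(r$individual$AFF, "2")
  expect_identical(nrow(r$conflicts), 1L)
  expect_identical(r$conflicts$kept_value, "2")
  expect_identical(r$conflicts$dest_value, "2")

  same <- resolve_duplicate(mk("2", "174"), mk("2", "174"))
  expect_identical(nrow(same$conflicts), 0L)
  expect_identical(nrow(same$gap_fills), 0L)

  # destination missing, source present: source fills the gap and the fill
  # survives a role swap (the value wins from either side)
  fill <- resolve_duplicate(mk("2", "174"), mk("2", "0"))
  expect_identical(fill$individual$HT, "174")
  expect_identical(fill$gap_fills$field, "HT")
  swapped <- resolve_duplicate(mk("2", "0"), mk("2", "174"))
  expect_identical(swapped$individual$HT, "174")
  expect_identical(nrow(swapped$gap_fills), 0L)
})

test_that("replacement substitutes the anchored branch", {
  src <- fam_a_replace()
  dst <- fam_b_replace()
  res <- merge_replace(src, dst, "A.4", dest_anchor = "B.5")

  # B.5's branch went; B.6 married in only there, so she is pruned too
  expect_setequal(res$report$removed_ids, c("B.5", "B.7", "B.8", "B.6"))
  expect_setequal(res$report$added_ids, c("A.4", "A.5", "A.6", "A.7"))
  expect_setequal(ped_ids(res$ped),
                  c("B.1", "B.2", "B.3", "A.4", "A.5", "A.6", "A.7"))
  expect_identical(nrow(res$report$duplicate_pairs), 0L)

  # the incoming root occupies the anchor's position in the family
  a4 <- ped_member(res$ped, "A.4")
  expect_identical(a4$father, "B.1")
  expect_identical(a4$mother, "B.2")
  expect_false(ped_has_errors(ped_validate(res$ped)))

  # count identity on the schematic example
  expect_identical(ped_size(res$ped), 7L - 4L + 4L)
})

test_that("replacement keeps married-in partners with remaining ties", {
  dst <- ped_from_text("
id  father mother sex
B.1 0      0      1
B.2 0      0      2
B.5 B.1    B.2    1
B.6 0      0      2
B.7 B.5    B.6    1
X.1 0      0      1
X.2 X.1    B.6    2
", name = "famB")
  src <- fam_a_replace()
  res <- merge_replace(src, dst, "A.4", dest_anchor = "B.5")
  # B.6 has a child X.2 outside the replaced branch: she must survive
  expect_true("B.6" %in% ped_ids(res$ped))
  expect_setequal(res$report$removed_ids, c("B.5", "B.7"))
})

test_that("replacing a leaf swaps exactly one member", {
  src <- ped_from_text("
id  father mother sex AFF
N.1 0      0      2   2
", name = "famN")
  dst <- fam_b_replace()
  res <- merge_replace(src, dst, "N.1", dest_anchor = "B.8")
  expect_identical(res$report$removed_ids, "B.8")
  expect_identical(res$report$added_ids, "N.1")
  expect_identical(ped_size(res$ped), ped_size(dst))
  n1 <- ped_member(res$ped, "N.1")
  expect_identical(c(n1$father, n1$mother), c("B.5", "B.6"))
})

test_that("combination folds sublineages and retains destination attributes", {
  src <- fam_a_combine()
  dst <- fam_b_combine()
  res <- merge_combine(src, dst, "AB.2")

  sub <- ped_sublineage(src, "AB.2")
  expect_identical(ped_size(res$ped),
                   ped_size(dst) + length(sub$member_ids) -
                     nrow(res$report$duplicate_pairs))
  expect_setequal(res$report$duplicate_pairs$source_id,
                  c("AB.2", "AB.4", "B.6"))
  expect_identical(res$report$added_ids, "A.8")
  a8 <- ped_member(res$ped, "A.8")
  expect_identical(c(a8$father, a8$mother), c("AB.2", "AB.4"))

  # discordant AFF values for AB.2, AB.4 and B.6: destination wins each time
  expect_identical(nrow(res$report$conflicts), 3L)
  expect_identical(res$report$conflicts$kept_value,
                   res$report$conflicts$dest_value)
  expect_identical(ped_member(res$ped, "B.6")$AFF,
                   ped_member(dst, "B.6")$AFF)
  expect_false(ped_has_errors(ped_validate(res$ped)))
})

test_that("combining a pedigree with itself is the identity", {
  for (p in list(fam_b_combine(), rand_ped(5, generations = 4L))) {
    root <- lineage_head(p)
    res <- merge_combine(p, p, root)
    expect_isomorphic(res$ped, p)
    expect_identical(length(res$report$added_ids), 0L)
    expect_identical(nrow(res$report$conflicts), 0L)
  }
})

test_that("iterated combination converges to the composite", {
  truth <- rand_ped(9, generations = 5L, mean_children = 2.0)
  vs <- make_informant_views(truth, view_spec(n_views = 3, seed = 21,
                                              discordance_rate = 0))
  root <- lineage_head(truth)
  acc <- vs[[1]]$ped
  for (v in vs[-1]) acc <- merge_combine(v$ped, acc, root)$ped
  covered <- Reduce(union, lapply(vs, function(v) ped_ids(v$ped)))
  expect_isomorphic(acc, ped_subset(truth, covered))
  # a further iteration changes nothing
  again <- merge_combine(vs[[2]]$ped, acc, root)$ped
  expect_isomorphic(again, acc)
})

test_that("addition appends the sublineage as a sibling of the anchor", {
  src <- fam_a_add()
  dst <- fam_b_add()
  res <- merge_add(src, dst, "A.2", dest_anchor = "B.3")

  expect_setequal(ped_ids(res$ped),
                  union(ped_ids(dst), c("A.2", "A.5", "A.6")))
  expect_identical(length(res$report$removed_ids), 0L)
  a2 <- ped_member(res$ped, "A.2")
  b3 <- ped_member(dst, "B.3")
  expect_identical(c(a2$father, a2$mother), c(b3$father, b3$mother))
  # A.2's original parents were outside the sublineage and stay behind
  expect_false(any(c("A.1", "A.9") %in% ped_ids(res$ped)))

  # edge-set diff: apart from the new root's parents, parent-child edges
  # of the destination are untouched and the source branch arrives intact
  edges <- function(p) {
    m <- p$members
    sort(c(paste(m$id, m$father), paste(m$id, m$mother)))
  }
  expect_true(all(edges(dst) %in% edges(res$ped)))

  expect_error(merge_add(src, dst, "A.2", dest_anchor = "B.1"),
               "sibling of founder")
})

test_that("adding one childless individual grows the sibship by one", {
  src <- ped_from_text("
id  father mother sex AFF
N.5 0      0      2   1
", name = "famN")
  dst <- fam_b_add()
  res <- merge_add(src, dst, "N.5", dest_anchor = "B.4")
  expect_identical(ped_size(res$ped), ped_size(dst) + 1L)
  sibs <- ped_children(res$ped, "B.1")
  expect_setequal(sibs, c("B.3", "B.4", "N.5"))
})

test_that("id collisions fail loudly or rename on request", {
  src <- ped_from_text("
id  father mother sex BORN
B.3 0      0      1   1950
", name = "famX")
  dst <- fam_b_add()  # already has a different B.3 (female, born elsewhere)
  dst$members$BORN <- c("1920", "1921", "1948", "1952")
  dst$attr_columns <- "BORN"

  key <- c("id", "BORN")
  expect_error(
    merge_combine(src, dst, "B.3", dest_anchor = "B.3", match_key = key),
    "id collision.*'B.3'")
  res <- merge_combine(src, dst, "B.3", dest_anchor = "B.3", match_key = key,
                       on_collision = "rename")
  expect_identical(res$report$renamed_ids$old, "B.3")
  new_id <- res$report$renamed_ids$new
  expect_true(new_id %in% ped_ids(res$ped))
  expect_identical(ped_member(res$ped, "B.3")$BORN, "1948")
  expect_identical(ped_member(res$ped, new_id)$BORN, "1950")
})

test_that("merge operations never modify their inputs", {
  src <- fam_a_combine()
  dst <- fam_b_combine()
  src_copy <- src
  dst_copy <- dst
  sp <- default_provenance(src, "a.ped")
  dp <- default_provenance(dst, "b.ped")
  sp_copy <- sp
  dp_copy <- dp
  invisible(merge_combine(src, dst, "AB.2", source_prov = sp, dest_prov = dp))
  invisible(merge_replace(fam_a_replace(), fam_b_replace(), "A.4", "B.5"))
  invisible(merge_add(fam_a_add(), fam_b_add(), "A.2", "B.3"))
  expect_isomorphic(src, src_copy)
  expect_isomorphic(dst, dst_copy)
  expect_identical(sp$labels, sp_copy$labels)
  expect_identical(dp$labels, dp_copy$labels)
})

test_that("merge size obeys the mode-specific set algebra (sample)", {
  for (seed in 1:25) {
    set.seed(seed * 17L)
    truth <- rand_ped(seed + 300L, generations = 4L)
    mode <- c("replace", "combine", "add")[seed %% 3 + 1]
    if (seed %% 2 == 0) {
      vs <- make_informant_views(truth, view_spec(seed = seed))
      src <- vs[[1]]$ped
      dst <- vs[[2]]$ped
    } else {
      src <- prefix_ids(rand_ped(seed + 600L), "S:")
      dst <- truth
    }
    src_root <- sample(ped_ids(src), 1)
    dst_ids <- ped_ids(dst)
    if (mode == "add") {
      m <- dst$members
      eligible <- m$id[m$father != dst$missing | m$mother != dst$missing]
      if (!length(eligible)) next
      anchor <- sample(eligible, 1)
    } else {
      anchor <- sample(dst_ids, 1)
    }
    res <- ped_merge(merge_plan(mode, src, dst, src_root, anchor))
    expected <- switch(mode,
      replace = oracle_replace_ids(src, dst, src_root, anchor),
      combine = union(dst_ids, oracle_sublineage_members(src, src_root)),
      add = union(dst_ids, oracle_sublineage_members(src, src_root)))
    expect_setequal(ped_ids(res$ped), expected)
    expect_false(ped_has_errors(ped_validate(res$ped)))
  }
})

test_that("merge reports serialize to sectioned TSV", {
  dir <- withr::local_tempdir()
  res <- merge_combine(fam_a_combine(), fam_b_combine(), "AB.2")
  f <- file.path(dir, "report.tsv")
  write_merge_report(res$report, f)
  lines <- readLines(f)
  expect_true(all(c("## added_ids", "## conflicts", "## duplicate_pairs")
                  %in% lines))
  expect_true("A.8" %in% lines)
})
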