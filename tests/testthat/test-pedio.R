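test_that("configuration files parse, refuse duplicates, and round-trip", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "famA.cfg")
  writeLines(c("# demo configuration",
               "PedigreeFile\tfamA.ped",
               "NameColumn NAME",
               "FatherColumn  FATHER",
               "MotherColumn\tMOTHER",
               "SexColumn SEX",
               "PageSize A4",
               "SymbolColor black"),
             cfg_path)
  cfg <- read_ped_config(cfg_path)
  expect_identical(unname(cfg$column_roles),
                   c("NAME", "FATHER", "MOTHER", "SEX"))
  expect_identical(cfg$pedigree_path, "famA.ped")
  expect_identical(cfg$pedigree_name, "famA")
  # unknown keys are appearance options, preserved verbatim
  expect_identical(cfg$appearance, c("PageSize A4", "SymbolColor black"))

  out1 <- file.path(dir, "out1.cfg")
  out2 <- file.path(dir, "out2.cfg")
  write_ped_config(cfg, out1)
  write_ped_config(read_ped_config(out1), out2)
  expect_identical(readBin(out1, "raw", file.size(out1)),
                   readBin(out2, "raw", file.size(out2)))
  # appearance lines survive byte-for-byte
  expect_true(all(c("PageSize A4", "SymbolColor black") %in% readLines(out1)))

  writeLines(c("PedigreeFile famA.ped", "NameColumn NAME",
               "FatherColumn FATHER", "SexColumn SEX"),
             file.path(dir, "missing.cfg"))
  expect_error(read_ped_config(file.path(dir, "missing.cfg")),
               "MotherColumn.*mother")

  writeLines(c("PedigreeFile a.ped", "PedigreeFile b.ped",
               "NameColumn N", "FatherColumn F", "MotherColumn M",
               "SexColumn S"),
             file.path(dir, "dup.cfg"))
  expect_error(read_ped_config(file.path(dir, "dup.cfg")), "duplicate")
})

test_that("pedigree files round-trip and serialization is a byte fixed point", {
  dir <- withr::local_tempdir()
  for (seed in 1:4) {
    p <- rand_ped(seed)
    f1 <- file.path(dir, sprintf("p%d_1.ped", seed))
    f2 <- file.path(dir, sprintf("p%d_2.ped", seed))
    f3 <- file.path(dir, sprintf("p%d_3.ped", seed))
    write_pedigree(p, f1)
    write_pedigree(p, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))

    cfg <- ped_config(f1, pedigree_name = p$name)
    back <- read_pedigree(cfg)
    expect_isomorphic(p, back)

    write_pedigree(back, f3)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f3, "raw", file.size(f3)))
  }
})

test_that("reading tolerates padding and reports parse errors precisely", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "fam.ped")

  writeLines(c("id\tfather\tmother\tsex\tAFF\tHT",
               "x1\t0\t0\t1\t2\t170",
               "x2\t0\t0\t2",              # short row: padded with sentinel
               "x3\tx1\tx2\t1\t\t180"),    # empty cell: sentinel
             f)
  p <- read_pedigree(ped_config(f))
  expect_identical(ped_size(p), 3L)
  expect_identical(ped_member(p, "x2")$AFF, "0")
  expect_identical(ped_member(p, "x2")$HT, "0")
  expect_identical(ped_member(p, "x3")$AFF, "0")
  expect_identical(ped_member(p, "x3")$HT, "180")

  writeLines(c("id\tfather\tmother\tsex", "x1\t0\t0\t1\textra\tmore"), f)
  expect_error(read_pedigree(ped_config(f)), "line 2")

  writeLines(c("id\tfather\tmother\tsex", "x1\t0\t0\t1", "x2\t0\t0\t2",
               "x1\t0\t0\t1"), f)
  expect_error(read_pedigree(ped_config(f)), "duplicate id 'x1'.*2 and 4")

  writeLines("id\tfather\tmother\tsex\tAFF", f)
  empty <- read_pedigree(ped_config(f))
  expect_identical(ped_size(empty), 0L)
  expect_identical(empty$attr_columns, "AFF")
})

test_that("writers never clobber session inputs without in_place", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "src.ped")
  p <- fam_b_replace()
  write_pedigree(p, f)
  cfg <- ped_config(f)
  q <- read_pedigree(cfg)
  expect_error(write_pedigree(q, f), "refusing to overwrite")
  before <- readBin(f, "raw", file.size(f))
  # the refused write must not have touched the file
  expect_identical(readBin(f, "raw", file.size(f)), before)
  q$members$AFF[1] <- "2"
  expect_silent(write_pedigree(q, f, in_place = TRUE))
  expect_false(identical(readBin(f, "raw", file.size(f)), before))
})

test_that("LINKAGE export emits 0-sentinels and an invertible recoding map", {
  dir <- withr::local_tempdir()
  p <- fam_a_replace()
  f <- file.path(dir, "a.linkage")
  export_linkage_ped(p, f)
  rows <- strsplit(readLines(f), "\t")
  expect_identical(length(rows), ped_size(p))
  expect_identical(rows[[1]],
                   c("famA", "A.1", "0", "0", "1", "1"))

  # whitespace ids require recoding
  ws <- p
  ws$members$id[1] <- "A 1"
  ws$members$father[3] <- "A 1"
  expect_error(export_linkage_ped(ws, f), "whitespace.*recode")
  export_linkage_ped(ws, f, recode = TRUE)
  map <- utils::read.table(paste0(f, ".map"), header = TRUE, sep = "\t",
                           colClasses = "character")
  # recoding is a bijection
  expect_identical(sort(map$id), sort(ws$members$id))
  expect_identical(anyDuplicated(map$code), 0L)
  # structure is preserved under the inverse map
  lk <- utils::read.table(f, sep = "\t", colClasses = "character")
  inv <- stats::setNames(map$id, map$code)
  expect_identical(unname(inv[lk$V2]), ws$members$id)
  back_father <- ifelse(lk$V3 == "0", "0", unname(inv[lk$V3]))
  expect_identical(back_father, ws$members$father)

  empty <- ped_new(data.frame(id = character(0), father = character(0),
                              mother = character(0), sex = character(0)))
  export_linkage_ped(empty, f)
  expect_identical(readLines(f), character(0))
})

test_that("DOT export satisfies the marriage-node counting identity", {
  count_expected <- function(p) {
    m <- p$members
    with_parent <- m$father != p$missing | m$mother != p$missing
    pairs <- unique(paste(m$father, m$mother)[with_parent])
    n_parent_edges <- sum(vapply(pairs, function(k) {
      fm <- strsplit(k, " ")[[1]]
      sum(fm != p$missing)
    }, numeric(1)))
    list(nodes = nrow(m) + length(pairs),
         edges = as.integer(n_parent_edges + sum(with_parent)))
  }
  for (p in list(fam_b_replace(), fam_a_combine(), rand_ped(3))) {
    lines <- export_dot(p)
    nodes <- sum(grepl("\\[shape=", lines))
    edges <- sum(grepl("->", lines))
    exp <- count_expected(p)
    expect_identical(nodes, exp$nodes)
    expect_identical(edges, exp$edges)
  }

  # two individuals with no recorded children: no parental pair exists,
  # hence no marriage node and no edges
  couple <- ped_from_text("
id father mother sex
h  0      0      1
w  0      0      2
")
  lines <- export_dot(couple)
  expect_identical(sum(grepl("shape=point", lines)), 0L)
  expect_identical(sum(grepl("->", lines)), 0L)

  empty <- ped_new(data.frame(id = character(0), father = character(0),
                              mother = character(0), sex = character(0)),
                   name = "none")
  expect_identical(export_dot(empty), c('digraph "none" {', "}"))

  dir <- withr::local_tempdir()
  export_dot(fam_b_replace(), file.path(dir, "b.dot"))
  expect_true(file.exists(file.path(dir, "b.dot")))
})
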