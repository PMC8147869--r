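# Data model and the deposited tab-delimited dialect.

test_that("group and dataset constructors enforce their invariants", {
  g <- make_group(0L, "M1", c("T1", "T2", "T3"),
                  c(T1 = "S1", T3 = "S3"))
  expect_s3_class(g, "compound_group")
  # ST members are ordered by target position
  expect_identical(names(g$st_members), c("T1", "T3"))

  expect_error(make_group(0L, "M1", c("T1", "T2"), character(0)),
               "zero ST members")
  expect_error(make_group(0L, "M1", c("T1", "T2"), c(T9 = "S1")),
               "outside target set")
  expect_error(make_group(0L, "M1", c("T1", "T2"), c(T1 = "M1")),
               "reused as ST")

  # one compound in two groups is rejected at the dataset level
  g1 <- make_group(0L, "M1", c("T1", "T2"), c(T1 = "S1"))
  g2 <- make_group(1L, "M2", c("T3", "T4"), c(T3 = "S1"))
  expect_error(promiscuity_dataset(list(g1, g2)), "more than one group")
  expect_error(promiscuity_dataset(list(g1, g1)), "duplicate group ids")
})

test_that("dataset_summary counts compounds, groups, targets and histogram", {
  g1 <- make_group(0L, "M1", c("T1", "T2", "T3"), c(T1 = "S1", T2 = "S2"))
  g2 <- make_group(1L, "M2", c("T3", "T4", "T5"),
                   c(T3 = "S3", T4 = "S4", T5 = "S5"))
  s <- dataset_summary(promiscuity_dataset(list(g1, g2)))
  expect_equal(s$n_mt, 2)
  expect_equal(s$n_st, 5)
  expect_equal(s$n_groups, 2)
  expect_equal(s$n_targets, 5)  # T3 shared
  expect_equal(s$st_per_mt_histogram, c("2" = 1L, "3" = 1L))
})

test_that("dataset_summary invariants hold on assembled synthetic datasets", {
  for (seed in 1:5) {
    w <- cached_world("tiny", seed)
    m <- build_activity_matrix(w$records)
    ds <- assemble_groups(m, 5L)
    s <- dataset_summary(ds)
    expect_equal(s$n_groups, s$n_mt)
    hist <- s$st_per_mt_histogram
    expect_equal(sum(as.integer(names(hist)) * hist), s$n_st)
  }
})

test_that("write_dataset_tsv emits the seven deposited columns, one row per compound", {
  g <- make_group(0L, "M1", c("T1", "T2", "T3"),
                  c(T1 = "S1", T2 = "S2", T3 = "S3"))
  cids <- c("M1", "S1", "S2", "S3")
  ds <- promiscuity_dataset(list(g),
                            smiles = stats::setNames(rep("CCO", 4), cids))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  df <- read.delim(path, colClasses = "character")
  expect_equal(names(df), c("NostereoAromaticSMILES", "is_MT", "group", "cid",
                            "target_ids", "n_tested", "random_removal_set",
                            "nn_removal_set"))
  expect_equal(nrow(df), 4)
  expect_equal(df$is_MT, c("True", "False", "False", "False"))
  expect_equal(df$target_ids, c("T1;T2;T3", "T1", "T2", "T3"))

  # empty dataset -> header-only file
  empty <- promiscuity_dataset(list())
  write_dataset_tsv(empty, path)
  df <- read.delim(path, colClasses = "character")
  expect_equal(nrow(df), 0)
  back <- read_dataset_tsv(path)
  expect_equal(dataset_summary(back)$n_groups, 0)
})

test_that("read/write round-trips assembled datasets field by field", {
  for (seed in c(2, 7)) {
    w <- cached_world("tiny", seed)
    m <- build_activity_matrix(w$records)
    ds <- assemble_groups(m, 5L, smiles = world_smiles(w))
    # add removal marks so those columns round-trip too
    ds <- random_removal(ds, 0.5, seed = seed)$marked
    path <- withr::local_tempfile(fileext = ".tsv")
    write_dataset_tsv(ds, path)
    back <- read_dataset_tsv(path)
    expect_same_dataset(ds, back)
    # idempotence of the dialect: write(read(write(d))) == write(d)
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_dataset_tsv(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("reader is liberal in booleans and list separators", {
  g <- make_group(0L, "M1", c("T1", "T2"), c(T1 = "S1", T2 = "S2"))
  ds <- promiscuity_dataset(list(g),
                            smiles = stats::setNames(rep("CCO", 3),
                                                     c("M1", "S1", "S2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  txt <- readLines(path)
  txt <- gsub("True", "1", txt, fixed = TRUE)
  txt <- gsub("False", "false", txt, fixed = TRUE)
  txt <- gsub("T1;T2", "T1|T2", txt, fixed = TRUE)
  writeLines(txt, path)
  back <- read_dataset_tsv(path)
  expect_equal(back$groups[[1]]$target_set, c("T1", "T2"))
  expect_equal(unname(back$groups[[1]]$st_members), c("S1", "S2"))
})

test_that("reader rejects malformed files with named errors", {
  g <- make_group(0L, "M1", c("T1", "T2"), c(T1 = "S1"))
  ds <- promiscuity_dataset(list(g),
                            smiles = stats::setNames(rep("CCO", 2),
                                                     c("M1", "S1")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  lines <- readLines(path)

  # missing mandatory column, named in the error
  bad <- sub("\tcid", "\tcompound", lines)
  writeLines(bad, path)
  expect_error(read_dataset_tsv(path), "cid")

  # duplicate cid
  writeLines(c(lines, lines[3]), path)
  expect_error(read_dataset_tsv(path), "duplicate cid")

  # ST target outside the MT target list
  bad <- lines
  bad[3] <- sub("\tT1\t", "\tT9\t", bad[3])
  writeLines(bad, path)
  expect_error(read_dataset_tsv(path), "disagree on target_ids")

  # two MT rows in one group
  bad <- lines
  bad[3] <- gsub("False", "True", bad[3])
  bad[3] <- sub("\tS1\t", "\tS9\t", bad[3])
  writeLines(bad, path)
  expect_error(read_dataset_tsv(path), "exactly 1 MT row")

  expect_error(read_dataset_tsv(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("verify_deposition checks the published composition counts", {
  # synthetic stand-ins with deliberately wrong sizes fail the count check
  g <- make_group(0L, "M1", c("T1", "T2"), c(T1 = "S1"))
  ds <- promiscuity_dataset(list(g),
                            smiles = stats::setNames(rep("CCO", 2),
                                                     c("M1", "S1")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, path)
  res <- verify_deposition(path, path, path)
  expect_equal(nrow(res), 3)
  expect_false(any(res$ok))
  expect_equal(res$expect_mt, c(2858L, 1242L, 3468L))
  expect_equal(res$expect_st, c(15839L, 6629L, 11793L))
})
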