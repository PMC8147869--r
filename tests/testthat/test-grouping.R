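# Activity matrix, promiscuity degrees, MT selection, group assembly and
# the completeness certificate.

records_from_calls <- function(calls) {
  # calls: data.frame(compound_id, target_id, outcome)
  activity_records(calls$compound_id, calls$target_id,
                   paste0(calls$target_id, "_A1"), calls$outcome)
}

test_that("build_activity_matrix collapses records to ternary calls", {
  rec <- activity_records(
    compound_id = c("c1", "c2", "c2"),
    target_id = c("T1", "T1", "T2"),
    assay_id = c("A1", "A1", "A2"),
    outcome = c("active", "inactive", "inactive"))
  m <- build_activity_matrix(rec)
  expect_equal(m$outcome["c1", "T1"], 2L)   # active
  expect_equal(m$outcome["c2", "T1"], 1L)   # inactive
  expect_equal(m$outcome["c1", "T2"], 0L)   # untested

  # two inactive records from different assays stay inactive
  rec2 <- activity_records("c1", "T1", c("A1", "A2"), c("inactive", "inactive"))
  expect_equal(build_activity_matrix(rec2)$outcome["c1", "T1"], 1L)

  # unresolved conflict is an error naming the pair
  conflict <- activity_records("c1", "T1", c("A1", "A2"),
                               c("active", "inactive"))
  expect_error(build_activity_matrix(conflict), "c1.*T1")
})

test_that("promiscuity degree and test frequency match a brute-force row scan", {
  calls <- data.frame(
    compound_id = rep("c1", 6),
    target_id = paste0("T", 1:6),
    outcome = c("active", "active", "active", "inactive", "inactive", "active"),
    stringsAsFactors = FALSE)
  m <- records_from_calls(calls) |> build_activity_matrix()
  expect_equal(promiscuity_degree(m, "c1"), 4)
  expect_equal(test_frequency(m, "c1"), 6)
  expect_error(promiscuity_degree(m, "ghost"), "unknown compound")

  withr::local_seed(31)
  for (k in 1:20) {
    m <- random_matrix(12, 8)
    if (is.null(m)) next
    prof <- promiscuity_profile(m)
    for (cid in m$compounds) {
      row <- m$outcome[cid, ]
      pd_naive <- 0L; tf_naive <- 0L
      for (t in m$targets) {
        if (row[t] == 2L) pd_naive <- pd_naive + 1L
        if (row[t] != 0L) tf_naive <- tf_naive + 1L
      }
      expect_identical(promiscuity_degree(m, cid), pd_naive)
      expect_identical(test_frequency(m, cid), tf_naive)
      expect_lte(pd_naive, tf_naive)
    }
    expect_equal(prof$pd,
                 vapply(m$compounds, function(c) promiscuity_degree(m, c),
                        integer(1), USE.NAMES = FALSE))
  }
})

test_that("select_mt orders by PD descending then id, and is threshold-monotone", {
  calls <- do.call(rbind, lapply(seq_along(c(1, 2, 5, 7)), function(i) {
    pd <- c(1, 2, 5, 7)[i]
    data.frame(compound_id = paste0("c", i), target_id = paste0("T", 1:pd),
               outcome = "active", stringsAsFactors = FALSE)
  }))
  m <- records_from_calls(calls) |> build_activity_matrix()
  expect_equal(select_mt(m, 5), c("c4", "c3"))
  expect_equal(select_mt(m, 3), c("c4", "c3"))
  expect_equal(select_mt(m, 2), c("c4", "c3", "c2"))
  expect_error(select_mt(m, 1), "pd_min")

  withr::local_seed(11)
  for (k in 1:10) {
    m <- random_matrix(15, 10, p_active = 0.4)
    if (is.null(m)) next
    expect_true(all(select_mt(m, 5) %in% select_mt(m, 3)))
  }
})

test_that("assemble_groups pairs each MT target with a confirmed-inactive ST", {
  # 1 MT on T1..T5 plus 5 disjoint fully-tested ST candidates: all selected
  calls <- rbind(
    data.frame(compound_id = "mt", target_id = paste0("T", 1:5),
               outcome = "active", stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:5, function(i) {
      data.frame(compound_id = paste0("st", i), target_id = paste0("T", 1:5),
                 outcome = ifelse(seq_len(5) == i, "active", "inactive"),
                 stringsAsFactors = FALSE)
    })))
  m <- records_from_calls(calls) |> build_activity_matrix()
  ds <- assemble_groups(m, 5)
  expect_length(ds$groups, 1)
  g <- ds$groups[[1]]
  expect_equal(g$mt_compound, "mt")
  expect_equal(unname(g$st_members), paste0("st", 1:5))
  expect_equal(verify_completeness(ds, m)$n_violations, 0)

  # a candidate untested on one group target is skipped (completeness rule)
  calls2 <- calls[!(calls$compound_id == "st2" & calls$target_id == "T3"), ]
  m2 <- records_from_calls(calls2) |> build_activity_matrix()
  ds2 <- assemble_groups(m2, 5)
  expect_false("st2" %in% unname(ds2$groups[[1]]$st_members))
  expect_length(ds2$groups[[1]]$st_members, 4)
})

test_that("ST compounds are allocated once, in MT processing order", {
  # two MT compounds share target set T1..T5; one qualifying ST for T1 only.
  # mt_a (PD 6) processes before mt_b (PD 5): mt_a gets the ST, mt_b is
  # omitted for lack of any ST member.
  calls <- rbind(
    data.frame(compound_id = "mt_a", target_id = paste0("T", 1:6),
               outcome = "active", stringsAsFactors = FALSE),
    data.frame(compound_id = "mt_b", target_id = paste0("T", 1:5),
               outcome = c(rep("active", 5)), stringsAsFactors = FALSE),
    data.frame(compound_id = "mt_b", target_id = "T6",
               outcome = "inactive", stringsAsFactors = FALSE),
    data.frame(compound_id = "st1", target_id = paste0("T", 1:6),
               outcome = c("active", rep("inactive", 5)),
               stringsAsFactors = FALSE))
  m <- records_from_calls(calls) |> build_activity_matrix()
  ds <- assemble_groups(m, 5)
  expect_length(ds$groups, 1)
  expect_equal(ds$groups[[1]]$mt_compound, "mt_a")
  expect_equal(unname(ds$groups[[1]]$st_members), "st1")

  # exhaustive check: no valid unused candidate was skipped for mt_b
  prof <- promiscuity_profile(m)
  st_pool <- prof$compound_id[prof$pd == 1]
  remaining <- setdiff(st_pool, unlist(lapply(ds$groups, `[[`, "st_members")))
  tset_b <- c(paste0("T", 1:5))
  for (cand in remaining) {
    qualifies <- any(vapply(tset_b, function(t) {
      m$outcome[cand, t] == 2L &&
        all(m$outcome[cand, setdiff(tset_b, t)] == 1L)
    }, logical(1)))
    expect_false(qualifies)
  }
})

test_that("candidate tie-break prefers the better-tested, then lower id", {
  # two candidates qualify for T1; st_hi has higher test frequency
  calls <- rbind(
    data.frame(compound_id = "mt", target_id = paste0("T", 1:5),
               outcome = "active", stringsAsFactors = FALSE),
    data.frame(compound_id = "st_zlo", target_id = paste0("T", 1:5),
               outcome = c("active", rep("inactive", 4)),
               stringsAsFactors = FALSE),
    data.frame(compound_id = "st_ahi", target_id = paste0("T", 1:6),
               outcome = c("active", rep("inactive", 5)),
               stringsAsFactors = FALSE))
  m <- records_from_calls(calls) |> build_activity_matrix()
  ds <- assemble_groups(m, 5)
  expect_equal(unname(ds$groups[[1]]$st_members["T1"]), "st_ahi")

  # equal test frequency: lower compound id wins ("st_ahi" keeps winning
  # after losing its extra tested target because it sorts before "st_zlo")
  calls <- calls[!(calls$compound_id == "st_ahi" & calls$target_id == "T6"), ]
  m2 <- records_from_calls(calls) |> build_activity_matrix()
  ds2 <- assemble_groups(m2, 5)
  expect_equal(unname(ds2$groups[[1]]$st_members["T1"]), "st_ahi")
})

test_that("verify_completeness itemizes planted violations", {
  w <- cached_world("tiny", 8)
  m <- build_activity_matrix(w$records)
  ds <- assemble_groups(m, 5L)
  expect_equal(verify_completeness(ds, m)$n_violations, 0)

  # tamper: reuse one group's ST in another group
  if (length(ds$groups) >= 2 &&
      length(ds$groups[[2]]$st_members) >= 1) {
    bad <- ds
    vict <- bad$groups[[2]]
    vict$st_members[1] <- bad$groups[[1]]$st_members[[1]]
    bad$groups[[2]] <- vict
    rep <- verify_completeness(bad, m)
    expect_gt(rep$n_violations, 0)
    expect_true("st_reused" %in% rep$violations$rule)
  }

  # tamper: claim an untested target in a group's target set
  bad2 <- ds
  g <- bad2$groups[[1]]
  untested_t <- m$targets[m$outcome[g$mt_compound, ] == 0L]
  if (length(untested_t)) {
    g$target_set <- c(g$target_set, untested_t[1])
    bad2$groups[[1]] <- g
    rep2 <- verify_completeness(bad2, m)
    expect_true("incomplete" %in% rep2$violations$rule)
  }
})

test_that("planted ST test-frequency contrast shows up in assembled datasets", {
  meds <- sapply(1:5, function(s) {
    w <- cached_world("contrast", s)
    m <- build_activity_matrix(w$records)
    ds <- assemble_groups(m, 5L)
    mt_n <- unlist(lapply(ds$groups, function(g) g$n_tested[g$mt_compound]))
    st_n <- unlist(lapply(ds$groups, function(g)
      g$n_tested[unname(g$st_members)]))
    c(mt = mean(mt_n), st = mean(st_n))
  })
  # ST compounds are tested more broadly than MT compounds on average
  expect_gt(mean(meds["st", ] - meds["mt", ]), 0)
})
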