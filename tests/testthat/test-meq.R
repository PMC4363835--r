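test_that("packaged instrument spans exactly 16..86 with valid items", {
  ins <- meq_instrument()
  expect_length(ins$items, 19)
  lo <- sum(vapply(ins$items, function(it) min(it$scores), numeric(1)))
  hi <- sum(vapply(ins$items, function(it) max(it$scores), numeric(1)))
  expect_identical(c(lo, hi), c(16, 86))
  for (it in ins$items) {
    expect_true(all(it$scores >= 0 & it$scores <= 6))
    if (it$kind == "time_scale") expect_false(anyNA(it$mids))
  }
})

test_that("extreme response vectors hit the scale floor and ceiling", {
  ins <- meq_instrument()
  rmax <- vapply(ins$items, function(it) which.max(it$scores), integer(1))
  rmin <- vapply(ins$items, function(it) which.min(it$scores), integer(1))
  expect_identical(score_meq(rmax, ins)$total, 86L)
  expect_identical(score_meq(rmin, ins)$total, 16L)
  expect_equal(as.character(score_meq(rmax, ins)$category), "definitely_morning")
  expect_equal(as.character(score_meq(rmin, ins)$category), "definitely_evening")
})

test_that("typology bands partition 16..86 with the published boundaries", {
  cats <- as.character(classify_meq(16:86))
  expect_false(anyNA(cats))  # every total is in exactly one band
  expect_identical(unique(cats[(16:86) <= 30]), "definitely_evening")
  expect_identical(unique(cats[(16:86) >= 31 & (16:86) <= 41]), "moderately_evening")
  expect_identical(unique(cats[(16:86) >= 42 & (16:86) <= 58]), "intermediate")
  expect_identical(unique(cats[(16:86) >= 59 & (16:86) <= 69]), "moderately_morning")
  expect_identical(unique(cats[(16:86) >= 70]), "definitely_morning")
  expect_error(classify_meq(15), "16..86")
  expect_error(classify_meq(87), "16..86")
})

test_that("invalid responses are refused with the item index named", {
  ins <- meq_instrument()
  expect_error(score_meq(rep(1, 18), ins), "19 responses")
  bad <- rep(1, 19); bad[7] <- NA
  expect_error(score_meq(bad, ins), "item 7")
  bad <- rep(1, 19); bad[3] <- 9
  expect_error(score_meq(bad, ins), "item 3")
  bad <- rep(1, 19); bad[11] <- 0
  expect_error(score_meq(bad, ins), "item 11")
})

test_that("random response vectors always score into 16..86 and scoring is monotone", {
  ins <- meq_instrument()
  set.seed(101)
  nopt <- vapply(ins$items, function(it) length(it$scores), integer(1))
  for (case in 1:50) {
    r <- vapply(nopt, function(k) sample.int(k, 1), integer(1))
    rec <- score_meq(r, ins)
    expect_true(rec$total >= 16 && rec$total <= 86)
    expect_false(is.na(rec$category))
    # bump one item to a strictly higher-scored option if one exists
    k <- sample.int(19, 1)
    sc <- ins$items[[k]]$scores
    higher <- which(sc > sc[r[k]])
    if (length(higher)) {
      r2 <- r; r2[k] <- higher[1]
      expect_gte(score_meq(r2, ins)$total, rec$total)
    }
  }
})

test_that("preferred times are the selected option midpoints", {
  ins <- meq_instrument()
  r <- rep(1, 19)
  rec <- score_meq(r, ins)  # earliest rise option 05:00-06:30
  expect_equal(preferred_times(rec)[["wake"]], 5.75)
  expect_lte(preferred_times(rec)[["wake"]], 6.5)
  # identical records give identical times
  expect_identical(preferred_times(score_meq(r, ins)), preferred_times(rec))
  # after-midnight bedtimes stay on the offset scale, wrap folds them back
  r2 <- r; r2[2] <- 5  # 01:45-03:00
  rec2 <- score_meq(r2, ins)
  expect_equal(preferred_times(rec2)[["bed"]], 26.375)
  expect_equal(preferred_times(rec2, wrap = TRUE)[["bed"]], 2.375)
})

test_that("cohort mean preferred times match a hand-computed oracle", {
  ins <- meq_instrument()
  # three records choosing Question-1 options 1, 2, 4
  recs <- lapply(c(1, 2, 4), function(o1) {
    r <- rep(1, 19); r[1] <- o1
    score_meq(r, ins)
  })
  wakes <- vapply(recs, function(x) preferred_times(x)[["wake"]], numeric(1))
  expect_equal(mean(wakes), (5.75 + 7.125 + 10.375) / 3)
})

test_that("table scoring round-trips through CSV and names failing individuals", {
  ins <- meq_instrument()
  set.seed(77)
  nopt <- vapply(ins$items, function(it) length(it$scores), integer(1))
  tab <- as.data.frame(t(replicate(5, vapply(nopt, function(k)
    sample.int(k, 1), integer(1)))))
  names(tab) <- paste0("q", 1:19)
  tab <- cbind(individual_id = paste0("P", 1:5), tab)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
  scored <- score_meq_table(read_meq_responses(f), ins)
  expect_identical(nrow(scored), 5L)
  expect_true(all(scored$meq_total >= 16 & scored$meq_total <= 86))
  out <- tempfile(fileext = ".csv")
  write_meq_scores(scored, out)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(back$meq_total, scored$meq_total)
  tab$q5[2] <- NA
  expect_error(score_meq_table(tab, ins), "P2")
})

test_that("response allocator reaches every attainable total", {
  ins <- meq_instrument()
  for (target in 16:86) {
    r <- simulate_responses(target, ins)
    expect_identical(score_meq(r, ins)$total, as.integer(target))
  }
  expect_error(simulate_responses(15), "16..86")
})
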