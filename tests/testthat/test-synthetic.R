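test_that("default frequency table matches the published class frequencies", {
  tab <- default_frequency_table()
  # BRCA1 TNBC 82/131, non-carrier family breast cancer 254/2347
  expect_equal(tab$tnbc[["brca1"]], 82 / 131)
  expect_equal(tab$flags["family_breast", "non_carrier"], 254 / 2347)
  # BRCA1 age of onset 39.1 +/- 8.4
  expect_equal(tab$age_mean[["brca1"]], 39.1)
  expect_equal(tab$age_sd[["brca1"]], 8.4)
  # prevalences (2596, 131, 132, 43, 26)/2928, any-carrier 11.3%
  expect_equal(sum(tab$prevalences), 1)
  expect_equal(unname(tab$prevalences["non_carrier"]), 2596 / 2928)
  expect_equal(round(100 * (1 - tab$prevalences[["non_carrier"]]), 1), 11.3)
  # every categorical column is a probability simplex
  for (m in tab$categoricals) expect_equal(unname(colSums(m)), rep(1, 5))
})

test_that("frequency table JSON round-trips", {
  tab <- default_frequency_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_frequency_table(tab, path)
  back <- read_frequency_table(path)
  expect_equal(back$prevalences, tab$prevalences)
  expect_equal(back$flags, tab$flags)
  expect_equal(back$categoricals$her2, tab$categoricals$her2)
  expect_equal(back$tnbc, tab$tnbc)
})

test_that("generate_cohort honors degenerate and empty inputs", {
  expect_equal(nrow(generate_cohort(0, seed = 1)), 0L)

  tab <- default_frequency_table()
  tab$prevalences[] <- c(0, 1, 0, 0, 0)
  co <- generate_cohort(50, tab, seed = 2)
  expect_true(all(co$group == "brca1"))
})

test_that("generation is deterministic and ages respect truncation", {
  a <- generate_cohort(400, seed = 7)
  b <- generate_cohort(400, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$age_at_diagnosis >= 18))
  expect_false(identical(a$er, generate_cohort(400, seed = 8)$er))
})

test_that("sampling hits the generating frequencies (property)", {
  tab <- default_frequency_table()
  co <- generate_cohort(5000, tab, seed = 1)

  # group sizes within 4 multinomial SE
  for (g in carrier_groups()) {
    p <- tab$prevalences[[g]]
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(mean(co$group == g) - p), 4 * se + 1e-12)
  }

  # TNBC among brca1 within 3 binomial SE of 82/131 (joint ER/PR/HER2 draw)
  b1 <- co[co$group == "brca1", ]
  p <- 82 / 131
  se <- sqrt(p * (1 - p) / nrow(b1))
  expect_lt(abs(mean(b1$tnbc) - p), 3 * se)

  # ER/PR/HER2 marginals preserved despite the coupling
  nc <- co[co$group == "non_carrier", ]
  for (feat in c("er", "pr")) {
    p <- tab$categoricals[[feat]]["negative", "non_carrier"]
    se <- sqrt(p * (1 - p) / nrow(nc))
    expect_lt(abs(mean(nc[[feat]] == "negative") - p), 4 * se)
  }
})

test_that("summarize_cohort recovers the generating table (property)", {
  tab <- default_frequency_table()
  co <- generate_cohort(20000, tab, seed = 3)
  sm <- summarize_cohort(co)

  # age means within 3 SE per group
  for (g in carrier_groups()) {
    row <- sm$age[sm$age$group == g, ]
    expect_lt(abs(row$mean - tab$age_mean[[g]]),
              3 * tab$age_sd[[g]] / sqrt(row$n) + 0.12)  # +truncation bias pad
  }
  # a spread of binary/categorical cells within 3 SE
  check <- function(feature, level, g, p) {
    row <- sm$features[sm$features$feature == feature &
                         sm$features$level == level &
                         sm$features$group == g, ]
    se <- sqrt(p * (1 - p) / row$denom)
    expect_lt(abs(row$prop - p), 3 * se + 1e-12)
  }
  check("family_breast", "1", "brca1", tab$flags["family_breast", "brca1"])
  check("er", "negative", "brca1",
        tab$categoricals$er["negative", "brca1"])
  check("her2", "uncertain", "non_carrier",
        tab$categoricals$her2["uncertain", "non_carrier"])
  check("grade", "iii", "brca1", tab$categoricals$grade["iii", "brca1"])
  check("tnbc", "1", "brca1", tab$tnbc[["brca1"]])
})

test_that("summarize_cohort reproduces printed proportions on exact counts", {
  # 82 TNBC of 131 BRCA1 carriers vs 303 of 2347 non-carriers (scaled: the
  # proportions, not the cohort, are what the fixture pins down)
  rows <- c(
    lapply(seq_len(131), function(i)
      make_record(group = "brca1", variant_status = "pathogenic",
                  er = if (i <= 82) "negative" else "positive")),
    lapply(seq_len(235), function(i)
      make_record(patient_id = sprintf("N%d", i),
                  er = if (i <= 30) "negative" else "positive")))
  for (i in seq_along(rows)) rows[[i]]$patient_id <- sprintf("R%03d", i)
  co <- as_cohort(do.call(rbind, rows))
  sm <- summarize_cohort(co)
  tn <- sm$features[sm$features$feature == "tnbc" & sm$features$level == "1", ]
  expect_equal(round(100 * tn$prop[tn$group == "brca1"], 1), 62.6)
  expect_equal(tn$count[tn$group == "brca1"], 82)
  # group-vs-noncarrier test present and extreme
  expect_lt(tn$p[tn$group == "brca1"], 1e-10)
})

test_that("identical groups give a null age comparison", {
  rows <- c(lapply(1:20, function(i)
    make_record(age_at_diagnosis = 30 + i)),
    lapply(1:20, function(i)
      make_record(age_at_diagnosis = 30 + i, group = "brca1",
                  variant_status = "pathogenic")))
  for (i in seq_along(rows)) rows[[i]]$patient_id <- sprintf("Q%03d", i)
  co <- as_cohort(do.call(rbind, rows))
  sm <- summarize_cohort(co)
  expect_equal(sm$age$p[sm$age$group == "brca1"], 1)
})
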