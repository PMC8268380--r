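# Cohort extraction: inclusion/exclusion rules, flag derivation, attrition
# accounting, idempotence.

test_that("single records are retained or excluded by the stated rules", {
  keep <- make_record(dx = "153.4;278.00", proc = "45.73", age = 60)
  out <- extract_cohort(keep)
  expect_identical(nrow(out), 1L)
  expect_true(out$obese)

  # other primary cancer (lung, 162.9) excludes the record
  out <- extract_cohort(make_record(dx = "153.4;162.9", proc = "45.73"))
  expect_identical(nrow(out), 0L)

  # metastasis codes (196-199) are severity markers, not exclusions
  out <- extract_cohort(make_record(dx = "153.4;197.7", proc = "45.73"))
  expect_identical(nrow(out), 1L)
  expect_true(out$metastasis)

  # no qualifying surgery
  expect_identical(nrow(extract_cohort(make_record(proc = "38.93"))), 0L)
  # rectal resection roots qualify
  expect_identical(nrow(extract_cohort(make_record(proc = "48.62"))), 1L)
  # under 20
  expect_identical(nrow(extract_cohort(make_record(age = 19))), 0L)
  # no CRC diagnosis at all
  expect_identical(nrow(extract_cohort(make_record(dx = "278.00"))), 0L)
})

test_that("analytic flags derive from the diagnosis codes alone", {
  rec <- make_record(
    dx = "154.1;198.5;278.01;250.00;571.5;303.90;998.59;997.4", age = 81,
    sex = "female")
  row <- extract_cohort(rec)
  expect_true(row$obese)
  expect_true(row$metastasis)
  expect_true(row$diabetes)
  expect_true(row$liver_disease)
  expect_true(row$alcohol_abuse)
  expect_true(row$c_infection)
  expect_true(row$c_digestive)
  expect_false(any(unlist(
    row[paste0("c_", setdiff(COMPLICATIONS, c("infection", "digestive")))])))
  expect_identical(row$age_group, "75+")

  # 278.1 (obesity-adjacent but different fourth digit) is not the exposure
  expect_false(extract_cohort(make_record(dx = "153.4;278.1"))$obese)
})

test_that("a generated population with planted violations matches the brute-force rule filter", {
  cfg <- sim_config(n_patients = 700, seed = 77, distractor_fraction = 0.45,
                    calibrate = FALSE)
  pop <- generate_population(cfg)
  keep <- oracle_keep(pop)
  cohort <- extract_cohort(pop)
  expect_identical(nrow(cohort), sum(keep))
  expect_setequal(cohort$record_id, pop$record_id[keep])
  # at least one violation of each kind was planted
  log <- attr(cohort, "attrition")
  expect_identical(log$rule,
                   c("crc_diagnosis", "surgery", "age_20_plus",
                     "no_other_cancer"))
  expect_true(all(log$n_removed[c(2, 3, 4)] > 0))
})

test_that("attrition accounting is sequential and internally consistent", {
  cfg <- sim_config(n_patients = 500, seed = 3, distractor_fraction = 0.3,
                    calibrate = FALSE)
  pop <- generate_population(cfg)
  cohort <- extract_cohort(pop)
  log <- attr(cohort, "attrition")
  expect_identical(log$n_before[1], nrow(pop))
  expect_identical(log$n_after[4], nrow(cohort))
  expect_identical(log$n_before[-1], log$n_after[-4])
  expect_identical(log$n_before - log$n_removed, log$n_after)
  path <- withr::local_tempfile(fileext = ".json")
  write_attrition(cohort, path)
  expect_identical(jsonlite::read_json(path, simplifyVector = TRUE)$rule,
                   log$rule)
})

test_that("extraction is idempotent", {
  cohort <- small_cohort(n = 5000, seed = 12)
  again <- extract_cohort(cohort)
  expect_identical(nrow(again), nrow(cohort))
  expect_equal(as.data.frame(again), as.data.frame(cohort),
               ignore_attr = TRUE)
  expect_identical(attr(again, "attrition")$n_removed, rep(0L, 4))
})

test_that("the code book validates internal consistency and round-trips through YAML", {
  expect_error(
    default_codebook(overrides = list(
      complication_dx = list(infection = "162"))),
    "exclusion range")
  cb <- default_codebook()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_equal(back$complication_dx, cb$complication_dx)
  expect_equal(back$surgery_proc, cb$surgery_proc)
})
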