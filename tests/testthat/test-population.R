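test_that("subject sampling is deterministic and respects constraints", {
  spec <- population_spec("general_nec")
  s1 <- sample_subject(spec, seed = 11)
  s2 <- sample_subject(spec, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(sample_subject(spec, seed = 12)$weight_kg, s1$weight_kg))
  # organ volumes stay inside the body
  phys <- subject_physiology(s1)
  expect_lt(sum(phys$volume_L), s1$weight_kg)
})

test_that("sampled cohorts match the requested demographics", {
  spec <- population_spec("healthy_adult")
  cohort <- generate_cohort(spec, n = 200, male_fraction = 0.5,
                            age_range = c(18, 50), seed = 3)
  expect_equal(nrow(cohort), 200)
  expect_true(all(cohort$age >= 18 & cohort$age <= 50))
  expect_equal(sum(cohort$sex == "M"), 100)
  # realized weight CV within 20% of the specified CV
  cv_emp <- sd(cohort$weight_kg) / mean(cohort$weight_kg)
  expect_lt(abs(cv_emp - spec$weight_cv) / spec$weight_cv, 0.20)
  # all sampled physiology positive
  expect_true(all(cohort$liver_g > 0 & cohort$mppgl > 0 & cohort$qh_Lh > 0))
})

test_that("trial-sized cohorts reproduce the study design demographics", {
  cohort <- generate_cohort(population_spec("general_nec"), n = 27,
                            male_fraction = 0.6, age_range = c(47, 81), seed = 1)
  expect_equal(nrow(cohort), 27)
  expect_true(all(cohort$age >= 47 & cohort$age <= 81))
  expect_equal(sum(cohort$sex == "M"), round(0.6 * 27))
  one <- generate_cohort(population_spec("general_nec"), n = 1, seed = 5)
  expect_equal(nrow(one), 1)
  # disjoint seeds give different cohorts
  c2 <- generate_cohort(population_spec("general_nec"), n = 27,
                        male_fraction = 0.6, age_range = c(47, 81), seed = 2)
  expect_false(isTRUE(all.equal(cohort$weight_kg, c2$weight_kg)))
})

test_that("invalid specs and cohort sizes are rejected", {
  spec <- population_spec("general_nec")
  bad <- spec; bad$weight_cv <- -0.1
  expect_error(sample_subject(bad, seed = 1), class = "ropipbpk_spec_error")
  expect_error(generate_cohort(spec, n = 0), class = "ropipbpk_spec_error")
})

test_that("age-related declines lower hepatic flow and clearance in the old", {
  ger <- population_spec("geriatric_nec")
  adult <- population_spec("healthy_adult")
  old <- generate_cohort(ger, n = 100, age_range = c(85, 98), seed = 4)
  young <- generate_cohort(adult, n = 100, age_range = c(18, 50), seed = 4)
  expect_lt(mean(old$qh_Lh) / mean(old$weight_kg^0.75),
            mean(young$qh_Lh) / mean(young$weight_kg^0.75))
  # predicted hepatic clearance decreases across geriatric age bands
  mean_clh <- function(band) {
    coh <- generate_cohort(ger, n = 100, age_range = band, seed = 10)
    mean(purrr::map_dbl(seq_len(nrow(coh)), function(i) {
      s <- coh[i, ]
      clint <- ivive_hepatic_clint(enzyme_pathways_ropinirole(), 0.39,
                                   mppgl = s$mppgl, liver_g = s$liver_g) * s$clint_mult
      hepatic_clearance_well_stirred(clint, 0.68, 1.09, s$qh_Lh)
    }))
  }
  cls <- vapply(list(c(65, 75), c(75, 85), c(85, 98)), mean_clh, numeric(1))
  expect_true(all(diff(cls) < 0))
})

test_that("weight-normalized distribution volume is age-stable", {
  spec <- population_spec("general_nec")
  drug <- drug_ropinirole()
  vss_kg <- function(band) {
    coh <- generate_cohort(spec, n = 50, age_range = band, seed = 21)
    mean(purrr::map_dbl(seq_len(nrow(coh)), function(i) {
      s <- coh[i, ]
      predict_vss(kpu_rodgers_rowland(drug), drug,
                  organs = subject_physiology(s), body_weight_kg = s$weight_kg)
    }))
  }
  v_young <- vss_kg(c(25, 40)); v_old <- vss_kg(c(70, 85))
  expect_lt(abs(v_old - v_young) / v_young, 0.10)
})

test_that("cohorts export the standard CSV columns", {
  cohort <- generate_cohort(population_spec("general_nec"), n = 3, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, csv)
  expect_equal(names(read.csv(csv)),
               c("subject_id", "age", "sex", "weight_kg", "liver_g", "mppgl", "qh_Lh"))
})
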