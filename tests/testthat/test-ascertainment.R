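test_that("domain scores standardise against the reference stratum", {
  ref <- reference_rows()
  ## a subject whose orientation equals the reference mean scores z = 0
  ## (aged 85: outside the reference stratum, so the stratum is untouched)
  subj <- make_panel_row(1, 1, 2002, 85, orientation = 0,
                         immediate_recall = 1, delayed_recall = 1,
                         verbal_fluency = -1)
  z <- standardize_domain_scores(rbind(ref, subj))
  z1 <- z[z$person_id == 1, ]
  expect_equal(z1$z_concentration, 0, tolerance = 1e-10)

  ## hand computation: reference has mean 0, SD 1 per test, so a score x
  ## maps to (x - 0) / 1 in each single-test domain
  subj2 <- make_panel_row(2, 1, 2002, 85, orientation = -1.5)
  z2 <- standardize_domain_scores(rbind(ref, subj2))
  expect_equal(z2$z_concentration[z2$person_id == 2], -1.5, tolerance = 1e-10)

  ## fewer than three answered tests invalidates the assessment
  subj3 <- make_panel_row(3, 1, 2002, 85, n_tests_answered = 2L)
  z3 <- standardize_domain_scores(rbind(ref, subj3))
  expect_false(z3$valid_assessment[z3$person_id == 3])
  expect_true(all(z3$valid_assessment[z3$person_id != 3]))

  ## errors: empty reference stratum, zero SD
  lone <- make_panel_row(1, 1, 2002, 85, education = "higher")
  expect_error(standardize_domain_scores(rbind(ref, lone)), "reference stratum")
  flat <- ref; flat$orientation <- 1
  expect_error(standardize_domain_scores(flat), "SD")
})

test_that("cognitive impairment needs two or more domains at -1.5 SD, boundary inclusive", {
  ref <- reference_rows()
  p <- rbind(
    ref,
    ## exactly at the boundary in two domains -> impaired
    make_panel_row(1, 1, 2002, 85, orientation = -1.5,
                   immediate_recall = -1.5, delayed_recall = -1.5,
                   verbal_fluency = 0),
    ## one impaired domain only -> not impaired
    make_panel_row(2, 1, 2002, 85, orientation = -1.6)
  )
  z <- standardize_domain_scores(p)
  cg <- classify_cognitive_impairment(z)
  expect_true(cg$cognitive_impairment[cg$person_id == 1])
  expect_false(cg$cognitive_impairment[cg$person_id == 2])

  ## disorder within a multi-wave person is rejected
  two <- rbind(make_panel_row(30, 1, 2002, 85), make_panel_row(30, 2, 2004, 87))
  z_two <- standardize_domain_scores(rbind(ref, two))
  expect_error(classify_cognitive_impairment(z_two[rev(seq_len(nrow(z_two))), ]),
               "increasing")
})

test_that("a 1 SD improvement at the consecutive wave rescinds impairment", {
  ref <- rbind(reference_rows(), {
    r <- reference_rows(start_id = 9500)
    r$wave <- 2L; r$year <- 2004L; r
  })
  low <- make_panel_row(1, 1, 2002, 85, orientation = -2, immediate_recall = -2,
                        delayed_recall = -2, verbal_fluency = -2)
  rec <- make_panel_row(1, 2, 2004, 87, orientation = -0.5,
                        immediate_recall = -0.5, delayed_recall = -0.5,
                        verbal_fluency = -0.5)
  z <- standardize_domain_scores(rbind(ref, low, rec))
  cg <- classify_cognitive_impairment(z)
  r1 <- cg[cg$person_id == 1 & cg$wave == 1, ]
  expect_true(r1$cognitive_impairment_raw)
  expect_true(r1$transient_cognitive)
  expect_false(r1$cognitive_impairment)

  ## without recovery the impairment stands
  stay <- rec; stay[c("orientation", "immediate_recall", "delayed_recall",
                      "verbal_fluency")] <- -2
  z2 <- standardize_domain_scores(rbind(ref, low, stay))
  cg2 <- classify_cognitive_impairment(z2)
  expect_true(cg2$cognitive_impairment[cg2$person_id == 1 & cg2$wave == 1])
})

test_that("functional impairment follows the ADL rule with single-wave transience", {
  mk <- function(id, counts) {
    do.call(rbind, lapply(seq_along(counts), function(w) {
      make_panel_row(id, w, 2000 + 2 * w, 70 + 2 * w,
                     adl_impaired_count = counts[w])
    }))
  }
  p <- rbind(mk(1, c(0, 1, 0, 0, 0, 0)),   # transient
             mk(2, c(0, 1, 1, 1, 1, 1)),   # persistent from wave 2
             mk(3, c(0, 0, 0, 0, 0, 0)))   # never
  fc <- classify_functional_impairment(p)
  expect_false(any(fc$functional_impairment[fc$person_id == 1]))
  expect_true(fc$transient_functional[fc$person_id == 1 & fc$wave == 2])
  expect_true(all(fc$functional_impairment[fc$person_id == 2 & fc$wave >= 2]))
  expect_false(any(fc$functional_impairment[fc$person_id == 3]))
})

test_that("dementia is ascertained by three routes with mid-point onset dating", {
  ref <- reference_rows()
  p <- rbind(
    ref,
    ## IQCODE route: cut-point 3.6 inclusive, plus one ADL impairment
    make_panel_row(1, 1, 2002, 78),
    make_panel_row(1, 2, 2004, 80, iqcode = 3.6, adl_impaired_count = 1,
                   n_tests_answered = 0L, proxy_interview = TRUE),
    ## doctor diagnosis alone, normal scores
    make_panel_row(2, 1, 2002, 70),
    make_panel_row(2, 4, 2008, 76, doctor_dx_dementia = TRUE),
    ## tests route: ascertained 2008 after a 2006 assessment -> onset 2007
    make_panel_row(3, 3, 2006, 82),
    make_panel_row(3, 4, 2008, 84, orientation = -2.5, immediate_recall = -2.5,
                   delayed_recall = -2.5, verbal_fluency = -2.5,
                   adl_impaired_count = 2)
  )
  a <- ascertain_panel(p)
  st <- a$statuses
  s1 <- st[st$person_id == 1, ]
  expect_true(s1$is_case); expect_equal(s1$route, "IQCODE+ADL")
  expect_equal(s1$onset_year, 2003)
  s2 <- st[st$person_id == 2, ]
  expect_true(s2$is_case); expect_equal(s2$route, "doctor-diagnosis")
  expect_equal(s2$onset_year, (2002 + 2008) / 2)
  s3 <- st[st$person_id == 3, ]
  expect_true(s3$is_case); expect_equal(s3$route, "cognitive-tests+ADL")
  expect_equal(s3$onset_year, 2007)
  ## below the cut-point the IQCODE route must not fire
  p2 <- p; p2$iqcode[!is.na(p2$iqcode)] <- 3.5
  expect_false(ascertain_panel(p2)$statuses$is_case[1])
})

test_that("caseness hinging solely on numeracy is dated between numeracy waves", {
  ref <- rbind(reference_rows(), {
    r <- reference_rows(start_id = 9500)
    r$wave <- 4L; r$year <- 2008L
    r$numeracy <- r$orientation  # numeracy administered this wave
    r
  })
  ## wave 4 (2008): memory impaired; executive impaired only through
  ## numeracy; previous assessments at waves 1 (2002, numeracy-bearing)
  ## and 2 (2004, not)
  p <- rbind(
    ref,
    make_panel_row(1, 1, 2002, 80, numeracy = 0),
    make_panel_row(1, 2, 2004, 82),
    make_panel_row(1, 4, 2008, 86, orientation = 0, immediate_recall = -2.5,
                   delayed_recall = -2.5, verbal_fluency = 0, numeracy = -6,
                   adl_impaired_count = 1, n_tests_answered = 5L)
  )
  st <- ascertain_panel(p)$statuses
  s <- st[st$person_id == 1, ]
  expect_true(s$is_case)
  ## mid-point of 2002 and 2008, not of 2004 and 2008
  expect_equal(s$onset_year, 2005)
})

test_that("cases at the first observed wave are prevalent at entry", {
  ref <- reference_rows()
  p <- rbind(ref,
             make_panel_row(1, 1, 2002, 80, doctor_dx_dementia = TRUE),
             make_panel_row(2, 1, 2002, 70))
  st <- ascertain_panel(p)$statuses
  expect_true(st$prevalent_at_entry[st$person_id == 1])
  expect_equal(st$onset_year[st$person_id == 1], 2002)
  expect_false(st$is_case[st$person_id == 2])
  ## no non-case carries an onset date
  expect_true(all(is.na(st$onset_year[!st$is_case])))
})

test_that("worsening never removes caseness (uniform shift / extra ADL)", {
  f <- small_dataset(42)
  st0 <- f$asc$statuses
  p <- f$data$panel
  ## shift one subset's cognitive scores uniformly downwards (a uniform
  ## per-person shift leaves wave-to-wave improvements, and hence the
  ## transience rule, untouched)
  shift_ids <- unique(p$person_id)[seq_len(500)]
  p_low <- p
  sel <- p_low$person_id %in% shift_ids
  for (v in c("orientation", "immediate_recall", "delayed_recall",
              "verbal_fluency", "numeracy", "literacy")) {
    p_low[[v]][sel] <- p_low[[v]][sel] - 0.5
  }
  st1 <- ascertain_panel(p_low)$statuses
  was_case_shifted <- intersect(st0$person_id[st0$is_case], shift_ids)
  expect_true(all(was_case_shifted %in% st1$person_id[st1$is_case]))

  ## one extra ADL impairment everywhere never removes caseness
  p_adl <- p
  p_adl$adl_impaired_count <- pmin(7L, p_adl$adl_impaired_count + 1L)
  st2 <- ascertain_panel(p_adl)$statuses
  was_case <- st0$person_id[st0$is_case]
  expect_true(all(was_case %in% st2$person_id[st2$is_case]))
})

test_that("appending a follow-up wave only affects last-wave transience", {
  f <- small_dataset(42)
  p <- f$data$panel
  st_with7 <- ascertain_panel(p)$statuses
  st_no7 <- ascertain_panel(p[p$wave <= 6, ])$statuses
  ## discrepancies may only involve wave-6 ascertainments (wave-7 data
  ## resolves transience at wave 6)
  m <- merge(st_with7, st_no7, by = "person_id")
  changed <- m$is_case.x != m$is_case.y |
    paste(m$ascertainment_wave.x) != paste(m$ascertainment_wave.y)
  wx <- m$ascertainment_wave.x[changed]
  wy <- m$ascertainment_wave.y[changed]
  expect_true(all(is.na(wx) | wx >= 6))
  expect_true(all(is.na(wy) | wy >= 6))
  ## and every wave-<=5 ascertainment is identical
  early_x <- st_with7[!is.na(st_with7$ascertainment_wave) &
                        st_with7$ascertainment_wave <= 5, ]
  early_y <- st_no7[!is.na(st_no7$ascertainment_wave) &
                      st_no7$ascertainment_wave <= 5, ]
  rownames(early_x) <- rownames(early_y) <- NULL
  expect_equal(early_x, early_y)
})
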