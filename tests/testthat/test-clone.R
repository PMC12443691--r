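test_that("every eligible subject yields exactly two clones with shared grace deaths", {
  el <- make_eligible(1:5,
                      init_rel = c(2, NA, 5, NA, 80),
                      death_rel = c(10, 3, NA, NA, 100))
  cl <- clone_subjects(el, grace_hours = 4, horizon_days = 1)
  expect_equal(nrow(cl), 10L)
  expect_equal(as.vector(table(cl$arm)), c(5L, 5L))
  cl <- apply_protocol_censoring(cl)
  # subject 2 dies at hour 3 (within grace, untreated): event in BOTH clones
  s2 <- cl[cl$subject_id == 2, ]
  expect_equal(s2$event, c(1L, 1L))
  expect_equal(s2$time, c(3, 3))
})

test_that("protocol censoring follows the hand-enumerated deviation rules", {
  g <- 72; hz <- 90 * 24
  el <- make_eligible(1:3,
                      init_rel = c(30, NA, 80),
                      death_rel = c(NA, NA, NA))
  cl <- apply_protocol_censoring(clone_subjects(el, g, 90))
  early <- cl[cl$arm == "early", ]
  never <- cl[cl$arm == "never", ]
  # initiation at 30: early clone runs to the horizon, never clone censored at 30
  expect_equal(early$time[1], hz); expect_equal(early$artificial_censor[1], 0L)
  expect_equal(never$time[1], 30); expect_equal(never$artificial_censor[1], 1L)
  # no initiation: never clone runs to horizon, early clone censored at 72
  expect_equal(never$time[2], hz); expect_equal(never$artificial_censor[2], 0L)
  expect_equal(early$time[2], g); expect_equal(early$artificial_censor[2], 1L)
  # initiation at 80 (> grace): early censored at 72, never censored at 80
  expect_equal(early$time[3], g); expect_equal(early$artificial_censor[3], 1L)
  expect_equal(never$time[3], 80); expect_equal(never$artificial_censor[3], 1L)
})

test_that("censoring agrees with an independent per-subject re-derivation on random fixtures", {
  set.seed(99)
  n <- 200
  init <- ifelse(runif(n) < 0.5, NA, sample(0:120, n, replace = TRUE))
  death <- ifelse(runif(n) < 0.6, NA, sample(1:2160, n, replace = TRUE))
  el <- make_eligible(1:n, init, death)
  cl <- apply_protocol_censoring(clone_subjects(el, 72, 90))
  for (i in seq_len(n)) {
    bf <- brute_force_clone(init[i], death[i], 72, 2160)
    for (arm in c("early", "never")) {
      row <- cl[cl$subject_id == i & cl$arm == arm, ]
      expect_equal(row$time, bf[[arm]]$time, info = paste(i, arm))
      expect_equal(row$event, bf[[arm]]$event, info = paste(i, arm))
      expect_equal(row$artificial_censor, bf[[arm]]$acens, info = paste(i, arm))
    }
  }
})

test_that("an infinite grace period turns the early arm into ever-initiate", {
  el <- make_eligible(1:4, init_rel = c(10, 100, NA, 50),
                      death_rel = c(NA, 300, 400, NA))
  cl <- apply_protocol_censoring(clone_subjects(el, 72, 90), grace_hours = Inf)
  early <- cl[cl$arm == "early", ]
  expect_true(all(early$artificial_censor == 0L))
  expect_equal(early$time, c(2160, 300, 400, 2160))
})

test_that("person-time expansion matches the hand-written golden table", {
  el <- make_eligible(1:3, init_rel = c(2, NA, 5), death_rel = c(10, 3, NA))
  cl <- apply_protocol_censoring(clone_subjects(el, grace_hours = 4,
                                                horizon_days = 1))
  pt <- person_time_expand(cl, covariates = FALSE)
  golden <- data.frame(
    subject_id = c(1, 1, 1, 1, 1,   1, 1,   2, 2, 2,  2, 2, 2,  3, 3, 3, 3,  3, 3, 3, 3, 3),
    arm     = c(rep("early", 5), "never", "never",
                rep("early", 3), rep("never", 3),
                rep("early", 4), rep("never", 5)),
    tstart  = c(0, 1, 2, 3, 4,  0, 1,  0, 1, 2,  0, 1, 2,  0, 1, 2, 3,  0, 1, 2, 3, 4),
    tstop   = c(1, 2, 3, 4, 10, 1, 2,  1, 2, 3,  1, 2, 3,  1, 2, 3, 4,  1, 2, 3, 4, 5),
    event   = c(0, 0, 0, 0, 1,  0, 0,  0, 0, 1,  0, 0, 1,  0, 0, 0, 0,  0, 0, 0, 0, 0),
    acens   = c(0, 0, 0, 0, 0,  0, 1,  0, 0, 0,  0, 0, 0,  0, 0, 0, 1,  0, 0, 0, 0, 1),
    treated = c(0, 0, 1, 1, 1,  0, 0,  0, 0, 0,  0, 0, 0,  0, 0, 0, 0,  0, 0, 0, 0, 0))
  expect_equal(nrow(pt), nrow(golden))
  expect_equal(pt$subject_id, golden$subject_id)
  expect_equal(pt$arm, golden$arm)
  expect_equal(pt$tstart, golden$tstart)
  expect_equal(pt$tstop, golden$tstop)
  expect_equal(pt$event, golden$event)
  expect_equal(pt$artificial_censor, golden$acens)
  expect_equal(pt$treated, golden$treated)
})

test_that("expansion conserves person-time and flags only final rows", {
  coh <- simulate_cohort(sim_config(150, seed = 14))
  el <- apply_eligibility(coh, eligibility_criteria())
  cl <- apply_protocol_censoring(clone_subjects(el, 72, 90))
  pt <- person_time_expand(cl)
  expect_equal(sum(pt$tstop - pt$tstart), sum(cl$time))
  expect_equal(sum(pt$event), sum(cl$event))
  # clones censored at time zero contribute no person-time rows
  expect_equal(sum(pt$artificial_censor),
               sum(cl$artificial_censor[cl$time > 0]))
  last <- !duplicated(pt$clone_row, fromLast = TRUE)
  expect_true(all(pt$event[!last] == 0))
  # a clone censored within its first hour contributes a single short row
  el1 <- make_eligible(9, init_rel = 0, death_rel = NA)
  pt1 <- person_time_expand(apply_protocol_censoring(clone_subjects(el1, 72, 90)))
  expect_equal(sum(pt1$arm == "never"), 0L)  # zero-length clone: no rows
})
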