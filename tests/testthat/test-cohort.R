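test_that("cohort profiles have the documented marginals", {
  prof <- make_cohort(19, rng_seed = 1)
  expect_s3_class(prof, "cohort")
  expect_identical(nrow(prof), 19L)
  expect_identical(prof$id[1], "P01")
  expect_true(all(prof$vocal_inaccuracy_cents > 0))
  expect_setequal(unique(prof$tessitura), c("female", "male"))
  # log-normal marginal: median near 52 cents over a large draw
  big <- make_cohort(4000, rng_seed = 2)
  expect_equal(median(big$vocal_inaccuracy_cents), 52, tolerance = 0.05)
  expect_equal(sd(log(big$vocal_inaccuracy_cents)), 0.35, tolerance = 0.05)
  expect_equal(mean(big$beta_humanness_effect), 0.15, tolerance = 0.01)
  expect_equal(sd(big$beta_humanness_effect), 0.06, tolerance = 0.01)
})

test_that("copula coupling reproduces the target Spearman correlation", {
  # rho = 0: mean sample correlation near zero
  r0 <- mean(replicate(200, {
    p <- make_cohort(19, rng_seed = sample.int(1e6, 1), coupling_rho = 0)
    cor(p$vocal_inaccuracy_cents, p$beta_humanness_effect,
        method = "spearman")
  }))
  expect_lt(abs(r0), 0.05)
  # rho = 1: comonotone, sample Spearman exactly 1
  p1 <- make_cohort(19, rng_seed = 3, coupling_rho = 1)
  expect_equal(cor(p1$vocal_inaccuracy_cents, p1$beta_humanness_effect,
                   method = "spearman"), 1)
  # default rho = 0.49 at n = 18: mean sample Spearman within +-0.10
  set.seed(4)
  r <- mean(replicate(500, {
    p <- make_cohort(18, rng_seed = sample.int(1e6, 1))
    cor(p$vocal_inaccuracy_cents, p$beta_humanness_effect,
        method = "spearman")
  }))
  expect_gt(r, 0.39)
  expect_lt(r, 0.59)
})

test_that("cohort construction validates its inputs and is reproducible", {
  expect_error(make_cohort(2), "at least 3")
  expect_error(make_cohort(10, coupling_rho = 1.2), "coupling_rho")
  expect_identical(make_cohort(10, rng_seed = 7), make_cohort(10, rng_seed = 7))
  expect_false(identical(make_cohort(10, rng_seed = 7),
                         make_cohort(10, rng_seed = 8)))
})

test_that("trial schedules satisfy the timing invariants", {
  sch <- make_schedule(120, rng_seed = 1)
  expect_s3_class(sch, "trial_schedule")
  expect_identical(nrow(sch), 120L)
  expect_identical(sum(sch$condition == "vocal"), 60L)
  expect_equal(sch$go_s - sch$onset_s, rep(5, 120))
  # adjacent epochs never overlap: next onset - 1 > go + production
  expect_true(all(diff(sch$onset_s) - 1 >
                    sch$go_s[-120] + sch$production_dur_s[-120] -
                    sch$onset_s[-120]))
  expect_error(make_schedule(7))
  expect_error(make_schedule(10, gap_s = 1))
  expect_identical(make_schedule(20, rng_seed = 2)$condition,
                   make_schedule(20, rng_seed = 2)$condition)
})

test_that("erd truth tables are validated for the built-in ordering", {
  tr <- default_erd_truth()
  expect_s3_class(tr, "erd_truth")
  bad <- tr
  bad$depth[bad$band == "mu" & bad$gradient == "FC" &
              bad$condition == "vocal"] <- 0.1     # shallower than nonvocal
  expect_error(simulate_eeg(make_cohort(3)[1, ], make_schedule(10),
                            erd = bad), "deeper and earlier")
})

test_that("simulate_eeg validates the montage and is seed-deterministic", {
  prof <- make_cohort(3, rng_seed = 1)[1, ]
  sch <- make_schedule(4, rng_seed = 1, production_dur_s = 0, gap_s = 2)
  mont <- default_montage()
  expect_error(simulate_eeg(prof, sch, montage = mont[mont$name != "C3", ]),
               "ROI electrodes")
  expect_error(simulate_eeg(prof, sch, montage = mont[mont$name != "M1", ]),
               "M1")
  a <- simulate_eeg(prof, sch, rng_seed = 5)
  b <- simulate_eeg(prof, sch, rng_seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  expect_false(identical(a$data, simulate_eeg(prof, sch, rng_seed = 6)$data))
  # events: one stimulus and one go per trial, labels match the schedule
  stim <- a$events[grepl("^stim_", a$events$label), ]
  expect_identical(nrow(stim), nrow(sch))
  expect_identical(sub("^stim_", "", stim$label), sch$condition)
  expect_identical(sum(a$events$label == "go"), nrow(sch))
})
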