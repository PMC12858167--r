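test_that("evidence levels map admissible rating gaps and reject others", {
  expect_identical(compute_evidence_level(70, 50, "perceptual"), 4L)
  expect_identical(compute_evidence_level(50, 55, "perceptual"), 1L)
  expect_identical(compute_evidence_level(5, 8, "value"), 3L)
  expect_identical(compute_evidence_level(9, 5, "value"), 4L)
  expect_error(compute_evidence_level(50, 50, "perceptual"), "rejected")
  expect_error(compute_evidence_level(50, 57, "perceptual"), "rejected")
  expect_error(compute_evidence_level(1, 6.5, "value"), "rejected")
})

test_that("default design is 256 trials in 8 sessions, exactly balanced", {
  d <- build_design(design_spec(3), seed = 2)
  per_subj <- split(d, d$subject_id)
  expect_length(per_subj, 3)
  for (s in per_subj) {
    expect_identical(nrow(s), 256L)
    expect_identical(length(unique(s$session)), 8L)
    expect_true(all(table(s$session) == 32))
    # every task x evidence x side cell holds 256 / 16 = 16 trials
    cell_counts <- table(s$task, s$evidence_level, s$target)
    expect_true(all(cell_counts == 16))
    # sessions 1-4 pre, 5-8 post; last two sessions flagged as recovery
    expect_true(all(s$phase[s$session <= 4] == "pre"))
    expect_true(all(s$phase[s$session >= 5] == "post"))
    expect_identical(sort(unique(s$session[s$recovery])), c(7L, 8L))
    # blocks alternate tasks with lengths in 7..9
    for (ses in split(s, s$session)) {
      lens <- rle(paste(ses$block_id, ses$task))$lengths
      expect_true(all(lens >= 7 & lens <= 9))
      btask <- tapply(ses$task, ses$block_id, function(x) x[1])
      expect_true(all(btask[-1] != btask[-length(btask)]))
    }
  }
})

test_that("scaled designs stay balanced and infeasible ones are rejected", {
  d <- build_design(design_spec(1, n_sessions = 2, trials_per_session = 16,
                                block_length_range = c(4, 4),
                                phase_split = 1), seed = 1)
  expect_identical(nrow(d), 32L)
  expect_true(all(table(d$task, d$evidence_level, d$target) == 2))
  expect_error(design_spec(1, trials_per_session = 31), "even")
  expect_error(design_spec(1, n_sessions = 3, trials_per_session = 8,
                           phase_split = 1),
               "16 design cells")
  expect_error(design_spec(1, trials_per_session = 32,
                           block_length_range = c(5, 5)),
               "no block partition")
})

test_that("trial tables are byte-identical under the same seed", {
  spec <- design_spec(2)
  tr <- ground_truth(2, scenario = "both", gamma = 0.3, seed = 4)
  a <- simulate_experiment(spec, tr, seed = 11)
  b <- simulate_experiment(spec, tr, seed = 11)
  cc <- simulate_experiment(spec, tr, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, cc))
})

test_that("stimulation deltas move accuracy and RT in the modelled directions", {
  # Monte-Carlo oracle on the trial simulator itself, 10,000 trials per cell
  n <- 10000
  pre <- simulate_trials(n, wiener_params(0.4 * 2, 1.6, 0.35), seed = 5)
  post <- simulate_trials(n, wiener_params(0.4 * 2, 1.6 * 0.7, 0.35),
                          seed = 6)
  expect_gt(mean(pre$upper), mean(post$upper))     # accuracy drops
  expect_gt(mean(pre$rt_s), mean(post$rt_s))       # RTs speed up
  # accuracy strictly increases over evidence levels within a cell
  acc <- vapply(1:4, function(E) {
    mean(simulate_trials(n, wiener_params(0.4 * E, 1.6, 0.35),
                         seed = 100 + E)$upper)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("null ground truth produces no pre/post differences beyond noise", {
  tr <- ground_truth(6, scenario = "null", seed = 8)
  rec <- simulate_experiment(design_spec(6), tr, seed = 9)
  v <- rec[rec$valid == 1, ]
  for (tk in c("perceptual", "value")) {
    x <- v[v$task == tk, ]
    d_acc <- mean(x$correct[x$phase == "post"]) -
      mean(x$correct[x$phase == "pre"])
    se <- sqrt(2 * 0.25 / (nrow(x) / 2))
    expect_lt(abs(d_acc), 3 * se)
  }
})

test_that("invalid-trial fraction tracks the miss rate plus window censoring", {
  tr <- ground_truth(8, scenario = "null", seed = 14, miss_rate = 0.05)
  rec <- simulate_experiment(design_spec(8), tr, seed = 15)
  n <- nrow(rec)
  # valid trials never exceed the 3 s response window
  expect_identical(sum(rec$valid == 1 & rec$rt_s > 3, na.rm = TRUE), 0L)
  frac <- mean(rec$valid == 0)
  # expected: miss_rate + (1 - miss_rate) * P(RT > 3); bound the latter
  # empirically from the simulator at the group parameters
  sim <- simulate_trials(20000, wiener_params(0.4 * 2.5, 1.6, 0.35),
                         seed = 16)
  p3 <- mean(sim$rt_s > 3)
  expected <- 0.05 + 0.95 * p3
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 4 * se + 0.01)
  # invalid rows carry no outcome
  inv <- rec[rec$valid == 0, ]
  expect_true(all(is.na(inv$response) & is.na(inv$rt_s)))
})

test_that("neural betas are z-scored per subject and couple through gamma", {
  tr0 <- ground_truth(3, scenario = "null", gamma = 0, seed = 20)
  rec0 <- simulate_experiment(design_spec(3), tr0, seed = 21)
  v0 <- rec0[rec0$valid == 1, ]
  for (s in split(v0$sfs_beta, v0$subject_id)) {
    expect_equal(mean(s), 0, tolerance = 1e-12)
    expect_equal(sd(s), 1, tolerance = 1e-12)
  }
  # decoupled null: beta carries no information about accuracy
  r0 <- cor(v0$sfs_beta, v0$correct)
  expect_lt(abs(r0), 3 / sqrt(nrow(v0)))
  # gamma > 0: higher beta -> higher boundary -> slower perceptual RTs
  tr1 <- ground_truth(3, scenario = "null", gamma = 0.4, seed = 22)
  rec1 <- simulate_experiment(design_spec(3, n_sessions = 8,
                                          trials_per_session = 32),
                              tr1, seed = 23)
  v1 <- rec1[rec1$valid == 1 & rec1$task == "perceptual", ]
  expect_gt(nrow(v1), 300)
  r1 <- cor(v1$sfs_beta, v1$rt_s)
  expect_gt(r1, 3 / sqrt(nrow(v1)))
  # too few valid trials for z-scoring is an error
  few <- rec0[rec0$subject_id == 1, ][1:3, ]
  few$valid <- c(1L, 0L, 0L)
  expect_error(generate_neural(few, tr0, seed = 1), "fewer than 2")
})

test_that("trial CSV round-trips with ground-truth sidecar", {
  tr <- ground_truth(2, seed = 30)
  rec <- simulate_experiment(design_spec(2), tr, seed = 31)
  path <- file.path(tempdir(), "trials_fixture.csv")
  write_trials(rec, path, truth = tr)
  back <- read_trials(path)
  expect_identical(nrow(back), nrow(rec))
  expect_equal(back$rt_s, round(rec$rt_s, 6), tolerance = 1e-9)
  expect_identical(back$correct, rec$correct)
  side <- yaml::read_yaml(paste0(path, ".truth.yml"))
  expect_equal(side$d_alpha_pdm_post, tr$d_alpha_pdm_post)
  expect_identical(side$scenario, "boundary")
  unlink(c(path, paste0(path, ".truth.yml")))
})
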