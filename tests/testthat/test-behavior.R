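test_that("schedule presets reproduce the two task layouts", {
  p1 <- sart_preset("exp1")
  s1 <- generate_schedule(p1$n_trials, n_blocks = p1$n_blocks, seed = 1)
  expect_equal(nrow(s1), 1200)
  expect_equal(unname(table(s1$block)), rep(200L, 6), ignore_attr = TRUE)
  expect_equal(sum(s1$is_target), 120) # 10% withhold targets
  expect_equal(max(abs(diff(s1$onset_s) - 1.150)), 0, tolerance = 1e-9)
  p4 <- sart_preset("exp4")
  s4 <- generate_schedule(p4$n_trials, n_blocks = p4$n_blocks, seed = 1)
  expect_equal(unname(table(s4$block)), rep(270L, 4), ignore_attr = TRUE)
})

test_that("schedules respect constraints and seeding", {
  s <- generate_schedule(500, seed = 42)
  expect_false(any(s$is_target[-1] & s$is_target[-nrow(s)])) # no adjacent targets
  expect_true(all(s$digit[s$is_target] == 0))
  expect_true(all(s$digit[!s$is_target] %in% 1:9))
  expect_identical(s, generate_schedule(500, seed = 42))
  expect_false(identical(s$digit, generate_schedule(500, seed = 43)$digit))
  expect_warning(s0 <- generate_schedule(100, target_prop = 0, seed = 1), "all-go")
  expect_equal(sum(s0$is_target), 0)
  expect_error(generate_schedule(100, n_blocks = 3), class = "ammod_invalid_parameter")
})

test_that("perfect responder d' matches the closed-form log-linear value", {
  s <- generate_schedule(200, n_blocks = 1, seed = 3) # 180 go, 20 no-go
  log <- tibble::tibble(pressed = !s$is_target,
                        rt_s = ifelse(!s$is_target, 0.3, NA_real_))
  sdt <- score_responses(s, log)
  expect_equal(sdt$hits, 180)
  expect_equal(sdt$correct_rejections, 20)
  # oracle: z((180+.5)/181) - z((0+.5)/21), computed independently
  expect_equal(sdt$dprime, 4.755476, tolerance = 1e-6)
  expect_equal(sdt$correction_tag, "loglinear")
})

test_that("all-press responding follows the corrected closed form", {
  # with equal go/no-go counts the log-linear correction is symmetric: d' = 0
  s_eq <- generate_schedule(100, target_prop = 0.49, n_blocks = 1, seed = 3)
  n_t <- sum(s_eq$is_target)
  s_eq$is_target[which(!s_eq$is_target)[seq_len(50 - n_t)]] <- TRUE
  s_eq$digit[s_eq$is_target] <- 0L
  log_eq <- tibble::tibble(pressed = rep(TRUE, 100), rt_s = 0.3)
  expect_equal(score_responses(s_eq, log_eq)$dprime, 0, tolerance = 1e-12)
  # with 180 go / 20 no-go the correction is asymmetric (oracle: direct z-scores)
  s <- generate_schedule(200, n_blocks = 1, seed = 3)
  log <- tibble::tibble(pressed = rep(TRUE, 200), rt_s = 0.3)
  expect_equal(score_responses(s, log)$dprime, qnorm(361 / 362) - qnorm(41 / 42))
})

test_that("coin-flip responding is unbiased around d' = 0", {
  s <- generate_schedule(200, n_blocks = 1, seed = 3)
  set.seed(99)
  dps <- replicate(100, {
    log <- tibble::tibble(pressed = runif(200) < 0.5,
                          rt_s = NA_real_)
    log$rt_s[log$pressed] <- 0.3
    score_responses(s, log)$dprime
  })
  expect_lt(abs(mean(dps)), 0.1)
})

test_that("counts conserve within every cell", {
  s <- generate_schedule(400, n_blocks = 2, conditions = c("a", "b"), seed = 8)
  set.seed(1)
  log <- tibble::tibble(pressed = runif(400) < 0.8, rt_s = NA_real_)
  log$rt_s[log$pressed] <- 0.3
  sdt <- score_responses(s, log)
  expect_true(all(sdt$hits + sdt$misses + sdt$false_alarms + sdt$correct_rejections == 200))
  expect_error(score_responses(s, log[1:399, ]), class = "ammod_invalid_input")
})

test_that("RT coefficient of variation matches hand computation", {
  log <- tibble::tibble(
    pressed = c(TRUE, TRUE, rep(FALSE, 8), TRUE, rep(FALSE, 9)),
    rt_s = c(0.3, 0.5, rep(NA, 8), 0.4, rep(NA, 9))
  )
  cv <- rt_variability(log, window = 10)
  expect_equal(cv$cv[1], sd(c(0.3, 0.5)) / 0.4) # 0.1*sqrt(2)/0.4
  expect_true(is.na(cv$cv[2])) # single RT: missing, not an error
  const <- tibble::tibble(pressed = rep(TRUE, 20), rt_s = 0.35)
  expect_equal(rt_variability(const)$cv, c(0, 0))
  none <- tibble::tibble(pressed = rep(FALSE, 20), rt_s = NA_real_)
  expect_error(rt_variability(none), class = "ammod_insufficient_data")
})

test_that("identical conditions yield zero d'-differences and zero SEM", {
  sdt <- tibble::tibble(
    subject = rep(c("s1", "s2"), each = 4),
    condition = rep(c("none", "none", "16", "16"), 2),
    block = rep(c(1, 2, 3, 4), 2),
    dprime = rep(2.2, 8)
  )
  dd <- condition_block_summary(sdt, baseline = "none")
  expect_true(all(dd$ddprime == 0))
  cm <- condition_means(dd)
  expect_true(all(cm$mean == 0 & cm$sem_ws == 0))
  expect_error(condition_block_summary(sdt, baseline = "zzz"),
               class = "ammod_invalid_input")
})

test_that("within-subject SEM equals classic SEM times the Morey factor", {
  set.seed(11)
  n <- 20
  m <- 4 # 2 conditions x 2 blocks
  subj_eff <- rnorm(n, 0, 2)
  dd <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                           condition = c("8", "16"), block = c(1, 2)) |>
    dplyr::mutate(ddprime = subj_eff[as.integer(factor(subject))] +
                    rnorm(n * m, 0, 0.3))
  class(dd) <- c("ddprime_table", class(dd))
  cm <- condition_means(dd)
  # oracle: classic SEM of subject-mean-centered values, inflated by sqrt(m/(m-1))
  centered <- dd |>
    dplyr::group_by(subject) |>
    dplyr::mutate(c = ddprime - mean(ddprime) + mean(dd$ddprime)) |>
    dplyr::ungroup()
  cell <- centered[centered$condition == "8" & centered$block == 1, ]
  expect_equal(cm$sem_ws[cm$condition == "8" & cm$block == 1],
               sd(cell$c) / sqrt(n) * sqrt(m / (m - 1)), tolerance = 1e-12)
})

test_that("a designed condition effect is recovered in the group mean", {
  sched <- generate_schedule(1080, n_blocks = 8,
                             conditions = c("none", "8", "16", "32"), seed = 5)
  eff <- effect_map(baseline_dprime = 2,
                    condition_offsets = c(none = 0, `8` = 0, `16` = 0.3, `32` = 0))
  coh <- synth_cohort(80, sched, eff, seed = 17)
  dd <- condition_block_summary(score_responses(sched, coh$logs), "none")
  cm <- condition_means(dd)
  est <- mean(cm$mean[cm$condition == "16"])
  sem <- mean(cm$sem_ws[cm$condition == "16"])
  expect_lt(abs(est - 0.3), 2 * sem + 0.05)
})

test_that("zero tables give a zero slope and a null p-value", {
  dd <- tidyr::expand_grid(subject = sprintf("s%02d", 1:12),
                           condition = c("8", "16", "32"), block = c(1, 2)) |>
    dplyr::mutate(ddprime = 0)
  profiles <- tibble::tibble(subject = sprintf("s%02d", 1:12),
                             asrs_score = seq(10, 65, length.out = 12))
  ctr <- interaction_contrast(dd, profiles, n_perm = 199, seed = 1)
  expect_equal(ctr$estimate, 0)
  expect_equal(ctr$p_value, 1)
  expect_equal(tidy(ctr)$estimate, 0)
  expect_equal(glance(ctr)$n_subjects, 12)
})

test_that("the designed ASRS interaction is detected with high power", {
  sched <- generate_schedule(1080, n_blocks = 8,
                             conditions = c("none", "8", "16", "32"), seed = 5)
  eff <- effect_map(baseline_dprime = 2, asrs_interaction = 0.4,
                    condition_offsets = c(none = 0, `8` = 0, `16` = 0, `32` = 0))
  hits <- vapply(1:20, function(i) {
    coh <- synth_cohort(82, sched, eff, seed = 300 + i)
    dd <- condition_block_summary(score_responses(sched, coh$logs), "none")
    ctr <- interaction_contrast(dd, coh$profiles, n_perm = 199, seed = i)
    ctr$estimate > 0 && ctr$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("subjects with missing cells are excluded with a warning", {
  dd <- tidyr::expand_grid(subject = sprintf("s%02d", 1:10),
                           condition = c("8", "16", "32"), block = c(1, 2)) |>
    dplyr::mutate(ddprime = rnorm(60))
  dd <- dd[-1, ] # s01 loses a cell
  profiles <- tibble::tibble(subject = sprintf("s%02d", 1:10),
                             asrs_score = seq(5, 60, length.out = 10))
  expect_warning(ctr <- interaction_contrast(dd, profiles, n_perm = 99, seed = 2),
                 "excluded")
  expect_equal(ctr$n_subjects, 9)
})

test_that("trial tables round-trip through TSV", {
  s <- generate_schedule(60, n_blocks = 2, conditions = c("a", "b"), seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials(s, path)
  back <- read_trials(path)
  expect_equal(back$digit, s$digit)
  expect_equal(back$onset_s, s$onset_s, tolerance = 1e-9)
})
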