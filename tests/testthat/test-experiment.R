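small <- list(days = 0:10, iters_per_day = 150, replicates = 2, seed = 9)

test_that("developmental runs are deterministic given the seed and well-formed", {
  a <- do.call(run_development, c(list(condition = "control"), small))
  b <- do.call(run_development, c(list(condition = "control"), small))
  expect_identical(a$stats, b$stats)
  expect_identical(a$replicates, b$replicates)
  expect_s3_class(a, "huddle_development")
  st <- tidy(a)
  expect_named(st, c("day", "condition", "mean_group_size", "sd", "mean_rho"))
  expect_true(all(st$mean_group_size >= 1 & st$mean_group_size <= 7))
  expect_true(all(st$mean_rho > 0 & st$mean_rho < 1))
  expect_equal(nrow(glance(a)), 1)
  c2 <- do.call(run_development, c(list(condition = "control"),
                                   utils::modifyList(small, list(seed = 10))))
  expect_false(identical(a$stats, c2$stats))
})

test_that("the litter starts postnatal life as a single huddle", {
  a <- run_development("control", days = 0:3, iters_per_day = 25,
                       replicates = 4, seed = 3)
  st <- tidy(a)
  # day 0 statistics are taken while the initial single group of 7 relaxes,
  # so they sit far above the dispersed regime
  expect_gt(st$mean_group_size[st$day == 0], 4.5)
})

test_that("learning with a frozen rate reproduces the control trajectories exactly", {
  frozen <- huddle_constants(gamma = 0)
  ctrl <- do.call(run_development, c(list(condition = "control"), small))
  lrn <- do.call(run_development,
                 c(list(condition = "learning", alpha_init = 1,
                        constants = frozen, alpha_snapshots = FALSE), small))
  expect_identical(ctrl$replicates$mean_group_size, lrn$replicates$mean_group_size)
  expect_identical(ctrl$replicates$mean_rho, lrn$replicates$mean_rho)
})

test_that("learning snapshots exist per day and control runs carry none", {
  lrn <- do.call(run_development, c(list(condition = "learning"), small))
  expect_named(lrn$alpha, c("replicate", "day", "a", "b", "alpha"))
  expect_equal(sort(unique(lrn$alpha$day)), small$days)
  expect_equal(nrow(lrn$alpha), length(small$days) * 7 * 6 * small$replicates)
  ctrl <- do.call(run_development, c(list(condition = "control"), small))
  expect_null(ctrl$alpha)
})

test_that("divergence detection follows its persistent-exceedance definition", {
  days <- 0:30
  base <- tibble::tibble(day = days, mean_group_size = 3)
  same <- detect_divergence_day(base, base)
  expect_true(is.na(same))
  # equal until day 19, learning one pup larger from day 20 onwards
  lrn <- base
  lrn$mean_group_size[days >= 20] <- 4
  expect_equal(detect_divergence_day(base, lrn), 20)
  # a 3-day noise crossing is ignored; the persistent rise from 22 is found
  lrn2 <- base
  lrn2$mean_group_size[days %in% 8:10] <- 4
  lrn2$mean_group_size[days >= 22] <- 4
  expect_equal(detect_divergence_day(base, lrn2, persistence = 5), 22)
  expect_error(detect_divergence_day(base, lrn[1:20, ]), "day grid")
})

test_that("steady-state rho averages encounters over the late window", {
  tab <- tibble::tibble(
    replicate = rep(1:2, each = 16), day = rep(45:60, 2),
    mean_rho = rep(0.5, 32)
  )
  expect_equal(steady_state_rho(tab), 0.5)
  expect_error(steady_state_rho(tab, window = c(70, 80)), "window")
  expect_error(steady_state_rho(list()), "huddle_development")
})

test_that("condition comparison reports divergence and late-phase contrasts", {
  runs <- default_runs()
  cmp <- compare_conditions(runs$control, runs$learning)
  expect_named(cmp, c("divergence_day", "rho_learning", "rho_control",
                      "late_group_size_learning", "late_group_size_control"))
  # late in development learnt preferences keep huddles larger than thermal
  # drives alone can
  expect_gt(cmp$late_group_size_learning, cmp$late_group_size_control)
  ls_ <- tidy(runs$learning); cs <- tidy(runs$control)
  late <- ls_$day >= 40
  expect_true(all(ls_$mean_group_size[late] > cs$mean_group_size[late]))
})

test_that("day-60 associations are heterogeneous: strong likes and dislikes", {
  # The amplification of early individual differences needs enough
  # conditioning trials per pair: at gamma = 0.001 each ordered pair must see
  # well over 1/gamma encounters across development, so the litter is given a
  # richer daily encounter budget here than in the group-size experiments.
  rich <- run_development("learning", iters_per_day = 10000, replicates = 10,
                          seed = 1)
  al <- dplyr::filter(rich$alpha, .data$day == 60)
  signs <- al |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(pos = any(.data$alpha > 0), neg = any(.data$alpha < 0))
  expect_gte(sum(signs$pos & signs$neg), 8) # of 10 replicate litters
})

test_that("control group sizes track the sign of the thermal drive", {
  runs <- default_runs()
  cs <- tidy(runs$control)
  drive <- huddling_drive(cs$day)
  expect_gt(mean(cs$mean_group_size[drive > 0]), mean(cs$mean_group_size[drive < 0]))
})
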