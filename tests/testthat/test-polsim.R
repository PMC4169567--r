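test_that("the kernel reproduces the brute-force event log exactly", {
  cases <- list(
    list(L = 60L, pp = 20L, st = 9L, dtau = 4L, T = 600L),
    list(L = 60L, pp = 20L, st = 3L, dtau = 4L, T = 600L),   # stall < dtau
    list(L = 80L, pp = c(15L, 40L), st = c(12L, 30L), dtau = 5L, T = 800L),
    list(L = 50L, pp = integer(0), st = integer(0), dtau = 7L, T = 400L),
    list(L = 40L, pp = 1L, st = 11L, dtau = 3L, T = 500L)    # pause at base 1
  )
  for (cs in cases) {
    bf <- brute_polsim(cs$L, cs$pp, cs$st, cs$dtau, cs$T)
    cfg <- polsim_config(
      L = cs$L,
      pauses = if (length(cs$pp)) data.frame(position = cs$pp, stall = cs$st),
      dtau = cs$dtau, T = cs$T, burn_in = 0L
    )
    r <- polsim(cfg)
    ev <- bf$events
    expect_equal(r$full_length_count, sum(ev$type == "full"))
    expect_equal(r$in_progress, bf$in_progress)
    bf_trunc <- table(ev$len[ev$type %in% c("trunc", "blocked_init")])
    expected <- tibble::tibble(length = as.integer(names(bf_trunc)),
                               count = as.numeric(bf_trunc))
    expect_equal(dplyr::arrange(r$truncated_counts, length), expected)
    expect_equal(r$first_full_release_time,
                 if (any(ev$type == "full")) min(ev$t[ev$type == "full"])
                 else NA_integer_)
  }
})

test_that("closed-form single-pause rates agree with brute-force enumeration", {
  # validate the steady-state formulas themselves on small horizons
  for (cs in list(c(dtau = 4, st = 20), c(dtau = 6, st = 4),
                  c(dtau = 5, st = 25), c(dtau = 3, st = 33))) {
    m <- max(cs[["dtau"]], cs[["st"]])
    Tt <- 60L + 200L * as.integer(m) # transit (L = 60) + long window
    bf <- brute_polsim(60L, 20L, cs[["st"]], cs[["dtau"]], Tt)
    ev <- bf$events[bf$events$t > 60 + 10 * m, ]
    win <- Tt - (60 + 10 * m)
    cf <- polsim_closed_form(cs[["dtau"]], cs[["st"]])
    expect_equal(sum(ev$type == "full") / win, cf[["full_length"]],
                 tolerance = 0.02)
    expect_equal(sum(ev$type == "trunc") / win, cf[["truncated"]],
                 tolerance = 0.02)
  }
})

test_that("simulated steady-state rates match the closed forms within 2%
           over random single-pause configurations", {
  set.seed(91)
  n_cfg <- 0
  draw <- function() {
    stratum <- sample(3, 1)
    dtau <- sample(2:40, 1)
    if (stratum == 1) {          # free flow: stall below the initiation gap
      st <- sample(seq_len(dtau), 1)
    } else if (stratum == 2) {   # congested, stall on the initiation lattice
      st <- dtau * sample(2:12, 1)
    } else {                     # strongly congested: stall >> dtau
      dtau <- sample(2:6, 1)
      st <- sample(150:400, 1)
    }
    c(dtau = dtau, st = st)
  }
  while (n_cfg < 50) {
    cs <- draw()
    m <- max(cs)
    cfg <- polsim_config(L = 400L,
                         pauses = data.frame(position = 36L, stall = cs[["st"]]),
                         dtau = cs[["dtau"]],
                         burn_in = 400L + 10L * m,
                         T = 400L + 10L * m + 500L * m)
    r <- polsim(cfg)
    cf <- polsim_closed_form(cs[["dtau"]], cs[["st"]])
    expect_equal(r$rates[["full_length"]], cf[["full_length"]],
                 tolerance = 0.02)
    if (cf[["truncated"]] == 0) {
      expect_equal(r$rates[["truncated"]], 0)
    } else {
      expect_equal(r$rates[["truncated"]], cf[["truncated"]],
                   tolerance = 0.02)
    }
    n_cfg <- n_cfg + 1
  }
})

test_that("initiations are conserved exactly in every simulation", {
  set.seed(92)
  for (i in 1:30) {
    n_pause <- sample(0:3, 1)
    pp <- sort(sample(2:180, n_pause))
    cfg <- polsim_config(
      L = 200L,
      pauses = if (n_pause) data.frame(position = pp,
                                       stall = sample(2:60, n_pause)),
      dtau = sample(2:15, 1),
      T = sample(500:3000, 1), burn_in = 0L
    )
    r <- polsim(cfg)
    expect_identical(
      r$initiations,
      r$full_length_count + sum(r$truncated_counts$count) + r$in_progress
    )
  }
})

test_that("the model is deterministic and truncations sit one base behind
           the pause", {
  cfg <- polsim_config(L = 2000L,
                       pauses = data.frame(position = 36L, stall = 250L),
                       dtau = 4L)
  r1 <- polsim(cfg)
  r2 <- polsim(cfg)
  expect_identical(r1$truncated_counts, r2$truncated_counts)
  expect_identical(r1$rates, r2$rates)
  expect_equal(r1$truncated_counts$length, 35)
})

test_that("free flow: no pause means no truncation and first release at
           L / v", {
  cfg <- polsim_config(L = 300L, dtau = 10L, T = 2000L, burn_in = 0L)
  r <- polsim(cfg)
  expect_equal(nrow(r$truncated_counts), 0)
  expect_equal(r$first_full_release_time, 300)
  expect_equal(length_histogram(r)$histogram$count, numeric(0))
  # stall below the initiation interval behaves identically in rates
  cfg2 <- polsim_config(L = 300L,
                        pauses = data.frame(position = 50L, stall = 3L),
                        dtau = 4L)
  r2 <- polsim(cfg2)
  expect_equal(nrow(r2$truncated_counts), 0)
  expect_equal(r2$rates[["full_length"]], 1 / 4, tolerance = 0.01)
})

test_that("multiple pause sites imprint a multi-band length census", {
  cfg <- polsim_config(
    L = 2000L,
    pauses = data.frame(position = c(27L, 63L, 91L, 107L),
                        stall = c(250L, 500L, 1000L, 2000L)),
    dtau = 4L
  )
  lh <- length_histogram(polsim(cfg))
  expect_equal(lh$histogram$length, c(26, 62, 90, 106))
  expect_equal(sort(lh$modes), c(26, 62, 90, 106))
  single <- polsim_config(L = 2000L,
                          pauses = data.frame(position = 73L, stall = 300L),
                          dtau = 5L)
  expect_equal(length_histogram(polsim(single))$modes, 72)
})

test_that("total outcome rate equals the initiation rate 1/dtau regardless
           of pause configuration", {
  set.seed(93)
  for (i in 1:6) {
    n_pause <- sample(1:3, 1)
    cfg <- polsim_config(
      L = 500L,
      pauses = data.frame(position = sort(sample(10:400, n_pause)),
                          stall = sample(5:80, n_pause)),
      dtau = sample(3:12, 1)
    )
    r <- polsim(cfg)
    expect_equal(r$rates[["full_length"]] + r$rates[["truncated"]],
                 r$rates[["initiation"]], tolerance = 0.02)
    expect_equal(r$rates[["initiation"]], 1 / cfg$dtau, tolerance = 0.01)
  }
})

test_that("the parameter scan reports identity folds against itself and
           recovers the printed fold contrasts", {
  base <- polsim_config(L = 2000L,
                        pauses = data.frame(position = 36L, stall = 250L),
                        dtau = 4L)
  sc <- polsim_scan(dtau_grid = c(4, 84), stall_grid = 250, base,
                    reference = c(4, 250))
  self <- sc[sc$dtau == 4, ]
  expect_equal(self$log2_tssarna_fold, 0)
  expect_equal(self$log2_cognate_fold, 0)
  other <- sc[sc$dtau == 84, ]
  expect_equal(other$log2_cognate_fold, 0)              # equal full-length rates
  expect_equal(2^(-other$log2_tssarna_fold), 31, tolerance = 0.01)
})

test_that("a constant growth-curve schedule yields flat profiles and varying
           dtau at fixed stall leaves the cognate profile flat", {
  base <- polsim_config(L = 1000L,
                        pauses = data.frame(position = 36L, stall = 120L),
                        dtau = 6L)
  flat <- tibble::tibble(timepoint = 1:4, dtau = 6L, stall = 120L)
  pf <- polsim_growth_curve(flat, base, ref_timepoint = 1)
  expect_equal(pf$tssarna_log2, rep(0, 4))
  expect_equal(pf$cognate_log2, rep(0, 4))
  # dtau divides the stall everywhere: full-length rate pinned at 1/stall
  vary <- tibble::tibble(timepoint = 1:4, dtau = c(4L, 6L, 10L, 12L),
                         stall = 120L)
  pv <- polsim_growth_curve(vary, base, ref_timepoint = 1)
  expect_equal(pv$cognate_log2, rep(0, 4), tolerance = 0.05)
  expect_gt(max(abs(pv$tssarna_log2)), 0.5)
})

test_that("initiation totals are conserved when the stall varies over the
           curve at fixed dtau", {
  base <- polsim_config(L = 1000L,
                        pauses = data.frame(position = 36L, stall = 120L),
                        dtau = 8L)
  sched <- tibble::tibble(timepoint = 1:4, dtau = 8L,
                          stall = c(40L, 80L, 120L, 160L))
  pf <- polsim_growth_curve(sched, base, ref_timepoint = 1)
  expect_equal(pf$tssarna_rate + pf$cognate_rate, rep(1 / 8, 4),
               tolerance = 0.02)
})
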