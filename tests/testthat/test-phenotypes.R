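make_records <- function(entry_means, reps, sigma_e = 0, seed = NULL,
                         trait = "mf_days") {
  if (!is.null(seed)) set.seed(seed)
  n <- length(entry_means)
  ids <- sprintf("E%03d", seq_len(n))
  reps <- rep_len(reps, n)
  idx <- rep(seq_len(n), times = reps)
  out <- data.frame(
    plant_id = paste0(ids[idx], "_", unlist(lapply(reps, seq_len))),
    entry_id = ids[idx],
    replicate = unlist(lapply(reps, seq_len)),
    mf_days = 70, ff_days = 72, gs_pg = 5.5,
    stringsAsFactors = FALSE
  )
  out[[trait]] <- entry_means[idx] + stats::rnorm(length(idx), 0, sigma_e)
  out
}

test_that("BLUEs equal replicate means under the completely randomized design", {
  rec <- data.frame(
    plant_id = c("a1", "a2", "a3", "b1"),
    entry_id = c("A", "A", "A", "B"),
    replicate = c(1, 2, 3, 1),
    mf_days = c(60, 62, 64, 70), ff_days = 1, gs_pg = 1
  )
  b <- compute_blues(rec, "mf")
  expect_equal(b$blue[b$entry_id == "A"], 62)
  expect_equal(b$blue[b$entry_id == "B"], 70)
  expect_equal(b$n_reps, c(3L, 1L))

  # permutation of record order leaves BLUEs unchanged
  b2 <- compute_blues(rec[c(4, 2, 1, 3), ], "mf")
  expect_equal(b2[order(b2$entry_id), ], b[order(b$entry_id), ],
               ignore_attr = TRUE)

  # requested ordering and missing-entry error
  b3 <- compute_blues(rec, "mf", entries = c("B", "A"))
  expect_equal(b3$entry_id, c("B", "A"))
  expect_error(compute_blues(rec, "mf", entries = c("A", "B", "C")), "C")
})

test_that("heritability matches its closed form and handles degenerate cases", {
  # sigma_g2 = sigma_e2 = 1, r = 5 -> h2 = 1/(1 + 1/5)
  set.seed(8)
  g <- rnorm(500)
  rec <- make_records(g + 70, reps = 5, sigma_e = 1)
  h <- estimate_heritability(rec, "mf")
  expect_equal(h$h2, 1 / (1 + 1 / 5), tolerance = 0.02 / 0.83)
  expect_equal(h$r_eff, 5)

  # zero residual variance, entries differ -> h2 = 1
  rec0 <- make_records(c(60, 65, 70), reps = 3, sigma_e = 0)
  expect_equal(estimate_heritability(rec0, "mf")$h2, 1)

  # sigma_g2 = 0 -> h2 near zero (median over replicates)
  h0 <- replicate(20, {
    rec <- make_records(rep(70, 50), reps = 5, sigma_e = 2)
    estimate_heritability(rec, "mf")$h2
  })
  expect_lt(median(h0), 0.05)

  # all single-replicate entries: unidentifiable
  rec1 <- make_records(c(60, 65, 70), reps = 1)
  expect_error(estimate_heritability(rec1, "mf"), "single replicate")
})

test_that("heritability is invariant to location shifts and scaling", {
  set.seed(13)
  rec <- make_records(rnorm(60, 70, 1.5), reps = 4, sigma_e = 2)
  h <- estimate_heritability(rec, "mf")
  rec_shift <- rec; rec_shift$mf_days <- rec$mf_days + 100
  rec_scale <- rec; rec_scale$mf_days <- rec$mf_days * 3
  expect_equal(estimate_heritability(rec_shift, "mf")$h2, h$h2, tolerance = 1e-6)
  hs <- estimate_heritability(rec_scale, "mf")
  expect_equal(hs$h2, h$h2, tolerance = 1e-6)
  expect_equal(hs$sigma_e2, 9 * h$sigma_e2, tolerance = 1e-4)
})

test_that("REML equals the method-of-moments ANOVA estimators for balanced designs", {
  set.seed(4)
  r <- 4
  rec <- make_records(rnorm(40, 70, 2), reps = r, sigma_e = 1.5)
  h <- estimate_heritability(rec, "mf")
  fit <- stats::aov(mf_days ~ entry_id, data = rec)
  ms <- summary(fit)[[1]]$`Mean Sq`
  sigma_e_mom <- ms[2]
  sigma_g_mom <- (ms[1] - ms[2]) / r
  expect_equal(h$sigma_e2, sigma_e_mom, tolerance = 1e-6)
  expect_equal(h$sigma_g2, sigma_g_mom, tolerance = 1e-6)
})

test_that("generator heritability targets are recovered on large single-group panels", {
  for (h2 in c(0.1, 0.5, 0.9)) {
    est <- vapply(1:3, function(i) {
      p <- null_params(n_lines = 500, n_hybrids = 0, reps_line = 5,
                       h2_mf = h2, seed = 700 + 10 * i + round(100 * h2))
      s <- simulate_knob_study(p)
      estimate_heritability(s$records, "mf")$h2
    }, 0)
    expect_lt(abs(median(est) - h2), 0.03)
  }
})

test_that("flow-cytometry arithmetic and the pg-to-Mbp conversion are exact", {
  expect_equal(genome_size_from_peaks(200, 200, 5.43), 5.43)
  expect_equal(genome_size_from_peaks(206, 200, 5.43), 1.03 * 5.43)
  expect_equal(genome_size_from_peaks(1.03, 1, 5.43),
               genome_size_from_peaks(2.06, 2, 5.43))
  expect_error(genome_size_from_peaks(-1, 200, 5.43), "positive")

  expect_identical(pg_to_mbp(5.6), 5477L)
  expect_identical(pg_to_mbp(5.4), 5281L)
  expect_identical(pg_to_mbp(0), 0L)
  expect_error(pg_to_mbp(-1), "non-negative")
  # monotone and linear before rounding
  x <- seq(0, 10, by = 0.37)
  expect_true(all(diff(pg_to_mbp(x)) >= 0))
  expect_true(all(abs(pg_to_mbp(x) - x * 978) <= 0.5))
})

test_that("trait correlations follow Pearson with undefined zero-variance pairs", {
  # hand-computed: r((1,2,3,4),(1,2,3,100)) = 149 / sqrt(5 * 7205)
  r_hand <- 149 / sqrt(5 * 7205)
  cc <- trait_correlations(ff = c(1, 2, 3, 4), mf = c(1, 2, 3, 100),
                           gs = c(3, 2, 1, 0), dosage = c(0, 2, 4, 8))
  expect_equal(cc["FF", "MF"], r_hand, tolerance = 1e-12)
  expect_equal(cc["FF", "GS"], -1)
  expect_equal(cc, t(cc))

  cz <- trait_correlations(ff = c(1, 2, 3), mf = c(5, 5, 5), gs = c(1, 2, 4),
                           dosage = c(0, 1, 2))
  expect_true(all(is.na(cz["MF", ])))
  expect_false(is.na(cz["FF", "GS"]))
})

test_that("group summaries use inclusive-median quartiles", {
  rec <- make_records(c(60, 70), reps = c(5, 1))
  rec$mf_days <- c(1, 2, 3, 4, 5, 9)
  g <- c(E001 = "a", E002 = "b")
  s <- group_summaries(rec, g)
  a_mf <- s[s$group == "a" & s$trait == "MF", ]
  expect_equal(a_mf$median, 3)
  expect_equal(a_mf$q1, 2)
  expect_equal(a_mf$q3, 4)
  b_mf <- s[s$group == "b" & s$trait == "MF", ]
  expect_equal(b_mf$mean, 9)
  expect_equal(b_mf$sd, 0)

  # default simulation: hybrids flower earlier than lines on average
  st <- simulate_knob_study(generator_params(seed = 2))
  ss <- group_summaries(st$records, st$panel)
  expect_lt(ss$mean[ss$group == "hybrid" & ss$trait == "MF"],
            ss$mean[ss$group == "line" & ss$trait == "MF"])
})
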