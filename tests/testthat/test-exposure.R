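test_that("EDI and HQ match published worked values", {
  children <- group_named("children")
  adults <- group_named("adults")
  teenager <- group_named("teenager")

  expect_printed_equal(compute_edi(12, children), 0.6800)
  expect_printed_equal(compute_edi(24, children), 1.3600)
  expect_equal(compute_edi(0, children), 0)

  expect_printed_equal(compute_hq(compute_edi(12, children), 1.6), 0.4250)
  expect_printed_equal(compute_hq(compute_edi(12, adults), 1.6), 0.2404)
  expect_printed_equal(compute_hq(compute_edi(25, teenager), 1.6), 0.6250)
  expect_equal(compute_hq(1.6, 1.6), 1)
  expect_equal(compute_hq(0, 1.6), 0)
})

test_that("input validation rejects bad concentrations and parameters", {
  children <- group_named("children")
  expect_error(compute_edi(-1, children), "negative or non-finite")
  expect_error(compute_edi(NaN, children), "negative or non-finite")
  expect_error(compute_hq(0.5, 0), "positive")
  expect_error(compute_hq(0.5, -1.6), "positive")
  bad <- data.frame(id = c("1", "1"), cf = c(1, 2))
  expect_error(assess(bad), "duplicate sample ids: 1")
  neg <- data.frame(id = c("1", "2"), cf = c(1, -2))
  expect_error(assess(neg), "sample\\(s\\): 2")
  expect_error(assess(data.frame(id = "1", cf = 1),
                      data.frame(name = "g", cd = 0, bw = 10, rfd = 1.6)),
               "positive")
})

test_that("assess yields one ordered record per sample-group pair", {
  wells <- iranshahr_nitrate()
  res <- assess(wells)
  expect_equal(nrow(res), 66 * 4)
  expect_equal(res$sample_id[1:4], rep("1", 4))
  expect_equal(res$group[1:4], c("infant", "children", "teenager", "adults"))
  expect_equal(res$hq, res$edi / 1.6)

  one <- assess(data.frame(id = "x", cf = 5), group_named("infant"))
  expect_equal(nrow(one), 1)
  expect_equal(one$edi, 5 * 0.08 / 10)
})

test_that("the full published per-sample table reproduces cell-for-cell", {
  res <- assess(iranshahr_nitrate())
  ref <- iranshahr_hq_reference()
  for (g in c("infant", "children", "teenager", "adults")) {
    r <- res[res$group == g, ]
    expect_equal(round_printed(r$edi), ref[[paste0("edi_", g)]],
                 tolerance = 1e-12)
    expect_equal(round_printed(r$hq), ref[[paste0("hq_", g)]],
                 tolerance = 1e-12)
  }
})

test_that("summaries use exact min/max and sample-sd convention", {
  res <- assess(iranshahr_nitrate())
  s <- summarize_risk(res)
  children <- s[s$group == "children", ]
  expect_printed_equal(children$hq_max, 1.7354)
  expect_equal(children$cf_min, 6)
  expect_equal(children$cf_max, 49)
  # recomputed mean/sd: the published summary rows are a documented erratum
  expect_equal(children$cf_mean, mean(iranshahr_nitrate()$cf))
  expect_equal(round(children$cf_mean, 2), 15.10)
  expect_equal(children$cf_sd, stats::sd(iranshahr_nitrate()$cf))
  expect_true(all(s$hq_min <= s$hq_mean & s$hq_mean <= s$hq_max))

  single <- summarize_risk(assess(data.frame(id = "x", cf = 7),
                                  group_named("adults")))
  expect_equal(single$hq_mean, single$hq_min)
  expect_equal(single$hq_mean, single$hq_max)
  expect_equal(single$hq_sd, 0)
})

test_that("mean HQ orders children > teenager > adults > infant", {
  s <- summarize_risk(assess(iranshahr_nitrate()))
  hq <- stats::setNames(s$hq_mean, s$group)
  expect_true(hq["children"] > hq["teenager"])
  expect_true(hq["teenager"] > hq["adults"])
  expect_true(hq["adults"] > hq["infant"])
})

test_that("exceedance flags are strict and threshold-sensitive", {
  res <- assess(iranshahr_nitrate())
  fl <- exceedance_flags(res)
  flagged <- fl[fl$exceeds, ]
  expect_equal(sort(unique(flagged$group)), c("children", "teenager"))
  expect_true(all(flagged$sample_id == "35"))  # the 49 mg/L well
  expect_equal(sum(fl$exceeds[fl$group == "infant"]), 0)
  expect_equal(sum(fl$exceeds[fl$group == "adults"]), 0)

  # HQ exactly at the threshold is not an exceedance
  at <- exceedance_flags(data.frame(sample_id = "x", group = "g", hq = 1))
  expect_false(at$exceeds)
  all_pos <- exceedance_flags(res, threshold = 0)
  expect_true(all(all_pos$exceeds[res$hq > 0]))
})

test_that("exposure model is linear, monotone and composition-consistent", {
  grids <- expand.grid(cf = c(0.5, 6, 15.0969, 49), k = c(0, 0.5, 2, 10))
  children <- group_named("children")
  for (i in seq_len(nrow(grids))) {
    cf <- grids$cf[i]; k <- grids$k[i]
    expect_equal(compute_edi(k * cf, children), k * compute_edi(cf, children))
  }
  set.seed(202)
  for (i in 1:25) {
    cf <- runif(1, 1, 50); cd <- runif(1, 0.05, 3)
    bw <- runif(1, 5, 100); rfd <- runif(1, 0.5, 3)
    g <- exposure_group("g", cd, bw, rfd)
    hq <- compute_hq(compute_edi(cf, g), rfd)
    expect_equal(hq, cf * cd / (bw * rfd))
    # strict monotonicity in each argument
    eps <- 1.1
    expect_gt(compute_hq(compute_edi(cf * eps, g), rfd), hq)
    g2 <- exposure_group("g", cd * eps, bw, rfd)
    expect_gt(compute_hq(compute_edi(cf, g2), rfd), hq)
    g3 <- exposure_group("g", cd, bw * eps, rfd)
    expect_lt(compute_hq(compute_edi(cf, g3), rfd), hq)
    expect_lt(compute_hq(compute_edi(cf, g), rfd * eps), hq)
  }
})

test_that("round_printed is decimal half-up at published precision", {
  expect_equal(round_printed(0.53125), 0.5313)
  expect_equal(round_printed(0.31875), 0.3188)
  expect_equal(round_printed(0.24038), 0.2404)
  expect_equal(round_printed(-0.00005), -0.0001)
  expect_equal(round_printed(1.72, 1), 1.7)
})
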