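# Risk field with two straight channels of different risk in a risky
# background; returns the field plus entry/target voxels per channel.
two_channel_field <- function(dims = c(24, 24, 8), low = 0.05, high = 0.5) {
  sp <- c(0.8, 0.8, 0.8)
  geom <- volume_geometry(dims, sp)
  a1 <- c(0, 6, 4) * sp;  b1 <- c(20, 6, 4) * sp
  a2 <- c(0, 17, 4) * sp; b2 <- c(20, 17, 4) * sp
  ch1 <- voxelize_cylinder(a1, b1, 4, geom)
  ch2 <- voxelize_cylinder(a2, b2, 4, geom)
  risk <- array(1.0, dim = dims)
  risk[qpath:::vox_to_lin(ch1$voxels, dims)] <- low
  risk[qpath:::vox_to_lin(ch2$voxels, dims)] <- high
  list(risk = risk_volume(risk, sp),
       cases = list(
         approach_case("low channel", entry = c(0, 6, 4),
                       target = matrix(c(20, 6, 4), 1), hand_mask = ch1),
         approach_case("high channel", entry = c(0, 17, 4),
                       target = matrix(c(20, 17, 4), 1), hand_mask = ch2)))
}

test_that("a single case trivially ranks first", {
  f <- two_channel_field()
  rep1 <- compare_approaches(f$cases[1], f$risk,
                             qlearn_config(seed = 1, episodes_max = 3000))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$rank_by_q, 1L)
  expect_equal(rep1$status, "ok")
})

test_that("the low-risk corridor's approach ranks first by Q-score", {
  f <- two_channel_field()
  cfg <- qlearn_config(seed = 3, episodes_max = 30000)
  rep <- compare_approaches(f$cases, f$risk, cfg)
  expect_equal(rep$name[which(rep$rank_by_q == 1L)], "low channel")
  # the oracle confirms the cheaper corridor
  o_low <- dijkstra_oracle(f$risk, c(0, 6, 4), matrix(c(20, 6, 4), 1), cfg)
  o_high <- dijkstra_oracle(f$risk, c(0, 17, 4), matrix(c(20, 17, 4), 1), cfg)
  expect_lt(o_low$cost, o_high$cost)
  # hand totals reflect the channel risks
  expect_lt(rep$hand_total_risk[rep$name == "low channel"],
            rep$hand_total_risk[rep$name == "high channel"])
})

test_that("reports are deterministic and rows independent", {
  f <- two_channel_field()
  cfg <- qlearn_config(seed = 5, episodes_max = 3000)
  r1 <- compare_approaches(f$cases, f$risk, cfg)
  r2 <- compare_approaches(f$cases, f$risk, cfg)
  expect_identical(render_report(r1, "csv"), render_report(r2, "csv"))
  expect_identical(render_report(r1, "json"), render_report(r2, "json"))
  # adding an approach never changes the other rows' scores
  solo <- compare_approaches(f$cases[1], f$risk, cfg)
  expect_equal(r1$q_score[r1$name == "low channel"], solo$q_score[1])
  expect_equal(r1$qr_score[r1$name == "low channel"], solo$qr_score[1])
  # sorting rows by q_score reproduces rank_by_q
  expect_equal(order(r1$q_score, r1$name), order(r1$rank_by_q))
  # hand totals do not depend on the planner configuration
  other <- compare_approaches(f$cases, f$risk,
                              qlearn_config(seed = 99, alpha = 0.5,
                                            episodes_max = 1000))
  expect_equal(r1$hand_total_risk, other$hand_total_risk)
})

test_that("planner failures are reported as failed rows, not dropped", {
  a <- array(0, dim = c(8, 8, 8))
  a[4:5, , ] <- 1  # impassable slab under a barrier
  rv <- risk_volume(a, c(1, 1, 1))
  cases <- list(
    approach_case("blocked", entry = c(0, 0, 0),
                  target = matrix(c(7, 7, 7), 1)),
    approach_case("clear", entry = c(0, 0, 0),
                  target = matrix(c(2, 2, 2), 1)))
  cfg <- qlearn_config(barrier_threshold = 0.9, seed = 2,
                       episodes_max = 200)
  rep <- compare_approaches(cases, rv, cfg)
  expect_equal(nrow(rep), 2L)
  expect_match(rep$status[rep$name == "blocked"], "failed")
  expect_true(is.na(rep$q_score[rep$name == "blocked"]))
  expect_equal(rep$status[rep$name == "clear"], "ok")
  expect_equal(rep$rank_by_q[rep$name == "clear"], 1L)
})

test_that("rendered reports round-trip and carry provenance", {
  f <- two_channel_field()
  cfg <- qlearn_config(seed = 4, episodes_max = 2000)
  rep <- compare_approaches(f$cases, f$risk, cfg)
  csv <- render_report(rep, "csv")
  back <- parse_report_csv(csv)
  expect_equal(back$q_score, rep$q_score, tolerance = 1e-12)
  expect_equal(back$qr_score, rep$qr_score, tolerance = 1e-12)
  expect_equal(back$name, rep$name)
  js <- jsonlite::fromJSON(render_report(rep, "json"))
  expect_equal(js$approaches$q_score, rep$q_score, tolerance = 1e-12)
  expect_equal(js$provenance$seed, cfg$seed)
  expect_match(js$provenance$volume_md5, "^[0-9a-f]{32}$")
  md <- render_report(rep, "markdown")
  expect_equal(length(strsplit(md, "\n")[[1]]), 2L + nrow(rep))
  expect_error(render_report(rep, "xml"), "unknown report format")
})

test_that("duplicate approach names are rejected", {
  f <- two_channel_field()
  cases <- list(f$cases[[1]], f$cases[[1]])
  expect_error(compare_approaches(cases, f$risk), "unique")
})
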