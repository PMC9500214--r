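# Associations, R^2 strength labels, repeated-measures ANOVA, speed
# variability check.

test_that("classify_r2 follows the published bounds with lower-bin boundaries", {
  expect_equal(classify_r2(0.84), "very strong")
  expect_equal(classify_r2(0.12), "very weak")
  expect_equal(classify_r2(c(0.8, 0.6, 0.4, 0.2)),
               c("strong", "moderate", "weak", "very weak"))
  expect_error(classify_r2(1.2), "\\[0, 1\\]")
})

test_that("association recovers exact and null relations per clamp", {
  d <- data.frame(clamp_type = rep(c("speed", "fp"), each = 50),
                  x = rep(seq(1, 2, length.out = 50), 2))
  d$y <- 2 * d$x
  a <- association(d, "x", "y")
  expect_equal(a$r2[a$group != "average"], c(1, 1))
  expect_equal(a$slope[a$group == "average"], 2)
  expect_equal(a$n[a$group == "average"], sum(a$n[a$group != "average"]))
  expect_equal(a$r2[a$group == "average"],
               mean(a$r2[a$group != "average"]))
  set.seed(41)
  d$y <- stats::rnorm(100)
  a0 <- association(d, "x", "y")
  expect_lt(a0$r2[a0$group == "average"], 0.1)
  d$y <- 1
  expect_error(association(d, "x", "y"), "zero variance")
})

test_that("rm_anova matches the aov() Error-strata oracle", {
  tab <- make_rm_table(n_subj = 10, clamp_effect = 0.4, intensity_slope = 3,
                       noise_sd = 0.5, seed = 8)
  res <- rm_anova(tab, "y")
  ref <- summary(stats::aov(
    y ~ clamp_type * intensity + Error(factor(participant_id) /
                                         (clamp_type * intensity)),
    data = transform(tab, clamp_type = factor(clamp_type),
                     intensity = factor(intensity))))
  get_ref <- function(stratum, row) {
    s <- ref[[stratum]][[1]]
    unlist(s[row, c("Df", "F value", "Pr(>F)")])
  }
  r_clamp <- get_ref("Error: factor(participant_id):clamp_type", 1)
  r_int <- get_ref("Error: factor(participant_id):intensity", 1)
  r_ab <- get_ref("Error: factor(participant_id):clamp_type:intensity", 1)
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "clamp"], unname(r_clamp[2]), tolerance = 1e-8)
  expect_equal(eff$p[eff$effect == "clamp"], unname(r_clamp[3]), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "intensity"], unname(r_int[2]), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "clamp:intensity"], unname(r_ab[2]),
               tolerance = 1e-8)
  # eta_p^2 / F algebraic identity within each stratum
  expect_equal(eff$partial_eta_sq,
               eff$F * eff$df1 / (eff$F * eff$df1 + eff$df2))
})

test_that("rm_anova handles null and injected-effect designs", {
  # constant dv: degenerate zero-variance design
  tab0 <- make_rm_table(noise_sd = 0)
  tab0$y <- 5
  res0 <- rm_anova(tab0, "y")
  expect_equal(res0$effects$F, c(0, 0, 0))
  expect_equal(res0$effects$partial_eta_sq, c(0, 0, 0))
  expect_equal(nrow(res0$posthoc), 0)
  # pure intensity effect: only the intensity main effect fires
  tab1 <- make_rm_table(clamp_effect = 0, intensity_slope = 4, noise_sd = 0.3,
                        seed = 9)
  res1 <- rm_anova(tab1, "y")
  eff <- res1$effects
  expect_lt(eff$p[eff$effect == "intensity"], 0.001)
  expect_gt(eff$p[eff$effect == "clamp"], 0.05)
  expect_gt(eff$p[eff$effect == "clamp:intensity"], 0.05)
  expect_true(all(res1$posthoc$effect == "intensity"))
  # zero-noise injection recovered to numerical precision in the post-hocs
  tab2 <- make_rm_table(clamp_effect = 0.7, intensity_slope = 0, noise_sd = 1e-6,
                        seed = 10)
  res2 <- rm_anova(tab2, "y")
  clamp_ph <- res2$posthoc[res2$posthoc$effect == "clamp", ]
  expect_equal(nrow(clamp_ph), 5)
  expect_equal(clamp_ph$estimate, rep(0.7, 5), tolerance = 1e-4)
  expect_error(rm_anova(make_rm_table()[-3, ], "y"), "complete")
})

test_that("speed variability is unlinked to metabolic outcomes by construction", {
  s <- tiny_run()$summaries
  sv <- speed_variability_check(s)
  expect_equal(nrow(sv), 2)
  # injected coupling becomes visible through the same machinery: scale the
  # injection so its variance dominates the metabolic noise
  s2 <- s[s$clamp_type == "fp", ]
  k <- 3 * stats::sd(s2$net_power) / stats::sd(s2$speed_sd_within)
  s2$net_power <- s2$net_power + k * s2$speed_sd_within
  sv2 <- speed_variability_check(s2)
  expect_gt(sv2$r2[sv2$y == "net_power"], 0.5)
})
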