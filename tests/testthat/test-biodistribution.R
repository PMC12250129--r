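test_that("%IA/g arithmetic is correct for a same-session worksheet", {
  ws <- make_worksheet(cpm = 5000, std_cpm = 10000, f_std = 0.01,
                       mass_g = 0.1)
  res <- percent_ia_per_gram(ws)
  expect_equal(res$pia, 0.5)
  expect_equal(res$pia_g, 5.0)
})

test_that("decay referencing doubles a sample counted one half-life late", {
  lu <- lu177()
  same <- percent_ia_per_gram(make_worksheet(t_sample_h = 1, t_std_h = 1))
  late <- percent_ia_per_gram(make_worksheet(t_sample_h = 1 + lu$half_life_h,
                                             t_std_h = 1 + lu$half_life_h))
  # same counts, both one session: decay cancels exactly
  expect_equal(late$pia_g, same$pia_g)
  # sample counted one half-life after its standard: corrected twofold
  # (pairing-gap tolerance relaxed to allow the split session)
  split <- percent_ia_per_gram(
    make_worksheet(t_sample_h = 1 + lu$half_life_h, t_std_h = 1),
    max_standard_gap_h = 2 * lu$half_life_h)
  expect_equal(split$pia_g, 2 * same$pia_g)
  # a 20 h split within the default gap follows the same decay law
  part <- percent_ia_per_gram(make_worksheet(t_sample_h = 21, t_std_h = 1))
  expect_equal(part$pia_g / same$pia_g, 2^(20 / lu$half_life_h))
})

test_that("timestamp and standard-matching errors are raised", {
  expect_error(percent_ia_per_gram(make_worksheet(t_sample_h = -1)),
               "before injection")
  expect_error(percent_ia_per_gram(make_worksheet(t_sample_h = 30,
                                                  t_std_h = 1)),
               "within 24 h")
  expect_error(count_worksheet("A", fix_time0(), 37,
                               data.frame(organ = "t", mass_g = 1, cpm = 1,
                                          count_time = fix_time0()),
                               data.frame(f_std = numeric(),
                                          cpm = numeric(),
                                          count_time = fix_time0()[0])),
               "at least one standard")
})

test_that("zero-noise worksheets invert to the preset curve exactly", {
  preset <- biodist_preset_lncap()
  sheets <- simulate_worksheet(preset, sim_config(seed = 42))
  bt <- summarize_biodist(lapply(sheets, percent_ia_per_gram))
  for (org in names(preset)) {
    for (tt in c(1, 4, 24, 48)) {
      row <- bt[bt$organ == org & bt$time_h == tt, ]
      expect_equal(row$mean_pia_g, preset_pia_g(preset, org, tt),
                   tolerance = 1e-9)
    }
  }
  # published anchors fall out of the pipeline
  expect_equal(bt$mean_pia_g[bt$organ == "tumor" & bt$time_h == 4], 23.31,
               tolerance = 1e-9)
  expect_equal(bt$mean_pia_g[bt$organ == "kidney" & bt$time_h == 1], 43.83,
               tolerance = 1e-9)
})

test_that("%IA/g is invariant under uniform count rescaling", {
  ws <- make_worksheet()
  ws2 <- ws
  ws2$records$cpm <- ws2$records$cpm * 7.3
  ws2$standards$cpm <- ws2$standards$cpm * 7.3
  expect_equal(percent_ia_per_gram(ws2)$pia_g,
               percent_ia_per_gram(ws)$pia_g)
})

test_that("whole-body activity accounting never exceeds the injection", {
  sheets <- simulate_worksheet(biodist_preset_lncap(), sim_config(seed = 42))
  for (ws in sheets) {
    res <- percent_ia_per_gram(ws)
    recovered <- sum(res$pia_g * ws$records$mass_g) / 100
    expect_lte(recovered, 1 + 1e-9)   # excreta carry the remainder
  }
})

test_that("summaries report mean, sample SD and group size", {
  t0 <- fix_time0()
  per <- data.frame(animal_id = c("a", "b", "c"), organ = "tumor",
                    time_h = 4, pia = NA, pia_g = c(22, 23, 24))
  s <- summarize_biodist(per)
  expect_equal(s$mean_pia_g, 23)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  single <- summarize_biodist(per[1, ])
  expect_true(is.na(single$sd))
  same <- summarize_biodist(transform(per, pia_g = 5))
  expect_equal(same$sd, 0)
})

test_that("tumor-to-normal ratios reproduce the published pharmacokinetics", {
  sheets <- simulate_worksheet(biodist_preset_lncap(), sim_config(seed = 42))
  bt <- summarize_biodist(lapply(sheets, percent_ia_per_gram))
  r <- tn_ratios(bt, "tumor")
  get <- function(org, tt) r$ratio[r$organ == org & r$time_h == tt]
  expect_equal(round(get("blood", 24), 1), 434.4)
  expect_equal(round(get("muscle", 24), 1), 857.4)
  expect_equal(round(get("blood", 1), 1), 69.5)
  expect_equal(round(get("muscle", 1), 1), 60.2)
  expect_equal(round(get("kidney", 1), 1), 0.3)
  expect_equal(round(get("kidney", 48), 1), 26.3)
})

test_that("ratio cells with zero organ mean are marked absent", {
  bt <- summarize_biodist(data.frame(
    animal_id = "a", organ = c("tumor", "blood"), time_h = 4, pia = NA,
    pia_g = c(10, 0)))
  expect_warning(r <- tn_ratios(bt), "absent")
  expect_true(is.na(r$ratio))
  # organ equal to tumor gives ratio one
  bt2 <- summarize_biodist(data.frame(
    animal_id = "a", organ = c("tumor", "liver"), time_h = 4, pia = NA,
    pia_g = c(10, 10)))
  expect_equal(tn_ratios(bt2)$ratio, 1.0)
})

test_that("worksheet CSV serialisation round-trips", {
  ws <- simulate_worksheet(biodist_preset_lncap(), sim_config(seed = 42))[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_worksheet_csv(ws, path)
  back <- read_worksheet_csv(path)
  expect_equal(back$animal_id, ws$animal_id)
  expect_equal(back$injected_activity_MBq, ws$injected_activity_MBq)
  expect_equal(back$records$cpm, ws$records$cpm, tolerance = 1e-12)
  expect_equal(percent_ia_per_gram(back)$pia_g,
               percent_ia_per_gram(ws)$pia_g, tolerance = 1e-12)
})
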