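admet <- read_admet(ip_extdata("admet.csv"))
topkat <- read_topkat(ip_extdata("topkat.csv"))

test_that("level decoding maps codes to labels and rejects bad codes", {
  lab <- decode_levels(data.frame(compound_id = "4f", bbb_level = 4,
                                  absorption_level = 0, hepatotoxicity = 0,
                                  cyp2d6 = 0, ppb = "true"))
  expect_equal(lab$bbb, "undefined")
  expect_equal(lab$absorption, "good")
  expect_equal(lab$hepatotoxicity, "nontoxic")
  expect_equal(lab$cyp2d6, "noninhibitor")
  expect_equal(lab$ppb, "binding")
  expect_equal(decode_levels(data.frame(bbb_level = 0))$bbb, "very high")
  expect_error(decode_levels(data.frame(bbb_level = 7)), "out-of-range")
  expect_error(decode_levels(data.frame(absorption_level = 4)),
               "out-of-range")
  expect_error(decode_levels(data.frame(ppb = "maybe")), "PPB")
})

test_that("solubility banding is half-open and never clamps", {
  expect_equal(solubility_band(-5.186), "low")
  expect_equal(solubility_band(-1.462), "optimal")
  expect_equal(solubility_band(-6.455), "out_of_band")
  # boundaries are low-inclusive
  expect_equal(solubility_band(c(-6, -4, -2, 0, 0.1, -6.0001)),
               c("low", "good", "optimal", "optimal", "out_of_band",
                 "out_of_band"))
  # every value in the domain maps to exactly one band
  grid <- seq(-6, 0, by = 0.01)
  expect_true(all(solubility_band(grid) %in% c("low", "good", "optimal")))
})

test_that("the AlogP98 flag is strict at 5", {
  expect_true(alogp98_flag(5.166))
  expect_false(alogp98_flag(3.932))
  expect_false(alogp98_flag(5.0))
})

test_that("toxicity probabilities band into three half-open intervals", {
  expect_equal(topkat_band(0.992), "toxic")
  expect_equal(topkat_band(0.000), "nontoxic")
  expect_equal(topkat_band(0.5), "intermediate")
  expect_equal(topkat_band(c(0.2999, 0.30, 0.6999, 0.70, 1)),
               c("nontoxic", "intermediate", "intermediate", "toxic",
                 "toxic"))
  expect_error(topkat_band(1.01), "outside")
  expect_error(topkat_band(-0.1), "outside")
})

test_that("TOPKAT cells parse from 'label (p)' strings and bare numbers", {
  expect_equal(topkat$skin_irritation[topkat$compound_id == "4m"], 0.992)
  expect_equal(topkat$band_skin_irritation[topkat$compound_id == "4m"],
               "toxic")
  expect_equal(topkat$aerobic_biodegradability[topkat$compound_id == "4h"],
               1.000)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,ames", "x,0.25", "y,mutagen (0.81)"), tmp)
  tk <- read_topkat(tmp)
  expect_equal(tk$ames, c(0.25, 0.81))
  expect_equal(tk$band_ames, c("nontoxic", "toxic"))
})

test_that("the drug-likeness report reproduces the published counts", {
  dl <- druglikeness_report(admet, topkat, ids = library_ids)
  expect_equal(unname(dl$summary$n_per_bbb_level[["level_4"]]), 4L)
  expect_equal(dl$summary$cyp2d6_inhibitors, c("4b", "4h", "4m"))
  expect_equal(dl$summary$n_alogp98_flagged, 2L)  # 4i and 4m exceed 5
  # counts equal direct column scans (oracle: recount)
  sub <- admet[admet$compound_id %in% library_ids, ]
  expect_equal(unname(dl$summary$n_per_bbb_level),
               unname(as.integer(table(factor(sub$bbb_level, 0:4)))))
  expect_equal(dl$summary$n_alogp98_flagged, sum(sub$alogp98 > 5))
  # the two flagged-toxic library members carry a toxic endpoint each
  expect_equal(dl$summary$n_any_toxic, 2L)
  expect_true(all(c("4h", "4m") %in%
                    dl$per_compound$compound_id[dl$per_compound$any_toxic]))
})

test_that("id misalignment is reported with the orphan ids", {
  expect_error(druglikeness_report(admet, topkat, ids = c("4a", "nope")),
               "nope")
  expect_error(druglikeness_report(admet[0, ], topkat), "empty")
  tk_short <- topkat[topkat$compound_id != "4a", ]
  attr(tk_short, "endpoints") <- attr(topkat, "endpoints")
  expect_error(druglikeness_report(admet, tk_short, ids = library_ids),
               "4a")
})
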