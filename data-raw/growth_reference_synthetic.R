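# Builds inst/extdata/growth_reference_synthetic.csv
#
# A synthetic LMS growth-reference table with the same schema as the WHO
# Child Growth Standards weight-for-age / weight-for-height tables
# (indicator, sex, index, L, M, S).  Median curves pass through plausible
# anchor medians and are smoothed with monotone Hermite splines; L and S
# follow smooth age trends of realistic magnitude.  The table exists so the
# package is self-contained and testable; real WHO tables with identical
# columns are drop-in replacements.

anchor_wfa <- data.frame(
  age = c(6, 12, 24, 36, 48, 60, 84, 120, 150, 180),
  M_male   = c(7.9, 9.6, 12.2, 14.3, 16.3, 18.2, 22.9, 31.9, 41.5, 50.8),
  M_female = c(7.3, 8.9, 11.5, 13.9, 16.1, 18.2, 23.4, 32.8, 43.0, 51.5)
)
anchor_L <- data.frame(
  age = c(6, 24, 60, 120, 180),
  L   = c(-0.10, -0.20, -0.35, -0.90, -1.30)
)
anchor_S <- data.frame(
  age = c(6, 24, 60, 120, 180),
  S   = c(0.110, 0.115, 0.125, 0.140, 0.150)
)

ages <- 6:180
wfa <- do.call(rbind, lapply(c("male", "female"), function(sx) {
  mcol <- if (sx == "male") anchor_wfa$M_male else anchor_wfa$M_female
  data.frame(
    indicator = "weight_for_age", sex = sx, index = ages,
    L = round(splinefun(anchor_L$age, anchor_L$L, method = "monoH.FC")(ages), 4),
    M = round(splinefun(anchor_wfa$age, mcol, method = "monoH.FC")(ages), 4),
    S = round(splinefun(anchor_S$age, anchor_S$S, method = "monoH.FC")(ages), 4)
  )
}))

anchor_wfh <- data.frame(
  ht = c(65, 75, 85, 95, 105, 115, 120),
  M_male   = c(7.4, 9.5, 11.7, 14.0, 16.8, 20.0, 22.0),
  M_female = c(7.2, 9.2, 11.4, 13.8, 16.6, 19.9, 22.0)
)
hts <- seq(65, 120, by = 1)
wfh <- do.call(rbind, lapply(c("male", "female"), function(sx) {
  mcol <- if (sx == "male") anchor_wfh$M_male else anchor_wfh$M_female
  data.frame(
    indicator = "weight_for_height", sex = sx, index = hts,
    L = -0.35,
    M = round(splinefun(anchor_wfh$ht, mcol, method = "monoH.FC")(hts), 4),
    S = 0.082
  )
}))

out <- rbind(wfa, wfh)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(out, "inst/extdata/growth_reference_synthetic.csv", row.names = FALSE)
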