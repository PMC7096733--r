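# Shared configuration for the analysis drivers.
#
# The cohort keeps the study's sample size (31 subjects, three stimulation
# conditions, pre/post resting runs) on a reduced 18 x 18 x 14 grid at 3 mm
# with 160 raw volumes, so the whole chain runs in minutes on one CPU. The
# methods vignette discusses these problem-size choices.

library(rehodc)

analysis_cfg <- sim_config(grid_shape = c(18, 18, 14), n_subjects = 31,
                           n_timepoints = 160, effect_center = c(12, 8, 6),
                           seed = 20260919)

paths <- list(
  scratch = "scratch",
  results = "results",
  panels = file.path("scratch", "panels.rds"),
  truth = file.path("scratch", "truth.rds")
)
for (p in paths[c("scratch", "results")])
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
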