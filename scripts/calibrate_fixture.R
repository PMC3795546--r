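#!/usr/bin/env Rscript
# Calibration of the canonical LUV fixture contrasts.
#
# The wall geometry (thicknesses 6/9/24/9/12 A, mean outer radius 400 A,
# sigma 30%, r_min 100 A) is fixed a priori; the published constraint set
# for an empty ganglioside/cholesterol/egg-PC LUV consists of observables,
# not parameter values, so the contrasts are chosen to reproduce those
# observables:
#
#   - Guinier Rg of the empty model in [500, 650] A (measured: 587 A)
#   - p(r) global maximum ~700 A empty, ~500 A at core contrast 2.6
#   - sub-bilayer p(r) ripple extending to ~55 A (bracket [45, 65])
#   - Rg decrement ~0.138 at core contrast ~0.099 (the value implied by an
#     encapsulated concentration of 5.5% w/v under the default constants)
#
# Holding the sign pattern (+, +high, -, +high, +low) and the head/
# hydration values at chemically sensible magnitudes, the oligosaccharide
# (sugar) layer contrast is the effective knob: it sets the net wall excess
# (small and positive), which controls both the empty-vesicle Rg and the
# sensitivity of Rg to pool filling. This script scans it and prints the
# scorecard; the chosen value is frozen in R/synthetic_data.R.
#
# Run from the repository root:  Rscript scripts/calibrate_fixture.R

suppressMessages(library(luvsaxs))

thicknesses <- c(6, 9, 24, 9, 12)
base <- c(hydration = 0.80, inner_head = 2.30, core = -2.28,
          outer_head = 2.30, sugar = NA)
dist <- size_distribution(400, sigma_percent = 30, r_min = 100)
q <- default_q_grid()
target_contrast_5p5 <- {
  pc <- physical_constants()
  core_contrast_from_volume_fraction(
    concentration_to_volume_fraction(5.5, pc), pc)
}

score <- function(sugar) {
  co <- base; co["sugar"] <- sugar
  mk <- function(core) vesicle_profile(400 - sum(thicknesses), thicknesses,
                                       co, core_contrast = core)
  cv0 <- model_curve(mk(0), dist, q = q)
  cv26 <- model_curve(mk(2.6), dist, q = q)
  cvp <- model_curve(mk(target_contrast_5p5), dist, q = q)
  rg0 <- guinier_fit(cv0)$rg
  dd0 <- distance_distribution(cv0)
  c(sugar = sugar,
    rg_empty = rg0,
    decrement_at_5p5 = (rg0 - guinier_fit(cvp)$rg) / rg0,
    peak_empty = attr(dd0, "peak_position"),
    peak_filled = attr(distance_distribution(cv26), "peak_position"),
    ripple = attr(dd0, "ripple_extent"))
}

cat(sprintf("target contrast for 5.5%% w/v: %.4f (decrement target ~0.138)\n\n",
            target_contrast_5p5))
grid <- seq(1.05, 1.65, by = 0.10)
tab <- t(vapply(grid, score, numeric(6)))
print(round(tab, 3))

ok <- tab[, "rg_empty"] >= 500 & tab[, "rg_empty"] <= 650 &
  tab[, "peak_empty"] >= 630 & tab[, "peak_empty"] <= 770 &
  tab[, "peak_filled"] >= 450 & tab[, "peak_filled"] <= 550 &
  tab[, "ripple"] >= 45 & tab[, "ripple"] <= 65
cand <- tab[ok, , drop = FALSE]
if (nrow(cand) == 0L) stop("no candidate satisfies all brackets")
pick <- cand[which.min(abs(cand[, "decrement_at_5p5"] - 0.138)), ]
cat(sprintf("\nchosen sugar contrast: %.2f (frozen as 1.35 in the package)\n",
            pick["sugar"]))
print(round(pick, 3))
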