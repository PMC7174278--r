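#!/usr/bin/env Rscript
## Step 5: the mass-transfer-resistance analysis. The NIR-predicted
## moisture trajectory of the reference batch is differentiated to the
## molar drying rate, combined with the bed temperature, the aggregate
## sorption isotherm and the vapour-pressure correlation into the rate
## fraction f_MTR, inverted to the total resistance Omega_tot(F_w), and
## fitted with the two-term (external + exponential internal) resistance
## model. The fitted parameters are compared with the generating truth.

library(granudry)

pred_path <- "results/predicted_moisture.csv"
if (!file.exists(pred_path)) stop("run analysis/03_pls_moisture.R first")
pred <- read.csv(pred_path)
run <- read_drying_run("results/batch600/run.csv")

moist <- with(subset(pred, !warmup), data.frame(time = time, f_w = f_w_pred))
out <- analyze_run(run, moisture = moist, half_window = 36, inlet = "auto")

write.csv(out$trace, "results/mtr_trace.csv", row.names = FALSE)
save_model(out$fit, "results/resistance_fit.json")

se <- attr(out$fit, "std_errors")
truth <- run$truth
cat("Mass-transfer analysis of the reference batch (NIR-predicted moisture):\n")
cat(sprintf("  inlet concentration: %.3f mol/m^3 (%s)\n", out$c_g_in, out$inlet_method))
cat(sprintf("  %d usable time points in the resistance fit\n",
            sum(!out$trace$clipped & !out$trace$edge, na.rm = TRUE)))
cat(sprintf("  Omega_ext  = %.4f s   (truth %.3f, dev %+.0f%%)\n",
            out$fit$omega_ext, truth$omega_ext,
            100 * (out$fit$omega_ext / truth$omega_ext - 1)))
cat(sprintf("  Omega_max  = %.3f s    (truth %.2f at F_w,end = %.2f)\n",
            out$fit$omega_max, truth$omega_max, truth$f_w_end))
cat(sprintf("  F_w,crit   = %.4f     (truth %.2f, dev %+.0f%%)\n",
            out$fit$f_w_crit, truth$f_w_crit,
            100 * (out$fit$f_w_crit / truth$f_w_crit - 1)))
if (!is.null(se)) {
  cat(sprintf("  fit standard errors (log-space): %s\n",
              paste(sprintf("%s %.3g", names(se), se), collapse = ", ")))
}
cat("trace -> results/mtr_trace.csv; fit -> results/resistance_fit.json\n")
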