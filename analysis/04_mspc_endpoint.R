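#!/usr/bin/env Rscript
## Step 4: build the PCA-based process-control model from the end-point
## spectra (true moisture < 2%) of seven normal-operating-condition
## batches, then run the Q-statistic chart on the reference batch and
## detect its drying end-point (10 consecutive observations below the 95%
## Jackson-Mudholkar limit). A truncated copy of the batch checks that an
## off-specification run is never flagged.

library(granudry)

abs_path <- "results/batch600/absorbance.csv"
if (!file.exists(abs_path)) stop("run analysis/02_preprocess.R first")
val_abs <- read_spectra(abs_path)
val_run <- read_drying_run("results/batch600/run.csv")

iso <- aggregate_isotherm(placebo_formulation())$params
noc <- lapply(2:8, function(s) {
  b <- synthetic_batch(seed = s, isotherm = iso, duration = 7200, vary = TRUE)
  sn <- snv(preprocess_spectra(b$spectra))
  fw <- approx(b$run$time, b$run$f_w, sn$timestamps, rule = 2)$y
  sn$values[fw < 0.02 & !sn$meta$warmup, , drop = FALSE]
})
mspc <- build_mspc(do.call(rbind, noc), n_pc = "auto")
save_model(mspc, "results/mspc_model.json")

chart <- q_chart(mspc, snv(val_abs), run_length = 10)
write.csv(chart, "results/q_chart.csv", row.names = FALSE)

cat(sprintf("MSPC model: %d principal components from %d end-point spectra (7 NOC batches).\n",
            mspc$n_pc, sum(sapply(noc, nrow))))
cat(sprintf("  Q limits: 95%% = %.3g, 99%% = %.3g\n",
            mspc$limits[["q95"]], mspc$limits[["q99"]]))
ep <- attr(chart, "endpoint_time")
if (is.na(ep)) {
  cat("  reference batch: no end-point detected (off-specification)\n")
} else {
  fw_ep <- approx(val_run$time, val_run$f_w, ep, rule = 2)$y
  cat(sprintf("  reference batch end-point: %.1f min (true moisture there %.2f%%)\n",
              ep / 60, 100 * fw_ep))
}
keep <- val_abs$timestamps <= 3300
off <- spectra_series(val_abs$wavelengths, val_abs$timestamps[keep],
                      val_abs$values[keep, , drop = FALSE], "absorbance")
ep_off <- attr(q_chart(mspc, snv(off)), "endpoint_index")
cat(sprintf("  batch truncated at 55 min: %s\n",
            if (is.na(ep_off)) "not flagged (correctly off-specification)" else
              sprintf("flagged at index %d (unexpected)", ep_off)))
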