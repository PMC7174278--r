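#!/usr/bin/env Rscript
## Step 3: calibrate the PLS moisture model on three further synthetic
## batches (varying initial moisture and ambient humidity, as real batches
## do) against their sparse LOD samples, then predict the reference
## batch's moisture trajectory from its NIR spectra alone and score it
## against the noise-free truth.

library(granudry)

abs_path <- "results/batch600/absorbance.csv"
if (!file.exists(abs_path)) stop("run analysis/02_preprocess.R first")
val_abs <- read_spectra(abs_path)
val_run <- read_drying_run("results/batch600/run.csv")

iso <- aggregate_isotherm(placebo_formulation())$params
cal <- lapply(71:73, function(s) {
  synthetic_batch(seed = s, isotherm = iso, duration = 7200, vary = TRUE)
})
cal_abs <- lapply(cal, function(b) preprocess_spectra(b$spectra))

pls <- train_moisture_model(cal_abs, lapply(cal, `[[`, "lod"),
                            max_lv = 6, folds = 5)
save_model(pls, "results/pls_model.json")

pred <- predict_moisture(pls, val_abs)
warmup <- val_abs$meta$warmup
truth <- approx(val_run$time, val_run$f_w, val_abs$timestamps, rule = 2)$y
e_rel <- relative_error(pred[!warmup], truth[!warmup])

write.csv(data.frame(time = val_abs$timestamps, f_w_pred = pred,
                     f_w_true = truth, warmup = warmup),
          "results/predicted_moisture.csv", row.names = FALSE)

cat(sprintf("PLS calibration: %d LOD/spectrum pairs from %d batches, %d latent variables.\n",
            length(pls$residuals), length(cal), pls$n_lv))
cat(sprintf("Validation batch relative prediction error (warm-up excluded): %.1f%%\n",
            e_rel))
cat("model -> results/pls_model.json; trajectory -> results/predicted_moisture.csv\n")
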