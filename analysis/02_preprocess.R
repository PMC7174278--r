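#!/usr/bin/env Rscript
## Step 2: turn the raw intensity scans of the reference batch into the
## smoothed absorbance matrix the chemometric models consume
## (10-scan block average -> absorbance -> 75-spectrum causal moving
## average), and store it next to the raw data.

library(granudry)

raw_path <- "results/batch600/raw_spectra.csv"
if (!file.exists(raw_path)) stop("run analysis/01_simulate_batch.R first")

raw <- read_spectra(raw_path, validate_grid = 401)
abs_series <- preprocess_spectra(raw, block = 10, window = 75)
write_spectra(abs_series, "results/batch600/absorbance.csv")

n <- length(abs_series$timestamps)
cat(sprintf("Preprocessed %d scans into %d absorbance spectra (1 per ~10 s).\n",
            length(raw$timestamps), n))
cat(sprintf("  %d spectra are filter warm-up and flagged as such\n",
            sum(abs_series$meta$warmup)))
cat(sprintf("  clipped non-physical transmittance points: %s\n",
            if (is.null(abs_series$meta$clipped_points)) "0" else
              abs_series$meta$clipped_points))
band <- abs_series$values[, which.min(abs(abs_series$wavelengths - 1940))]
cat(sprintf("  water-band absorbance (1940 nm) falls from %.3f to %.3f AU\n",
            band[75], band[n]))
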