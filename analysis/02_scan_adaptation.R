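#!/usr/bin/env Rscript
# Calibrate the two brain-state defaults by scanning the spike-triggered
# adaptation increment b. The interictal default is the largest grid b still
# classified asynchronous-irregular; the ictal default is the smallest grid
# b whose oscillation peak falls inside the 7-12 Hz SWD band of the GAERS.

library(gaersim)

dir.create("results", showWarnings = FALSE)
b_grid <- c(0, 100, 200, 300, 400)

message("Scanning b over {", paste(b_grid, collapse = ", "), "} pA/Hz ...")
scan <- scan_adaptation(b_grid, duration_s = 11, seed = 1)
print(scan)
write.table(scan, "results/adaptation_scan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

b_interictal <- max(scan$b_pA[scan$regime == "AI"])
in_band <- scan$regime == "SWD" & scan$peak_hz >= 7 & scan$peak_hz <= 12
b_ictal <- min(scan$b_pA[in_band])
message(sprintf("largest AI b: %g (shipped interictal default %g)",
                b_interictal, default_params("interictal")$b))
message(sprintf("smallest in-band SWD b: %g (shipped ictal default %g)",
                b_ictal, default_params("ictal")$b))

stopifnot(b_interictal == default_params("interictal")$b,
          b_ictal == default_params("ictal")$b)
message("Shipped defaults match the calibration scan.")
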