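#!/usr/bin/env Rscript
# Stage 3: pharmacology summaries.
#
# 4PL fits of the stage-1 concentration-response datasets (Emax as % of
# the reference agonist maximum, EC50/pEC50, free Hill slope, baseline
# fixed at 0), the log-logistic ED50 fit of the %MPE data with a
# delta-method 95% CI, and the brain:plasma exposure ratio from the
# measured concentrations (5.3 uM plasma, 2.8 uM brain).

suppressPackageStartupMessages(library(aquabridge))

src <- "results/synthetic"
out <- "results/pharmacology"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("== 4PL concentration-response fits ==")
fits <- list()
for (nm in c("ligand_gi1", "ligand_gz", "damgo_gi1")) {
  d <- read.csv(file.path(src, paste0(nm, ".csv")))
  f <- fit_4pl(d)
  fits[[nm]] <- f
  message(sprintf("  %-10s Emax %5.1f%%  pEC50 %.2f +/- %.2f  EC50 %6.1f nM  hill %.2f  [%s]",
                  nm, f$emax, f$pec50, f$se[["pec50"]], f$ec50_nM, f$hill,
                  f$status))
}
fit_tab <- do.call(rbind, lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  data.frame(dataset = nm, emax = f$emax, pec50 = f$pec50,
             pec50_se = f$se[["pec50"]], ec50_nM = f$ec50_nM,
             hill = f$hill, status = f$status)
}))
write.csv(fit_tab, file.path(out, "fits_4pl.csv"), row.names = FALSE)

message("== ED50 from %MPE dose-response ==")
m <- read.csv(file.path(src, "mpe_doses.csv"))
fe <- fit_ed50(m)
message(sprintf("  ED50 %.2f mg/kg (95%% CI %.2f-%.2f, %s), slope %.2f",
                fe$ed50, fe$ci[1], fe$ci[2], fe$ci_method, fe$slope))
write.csv(data.frame(ed50 = fe$ed50, ci_lo = fe$ci[1], ci_hi = fe$ci[2],
                     slope = fe$slope, ci_method = fe$ci_method),
          file.path(out, "ed50.csv"), row.names = FALSE)

message("== brain:plasma ratio ==")
r <- brain_plasma_ratio(brain = 2.8, plasma = 5.3)
message(sprintf("  ratio %.3f, reported %.1f", r$ratio, r$ratio_1dp))
write.csv(data.frame(brain_uM = 2.8, plasma_uM = 5.3,
                     ratio = r$ratio, ratio_1dp = r$ratio_1dp),
          file.path(out, "brain_plasma.csv"), row.names = FALSE)

message("done: tables under ", out)
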