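#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input for the downstream analyses,
# with known ground truth, under fixed seeds.
#
#   - structural frames for two ligand conditions (hydrogen-bond donor vs
#     acceptor warhead), 5 replicate trajectories x 200 frames each,
#     written as multi-model PDB + truth-label sidecar CSVs
#   - BRET-style concentration-response data at the published generating
#     parameters for the test ligand (Gi1, Gz) and the reference agonist
#   - an APEX time-course intensity table (500 proteins, 3 planted
#     changing proteins, internalizing mixing series)
#   - warm-water tail-withdrawal %MPE data at the published ED50

suppressPackageStartupMessages(library(aquabridge))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20260923)   # only used to draw per-replicate label sequences

message("== frames: donor-warhead condition (frequent one-water bridge) ==")
# per-frame class probabilities per condition; replicate-to-replicate
# variation comes from the multinomial draw
p_donor <- c(direct = 0.05, water1 = 0.55, water2 = 0.20, none = 0.20)
p_accep <- c(direct = 0.02, water1 = 0.25, water2 = 0.13, none = 0.60)
n_frames <- 200L

gen_condition <- function(name, probs, seed0) {
  for (r in 1:5) {
    labs <- sample(names(probs), n_frames, replace = TRUE, prob = probs)
    g <- gen_bridge_frames(frame_spec(labs, jitter_sd = 0.04,
                                      seed = seed0 + r,
                                      replicate_id = paste0("rep", r)))
    write_frames_pdb(g$frames, file.path(out, sprintf("%s_rep%d.pdb", name, r)))
    write.csv(g$truth, file.path(out, sprintf("%s_rep%d_truth.csv", name, r)),
              row.names = FALSE)
  }
  message("  ", name, ": 5 replicates x ", n_frames, " frames")
}
gen_condition("donor", p_donor, 100L)
gen_condition("acceptor", p_accep, 200L)

message("== concentration-response datasets ==")
curves <- list(
  ligand_gi1 = curve_truth(6.34, 65, noise_sd = 5, seed = 301L),
  ligand_gz  = curve_truth(7.09, 65, noise_sd = 5, seed = 302L),
  damgo_gi1  = curve_truth(7.50, 99, noise_sd = 5, seed = 303L)
)
for (nm in names(curves)) {
  d <- gen_dose_response(curves[[nm]])
  write.csv(d, file.path(out, paste0(nm, ".csv")), row.names = FALSE)
}
message("  ", paste(names(curves), collapse = ", "))

message("== APEX time course ==")
tr <- apex_truth(seed = 401L)
g <- gen_apex_timecourse(tr)
write.csv(g$data, file.path(out, "apex_timecourse.csv"), row.names = FALSE)
ind <- data.frame(location = rep(names(tr$indicator_map),
                                 lengths(tr$indicator_map)),
                  protein_id = unlist(tr$indicator_map))
write.csv(ind, file.path(out, "apex_indicators.csv"), row.names = FALSE)
write.csv(data.frame(protein_id = tr$changing_ids),
          file.path(out, "apex_truth_changing.csv"), row.names = FALSE)
message("  500 proteins, planted changers: ",
        paste(tr$changing_ids, collapse = ", "))

message("== %MPE antinociception ==")
m <- gen_mpe_doses(mpe_truth(10.18, slope = 2, doses = c(3, 10, 30),
                             n_subjects = 8L, noise_sd = 10, seed = 501L))
write.csv(m, file.path(out, "mpe_doses.csv"), row.names = FALSE)
message("  doses 3/10/30 mg/kg, 8 subjects per dose")

message("done: inputs under ", out)
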