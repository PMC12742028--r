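#!/usr/bin/env Rscript
# Step 1 - simulate a cohort of self-boundary meditation sessions.
#
# Emulates the study protocol: per session two blocks, each 100 s of
# rest followed by five 60 s alternations between self-boundary
# dissolution (SBminus) and maintenance (SBplus), plus a final 100 s
# rest, at 300 Hz over the 62 merged atlas regions - 300 s per state.
# Effects follow the "small_to_medium" preset: beta (~27 Hz) power
# reduced and broadband complexity raised in SBminus, with region-level
# between-participant variability.
#
# Writes per-participant segment manifests and the cohort description;
# the raw signals are regenerated deterministically downstream from the
# same seed, so they are not stored.

library(megstates)

seed <- 20260919
n_participants <- 6
dir.create("results", showWarnings = FALSE)

protocol <- default_protocol()
cat("Session protocol: ", nrow(protocol), "segments;",
    "per-state seconds:\n")
print(protocol_state_totals(protocol))

effects <- effect_preset("small_to_medium")
pars <- megstates:::cohort_params(n_participants, effects,
                                  between_participant_sd = 0.3, seed = seed)
demo <- generate_session(protocol, pars$effects[[1]], seed = pars$seeds[1],
                         participant_id = pars$ids[1])
print(demo)

man <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
  ts <- generate_session(protocol, pars$effects[[p]], seed = pars$seeds[p],
                         participant_id = pars$ids[p])
  session_manifest(ts)
}))
write.table(man, "results/cohort_manifest.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/cohort_manifest.tsv:", nrow(man), "segments across",
    n_participants, "participants\n")
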