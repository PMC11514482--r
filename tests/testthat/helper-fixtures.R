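# Shared in-code fixtures: small synthetic reference sets and hand-built
# molecules with known structure.

tiny_refset <- function(n_arms = 3, seed = 7, ...) {
  synthesize_reference(n_arms = n_arms, seed = seed, ...)
}

# Noise-free measurement: every observation channel switched off.
noiseless_config <- function(...) {
  sim_config(sizing_error_cv = 0, p_missing_label = 0,
             false_labels_per_100kb = 0, resolution_kb = 0,
             intensity_cv = 0, flip_prob = 0, ...)
}

# Distal labels of an arm inside a window of length L (kb), molecule-local.
distal_window <- function(arm, L) {
  term <- arm$terminus_pos / 1000
  lab <- arm$label_positions / 1000
  lab[lab > term - L] - (term - L)
}

# Hand-built molecules with exact structure (no noise).
make_end_tel_mol <- function(arm, L = 200, telo = 11, id = "m1",
                             intensity = telo * 100) {
  g <- distal_window(arm, L)
  structure(list(molecule_id = id, length_kb = L + telo, green_labels = g,
                 red_segments = data.frame(start_kb = L, end_kb = L + telo,
                                           intensity = intensity),
                 cohort = "test"),
            class = "smta_molecule")
}

make_tfe_mol <- function(arm, L = 200, id = "m1") {
  g <- distal_window(arm, L)
  structure(list(molecule_id = id, length_kb = L, green_labels = g,
                 red_segments = data.frame(start_kb = numeric(0),
                                           end_kb = numeric(0),
                                           intensity = numeric(0)),
                 cohort = "test"),
            class = "smta_molecule")
}

# Fusion with ITS: arm fragment, red tract, then a short labelled tail.
make_its_plus_mol <- function(arm, L = 200, telo = 11, tail_labels = 4,
                              tail_len = 40, id = "m1") {
  g <- distal_window(arm, L)
  tail <- L + telo + seq(5, tail_len - 5, length.out = tail_labels)
  structure(list(molecule_id = id, length_kb = L + telo + tail_len,
                 green_labels = c(g, tail),
                 red_segments = data.frame(start_kb = L, end_kb = L + telo,
                                           intensity = telo * 100),
                 cohort = "test"),
            class = "smta_molecule")
}

# Fusion without ITS: arm fragment joined directly to a short labelled tail.
make_its_minus_mol <- function(arm, L = 200, tail_labels = 4, tail_len = 40,
                               id = "m1") {
  g <- distal_window(arm, L)
  tail <- L + seq(5, tail_len - 5, length.out = tail_labels)
  structure(list(molecule_id = id, length_kb = L + tail_len,
                 green_labels = c(g, tail),
                 red_segments = data.frame(start_kb = numeric(0),
                                           end_kb = numeric(0),
                                           intensity = numeric(0)),
                 cohort = "test"),
            class = "smta_molecule")
}
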