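# Shared fixtures: packaged models are loaded once per test session and a
# coarse grid keeps property tests fast without touching their conclusions.

mouse_model <- load_species_model("mouse")
dog_model <- load_species_model("dog")
human_model <- load_species_model("human")

coarse_grid <- function(t_end = 120) {
  sort(unique(c(seq(0, 2, by = 0.05), seq(2, t_end, by = 0.5), t_end)))
}

mouse_bolus <- dose_regimen(10, "bolus")
dog_infusion <- dose_regimen(12, "infusion", infusion_duration = 0.5)
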