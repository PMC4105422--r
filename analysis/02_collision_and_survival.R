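#!/usr/bin/env Rscript
# Collision-complex formation in the canonical warm dense cloud, the
# internal-energy-redistribution sticking argument, and the competition
# between dimerization and UV photodestruction.

library(cloudamide)
dir.create("results", showWarnings = FALSE)

env <- read_environment(system.file("extdata", "cloud_dc.yaml",
                                    package = "cloudamide"))
params <- kinetic_parameters()
n <- species_density(env)
t_coll <- collision_timescale(n, params)
message(sprintf(
  "amino acid density %.1f cm^-3 -> complex formation every %.3g yr", n, t_coll))

gly <- species_info("Gly", 10, 75.07, "amino_acid")
ala <- species_info("Ala", 13, 89.09, "amino_acid")
stick <- sticking_assessment(gly, ala, env)
message(sprintf(
  "Gly+Ala: %d internal modes, temperature factor %.3f (-> %.1f K), two-body sticking: %s",
  stick$modes, stick$factor, stick$effective_internal_temperature_K,
  stick$two_body_sticking))

kc <- collision_rate(n, params)
rows <- do.call(rbind, lapply(c("DC", "DISM"), function(cls) {
  kp <- photolysis_rate(uv_environment(cls))
  data.frame(uv_class = cls,
             half_life_yr = uv_environment(cls)$monomer_half_life_yr,
             photolysis_rate_s = kp,
             collision_rate_s = kc,
             p_dimerize_first = dimerize_before_destruction(kc, kp))
}))
write.csv(rows, "results/uv_competition.csv", row.names = FALSE)
message(sprintf(
  "P(dimerize before UV destruction): %.5f in a dark cloud, %.3f in the diffuse medium",
  rows$p_dimerize_first[1], rows$p_dimerize_first[2]))

uv <- uv_fixture_data()
for (i in seq_len(nrow(uv$peptides))) {
  note <- peptide_photostability_note(uv$peptides$species[i],
                                      uv$peptides$wavelength_nm[i],
                                      uv$peptides$quantum_efficiency[i])
  message(note$note)
}
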