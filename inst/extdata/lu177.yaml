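# Lu-177 physical constants and tissue defaults used by rltdosim.
# version: 1 (values configurable per call; see ?radionuclide)
name: Lu-177
# ICRP Publication 107 physical half-life, hours (6.647 d)
physical_half_life_h: 159.53
# mean energy of all electron emissions per decay (beta + conversion + Auger), keV
electron_energy_keV: 147.9
densities:
  # g/cm^3
  kidney: 1.06
  soft_tissue: 1.04
  soft_tissue_lesion: 1.03
  bone_lesion: 1.92
gland_masses_g:
  # ICRP reference masses, single gland
  parotid: 25.0
  submandibular: 12.5
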