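# Constants for the microbiota-to-host vitamin supply model.
#
# cell_model: the colonic bacterial biomass assumptions.  Available
# biomass = n_cells * cell_dry_mass * dead_fraction (intracellular
# vitamins are released on cell lysis).
#
# vitamins: per-vitamin canonical intracellular concentration (mmol/gDW),
# human dietary reference intake (mg/day, averaged adult male/female),
# fraction of gut genomes predicted to produce the vitamin, and molar mass
# (g/mol, ChEBI).  Molar masses are for the measured chemical form:
# dihydrofolic acid, nicotinic acid, pyridoxine 5'-phosphate and thiamine
# monophosphate; base forms otherwise.
avogadro: 6.02214e+23
cell_model:
  n_cells: 1.0e+14          # bacterial cells in the colonic space
  cell_dry_mass: 4.89e-13  # gDW per cell (E. coli)
  dead_fraction: 0.317     # fraction of cells lysed (fecal dead-cell ratio)
  cell_volume: 1.1e-15     # L per cell (1.1 um^3, E. coli)
  growth_rate: 0.26        # h^-1, anaerobic E. coli growth
vitamins:
  biotin:
    conc_mmol_per_gdw: 9.0e-7
    dri_mg_per_day: 0.03
    hgm_producer_ratio: 0.40
    molar_mass: 244.31
  cobalamin:
    conc_mmol_per_gdw: 8.5e-8
    dri_mg_per_day: 0.0024
    hgm_producer_ratio: 0.42
    molar_mass: 1329.35
  folate:
    conc_mmol_per_gdw: 5.0e-5
    dri_mg_per_day: 0.4
    hgm_producer_ratio: 0.43
    molar_mass: 443.41
  niacin:
    conc_mmol_per_gdw: 3.3e-3
    dri_mg_per_day: 15
    hgm_producer_ratio: 0.63
    molar_mass: 123.11
  pantothenate:
    conc_mmol_per_gdw: 2.3e-6
    dri_mg_per_day: 5
    hgm_producer_ratio: 0.51
    molar_mass: 219.23
  pyridoxine:
    conc_mmol_per_gdw: 5.8e-4
    dri_mg_per_day: 1.3
    hgm_producer_ratio: 0.50
    molar_mass: 249.16
  riboflavin:
    conc_mmol_per_gdw: 9.0e-6
    dri_mg_per_day: 1.2
    hgm_producer_ratio: 0.65
    molar_mass: 376.36
  thiamin:
    conc_mmol_per_gdw: 8.7e-6
    dri_mg_per_day: 1.15
    hgm_producer_ratio: 0.56
    molar_mass: 345.3
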