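# Default parameterization of the IL-2 cohort model.
# Keys are il2_params() field names; any key may be omitted (defaults apply)
# or overridden. Units: molecule counts, hours, liters, per-molar rates.
K_TCR_pMHC: 30000          # pMHC-TCR equilibrium constant
K_IL2R_pre: 2700           # IL-2Ralpha / IL-2Rbeta-gamma pre-assembly
sigma_TCR_inh: 0.01        # TCR inhibition of STAT5 phosphorylation
K_IL2_pSTAT5: 1.0e+4       # half-saturation of pSTAT5 vs bound complex
k_ag_consume: 0.19804205158855578   # ln(2)/3.5 per hour
tau_activation: 1          # engaged TCR to start activation / production
n_TCR_IL2Ra_max: 1000      # TCR-driven IL-2Ralpha plateau
k_receptor_deg: 0.13862943611198905 # ln(2)/5 per hour
n_pSTAT5_IL2Ra_max: 2.0e+6 # pSTAT5-driven IL-2Ralpha plateau
n_IL2Rb_0: 1000            # basal IL-2Rbeta
n_IL2Rb_max: 10000         # activated IL-2Rbeta
k_bind: 1.0e+11            # IL-2 association, per molar per hour
k_endo: 2.772588722239781  # ln(2)/0.25 per hour, full-complex endocytosis
k_IL2_basal: 27000         # 7.5 molecules/s = 7.5*3600 per hour
sigma_pSTAT5_inh: 3.0e+5   # pSTAT5 inhibition of IL-2 production
n_Boost_total: 1.0e+5      # Boost molecules per cell
k_TCR_Boost: 1.0e-3        # TCR-dependent Boost seeding
k_Boost_Boost: 0.3         # autocatalytic Boost activation, per hour
k_Boost_IL2: 810000        # 30 x k_IL2_basal
n_TCR_0: 30000             # TCR per cell
V: 2.0e-4                  # culture volume, liters
n_sim_cells: 50
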