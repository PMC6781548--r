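# Physical constants and species data used throughout the package.
# Plain key = value; comma-separated lists allowed; '#' starts a comment.

R_J_per_mol_K = 8.314462618
kcal_to_kJ    = 4.184
Kw_default    = 1e-14          # water ionization constant, mol^2 L^-2

# Molar masses, g/mol (IUPAC 2021 atomic weights: H 1.008, C 12.011,
# N 14.007, O 15.999). PEG is counted per ethylene-oxide repeat unit.
M_PEG  = 44.053                # C2H4O repeat unit
M_GA   = 76.051                # glycolic acid, C2H4O3
M_A    = 44.053                # acetaldehyde, C2H4O
M_F    = 30.026                # formaldehyde, CH2O
M_FA   = 46.025                # formic acid, CH2O2
M_SAXA = 315.417               # saxagliptin free base, C18H25N3O2
M_SCA  = 297.402               # cyclic amidine (SAXA - H2O), C18H23N3O
M_ESCA = 297.402               # epimer of SCA, C18H23N3O
M_SFA  = 343.427               # formyl amide (SAXA + FA - H2O), C19H25N3O3

# Out-of-phase PEG fraction vs PEG w/w ratio relative to the film polymer
# (melt-behaviour anchor points for PEG in a higher-melting polymer matrix).
phase_anchor_ratio    = 0.10, 0.20, 0.30
phase_anchor_fraction = 0.00, 0.05, 0.22

# Formic-acid pH closure: pH = ph_intercept + ph_slope * w_FA (kg/kg)
ph_slope     = -570.45
ph_intercept = 5.6703
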