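# United-atom force-field constants for tetrahedrally substituted
# organosilicon molecules (alkylsilane / alkoxysilane / silanol / siloxane).
# Human-editable: values are loaded at startup by defaultParameters().
#
# Units: charges in e, lengths in nm, angles in degrees,
#        k_angle in kJ mol^-1 rad^-2, torsion coefficients and epsilon in kJ/mol.

# Point-charge rules per substituent environment.  The silicon charge is
# never tabulated: it is computed per molecule by closing charge neutrality
# over its own substituents.
charges:
  CHx_Si_alkyl:  -0.24   # any alkyl CH_x bonded to an all-alkyl silicon
  CH3_Si_oxy:    -0.32   # CH3 bonded to Si in a silanol/alkoxysilane/siloxane
  CH2_Si_oxy:    -0.27   # CH2 bonded to Si in a silanol/alkoxysilane/siloxane
  CHx_OC:         0.25   # alkyl CH_x bonded to an alkoxy oxygen
  O_C:           -0.68   # alkoxy oxygen (Si-O-C)
  O_H:           -0.88   # silanol oxygen (Si-O-H)
  H_O:            0.44   # silanol hydrogen
  O_B:           -0.88   # bridging siloxane oxygen (Si-O-Si)

# Rigid bond (constraint) lengths
bonds:
  Si-C:    0.1875
  Si-O_H:  0.1653
  Si-O_C:  0.1656
  Si-O_B:  0.1640
  C-C:     0.1540
  C-O_C:   0.1410
  O_H-H:   0.0945

# Harmonic angle terms: [theta0 (deg), k (kJ mol^-1 rad^-2)]
angles:
  C-Si-C:     [112.0, 656.2]
  Si-C-C:     [111.5, 726.5]
  C-Si-O_H:   [107.4, 774.6]
  Si-O_H-H:   [115.5, 257.8]
  O_H-Si-O_H: [104.4, 872.6]
  Si-O_B-Si:  [149.5,  61.3]
  Si-O_C-C:   [124.8, 298.1]
  C-Si-O_C:   [111.0, 774.6]
  O_C-Si-O_C: [105.7, 795.0]
  C-C-C:      [114.0, 519.7]
  O_C-C-C:    [112.0, 418.2]
  # O_B-containing angle terms at silicon are not tabulated in the source
  # parameter set; transferred from the alkoxy (O_C) analogues.
  C-Si-O_B:   [111.0, 774.6]
  O_C-Si-O_B: [105.7, 795.0]
  O_B-Si-O_B: [105.7, 795.0]
  O_H-Si-O_B: [105.7, 795.0]

# Ryckaert-Bellemans torsion coefficients C0..C5 per dihedral class.
# Class names list the four atom classes along the dihedral; C stands for
# any CH_x united-atom site and H for the explicit hydroxyl hydrogen.
torsions:
  C-C-Si-C:      [ 1.224,  3.672,   0.0,    -4.895,   0.0,    0.0]
  C-Si-O_C-C:    [ 1.364,  4.093,   0.0,    -5.457,   0.0,    0.0]
  C-C-Si-O_C:    [ 0.692,  2.456,   0.437,  -3.416,   0.0,    0.0]
  C-C-O_C-Si:    [ 7.949,  7.892,   2.723, -18.563,   0.0,    0.0]
  C-O_C-Si-O_C:  [ 4.314,  4.803,   0.0,    -0.489,   0.0,    0.0]
  C-Si-O_H-H:    [ 0.870,  2.600,   0.0,    -3.470,   0.0,    0.0]
  C-C-Si-O_H:    [ 0.801,  2.760,   0.508,  -3.615,   0.0,    0.0]
  O_C-Si-O_H-H:  [10.189,  2.939,   0.0,     6.918,   0.0,    0.0]
  C-O_C-Si-O_H:  [13.021,  0.350, -39.801, -25.132,  39.605, 31.769]
  O_H-Si-O_H-H:  [10.071,  6.167,   2.322,   6.236,   0.0,    0.0]
  C-C-Si-O_B:    [ 0.692,  2.456,   0.437,  -3.416,   0.0,    0.0]
  C-O_C-Si-O_B:  [ 4.314,  4.803,   0.0,    -0.489,   0.0,    0.0]
  C-Si-O_B-Si:   [ 0.0503, 0.151,   0.0,    -0.201,   0.0,    0.0]
  O_C-Si-O_B-Si: [10.607,  0.420,   0.0,    10.187,   0.0,    0.0]
  O_B-Si-O_B-Si: [10.607,  0.420,   0.0,    10.187,   0.0,    0.0]
  O_H-Si-O_B-Si: [14.871,  8.170,   0.0,     6.700,   0.0,    0.0]

# Lennard-Jones parameters: [sigma (nm), epsilon (kJ/mol)].
# Si^k denotes silicon with k oxygenated substituent groups; the sigma series
# follows sigma(Si^k) = sigma(Si^0) * (1 - 0.05 k) and is stored verbatim.
# The hydroxyl hydrogen carries charge only (no dispersion site).
lj:
  Si0: [0.580, 0.108]
  Si1: [0.551, 0.108]
  Si2: [0.522, 0.108]
  Si3: [0.493, 0.108]
  Si4: [0.464, 0.108]
  O_C: [0.235, 1.344]
  O_B: [0.235, 1.344]
  O_H: [0.304, 1.750]
  H_O: [0.0,   0.0]

sigma_scale_per_oxygen: 0.05

# Alkane CH_x constants carried over from the united-atom alkane
# parametrization.  Defaults below are the TraPPE-UA values (epsilon = kB * T
# with T = 98, 46, 10, 0.5 K); replace with your preferred alkane set if it
# differs.
alkane_lj:
  CH3: [0.375, 0.814817]
  CH2: [0.395, 0.382465]
  CH:  [0.468, 0.083145]
  C:   [0.640, 0.004157]
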