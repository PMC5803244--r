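# SYNTHETIC reference stopping powers for SiO2 (I = 139.2 eV) and
# polyethylene (I = 57.4 eV): computed with an independent fine-quadrature
# evaluation of the Bethe formula (full maximum-energy-transfer kinematics,
# no shell/Barkas corrections), NOT an archival tabulation.  Used to guard
# against implementation errors; the water PSTAR file is the archival
# oracle.  Units: MeV, MeV cm^2/g.
material	energy	stopping_power
SiO2	5	63.10
SiO2	10	36.81
SiO2	20	21.21
SiO2	30	15.35
SiO2	50	10.24
SiO2	70	7.894
polyethylene	5	86.75
polyethylene	10	49.44
polyethylene	20	27.99
polyethylene	30	20.07
polyethylene	50	13.27
polyethylene	70	10.17
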