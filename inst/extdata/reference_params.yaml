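# literature reference values for the kinetic parameters
kinetics:
  Td: 29      # tumor doubling time [d]
  Tc: 23      # cell cycle duration [h]
  TG0: 96     # dormant-cell necrosis time [h]
  TN: 20      # necrosis product clearance [h]
  TA: 6       # apoptosis product clearance [h]
  RA: 0.001   # apoptosis rate, undifferentiated [1/h]
  RADiff: 0.003
  RNDiff: 0.001
  PG0toG1: 0.01
  NLIMP: 3
  Psym: 0.45
  Psleep: 0.28
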