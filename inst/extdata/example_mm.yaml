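# Example: 1D search + full refinement of hydrogen peroxide on the
# built-in molecular-mechanics backend. The dihedral quadruple is 0-based.
backend: mm
molecule:
  xyz: hooh_synthetic.xyz        # resolve relative to this file's directory
  dihedrals: [[0, 1, 2, 3]]
mm:
  amplitudes: [[0.05, 0.10, 0.002]]
  phases: [[0.0, 0.0, 0.0]]
search:
  budget: 15
  seed: 5
vibrations:
  temperature: 300
  delta: 0.0025
output: tbo_hooh
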