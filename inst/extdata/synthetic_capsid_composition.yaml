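# Synthetic AAV capsid composition fixture (NOT a real serotype sequence).
# Aromatic residue counts per VP monomer are plausible for a ~60/66/73 kDa
# VP3/VP2/VP1 set and give a per-60-mer molar e280 near the packaged
# empty-capsid default; they exist so the sequence-based route can be
# exercised without shipping a proprietary sequence.
composition:
  vp_counts: [5, 5, 50]
  aromatics:            # [Trp, Tyr, Cystine] per monomer
    VP1: [9, 55, 6]
    VP2: [8, 48, 6]
    VP3: [7, 44, 6]
  genome_mw: 1227296.9
  empty_capsid_mw: 3755952.4
  vp_vg: 1
fill_model:
  empty: {e260_mass: 0.98, e280_mass: 1.68, mw: 3755952.4}
  full:  {e260_mass: 5.65, e280_mass: 4.0,  mw: 4983249.3}
  interpolation: linear_in_fill
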